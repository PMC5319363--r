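test_that("tree simulation is reproducible and meets its stopping rules", {
  t1 <- simulate_bd_tree(0.15, 0.05, stop = "taxa", n = 40, seed = 42)
  t2 <- simulate_bd_tree(0.15, 0.05, stop = "taxa", n = 40, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 40L)
  t3 <- simulate_bd_tree(0.1, 0, stop = "age", age = 25, seed = 7)
  expect_equal(t3$crown_age, 25, tolerance = 1e-8)
  expect_error(simulate_bd_tree(function(t) 0.1, 0, stop = "taxa", n = 10),
               "constant rates")
})

test_that("Yule age-stopped simulations match the exponential-growth expectation", {
  ns <- vapply(1:200, function(s)
    ape::Ntip(simulate_bd_tree(0.1, 0, stop = "age", age = 20, seed = s)), 0L)
  target <- 2 * exp(0.1 * 20)
  # crown-survival conditioning biases the mean up slightly; allow 15%
  expect_lt(abs(mean(ns) - target) / target, 0.15)
})

test_that("an injected mass extinction depresses the surviving lineage count", {
  with_ev <- vapply(1:40, function(s)
    ape::Ntip(simulate_bd_tree(0.15, 0.02, stop = "age", age = 40,
                               event = list(age = 20, survival = 0.2),
                               seed = s)), 0L)
  without <- vapply(1:40, function(s)
    ape::Ntip(simulate_bd_tree(0.15, 0.02, stop = "age", age = 40,
                               seed = 1000 + s)), 0L)
  expect_lt(mean(with_ev), 0.55 * mean(without))
})

test_that("Mk niche simulation honours its limits and stationarity", {
  tr <- simulate_bd_tree(0.2, 0, stop = "taxa", n = 40, seed = 5)
  # vanishing rate: every tip keeps the root state
  Q0 <- mk_q(c("a", "b"), 1e-12)
  s0 <- simulate_niche(tr, Q0, root_state = "a", seed = 1)
  expect_true(all(s0$tip_state == "a"))
  # long branches, symmetric rates: tip frequencies near uniform
  long <- tr; long$edge.length <- long$edge.length * 1000
  long <- as_dated_tree(long)
  Q <- mk_q(c("a", "b"), 0.05)
  freqs <- rowMeans(vapply(1:30, function(s) {
    st <- simulate_niche(long, Q, root_state = "a", seed = s)$tip_state
    c(mean(st == "a"), mean(st == "b"))
  }, numeric(2L)))
  expect_lt(abs(freqs[1L] - 0.5), 0.06)
  # the returned true-history paint tiles the tree and matches the tips
  s1 <- simulate_niche(tr, Q, root_state = "a", seed = 2)
  expect_s3_class(s1$paint, "regime_paint")
  expect_equal(vapply(s1$paint$maps, sum, 0), tr$edge.length, tolerance = 1e-9)
})

test_that("OU trait simulation matches stationary and Brownian moments", {
  # near-star tree: tiny internal and long terminal branches, so tips are
  # effectively independent draws from the stationary distribution
  tr <- ape::stree(64, type = "balanced")
  tr$edge.length <- ifelse(tr$edge[, 2L] <= 64, 200, 0.01)
  tr <- as_dated_tree(tr)
  pt <- one_state_paint(tr, "a")
  y <- simulate_trait(pt, theta = c(a = 5), alpha = 0.1, sigma2 = 0.4, seed = 3)
  expect_lt(abs(mean(y) - 5), 3 * sqrt(0.4 / 0.2 / 64))
  expect_lt(abs(var(y) - 0.4 / 0.2), 3 * (0.4 / 0.2) * sqrt(2 / 63))
  # alpha = 0: Brownian, marginal tip variance = sigma2 * depth
  yb <- vapply(1:200, function(s)
    simulate_trait(pt, theta = c(a = 0), alpha = 0, sigma2 = 0.3,
                   x0 = 0, seed = s)[[1L]], 0)
  expect_lt(abs(var(yb) - 0.3 * tr$crown_age) / (0.3 * tr$crown_age), 0.35)
})

test_that("the default scenario reproduces the intended study conditions", {
  sc <- make_scenario(seed = 11, n_posterior = 5L)
  expect_equal(ape::Ntip(sc$tree), 120L)
  expect_equal(sc$tree$crown_age, 50, tolerance = 1e-6)
  expect_length(sc$clades$clade1, 101L)
  expect_length(sc$clades$clade2, 19L)
  # one species lacks body mass (n - 1 trait table)
  expect_length(sc$mass, 119L)
  expect_equal(sum(sc$extinct), 17L)
  expect_length(sc$posterior, 5L)
  expect_true(all(vapply(sc$posterior, function(p)
    ape::is.ultrametric(p, tol = 1e-6), TRUE)))
  # byte-identical regeneration under the same seed
  sc2 <- make_scenario(seed = 11, n_posterior = 5L)
  expect_identical(ape::write.tree(sc$tree), ape::write.tree(sc2$tree))
  expect_identical(sc$mass, sc2$mass)
  expect_identical(sc$niche, sc2$niche)
})

test_that("scenario bundles round-trip through their plain-text files", {
  dir <- tempfile()
  sc <- make_scenario(seed = 3, n_posterior = 3L, dir = dir)
  expect_true(file.exists(file.path(dir, "tree.nwk")))
  tr <- read_tree(file.path(dir, "tree.nwk"))
  expect_equal(ape::Ntip(tr), 120L)
  tab <- read.csv(file.path(dir, "traits.csv"))
  expect_equal(nrow(tab), 120L)
  expect_equal(sum(is.na(tab$ln_mass_g)), 1L)
  rich <- read_richness(file.path(dir, "richness.csv"))
  expect_true(all(rich$n_species >= 1L))
  unlink(dir, recursive = TRUE)
})
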