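test_that("a one-regime painted OU equals the single stationary OU model", {
  tr <- simulate_bd_tree(0.2, 0, stop = "taxa", n = 40, seed = 4)
  pt <- one_state_paint(tr, "a")
  y <- simulate_trait(pt, theta = c(a = 2), alpha = 0.06, sigma2 = 0.1, seed = 3)
  # fixed parameters: painted likelihood vs direct stationary-OU MVN density
  D <- patristic_matrix(tr)
  V <- 0.1 / (2 * 0.06) * exp(-0.06 * D)
  ll_direct <- radiate:::mvn_loglik_chol(y[tr$tip.label],
                                         rep(2, 40), chol(V))
  ll_paint <- multiregime_loglik(pt, y, theta = c(a = 2), alpha = 0.06,
                                 sigma2 = 0.1)
  expect_equal(ll_paint, ll_direct, tolerance = 1e-6)
  # fitted: one-regime OUM and single OU agree, and match fit_trait_model
  mf <- fit_multiregime(pt, y, models = c("ou", "oum"), seed = 1)
  expect_lt(abs(diff(mf$table$logL)), 1e-6)
  fo <- fit_trait_model(tr, y, "OU")
  expect_lt(abs(mf$fits$ou$logL - fo$logL), 1e-5)
})

test_that("all-zero alpha reduces the painted model to Brownian motion", {
  tr <- simulate_bd_tree(0.2, 0, stop = "taxa", n = 30, seed = 5)
  pt <- one_state_paint(tr, "a")
  y <- simulate_trait(pt, theta = c(a = 0), alpha = 0, sigma2 = 0.4, x0 = 1,
                      seed = 6)
  C <- ape::vcv(tr)
  ll_direct <- radiate:::mvn_loglik_chol(y[tr$tip.label], rep(1, 30),
                                         chol(0.4 * C))
  ll_paint <- multiregime_loglik(pt, y, alpha = 0, sigma2 = 0.4, x0 = 1)
  expect_equal(ll_paint, ll_direct, tolerance = 1e-8)
})

test_that("painted likelihoods are invariant to the segment subdivision", {
  tr <- simulate_bd_tree(0.2, 0, stop = "taxa", n = 20, seed = 7)
  pt <- one_state_paint(tr, "a")
  # split every edge into two same-state segments: identical process
  maps2 <- lapply(tr$edge.length, function(l) setNames(c(l / 3, 2 * l / 3),
                                                       c("a", "a")))
  pt2 <- regime_paint(tr, maps2, source = "manual")
  y <- simulate_trait(pt, theta = c(a = 1), alpha = 0.08, sigma2 = 0.2, seed = 8)
  expect_equal(multiregime_loglik(pt, y, theta = c(a = 1), alpha = 0.08,
                                  sigma2 = 0.2),
               multiregime_loglik(pt2, y, theta = c(a = 1), alpha = 0.08,
                                  sigma2 = 0.2),
               tolerance = 1e-9)
})

test_that("two-regime optima are recovered and ordered correctly", {
  tr <- simulate_bd_tree(0.15, 0.05, stop = "taxa", n = 80, seed = 4)
  nodes <- pick_disjoint_clades(tr, k = 2L, min_tips = 10L, max_tips = 30L)
  pt <- clade_paint(tr, nodes, "a", "b")
  ok_order <- 0L
  for (s in 1:20) {
    y <- simulate_trait(pt, theta = c(a = 4, b = 8), alpha = 0.3, sigma2 = 0.3,
                        seed = 500 + s)
    f <- fit_multiregime(pt, y, models = "oum", n_starts = 1L, seed = 1)$fits$oum
    ok_order <- ok_order + (f$theta[["b"]] > f$theta[["a"]])
  }
  expect_gte(ok_order, 19L)
})

test_that("regimes with fewer than 2 tips are rejected for state-dependent models", {
  tr <- simulate_bd_tree(0.2, 0, stop = "taxa", n = 20, seed = 9)
  maps <- lapply(seq_len(nrow(tr$edge)), function(e)
    setNames(tr$edge.length[e], "a"))
  # paint exactly one terminal branch as "b"
  term <- which(tr$edge[, 2L] == 1L)
  maps[[term]] <- setNames(tr$edge.length[term], "b")
  pt <- regime_paint(tr, maps, source = "manual")
  y <- setNames(rnorm(20), tr$tip.label)
  expect_error(fit_multiregime(pt, y, models = "oum"), "fewer than 2 tips")
  # but the single-regime models still run
  expect_s3_class(fit_multiregime(pt, y, models = c("bm", "ou")),
                  "multiregime_fit")
})

test_that("the posterior tally concentrates when every sample is identical", {
  tr <- simulate_bd_tree(0.2, 0, stop = "taxa", n = 40, seed = 10)
  for (s in 30:60) {   # first niche history with both states represented
    sim <- simulate_niche(tr, mk_q(c("a", "b"), 0.008), root_state = "a", seed = s)
    if (min(table(factor(sim$tip_state, levels = c("a", "b")))) >= 4L) break
  }
  expect_gte(min(table(sim$tip_state)), 4L)
  y <- simulate_trait(sim$paint, theta = c(a = 2, b = 6), alpha = 0.3,
                      sigma2 = 0.3, seed = 3)
  tally <- multiregime_over_posterior(list(tr, tr), y, sim$tip_state,
                                      n_samples = 4L,
                                      models = c("bm", "oum"), seed = 2)
  expect_equal(sum(tally$wins), 4)
  expect_equal(unname(tally$wins[["oum"]]), 4)
})
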