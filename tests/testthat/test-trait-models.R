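sim_bm_trait <- function(tree, sigma2, seed, mean = 0) {
  simulate_trait(one_state_paint(tree), theta = c(a = mean), alpha = 0,
                 sigma2 = sigma2, x0 = mean, seed = seed)
}

test_that("nested trait models coincide at their boundary parameters", {
  tr <- simulate_bd_tree(0.15, 0.05, stop = "taxa", n = 50, seed = 9)
  y <- sim_bm_trait(tr, 0.5, seed = 1)
  bm <- fit_trait_model(tr, y, "BM")
  expect_equal(fit_trait_model(tr, y, "lambda", fix = list(lambda = 1))$logL,
               bm$logL, tolerance = 1e-6)
  expect_equal(fit_trait_model(tr, y, "ACDC", fix = list(g = 0))$logL,
               bm$logL, tolerance = 1e-6)
  ou0 <- fit_trait_model(tr, y, "OU", root = "fixed", fix = list(alpha = 1e-8))
  expect_lt(abs(ou0$logL - bm$logL), 1e-4)
})

test_that("lambda = 0 reduces to an iid normal fit", {
  tr <- simulate_bd_tree(0.15, 0.05, stop = "taxa", n = 40, seed = 2)
  y <- sim_bm_trait(tr, 0.3, seed = 5)
  l0 <- fit_trait_model(tr, y, "lambda", fix = list(lambda = 0))
  # iid ML: mean and variance with n divisor
  mu <- mean(y); s2 <- mean((y - mu)^2) / tr$crown_age  # per-My rate on T-depth tips
  ll_iid <- sum(dnorm(y, mu, sqrt(s2 * tr$crown_age), log = TRUE))
  expect_equal(l0$logL, ll_iid, tolerance = 1e-8)
})

test_that("likelihoods are invariant to tip order", {
  tr <- simulate_bd_tree(0.15, 0.05, stop = "taxa", n = 30, seed = 3)
  y <- sim_bm_trait(tr, 0.5, seed = 2)
  f1 <- fit_trait_model(tr, y, "OU")
  f2 <- fit_trait_model(tr, y[sample(names(y))], "OU")
  expect_equal(f1$logL, f2$logL, tolerance = 1e-8)
})

test_that("the Brownian rate is recovered across replicates", {
  tr <- simulate_bd_tree(0.15, 0.05, stop = "taxa", n = 80, seed = 4)
  s2 <- vapply(1:50, function(s)
    coef(fit_trait_model(tr, sim_bm_trait(tr, 0.5, seed = 100 + s), "BM"))[["sigma2"]],
    0)
  expect_lt(abs(median(s2) - 0.5) / 0.5, 0.1)
})

test_that("an early-burst generating process yields a negative ACDC exponent", {
  tr <- simulate_bd_tree(0.2, 0.02, stop = "taxa", n = 80, seed = 6)
  Tmax <- tr$crown_age
  g_true <- -3 / Tmax
  # simulate ACDC by time-warping the tree, then Brownian simulation on it
  warp <- tr
  h <- Tmax - tr$node_age
  hh <- (exp(g_true * h) - 1) / g_true
  warp$edge.length <- hh[warp$edge[, 2L]] - hh[warp$edge[, 1L]]
  y <- setNames(ape::rTraitCont(warp, model = "BM", sigma = sqrt(0.5)),
                tr$tip.label)
  fit <- fit_trait_model(tr, y, "ACDC")
  expect_lt(coef(fit)[["g"]], 0)
  rtt <- acdc_rate_through_time(fit)
  expect_true(all(diff(rtt$sigma2[order(rtt$age)]) >= -1e-12) ||
              all(diff(rtt$sigma2[order(rtt$age)]) <= 1e-12))
})

test_that("trait adequacy statistics behave as contrast theory predicts", {
  tr <- simulate_bd_tree(0.15, 0.05, stop = "taxa", n = 60, seed = 8)
  y <- sim_bm_trait(tr, 0.4, seed = 9)
  fit <- fit_trait_model(tr, y, "BM")
  # mean squared standardized contrast on the unit-rescaled tree is ~1 at the ML
  resc <- rescale_tree(fit)
  pc <- ape::pic(y[tr$tip.label], resc)
  expect_equal(mean(pc^2), 1, tolerance = 0.05)
  ad <- trait_adequacy(fit, n_sims = 200L, seed = 1)
  expect_true(all(ad$quantiles >= 0 & ad$quantiles <= 1))
  # rate-heterogeneous data violate a BM fit: inflate one clade's rate 25x
  nodes <- pick_disjoint_clades(tr, k = 1L, min_tips = 15L, max_tips = 40L)
  pt <- clade_paint(tr, nodes, "a", "b")
  y_het <- simulate_trait(pt, theta = c(a = 0, b = 0), alpha = 0,
                          sigma2 = c(a = 0.04, b = 1), x0 = 0, seed = 11)
  fit_het <- fit_trait_model(tr, y_het, "BM")
  ad_het <- trait_adequacy(fit_het, n_sims = 300L, seed = 2)
  expect_false(ad_het$adequate)
})

test_that("PGLS with lambda = 0 equals ordinary least squares", {
  tr <- simulate_bd_tree(0.15, 0.03, stop = "taxa", n = 50, seed = 6)
  Q <- mk_q(c("nf", "no", "df"), 0.02)
  sim <- simulate_niche(tr, Q, root_state = "nf", seed = 5)
  y <- simulate_trait(sim$paint, theta = c(nf = 4, no = 5, df = 8),
                      alpha = 0.1, sigma2 = 0.2, seed = 7)
  p0 <- pgls_fit(tr, y, sim$tip_state, corr = "lambda", fix_par = 0)
  dat <- data.frame(yy = y[tr$tip.label],
                    nn = factor(sim$tip_state[tr$tip.label]))
  ols <- lm(yy ~ nn, data = dat, contrasts = list(nn = "contr.sum"))
  expect_equal(unname(coef(p0)), unname(coef(ols)), tolerance = 1e-6)
})

test_that("PGLS recovers planted niche offsets with the right sign", {
  tr <- simulate_bd_tree(0.15, 0.03, stop = "taxa", n = 80, seed = 16)
  Q <- mk_q(c("low1", "low2", "high"), 0.01)
  hits <- 0L
  n_rep <- 10L
  done <- 0L
  s <- 0L
  while (done < n_rep && s < 50L) {
    s <- s + 1L
    sim <- simulate_niche(tr, Q, root_state = "high", seed = 300 + s)
    if (min(table(factor(sim$tip_state, levels = rownames(Q)))) < 5L) next
    done <- done + 1L
    y <- simulate_trait(sim$paint, theta = c(low1 = 4, low2 = 4.5, high = 8),
                        alpha = 0.15, sigma2 = 0.15, seed = 400 + s)
    pf <- pgls_average(tr, y, sim$tip_state)
    eff <- pf$niche_effects
    hits <- hits + (eff[["low1"]] < 0 && eff[["low2"]] < 0 && eff[["high"]] > 0)
  }
  expect_gte(hits / done, 0.9)
})

test_that("PGLS rejects designs with an empty niche level", {
  tr <- simulate_bd_tree(0.15, 0.03, stop = "taxa", n = 30, seed = 2)
  niche <- setNames(rep("only", 30), tr$tip.label)
  y <- sim_bm_trait(tr, 0.3, seed = 1)
  expect_error(pgls_fit(tr, y, niche), "2 observed levels")
})
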