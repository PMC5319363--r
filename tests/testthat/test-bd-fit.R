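test_that("the pure-birth MLE matches the closed-form Yule estimator", {
  tr <- simulate_bd_tree(0.15, 0, stop = "taxa", n = 60, seed = 3)
  fit <- fit_bd(tr, bd_model("constant", "zero"), seed = 1)
  lam_closed <- (ape::Ntip(tr) - 2) / sum(tr$edge.length)
  expect_equal(coef(fit)[["lambda0"]], lam_closed, tolerance = 1e-6)
  expect_equal(fit$k, 1L)
  expect_s3_class(logLik(fit), "logLik")
})

test_that("the constant birth-death MLE agrees with ape::birthdeath", {
  tr <- simulate_bd_tree(0.15, 0.05, stop = "taxa", n = 80, seed = 7)
  fit <- fit_bd(tr, bd_model("constant", "constant"), seed = 1)
  bd <- ape::birthdeath(tr)      # reports (mu/lambda, lambda - mu)
  expect_equal(coef(fit)[["lambda0"]] - coef(fit)[["mu0"]],
               unname(bd$para["b-d"]), tolerance = 0.02)
  expect_equal(coef(fit)[["mu0"]] / coef(fit)[["lambda0"]],
               unname(bd$para["d/b"]), tolerance = 0.05)
})

test_that("Akaike weights follow the exp(-delta/2) normalization", {
  expect_equal(akaike_weights(c(0, 2)), c(exp(0), exp(-1)) / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(round(akaike_weights(c(0, 2)), 3), c(0.731, 0.269))
  w <- akaike_weights(c(3.2, 0.4, 9.9, 1.1))
  expect_equal(sum(w), 1)
  perm <- c(3, 1, 4, 2)
  expect_equal(akaike_weights(c(3.2, 0.4, 9.9, 1.1)[perm]), w[perm])
})

test_that("model comparison and averaging behave across a candidate set", {
  tr <- simulate_bd_tree(0.15, 0.05, stop = "taxa", n = 60, seed = 11)
  fits <- list(fit_bd(tr, bd_model("constant", "zero"), seed = 1),
               fit_bd(tr, bd_model("constant", "constant"), seed = 2),
               fit_bd(tr, bd_model("exponential", "zero"), seed = 3))
  set <- compare_and_average(fits, eval_age = 0)
  expect_equal(sum(set$table$weight), 1, tolerance = 1e-10)
  expect_equal(min(set$table$dAICc), 0)
  # averaged rate is the weighted sum of the per-model present-day rates
  w <- akaike_weights(vapply(fits, `[[`, 0, "aicc"))
  lam0 <- vapply(fits, function(f) bd_lambda_fun(f$model, f$par)(0), 0)
  expect_equal(set$lambda, sum(w * lam0), tolerance = 1e-10)
  # single model: weight 1 and averaged rate equals its estimate
  one <- compare_and_average(fits[1])
  expect_equal(one$table$weight, 1)
  expect_equal(one$lambda, lam0[1L], tolerance = 1e-10)
  expect_error(compare_and_average(list(fits[[1]],
    fit_bd(simulate_bd_tree(0.2, 0, stop = "taxa", n = 20, seed = 1),
           bd_model("constant", "zero"), seed = 1))), "same tree")
})

test_that("rate-through-time curves have the right shape", {
  tr <- simulate_bd_tree(0.15, 0.05, stop = "taxa", n = 60, seed = 11)
  fc <- fit_bd(tr, bd_model("constant", "constant"), seed = 1)
  rtt <- rate_through_time(fc, ages = seq(0, tr$crown_age, length.out = 20))
  expect_equal(var(rtt$net), 0, tolerance = 1e-20)   # flat for constant rates
  expect_equal(rtt$net, rtt$lambda - rtt$mu)
  # exponential speciation with negative age-slope: increasing toward present
  fe <- fit_bd(tr, bd_model("exponential", "zero"), seed = 1)
  if (coef(fe)[["lambda_slope"]] < 0) {
    r <- rate_through_time(fe)$net
    expect_true(all(diff(rev(r)) <= 1e-12))  # monotone along increasing age
  }
  expect_error(rate_through_time(fc, ages = c(-1, 2)), "age grid")
})

test_that("the covariate-dependent fit recovers the direction of a planted link", {
  # speciation tied to a rising-with-age covariate (beta > 0 truth)
  curve <- covariate_curve(c(0, 60), c(0, 3), allow_extrapolation = TRUE)
  hits <- 0L
  n_rep <- 8L
  for (s in 1:n_rep) {
    lam <- function(t) 0.08 * exp(0.5 * curve$fun(t))
    tr <- simulate_bd_tree(lam, 0.02, stop = "age", age = 30, seed = 100 + s)
    if (ape::Ntip(tr) < 15) next
    fit <- covariate_bd(tr, curve, mu = "constant", starts = 3L, seed = s)
    hits <- hits + (coef(fit)[["beta"]] > 0)
  }
  expect_gte(hits / n_rep, 0.75)
})

test_that("simulate() from a fitted model is reproducible and respects the crown age", {
  tr <- simulate_bd_tree(0.2, 0.05, stop = "taxa", n = 40, seed = 9)
  fit <- fit_bd(tr, bd_model("constant", "constant"), seed = 1)
  s1 <- simulate(fit, nsim = 2, seed = 5)
  s2 <- simulate(fit, nsim = 2, seed = 5)
  expect_equal(ape::write.tree(s1[[1]]), ape::write.tree(s2[[1]]))
  expect_equal(s1[[2]]$crown_age, tr$crown_age, tolerance = 1e-8)
})
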