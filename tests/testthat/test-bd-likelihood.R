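tr4 <- as_dated_tree(ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);"))

test_that("constant-rate likelihood reduces to the closed-form Yule likelihood", {
  for (lam in c(0.05, 0.15, 0.4)) {
    ll <- bd_loglik(tr4, bd_model("constant", "zero"), c(lambda0 = lam))
    expect_equal(ll, oracle_yule_loglik(tr4, lam), tolerance = 1e-10)
  }
  tr <- simulate_bd_tree(0.2, 0, stop = "taxa", n = 25, seed = 3)
  ll <- bd_loglik(tr, bd_model("constant", "zero"), c(lambda0 = 0.2))
  expect_equal(ll, oracle_yule_loglik(tr, 0.2), tolerance = 1e-8)
})

test_that("constant-rate likelihood matches the textbook p0/p1 closed form", {
  bt <- branching_times(tr4)
  for (rho in c(1, 0.6)) {
    ll <- bd_loglik(tr4, bd_model("constant", "constant", rho = rho),
                    c(lambda0 = 0.15, mu0 = 0.05))
    expect_equal(ll, oracle_crbd_loglik(bt, 0.15, 0.05, rho), tolerance = 1e-8)
  }
})

test_that("time-varying likelihood matches a fine-grid RK4 oracle", {
  bt <- branching_times(tr4)
  ll <- bd_loglik(tr4, bd_model("exponential", "linear"),
                  c(lambda0 = 0.15, lambda_slope = 0.05, mu0 = 0.02,
                    mu_slope = 0.005))
  llo <- oracle_bd_loglik(bt, function(t) 0.15 * exp(0.05 * t),
                          function(t) 0.02 + 0.005 * t, rho = 1)
  expect_equal(ll, llo, tolerance = 1e-6)
  # 10-tip tree, with incomplete sampling
  tr <- simulate_bd_tree(0.12, 0.03, stop = "taxa", n = 10, seed = 11)
  bt10 <- branching_times(tr)
  ll2 <- bd_loglik(tr, bd_model("exponential", "constant", rho = 0.7),
                   c(lambda0 = 0.2, lambda_slope = -0.04, mu0 = 0.03))
  llo2 <- oracle_bd_loglik(bt10, function(t) 0.2 * exp(-0.04 * t),
                           function(t) rep(0.03, length(t)), rho = 0.7)
  expect_equal(ll2, llo2, tolerance = 1e-6)
})

test_that("nested models give identical likelihoods at nested parameter values", {
  ll_const <- bd_loglik(tr4, bd_model("constant", "constant"),
                        c(lambda0 = 0.15, mu0 = 0.05))
  ll_lin <- bd_loglik(tr4, bd_model("linear", "constant"),
                      c(lambda0 = 0.15, lambda_slope = 0, mu0 = 0.05))
  ll_exp <- bd_loglik(tr4, bd_model("exponential", "constant"),
                      c(lambda0 = 0.15, lambda_slope = 0, mu0 = 0.05))
  expect_equal(ll_lin, ll_const, tolerance = 1e-8)
  expect_equal(ll_exp, ll_const, tolerance = 1e-8)
  # covariate model with beta = 0 reduces exactly to the constant model
  curve <- covariate_curve(c(0, 2, 4), c(10, 14, 12))
  ll_cov <- bd_loglik(tr4, bd_model("covariate", "constant", covariate = curve),
                      c(lambda0 = 0.15, beta = 0, mu0 = 0.05))
  expect_equal(ll_cov, ll_const, tolerance = 1e-8)
})

test_that("invalid rates and event specifications are rejected", {
  # strongly negative linear speciation over the tree span: -Inf / penalized
  ll <- bd_loglik(tr4, bd_model("linear", "zero"),
                  c(lambda0 = 0.1, lambda_slope = -0.2))
  ll_ok <- bd_loglik(tr4, bd_model("linear", "zero"),
                     c(lambda0 = 0.1, lambda_slope = -0.01))
  expect_true(ll < ll_ok)  # penalty pushes the likelihood down
  expect_error(bd_loglik(tr4, bd_model("constant", "zero"), c(lambda0 = 0.1),
                         event = list(age = 5, survival = 0.5)),
               "event age")
  expect_error(bd_model("constant", "zero", rho = 0), "rho")
  expect_error(bd_model("covariate", "zero"), "covariate")
})

test_that("mass-extinction events agree between closed form and ODE route", {
  ev <- list(age = 1.5, survival = 0.4)
  ll_c <- bd_loglik(tr4, bd_model("constant", "constant"),
                    c(lambda0 = 0.15, mu0 = 0.05), event = ev)
  ll_o <- bd_loglik(tr4, bd_model("linear", "constant"),
                    c(lambda0 = 0.15, lambda_slope = 0, mu0 = 0.05), event = ev)
  expect_equal(ll_c, ll_o, tolerance = 1e-7)
  # survival = 1 means no event at all
  ll_1 <- bd_loglik(tr4, bd_model("constant", "constant"),
                    c(lambda0 = 0.15, mu0 = 0.05),
                    event = list(age = 1.5, survival = 1))
  ll_none <- bd_loglik(tr4, bd_model("constant", "constant"),
                       c(lambda0 = 0.15, mu0 = 0.05))
  expect_equal(ll_1, ll_none, tolerance = 1e-9)
})

test_that("covariate curves interpolate, flag extrapolation, and derive from LTTs", {
  cv <- covariate_curve(c(0, 10, 20), c(1, 2, 5))
  expect_equal(cv$fun(5), 1.5)
  expect_error(cv$fun(25), "span")
  cv2 <- covariate_curve(c(0, 10, 20), c(1, 2, 5), allow_extrapolation = TRUE)
  expect_equal(cv2$fun(25), 5)
  # LTT-derived diversity curve: 3-tip example
  tr <- as_dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  dc <- ltt_to_diversity_curve(tr)
  expect_equal(dc$fun(0), 3)
  expect_equal(dc$fun(0.5), 3)
  expect_equal(dc$fun(1.5), 2)
  expect_equal(dc$fun(2), 2)
})
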