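# Maximum-likelihood fitting of birth--death models, AICc model comparison
# and averaging, rate-through-time curves, and the fixed-time
# mass-extinction test.

# parameter transforms for unconstrained optimization
bd_to_opt <- function(par) {
  out <- par
  for (nm in names(par)) {
    out[nm] <- switch(nm,
      lambda0 = , mu0 = log(par[[nm]]),
      survival = qlogis(par[[nm]]),
      par[[nm]])
  }
  out
}

bd_from_opt <- function(x) {
  out <- x
  for (nm in names(x)) {
    out[nm] <- switch(nm,
      lambda0 = , mu0 = exp(x[[nm]]),
      survival = plogis(x[[nm]]),
      x[[nm]])
  }
  out
}

bd_start_values <- function(tree, model, event_age = NULL) {
  n <- ape::Ntip(tree)
  lam0 <- max((n - 2) / sum(tree$edge.length), 1e-4)  # Yule heuristic
  par <- c(lambda0 = lam0)
  if (model$lambda %in% c("linear", "exponential")) par["lambda_slope"] <- 0
  if (model$lambda == "covariate") par["beta"] <- 0
  if (model$mu != "zero") par["mu0"] <- lam0 / 5
  if (model$mu %in% c("linear", "exponential")) par["mu_slope"] <- 0
  if (!is.null(event_age)) par["survival"] <- 0.9
  par
}

bd_jitter_sd <- function(par_names, model, t_max) {
  vapply(par_names, function(nm) switch(nm,
    lambda0 = , mu0 = 0.7,           # on log scale
    lambda_slope = , mu_slope = 1.5 / t_max,
    survival = 1.0,                  # on logit scale
    beta = {
      V <- model$covariate$fun(seq(0, t_max, length.out = 33))
      1 / max(diff(range(V)), 1e-8)
    }), numeric(1L))
}

#' Fit a birth--death model to a dated tree by maximum likelihood
#'
#' Multi-start bounded optimization of [bd_loglik()] over the model's free
#' parameters (log-parameterized rates), reproducible given `seed`.
#'
#' @param tree a `dated_tree`.
#' @param model a [bd_model()].
#' @param starts number of random multi-starts (default 10).
#' @param seed optional integer seed controlling the random starts.
#' @param event_age optional age (My) of an instantaneous mass-extinction
#'   event whose per-lineage survival probability is estimated as an extra
#'   free parameter (see [mass_extinction_test()]).
#' @param label optional model label used in printed tables.
#' @return an object of class `bd_fit` with components `model`, `par`
#'   (natural scale), `logL`, `k`, `n_obs`, `aicc`, `crown_age`,
#'   `convergence`.
#' @examples
#' tr <- simulate_bd_tree(lambda = 0.15, mu = 0.05, stop = "taxa", n = 40, seed = 1)
#' fit_bd(tr, bd_model("constant", "constant"), seed = 1)
#' @export
fit_bd <- function(tree, model, starts = 10L, seed = NULL, event_age = NULL,
                   label = NULL) {
  tree <- as_dated_tree(tree)
  bt <- branching_times(tree)
  event <- NULL
  start <- bd_start_values(tree, model, event_age)
  if (length(start) < 1L) stop("model has no free parameters")
  nm <- names(start)
  obj <- function(x) {
    par <- bd_from_opt(setNames(x, nm))
    ev <- if (!is.null(event_age)) list(age = event_age, survival = par[["survival"]])
    ll <- bd_loglik_bt(bt, model, par, event = ev)
    if (!is.finite(ll)) 1e10 else -ll
  }
  x0 <- bd_to_opt(start)
  sds <- bd_jitter_sd(nm, model, bt[1L])
  start_mat <- with_seed(seed, {
    jit <- matrix(rnorm((starts - 1L) * length(nm), 0, rep(sds, each = starts - 1L)),
                  nrow = max(starts - 1L, 0L))
    rbind(x0, sweep(jit, 2L, x0, `+`))
  })
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(start_mat))) {
    res <- if (length(nm) == 1L) {
      o <- optimize(obj, interval = start_mat[i, 1L] + c(-9, 9), tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      tryCatch(optim(start_mat[i, ], obj, method = "Nelder-Mead",
                     control = list(maxit = 2000L, reltol = 1e-12)),
               error = function(e) NULL)
    }
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("fit_bd: no start converged to a finite likelihood for model '",
         model$lambda, "/", model$mu, "'")
  # polish from the incumbent
  if (length(nm) > 1L) {
    res <- tryCatch(optim(best$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000L, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(res) && res$value <= best$value) best <- res
  }
  par <- bd_from_opt(setNames(best$par, nm))
  if (!is.null(event_age)) event <- list(age = event_age, survival = par[["survival"]])
  logL <- bd_loglik_bt(bt, model, par, event = event)
  k <- length(par)
  n_obs <- ape::Ntip(tree)
  structure(list(model = model, par = par, logL = logL, k = k, n_obs = n_obs,
                 aicc = aicc(logL, k, n_obs), crown_age = bt[1L],
                 event_age = event_age,
                 label = label %||% bd_model_label(model, event_age),
                 convergence = list(code = best$convergence, starts_ok = n_ok)),
            class = "bd_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bd_model_label <- function(model, event_age = NULL) {
  paste0("lambda-", model$lambda, "/mu-", model$mu,
         if (!is.null(event_age)) paste0("+event@", signif(event_age, 4)))
}

#' @export
print.bd_fit <- function(x, ...) {
  cat("Birth-death fit [", x$label, "]\n", sep = "")
  cat("  logL = ", format(x$logL, digits = 7), ",  k = ", x$k,
      ",  AICc = ", format(x$aicc, digits = 7),
      "  (n = ", x$n_obs, " tips)\n", sep = "")
  cat("  parameters:\n")
  print(signif(x$par, 5))
  invisible(x)
}

#' @export
logLik.bd_fit <- function(object, ...) {
  structure(object$logL, df = object$k, nobs = object$n_obs, class = "logLik")
}

#' @export
coef.bd_fit <- function(object, ...) object$par

#' @export
summary.bd_fit <- function(object, ...) {
  rates <- bd_rates_at(object, c(0, object$crown_age))
  cat("Rates (lineages/My):  present  lambda = ",
      format(rates$lambda[1L], digits = 4), ", mu = ",
      format(rates$mu[1L], digits = 4), ";  crown  lambda = ",
      format(rates$lambda[2L], digits = 4), ", mu = ",
      format(rates$mu[2L], digits = 4), "\n", sep = "")
  print(object)
  invisible(object)
}

# evaluate fitted rate functions at given ages
bd_rates_at <- function(fit, ages) {
  lam <- bd_lambda_fun(fit$model, fit$par)(ages)
  mu <- bd_mu_fun(fit$model, fit$par)(ages)
  data.frame(age = ages, lambda = lam, mu = mu, net = lam - mu)
}

#' Simulate trees from a fitted birth--death model
#'
#' Draws reconstructed trees under the fitted rate functions, conditioned on
#' the fitted tree's crown age and survival of both crown lineages.
#'
#' @param object a `bd_fit`.
#' @param nsim number of trees.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `dated_tree` objects.
#' @export
simulate.bd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- child_seeds(seed %||% sample.int(2^30, 1L), nsim)
  lapply(seeds, function(s)
    simulate_bd_tree(lambda = bd_lambda_fun(object$model, object$par),
                     mu = bd_mu_fun(object$model, object$par),
                     stop = "age", age = object$crown_age, seed = s))
}

#' Compare fitted birth--death models and average their rates
#'
#' Computes delta-AICc and Akaike weights across fits on the same tree and
#' reports model-averaged speciation and extinction rates at a reference age
#' (weights `exp(-delta/2)`, normalized; averaged rate is the weighted sum of
#' each model's rate function at that age). The averaged speciation slope
#' (the "time-varying function") is the weighted sum of slope parameters,
#' counting 0 for constant models.
#'
#' @param fits list of `bd_fit` objects on the same tree.
#' @param eval_age age (My) at which averaged rates are reported (default 0,
#'   the present).
#' @return an object of class `bd_model_set` with the weight table and
#'   averaged rates.
#' @export
compare_and_average <- function(fits, eval_age = 0) {
  if (inherits(fits, "bd_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "bd_fit")))
  n_obs <- vapply(fits, `[[`, 0, "n_obs")
  if (length(unique(n_obs)) != 1L)
    stop("all fits must be on the same tree (differing n_obs)")
  ai <- vapply(fits, `[[`, 0, "aicc")
  w <- akaike_weights(ai)
  rates <- lapply(fits, bd_rates_at, ages = eval_age)
  slope <- vapply(fits, function(f) {
    if ("lambda_slope" %in% names(f$par)) f$par[["lambda_slope"]] else 0
  }, 0)
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "label"),
    k = vapply(fits, `[[`, 0, "k"),
    logL = vapply(fits, `[[`, 0, "logL"),
    AICc = ai, dAICc = ai - min(ai), weight = w)
  structure(list(
    table = tab[order(tab$dAICc), ], fits = fits, eval_age = eval_age,
    lambda = sum(w * vapply(rates, function(r) r$lambda, 0)),
    mu = sum(w * vapply(rates, function(r) r$mu, 0)),
    lambda_slope = sum(w * slope),
    crown_age = fits[[1L]]$crown_age, n_obs = n_obs[1L]),
    class = "bd_model_set")
}

#' @export
print.bd_model_set <- function(x, digits = 4, ...) {
  cat("Birth-death model set (n = ", x$n_obs, " tips)\n", sep = "")
  tab <- x$table
  tab$logL <- round(tab$logL, 3); tab$AICc <- round(tab$AICc, 3)
  tab$dAICc <- round(tab$dAICc, 3); tab$weight <- round(tab$weight, 3)
  print(tab, row.names = FALSE)
  cat("Model-averaged rates at age ", format(x$eval_age, digits = 4),
      " My:  lambda = ", format(x$lambda, digits = digits),
      ",  mu = ", format(x$mu, digits = digits),
      ",  lambda slope = ", format(x$lambda_slope, digits = digits), "\n",
      sep = "")
  invisible(x)
}

#' Diversification rate through time
#'
#' Speciation, extinction and net diversification (`lambda - mu`) on an age
#' grid, from a single fit or model-averaged over a [compare_and_average()]
#' set.
#'
#' @param x a `bd_fit` or `bd_model_set`.
#' @param ages age grid in My; must lie within `[0, crown_age]`. Defaults to
#'   100 points from the crown to the present.
#' @return data frame with columns `age`, `lambda`, `mu`, `net`.
#' @export
rate_through_time <- function(x, ages = NULL) {
  crown <- x$crown_age
  if (is.null(ages)) ages <- seq(crown, 0, length.out = 100L)
  if (any(ages < 0) || any(ages > crown + 1e-9))
    stop("age grid must lie within [0, crown age]")
  if (inherits(x, "bd_fit")) return(bd_rates_at(x, ages))
  if (!inherits(x, "bd_model_set")) stop("x must be a bd_fit or bd_model_set")
  w <- x$table$weight[order(match(x$table$model,
                                  vapply(x$fits, `[[`, "", "label")))]
  w <- akaike_weights(vapply(x$fits, `[[`, 0, "aicc"))
  parts <- lapply(x$fits, bd_rates_at, ages = ages)
  out <- data.frame(age = ages,
                    lambda = Reduce(`+`, Map(function(p, wi) wi * p$lambda, parts, w)),
                    mu = Reduce(`+`, Map(function(p, wi) wi * p$mu, parts, w)))
  out$net <- out$lambda - out$mu
  out
}

#' Plot net diversification through time
#' @param x a `bd_fit` or `bd_model_set`.
#' @param ... passed to [plot()].
#' @export
plot_rate_through_time <- function(x, ...) {
  rtt <- rate_through_time(x)
  plot(rtt$age, rtt$net, type = "l", xlim = rev(range(rtt$age)),
       xlab = "age (My before present)",
       ylab = expression(lambda - mu ~ "(lineages/My)"), ...)
  lines(rtt$age, rtt$lambda, lty = 2)
  lines(rtt$age, rtt$mu, lty = 3)
  legend("topleft", c("net", "speciation", "extinction"), lty = 1:3, bty = "n")
  invisible(rtt)
}

#' Fit a covariate-dependent speciation model
#'
#' Speciation follows `lambda(t) = lambda0 * exp(beta * V(t))` with `V` an
#' interpolated covariate (e.g. Cenozoic temperature or competitor diversity
#' through time); `beta = 0` reduces exactly to the constant-rate model.
#'
#' @param tree a `dated_tree`.
#' @param curve a [covariate_curve()] spanning the tree's ages.
#' @param mu extinction form, as in [bd_model()].
#' @inheritParams fit_bd
#' @return a `bd_fit`.
#' @export
covariate_bd <- function(tree, curve, mu = "constant", rho = 1, starts = 10L,
                         seed = NULL) {
  tree <- as_dated_tree(tree)
  if (!curve$span[2L] >= tree$crown_age - 1e-9) {
    # evaluating will error unless the curve allows extrapolation
    curve$fun(tree$crown_age)
  }
  fit_bd(tree, bd_model("covariate", mu, rho = rho, covariate = curve),
         starts = starts, seed = seed)
}

#' Likelihood test for a mass-extinction event at a fixed age
#'
#' Compares a base birth--death model against the same model augmented with
#' an instantaneous extinction event at age `t0`: every lineage alive at `t0`
#' survives it with probability `s`, estimated by maximum likelihood with the
#' event folded into the likelihood's survival function. Positive
#' `delta_aicc` means the augmented model is preferred. "No evidence" is
#' declared when AICc favours the base model or when the estimated survival
#' is near 1.
#'
#' @param tree a `dated_tree`.
#' @param t0 event age in My, strictly inside (0, crown age).
#' @param base a [bd_model()] for the background dynamics (default constant
#'   birth--death).
#' @param s_null survival probability above which the event is considered
#'   absent even if AICc marginally favours the augmented model (default
#'   0.9).
#' @inheritParams fit_bd
#' @return object of class `mass_extinction_test` with `s_hat`,
#'   `delta_aicc` (base AICc minus augmented AICc), `supported`, and both
#'   fits.
#' @export
mass_extinction_test <- function(tree, t0, base = bd_model("constant", "constant"),
                                 starts = 10L, seed = NULL, s_null = 0.9) {
  tree <- as_dated_tree(tree)
  if (t0 <= 0 || t0 >= tree$crown_age)
    stop("t0 must lie strictly inside (0, crown age = ",
         format(tree$crown_age, digits = 5), ")")
  seeds <- child_seeds(seed %||% 1L, 2L)
  fit0 <- fit_bd(tree, base, starts = starts, seed = seeds[[1L]])
  fit1 <- fit_bd(tree, base, starts = starts, seed = seeds[[2L]], event_age = t0)
  s_hat <- fit1$par[["survival"]]
  delta <- fit0$aicc - fit1$aicc
  structure(list(t0 = t0, s_hat = s_hat, delta_aicc = delta,
                 supported = delta > 0 && s_hat < s_null,
                 base_fit = fit0, event_fit = fit1),
            class = "mass_extinction_test")
}

#' @export
print.mass_extinction_test <- function(x, ...) {
  cat("Mass-extinction test at age ", format(x$t0, digits = 5), " My\n",
      "  estimated survival s = ", format(x$s_hat, digits = 4),
      ",  delta AICc (base - augmented) = ", format(x$delta_aicc, digits = 4),
      "\n  ", if (x$supported) "evidence FOR an extinction shift"
      else "no evidence for an extinction shift", "\n", sep = "")
  invisible(x)
}
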