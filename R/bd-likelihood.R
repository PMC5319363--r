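# Birth--death model specification and log-likelihood.
#
# Time is age in My before present (present = 0, increasing into the past).
# The likelihood of the branching times t_1 > t_2 > ... > t_{n-1} (t_1 the
# crown age) under a birth--death process with rates lambda(t), mu(t) and
# present-day sampling fraction rho, conditioned on the crown age and on both
# crown lineages surviving to be sampled, is computed from two functions of
# age:
#
#   F(t): probability that a lineage alive at age t has at least one sampled
#         descendant at present. Solves dF/dt = r(t) F - lambda(t) F^2 with
#         F(0) = rho, where r = lambda - mu.
#   Q(t): probability density that a lineage alive at age t produces exactly
#         the single observed reconstructed lineage. The identity
#         Q(t) = F(t)^2 exp(-int_0^t r) / rho holds because
#         d log Q / dt = r - 2 lambda F = d/dt [2 log F - int r].
#
# With these, conditioning on crown survival,
#   log L = sum_{i=2}^{n-1} [log lambda(t_i) + log Q(t_i)]
#           + 2 log Q(t_1) - 2 log F(t_1).
# For constant rates F is logistic and everything is closed form (this
# reduces to the classical constant-rate likelihood with sampling, with
# Q(t) equal to the probability of exactly one sampled descendant); for
# time-varying rates F is integrated numerically.
#
# An instantaneous mass-extinction event at age t0 with per-lineage survival
# probability s multiplies F by s across t0 (going into the past) and
# multiplies Q by s once, i.e. log Q gains log(s) - not 2 log(s) - so the
# closed form carries an explicit -log(s) correction for ages older than t0.

#' Specify a birth--death model
#'
#' @param lambda functional form of speciation: "constant",
#'   `lambda(t) = lambda0`; "linear", `lambda0 + lambda_slope * t` (clipped at
#'   0 with a likelihood penalty); "exponential",
#'   `lambda0 * exp(lambda_slope * t)`; or "covariate",
#'   `lambda0 * exp(beta * V(t))` with `V` an interpolated covariate curve.
#'   On the age axis a negative slope means speciation increasing toward the
#'   present.
#' @param mu functional form of extinction: "zero", "constant", "linear" or
#'   "exponential" (parameters `mu0`, `mu_slope`).
#' @param rho sampling fraction at present, in (0, 1].
#' @param covariate a [covariate_curve()] (required when
#'   `lambda = "covariate"`).
#' @return an object of class `bd_model`.
#' @seealso [bd_loglik()], [fit_bd()]
#' @export
bd_model <- function(lambda = c("constant", "linear", "exponential", "covariate"),
                     mu = c("zero", "constant", "linear", "exponential"),
                     rho = 1, covariate = NULL) {
  lambda <- match.arg(lambda)
  mu <- match.arg(mu)
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0, rho <= 1)
  if (lambda == "covariate" && is.null(covariate))
    stop("lambda = \"covariate\" requires a covariate curve")
  if (!is.null(covariate) && !inherits(covariate, "covariate_curve"))
    stop("`covariate` must be built with covariate_curve()")
  structure(list(lambda = lambda, mu = mu, rho = rho, covariate = covariate),
            class = "bd_model")
}

#' @export
print.bd_model <- function(x, ...) {
  cat("Birth-death model: lambda ", x$lambda, ", mu ", x$mu,
      ", rho = ", format(x$rho, digits = 4), "\n", sep = "")
  invisible(x)
}

# Names of the free parameters of a bd_model.
bd_par_names <- function(model) {
  c(switch(model$lambda,
           constant = "lambda0",
           linear = , exponential = c("lambda0", "lambda_slope"),
           covariate = c("lambda0", "beta")),
    switch(model$mu,
           zero = character(),
           constant = "mu0",
           linear = , exponential = c("mu0", "mu_slope")))
}

# Build lambda(t) as a vectorized function of age; raw (unclipped) version
# is used for the negativity penalty.
bd_lambda_fun <- function(model, par, clip = TRUE) {
  l0 <- par[["lambda0"]]
  f <- switch(model$lambda,
    constant = function(t) rep_len(l0, length(t)),
    linear = function(t) l0 + par[["lambda_slope"]] * t,
    exponential = function(t) l0 * exp(par[["lambda_slope"]] * t),
    covariate = {
      V <- model$covariate$fun
      function(t) l0 * exp(par[["beta"]] * V(t))
    })
  if (clip) function(t) pmax(f(t), 0) else f
}

bd_mu_fun <- function(model, par, clip = TRUE) {
  f <- switch(model$mu,
    zero = function(t) rep_len(0, length(t)),
    constant = function(t) rep_len(par[["mu0"]], length(t)),
    linear = function(t) par[["mu0"]] + par[["mu_slope"]] * t,
    exponential = function(t) par[["mu0"]] * exp(par[["mu_slope"]] * t))
  if (clip) function(t) pmax(f(t), 0) else f
}

bd_is_constant <- function(model) {
  model$lambda == "constant" && model$mu %in% c("zero", "constant")
}

# Penalty for rate functions dipping below zero on [0, T] (checked on a grid);
# keeps clipped "linear" fits away from degenerate regions.
bd_negativity_penalty <- function(model, par, t_max, n_grid = 64L) {
  grid <- seq(0, t_max, length.out = n_grid)
  pen <- 0
  lr <- bd_lambda_fun(model, par, clip = FALSE)(grid)
  mr <- bd_mu_fun(model, par, clip = FALSE)(grid)
  pen <- pen + sum(pmax(-lr, 0)) + sum(pmax(-mr, 0))
  1e3 * pen
}

# --- constant-rate closed form ----------------------------------------------

# Survival probability F(t) for constant rates, initial value F0 at t = t_init.
const_F <- function(t, lambda, mu, F0, t_init = 0) {
  r <- lambda - mu
  dt <- t - t_init
  if (abs(r) < 1e-12) F0 / (1 + lambda * F0 * dt)
  else r / (lambda + (r / F0 - lambda) * exp(-r * dt))
}

# log F and log Q at the requested ages for constant rates, with an optional
# instantaneous extinction event (age t0, per-lineage survival s).
const_FQ <- function(ages, lambda, mu, rho, event = NULL) {
  r <- lambda - mu
  if (is.null(event)) {
    Fv <- const_F(ages, lambda, mu, rho)
    logQ <- 2 * log(Fv) - r * ages - log(rho)
  } else {
    t0 <- event$age; s <- event$survival
    F_t0 <- s * const_F(t0, lambda, mu, rho)
    Fv <- ifelse(ages <= t0,
                 const_F(ages, lambda, mu, rho),
                 const_F(ages, lambda, mu, F_t0, t_init = t0))
    logQ <- 2 * log(Fv) - r * ages - log(rho) - ifelse(ages > t0, log(s), 0)
  }
  list(logF = log(Fv), logQ = logQ)
}

# --- time-varying: numerical integration ------------------------------------

# Solve for F(t) and R(t) = int_0^t r(u) du at the requested ages.
ode_FQ <- function(ages, lam_fun, mu_fun, rho, event = NULL,
                   rtol = 1e-10, atol = 1e-12) {
  deriv <- function(t, y, parms) {
    lam <- lam_fun(t); mu <- mu_fun(t); r <- lam - mu
    list(c(r * y[1L] - lam * y[1L]^2, r))
  }
  solve_piece <- function(y0, t_from, t_to, t_out) {
    times <- sort(unique(c(t_from, t_out, t_to)))
    out <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(out, "istate")[1L] < 0) stop("birth-death ODE integration failed")
    out
  }
  t_max <- max(ages)
  if (is.null(event) || event$age >= t_max) {
    out <- solve_piece(c(F = rho, R = 0), 0, t_max, ages)
    Fv <- out[match(ages, out[, 1L]), 2L]
    Rv <- out[match(ages, out[, 1L]), 3L]
    logs_corr <- rep(0, length(ages))
  } else {
    t0 <- event$age; s <- event$survival
    lo <- ages[ages <= t0]; hi <- ages[ages > t0]
    out1 <- solve_piece(c(F = rho, R = 0), 0, t0, lo)
    F_t0 <- out1[nrow(out1), 2L]; R_t0 <- out1[nrow(out1), 3L]
    out2 <- solve_piece(c(F = s * F_t0, R = R_t0), t0, t_max, hi)
    Fv <- c(out1[match(lo, out1[, 1L]), 2L], out2[match(hi, out2[, 1L]), 2L])
    Rv <- c(out1[match(lo, out1[, 1L]), 3L], out2[match(hi, out2[, 1L]), 3L])
    logs_corr <- ifelse(ages > t0, log(s), 0)
    ord <- order(c(lo, hi)); # restore the order of `ages` (already sorted in)
    stopifnot(identical(c(lo, hi), ages))
  }
  list(logF = log(pmax(Fv, .Machine$double.xmin)),
       logQ = 2 * log(pmax(Fv, .Machine$double.xmin)) - Rv - log(rho) - logs_corr)
}

#' Birth--death log-likelihood of a dated tree
#'
#' Log-likelihood of the tree's branching times under a (possibly
#' time-varying) birth--death process with sampling fraction `rho`,
#' conditioned on the crown age and survival of both crown lineages to the
#' present. Constant-rate models use the closed form; time-varying models
#' integrate the survival-probability ODE numerically.
#'
#' @param tree a `dated_tree` (ultrametric, binary).
#' @param model a [bd_model()].
#' @param par named numeric vector of parameters (see [bd_model()] for names).
#' @param event optional instantaneous mass-extinction event,
#'   `list(age =, survival =)`: every lineage alive at that age survives it
#'   with the given probability.
#' @param penalize if TRUE (default), subtract a penalty when an unclipped
#'   rate function dips below zero on the tree's age span (used during
#'   optimization).
#' @return the log-likelihood (scalar; `-Inf` for invalid parameters).
#' @export
bd_loglik <- function(tree, model, par, event = NULL, penalize = TRUE) {
  tree <- as_dated_tree(tree)
  par <- unlist(par)
  need <- bd_par_names(model)
  if (!all(need %in% names(par)))
    stop("missing parameter(s): ", paste(setdiff(need, names(par)), collapse = ", "))
  bt <- branching_times(tree)
  bd_loglik_bt(bt, model, par, event = event, penalize = penalize)
}

# Workhorse on branching times directly (decreasing, bt[1] = crown age).
bd_loglik_bt <- function(bt, model, par, event = NULL, penalize = TRUE) {
  t1 <- bt[1L]
  if (!is.null(event) && (event$age <= 0 || event$age >= t1))
    stop("event age must lie strictly inside (0, crown age)")
  if (!is.null(event) && (event$survival <= 0 || event$survival > 1))
    return(-Inf)
  rho <- model$rho
  lam_fun <- bd_lambda_fun(model, par)
  mu_fun <- bd_mu_fun(model, par)
  # quick invalidity checks
  if (any(!is.finite(par))) return(-Inf)
  lam_at_nodes <- lam_fun(bt)
  if (any(lam_at_nodes[-1L] <= 0)) return(-Inf)
  ages <- sort(unique(bt))
  if (bd_is_constant(model)) {
    fq <- const_FQ(ages, par[["lambda0"]],
                   if (model$mu == "zero") 0 else par[["mu0"]], rho, event)
  } else {
    fq <- ode_FQ(ages, lam_fun, mu_fun, rho, event)
  }
  logF <- fq$logF[match(bt, ages)]
  logQ <- fq$logQ[match(bt, ages)]
  ll <- sum(log(lam_at_nodes[-1L])) + sum(logQ[-1L]) + 2 * logQ[1L] - 2 * logF[1L]
  if (penalize) ll <- ll - bd_negativity_penalty(model, par, t1)
  if (!is.finite(ll)) -Inf else unname(ll)
}

#' Covariate curve for covariate-dependent speciation models
#'
#' @param age numeric vector of ages (My before present), strictly monotone.
#' @param value covariate values at those ages.
#' @param method interpolation: "linear" (default) or "constant" (step,
#'   appropriate for diversity-through-time curves).
#' @param allow_extrapolation if FALSE (default), evaluating the curve outside
#'   its age span is an error; if TRUE the boundary value is carried flat.
#' @return an object of class `covariate_curve` with element `fun`, a
#'   vectorized function of age.
#' @export
covariate_curve <- function(age, value, method = c("linear", "constant"),
                            allow_extrapolation = FALSE) {
  method <- match.arg(method)
  stopifnot(length(age) == length(value), length(age) >= 2L)
  ord <- order(age)
  if (any(diff(age[ord]) == 0)) stop("covariate ages must be strictly monotone")
  age <- age[ord]; value <- value[ord]
  base <- stats::approxfun(age, value, method = method, rule = 2, f = 1)
  span <- range(age)
  fun <- function(t) {
    if (!allow_extrapolation && (any(t < span[1L] - 1e-9) || any(t > span[2L] + 1e-9)))
      stop("covariate curve evaluated outside its age span [",
           span[1L], ", ", span[2L], "] My; supply a longer curve or set ",
           "allow_extrapolation = TRUE")
    base(t)
  }
  structure(list(age = age, value = value, method = method, span = span,
                 fun = fun), class = "covariate_curve")
}

#' @export
print.covariate_curve <- function(x, ...) {
  cat("Covariate curve: ", length(x$age), " points over [",
      format(x$span[1L], digits = 4), ", ", format(x$span[2L], digits = 4),
      "] My (", x$method, " interpolation)\n", sep = "")
  invisible(x)
}

#' Read a covariate curve from a two-column CSV (age_my, value)
#'
#' @param path CSV file path with columns `age_my` and `value`.
#' @inheritParams covariate_curve
#' @return a [covariate_curve()].
#' @export
read_covariate <- function(path, method = "linear", allow_extrapolation = FALSE) {
  x <- read.csv(path)
  if (!all(c("age_my", "value") %in% names(x)))
    stop("covariate CSV must have columns age_my,value")
  covariate_curve(x$age_my, x$value, method = method,
                  allow_extrapolation = allow_extrapolation)
}

#' Convert a tree's lineage-through-time plot into a diversity covariate
#'
#' The step curve of reconstructed lineage counts through time, usable as the
#' covariate in [covariate_bd()] (e.g. competitor diversity through time
#' estimated from the competitor clade's phylogeny).
#'
#' @param tree an ultrametric `dated_tree` for the competitor clade.
#' @param span_to optionally extend the curve (flat at 2 lineages) back to
#'   this age so it spans an older focal tree.
#' @return a [covariate_curve()] with constant (step) interpolation.
#' @export
ltt_to_diversity_curve <- function(tree, span_to = NULL) {
  tree <- as_dated_tree(tree)
  lt <- ltt_curve(tree)
  age <- lt$age; n <- lt$lineages
  if (!is.null(span_to) && span_to > max(age)) {
    age <- c(span_to, age); n <- c(2L, n)
  }
  covariate_curve(age, n, method = "constant", allow_extrapolation = TRUE)
}
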