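# Continuous-trait models on a phylogeny: Brownian motion, Ornstein--Uhlenbeck
# (stationary or fixed-root covariance), Pagel's lambda, and ACDC/early burst.
#
# All are multivariate-normal models with covariance built from the tree:
#   BM      V_ij = sigma2 * s_ij                     (s_ij = shared path length)
#   lambda  off-diagonals of the BM covariance scaled by lambda in [0, 1]
#   OU      stationary: V_ij = sigma2/(2 alpha) * exp(-alpha * d_ij)
#           fixed-root: V_ij = sigma2/(2 alpha) * (1 - exp(-2 alpha s_ij))
#                               * exp(-alpha * d_ij)   (d_ij = patristic)
#   ACDC    V_ij = sigma2 * (exp(g * s_ij) - 1) / g   (g < 0 = early burst)
# The mean and the overall variance scale are profiled analytically; the one
# remaining shape parameter is optimized within bounds.

trait_structure <- function(model, C, D, par, root = "stationary") {
  switch(model,
    BM = C,
    lambda = {
      V <- par[["lambda"]] * C
      diag(V) <- diag(C)
      V
    },
    OU = {
      a <- par[["alpha"]]
      if (a <= 0) stop("alpha must be positive for the OU structure")
      if (root == "stationary") exp(-a * D)
      else (1 - exp(-2 * a * C)) * exp(-a * D)   # scale sigma2/(2 alpha) profiled
    },
    ACDC = {
      g <- par[["g"]]
      if (abs(g) < 1e-10) C else (exp(g * C) - 1) / g
    },
    stop("unknown trait model: ", model))
}

# profile the mean and the scale of y ~ N(mu * 1, s * V0); returns logL at
# the profiled maximum plus the profiled estimates
profile_mvn <- function(y, V0) {
  n <- length(y)
  L <- tryCatch(chol(V0), error = function(e)
    stop("singular phylogenetic covariance; check for duplicated tips or a ",
         "degenerate model parameter"))
  z <- backsolve(L, y, transpose = TRUE)
  o <- backsolve(L, rep(1, n), transpose = TRUE)
  mu <- sum(o * z) / sum(o * o)
  r <- z - mu * o
  s <- sum(r^2) / n
  logL <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s) - sum(log(diag(L))) - 0.5 * n
  list(logL = logL, mu = mu, scale = s)
}

#' Fit a continuous-trait evolution model by maximum likelihood
#'
#' @param tree a `dated_tree`.
#' @param trait named numeric vector (names are tip labels; tips without data
#'   are pruned). At least 10 species are required.
#' @param model "BM", "OU", "lambda" or "ACDC" (exponentially time-rescaled
#'   Brownian motion; a negative rate exponent is an early burst).
#' @param root for OU, "stationary" (root drawn from the stationary
#'   distribution; default) or "fixed" (root at the optimum with zero
#'   variance).
#' @param fix optional named list fixing a shape parameter (e.g.
#'   `list(alpha = 1e-8)` or `list(lambda = 0)`), used for nested-model
#'   comparisons.
#' @return object of class `trait_fit` with `par` (sigma2, mean/theta and the
#'   shape parameter), `logL`, `k`, `aicc`, `n`, and `bound_hit` flag.
#' @export
fit_trait_model <- function(tree, trait, model = c("BM", "OU", "lambda", "ACDC"),
                            root = c("stationary", "fixed"), fix = NULL) {
  model <- match.arg(model)
  root <- match.arg(root)
  tree <- as_dated_tree(tree)
  trait <- trait[!is.na(trait)]
  sp <- intersect(tree$tip.label, names(trait))
  if (length(sp) < 10L) stop("trait must cover at least 10 tips of the tree")
  if (length(sp) < ape::Ntip(tree))
    tree <- as_dated_tree(ape::keep.tip(tree, sp))
  y <- trait[tree$tip.label]
  C <- ape::vcv(tree)
  D <- patristic_matrix(tree)
  Tmax <- tree$crown_age
  n <- length(y)
  shape_name <- switch(model, BM = NULL, OU = "alpha", lambda = "lambda", ACDC = "g")
  bounds <- switch(model,
    OU = log(c(1e-8, 100 / Tmax)),
    lambda = c(0, 1),
    ACDC = c(-5 / Tmax, 5 / Tmax),
    NULL)
  ll_at <- function(shape) {
    par <- if (is.null(shape_name)) numeric(0) else setNames(shape, shape_name)
    V0 <- trait_structure(model, C, D, as.list(par), root)
    profile_mvn(y, V0)
  }
  bound_hit <- FALSE
  if (model == "BM") {
    shape <- NULL
    prof <- ll_at(NULL)
  } else if (!is.null(fix) && shape_name %in% names(fix)) {
    shape <- fix[[shape_name]]
    if (model == "lambda" && shape == 0) {
      # star-tree reduction: iid normal
      V0 <- diag(diag(C))
      prof <- profile_mvn(y, V0)
    } else prof <- ll_at(shape)
  } else {
    trans <- if (model == "OU") exp else identity
    o <- optimize(function(x) -ll_at(trans(x))$logL, interval = bounds, tol = 1e-9)
    shape <- trans(o$minimum)
    prof <- ll_at(shape)
    edge <- 0.01 * diff(bounds)
    bound_hit <- o$minimum <= bounds[1L] + edge || o$minimum >= bounds[2L] - edge
  }
  par <- switch(model,
    BM = c(sigma2 = prof$scale, mean = prof$mu),
    OU = c(sigma2 = 2 * shape * prof$scale, alpha = shape, theta = prof$mu),
    lambda = c(sigma2 = prof$scale, lambda = shape, mean = prof$mu),
    ACDC = c(sigma2 = prof$scale, g = shape, mean = prof$mu))
  k <- if (model == "BM") 2L else 3L
  fixed <- !is.null(fix) && !is.null(shape_name) && shape_name %in% names(fix)
  if (fixed) k <- k - 1L
  structure(list(model = model, root = root, par = par, logL = prof$logL,
                 k = k, n = n, aicc = aicc(prof$logL, k, n),
                 bound_hit = bound_hit, fixed = fixed,
                 tree = tree, trait = y),
            class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat("Trait model fit [", x$model,
      if (x$model == "OU") paste0(", ", x$root, " root"), "]\n", sep = "")
  cat("  logL = ", format(x$logL, digits = 7), ",  k = ", x$k,
      ",  AICc = ", format(x$aicc, digits = 7), "  (n = ", x$n, ")\n", sep = "")
  print(signif(x$par, 5))
  if (x$bound_hit) cat("  note: shape parameter at its optimization bound\n")
  invisible(x)
}

#' @export
logLik.trait_fit <- function(object, ...) {
  structure(object$logL, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
coef.trait_fit <- function(object, ...) object$par

#' Implied Brownian rate through time of an ACDC fit
#'
#' Under the ACDC model the instantaneous Brownian variance at age `t`
#' (My before present) is `sigma2 * exp(g * (T - t))` with `T` the crown
#' age; a negative `g` (early burst) means a rate that declines from the
#' root toward the present.
#'
#' @param fit a `trait_fit` with `model = "ACDC"`.
#' @param ages age grid (default crown to present).
#' @return data frame with columns `age` and `sigma2`.
#' @export
acdc_rate_through_time <- function(fit, ages = NULL) {
  stopifnot(inherits(fit, "trait_fit"), fit$model == "ACDC")
  Tmax <- fit$tree$crown_age
  if (is.null(ages)) ages <- seq(Tmax, 0, length.out = 100L)
  data.frame(age = ages,
             sigma2 = fit$par[["sigma2"]] * exp(fit$par[["g"]] * (Tmax - ages)))
}

#' Compare trait models by AICc and average parameters
#'
#' Fits the four single-regime models, keeps those with delta-AICc below a
#' cutoff (default 3) as the candidate set, and averages parameters across
#' the candidates with Akaike weights.
#'
#' @param tree a `dated_tree`.
#' @param trait named trait vector.
#' @param models models to compare (default all four).
#' @param cutoff delta-AICc below which a model enters the averaging set.
#' @return object of class `trait_model_set` with the AICc table, weights and
#'   weighted-average sigma2.
#' @export
compare_trait_models <- function(tree, trait,
                                 models = c("BM", "OU", "lambda", "ACDC"),
                                 cutoff = 3) {
  fits <- lapply(models, function(m) fit_trait_model(tree, trait, model = m))
  names(fits) <- models
  ai <- vapply(fits, `[[`, 0, "aicc")
  w <- akaike_weights(ai)
  keep <- (ai - min(ai)) < cutoff
  w_avg <- akaike_weights(ai[keep])
  sigma2 <- sum(w_avg * vapply(fits[keep], function(f) f$par[["sigma2"]], 0))
  tab <- data.frame(model = models, k = vapply(fits, `[[`, 0L, "k"),
                    logL = vapply(fits, `[[`, 0, "logL"), AICc = ai,
                    dAICc = ai - min(ai), weight = w, candidate = keep)
  structure(list(table = tab[order(tab$dAICc), ], fits = fits,
                 averaged = c(sigma2 = sigma2), cutoff = cutoff),
            class = "trait_model_set")
}

#' @export
print.trait_model_set <- function(x, ...) {
  cat("Trait model comparison (candidate set: dAICc < ", x$cutoff, ")\n", sep = "")
  tab <- x$table
  tab$logL <- round(tab$logL, 3); tab$AICc <- round(tab$AICc, 3)
  tab$dAICc <- round(tab$dAICc, 3); tab$weight <- round(tab$weight, 3)
  print(tab, row.names = FALSE)
  cat("Model-averaged sigma2 =", format(x$averaged[["sigma2"]], digits = 4), "\n")
  invisible(x)
}
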