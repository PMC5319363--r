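# State-dependent (multi-regime) Ornstein--Uhlenbeck and Brownian trait
# models along a regime painting.
#
# The trait is multivariate normal with moments accumulated segment by
# segment along the painted branches. Writing A(v) for the integral of alpha
# along the root-to-v path and W(v) for the trait variance accumulated at v,
# a segment in state k of length l updates
#   W  <- W * e^{-2 a_k l} + s2_k (1 - e^{-2 a_k l}) / (2 a_k)   (s2_k l if a_k = 0)
#   w  <- w * e^{-a_k l};  w[k] <- w[k] + (1 - e^{-a_k l})
# where w is the vector of optimum weights, so a tip's expected value is
#   E[x_i] = x0 e^{-A_i} + sum_k w_ik theta_k,
# and for tips i, j with MRCA node v,
#   Cov(x_i, x_j) = W(v) e^{-(A_i - A(v))} e^{-(A_j - A(v))}.
# With a stationary root (the default), W(root) = s2_root / (2 a_root) and
# x0 = theta of the root regime, which makes a one-regime OUM model identical
# to the single stationary OU model. The optima (and x0 for Brownian models)
# are profiled by GLS; one overall variance scale is profiled analytically;
# the remaining shape parameters (alphas, rate ratios) are optimized
# numerically.

MULTIREGIME_MODELS <- c("bm", "ou", "bms", "oum", "ouma", "oumv", "oumva")

# moments of the painted OU process; alpha_k, sigma2_k named by state
ou_moments <- function(paint, alpha_k, sigma2_k, stationary = TRUE) {
  tree <- paint$tree
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  states <- paint$states
  K <- length(states)
  A <- numeric(n + m); W <- numeric(n + m)
  wmat <- matrix(0, n + m, K, dimnames = list(NULL, states))
  decay <- numeric(n + m)
  root <- n + 1L
  root_edge <- which(tree$edge[, 1L] == root)[1L]
  root_state <- names(paint$maps[[root_edge]])[1L]
  a_root <- alpha_k[[root_state]]
  W[root] <- if (stationary && a_root > 0) sigma2_k[[root_state]] / (2 * a_root) else 0
  decay[root] <- 1
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  idx <- match(paste(ord[, 1L], ord[, 2L]), paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (e in seq_along(idx)) {
    row <- idx[e]
    par <- tree$edge[row, 1L]; chd <- tree$edge[row, 2L]
    Av <- A[par]; Wv <- W[par]; wv <- wmat[par, ]; dv <- decay[par]
    seg <- paint$maps[[row]]
    for (k in seq_along(seg)) {
      st <- names(seg)[k]; len <- seg[[k]]
      a <- alpha_k[[st]]; s2 <- sigma2_k[[st]]
      if (a > 0) {
        d1 <- exp(-a * len)
        Wv <- Wv * d1 * d1 + s2 * (1 - d1 * d1) / (2 * a)
        wv <- wv * d1; wv[st] <- wv[st] + (1 - d1)
        dv <- dv * d1
        Av <- Av + a * len
      } else {
        Wv <- Wv + s2 * len
      }
    }
    A[chd] <- Av; W[chd] <- Wv; wmat[chd, ] <- wv; decay[chd] <- dv
  }
  list(A = A, W = W, wmat = wmat, decay = decay, root_state = root_state,
       n = n)
}

# tip covariance matrix from the accumulated moments
ou_cov <- function(mom, paint) {
  n <- mom$n
  mm <- paint$mrca %||% ape::mrca(paint$tree)
  At <- mom$A[seq_len(n)]
  V <- mom$W[mm] * exp(-(outer(At, At, `+`) - 2 * mom$A[mm]))
  dimnames(V) <- list(paint$tree$tip.label, paint$tree$tip.label)
  V
}

# mean design matrix: optimum weights with the root column absorbing the
# x0 decay (OU-type), or a single intercept column (Brownian-type)
ou_design <- function(mom, ou_type) {
  n <- mom$n
  if (!ou_type) return(matrix(1, n, 1L, dimnames = list(NULL, "x0")))
  X <- mom$wmat[seq_len(n), , drop = FALSE]
  X[, mom$root_state] <- X[, mom$root_state] + mom$decay[seq_len(n)]
  X
}

# profiled GLS of y on X under covariance scale * V0
profile_gls <- function(y, X, V0) {
  n <- length(y)
  L <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  z <- backsolve(L, y, transpose = TRUE)
  Xs <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(Xs)
  bhat <- tryCatch(solve(XtX, crossprod(Xs, z)), error = function(e) NULL)
  if (is.null(bhat)) return(NULL)
  r <- z - Xs %*% bhat
  s <- sum(r^2) / n
  logL <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s) - sum(log(diag(L))) - 0.5 * n
  bhat <- setNames(drop(bhat), colnames(X))
  list(logL = logL, beta = bhat, scale = s,
       beta_cov = s * tryCatch(solve(XtX), error = function(e) XtX * NA))
}

# per-model free-parameter layout (psi is the optimized vector)
mr_layout <- function(model, states) {
  K <- length(states)
  switch(model,
    bm = list(np = 0L, k = 2L),
    ou = list(np = 1L, k = 3L),
    bms = list(np = K - 1L, k = K + 1L),
    oum = list(np = 1L, k = K + 2L),
    ouma = list(np = K, k = 2L * K + 1L),
    oumv = list(np = K, k = 2L * K + 1L),
    oumva = list(np = 2L * K - 1L, k = 3L * K),
    stop("unknown multiregime model: ", model))
}

# expand psi into per-state alpha and relative sigma2 (first state ratio = 1)
mr_params <- function(model, psi, states) {
  K <- length(states)
  one <- setNames(rep(1, K), states)
  zero <- setNames(rep(0, K), states)
  switch(model,
    bm = list(alpha = zero, s2 = one, ou = FALSE),
    ou = list(alpha = one * exp(psi[1L]), s2 = one, ou = TRUE),
    bms = list(alpha = zero, s2 = setNames(c(1, exp(psi)), states), ou = FALSE),
    oum = list(alpha = one * exp(psi[1L]), s2 = one, ou = TRUE),
    ouma = list(alpha = setNames(exp(psi), states), s2 = one, ou = TRUE),
    oumv = list(alpha = one * exp(psi[1L]),
                s2 = setNames(c(1, exp(psi[-1L])), states), ou = TRUE),
    oumva = list(alpha = setNames(exp(psi[seq_len(K)]), states),
                 s2 = setNames(c(1, exp(psi[-seq_len(K)])), states), ou = TRUE))
}

# standard errors of the optima from the joint observed information
# (theta, shape psi, log scale); NULL when the Hessian is not usable
mr_theta_se <- function(paint, y, model, res, psi, stationary) {
  theta <- res$beta
  p_theta <- length(theta)
  full <- c(theta, psi, log(res$scale))
  nll <- function(par) {
    th <- par[seq_len(p_theta)]
    ps <- par[p_theta + seq_along(psi)]
    sc <- exp(par[length(par)])
    pr <- mr_params(model, ps, paint$states)
    mom <- ou_moments(paint, pr$alpha, pr$s2, stationary = stationary)
    V <- sc * ou_cov(mom, paint)
    X <- ou_design(mom, pr$ou)
    if (model == "ou") X <- matrix(rowSums(X), ncol = 1L)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    -mvn_loglik_chol(y, drop(X %*% th), L)
  }
  H <- tryCatch(stats::optimHess(full, nll), error = function(e) NULL)
  if (is.null(H)) return(NULL)
  Vc <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Vc)) return(NULL)
  d <- diag(Vc)[seq_len(p_theta)]
  if (any(!is.finite(d)) || any(d <= 0)) return(NULL)
  setNames(sqrt(d), names(theta))
}

mr_profile <- function(paint, y, model, psi, stationary = TRUE) {
  p <- mr_params(model, psi, paint$states)
  mom <- ou_moments(paint, p$alpha, p$s2, stationary = stationary)
  V0 <- ou_cov(mom, paint)
  X <- ou_design(mom, p$ou)
  if (model == "ou")   # single optimum: weight columns collapse (sum to 1)
    X <- matrix(rowSums(X), ncol = 1L, dimnames = list(NULL, "theta"))
  res <- profile_gls(y, X, V0)
  if (is.null(res)) return(NULL)
  c(res, list(params = p, mom = mom))
}

#' Fit state-dependent OU/BM trait models along a regime painting
#'
#' Candidate models: single Brownian motion (`"bm"`), single OU (`"ou"`),
#' state-dependent Brownian rates (`"bms"`), and the state-dependent OU
#' family -- unique optima (`"oum"`), unique optima and constraints
#' (`"ouma"`), unique optima and rates (`"oumv"`), all unique (`"oumva"`).
#' Optima are profiled by GLS, one variance scale analytically, remaining
#' shape parameters numerically with warm starts chained from simpler
#' models. Results are ranked by AICc with Akaike weights.
#'
#' @param paint a [regime_paint()] (carries the tree).
#' @param trait named trait vector covering every tip of the painted tree.
#' @param models subset of the candidate models (default: all seven).
#' @param root "stationary" (default; the root trait is drawn from the root
#'   regime's stationary distribution, with the root value at that regime's
#'   optimum) or "optimum" (root at the optimum with zero initial variance).
#' @param n_starts extra random starts per model beyond the warm start.
#' @param seed optional integer seed for the extra starts.
#' @return object of class `multiregime_fit`: AICc `table`, per-model `fits`
#'   (each with `theta`, `se_theta`, `alpha`, `sigma2`, `logL`, `aicc`), and
#'   `best`.
#' @export
fit_multiregime <- function(paint, trait, models = MULTIREGIME_MODELS,
                            root = c("stationary", "optimum"), n_starts = 2L,
                            seed = NULL) {
  root <- match.arg(root)
  stationary <- root == "stationary"
  models <- match.arg(models, MULTIREGIME_MODELS, several.ok = TRUE)
  tree <- paint$tree
  y <- trait[tree$tip.label]
  if (any(is.na(y)))
    stop("trait must cover every tip of the painted tree; prune the tree and ",
         "repaint before fitting")
  states <- paint$states
  K <- length(states)
  # every regime needs at least 2 tips for the state-dependent models
  n <- ape::Ntip(tree)
  term <- which(tree$edge[, 2L] <= n)
  tip_st <- vapply(paint$maps[term], function(m) names(m)[length(m)], "")
  tip_counts <- table(factor(tip_st, levels = states))
  if (any(tip_counts < 2L) && any(!models %in% c("bm", "ou")))
    stop("regime(s) with fewer than 2 tips: ",
         paste(names(tip_counts)[tip_counts < 2L], collapse = ", "))
  Tmax <- tree$crown_age
  a0 <- log(log(2) / (Tmax / 2))     # half-life = half the crown age
  seeds <- child_seeds(seed %||% 1L, length(models))
  fits <- list()
  warm <- list()   # remembered psi pieces for chaining
  for (mi in seq_along(models)) {
    model <- models[mi]
    lay <- mr_layout(model, states)
    objective <- function(psi) {
      res <- mr_profile(paint, y, model, psi, stationary)
      if (is.null(res) || !is.finite(res$logL)) 1e10 else -res$logL
    }
    if (lay$np == 0L) {
      best_psi <- numeric(0L)
    } else {
      psi0 <- switch(model,
        ou = , oum = a0,
        bms = rep(warm$log_ratio %||% 0, K - 1L),
        ouma = rep(warm$log_alpha %||% a0, K),
        oumv = c(warm$log_alpha %||% a0, rep(warm$log_ratio %||% 0, K - 1L)),
        oumva = c(rep(warm$log_alpha %||% a0, K),
                  rep(warm$log_ratio %||% 0, K - 1L)))
      psi0 <- rep_len(psi0, lay$np)
      starts <- with_seed(seeds[[mi]], {
        extra <- lapply(seq_len(n_starts), function(i)
          psi0 + rnorm(lay$np, 0, 1))
        c(list(psi0), extra)
      })
      best <- NULL
      for (s0 in starts) {
        res <- if (lay$np == 1L) {
          o <- optimize(function(x) objective(x), interval = s0 + c(-8, 8),
                        tol = 1e-9)
          list(par = o$minimum, value = o$objective)
        } else {
          tryCatch(optim(s0, objective, method = "Nelder-Mead",
                         control = list(maxit = 3000L, reltol = 1e-11)),
                   error = function(e) NULL)
        }
        if (!is.null(res) && is.finite(res$value) &&
            (is.null(best) || res$value < best$value)) best <- res
      }
      if (is.null(best)) stop("multiregime fit failed for model '", model, "'")
      best_psi <- best$par
    }
    res <- mr_profile(paint, y, model, best_psi, stationary)
    p <- res$params
    sigma2 <- res$scale * p$s2
    alpha <- p$alpha
    if (p$ou) {
      theta <- res$beta
      # full-information standard errors: numerical Hessian over the optima,
      # the shape parameters and the log variance scale jointly (the
      # GLS-conditional covariance understates uncertainty when alpha is
      # itself estimated)
      se <- mr_theta_se(paint, y, model, res, best_psi, stationary)
      if (is.null(se)) {
        se <- sqrt(pmax(diag(as.matrix(res$beta_cov)), 0))
        names(se) <- names(theta)
      }
      x0 <- if (model == "ou") res$beta[[1L]] else res$beta[[res$mom$root_state]]
    } else {
      theta <- NULL; se <- NULL; x0 <- res$beta[[1L]]
    }
    fits[[model]] <- list(model = model, logL = res$logL, k = lay$k,
                          n = length(y), aicc = aicc(res$logL, lay$k, length(y)),
                          theta = theta, se_theta = se, alpha = alpha,
                          sigma2 = sigma2, x0 = x0, psi = best_psi,
                          bound_hit = p$ou && any(alpha > 50 / Tmax))
    # remember warm-start pieces
    if (model %in% c("ou", "oum")) warm$log_alpha <- best_psi[1L]
    if (model == "bms" && K > 1L) warm$log_ratio <- mean(best_psi)
  }
  ai <- vapply(fits, `[[`, 0, "aicc")
  tab <- data.frame(model = names(fits),
                    k = vapply(fits, `[[`, 0L, "k"),
                    logL = vapply(fits, `[[`, 0, "logL"),
                    AICc = ai, dAICc = ai - min(ai),
                    weight = akaike_weights(ai))
  structure(list(table = tab[order(tab$dAICc), ], fits = fits,
                 best = names(fits)[which.min(ai)], states = states,
                 root = root, n = length(y)),
            class = "multiregime_fit")
}

#' @export
print.multiregime_fit <- function(x, ...) {
  cat("State-dependent trait models over ", length(x$states),
      " regimes (n = ", x$n, ", ", x$root, " root)\n", sep = "")
  tab <- x$table
  tab$logL <- round(tab$logL, 3); tab$AICc <- round(tab$AICc, 3)
  tab$dAICc <- round(tab$dAICc, 3); tab$weight <- round(tab$weight, 3)
  print(tab, row.names = FALSE)
  bf <- x$fits[[x$best]]
  if (!is.null(bf$theta)) {
    cat("Best model '", x$best, "' optima (theta):\n", sep = "")
    print(signif(bf$theta, 4))
  }
  invisible(x)
}

#' @export
coef.multiregime_fit <- function(object, model = object$best, ...) {
  f <- object$fits[[model]]
  c(setNames(as.numeric(f$theta), paste0("theta_", names(f$theta))),
    setNames(as.numeric(f$alpha), paste0("alpha_", names(f$alpha))),
    setNames(as.numeric(f$sigma2), paste0("sigma2_", names(f$sigma2))))
}

#' Multi-regime log-likelihood at fixed parameters
#'
#' Exact multivariate-normal log-likelihood of a trait under a painted
#' OU/BM process with all parameters supplied (no profiling); used for
#' nested-model identities and external checks.
#'
#' @param paint a [regime_paint()].
#' @param trait named trait vector covering the painted tree's tips.
#' @param theta named optimum per state (ignored when all `alpha` are 0).
#' @param alpha named (or scalar) selection strength per state; 0 = BM.
#' @param sigma2 named (or scalar) diffusion variance per state.
#' @param x0 root value; defaults to the root regime's optimum.
#' @param root "stationary" or "optimum" root variance, as in
#'   [fit_multiregime()].
#' @return log-likelihood (scalar).
#' @export
multiregime_loglik <- function(paint, trait, theta = NULL, alpha, sigma2,
                               x0 = NULL, root = c("stationary", "optimum")) {
  root <- match.arg(root)
  states <- paint$states
  al <- expand_by_state(alpha, states)
  s2 <- expand_by_state(sigma2, states)
  y <- trait[paint$tree$tip.label]
  mom <- ou_moments(paint, al, s2, stationary = root == "stationary")
  V <- ou_cov(mom, paint)
  n <- mom$n
  if (all(al == 0)) {
    if (is.null(x0)) stop("x0 required when all alpha are 0")
    mu <- rep(x0, n)
  } else {
    th <- expand_by_state(theta, states)
    if (is.null(x0)) x0 <- th[[mom$root_state]]
    mu <- drop(mom$wmat[seq_len(n), , drop = FALSE] %*% th) +
      x0 * mom$decay[seq_len(n)]
  }
  mvn_loglik_chol(y, mu, chol(V))
}

#' Model preference tally across a posterior-like tree set
#'
#' For each sample: take the next tree from the set, draw one stochastic map
#' of the niche under its ML Mk matrix, fit the candidate multi-regime
#' models, and record the AICc-best model. The tally across samples measures
#' robustness of the model choice to tree and ancestral-state uncertainty.
#'
#' @param trees list of `dated_tree` objects (>= 2).
#' @param trait named trait vector.
#' @param niche named tip-state vector.
#' @param n_samples number of (tree, map) samples (default: one per tree).
#' @param models candidate models passed to [fit_multiregime()].
#' @param seed optional integer seed.
#' @return object of class `posterior_tally`: `wins` (named counts), and the
#'   per-sample best-model vector.
#' @export
multiregime_over_posterior <- function(trees, trait, niche, n_samples = length(trees),
                                       models = c("bm", "ou", "bms", "oum", "oumv"),
                                       seed = NULL) {
  if (length(trees) < 2L) stop("supply at least 2 trees")
  seeds <- child_seeds(seed %||% 1L, n_samples)
  best <- character(n_samples)
  for (i in seq_len(n_samples)) {
    tr <- trees[[(i - 1L) %% length(trees) + 1L]]
    paint <- stochastic_map(tr, niche, n_maps = 1L, seed = seeds[[i]])[[1L]]
    fit <- tryCatch(fit_multiregime(paint, trait, models = models,
                                    seed = seeds[[i]]),
                    error = function(e) NULL)
    best[i] <- if (is.null(fit)) NA_character_ else fit$best
  }
  wins <- table(factor(best, levels = models))
  structure(list(wins = wins, best = best, models = models),
            class = "posterior_tally")
}

#' @export
print.posterior_tally <- function(x, ...) {
  cat("Model preference across", length(x$best), "posterior samples:\n")
  print(x$wins)
  invisible(x)
}
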