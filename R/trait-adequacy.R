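# Simulation-based adequacy of a fitted continuous-trait model, via
# contrast statistics on the unit-rate rescaled tree.

#' Rescale a tree to unit rate under a fitted trait model
#'
#' Transforms branch lengths so that the fitted model becomes Brownian
#' motion with variance 1 on the rescaled tree: node heights h (time since
#' the root) map to
#' BM `sigma2 * h`; lambda: internal heights scaled by lambda, tip heights
#' kept (then times sigma2); ACDC `sigma2 * (e^{g h} - 1)/g`; stationary OU
#' `sigma2/(2 alpha) * e^{-2 alpha (T - h)}`.
#'
#' @param fit a `trait_fit`.
#' @return the rescaled tree (a "phylo"; generally not ultrametric in
#'   trait-variance units).
#' @export
rescale_tree <- function(fit) {
  tree <- fit$tree
  n <- ape::Ntip(tree)
  h <- tree$crown_age - tree$node_age      # height above the root
  Tmax <- tree$crown_age
  p <- fit$par
  hh <- switch(fit$model,
    BM = p[["sigma2"]] * h,
    lambda = {
      # internal heights scale by lambda; tips keep the full variance
      out <- p[["sigma2"]] * p[["lambda"]] * h
      out[seq_len(n)] <- p[["sigma2"]] * Tmax
      out
    },
    ACDC = {
      g <- p[["g"]]
      if (abs(g) < 1e-10) p[["sigma2"]] * h
      else p[["sigma2"]] * (exp(g * h) - 1) / g
    },
    OU = {
      a <- p[["alpha"]]
      p[["sigma2"]] / (2 * a) * exp(-2 * a * (Tmax - h))
    })
  out <- tree
  out$edge.length <- hh[out$edge[, 2L]] - hh[out$edge[, 1L]]
  out$node_age <- NULL; out$crown_age <- NULL
  class(out) <- "phylo"
  out
}

contrast_stats <- function(x, rescaled, node_age) {
  pc <- ape::pic(x, rescaled, var.contrasts = TRUE)
  cc <- pc[, 1L]; vv <- pc[, 2L]
  ac <- abs(cc)
  c(m_sig = mean(cc^2),
    cv = sd(ac) / mean(ac),
    s_age = unname(coef(lm(ac ~ node_age))[2L]),
    s_sd = unname(coef(lm(ac ~ sqrt(vv)))[2L]),
    ks = unname(ks.test(cc, pnorm)$statistic))
}

#' Adequacy of a fitted continuous-trait model
#'
#' Rescales the tree to unit rate under the fitted model, computes
#' contrast-based statistics on the observed data (mean squared standardized
#' contrast, coefficient of variation of absolute contrasts, slope of
#' absolute contrasts on node age, slope on contrast standard deviation, and
#' the Kolmogorov--Smirnov distance of the contrasts from standard normal),
#' simulates `n_sims` datasets from the fitted model, and reports the
#' observed statistics' two-sided quantiles in the simulated distributions.
#' Quantiles outside `[0.025, 0.975]` flag inadequacy.
#'
#' @param fit a `trait_fit` (carries its tree and data).
#' @param n_sims number of simulated datasets (default 1000).
#' @param seed optional integer seed.
#' @return object of class `trait_adequacy` with `quantiles`, `observed`,
#'   `simulated` and an `adequate` flag.
#' @export
trait_adequacy <- function(fit, n_sims = 1000L, seed = NULL) {
  stopifnot(inherits(fit, "trait_fit"))
  tree <- fit$tree
  n <- ape::Ntip(tree)
  resc <- rescale_tree(fit)
  node_age <- tree$node_age[(n + 1L):(n + tree$Nnode)]
  obs <- contrast_stats(fit$trait, resc, node_age)
  # simulate from the fitted multivariate normal
  C <- ape::vcv(tree); D <- patristic_matrix(tree)
  shape <- switch(fit$model, BM = NULL, OU = c(alpha = fit$par[["alpha"]]),
                  lambda = c(lambda = fit$par[["lambda"]]),
                  ACDC = c(g = fit$par[["g"]]))
  V0 <- trait_structure(fit$model, C, D, as.list(shape), fit$root)
  scale <- switch(fit$model, OU = fit$par[["sigma2"]] / (2 * fit$par[["alpha"]]),
                  fit$par[["sigma2"]])
  V <- scale * V0
  mu <- rep(fit$par[[if (fit$model == "OU") "theta" else "mean"]], n)
  L <- chol(V)
  sims <- with_seed(seed %||% 1L, {
    t(vapply(seq_len(n_sims), function(i) {
      y <- setNames(drop(mu + crossprod(L, rnorm(n))), tree$tip.label)
      contrast_stats(y, resc, node_age)
    }, obs))
  })
  q <- vapply(names(obs), function(s)
    (sum(sims[, s] < obs[s]) + 0.5 * sum(sims[, s] == obs[s])) / n_sims, 0)
  structure(list(quantiles = q, observed = obs, simulated = sims,
                 n_sims = n_sims,
                 adequate = all(q >= 0.025 & q <= 0.975)),
            class = "trait_adequacy")
}

#' @export
print.trait_adequacy <- function(x, ...) {
  cat("Trait model adequacy (", x$n_sims, " simulated datasets)\n", sep = "")
  tab <- data.frame(statistic = names(x$quantiles),
                    observed = signif(x$observed, 4),
                    quantile = round(x$quantiles, 3))
  print(tab, row.names = FALSE)
  cat(if (x$adequate) "  adequate: all quantiles within [0.025, 0.975]\n"
      else "  INADEQUATE: at least one statistic outside [0.025, 0.975]\n")
  invisible(x)
}
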