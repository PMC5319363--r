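# Simulation-based adequacy check for fitted diversification models.

#' Colless imbalance index
#'
#' Sum over internal nodes of the absolute difference in descendant tip
#' counts between the two daughter clades.
#'
#' @param tree a binary tree.
#' @return integer imbalance score.
#' @export
colless_index <- function(tree) {
  n <- ape::Ntip(tree)
  cnt <- c(rep(1L, n), integer(tree$Nnode))
  imb <- 0L
  po <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 1L])
  for (nd in unique(po)) {
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    cnt[nd] <- sum(cnt[kids])
    imb <- imb + abs(cnt[kids[1L]] - cnt[kids[2L]])
  }
  imb
}

adequacy_stats <- function(tree) {
  internal_edges <- tree$edge[, 2L] > ape::Ntip(tree)
  c(gamma = gamma_statistic(tree),
    colless = colless_index(tree),
    n_tips = ape::Ntip(tree),
    median_internal_edge = if (any(internal_edges))
      median(tree$edge.length[internal_edges]) else NA_real_)
}

#' Simulation-based adequacy check of a fitted birth--death model
#'
#' Simulates trees from the fitted model conditioned on the empirical crown
#' age (keeping those whose tip count falls within a window around the
#' empirical count), computes summary tree statistics (gamma, Colless
#' imbalance, tip count, median internal branch length) on each, and reports
#' the empirical tree's two-sided quantile per statistic. The model is
#' declared adequate when every quantile lies inside `[0.025, 0.975]`.
#'
#' @param tree the empirical `dated_tree`.
#' @param fit a `bd_fit` for that tree.
#' @param n_sims number of simulated trees retained (default 1000).
#' @param seed optional integer seed.
#' @param tip_window multiplicative window on the empirical tip count inside
#'   which simulated trees are accepted (default 0.5--2x).
#' @return object of class `bd_adequacy`: per-statistic quantiles, the
#'   simulated distributions, and an `adequate` flag.
#' @export
adequacy_check <- function(tree, fit, n_sims = 1000L, seed = NULL,
                           tip_window = c(0.5, 2)) {
  tree <- as_dated_tree(tree)
  n <- ape::Ntip(tree)
  lam_fun <- bd_lambda_fun(fit$model, fit$par)
  mu_fun <- bd_mu_fun(fit$model, fit$par)
  lo <- max(3L, floor(tip_window[1L] * n)); hi <- ceiling(tip_window[2L] * n)
  sims <- vector("list", n_sims)
  kept <- 0L; tried <- 0L
  seeds <- child_seeds(seed %||% 1L, 1L)[[1L]]
  rng_seed <- seeds
  while (kept < n_sims) {
    tried <- tried + 1L
    if (tried > 100L * n_sims)
      stop("simulation rejection rate above 99%; fitted parameters are ",
           "incompatible with the empirical crown age and tip count")
    tr <- tryCatch(simulate_bd_tree(lam_fun, mu_fun, stop = "age",
                                    age = tree$crown_age, seed = rng_seed,
                                    max_retry = 100L),
                   error = function(e) NULL)
    rng_seed <- (rng_seed + 1L) %% .Machine$integer.max
    if (is.null(tr)) next
    m <- ape::Ntip(tr)
    if (m < lo || m > hi) next
    kept <- kept + 1L
    sims[[kept]] <- adequacy_stats(tr)
  }
  sim_stats <- do.call(rbind, sims)
  emp <- adequacy_stats(tree)
  q <- vapply(names(emp), function(s) {
    (sum(sim_stats[, s] < emp[s]) + 0.5 * sum(sim_stats[, s] == emp[s])) / kept
  }, 0)
  structure(list(quantiles = q, empirical = emp, simulated = sim_stats,
                 n_sims = kept, acceptance = kept / tried,
                 adequate = all(q >= 0.025 & q <= 0.975)),
            class = "bd_adequacy")
}

#' @export
print.bd_adequacy <- function(x, ...) {
  cat("Diversification model adequacy (", x$n_sims, " simulated trees)\n", sep = "")
  tab <- data.frame(statistic = names(x$quantiles),
                    empirical = signif(x$empirical, 4),
                    quantile = round(x$quantiles, 3))
  print(tab, row.names = FALSE)
  cat(if (x$adequate) "  adequate: all quantiles within [0.025, 0.975]\n"
      else "  INADEQUATE: at least one statistic outside [0.025, 0.975]\n")
  invisible(x)
}
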