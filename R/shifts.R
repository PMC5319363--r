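# Stepwise AICc search for diversification-rate shifts.
#
# The likelihood decomposes per edge: each edge from young age v to old age u
# contributes log Q(u) - log Q(v) under its regime's (constant) rates, each
# non-root internal node contributes log lambda at its age under the regime
# of the edges below it, a tip standing for m species contributes
# (m - 1) * log beta(stem age) (the geometric tail of the constant-rate
# taxon-count distribution), and the background regime carries the crown
# survival conditioning -2 log F(crown age). A shift placed on an edge
# claims that edge and every descendant edge not already claimed by a more
# recent (nested) shift; each regime's rates are estimated independently
# (pure birth or birth--death, whichever AIC prefers), which is exactly the
# partition approximation of stepwise shift searches.

# geometric parameter of the constant-rate taxon-count distribution
bd_beta <- function(t, lambda, mu) {
  r <- lambda - mu
  ifelse(abs(r) < 1e-12,
         lambda * t / (1 + lambda * t),
         lambda * (exp(r * t) - 1) / (lambda * exp(r * t) - mu))
}

# per-regime data: ages of edge endpoints, internal-node ages, richness tips
regime_data <- function(info, edges, is_root_regime) {
  chd <- info$edge[edges, 2L]
  internal <- chd > info$ntip
  tips <- chd[!internal]
  m <- info$m[tips]
  rich <- m > 1L
  list(old = info$age[info$edge[edges, 1L]],
       young = info$age[chd],
       node_ages = info$age[chd[internal]],
       tip_stem = info$age[info$edge[edges, 1L]][!internal][rich],
       tip_m = m[rich],
       root = is_root_regime, crown = info$crown)
}

regime_ll <- function(lambda, mu, d) {
  if (lambda <= 0 || mu < 0) return(-Inf)
  logF <- function(t) log(const_F(t, lambda, mu, 1))
  logQ <- function(t) 2 * logF(t) - (lambda - mu) * t
  ll <- sum(logQ(d$old)) - sum(logQ(d$young)) +
    length(d$node_ages) * log(lambda)
  if (length(d$tip_m))
    ll <- ll + sum((d$tip_m - 1) * log(bd_beta(d$tip_stem, lambda, mu)))
  if (d$root) ll <- ll - 2 * logF(d$crown)
  if (!is.finite(ll)) -Inf else ll
}

# ML fit of one regime; pure birth and birth--death compared by AIC.
fit_regime <- function(d) {
  L_tot <- sum(d$old - d$young)
  n_nodes <- length(d$node_ages)
  # with rho = 1 and mu = 0 survival is certain, so the pure-birth MLE is
  # closed form (n_nodes / total regime length) whenever no richness terms
  # enter; a regime with no internal nodes has lambda-hat -> 0
  lam_hat <- if (n_nodes > 0L) n_nodes / max(L_tot, 1e-9) else 1e-8
  if (length(d$tip_m) == 0L) {
    yule <- list(lambda = lam_hat, mu = 0, ll = regime_ll(lam_hat, 0, d), k = 1L)
  } else {
    o <- optimize(function(x) -regime_ll(exp(x), 0, d),
                  interval = log(lam_hat) + c(-7, 7), tol = 1e-9)
    yule <- list(lambda = exp(o$minimum), mu = 0, ll = -o$objective, k = 1L)
  }
  # birth--death, parameterized as (lambda, relative extinction eps = mu/lambda)
  # with eps bounded in (0, 0.99]: an unbounded eps lets a small regime that
  # carries the crown-conditioning term inflate its likelihood without limit
  ob <- function(x) {
    lam <- exp(x[1L]); eps <- 0.99 * plogis(x[2L])
    -regime_ll(lam, eps * lam, d)
  }
  res <- tryCatch(optim(c(log(yule$lambda), qlogis(0.2)), ob,
                        method = "Nelder-Mead",
                        control = list(maxit = 500L, reltol = 1e-10)),
                  error = function(e) NULL)
  bd <- if (!is.null(res) && is.finite(res$value))
    list(lambda = exp(res$par[1L]),
         mu = 0.99 * plogis(res$par[2L]) * exp(res$par[1L]),
         ll = -res$value, k = 2L)
  else list(lambda = yule$lambda, mu = 0, ll = -Inf, k = 2L)
  # pick by AIC contribution (shared n_obs makes this the AICc-optimal choice
  # up to the joint small-sample correction)
  if (-2 * bd$ll + 2 * bd$k < -2 * yule$ll + 2 * yule$k) bd else yule
}

shift_tree_info <- function(tree, richness = NULL) {
  tree <- as_dated_tree(tree)
  ntip <- ape::Ntip(tree)
  list(tree = tree, edge = tree$edge, ntip = ntip, age = tree$node_age,
       crown = tree$crown_age, m = unname(tip_richness(tree, richness)),
       nedge = nrow(tree$edge),
       desc = edge_descendants(tree))
}

# list: for each edge, the indices of all edges in the subtree below it
# (including itself)
edge_descendants <- function(tree) {
  ne <- nrow(tree$edge)
  kids <- split(seq_len(ne), tree$edge[, 1L])  # edges by parent node
  out <- vector("list", ne)
  # postorder over edges so descendants are resolved before ancestors
  po <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 2L])
  idx_by_child <- match(seq_len(max(tree$edge)), tree$edge[, 2L])
  for (ch in po) {
    e <- idx_by_child[ch]
    if (is.na(e)) next
    below <- kids[[as.character(ch)]]
    out[[e]] <- c(e, unlist(out[below], use.names = FALSE))
  }
  out
}

config_aicc <- function(regime_fits, n_shifts, n_obs) {
  ll <- sum(vapply(regime_fits, `[[`, 0, "ll"))
  k <- sum(vapply(regime_fits, `[[`, 0L, "k")) + n_shifts
  aicc(ll, k, n_obs)
}

# one greedy step: best candidate shift given the current assignment
best_step <- function(info, assign, regime_fits, shift_edges) {
  base_aicc <- config_aicc(regime_fits, length(shift_edges), info$ntip)
  best <- NULL
  for (e in seq_len(info$nedge)) {
    if (e %in% shift_edges) next
    donor <- assign[e]
    claimed <- info$desc[[e]]
    claimed <- claimed[assign[claimed] == donor]
    rest <- which(assign == donor)
    rest <- setdiff(rest, claimed)
    if (length(rest) == 0L) next  # donor regime must keep at least one edge
    new_assign <- assign
    rid <- length(regime_fits) + 1L
    new_assign[claimed] <- rid
    fit_new <- fit_regime(regime_data(info, claimed, is_root_regime = FALSE))
    fit_donor <- fit_regime(regime_data(info, rest, is_root_regime = donor == 1L))
    fits <- regime_fits
    fits[[donor]] <- fit_donor
    fits[[rid]] <- fit_new
    a <- config_aicc(fits, length(shift_edges) + 1L, info$ntip)
    if (is.null(best) || a < best$aicc)
      best <- list(edge = e, aicc = a, assign = new_assign, fits = fits,
                   improvement = base_aicc - a)
  }
  best
}

#' Stepwise AICc search for diversification-rate shifts
#'
#' Greedy stepwise addition of the single best rate-shift breakpoint per
#' iteration (each regime fitted as pure birth or constant birth--death,
#' whichever AIC prefers), stopping when the best AICc improvement falls
#' below the calibrated threshold or `max_shifts` is reached. Shifts may sit
#' on internal or terminal branches; unsampled diversity enters as per-tip
#' richness (missing species assigned to their genus tip).
#'
#' @param tree a `dated_tree`.
#' @param richness optional richness table (columns `tip_label`,
#'   `n_species`); tips absent from it count as one species.
#' @param threshold delta-AICc acceptance threshold, normally from
#'   [calibrate_threshold()].
#' @param max_shifts maximum number of shifts to add.
#' @return object of class `shift_config`: accepted shifts (edge, clade tips,
#'   regime rates), background rates, AICc trace.
#' @export
stepwise_search <- function(tree, richness = NULL, threshold, max_shifts = 5L) {
  info <- shift_tree_info(tree, richness)
  assign <- rep(1L, info$nedge)
  fits <- list(fit_regime(regime_data(info, seq_len(info$nedge), TRUE)))
  shift_edges <- integer(0L)
  trace <- config_aicc(fits, 0L, info$ntip)
  repeat {
    if (length(shift_edges) >= max_shifts) break
    step <- best_step(info, assign, fits, shift_edges)
    if (is.null(step) || step$improvement < threshold) break
    assign <- step$assign
    fits <- step$fits
    shift_edges <- c(shift_edges, step$edge)
    trace <- c(trace, step$aicc)
  }
  shifts <- lapply(seq_along(shift_edges), function(i) {
    e <- shift_edges[i]
    node <- info$edge[e, 2L]
    tips <- if (node <= info$ntip) info$tree$tip.label[node]
            else info$tree$tip.label[intersect(
              unique(info$edge[info$desc[[e]], 2L]), seq_len(info$ntip))]
    f <- fits[[i + 1L]]
    list(edge = e, node = node, stem_age = info$age[info$edge[e, 1L]],
         tips = tips, lambda = f$lambda, mu = f$mu)
  })
  structure(list(tree = info$tree, threshold = threshold,
                 background = fits[[1L]][c("lambda", "mu")],
                 shifts = shifts, n_shifts = length(shift_edges),
                 aicc_trace = trace, assignment = assign),
            class = "shift_config")
}

#' @export
print.shift_config <- function(x, ...) {
  cat("Stepwise diversification-shift search (threshold dAICc = ",
      format(x$threshold, digits = 5), ")\n", sep = "")
  cat("  background: lambda = ", format(x$background$lambda, digits = 4),
      ", mu = ", format(x$background$mu, digits = 4), "\n", sep = "")
  if (x$n_shifts == 0L) cat("  no rate shifts accepted\n")
  else for (s in x$shifts)
    cat("  shift on stem of ", length(s$tips), "-tip clade (",
        paste(head(s$tips, 3L), collapse = ","),
        if (length(s$tips) > 3L) ",..." else "", "): lambda = ",
        format(s$lambda, digits = 4), ", mu = ", format(s$mu, digits = 4),
        "\n", sep = "")
  invisible(x)
}

#' Calibrate the shift-acceptance threshold by simulation
#'
#' Simulates `n_sims` single-regime constant-rate trees, records for each the
#' AICc improvement of the best single shift, and returns the smallest
#' threshold under which no simulated tree accepts a shift (the maximum
#' improvement plus a small guard epsilon). This is the false-positive
#' control for [stepwise_search()].
#'
#' @param template_size tip count of the simulated calibration trees.
#' @param lambda,mu generating rates (lineages/My); defaults 0.15 and 0.05.
#' @param n_sims number of calibration trees (>= 20).
#' @param seed integer seed.
#' @param epsilon strict-inequality guard added to the maximum improvement.
#' @return object of class `shift_threshold` with elements `threshold` and
#'   `improvements`.
#' @export
calibrate_threshold <- function(template_size = 120L, lambda = 0.15, mu = 0.05,
                                n_sims = 100L, seed = NULL, epsilon = 0.01) {
  if (n_sims < 20L) stop("n_sims must be at least 20")
  seeds <- child_seeds(seed %||% 1L, n_sims)
  imp <- vapply(seeds, function(s) {
    tr <- simulate_bd_tree(lambda, mu, stop = "taxa", n = template_size, seed = s)
    best_first_improvement(tr)
  }, 0)
  structure(list(threshold = max(imp) + epsilon, improvements = imp,
                 template_size = template_size, lambda = lambda, mu = mu),
            class = "shift_threshold")
}

# AICc improvement of the best single shift on a tree (no acceptance rule)
best_first_improvement <- function(tree, richness = NULL) {
  info <- shift_tree_info(tree, richness)
  fits <- list(fit_regime(regime_data(info, seq_len(info$nedge), TRUE)))
  step <- best_step(info, rep(1L, info$nedge), fits, integer(0L))
  if (is.null(step)) 0 else step$improvement
}

#' @export
print.shift_threshold <- function(x, ...) {
  cat("Calibrated shift threshold: dAICc = ", format(x$threshold, digits = 5),
      " (", length(x$improvements), " trees of ", x$template_size,
      " tips at lambda = ", x$lambda, ", mu = ", x$mu, ")\n", sep = "")
  invisible(x)
}
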