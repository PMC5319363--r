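# Discrete-niche evolution: regime paintings, Mk ancestral-state
# reconstruction and stochastic character mapping.

#' Regime painting of a tree
#'
#' Assigns a niche state to every branch segment. Segments on each edge are
#' stored rootward-to-tipward as a named numeric vector of lengths (names are
#' states), in the row order of `tree$edge` -- the same layout "simmap" trees
#' use, so stochastic maps convert losslessly.
#'
#' @param tree a `dated_tree`.
#' @param maps list (one element per edge row) of named segment-length
#'   vectors.
#' @param source provenance label, e.g. "marginal-ASR", "stochastic-map" or
#'   "true-history".
#' @param node_state optional character vector of internal-node states.
#' @param tip_state optional named vector of observed tip states; when given,
#'   each terminal edge's last segment is checked against it.
#' @return object of class `regime_paint`.
#' @export
regime_paint <- function(tree, maps, source = "manual", node_state = NULL,
                         tip_state = NULL) {
  tree <- as_dated_tree(tree)
  if (length(maps) != nrow(tree$edge))
    stop("`maps` must have one element per edge")
  lens <- vapply(maps, sum, 0)
  if (any(abs(lens - tree$edge.length) > 1e-6 * max(tree$crown_age, 1)))
    stop("segments do not tile the branches: segment sums differ from edge lengths")
  if (!is.null(tip_state)) {
    n <- ape::Ntip(tree)
    term <- which(tree$edge[, 2L] <= n)
    last <- vapply(maps[term], function(m) names(m)[length(m)], "")
    obs <- tip_state[tree$tip.label[tree$edge[term, 2L]]]
    if (any(last != obs))
      stop("tip segment state disagrees with the observed tip state for: ",
           paste(head(tree$tip.label[tree$edge[term, 2L]][last != obs], 5L),
                 collapse = ", "))
  }
  states <- sort(unique(unlist(lapply(maps, names))))
  structure(list(tree = tree, maps = maps, states = states, source = source,
                 node_state = node_state,
                 mrca = ape::mrca(tree)),   # cached for the OU covariance
            class = "regime_paint")
}

#' @export
print.regime_paint <- function(x, ...) {
  nseg <- sum(lengths(x$maps))
  cat("Regime painting (", x$source, "): ", length(x$states), " states [",
      paste(x$states, collapse = ", "), "], ", nseg, " segments on ",
      length(x$maps), " edges\n", sep = "")
  invisible(x)
}

# Total time spent in each state (useful summaries and sanity checks).
#' Time spent in each regime of a painting
#' @param paint a [regime_paint()].
#' @return named numeric vector of summed segment lengths per state.
#' @export
regime_times <- function(paint) {
  seg <- unlist(paint$maps)
  tapply(seg, names(seg), sum)[paint$states]
}

# Convert one phytools "simmap" tree to a regime_paint.
simmap_to_paint <- function(sm, source = "stochastic-map") {
  tree <- sm
  tree$maps <- NULL; tree$mapped.edge <- NULL; tree$Q <- NULL; tree$logL <- NULL
  class(tree) <- "phylo"
  regime_paint(as_dated_tree(tree), sm$maps, source = source)
}

#' Mk ancestral-state reconstruction of a discrete niche
#'
#' Fits an Mk model (equal-rates by default, symmetric optional) by maximum
#' likelihood, computes marginal state probabilities at every internal node
#' by the pruning/re-rooting method, and returns the maximum-a-posteriori
#' regime painting: every branch takes its parent node's MAP state, except
#' that a terminal branch whose tip state disagrees is split at its midpoint
#' so the tipward segment honours the observed state.
#'
#' @param tree a `dated_tree`.
#' @param niche named character vector of tip states (>= 2 observed states
#'   for a non-trivial fit).
#' @param model "ER" (single rate; default) or "SYM" (symmetric rates).
#' @return object of class `mk_asr`: `Q`, `logL`, `marginal` (matrix of
#'   internal-node state probabilities, ape node order), `node_map` (MAP
#'   states) and `paint` (a [regime_paint()]).
#' @export
mk_asr <- function(tree, niche, model = c("ER", "SYM")) {
  model <- match.arg(model)
  tree <- as_dated_tree(tree)
  x <- as.character(niche[tree$tip.label])
  if (any(is.na(x))) stop("niche states missing for some tips")
  names(x) <- tree$tip.label
  states <- sort(unique(x))
  n <- ape::Ntip(tree)
  if (length(states) == 1L) {
    warning("single observed state; returning the trivial painting")
    maps <- lapply(tree$edge.length, function(l) setNames(l, states))
    marg <- matrix(1, tree$Nnode, 1L, dimnames = list(NULL, states))
    paint <- regime_paint(tree, maps, source = "marginal-ASR",
                          node_state = rep(states, tree$Nnode), tip_state = x)
    return(structure(list(Q = matrix(0, 1, 1, dimnames = list(states, states)),
                          logL = 0, marginal = marg,
                          node_map = rep(states, tree$Nnode), paint = paint),
                     class = "mk_asr"))
  }
  fit <- phytools::fitMk(tree, x, model = model)
  Q <- as.Qmatrix_to_matrix(fit)
  anc <- phytools::ancr(fit)
  marg <- anc$ace                                 # rows: nodes n+1 .. n+Nnode
  if (is.null(dim(marg))) marg <- matrix(marg, 1L, dimnames = list(NULL, names(marg)))
  marg <- as.matrix(marg)[, states, drop = FALSE]
  node_map <- states[max.col(marg, ties.method = "first")]
  paint <- map_paint_from_nodes(tree, node_map, x)
  structure(list(Q = Q, logL = fit$logLik, marginal = marg,
                 node_map = node_map, paint = paint),
            class = "mk_asr")
}

as.Qmatrix_to_matrix <- function(fit) {
  Q <- matrix(0, length(fit$states), length(fit$states),
              dimnames = list(fit$states, fit$states))
  im <- fit$index.matrix
  im[is.na(im)] <- 0L
  Q[] <- c(0, fit$rates)[im + 1L]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# MAP painting: branch = parent's MAP state; terminal branches disagreeing
# with the observed tip state are split at the midpoint.
map_paint_from_nodes <- function(tree, node_map, tip_state) {
  n <- ape::Ntip(tree)
  maps <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; chd <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    ps <- node_map[par - n]
    if (chd <= n) {
      ts <- tip_state[[tree$tip.label[chd]]]
      maps[[e]] <- if (identical(ps, ts)) setNames(len, ps)
                   else setNames(c(len / 2, len / 2), c(ps, ts))
    } else {
      maps[[e]] <- setNames(len, ps)
    }
  }
  regime_paint(tree, maps, source = "marginal-ASR", node_state = node_map,
               tip_state = tip_state)
}

#' @export
print.mk_asr <- function(x, ...) {
  cat("Mk ancestral-state reconstruction: ", ncol(x$marginal), " states, logL = ",
      format(x$logL, digits = 6), "\n", sep = "")
  print(x$paint)
  invisible(x)
}

#' Stochastic character maps of a discrete niche
#'
#' Draws complete character histories conditioned on the tip states and a
#' rate matrix (stochastic mapping). Tip states are honoured by construction.
#'
#' @param tree a `dated_tree`.
#' @param niche named character vector of tip states.
#' @param Q fixed rate matrix; if NULL the ML matrix under `model` is used.
#' @param n_maps number of maps to draw.
#' @param model Mk structure used when `Q` is NULL ("ER" or "SYM").
#' @param seed optional integer seed.
#' @return list of [regime_paint()] objects.
#' @export
stochastic_map <- function(tree, niche, Q = NULL, n_maps = 1L,
                           model = "ER", seed = NULL) {
  tree <- as_dated_tree(tree)
  x <- as.character(niche[tree$tip.label])
  names(x) <- tree$tip.label
  with_seed(seed, {
    sm <- if (is.null(Q))
      phytools::make.simmap(tree, x, model = model, nsim = n_maps,
                            message = FALSE)
    else phytools::make.simmap(tree, x, Q = Q, nsim = n_maps, message = FALSE)
    if (n_maps == 1L) sm <- list(sm)
    lapply(sm, simmap_to_paint)
  })
}
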