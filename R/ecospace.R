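# Phylogeny-corrected multidimensional ecospace: Gower dissimilarity on
# mixed traits, residuals of a matrix regression of trait dissimilarity on
# phylogenetic distance, NMDS embedding, and convex-hull areas.

#' Gower dissimilarity for mixed continuous/categorical traits
#'
#' `d_ij` is the mean over variables of per-variable dissimilarity:
#' range-normalized absolute difference for continuous variables, 0/1
#' mismatch for categorical ones. A continuous variable with zero range is
#' dropped with a warning.
#'
#' @param data data frame of species traits (rownames = species): numeric
#'   columns are continuous, factor/character columns categorical.
#' @return symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @export
gower_matrix <- function(data) {
  stopifnot(is.data.frame(data), nrow(data) >= 2L)
  if (anyNA(data)) stop("missing cells are not allowed")
  sp <- rownames(data)
  n <- nrow(data)
  acc <- matrix(0, n, n, dimnames = list(sp, sp))
  used <- 0L
  for (j in seq_along(data)) {
    v <- data[[j]]
    if (is.numeric(v)) {
      rng <- diff(range(v))
      if (rng == 0) {
        warning("continuous variable '", names(data)[j],
                "' has zero range; dropped")
        next
      }
      acc <- acc + abs(outer(v, v, `-`)) / rng
    } else {
      v <- as.character(v)
      acc <- acc + outer(v, v, `!=`) * 1
    }
    used <- used + 1L
  }
  if (used == 0L) stop("no usable variables")
  acc / used
}

#' Residuals of a matrix regression of trait on phylogenetic dissimilarity
#'
#' Ordinary least squares (intercept + slope) of the vectorized lower
#' triangle of `D_trait` on that of `D_phylo`; residuals are refolded into a
#' symmetric zero-diagonal matrix. This removes the component of trait
#' dissimilarity explained by shared ancestry before ordination.
#'
#' @param D_trait,D_phylo symmetric matrices over the same species (same
#'   order).
#' @return list with `residuals` (symmetric matrix), `intercept`, `slope`.
#' @export
phylo_residual <- function(D_trait, D_phylo) {
  stopifnot(identical(dim(D_trait), dim(D_phylo)))
  if (!is.null(rownames(D_trait)) && !is.null(rownames(D_phylo)) &&
      !identical(rownames(D_trait), rownames(D_phylo)))
    stop("species order differs between the two matrices")
  lt <- lower.tri(D_trait)
  x <- D_phylo[lt]; y <- D_trait[lt]
  if (var(x) == 0) stop("phylogenetic distances are constant; regression undefined")
  fit <- lm(y ~ x)
  R <- matrix(0, nrow(D_trait), ncol(D_trait), dimnames = dimnames(D_trait))
  R[lt] <- stats::residuals(fit)
  R <- R + t(R)
  list(residuals = R, intercept = unname(coef(fit)[1L]),
       slope = unname(coef(fit)[2L]))
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Best-of-`n_starts` Kruskal stress-1 minimization (monotone regression
#' NMDS). Residual dissimilarities may be negative; they are shifted by
#' their minimum before embedding, which preserves ranks and therefore the
#' NMDS solution.
#'
#' @param D symmetric dissimilarity (or residual) matrix.
#' @param k embedding dimension (default 2).
#' @param n_starts random starts (default 50).
#' @param seed optional integer seed; fixes the embedding.
#' @return object of class `ecospace_embedding`: `points` (n x k, centered),
#'   `stress` (Kruskal stress-1, in [0, 1)), `k`.
#' @export
nmds_embed <- function(D, k = 2L, n_starts = 50L, seed = NULL) {
  stopifnot(isSymmetric(unname(as.matrix(D))))
  M <- as.matrix(D)
  if (min(M) < 0) M <- M - min(M)
  diag(M) <- 0
  d <- stats::as.dist(M)
  with_seed(seed %||% 1L, {
    best <- NULL
    init <- cmdscale(d, k = k)
    for (i in seq_len(n_starts)) {
      start <- if (i == 1L) init else matrix(rnorm(length(init)), ncol = k)
      fit <- tryCatch(
        vegan::monoMDS(d, y = start, k = k, model = "global",
                       maxit = 500L, smin = 1e-6, sfgrmin = 1e-8),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    if (is.null(best)) stop("all NMDS starts failed to converge")
    pts <- scale(best$points, center = TRUE, scale = FALSE)
    dimnames(pts) <- list(attr(d, "Labels"), paste0("MDS", seq_len(k)))
    structure(list(points = pts, stress = best$stress, k = k),
              class = "ecospace_embedding")
  })
}

#' @export
print.ecospace_embedding <- function(x, ...) {
  cat("NMDS embedding: ", nrow(x$points), " species in ", x$k,
      " dimensions, Kruskal stress-1 = ", format(x$stress, digits = 4),
      "\n", sep = "")
  invisible(x)
}

# shoelace polygon area of the convex hull of a 2-D point set
hull_area <- function(pts) {
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  if (nrow(pts) < 3L) return(0)
  h <- chull(pts)
  xy <- pts[h, , drop = FALSE]
  x <- xy[, 1L]; y <- xy[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Convex-hull areas of species groups in an embedding
#'
#' Planar convex-hull areas for named species groups, plus the contraction
#' ratio `area(extant) / area(all)` when groups named "extant" and "all" are
#' present. Groups with fewer than 3 non-collinear points get area 0 and a
#' flag.
#'
#' @param embedding an `ecospace_embedding` (or a 2-column coordinate
#'   matrix with species rownames).
#' @param groups named list of character vectors of species.
#' @return object of class `hull_table`: data frame `areas` (group, n, area,
#'   degenerate) and `contraction` (or NA).
#' @export
hull_areas <- function(embedding, groups) {
  pts <- if (inherits(embedding, "ecospace_embedding")) embedding$points
         else as.matrix(embedding)
  stopifnot(ncol(pts) >= 2L)
  pts <- pts[, 1:2, drop = FALSE]
  areas <- vapply(groups, function(g) {
    miss <- setdiff(g, rownames(pts))
    if (length(miss)) stop("species not in the embedding: ",
                           paste(head(miss, 5L), collapse = ", "))
    hull_area(pts[g, , drop = FALSE])
  }, 0)
  tab <- data.frame(group = names(groups),
                    n = lengths(groups),
                    area = unname(areas),
                    degenerate = lengths(groups) < 3L | unname(areas) == 0)
  contraction <- if (all(c("extant", "all") %in% names(groups)) &&
                     areas[["all"]] > 0)
    areas[["extant"]] / areas[["all"]] else NA_real_
  structure(list(areas = tab, contraction = contraction), class = "hull_table")
}

#' @export
print.hull_table <- function(x, ...) {
  cat("Ecospace convex-hull areas\n")
  tab <- x$areas; tab$area <- signif(tab$area, 5)
  print(tab, row.names = FALSE)
  if (!is.na(x$contraction))
    cat("Contraction ratio area(extant)/area(all) =",
        format(x$contraction, digits = 4), "\n")
  invisible(x)
}

#' Full ecospace construction from a mixed trait table
#'
#' Convenience wrapper: Gower dissimilarity, phylogenetic residual
#' correction, NMDS, and hulls for extant vs all species.
#'
#' @param tree a `dated_tree` covering the species.
#' @param data mixed trait data frame (rownames = species).
#' @param extinct named logical vector flagging extinct species.
#' @param k,n_starts,seed passed to [nmds_embed()].
#' @return list with `gower`, `residual`, `embedding`, `hulls`.
#' @export
build_ecospace <- function(tree, data, extinct, k = 2L, n_starts = 50L,
                           seed = NULL) {
  tree <- as_dated_tree(tree)
  sp <- intersect(tree$tip.label, rownames(data))
  data <- data[sp, , drop = FALSE]
  if (length(sp) < ape::Ntip(tree)) tree <- as_dated_tree(ape::keep.tip(tree, sp))
  G <- gower_matrix(data)
  P <- patristic_matrix(tree)[sp, sp]
  res <- phylo_residual(G, P)
  emb <- nmds_embed(res$residuals, k = k, n_starts = n_starts, seed = seed)
  ext <- names(extinct)[extinct]
  hulls <- hull_areas(emb, list(all = sp, extant = setdiff(sp, ext)))
  list(gower = G, residual = res, embedding = emb, hulls = hulls)
}

#' Plot an ecospace embedding with group hulls
#'
#' @param x an `ecospace_embedding`.
#' @param groups optional named list of species groups to outline.
#' @param ... passed to [plot()].
#' @export
plot.ecospace_embedding <- function(x, groups = NULL, ...) {
  pts <- x$points
  plot(pts, xlab = "MDS1", ylab = "MDS2", pch = 19, cex = 0.6, ...)
  if (!is.null(groups)) {
    for (i in seq_along(groups)) {
      g <- pts[groups[[i]], , drop = FALSE]
      if (nrow(g) >= 3L) {
        h <- chull(g)
        polygon(g[c(h, h[1L]), ], border = i + 1L)
      }
    }
    legend("topright", names(groups), col = seq_along(groups) + 1L,
           lty = 1, bty = "n")
  }
  invisible(x)
}
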