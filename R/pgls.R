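# Phylogenetic generalized least squares of a continuous trait on a
# categorical niche, with four correlation structures (BM, Pagel's lambda,
# OU/Martins, ACDC/Blomberg) whose parameters are profiled by maximum
# likelihood, and AICc model averaging of coefficients.
#
# Niche levels enter with sum-to-zero contrasts, so coefficients are
# deviations of each niche's expected trait value from the grand mean.

pgls_corstruct <- function(corr, par, phy, form) {
  switch(corr,
    BM = ape::corBrownian(1, phy, form = form),
    lambda = ape::corPagel(par, phy, form = form, fixed = TRUE),
    OU = ape::corMartins(par, phy, form = form, fixed = TRUE),
    ACDC = ape::corBlomberg(par, phy, form = form, fixed = TRUE))
}

pgls_gls <- function(dat, phy, corr, par) {
  cs <- pgls_corstruct(corr, par, phy, form = ~species)
  nlme::gls(ln_mass ~ niche, data = dat, correlation = cs, method = "ML")
}

#' Phylogenetic GLS of a trait on niche categories
#'
#' Regresses the trait on a categorical niche variable under a phylogenetic
#' correlation structure whose parameter (Pagel's lambda, the OU constraint
#' alpha, or the ACDC exponent) is estimated by profiled maximum likelihood.
#' Sum-to-zero contrasts are used, so each niche coefficient is that niche's
#' deviation from the grand mean.
#'
#' @param tree a `dated_tree`.
#' @param trait named numeric vector (tips without data are pruned).
#' @param niche named character/factor vector of niche states.
#' @param corr correlation structure: "BM", "lambda", "OU" or "ACDC".
#' @param fix_par optionally fix the correlation parameter instead of
#'   estimating it (e.g. `fix_par = 0` with `corr = "lambda"` gives ordinary
#'   least squares).
#' @return object of class `pgls_fit`: coefficients, the underlying
#'   [nlme::gls] fit, correlation parameter, `logL`, `k`, `aicc`.
#' @export
pgls_fit <- function(tree, trait, niche, corr = c("BM", "lambda", "OU", "ACDC"),
                     fix_par = NULL) {
  corr <- match.arg(corr)
  tree <- as_dated_tree(tree)
  trait <- trait[!is.na(trait)]
  sp <- Reduce(intersect, list(tree$tip.label, names(trait), names(niche)))
  if (length(sp) < ape::Ntip(tree)) tree <- as_dated_tree(ape::keep.tip(tree, sp))
  sp <- tree$tip.label
  niche <- droplevels(factor(niche[sp]))
  empty <- setdiff(levels(factor(niche)), unique(as.character(niche)))
  if (nlevels(niche) < 2L) stop("niche must have at least 2 observed levels")
  tab <- table(niche)
  if (any(tab == 0L))
    stop("empty niche level(s): ", paste(names(tab)[tab == 0L], collapse = ", "))
  dat <- data.frame(species = sp, ln_mass = unname(trait[sp]), niche = niche)
  contrasts(dat$niche) <- contr.sum(nlevels(niche))
  Tmax <- tree$crown_age
  bounds <- switch(corr, BM = NULL,
    lambda = c(1e-6, 1), OU = log(c(1e-6, 50 / Tmax)), ACDC = c(-5 / Tmax, 5 / Tmax))
  trans <- if (corr == "OU") exp else identity
  fit_at <- function(p) pgls_gls(dat, tree, corr, p)
  if (corr == "BM") {
    par <- NA_real_
    g <- fit_at(1)
  } else if (!is.null(fix_par)) {
    par <- fix_par
    g <- if (corr == "lambda" && fix_par == 0)
      nlme::gls(ln_mass ~ niche, data = dat, method = "ML")  # OLS limit
    else fit_at(fix_par)
  } else {
    safe_ll <- function(x) {
      p <- trans(x)
      if (corr == "ACDC" && abs(p) < 1e-8) p <- 1e-8
      f <- tryCatch(fit_at(p), error = function(e) NULL)
      if (is.null(f)) 1e10 else -as.numeric(logLik(f))
    }
    o <- optimize(safe_ll, interval = bounds, tol = 1e-8)
    par <- trans(o$minimum)
    if (corr == "ACDC" && abs(par) < 1e-8) par <- 1e-8
    g <- fit_at(par)
  }
  ll <- as.numeric(logLik(g))
  p_coef <- length(coef(g))
  k <- p_coef + 1L + as.integer(corr != "BM" && is.null(fix_par))  # + sigma2 (+ corr par)
  n <- nrow(dat)
  cf <- niche_deviation_coefs(g, dat$niche)
  structure(list(corr = corr, gls = g, par = par, coefficients = coef(g),
                 niche_effects = cf, logL = ll, k = k, n = n,
                 aicc = aicc(ll, k, n)),
            class = "pgls_fit")
}

# deviation-from-grand-mean effect of every niche level (sum-to-zero coding
# reports L-1 coefficients; the last level is minus their sum)
niche_deviation_coefs <- function(g, niche) {
  b <- coef(g)
  lev <- levels(niche)
  eff <- b[grep("^niche", names(b))]
  c(setNames(eff, lev[seq_along(eff)]),
    setNames(-sum(eff), lev[length(lev)]))
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit [", x$corr, " correlation",
      if (!is.na(x$par)) paste0(", parameter = ", signif(x$par, 4)), "]\n", sep = "")
  cat("  logL = ", format(x$logL, digits = 7), ",  AICc = ",
      format(x$aicc, digits = 7), "  (n = ", x$n, ")\n", sep = "")
  cat("  niche effects (deviation from grand mean):\n")
  print(signif(x$niche_effects, 4))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logL, df = object$k, nobs = object$n, class = "logLik")
}

#' PGLS over several correlation structures with model-averaged coefficients
#'
#' Fits the PGLS under BM, Pagel's lambda, OU and ACDC correlation, ranks the
#' fits by AICc, and averages coefficients across the models with delta-AICc
#' below `cutoff` (default 3) using Akaike weights.
#'
#' @inheritParams pgls_fit
#' @param corrs correlation structures to compare.
#' @param cutoff delta-AICc candidate-set rule.
#' @return object of class `pgls_set` with the AICc table, the fits, and
#'   model-averaged coefficients and niche effects.
#' @export
pgls_average <- function(tree, trait, niche,
                         corrs = c("BM", "lambda", "OU", "ACDC"), cutoff = 3) {
  fits <- lapply(corrs, function(cr) pgls_fit(tree, trait, niche, corr = cr))
  names(fits) <- corrs
  ai <- vapply(fits, `[[`, 0, "aicc")
  keep <- (ai - min(ai)) < cutoff
  w <- akaike_weights(ai[keep])
  avg <- Reduce(`+`, Map(function(f, wi) wi * f$coefficients, fits[keep], w))
  avg_eff <- Reduce(`+`, Map(function(f, wi) wi * f$niche_effects, fits[keep], w))
  tab <- data.frame(corr = corrs, AICc = ai, dAICc = ai - min(ai),
                    weight = akaike_weights(ai), candidate = keep)
  structure(list(table = tab[order(tab$dAICc), ], fits = fits,
                 coefficients = avg, niche_effects = avg_eff, cutoff = cutoff),
            class = "pgls_set")
}

#' @export
print.pgls_set <- function(x, ...) {
  cat("PGLS correlation-model comparison\n")
  tab <- x$table
  tab$AICc <- round(tab$AICc, 3); tab$dAICc <- round(tab$dAICc, 3)
  tab$weight <- round(tab$weight, 3)
  print(tab, row.names = FALSE)
  cat("Model-averaged niche effects:\n")
  print(signif(x$niche_effects, 4))
  invisible(x)
}
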