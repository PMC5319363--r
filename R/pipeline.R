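# End-to-end orchestration: diversification fits and averaging per clade,
# calibrated shift scan, mass-extinction test, trait-model comparison, PGLS,
# multi-regime fits over niche paintings, and ecospace construction, with a
# JSON manifest keyed to the four adaptive-radiation predictions:
#   (1) lineage diversification high early then slowing;
#   (2) focal-clade speciation exceeding the sister clade's;
#   (3) phenotypic evolutionary rate high early then declining;
#   (4) adaptive divergence: optima differing among niches, wider ecospace.

#' Configuration for [run_pipeline()]
#'
#' @param tree a `dated_tree` (or path to a Newick/NEXUS file).
#' @param traits data frame with rownames = species and columns
#'   `ln_mass_g` (numeric), `diet`, `activity` (categorical) and `extinct`
#'   (logical); or path to such a CSV with a `species` column.
#' @param clades named list of two character vectors of tip labels: the
#'   focal clade and its sister clade.
#' @param richness optional richness table (or CSV path).
#' @param covariate optional [covariate_curve()] (or CSV path).
#' @param extinction_age age (My) of the hypothesized mass-extinction event
#'   (default 33.9, the Eocene--Oligocene boundary).
#' @param n_calib calibration-tree count for the shift threshold.
#' @param n_adequacy simulated trees per adequacy check.
#' @param posterior optional list of trees for the posterior robustness loop
#'   (NULL skips it).
#' @param n_posterior_samples samples in the posterior robustness loop.
#' @param multiregime_models candidate set for the state-dependent stage
#'   (default: all seven models).
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory for JSON reports (NULL = no files).
#' @return a `run_config` list.
#' @export
run_config <- function(tree, traits, clades, richness = NULL, covariate = NULL,
                       extinction_age = 33.9, n_calib = 100L,
                       n_adequacy = 1000L, posterior = NULL,
                       n_posterior_samples = 20L,
                       multiregime_models = MULTIREGIME_MODELS,
                       seed = 1L, out_dir = NULL) {
  if (is.character(tree)) tree <- read_tree(tree)
  if (is.character(traits)) {
    tr <- read.csv(traits, stringsAsFactors = FALSE)
    rownames(tr) <- tr$species; tr$species <- NULL
    traits <- tr
  }
  if (is.character(richness)) richness <- read_richness(richness)
  if (is.character(covariate)) covariate <- read_covariate(covariate)
  stopifnot(all(c("ln_mass_g", "diet", "activity", "extinct") %in% names(traits)))
  missing_tips <- setdiff(as_dated_tree(tree)$tip.label, rownames(traits))
  if (length(missing_tips))
    stop("traits missing for tips: ", paste(head(missing_tips, 5L), collapse = ", "))
  structure(list(tree = as_dated_tree(tree), traits = traits, clades = clades,
                 richness = richness, covariate = covariate,
                 extinction_age = extinction_age, n_calib = n_calib,
                 n_adequacy = n_adequacy, posterior = posterior,
                 n_posterior_samples = n_posterior_samples,
                 multiregime_models = multiregime_models,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

# candidate diversification set fitted to one clade
fit_candidate_set <- function(tree, seed, rho = 1, starts = 6L) {
  specs <- list(
    `pure birth` = bd_model("constant", "zero", rho = rho),
    `constant birth-death` = bd_model("constant", "constant", rho = rho),
    `linear speciation` = bd_model("linear", "zero", rho = rho),
    `exponential speciation` = bd_model("exponential", "zero", rho = rho))
  seeds <- child_seeds(seed, length(specs))
  fits <- Map(function(spec, s, lab) fit_bd(tree, spec, starts = starts,
                                            seed = s, label = lab),
              specs, seeds, names(specs))
  compare_and_average(unname(fits), eval_age = 0)
}

#' Run the full adaptive-radiation analysis pipeline
#'
#' Executes every stage on the configured inputs and returns (and optionally
#' writes) a manifest keyed to the four predictions of adaptive-radiation
#' theory. Any stage failure is recorded in the manifest and its dependent
#' stages are skipped.
#'
#' @param config a [run_config()].
#' @return object of class `pipeline_result`: per-stage results and the
#'   manifest (also written as JSON when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- child_seeds(config$seed, 10L)
  tree <- config$tree
  out <- list()
  fail <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      fail[[name]] <<- conditionMessage(e)
      NULL
    })
    out[[name]] <<- res
    res
  }
  cl1 <- extract_clade(tree, config$clades[[1L]])
  cl2 <- extract_clade(tree, config$clades[[2L]])
  rho1 <- sampling_fraction(cl1, config$richness)
  rho2 <- sampling_fraction(cl2, config$richness)

  div1 <- stage("diversification_clade1", fit_candidate_set(cl1, seeds[[1L]], rho1))
  div2 <- stage("diversification_clade2", fit_candidate_set(cl2, seeds[[2L]], rho2))
  stage("gamma", c(clade1 = gamma_statistic(cl1), clade2 = gamma_statistic(cl2)))
  if (!is.null(config$covariate))
    stage("covariate_model", {
      fit <- covariate_bd(cl1, config$covariate, mu = "constant",
                          starts = 4L, seed = seeds[[3L]])
      best_plain <- min(div1$table$AICc)
      list(fit = fit, preferred = fit$aicc < best_plain)
    })
  stage("shift_scan", {
    thr <- calibrate_threshold(template_size = ape::Ntip(tree),
                               n_sims = config$n_calib, seed = seeds[[4L]])
    cfg <- stepwise_search(tree, richness = config$richness,
                           threshold = thr$threshold)
    list(threshold = thr, config = cfg)
  })
  stage("mass_extinction", mass_extinction_test(tree, config$extinction_age,
                                                seed = seeds[[5L]]))
  if (!is.null(div1))
    stage("adequacy", {
      best <- div1$fits[[which.min(vapply(div1$fits, `[[`, 0, "aicc"))]]
      adequacy_check(cl1, best, n_sims = config$n_adequacy, seed = seeds[[6L]])
    })

  mass <- setNames(config$traits$ln_mass_g, rownames(config$traits))
  niche <- setNames(paste(config$traits$activity, config$traits$diet, sep = "-"),
                    rownames(config$traits))
  trait_cmp <- stage("trait_models", compare_trait_models(tree, mass))
  stage("pgls", pgls_average(tree, mass, niche))
  mr <- stage("multiregime", {
    keep <- names(mass)[!is.na(mass)]
    tr2 <- as_dated_tree(ape::keep.tip(tree, intersect(tree$tip.label, keep)))
    asr <- mk_asr(tr2, niche[tr2$tip.label])
    # state-dependent models need >= 2 tips per regime; fall back to the
    # single-regime candidates when the painting leaves a regime too thin
    n2 <- ape::Ntip(tr2)
    term <- which(tr2$edge[, 2L] <= n2)
    tip_st <- vapply(asr$paint$maps[term], function(m) names(m)[length(m)], "")
    models <- if (min(table(factor(tip_st, levels = asr$paint$states))) >= 2L)
      config$multiregime_models else c("bm", "ou")
    fit_multiregime(asr$paint, mass, models = models, seed = seeds[[7L]])
  })
  if (!is.null(config$posterior))
    stage("posterior_tally",
          multiregime_over_posterior(config$posterior, mass, niche,
                                     n_samples = config$n_posterior_samples,
                                     seed = seeds[[8L]]))
  eco <- stage("ecospace", {
    dat <- data.frame(ln_mass_g = config$traits$ln_mass_g,
                      diet = config$traits$diet,
                      activity = config$traits$activity,
                      row.names = rownames(config$traits))
    dat <- dat[stats::complete.cases(dat), ]
    build_ecospace(tree, dat,
                   setNames(config$traits$extinct, rownames(config$traits)),
                   seed = seeds[[9L]])
  })

  manifest <- pipeline_manifest(config, out, fail)
  if (!is.null(config$out_dir)) write_manifest(manifest, out, config$out_dir)
  structure(list(results = out, failures = fail, manifest = manifest),
            class = "pipeline_result")
}

pipeline_manifest <- function(config, out, fail) {
  g <- out$gamma
  p1 <- if (!is.null(out$diversification_clade1)) {
    slope <- out$diversification_clade1$lambda_slope
    list(lambda_slope = slope, gamma_clade1 = unname(g["clade1"]),
         verdict = if (slope < 0) "speciation increasing toward the present (no early-burst slowdown)"
                   else if (slope > 0) "speciation declining toward the present (early-burst-like)"
                   else "constant speciation")
  }
  p2 <- if (!is.null(out$diversification_clade1) && !is.null(out$diversification_clade2)) {
    r1 <- out$diversification_clade1$lambda; r2 <- out$diversification_clade2$lambda
    list(lambda_clade1 = r1, lambda_clade2 = r2, ratio = r1 / r2,
         shift_at_clade_stem = !is.null(out$shift_scan) &&
           any(vapply(out$shift_scan$config$shifts, function(s)
             setequal(s$tips, config$clades[[1L]]), TRUE)),
         n_shifts = if (!is.null(out$shift_scan)) out$shift_scan$config$n_shifts,
         extinction_shift_supported = if (!is.null(out$mass_extinction))
           out$mass_extinction$supported)
  }
  p3 <- if (!is.null(out$trait_models)) {
    tab <- out$trait_models$table
    g_hat <- out$trait_models$fits$ACDC$par[["g"]]
    list(best_trait_model = tab$model[1L], acdc_g = g_hat,
         verdict = if (g_hat < 0) "early burst: phenotypic rate declining toward the present"
                   else "no early-burst signal in phenotypic rate")
  }
  p4 <- if (!is.null(out$multiregime)) {
    list(best_multiregime_model = out$multiregime$best,
         multiregime_weights = setNames(out$multiregime$table$weight,
                                        out$multiregime$table$model),
         ecospace_contraction = if (!is.null(out$ecospace))
           out$ecospace$hulls$contraction,
         nmds_stress = if (!is.null(out$ecospace)) out$ecospace$embedding$stress)
  }
  list(seed = config$seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       n_tips = ape::Ntip(config$tree),
       predictions = list(prediction1 = p1, prediction2 = p2,
                          prediction3 = p3, prediction4 = p4),
       failures = fail)
}

write_manifest <- function(manifest, out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  # per-stage light summaries
  summaries <- list(
    diversification_clade1 = if (!is.null(out$diversification_clade1))
      out$diversification_clade1$table,
    diversification_clade2 = if (!is.null(out$diversification_clade2))
      out$diversification_clade2$table,
    trait_models = if (!is.null(out$trait_models)) out$trait_models$table,
    multiregime = if (!is.null(out$multiregime)) out$multiregime$table,
    hull_areas = if (!is.null(out$ecospace)) out$ecospace$hulls$areas)
  for (nm in names(summaries)) {
    if (is.null(summaries[[nm]])) next
    f <- file.path(dir, paste0(nm, ".json"))
    jsonlite::write_json(summaries[[nm]], f, dataframe = "rows", digits = NA)
    files <- c(files, f)
  }
  mf <- file.path(dir, "manifest.json")
  manifest$files <- lapply(setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Adaptive-radiation pipeline result\n")
  p <- x$manifest$predictions
  if (!is.null(p$prediction1))
    cat("  (1) ", p$prediction1$verdict, "\n", sep = "")
  if (!is.null(p$prediction2))
    cat("  (2) speciation ratio clade1/clade2 = ",
        format(p$prediction2$ratio, digits = 3), "\n", sep = "")
  if (!is.null(p$prediction3))
    cat("  (3) ", p$prediction3$verdict, "\n", sep = "")
  if (!is.null(p$prediction4))
    cat("  (4) best state-dependent model: ",
        p$prediction4$best_multiregime_model,
        "; ecospace contraction = ",
        format(p$prediction4$ecospace_contraction, digits = 3), "\n", sep = "")
  if (length(x$failures))
    cat("  failed stages:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
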