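# End-to-end analysis pipeline: strata -> AROCM -> filters -> adjustment ->
# species aggregation -> lifespan correlations, with all artifacts written
# through writeOutputs. Deterministic given (inputs, config, seed).

#' Run the full analysis pipeline
#'
#' Loads a study from the four CSV paths (or simulates one when
#' \code{simulate} is given), selects the probe set, builds full-range
#' strata, estimates per-stratum rates, applies the mode's QC filters,
#' adjusts by a fixed power \code{p} or by the QCOD-selected optimum,
#' evaluates the proposition report, aggregates to species level, computes
#' lifespan correlations, and writes \code{stratum_stats.csv},
#' \code{species_stats.csv} and \code{report.json} into \code{outDir}.
#'
#' @param betaPath,samplePath,traitsPath,annotationPath input CSVs
#'   (ignored when \code{simulate} is given).
#' @param simulate optional \code{\link{syntheticConfig}}; when given the
#'   study is generated instead of loaded.
#' @param state,prc2 probe-set selection (default \code{"BivProm2"},
#'   \code{"+"}).
#' @param mode \code{"mammal"} or \code{"dog"} (filter thresholds).
#' @param interval relative-age interval, default \code{c(0, 1)}.
#' @param cutoff young/old relative-age cutoff recorded in the report.
#' @param p fixed adjustment power; ignored when \code{selectP = TRUE}.
#' @param selectP select the adjustment power by QCOD minimization.
#' @param seed integer seed (used by simulation; recorded in the report).
#' @param outDir output directory.
#' @return (invisibly) list with \code{stats}, \code{adjusted},
#'   \code{decisions}, \code{species}, \code{propositions},
#'   \code{correlations}, \code{manifest}.
#' @export
runPipeline <- function(betaPath = NULL, samplePath = NULL,
                        traitsPath = NULL, annotationPath = NULL,
                        simulate = NULL, state = "BivProm2", prc2 = "+",
                        mode = c("mammal", "dog"), interval = c(0, 1),
                        cutoff = 0.1, p = 0.25, selectP = FALSE,
                        seed = 1, outDir = "arocm_out") {
  mode <- match.arg(mode)
  if (!is.null(simulate)) {
    sim <- simulateStudy(simulate, seed = seed)
    study <- sim$study
  } else {
    if (is.null(betaPath) || is.null(samplePath) || is.null(traitsPath) ||
        is.null(annotationPath))
      stop("either all four input paths or a simulation config are required")
    study <- loadStudy(betaPath, samplePath, traitsPath, annotationPath)
  }
  cfg <- filterConfig(mode)
  probes <- selectStateCpGs(study, state, prc2)
  views <- buildStrata(study, probes, interval = interval, minN = cfg$minN)
  stats <- estimateStrata(views)
  if (nrow(stats) == 0) stop("no estimable strata")
  decisions <- applyFilters(stats, cfg, views = views)
  kept <- stats[stats$stratum_id %in%
                  decisions$stratum_id[decisions$kept], , drop = FALSE]
  if (nrow(kept) < 3) stop("fewer than 3 strata pass the filters")
  psel <- NULL
  if (selectP) {
    psel <- selectAdjustmentPower(kept)
    p <- psel$p_optimal
  }
  adjusted <- adjustStats(kept, p)
  props <- propositionChecks(adjusted)
  tr <- speciesTraits(study)
  if ("adult_weight" %in% colnames(tr))
    adjusted$adult_weight <- tr$adult_weight[
      match(adjusted$species, tr$species)]
  species <- aggregateBySpecies(adjusted)
  corrs <- list(
    log_log = lifespanCorrelations(species, "arocm", "pearson-log-log"),
    adj_log_log = lifespanCorrelations(species, "adj_arocm",
                                       "pearson-log-log"),
    vs_inverse_L = lifespanCorrelations(species, "arocm",
                                        "pearson-vs-inverse-L"),
    adj_vs_inverse_L = lifespanCorrelations(species, "adj_arocm",
                                            "pearson-vs-inverse-L",
                                            a = props$c_p))
  report <- list(
    config = list(state = state, prc2 = prc2, mode = mode,
                  interval = interval, cutoff = cutoff, p = p,
                  select_p = selectP,
                  simulated = !is.null(simulate)),
    seed = seed,
    package_version = as.character(utils::packageVersion("arocm")),
    n_strata = nrow(stats), n_kept = nrow(kept),
    skipped = attr(stats, "skipped"),
    filter_decisions = decisions,
    p_selection = if (!is.null(psel))
      psel[c("p_optimal", "objective", "degenerate", "n_used",
             "n_excluded")] else NULL,
    propositions = unclass(props),
    correlations = corrs)
  manifest <- writeOutputs(adjusted, species, report, outDir)
  invisible(list(stats = stats, adjusted = adjusted,
                 decisions = decisions, species = species,
                 propositions = props, correlations = corrs,
                 manifest = manifest))
}
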