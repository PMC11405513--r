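# Table readers/writers, CpG-set selection, stratum construction and trait
# conventions. All four input tables are plain CSV (header row, UTF-8):
#   beta matrix : first column sample_id, remaining columns probe ids
#   samples     : sample_id, species, tissue, age [, stratum_id]
#   traits      : stratum_id|species, max_lifespan [, gestation,
#                 adult_weight, median_lifespan]
#   annotation  : probe_id, chromatin_state, prc2_bound

#' Load a methylation study from four CSV files
#'
#' Reads the beta matrix, sample sheet, trait table and CpG annotation and
#' returns a validated \linkS4class{MethylStudy}. Cross-reference failures
#' (beta values outside [0,1], duplicate ids, samples whose species or
#' stratum lacks a trait row) raise errors naming the offending cells/ids.
#'
#' @param betaPath,samplePath,traitsPath,annotationPath CSV file paths.
#' @return a \linkS4class{MethylStudy}.
#' @export
loadStudy <- function(betaPath, samplePath, traitsPath, annotationPath) {
  bt <- read.csv(betaPath, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(bt)[1] != "sample_id")
    stop("beta matrix: first column must be 'sample_id'")
  betas <- as.matrix(bt[, -1, drop = FALSE])
  rownames(betas) <- as.character(bt[[1]])
  storage.mode(betas) <- "double"
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(betas))
    stop(sprintf(
      "beta value outside [0,1] at sample '%s', probe '%s' (value %.4g)%s",
      rownames(betas)[i[1]], colnames(betas)[i[2]], betas[bad[1]],
      if (length(bad) > 1) sprintf(" and %d more cell(s)", length(bad) - 1) else ""))
  }
  samples <- read.csv(samplePath, stringsAsFactors = FALSE)
  traits <- read.csv(traitsPath, stringsAsFactors = FALSE)
  annotation <- read.csv(annotationPath, stringsAsFactors = FALSE)
  MethylStudy(betas, samples, traits, annotation)
}

#' Select the CpGs of one chromatin state / PRC2 subset
#'
#' Chromatin states are split into PRC2-bound ("+") and unbound ("-")
#' subsets; a probe set is the CpGs matching both the state label and the
#' flag, in deterministic lexicographic order.
#'
#' @param study a \linkS4class{MethylStudy}.
#' @param state chromatin-state label, e.g. \code{"BivProm2"}.
#' @param prc2 PRC2 flag; any of \code{+/-}, \code{yes/no}, \code{1/0}.
#' @return character vector of probe ids (error if the subset is empty).
#' @export
selectStateCpGs <- function(study, state, prc2 = "+") {
  an <- cpgAnnotation(study)
  prc2 <- .normalizePrc2(prc2)
  hit <- an$chromatin_state == state & an$prc2_bound == prc2
  ids <- sort(an$probe_id[hit])
  if (!length(ids))
    stop(sprintf("no CpGs with chromatin state '%s' and PRC2 '%s'",
                 state, prc2))
  ids
}

.traitsFor <- function(study, stratum_id, species) {
  tr <- speciesTraits(study)
  row <- if ("stratum_id" %in% colnames(tr))
    tr[match(stratum_id, tr$stratum_id), , drop = FALSE]
  else
    tr[match(species, tr$species), , drop = FALSE]
  list(
    L = row$max_lifespan,
    GT = if ("gestation" %in% colnames(row) && !is.na(row$gestation))
      row$gestation else 0,
    weight = if ("adult_weight" %in% colnames(row)) row$adult_weight else NA_real_
  )
}

#' Build per-stratum views over a probe set and relative-age interval
#'
#' For each stratum: per-sample mean methylation is the mean beta over the
#' non-missing probes of the set (a sample with more than half of the set
#' missing is dropped and logged); relative ages use the stratum's maximum
#' lifespan and gestation time; samples are restricted to the half-open
#' relative-age interval \code{[lower, upper)}; strata with fewer than
#' \code{minN} retained samples are omitted (logged via \code{message}).
#'
#' @param study a \linkS4class{MethylStudy}.
#' @param probes character vector of probe ids (e.g. from
#'   \code{\link{selectStateCpGs}}).
#' @param interval numeric length 2, relative-age bounds in [0, 1].
#' @param minN minimum retained samples per stratum (default 3).
#' @return named list of \linkS4class{StratumView}.
#' @export
buildStrata <- function(study, probes, interval = c(0, 1), minN = 3) {
  stopifnot(length(interval) == 2, interval[1] >= 0, interval[2] <= 1,
            interval[1] < interval[2], minN >= 1)
  missing_probes <- setdiff(probes, rownames(study))
  if (length(missing_probes))
    stop("probe(s) not in study: ", paste(missing_probes, collapse = ", "))
  b <- betas(study)[probes, , drop = FALSE]
  cd <- sampleSheet(study)
  views <- list()
  for (sid in sort(unique(cd$stratum_id))) {
    idx <- cd$stratum_id == sid
    sub <- b[, idx, drop = FALSE]
    n_miss <- colSums(is.na(sub))
    keep <- n_miss <= length(probes) / 2
    if (any(!keep))
      message(sprintf("stratum '%s': dropped %d sample(s) with >50%% missing betas",
                      sid, sum(!keep)))
    if (!any(keep)) next
    methyl <- colMeans(sub[, keep, drop = FALSE], na.rm = TRUE)
    ages <- cd$age[idx][keep]
    tr <- .traitsFor(study, sid, cd$species[idx][1])
    R <- relativeAges(ages, tr$L, tr$GT)
    inside <- R >= interval[1] & R < interval[2]
    if (sum(inside) < minN) {
      message(sprintf("stratum '%s': %d sample(s) in interval (< %d), omitted",
                      sid, sum(inside), minN))
      next
    }
    views[[sid]] <- .newStratumView(
      sid, ages[inside], methyl[inside], tr$L, interval, tr$GT,
      species = cd$species[idx][1], tissue = cd$tissue[idx][1])
  }
  views
}

#' Maximum lifespan of a dog breed from its median lifespan
#'
#' Breed-level longevity records are scarce, so maximum lifespan is defined
#' by convention as 1.33 times the breed's median lifespan.
#'
#' @param medianLifespan median lifespan in years, positive.
#' @return maximum lifespan in years.
#' @examples
#' dogMaxLifespan(6.3)    # Great Dane: 8.379
#' dogMaxLifespan(14.6)   # Toy Poodle: 19.418
#' @export
dogMaxLifespan <- function(medianLifespan) {
  if (any(!is.finite(medianLifespan)) || any(medianLifespan <= 0))
    stop("median lifespan must be positive")
  1.33 * medianLifespan
}

.formatFull <- function(df) {
  # full floating precision so read(write(x)) round-trips exactly
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      x <- sprintf("%.17g", df[[j]])
      x[is.na(df[[j]])] <- NA_character_
      df[[j]] <- x
    }
  }
  df
}

#' Write analysis outputs
#'
#' Emits \code{stratum_stats.csv}, \code{species_stats.csv} and
#' \code{report.json} (configuration, seed, filter decisions, proposition
#' report, ...) into \code{outDir}. Numeric columns are written at full
#' floating precision with deterministic column order, so tables round-trip
#' exactly through \code{read.csv}.
#'
#' @param stratumStats data.frame of per-stratum statistics (may be empty).
#' @param speciesStats data.frame of species-level aggregates (may be empty).
#' @param report named list serialized as JSON.
#' @param outDir output directory (created if needed).
#' @return named character vector of the files written (the manifest).
#' @export
writeOutputs <- function(stratumStats, speciesStats, report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    stratum_stats = file.path(outDir, "stratum_stats.csv"),
    species_stats = file.path(outDir, "species_stats.csv"),
    report = file.path(outDir, "report.json"))
  write.csv(.formatFull(stratumStats), paths["stratum_stats"],
            row.names = FALSE, na = "")
  write.csv(.formatFull(speciesStats), paths["species_stats"],
            row.names = FALSE, na = "")
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       force = TRUE)
  paths
}
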