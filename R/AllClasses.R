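#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom stats cor lm coef quantile median pnorm pt resid sd setNames runif rnorm
#' @importFrom utils read.csv write.csv
NULL

#' MethylStudy: a methylation study with sample, trait and probe metadata
#'
#' Container for a cross-species (or cross-breed) methylation study. Extends
#' \linkS4class{SummarizedExperiment}: the \code{"beta"} assay holds
#' methylation beta values (proportions in \code{[0,1]}, probes in rows,
#' samples in columns, \code{NA} allowed), \code{colData} holds the sample
#' sheet (\code{species}, \code{tissue}, \code{age} in years and a derived
#' \code{stratum_id}), and \code{rowData} holds the CpG annotation
#' (\code{chromatin_state}, \code{prc2_bound} normalized to \code{"+"} /
#' \code{"-"}). Stratum-level traits (maximum lifespan in years, optional
#' gestation time, adult weight, median lifespan) live in the \code{traits}
#' slot and are keyed by \code{stratum_id} or by \code{species}.
#'
#' The estimation unit throughout the package is the stratum: a species x
#' tissue combination (mammal mode) or a breed (dog mode). Every stratum
#' referenced by a sample must resolve to a trait row with a positive
#' maximum lifespan; validity enforces this together with beta bounds and
#' unique probe/sample identifiers.
#'
#' @slot traits \code{DataFrame} of stratum- or species-level traits; must
#'   contain \code{max_lifespan} (years, positive) and a \code{stratum_id}
#'   or \code{species} key column. Optional columns: \code{gestation}
#'   (years), \code{adult_weight} (kg), \code{median_lifespan} (years).
#'
#' @seealso \code{\link{loadStudy}}, \code{\link{buildStrata}},
#'   \code{\link{simulateStudy}}
#' @export
setClass("MethylStudy",
  contains = "SummarizedExperiment",
  representation(traits = "DataFrame")
)

.normalizePrc2 <- function(x) {
  x <- trimws(tolower(as.character(x)))
  pos <- x %in% c("+", "yes", "y", "1", "true", "t")
  neg <- x %in% c("-", "no", "n", "0", "false", "f", "−")
  bad <- !(pos | neg)
  if (any(bad)) {
    stop("unrecognized PRC2 flag value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  ifelse(pos, "+", "-")
}

setValidity("MethylStudy", function(object) {
  msg <- character()
  b <- SummarizedExperiment::assay(object, "beta")
  bad <- which(!is.na(b) & (b < 0 | b > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(b))
    msg <- c(msg, sprintf(
      "beta values outside [0,1]: %d cell(s), first at probe '%s', sample '%s' (%.4g)",
      length(bad), rownames(b)[i[1]], colnames(b)[i[2]], b[bad[1]]))
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate probe ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  cd <- SummarizedExperiment::colData(object)
  need <- c("species", "tissue", "age", "stratum_id")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste("sample sheet lacks column(s):",
                        paste(miss, collapse = ", ")))
  } else {
    tr <- object@traits
    key <- if ("stratum_id" %in% colnames(tr)) tr$stratum_id else tr$species
    ref <- if ("stratum_id" %in% colnames(tr)) cd$stratum_id else cd$species
    if (is.null(key)) {
      msg <- c(msg, "traits need a 'stratum_id' or 'species' key column")
    } else if (!("max_lifespan" %in% colnames(tr))) {
      msg <- c(msg, "traits lack 'max_lifespan'")
    } else {
      orphan <- setdiff(unique(ref), key)
      if (length(orphan))
        msg <- c(msg, paste("no trait row (max_lifespan) for:",
                            paste(orphan, collapse = ", ")))
      badL <- key[!is.na(key) & (!is.finite(tr$max_lifespan) | tr$max_lifespan <= 0)]
      badL <- intersect(badL, ref)
      if (length(badL))
        msg <- c(msg, paste("non-positive max_lifespan for:",
                            paste(badL, collapse = ", ")))
    }
  }
  an <- SummarizedExperiment::rowData(object)
  if (!all(c("chromatin_state", "prc2_bound") %in% colnames(an)))
    msg <- c(msg, "probe annotation lacks chromatin_state/prc2_bound")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylStudy from in-memory tables
#'
#' @param betas numeric matrix of beta values, samples in rows (rownames =
#'   sample ids) and probes in columns, as laid out in the input CSV; it is
#'   transposed internally to the probes x samples assay.
#' @param samples data.frame with columns \code{sample_id}, \code{species},
#'   \code{tissue}, \code{age}; an optional \code{stratum_id} column
#'   overrides the default species x tissue key.
#' @param traits data.frame keyed by \code{stratum_id} or \code{species}
#'   with \code{max_lifespan} and optional \code{gestation},
#'   \code{adult_weight}, \code{median_lifespan}.
#' @param annotation data.frame with \code{probe_id},
#'   \code{chromatin_state}, \code{prc2_bound} (accepted encodings:
#'   \code{+/-}, \code{yes/no}, \code{1/0}; normalized to \code{+/-}).
#' @return a validated \linkS4class{MethylStudy}.
#' @export
MethylStudy <- function(betas, samples, traits, annotation) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "species", "tissue", "age")
  miss <- setdiff(need, colnames(samples))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in sample sheet: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (!("stratum_id" %in% colnames(samples)))
    samples$stratum_id <- paste(samples$species, samples$tissue, sep = ".")
  betas <- as.matrix(betas)
  if (is.null(rownames(betas)))
    stop("beta matrix needs sample ids as row names")
  missing_sheet <- setdiff(rownames(betas), samples$sample_id)
  if (length(missing_sheet))
    stop("beta matrix sample(s) absent from sample sheet: ",
         paste(missing_sheet, collapse = ", "))
  samples <- samples[match(rownames(betas), samples$sample_id), , drop = FALSE]

  annotation <- as.data.frame(annotation)
  if (!all(c("probe_id", "chromatin_state", "prc2_bound") %in% colnames(annotation)))
    stop("annotation needs probe_id, chromatin_state, prc2_bound")
  if (anyDuplicated(annotation$probe_id))
    stop("duplicate probe ids in annotation: ",
         paste(unique(annotation$probe_id[duplicated(annotation$probe_id)]),
               collapse = ", "))
  annotation$prc2_bound <- .normalizePrc2(annotation$prc2_bound)
  unannotated <- setdiff(colnames(betas), annotation$probe_id)
  if (length(unannotated))
    stop("probe(s) missing from annotation: ",
         paste(unannotated, collapse = ", "))
  annotation <- annotation[match(colnames(betas), annotation$probe_id), ,
                           drop = FALSE]

  # lexicographic probe and sample order: downstream sums reproducible
  po <- order(colnames(betas))
  so <- order(rownames(betas))
  betas <- betas[so, po, drop = FALSE]
  samples <- samples[so, , drop = FALSE]
  annotation <- annotation[po, , drop = FALSE]

  cd <- S4Vectors::DataFrame(samples, row.names = samples$sample_id)
  rd <- S4Vectors::DataFrame(annotation, row.names = annotation$probe_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = t(betas)), colData = cd, rowData = rd)
  new("MethylStudy", se, traits = S4Vectors::DataFrame(as.data.frame(traits)))
}

setMethod("show", "MethylStudy", function(object) {
  cat("MethylStudy:", ncol(object), "samples x", nrow(object), "probes\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  strata:", length(unique(cd$stratum_id)),
      "| species:", length(unique(cd$species)),
      "| tissues:", length(unique(cd$tissue)), "\n")
  cat("  age range [years]:",
      paste(signif(range(cd$age), 4), collapse = " - "), "\n")
  st <- SummarizedExperiment::rowData(object)$chromatin_state
  cat("  chromatin states:", length(unique(st)), "\n")
})

#' StratumView: one stratum's samples over a CpG set and age interval
#'
#' Holds, for a single stratum (breed or species x tissue), the ages,
#' relative ages \code{R = (A + GT) / (L + GT)}, per-sample mean methylation
#' over the selected CpG set, and the standardized (mean 0, population SD 1)
#' methylation used as the regression response. The relative-age interval is
#' half-open \code{[lower, upper)}.
#'
#' @slot stratumId,species,tissue character identifiers.
#' @slot ages numeric, years.
#' @slot relAges numeric, unitless relative ages within \code{interval}.
#' @slot methyl numeric, per-sample mean beta over the probe set.
#' @slot scaled numeric, standardized methyl (all \code{NA} when degenerate).
#' @slot L numeric, maximum lifespan (years).
#' @slot gestation numeric, gestation time (years) used in \code{relAges}.
#' @slot interval numeric length 2, relative-age bounds.
#' @export
setClass("StratumView", representation(
  stratumId = "character", species = "character", tissue = "character",
  ages = "numeric", relAges = "numeric", methyl = "numeric",
  scaled = "numeric", L = "numeric", gestation = "numeric",
  interval = "numeric"
))

setValidity("StratumView", function(object) {
  msg <- character()
  n <- length(object@ages)
  if (length(object@relAges) != n || length(object@methyl) != n ||
      length(object@scaled) != n)
    msg <- c(msg, "ages/relAges/methyl/scaled must share length")
  iv <- object@interval
  if (length(iv) != 2 || !(iv[1] < iv[2]) || iv[1] < 0 || iv[2] > 1)
    msg <- c(msg, "interval must satisfy 0 <= lower < upper <= 1")
  if (n > 0 && (any(object@relAges < iv[1]) || any(object@relAges >= iv[2])))
    msg <- c(msg, "relative ages must lie in [lower, upper)")
  if (length(object@L) != 1 || !is.finite(object@L) || object@L <= 0)
    msg <- c(msg, "L must be a single positive number")
  if (length(msg)) msg else TRUE
})

.newStratumView <- function(stratumId, ages, methyl, L, interval = c(0, 1),
                            gestation = 0, species = NA_character_,
                            tissue = NA_character_) {
  relAges <- relativeAges(ages, L, gestation)
  scaled <- tryCatch(scaleValues(methyl), error = function(e) rep(NA_real_, length(methyl)))
  new("StratumView", stratumId = as.character(stratumId),
      species = as.character(species), tissue = as.character(tissue),
      ages = as.numeric(ages), relAges = relAges,
      methyl = as.numeric(methyl), scaled = scaled,
      L = as.numeric(L), gestation = as.numeric(gestation),
      interval = as.numeric(interval))
}

setMethod("show", "StratumView", function(object) {
  cat("StratumView '", object@stratumId, "': n = ", length(object@ages),
      ", L = ", signif(object@L, 4), " y, R in [",
      object@interval[1], ", ", object@interval[2], ")\n", sep = "")
  if (length(object@ages))
    cat("  ages [y]:", paste(signif(range(object@ages), 4), collapse = " - "),
        "| SD(R):", signif(.popsd(object@relAges), 4), "\n")
})

#' @describeIn StratumView number of samples in the view
#' @param x a \code{StratumView}
#' @export
setMethod("length", "StratumView", function(x) length(x@ages))

#' LifeCourseFit: piecewise log-linear life-course model fit
#'
#' Least-squares fit of \code{ScaledM = gamma0 + gamma1 * g(R)} for one
#' stratum, where \code{g} is the piecewise log-linear relative-age
#' transform (or \code{g2}, its all-logarithmic variant).
#'
#' @slot stratumId character.
#' @slot transform \code{"g"} or \code{"g2"}.
#' @slot gamma0,gamma1 regression coefficients (unitless; response is
#'   standardized methylation).
#' @slot pearsonR Pearson correlation between response and transformed
#'   relative age.
#' @slot n number of samples used.
#' @slot knot relative-age knot of the transform (default 0.1).
#' @export
setClass("LifeCourseFit", representation(
  stratumId = "character", transform = "character",
  gamma0 = "numeric", gamma1 = "numeric", pearsonR = "numeric",
  n = "integer", knot = "numeric"
))

setMethod("show", "LifeCourseFit", function(object) {
  cat("LifeCourseFit '", object@stratumId, "' [", object@transform,
      ", knot ", object@knot, "]: gamma0 = ", signif(object@gamma0, 6),
      ", gamma1 = ", signif(object@gamma1, 6),
      ", r = ", signif(object@pearsonR, 4), ", n = ", object@n, "\n",
      sep = "")
})
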