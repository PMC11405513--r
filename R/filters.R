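# Stratum exclusion rules. Dog mode: n < 3, SD(R) < 0.1, fit R^2 < 0.2.
# Mammal mode: n < 3, SD(R) < 0.06, AROCM outside (-1, 10) unless the rates
# re-estimated on derived (wider or adjacent) relative-age intervals are
# out of range too. Rules are pure functions of (view, stats, config); all
# violated rules are reported, never short-circuited.

#' Filter configuration for dog or mammal mode
#'
#' @param mode \code{"mammal"} or \code{"dog"}.
#' @param minN minimum samples per stratum (default 3).
#' @param minSdR minimum SD of relative age; default 0.06 (mammal) or 0.1
#'   (dog). The dog threshold is stricter because far fewer strata are at
#'   stake there.
#' @param arocmRange open interval of admissible AROCM values (mammal mode
#'   only; default (-1, 10)).
#' @param minR2 minimum regression R-squared (dog mode only; default 0.2).
#' @param derivedIntervals relative-age upper bounds of the derived
#'   intervals used by the outlier check (default \code{c(0.1, 0.2, 0.3)}).
#' @return list of class \code{"arocm_filter_config"}.
#' @export
filterConfig <- function(mode = c("mammal", "dog"), minN = 3,
                         minSdR = NULL, arocmRange = c(-1, 10),
                         minR2 = 0.2, derivedIntervals = c(0.1, 0.2, 0.3)) {
  mode <- match.arg(mode)
  if (is.null(minSdR)) minSdR <- if (mode == "dog") 0.1 else 0.06
  stopifnot(minN >= 1, minSdR > 0, length(arocmRange) == 2,
            arocmRange[1] < arocmRange[2], minR2 > 0)
  structure(list(mode = mode, minN = minN, minSdR = minSdR,
                 arocmRange = arocmRange, minR2 = minR2,
                 derivedIntervals = derivedIntervals),
            class = "arocm_filter_config")
}

#' Re-estimate AROCM on derived intervals to confirm an out-of-range value
#'
#' An out-of-range AROCM is declared an outlier only if the rates
#' re-estimated on the derived intervals \code{[0, u)} (u from
#' \code{config$derivedIntervals}, excluding the primary interval's own
#' upper bound) BOTH fall inside the admissible range - i.e. the extreme
#' value is not reproduced on adjacent age windows. If a derived interval
#' holds fewer than \code{config$minN} samples (or is degenerate) the
#' check abstains for that interval.
#'
#' @param view the stratum's \emph{full-range} \linkS4class{StratumView}
#'   (it must contain the samples of the derived intervals).
#' @param stats the stratum's statistics row (from
#'   \code{\link{estimateAROCM}} on the primary interval).
#' @param config an \code{\link{filterConfig}} object.
#' @return list with \code{is_outlier} (TRUE when all estimable derived
#'   rates are in range and at least two were estimable), \code{derived}
#'   (named vector of derived AROCMs, NA where abstained) and
#'   \code{abstained} (number of unestimable intervals).
#' @export
derivedIntervalCheck <- function(view, stats, config) {
  uppers <- setdiff(config$derivedIntervals, stats$upper)
  derived <- setNames(rep(NA_real_, length(uppers)),
                      sprintf("[0,%g)", uppers))
  for (k in seq_along(uppers)) {
    idx <- view@relAges < uppers[k]
    if (sum(idx) < config$minN) next
    sub <- tryCatch(
      .newStratumView(view@stratumId, view@ages[idx], view@methyl[idx],
                      view@L, c(0, uppers[k]), view@gestation,
                      view@species, view@tissue),
      error = function(e) NULL)
    if (is.null(sub)) next
    est <- tryCatch(estimateAROCM(sub), arocm_degenerate_stratum =
                      function(e) NULL)
    if (!is.null(est)) derived[k] <- est$arocm
  }
  estimable <- !is.na(derived)
  inRange <- derived > config$arocmRange[1] & derived < config$arocmRange[2]
  list(is_outlier = sum(estimable) >= 2 && all(inRange[estimable]),
       derived = derived,
       abstained = sum(!estimable))
}

#' Classify strata against the exclusion rules
#'
#' Every stratum is classified with all violated rules listed. Reason
#' codes: \code{"small_n"} (n below minimum), \code{"low_sd_R"} (SD of
#' relative age below the mode's threshold), \code{"low_r2"} (dog mode,
#' poor regression fit), \code{"arocm_outlier"} (mammal mode, out-of-range
#' rate confirmed by the derived-interval check),
#' \code{"arocm_range_unverifiable"} (out-of-range rate whose derived
#' intervals could not be estimated; rejected conservatively). An
#' out-of-range rate whose derived intervals are \emph{also} out of range
#' is kept but flagged for review (\code{review = TRUE}).
#'
#' @param stats data.frame of per-stratum statistics.
#' @param config an \code{\link{filterConfig}} object.
#' @param views optional named list of full-range
#'   \linkS4class{StratumView}s (required for the mammal range rule; a
#'   missing view counts as unverifiable).
#' @return data.frame \code{(stratum_id, kept, reasons, review)}; reasons
#'   is a comma-separated string, empty iff kept.
#' @export
applyFilters <- function(stats, config, views = NULL) {
  stopifnot(inherits(config, "arocm_filter_config"))
  out <- lapply(seq_len(nrow(stats)), function(i) {
    row <- stats[i, ]
    reasons <- character()
    review <- FALSE
    if (row$n < config$minN) reasons <- c(reasons, "small_n")
    if (row$sd_R < config$minSdR) reasons <- c(reasons, "low_sd_R")
    if (config$mode == "dog" && row$r_squared < config$minR2)
      reasons <- c(reasons, "low_r2")
    if (config$mode == "mammal" &&
        (row$arocm <= config$arocmRange[1] ||
         row$arocm >= config$arocmRange[2])) {
      v <- views[[row$stratum_id]]
      if (is.null(v)) {
        reasons <- c(reasons, "arocm_range_unverifiable")
      } else {
        chk <- derivedIntervalCheck(v, row, config)
        if (chk$is_outlier) {
          reasons <- c(reasons, "arocm_outlier")
        } else if (chk$abstained >= length(chk$derived) - 1) {
          # fewer than two derived rates estimable: reject conservatively
          reasons <- c(reasons, "arocm_range_unverifiable")
        } else {
          review <- TRUE   # extreme rate reproduced on derived intervals
        }
      }
    }
    data.frame(stratum_id = row$stratum_id,
               kept = length(reasons) == 0,
               reasons = paste(reasons, collapse = ","),
               review = review, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
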