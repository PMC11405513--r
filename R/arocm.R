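# Per-stratum AROCM estimation and its correlation / SD(R) decomposition.
#
# All moments use the population divisor n; Pearson correlations are
# divisor-invariant but standardized values are not, so the divisor matters
# for the scaled response and for SD(R).

.popvar <- function(v) mean((v - mean(v))^2)
.popsd <- function(v) sqrt(.popvar(v))

.degenerate <- function(reason, stratum = NA_character_) {
  stop(structure(class = c("arocm_degenerate_stratum", "error", "condition"),
                 list(message = sprintf("degenerate stratum%s: %s",
                                        if (is.na(stratum)) "" else paste0(" '", stratum, "'"),
                                        reason),
                      call = sys.call(-1), reason = reason,
                      stratum = stratum)))
}

#' Standardize a vector to mean 0 and population SD 1
#'
#' The scaled methylation response: \code{(v - mean(v)) / SD(v)} with the
#' population (divisor n) standard deviation.
#'
#' @param v numeric vector, length >= 2, non-constant.
#' @return unitless vector with mean 0 and population SD 1.
#' @examples
#' scaleValues(c(1, 2, 3))   # -1.2247, 0, 1.2247
#' @export
scaleValues <- function(v) {
  if (length(v) < 2) .degenerate("fewer than 2 values")
  if (anyNA(v)) .degenerate("missing values")
  s <- .popsd(v)
  if (s == 0) .degenerate("constant vector (zero SD)")
  (v - mean(v)) / s
}

#' Relative ages
#'
#' \code{R = (A + GT) / (L + GT)}: age divided by maximum lifespan, both
#' shifted by gestation time so that prenatal samples (negative ages) map to
#' non-negative relative ages.
#'
#' @param ages numeric, years.
#' @param L maximum lifespan, years, positive.
#' @param GT gestation time, years, non-negative (default 0).
#' @return unitless vector.
#' @export
relativeAges <- function(ages, L, GT = 0) {
  stopifnot(is.finite(L), L > 0, is.finite(GT), GT >= 0)
  r <- (ages + GT) / (L + GT)
  if (any(r < 0, na.rm = TRUE))
    stop("negative relative age: prenatal sample(s) without sufficient ",
         "gestation time (GT)")
  r
}

#' Estimate the average rate of change in methylation for one stratum
#'
#' Fits the least-squares regression of standardized mean methylation on
#' chronological age; the slope is the AROCM (per year). The returned row
#' also carries the decomposition terms: the Pearson methylation-age
#' correlation, the population SDs of relative age, age and methylation,
#' the fit R-squared and the population residual SD. The identities
#' \code{arocm = cor / (sd_R * L)} (gestation 0) and \code{sd_A = sd_R * L}
#' hold to floating-point accuracy.
#'
#' @param view a \linkS4class{StratumView} with n >= 2 and non-constant
#'   ages and methylation.
#' @return one-row \code{data.frame} with columns \code{stratum_id},
#'   \code{species}, \code{tissue}, \code{n}, \code{lower}, \code{upper},
#'   \code{cor_methyl_age}, \code{sd_R}, \code{sd_A}, \code{sd_M},
#'   \code{arocm}, \code{intercept}, \code{r_squared}, \code{residual_sd},
#'   \code{L}.
#' @examples
#' v <- makeCorStratum(n = 3, L = 10, ages = c(1, 2, 3),
#'                     methyl = c(0.1, 0.2, 0.4))
#' estimateAROCM(v)   # cor 0.982, sd_R 0.0816, arocm 1.203
#' @export
estimateAROCM <- function(view) {
  stopifnot(is(view, "StratumView"))
  n <- length(view)
  if (n < 2) .degenerate("fewer than 2 samples", view@stratumId)
  a <- view@ages
  m <- view@methyl
  if (.popsd(a) == 0) .degenerate("constant ages", view@stratumId)
  if (.popsd(m) == 0) .degenerate("constant methylation", view@stratumId)
  scaled <- view@scaled
  if (anyNA(scaled)) scaled <- scaleValues(m)
  fit <- lm(scaled ~ a)
  res <- resid(fit)
  data.frame(
    stratum_id = view@stratumId,
    species = view@species,
    tissue = view@tissue,
    n = n,
    lower = view@interval[1],
    upper = view@interval[2],
    cor_methyl_age = cor(m, a),
    sd_R = .popsd(view@relAges),
    sd_A = .popsd(a),
    sd_M = .popsd(m),
    arocm = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = cor(m, a)^2,
    residual_sd = sqrt(mean(res^2)),
    L = view@L,
    stringsAsFactors = FALSE
  )
}

#' Estimate AROCM for a list of strata
#'
#' Applies \code{\link{estimateAROCM}} to each view; degenerate strata
#' (too few samples, constant ages or methylation) are skipped and reported
#' in the \code{"skipped"} attribute as a data.frame of
#' \code{(stratum_id, reason)}.
#'
#' @param views list of \linkS4class{StratumView}.
#' @return \code{data.frame} of per-stratum statistics.
#' @export
estimateStrata <- function(views) {
  rows <- list()
  skipped <- list()
  for (v in views) {
    r <- tryCatch(estimateAROCM(v), arocm_degenerate_stratum = function(e) e)
    if (inherits(r, "condition")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        stratum_id = v@stratumId, reason = r$reason,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    estimateStrataEmpty()
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(stratum_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

estimateStrataEmpty <- function() {
  data.frame(stratum_id = character(), species = character(),
             tissue = character(), n = integer(), lower = numeric(),
             upper = numeric(), cor_methyl_age = numeric(), sd_R = numeric(),
             sd_A = numeric(), sd_M = numeric(), arocm = numeric(),
             intercept = numeric(), r_squared = numeric(),
             residual_sd = numeric(), L = numeric(), stringsAsFactors = FALSE)
}

#' Split a stratum into young and old sub-strata
#'
#' Partitions at the relative-age cutoff: young is \code{R < cutoff}, old is
#' \code{R >= cutoff} (a boundary sample goes to the old side). Each
#' sub-view is re-standardized within itself; an empty side is returned as
#' an empty view.
#'
#' @param view a \linkS4class{StratumView}.
#' @param cutoff relative-age cutoff in (0, 1), default 0.1.
#' @return list with elements \code{young} and \code{old}.
#' @export
splitYoungOld <- function(view, cutoff = 0.1) {
  stopifnot(is(view, "StratumView"), cutoff > 0, cutoff < 1)
  young_idx <- view@relAges < cutoff
  sub <- function(idx, iv) {
    m <- view@methyl[idx]
    scaled <- if (sum(idx) >= 2 && .popsd(m) > 0) scaleValues(m) else
      rep(NA_real_, sum(idx))
    new("StratumView", stratumId = view@stratumId, species = view@species,
        tissue = view@tissue, ages = view@ages[idx],
        relAges = view@relAges[idx], methyl = m, scaled = scaled,
        L = view@L, gestation = view@gestation, interval = iv)
  }
  list(young = sub(young_idx, c(view@interval[1], cutoff)),
       old = sub(!young_idx, c(cutoff, view@interval[2])))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). Returns \code{NA} with a warning when either vector is constant.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return rank correlation in [-1, 1], or NA.
#' @export
spearmanCor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (.popsd(rx) == 0 || .popsd(ry) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(rx, ry)
}
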