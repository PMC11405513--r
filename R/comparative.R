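# Cross-stratum analyses: species-level aggregation, lifespan correlations,
# lifespan-group trend tests, multivariate lifespan models and the
# SD(R)-stratified cross-check.

#' Aggregate stratum statistics to species level
#'
#' The species-level value of each metric is the median across that
#' species' tissue strata (even counts: mean of the middle two). Only the
#' rows passed in are used, so apply QC filters first.
#'
#' @param stats data.frame of per-stratum statistics with a \code{species}
#'   column (adjusted columns are aggregated when present).
#' @return data.frame, one row per species: \code{species}, \code{L},
#'   \code{n_strata} and the per-metric medians.
#' @export
aggregateBySpecies <- function(stats) {
  metrics <- intersect(
    c("arocm", "adj_arocm", "cor_methyl_age", "adj_cor", "sd_R",
      "arocm_young", "arocm_old", "adj_arocm_young", "adj_arocm_old"),
    colnames(stats))
  sp <- sort(unique(stats$species))
  rows <- lapply(sp, function(s) {
    d <- stats[stats$species == s, , drop = FALSE]
    out <- data.frame(species = s, L = d$L[1], n_strata = nrow(d),
                      stringsAsFactors = FALSE)
    if ("adult_weight" %in% colnames(d)) out$adult_weight <- d$adult_weight[1]
    for (m in metrics) out[[m]] <- median(d[[m]], na.rm = TRUE)
    out
  })
  do.call(rbind, rows)
}

.corTestP <- function(r, n) {
  if (n < 3 || is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Correlation between a rate metric and maximum lifespan
#'
#' Modes: \code{"pearson-raw"} (metric vs L), \code{"pearson-log-log"}
#' (log metric vs log L, positive pairs only; also returns the log-log
#' regression slope), \code{"pearson-vs-inverse-L"} (metric vs a/L) and
#' \code{"spearman-vs-inverse-L"}. The constant \code{a} defaults to 1;
#' pass \code{c_p} from \code{\link{propositionChecks}} for the adjusted
#' metric. Two-sided p-values use the t approximation
#' \code{t = r sqrt((n-2)/(1-r^2))} for both Pearson and Spearman.
#'
#' @param table data.frame with an \code{L} column.
#' @param metric column name of the rate metric.
#' @param mode correlation mode (see above).
#' @param a proportionality constant for the inverse-lifespan modes.
#' @return list with \code{r}, \code{p}, \code{n} (and \code{slope} for
#'   log-log).
#' @export
lifespanCorrelations <- function(table, metric,
                                 mode = c("pearson-raw", "pearson-log-log",
                                          "pearson-vs-inverse-L",
                                          "spearman-vs-inverse-L"),
                                 a = 1) {
  mode <- match.arg(mode)
  x <- table[[metric]]
  L <- table$L
  ok <- is.finite(x) & is.finite(L) & L > 0
  if (mode == "pearson-log-log") ok <- ok & x > 0
  x <- x[ok]; L <- L[ok]
  n <- length(x)
  if (n < 3) stop("fewer than 3 complete pairs for '", metric, "'")
  out <- switch(mode,
    "pearson-raw" = list(r = cor(x, L)),
    "pearson-log-log" = {
      fit <- lm(log(x) ~ log(L))
      list(r = cor(log(x), log(L)), slope = unname(coef(fit)[2]))
    },
    "pearson-vs-inverse-L" = list(r = cor(x, a / L)),
    "spearman-vs-inverse-L" = list(r = spearmanCor(x, a / L)))
  out$p <- .corTestP(out$r, n)
  out$n <- n
  out
}

#' Assign a species to a maximum-lifespan group
#'
#' The five ordered groups: under 10 years, 10-19, 20-24, 25-39, and 40
#' years or more. Each boundary belongs to the upper group.
#'
#' @param L maximum lifespan(s), years, positive.
#' @return ordered factor with levels \code{"<10" < "10-19" < "20-24" <
#'   "25-39" < ">=40"}.
#' @export
assignLifespanGroup <- function(L) {
  stopifnot(all(L > 0))
  cut(L, breaks = c(0, 10, 20, 25, 40, Inf), right = FALSE,
      labels = c("<10", "10-19", "20-24", "25-39", ">=40"),
      ordered_result = TRUE)
}

#' Mann-Kendall trend test across ordered groups
#'
#' Tests for a monotone trend of \code{values} across the ordering given
#' by \code{groups} (group ranks; within-group order does not contribute,
#' since tied group ranks have zero sign). The statistic is
#' \code{S = sum_{i<j} sign(x_j - x_i) sign(v_j - v_i)}; its null variance
#' uses the full tie correction for ties in both rankings, and the normal
#' approximation applies a continuity correction. All values tied gives
#' \code{p = 1}.
#'
#' @param values numeric vector, length >= 3.
#' @param groups ordering variable (ordered factor, numeric, or omitted
#'   for the natural sequence order).
#' @return list with \code{S}, \code{var_S}, \code{z}, \code{p} (two-
#'   sided) and \code{n}.
#' @examples
#' mannKendallTrend(c(1, 2, 3, 4, 5))   # S = 10, z = 2.2045, p = 0.0275
#' @export
mannKendallTrend <- function(values, groups = NULL) {
  n <- length(values)
  stopifnot(n >= 3, !anyNA(values))
  x <- if (is.null(groups)) seq_len(n) else {
    stopifnot(length(groups) == n)
    if (is.factor(groups)) as.integer(groups) else as.numeric(groups)
  }
  dx <- sign(outer(x, x, "-"))
  dv <- sign(outer(values, values, "-"))
  S <- sum((dx * dv)[lower.tri(dx)])
  tieTerm <- function(v, f) {
    t <- table(v)
    sum(f(as.numeric(t)))
  }
  f0 <- function(t) t * (t - 1) * (2 * t + 5)
  f1 <- function(t) t * (t - 1) * (t - 2)
  f2 <- function(t) t * (t - 1)
  varS <- (n * (n - 1) * (2 * n + 5) - tieTerm(x, f0) - tieTerm(values, f0)) / 18 +
    tieTerm(x, f1) * tieTerm(values, f1) / (9 * n * (n - 1) * (n - 2)) +
    tieTerm(x, f2) * tieTerm(values, f2) / (2 * n * (n - 1))
  z <- if (varS <= 0 || S == 0) 0 else (S - sign(S)) / sqrt(varS)
  list(S = S, var_S = varS, z = z,
       p = if (varS <= 0) 1 else 2 * pnorm(-abs(z)), n = n)
}

#' Multivariate lifespan regression models
#'
#' Ordinary least squares on the log scale over rows with positive rate,
#' lifespan and weight:
#' \itemize{
#'   \item M1: \code{log(L) ~ log(AROCM) + log(Weight)}
#'   \item M2: \code{log(AROCM) ~ log(L) + log(Weight)}
#'   \item M3: M2 plus a brain-tissue indicator
#'   \item M4: M2 plus indicators for brain, blood, skin, liver, muscle
#'     and tail (stratum-level table required)
#' }
#'
#' @param table data.frame with columns \code{arocm}, \code{L},
#'   \code{adult_weight} and, for M3/M4, \code{tissue}.
#' @param model \code{"M1"}, \code{"M2"}, \code{"M3"} or \code{"M4"}.
#' @return data.frame \code{(term, estimate, std_error, t_value, p_value)}.
#' @export
fitLifespanModels <- function(table, model = c("M1", "M2", "M3", "M4")) {
  model <- match.arg(model)
  ok <- is.finite(table$arocm) & table$arocm > 0 &
    is.finite(table$L) & table$L > 0 &
    is.finite(table$adult_weight) & table$adult_weight > 0
  d <- data.frame(logA = log(table$arocm[ok]), logL = log(table$L[ok]),
                  logW = log(table$adult_weight[ok]))
  if (model %in% c("M3", "M4")) {
    if (!("tissue" %in% colnames(table)))
      stop("models M3/M4 need a 'tissue' column")
    tis <- tolower(table$tissue[ok])
    ind <- if (model == "M3") "brain" else
      c("brain", "blood", "skin", "liver", "muscle", "tail")
    for (t in ind) d[[t]] <- as.integer(tis == t)
  }
  form <- switch(model,
    M1 = logL ~ logA + logW,
    M2 = logA ~ logL + logW,
    M3 = logA ~ logL + logW + brain,
    M4 = logA ~ logL + logW + brain + blood + skin + liver + muscle + tail)
  if (nrow(d) <= length(all.vars(form)))
    stop("too few usable rows (", nrow(d), ") for model ", model)
  fit <- lm(form, data = d)
  if (anyNA(coef(fit)))
    stop("collinear design for model ", model)
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
             t_value = cf[, 3], p_value = cf[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Lifespan correlation within SD(R) bins
#'
#' The conventional cross-check of the SD(R) adjustment: restrict to
#' strata with comparable SD(R) and correlate the \emph{unadjusted} rate
#' with 1/L within each bin. Bins with fewer than 3 strata are skipped
#' (with a message).
#'
#' @param stats data.frame with \code{sd_R}, \code{arocm}, \code{L}.
#' @param bins list of open intervals \code{c(lo, hi)}; default
#'   \code{list(c(0.2, 0.4), c(0.4, 0.6))}.
#' @return data.frame \code{(bin_lo, bin_hi, n, r, p)} for evaluated bins.
#' @export
stratifiedBySdR <- function(stats, bins = list(c(0.2, 0.4), c(0.4, 0.6))) {
  rows <- list()
  for (b in bins) {
    stopifnot(length(b) == 2, b[1] < b[2])
    d <- stats[stats$sd_R > b[1] & stats$sd_R < b[2], , drop = FALSE]
    if (nrow(d) < 3) {
      message(sprintf("SD(R) bin (%g, %g): %d strata, skipped",
                      b[1], b[2], nrow(d)))
      next
    }
    cc <- lifespanCorrelations(d, "arocm", "pearson-vs-inverse-L")
    rows[[length(rows) + 1L]] <- data.frame(
      bin_lo = b[1], bin_hi = b[2], n = cc$n, r = cc$r, p = cc$p)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(bin_lo = numeric(), bin_hi = numeric(), n = integer(),
               r = numeric(), p = numeric())
}
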