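# SD(R)-power adjustment of rates and correlations, QCOD-based selection of
# the adjustment power p, and the closed-form proposition checks that link
# adjusted rates to the inverse of maximum lifespan.

#' Adjust per-stratum statistics by a power of SD(R)
#'
#' Uneven relative-age sampling makes both the rate and the methylation-age
#' correlation depend on SD(R), a design property rather than a biological
#' one. The adjustment divides the correlation by \code{SD(R)^p} and
#' multiplies the rate by \code{SD(R)^(1-p)}, so that
#' \code{adj_arocm = adj_cor / L} holds exactly for every p (gestation 0).
#' \code{p = 1} leaves the rate unadjusted; \code{p = 0} leaves the
#' correlation unadjusted.
#'
#' @param stats data.frame from \code{\link{estimateStrata}} (needs
#'   \code{cor_methyl_age}, \code{sd_R}, \code{arocm}, \code{L}).
#' @param p adjustment power in [0, 1].
#' @return \code{stats} with added columns \code{p}, \code{adj_cor},
#'   \code{adj_arocm}, \code{log_adj_cor}, \code{log_adj_arocm},
#'   \code{log_L} (logs are natural; \code{NA} when the argument is
#'   non-positive).
#' @export
adjustStats <- function(stats, p) {
  stopifnot(is.numeric(p), length(p) == 1, p >= 0, p <= 1)
  if (any(stats$sd_R <= 0))
    stop("sd_R must be positive for adjustment")
  out <- stats
  out$p <- p
  out$adj_cor <- out$cor_methyl_age / out$sd_R^p
  out$adj_arocm <- out$arocm * out$sd_R^(1 - p)
  safeLog <- function(x) {
    y <- rep(NA_real_, length(x))
    ok <- is.finite(x) & x > 0
    y[ok] <- log(x[ok])
    y
  }
  out$log_adj_cor <- safeLog(out$adj_cor)
  out$log_adj_arocm <- safeLog(out$adj_arocm)
  out$log_L <- safeLog(out$L)
  out
}

#' Quartile coefficient of dispersion
#'
#' \code{(Q3 - Q1) / (Q3 + Q1)}: a robust, scale-invariant alternative to
#' the coefficient of variation. Quartiles use linear interpolation between
#' order statistics (\code{stats::quantile} type 7).
#'
#' @param values numeric vector, length >= 2; \code{Q3 + Q1} must be
#'   positive, otherwise the measure is undefined and an error is raised.
#' @return non-negative scalar.
#' @examples
#' qcod(1:5)   # 1/3
#' @export
qcod <- function(values) {
  stopifnot(length(values) >= 2, !anyNA(values))
  q <- unname(quantile(values, c(0.25, 0.75), type = 7))
  if (q[1] + q[2] <= 0)
    stop("QCOD undefined: Q1 + Q3 <= 0")
  (q[2] - q[1]) / (q[2] + q[1])
}

.qcodOrNA <- function(values) {
  q <- unname(quantile(values, c(0.25, 0.75), type = 7))
  if (!all(is.finite(q)) || q[1] + q[2] <= 0) return(NA_real_)
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Select the SD(R) adjustment power
#'
#' Profiles a dispersion objective of the adjusted correlations
#' \code{Adj.Cor(p) = cor / sd_R^p} over a grid of powers and returns the
#' minimizer (smallest p on ties). The default objective is the QCOD of the
#' raw adjusted correlations; \code{"qcod-log"} applies the QCOD to their
#' natural logs, and \code{"cv"} uses the (population) coefficient of
#' variation. Strata with non-positive correlation are excluded and
#' counted. When SD(R) is (numerically) constant across strata the profile
#' is flat and the adjustment is undefined; the \code{degenerate} flag is
#' set and the smallest grid value returned.
#'
#' @param stats data.frame with \code{cor_methyl_age} and \code{sd_R}.
#' @param grid numeric grid of candidate powers within [0, 1]
#'   (default \code{seq(0, 1, by = 0.005)}).
#' @param objective \code{"qcod"} (default), \code{"qcod-log"} or
#'   \code{"cv"}.
#' @return list with \code{p_optimal}, \code{objective} (its value at the
#'   optimum), \code{profile} (data.frame \code{p}, \code{objective}),
#'   \code{degenerate} flag, \code{n_used} and \code{n_excluded}.
#' @export
selectAdjustmentPower <- function(stats, grid = seq(0, 1, by = 0.005),
                                  objective = c("qcod", "qcod-log", "cv")) {
  objective <- match.arg(objective)
  stopifnot(all(grid >= 0), all(grid <= 1), length(grid) >= 1)
  use <- stats$cor_methyl_age > 0 & stats$sd_R > 0
  n_excluded <- sum(!use)
  co <- stats$cor_methyl_age[use]
  sdR <- stats$sd_R[use]
  if (length(co) < 3)
    stop("need >= 3 strata with positive methylation-age correlation (have ",
         length(co), ")")
  obj <- vapply(grid, function(p) {
    a <- co / sdR^p
    switch(objective,
      "qcod" = .qcodOrNA(a),
      "qcod-log" = .qcodOrNA(log(a)),
      "cv" = .popsd(a) / mean(a))
  }, numeric(1))
  degenerate <- diff(range(sdR)) < 1e-12 ||
    (all(is.finite(obj)) && diff(range(obj)) < 1e-12)
  if (degenerate)
    warning("flat objective profile: SD(R) (near-)constant across strata, ",
            "adjustment power not identifiable")
  i <- which.min(obj)   # smallest p on exact ties (which.min takes first)
  list(p_optimal = grid[i], objective = obj[i],
       profile = data.frame(p = grid, objective = obj),
       degenerate = degenerate,
       n_used = length(co), n_excluded = n_excluded)
}

#' Closed-form proposition checks across strata
#'
#' Across S strata, writes \code{log(Adj.AROCM) = log(Adj.Cor) - log(L)}
#' and checks the consequences: when the lifespans and adjusted
#' correlations are uncorrelated on the log scale (condition C1), the
#' Pearson correlation between \code{log(Adj.AROCM)} and \code{log(L)}
#' equals \code{-1 / sqrt(1 + Var(log Adj.Cor) / Var(log L))}; as that
#' variance ratio vanishes the correlation approaches -1 and
#' \code{Adj.AROCM ~ c(p)/L} with \code{c(p) = exp(mean(log Adj.Cor))}.
#' Strata with non-positive adjusted correlation are excluded and counted.
#' Variances use the population divisor; the ratio is divisor-invariant.
#'
#' @param adjusted data.frame from \code{\link{adjustStats}}.
#' @return list (class \code{"arocm_proposition_report"}) with \code{S},
#'   \code{var_log_adj_cor}, \code{var_log_L}, \code{ratio_p}
#'   (log-variance ratio), \code{cv_ratio_p} (squared coefficient-of-
#'   variation ratio, the delta-method analogue), \code{predicted_cor},
#'   \code{observed_cor}, \code{c_p}, \code{c1_cor} and
#'   \code{n_excluded}.
#' @export
propositionChecks <- function(adjusted) {
  use <- is.finite(adjusted$log_adj_cor) & is.finite(adjusted$log_L) &
    is.finite(adjusted$log_adj_arocm)
  n_excluded <- sum(!use)
  d <- adjusted[use, , drop = FALSE]
  if (nrow(d) < 3)
    stop("need >= 3 strata with positive adjusted correlation and lifespan")
  vA <- .popvar(d$log_adj_cor)
  vL <- .popvar(d$log_L)
  ratio <- vA / vL
  out <- list(
    S = nrow(d),
    var_log_adj_cor = vA,
    var_log_L = vL,
    ratio_p = ratio,
    cv_ratio_p = (.popsd(d$adj_cor) / mean(d$adj_cor))^2 /
      (.popsd(d$L) / mean(d$L))^2,
    predicted_cor = -1 / sqrt(1 + ratio),
    observed_cor = cor(d$log_L, d$log_adj_arocm),
    c_p = exp(mean(d$log_adj_cor)),
    # constant adjusted correlations (to numerical precision) leave C1
    # undefined; report 0, the value it limits to
    c1_cor = if (sqrt(vA) > 1e-12) cor(d$log_L, d$log_adj_cor) else 0,
    n_excluded = n_excluded)
  class(out) <- c("arocm_proposition_report", "list")
  out
}

#' @export
print.arocm_proposition_report <- function(x, ...) {
  cat("Proposition report over", x$S, "strata",
      if (x$n_excluded) sprintf("(%d excluded, non-positive Adj.Cor)", x$n_excluded) else "",
      "\n")
  cat(sprintf("  Var(log Adj.Cor) = %.4g, Var(log L) = %.4g, Ratio(p) = %.4g\n",
              x$var_log_adj_cor, x$var_log_L, x$ratio_p))
  cat(sprintf("  Cor(log L, log Adj.Cor) [C1] = %.4g\n", x$c1_cor))
  cat(sprintf("  Cor(log L, log Adj.AROCM): observed %.4g, predicted under C1 %.4g\n",
              x$observed_cor, x$predicted_cor))
  cat(sprintf("  c(p) = exp(mean log Adj.Cor) = %.4g\n", x$c_p))
  invisible(x)
}
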