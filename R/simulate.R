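# Synthetic multi-stratum methylation studies with known ground truth.
#
# The generator emulates the statistical structure of a cross-species
# methylation study: many strata with log-uniform lifespans; uneven
# relative-age sampling windows (the mechanism behind heterogeneous SD(R));
# one low-methylated, age-gaining CpG group (bivalent-promoter-like,
# positive trajectory) and one high-methylated, age-losing group
# (quiescent-like, negative trajectory), both following the piecewise
# log-linear life-course curve; beta-value noise at the probe and sample
# level; clipping to [0,1] with the clipping rate reported.

#' Configuration for the synthetic study generator
#'
#' Defaults describe a mammalian-style study: lifespans log-uniform on
#' 2-80 years; per-stratum uniform relative-age windows with starts in
#' [0.02, 0.3] and widths in [0.3, 0.7] (windows, not biology, drive the
#' SD(R) heterogeneity); life-course amplitudes gamma1 uniform on
#' [0.5, 1.5] with per-probe beta amplitudes of 0.02-0.04; probe-level
#' noise SD 0.01 and sample-level noise SD 0.005 on the beta scale.
#' Windows and amplitudes are drawn independently of lifespan, so the
#' design satisfies condition C1 by construction.
#'
#' @param S number of strata.
#' @param n samples per stratum (scalar, or length-2 range sampled
#'   uniformly).
#' @param LRange lifespan range (years), sampled log-uniformly.
#' @param windowStart,windowWidth ranges for the relative-age sampling
#'   window per stratum; the window is clamped inside (0, 1).
#' @param gamma0 life-course intercept (shared).
#' @param gamma1Range range of the life-course amplitude per stratum.
#' @param transform \code{"g"} or \code{"g2"}.
#' @param knot relative-age knot (default 0.1).
#' @param mPerGroup CpGs per chromatin-state-like group.
#' @param probeNoiseSd,sampleNoiseSd beta-scale noise SDs (per cell / per
#'   sample shared across probes).
#' @param baselineLow,baselineHigh baseline beta ranges for the positive
#'   (low-methylated) and negative (high-methylated) groups.
#' @param kRange per-probe amplitude range on the beta scale.
#' @param seed default seed used by \code{\link{simulateStudy}}.
#' @return list of class \code{"arocm_synth_config"}.
#' @export
syntheticConfig <- function(S = 50, n = 30, LRange = c(2, 80),
                            windowStart = c(0.02, 0.3),
                            windowWidth = c(0.3, 0.7),
                            gamma0 = 0, gamma1Range = c(0.5, 1.5),
                            transform = c("g", "g2"), knot = 0.1,
                            mPerGroup = 20, probeNoiseSd = 0.01,
                            sampleNoiseSd = 0.005,
                            baselineLow = c(0.1, 0.2),
                            baselineHigh = c(0.8, 0.9),
                            kRange = c(0.02, 0.04), seed = 1) {
  stopifnot(S >= 1, all(n >= 2), LRange[1] > 0, LRange[1] < LRange[2],
            windowStart[1] > 0, probeNoiseSd >= 0, sampleNoiseSd >= 0,
            mPerGroup >= 1, kRange[1] >= 0)
  structure(list(S = S, n = n, LRange = LRange, windowStart = windowStart,
                 windowWidth = windowWidth, gamma0 = gamma0,
                 gamma1Range = gamma1Range,
                 transform = match.arg(transform), knot = knot,
                 mPerGroup = mPerGroup, probeNoiseSd = probeNoiseSd,
                 sampleNoiseSd = sampleNoiseSd, baselineLow = baselineLow,
                 baselineHigh = baselineHigh, kRange = kRange, seed = seed),
            class = "arocm_synth_config")
}

.runif1 <- function(range, k = 1) {
  if (length(range) == 1) rep(range, k) else runif(k, range[1], range[2])
}

#' Simulate a multi-stratum methylation study
#'
#' Each stratum's per-CpG trajectory is
#' \code{beta = clip(baseline_j + k_j (gamma0 + gamma1_s g(R_i)) + noise)}.
#' The truth table records, per stratum, the lifespan, window, realized
#' SD(R), the raw amplitude \code{gamma1} and its standardized-scale
#' counterpart \code{gamma1_scaled = 1 / SD(g(R))} (the coefficient
#' implied for the standardized mean-methylation response, which is what
#' \code{\link{fitLifeCourse}} estimates), and the model-implied
#' derivative rates at the reference relative ages \code{R0_young = 0.05}
#' and \code{R0_old = 0.5}.
#'
#' @param config an \code{\link{syntheticConfig}} object.
#' @param seed integer seed (defaults to \code{config$seed}); the run is
#'   fully reproducible from \code{(config, seed)}.
#' @return list with \code{study} (a \linkS4class{MethylStudy}),
#'   \code{truth} (data.frame) and \code{clip_rate}. A clipping rate above
#'   10\% triggers a warning.
#' @export
simulateStudy <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "arocm_synth_config"))
  set.seed(seed)
  S <- config$S
  m <- config$mPerGroup
  probes <- data.frame(
    probe_id = c(sprintf("cg_bp_%04d", seq_len(m)),
                 sprintf("cg_qs_%04d", seq_len(m))),
    chromatin_state = rep(c("BivProm2", "Quies1"), each = m),
    prc2_bound = rep(c("+", "-"), each = m),
    stringsAsFactors = FALSE)
  baseline <- c(.runif1(config$baselineLow, m),
                .runif1(config$baselineHigh, m))
  kamp <- c(.runif1(config$kRange, m), -.runif1(config$kRange, m))

  L <- exp(runif(S, log(config$LRange[1]), log(config$LRange[2])))
  a <- .runif1(config$windowStart, S)
  b <- pmin(a + .runif1(config$windowWidth, S), 0.999)
  gamma1 <- .runif1(config$gamma1Range, S)
  nper <- if (length(config$n) == 1) rep(config$n, S) else
    sample(config$n[1]:config$n[2], S, replace = TRUE)

  betas <- matrix(NA_real_, nrow = sum(nper), ncol = 2 * m,
                  dimnames = list(NULL, probes$probe_id))
  samples <- vector("list", S)
  truth <- vector("list", S)
  row0 <- 0L
  nclip <- 0L
  for (s in seq_len(S)) {
    n <- nper[s]
    sid <- sprintf("sp%03d.blood", s)
    R <- runif(n, a[s], b[s])
    g <- loglinearTransform(R, config$transform, config$knot)$value
    traj <- config$gamma0 + gamma1[s] * g
    eSample <- rnorm(n, 0, config$sampleNoiseSd)
    raw <- outer(traj, kamp) +
      matrix(baseline, n, 2 * m, byrow = TRUE) + eSample +
      matrix(rnorm(n * 2 * m, 0, config$probeNoiseSd), n, 2 * m)
    nclip <- nclip + sum(raw < 0 | raw > 1)
    betas[row0 + seq_len(n), ] <- pmin(pmax(raw, 0), 1)
    samples[[s]] <- data.frame(
      sample_id = sprintf("s%03d_%03d", s, seq_len(n)),
      species = sprintf("sp%03d", s), tissue = "blood",
      age = R * L[s], stringsAsFactors = FALSE)
    gsc <- 1 / .popsd(g)
    dyoung <- loglinearTransform(0.05, config$transform, config$knot)$deriv
    dold <- loglinearTransform(0.5, config$transform, config$knot)$deriv
    truth[[s]] <- data.frame(
      stratum_id = sid, species = sprintf("sp%03d", s), L = L[s],
      gamma0 = config$gamma0, gamma1 = gamma1[s],
      window_lo = a[s], window_hi = b[s], sd_R = .popsd(R),
      gamma1_scaled = gsc,
      R0_young = 0.05, R0_old = 0.5,
      arocm_young_true = gsc * dyoung / L[s],
      arocm_old_true = gsc * dold / L[s],
      stringsAsFactors = FALSE)
    row0 <- row0 + n
  }
  samples <- do.call(rbind, samples)
  rownames(betas) <- samples$sample_id
  truth <- do.call(rbind, truth)
  clip_rate <- nclip / length(betas)
  if (clip_rate > 0.1)
    warning(sprintf("%.1f%% of simulated betas were clipped to [0,1]",
                    100 * clip_rate))
  traits <- data.frame(species = sprintf("sp%03d", seq_len(S)),
                       max_lifespan = L,
                       adult_weight = exp(log(L) * 1.5 + rnorm(S, 0, 0.5)),
                       stringsAsFactors = FALSE)
  list(study = MethylStudy(betas, samples, traits, probes),
       truth = truth, clip_rate = clip_rate)
}

#' Construct a stratum with an exact methylation-age correlation
#'
#' Deterministic builder for validation studies: ages are placed at the
#' midpoints of \code{n} equal slices of \code{window} (times L), and the
#' methylation vector is engineered so that its Pearson correlation with
#' age equals \code{r} exactly (a standardized age component plus an
#' orthogonal alternating component, mapped affinely into the beta range).
#' Alternatively pass \code{ages} and/or \code{methyl} explicitly.
#'
#' @param n number of samples (>= 3 unless \code{abs(r) = 1}).
#' @param L maximum lifespan, years.
#' @param window relative-age window \code{c(lo, hi)} within [0, 1].
#' @param r target Pearson correlation in [-1, 1].
#' @param ages optional explicit ages (years).
#' @param methyl optional explicit methylation means (overrides \code{r}).
#' @param stratumId,species,tissue labels.
#' @return a \linkS4class{StratumView} over the full relative-age range.
#' @export
makeCorStratum <- function(n = 20, L = 10, window = c(0, 1), r = 1,
                           ages = NULL, methyl = NULL,
                           stratumId = "s1", species = stratumId,
                           tissue = "blood") {
  if (is.null(ages)) {
    stopifnot(window[1] >= 0, window[2] <= 1, window[1] < window[2])
    R <- window[1] + (seq_len(n) - 0.5) / n * (window[2] - window[1])
    ages <- R * L
  }
  n <- length(ages)
  if (is.null(methyl)) {
    stopifnot(r >= -1, r <= 1)
    za <- scaleValues(ages)
    if (abs(r) == 1) {
      target <- r * za
    } else {
      stopifnot(n >= 3)
      u <- rep_len(c(1, -1), n)
      zb <- resid(lm(u ~ za))
      if (.popsd(zb) < 1e-12) {
        u <- seq_len(n)^2
        zb <- resid(lm(u ~ za))
      }
      zb <- zb / .popsd(zb)
      target <- r * za + sqrt(1 - r^2) * zb
    }
    methyl <- 0.5 + 0.4 * target / max(abs(target))
  }
  .newStratumView(stratumId, ages, methyl, L, c(0, 1),
                  species = species, tissue = tissue)
}

#' Compare estimated stratum quantities with simulation truth
#'
#' Joins truth and estimates by \code{stratum_id} and reports bias, RMSE
#' and Pearson correlation for each shared metric
#' (\code{gamma1_scaled} vs estimated \code{gamma1},
#' \code{arocm_young_true} / \code{arocm_old_true} vs estimated rates),
#' plus the through-origin regression slope of the young rates on the old
#' rates across strata against its model-implied value
#' \code{knot / R0_young}.
#'
#' @param truth truth table from \code{\link{simulateStudy}}.
#' @param estimates data.frame with \code{stratum_id} and any of
#'   \code{gamma1}, \code{arocm_young}, \code{arocm_old}.
#' @param knot relative-age knot used in estimation.
#' @return list with \code{metrics} (data.frame metric/bias/rmse/cor),
#'   \code{eq34_slope}, \code{eq34_expected} and \code{n}.
#' @export
recoveryReport <- function(truth, estimates, knot = 0.1) {
  if (!all(estimates$stratum_id %in% truth$stratum_id))
    stop("estimates contain stratum ids absent from truth")
  for (nm in c("gamma1", "arocm_young", "arocm_old")) {
    if (nm %in% colnames(estimates))
      colnames(estimates)[colnames(estimates) == nm] <- paste0(nm, "_est")
  }
  d <- merge(truth, estimates, by = "stratum_id")
  pairs <- list(gamma1 = c("gamma1_scaled", "gamma1_est"),
                arocm_young = c("arocm_young_true", "arocm_young_est"),
                arocm_old = c("arocm_old_true", "arocm_old_est"))
  rows <- list()
  for (nm in names(pairs)) {
    tc <- pairs[[nm]][1]; ec <- pairs[[nm]][2]
    if (!(ec %in% colnames(d))) next
    err <- d[[ec]] - d[[tc]]
    rows[[nm]] <- data.frame(
      metric = nm, bias = mean(err), rmse = sqrt(mean(err^2)),
      cor = if (nrow(d) >= 3) cor(d[[tc]], d[[ec]]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- list(metrics = do.call(rbind, rows), n = nrow(d))
  if (all(c("arocm_young_est", "arocm_old_est") %in% colnames(d))) {
    out$eq34_slope <- sum(d$arocm_young_est * d$arocm_old_est) /
      sum(d$arocm_old_est^2)
    out$eq34_expected <- knot / d$R0_young[1]
  }
  out
}
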