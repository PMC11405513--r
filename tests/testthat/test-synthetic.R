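test_that("simulation is reproducible from (config, seed) and seed-sensitive", {
  cfg <- syntheticConfig(S = 5, n = 50, seed = 1)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_equal(ncol(a$study), 250)
  expect_identical(betas(a$study), betas(b$study))
  expect_identical(a$truth, b$truth)
  d <- simulateStudy(cfg, seed = 2)
  expect_false(identical(betas(a$study), betas(d$study)))
  # bundle passes load validation via the CSV round trip
  dir <- tempfile(); dir.create(dir)
  tb <- betas(a$study)
  write.csv(data.frame(sample_id = colnames(tb), t(tb),
                       check.names = FALSE),
            file.path(dir, "b.csv"), row.names = FALSE)
  write.csv(sampleSheet(a$study)[, c("sample_id", "species", "tissue", "age")],
            file.path(dir, "s.csv"), row.names = FALSE)
  write.csv(speciesTraits(a$study), file.path(dir, "t.csv"),
            row.names = FALSE)
  write.csv(cpgAnnotation(a$study), file.path(dir, "a.csv"),
            row.names = FALSE)
  back <- loadStudy(file.path(dir, "b.csv"), file.path(dir, "s.csv"),
                    file.path(dir, "t.csv"), file.path(dir, "a.csv"))
  expect_equal(dim(back), dim(a$study))
})

test_that("noiseless simulation gives perfectly log-linear trajectories", {
  cfg <- syntheticConfig(S = 4, n = 30, probeNoiseSd = 0, sampleNoiseSd = 0,
                         seed = 7)
  sim <- simulateStudy(cfg)
  views <- buildStrata(sim$study, selectStateCpGs(sim$study, "BivProm2", "+"))
  for (v in views) {
    g <- loglinearTransform(relAges(v), "g")$value
    expect_equal(abs(cor(methylMeans(v), g)), 1, tolerance = 1e-9)
    fit <- suppressWarnings(fitLifeCourse(v))
    tr <- sim$truth[sim$truth$stratum_id == stratumId(v), ]
    expect_equal(fit@gamma1, tr$gamma1_scaled, tolerance = 1e-7)
  }
  # negative-trajectory group yields negative age correlations
  vq <- buildStrata(sim$study, selectStateCpGs(sim$study, "Quies1", "-"))
  st <- estimateStrata(vq)
  expect_true(all(st$cor_methyl_age < 0))
  expect_true(all(st$arocm < 0))
})

test_that("realized SD(R) tracks the uniform-window value (b-a)/sqrt(12)", {
  cfg <- syntheticConfig(S = 40, n = 400, seed = 9)
  sim <- simulateStudy(cfg)
  expected <- (sim$truth$window_hi - sim$truth$window_lo) / sqrt(12)
  expect_equal(sim$truth$sd_R, expected, tolerance = 0.12)
  expect_gt(cor(sim$truth$sd_R, expected), 0.98)
})

test_that("recovery report: noiseless data has ~zero error, Eq-34 slope holds", {
  cfg <- syntheticConfig(S = 12, n = 60, probeNoiseSd = 0,
                         sampleNoiseSd = 0, windowStart = c(0.02, 0.05),
                         windowWidth = c(0.8, 0.93), seed = 13)
  sim <- simulateStudy(cfg)
  views <- buildStrata(sim$study, selectStateCpGs(sim$study, "BivProm2", "+"))
  est <- do.call(rbind, lapply(views, function(v) {
    fit <- fitLifeCourse(v)
    data.frame(stratum_id = stratumId(v), gamma1 = fit@gamma1,
               arocm_young = derivativeAROCM(fit, maxLifespan(v), 0.05),
               arocm_old = derivativeAROCM(fit, maxLifespan(v), 0.5))
  }))
  rep <- recoveryReport(sim$truth, est)
  g1 <- rep$metrics[rep$metrics$metric == "gamma1", ]
  expect_lt(g1$rmse, 1e-6)
  expect_lt(abs(g1$bias), 1e-6)
  expect_equal(rep$eq34_expected, 2)            # knot / 0.05
  expect_equal(rep$eq34_slope, 2, tolerance = 1e-6)
  expect_error(recoveryReport(sim$truth,
                              data.frame(stratum_id = "nope", gamma1 = 1)),
               "absent")
})

test_that("post-hoc probe selection inflates the inverse-lifespan correlation", {
  # null data: no age signal at all; selecting probes by their realized
  # positive age correlation within each stratum manufactures positive
  # rates whose size tracks 1/(SD(R) L) - a selection artifact the
  # state-based analysis avoids
  cfg <- syntheticConfig(S = 25, n = 40, gamma1Range = c(0, 0),
                         probeNoiseSd = 0.03, sampleNoiseSd = 0, seed = 17)
  sim <- simulateStudy(cfg)
  study <- sim$study
  all_probes <- rownames(study)
  cd <- sampleSheet(study)
  state_st <- estimateStrata(
    buildStrata(study, selectStateCpGs(study, "BivProm2", "+")))
  posthoc <- lapply(sort(unique(cd$stratum_id)), function(sid) {
    idx <- cd$stratum_id == sid
    b <- betas(study)[, idx, drop = FALSE]
    age <- cd$age[idx]
    rs <- apply(b, 1, function(x) cor(x, age))
    sel <- all_probes[rs > 0]
    if (length(sel) < 2) return(NULL)
    v <- buildStrata(study, sel)[[sid]]
    if (is.null(v)) NULL else estimateAROCM(v)
  })
  posthoc_st <- do.call(rbind, posthoc)
  r_state <- cor(state_st$arocm, 1 / state_st$L)
  r_posthoc <- cor(posthoc_st$arocm, 1 / posthoc_st$L)
  expect_gt(r_posthoc, r_state)
  expect_gt(r_posthoc, 0.5)   # strong artifactual correlation from nothing
})

test_that("C1-design: adjusted correlation decouples from lifespan", {
  cfg <- syntheticConfig(S = 200, n = 30, seed = 19)
  sim <- simulateStudy(cfg)
  st <- estimateStrata(
    buildStrata(sim$study, selectStateCpGs(sim$study, "BivProm2", "+")))
  adj <- adjustStats(st, 0.25)
  rep <- propositionChecks(adj)
  expect_lt(abs(rep$c1_cor), 0.15)
})

test_that("makeCorStratum hits the requested correlation exactly", {
  for (r in c(-0.8, -0.3, 0, 0.4, 0.9, 1)) {
    v <- makeCorStratum(n = 17, L = 12, window = c(0.05, 0.9), r = r)
    expect_equal(cor(methylMeans(v), sampleAges(v)), r, tolerance = 1e-10)
    expect_true(all(methylMeans(v) >= 0 & methylMeans(v) <= 1))
  }
})
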