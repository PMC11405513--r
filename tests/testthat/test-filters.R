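# helper: a stratum whose samples sit uniformly in [0, hi) of relative age
# with a perfectly linear methylation trajectory (cor = 1); its AROCM on a
# sub-interval [0, u) is 1 / (SD(R | R < u) * L), so small L inflates it.
linearStratum <- function(L, hi = 0.3, n = 60, id = "lin") {
  makeCorStratum(n = n, L = L, window = c(0.001, hi), r = 1, stratumId = id)
}

test_that("mode defaults follow the published thresholds", {
  m <- filterConfig("mammal")
  d <- filterConfig("dog")
  expect_equal(m$minSdR, 0.06)
  expect_equal(d$minSdR, 0.1)
  expect_equal(m$arocmRange, c(-1, 10))
  expect_equal(d$minR2, 0.2)
  expect_equal(m$minN, 3)
})

test_that("planted violations are recovered with perfect precision/recall", {
  set.seed(41)
  mkstats <- function(id, n = 30, sd_R = 0.2, r2 = 0.9, arocm = 0.5) {
    data.frame(stratum_id = id, n = n, sd_R = sd_R, r_squared = r2,
               arocm = arocm, stringsAsFactors = FALSE)
  }
  stats <- rbind(
    mkstats("ok1"), mkstats("ok2", sd_R = 0.3),
    mkstats("tiny", n = 2),
    mkstats("narrow", sd_R = 0.05),
    mkstats("dogonly", sd_R = 0.08),
    mkstats("badfit", r2 = 0.1))
  dec_m <- applyFilters(stats, filterConfig("mammal"))
  dec_d <- applyFilters(stats, filterConfig("dog"))

  # mammal: small_n and low_sd_R fire exactly where planted
  expect_identical(dec_m$kept,
                   c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(dec_m$reasons[3], "small_n")
  expect_identical(dec_m$reasons[4], "low_sd_R")
  # dog: additionally the 0.08 stratum and the poor fit are rejected
  expect_identical(dec_d$kept,
                   c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(dec_d$reasons[5], "low_sd_R")
  expect_identical(dec_d$reasons[6], "low_r2")
  # kept <=> reasons empty, all rules reported (no short-circuit)
  expect_identical(dec_m$kept, dec_m$reasons == "")
  multi <- applyFilters(mkstats("both", n = 2, sd_R = 0.01),
                        filterConfig("mammal"))
  expect_identical(multi$reasons, "small_n,low_sd_R")
})

test_that("derived-interval check confirms or clears out-of-range rates", {
  cfg <- filterConfig("mammal")
  # L = 2: the young-interval AROCM exceeds 10 but the derived intervals
  # [0,0.2) and [0,0.3) give in-range rates -> outlier
  full <- linearStratum(L = 2)
  young <- makeCorStratum(L = 2, ages = sampleAges(full)[relAges(full) < 0.1],
                          methyl = methylMeans(full)[relAges(full) < 0.1])
  st <- estimateAROCM(young)
  st$upper <- 0.1
  expect_gt(st$arocm, 10)
  chk <- derivedIntervalCheck(full, st, cfg)
  expect_true(chk$is_outlier)
  expect_true(all(chk$derived > -1 & chk$derived < 10))

  # L = 0.4: derived rates are out of range too -> not declared an outlier
  full2 <- linearStratum(L = 0.4)
  young2 <- makeCorStratum(L = 0.4,
                           ages = sampleAges(full2)[relAges(full2) < 0.1],
                           methyl = methylMeans(full2)[relAges(full2) < 0.1])
  st2 <- estimateAROCM(young2)
  st2$upper <- 0.1
  chk2 <- derivedIntervalCheck(full2, st2, cfg)
  expect_false(chk2$is_outlier)
  expect_true(all(chk2$derived >= 10))

  # too few samples in the derived intervals -> abstention
  sparse <- makeCorStratum(L = 2, ages = c(0.05, 0.1, 0.15),
                           methyl = c(0.1, 0.3, 0.2))
  st3 <- estimateAROCM(sparse)
  st3$upper <- 0.1
  chk3 <- derivedIntervalCheck(
    makeCorStratum(L = 2, ages = c(0.05, 0.1), methyl = c(0.1, 0.3)),
    st3, cfg)
  expect_equal(chk3$abstained, 2)
  expect_false(chk3$is_outlier)

  # in applyFilters: outlier rejected; unverifiable rejected conservatively;
  # reproduced extreme kept but flagged for review. The young interval has
  # a small SD(R) by construction, so loosen that threshold to isolate the
  # range rule.
  cfg_loose <- filterConfig("mammal", minSdR = 0.01)
  stats <- rbind(cbind(st, review_case = "outlier"),
                 cbind(st2, review_case = "extreme_everywhere"))
  stats$stratum_id <- c("A", "B")
  dec <- applyFilters(stats, cfg_loose, views = list(A = full, B = full2))
  expect_identical(dec$reasons[1], "arocm_outlier")
  expect_false(dec$kept[1])
  expect_true(dec$kept[2])
  expect_true(dec$review[2])
  dec2 <- applyFilters(stats[1, ], cfg_loose, views = list())
  expect_identical(dec2$reasons, "arocm_range_unverifiable")
  # in-range rate: the rule does not fire at all
  okv <- linearStratum(L = 30, id = "ok")
  stok <- estimateAROCM(okv)
  expect_true(applyFilters(stok, cfg, views = list(ok = okv))$kept)
})

test_that("filters are deterministic, permutation-invariant and monotone", {
  set.seed(43)
  views <- lapply(1:12, function(i) randomStratumView(id = paste0("s", i)))
  names(views) <- paste0("s", 1:12)
  stats <- estimateStrata(views)
  cfg <- filterConfig("mammal")
  dec <- applyFilters(stats, cfg, views)
  perm <- sample(nrow(stats))
  dec_p <- applyFilters(stats[perm, ], cfg, views)
  expect_equal(dec_p[order(dec_p$stratum_id), ],
               dec[order(dec$stratum_id), ], ignore_attr = TRUE)
  # loosening a threshold never rejects a previously kept stratum
  loose <- filterConfig("mammal", minSdR = 0.01, minN = 2)
  dec_l <- applyFilters(stats, loose, views)
  expect_true(all(dec_l$kept[dec$kept]))
})
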