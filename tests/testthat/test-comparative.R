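test_that("species aggregation takes tissue medians", {
  st <- data.frame(
    species = c("a", "a", "a", "b", "b", "c"),
    stratum_id = paste0("s", 1:6),
    L = c(10, 10, 10, 20, 20, 30),
    arocm = c(0.1, 0.2, 0.4, 0.1, 0.3, 0.7),
    cor_methyl_age = c(0.5, 0.6, 0.7, 0.4, 0.6, 0.9))
  sp <- aggregateBySpecies(st)
  expect_equal(sp$arocm, c(0.2, 0.2, 0.7))
  expect_equal(sp$cor_methyl_age, c(0.6, 0.5, 0.9))
  expect_equal(sp$n_strata, c(3, 2, 1))
})

test_that("lifespan correlation modes behave on exact power laws", {
  tab <- data.frame(L = c(5, 10, 20, 40), m = 2 / c(5, 10, 20, 40))
  cc <- lifespanCorrelations(tab, "m", "pearson-vs-inverse-L")
  expect_equal(cc$r, 1, tolerance = 1e-12)
  expect_equal(cc$p, 0)
  ll <- lifespanCorrelations(tab, "m", "pearson-log-log")
  expect_equal(ll$r, -1, tolerance = 1e-12)
  expect_equal(ll$slope, -1, tolerance = 1e-10)
  sp <- lifespanCorrelations(tab, "m", "spearman-vs-inverse-L")
  expect_equal(sp$r, 1)
  # monotone decreasing metric: spearman vs 1/L is +1, vs L would be -1
  tab2 <- data.frame(L = c(3, 7, 12, 30), m = c(8, 5, 4, 1))
  expect_equal(lifespanCorrelations(tab2, "m", "spearman-vs-inverse-L")$r, 1)
  # the a constant rescales but cannot change r
  expect_equal(lifespanCorrelations(tab, "m", "pearson-vs-inverse-L",
                                    a = 3.7)$r, 1, tolerance = 1e-12)
  expect_error(lifespanCorrelations(tab[1:2, ], "m", "pearson-raw"),
               "fewer than 3")
})

test_that("lifespan groups use the published five-way split", {
  expect_equal(as.character(assignLifespanGroup(c(9.9, 15, 22, 30, 45))),
               c("<10", "10-19", "20-24", "25-39", ">=40"))
  # boundaries belong to the upper group
  expect_equal(as.character(assignLifespanGroup(c(10, 20, 25, 40))),
               c("10-19", "20-24", "25-39", ">=40"))
  expect_true(is.ordered(assignLifespanGroup(5)))
})

test_that("Mann-Kendall trend test matches the frozen example and antisymmetry", {
  mk <- mannKendallTrend(1:5)
  expect_equal(mk$S, 10)
  expect_equal(mk$var_S, 50 / 3, tolerance = 1e-12)
  expect_equal(mk$z, 2.2045, tolerance = 1e-4)
  expect_equal(mk$p, 0.0275, tolerance = 1e-3)
  rev <- mannKendallTrend(5:1)
  expect_equal(rev$S, -10)
  expect_equal(abs(rev$z), abs(mk$z), tolerance = 1e-12)
  const <- mannKendallTrend(rep(2, 6))
  expect_equal(const$S, 0)
  expect_equal(const$p, 1)
})

test_that("Mann-Kendall S matches brute-force enumeration up to n = 50", {
  set.seed(52)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    v <- sample(1:8, n, replace = TRUE)          # ties in the values
    g <- sort(sample(1:5, n, replace = TRUE))    # ties in the ordering
    mk <- mannKendallTrend(v, groups = g)
    expect_identical(mk$S, bruteMannKendallS(g, v))
    expect_lte(abs(mk$S), n * (n - 1) / 2)
  }
  # without ties the variance is the textbook n(n-1)(2n+5)/18
  n <- 12
  v <- sample(seq_len(n))
  expect_equal(mannKendallTrend(v)$var_S, n * (n - 1) * (2 * n + 5) / 18)
})

test_that("lifespan models recover a planted generating model", {
  set.seed(53)
  n <- 150
  L <- exp(runif(n, log(2), log(80)))
  W <- exp(rnorm(n, log(L) * 1.4, 0.8))
  # generator uses the published M2-style coefficients
  arocm <- exp(1.92 - 1.3 * log(L) + 0.015 * log(W))
  tab <- data.frame(arocm = arocm, L = L, adult_weight = W)
  m2 <- suppressWarnings(fitLifespanModels(tab, "M2"))  # exact fit
  expect_equal(m2$estimate, c(1.92, -1.3, 0.015), tolerance = 1e-8)
  # a pure-noise weight column gets a near-zero, non-significant weight term
  tab$arocm <- exp(1.92 - 1.3 * log(L) + rnorm(n, 0, 0.3))
  tab$adult_weight <- exp(rnorm(n, 0, 1))
  m2n <- fitLifespanModels(tab, "M2")
  wrow <- m2n[m2n$term == "logW", ]
  expect_lt(abs(wrow$estimate), 0.15)
  expect_lt(abs(wrow$t_value), 2.5)
  # estimates agree with an independent normal-equations solve
  d <- data.frame(y = log(tab$arocm), x1 = log(tab$L),
                  x2 = log(tab$adult_weight))
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(m2n$estimate, as.numeric(beta), tolerance = 1e-8)
  expect_error(fitLifespanModels(tab[1:2, ], "M1"), "too few")
})

test_that("tissue-indicator models M3/M4 estimate planted tissue effects", {
  set.seed(54)
  n <- 200
  L <- exp(runif(n, log(2), log(80)))
  W <- exp(rnorm(n, log(L) * 1.4, 0.8))
  # a 7th tissue keeps the intercept identified alongside the indicators
  tissue <- sample(c("blood", "brain", "skin", "liver", "muscle", "tail",
                     "kidney"), n, replace = TRUE)
  arocm <- exp(1.7 - 1.2 * log(L) + 0.015 * log(W) -
               0.26 * (tissue == "brain") + 0.5 * (tissue == "liver"))
  tab <- data.frame(arocm = arocm, L = L, adult_weight = W, tissue = tissue)
  m4 <- suppressWarnings(fitLifespanModels(tab, "M4"))  # exact fit
  expect_equal(m4$estimate[m4$term == "brain"], -0.26, tolerance = 1e-8)
  expect_equal(m4$estimate[m4$term == "liver"], 0.5, tolerance = 1e-8)
  expect_equal(m4$estimate[m4$term == "muscle"], 0, tolerance = 1e-8)
  # M3 carries only the brain indicator, so plant only a brain effect
  tab3 <- tab
  tab3$arocm <- exp(1.7 - 1.2 * log(L) + 0.015 * log(W) -
                    0.26 * (tissue == "brain"))
  m3 <- suppressWarnings(fitLifespanModels(tab3, "M3"))
  expect_equal(m3$estimate[m3$term == "brain"], -0.26, tolerance = 1e-8)
  expect_setequal(m4$term, c("(Intercept)", "logL", "logW", "brain",
                             "blood", "skin", "liver", "muscle", "tail"))
  tab$tissue <- NULL
  expect_error(fitLifespanModels(tab, "M3"), "tissue")
})

test_that("SD(R)-stratified correlations isolate the inverse-lifespan law", {
  # constant SD(R) within a bin and cor = 1: r vs 1/L is exactly 1
  mkbin <- function(width, Ls, tag) {
    views <- lapply(seq_along(Ls), function(i)
      makeCorStratum(n = 25, L = Ls[i], window = c(0, width), r = 1,
                     stratumId = paste0(tag, i)))
    estimateStrata(views)
  }
  st <- rbind(mkbin(0.80, c(4, 9, 21, 55), "a"),
              mkbin(1.00, c(3, 8, 19, 47), "b"))
  res <- stratifiedBySdR(st, bins = list(c(0.2, 0.25), c(0.25, 0.45)))
  expect_equal(nrow(res), 2)
  expect_equal(res$r, c(1, 1), tolerance = 1e-9)
  # an empty bin is skipped with a message
  expect_message(out <- stratifiedBySdR(st, bins = list(c(0.55, 0.6))),
                 "skipped")
  expect_equal(nrow(out), 0)
})
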