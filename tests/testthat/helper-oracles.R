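# Independent oracles kept deliberately dumb: direct moment formulas and
# explicit pair enumeration, never the package's own code paths.

popsd <- function(v) sqrt(mean((v - mean(v))^2))

# least-squares slope/intercept from the normal equations
bruteSlope <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Mann-Kendall S by explicit double loop
bruteMannKendallS <- function(x, v) {
  n <- length(v)
  S <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(x[j] - x[i]) * sign(v[j] - v[i])
    }
  }
  S
}

# a random non-degenerate stratum view
randomStratumView <- function(n = sample(5:40, 1), L = runif(1, 2, 80),
                              id = "rand") {
  ages <- sort(runif(n, 0, 0.98 * L))
  while (popsd(ages) == 0) ages <- sort(runif(n, 0, 0.98 * L))
  methyl <- runif(n, 0.05, 0.95)
  while (popsd(methyl) == 0) methyl <- runif(n, 0.05, 0.95)
  makeCorStratum(L = L, ages = ages, methyl = methyl, stratumId = id)
}

# tiny four-table study: 3 strata x 2 states, written to CSVs on demand
toyStudyTables <- function() {
  betas <- rbind(
    s1 = c(0.10, 0.20, 0.90, 0.80),
    s2 = c(0.20, 0.30, 0.85, 0.75),
    s3 = c(0.40, 0.50, 0.70, 0.60),
    s4 = c(0.15, 0.25, 0.88, 0.78),
    s5 = c(0.30, 0.40, 0.80, 0.70),
    s6 = c(0.45, 0.55, 0.65, 0.55))
  colnames(betas) <- c("cg1", "cg2", "cg3", "cg4")
  samples <- data.frame(
    sample_id = paste0("s", 1:6),
    species = rep(c("human", "mouse"), each = 3),
    tissue = "blood",
    age = c(10, 30, 60, 0.3, 1.2, 2.5))
  traits <- data.frame(species = c("human", "mouse"),
                       max_lifespan = c(122, 4),
                       gestation = c(0.75, 0.05),
                       adult_weight = c(62, 0.02))
  annotation <- data.frame(
    probe_id = c("cg1", "cg2", "cg3", "cg4"),
    chromatin_state = c("BivProm2", "BivProm2", "Quies1", "Quies1"),
    prc2_bound = c("+", "-", "+", "-"))
  list(betas = betas, samples = samples, traits = traits,
       annotation = annotation)
}

writeToyStudy <- function(dir = tempfile("toy")) {
  tb <- toyStudyTables()
  dir.create(dir)
  paths <- list(
    beta = file.path(dir, "betas.csv"),
    samples = file.path(dir, "samples.csv"),
    traits = file.path(dir, "traits.csv"),
    annotation = file.path(dir, "annotation.csv"))
  write.csv(data.frame(sample_id = rownames(tb$betas), tb$betas,
                       check.names = FALSE),
            paths$beta, row.names = FALSE)
  write.csv(tb$samples, paths$samples, row.names = FALSE)
  write.csv(tb$traits, paths$traits, row.names = FALSE)
  write.csv(tb$annotation, paths$annotation, row.names = FALSE)
  paths
}
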