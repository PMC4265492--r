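test_that("the 2:1 noncentral-t sample size reproduces the design totals", {
  sgrq <- sampleSizeTwoSample(designAssumptions(11, 14))
  expect_equal(sgrq$n_control, 20)
  expect_equal(sgrq$n_treatment, 40)
  expect_equal(sgrq$n_total, 60)
  expect_gte(sgrq$achieved_power, 0.80)
  # the next-smaller multiple of 3 falls short of the target
  expect_lt(twoSampleTPower(11, 14, 38, 19), 0.80)

  fev1 <- sampleSizeTwoSample(designAssumptions(12, 15))
  expect_equal(fev1$n_total, 60)
})

test_that("the 1:1 sample size matches an independent power oracle", {
  res <- sampleSizeTwoSample(designAssumptions(11, 14,
                                               allocation_ratio = 1))
  oracle <- ceiling(stats::power.t.test(delta = 11, sd = 14,
                                        power = 0.80)$n)
  expect_equal(res$n_control, unname(oracle))   # 27 per group
  expect_equal(res$n_total, 2 * unname(oracle))
})

test_that("sample size saturates at the floor for overwhelming effects", {
  res <- sampleSizeTwoSample(designAssumptions(100, 1))
  expect_equal(res$n_control, 2)
  expect_equal(res$n_treatment, 4)
  expect_equal(res$n_total, 6)
  expect_error(sampleSizeTwoSample(designAssumptions(0, 14)),
               "unreachable")
})

test_that("sample size is monotone in effect, sd and power", {
  n <- function(delta, sd, power)
    sampleSizeTwoSample(designAssumptions(delta, sd, power))$n_total
  expect_gte(n(9, 14, 0.8), n(11, 14, 0.8))
  expect_gte(n(11, 16, 0.8), n(11, 14, 0.8))
  expect_gte(n(11, 14, 0.9), n(11, 14, 0.8))
})

test_that("dropout inflation is the ceiling of the inflated total", {
  expect_identical(inflateForDropout(60, 0.15), 69L)
  expect_identical(inflateForDropout(100, 0.10), 110L)
  expect_identical(inflateForDropout(59, 0.15), 68L)   # ceil(67.85)
  expect_identical(inflateForDropout(60, 0), 60L)
})

test_that("the Hochberg rule follows its two-branch truth table", {
  expect_equal(hochbergDecision(0.03, 0.049), "positive")  # both at 0.05
  expect_equal(hochbergDecision(0.020, 0.40), "positive")  # one at 0.025
  expect_equal(hochbergDecision(0.030, 0.20), "negative")
  expect_equal(hochbergDecision(0.05, 0.05), "positive")   # inclusive
  expect_equal(hochbergDecision(0.025, 0.9), "positive")
  expect_equal(hochbergDecision(0.0251, 0.0501), "negative")
  expect_error(hochbergDecision(-0.1, 0.5), "outside")
})

test_that("decreasing either p-value never turns positive into negative", {
  grid <- expand.grid(p1 = c(0.01, 0.03, 0.05, 0.2, 0.8),
                      p2 = c(0.01, 0.03, 0.05, 0.2, 0.8))
  for (i in seq_len(nrow(grid))) {
    d <- hochbergDecision(grid$p1[i], grid$p2[i])
    if (d == "positive") {
      expect_equal(hochbergDecision(grid$p1[i] / 2, grid$p2[i]), "positive")
      expect_equal(hochbergDecision(grid$p1[i], grid$p2[i] / 2), "positive")
    }
  }
})

test_that("responder thresholds are direction-aware and inclusive", {
  fev1 <- endpointSeries("s", "FEV1", baseline = 30)
  expect_true(responderFlag(fev1, 34))        # 13.3% relative gain
  expect_false(responderFlag(fev1, 33))       # 10% falls short
  exact <- endpointSeries("s", "FEV1", baseline = 25)
  expect_true(responderFlag(exact, 28))       # exactly 12%
  expect_true(responderFlag(fev1, 42, fev1_rule = "absolute"))
  expect_false(responderFlag(fev1, 41.9, fev1_rule = "absolute"))

  sgrq <- endpointSeries("s", "SGRQ", baseline = 60)
  expect_true(responderFlag(sgrq, 50))        # -10 points
  expect_true(responderFlag(sgrq, 52))        # exactly -8
  expect_false(responderFlag(sgrq, 53))

  mwt <- endpointSeries("s", "6MWT", baseline = 200)
  expect_false(responderFlag(mwt, 225))       # +25 m falls short
  expect_true(responderFlag(mwt, 230))        # exactly +30
})

test_that("primary-endpoint assembly covers all four provenance branches", {
  obs <- endpointSeries("s", "FEV1", 100, c(26, 39, 52), c(108, 112, 115))
  expect_equal(assemblePrimaryEndpoint(obs),
               list(value = 115, provenance = "observed",
                    sensitivity_exclude = FALSE))

  sae <- endpointSeries("s", "FEV1", 100, c(26, 39, 52), c(108, 112, NA),
                        c(NA, NA, "sae"))
  expect_equal(assemblePrimaryEndpoint(sae)$value, 108)   # worst prior
  expect_equal(assemblePrimaryEndpoint(sae)$provenance, "worst-prior")

  other <- endpointSeries("s", "FEV1", 100, c(26, 39, 52), c(108, 112, NA),
                          c(NA, NA, "other"))
  expect_equal(assemblePrimaryEndpoint(other)$value, 112) # last available
  expect_equal(assemblePrimaryEndpoint(other)$provenance, "locf")

  none <- endpointSeries("s", "FEV1", 100, c(26, 39, 52),
                         c(NA, NA, NA), c("other", "other", "other"))
  res <- assemblePrimaryEndpoint(none)
  expect_equal(res$value, 100)
  expect_equal(res$provenance, "baseline-itt")
  expect_true(res$sensitivity_exclude)

  # worst-prior is direction-aware: for SGRQ the worst value is the highest
  sgrq <- endpointSeries("s", "SGRQ", 60, c(26, 39, 52), c(50, 44, NA),
                         c(NA, NA, "sae"))
  expect_equal(assemblePrimaryEndpoint(sgrq)$value, 50)
})

test_that("every series maps to exactly one provenance class", {
  causes <- list(NULL, "sae", "other")
  for (obs52 in c(TRUE, FALSE)) for (anyPrior in c(TRUE, FALSE)) {
    vals <- c(if (anyPrior) 105 else NA, NA, if (obs52) 110 else NA)
    cause <- c(if (anyPrior) NA else "other", "other",
               if (obs52) NA else "sae")
    s <- endpointSeries("s", "FEV1", 100, c(26, 39, 52), vals, cause)
    res <- assemblePrimaryEndpoint(s)
    expect_true(res$provenance %in%
                  c("observed", "worst-prior", "locf", "baseline-itt"))
  }
})

test_that("blocked randomization keeps the 2:1 ratio in every complete block", {
  subj <- data.frame(subject = sprintf("S%02d", 1:9), site = "A")
  arms <- blockedRandomization(subj, seed = 7)$arm
  expect_equal(sum(arms == "treatment"), 6)
  expect_equal(sum(arms == "control"), 3)
  for (b in 0:2) {
    block <- arms[b * 3 + 1:3]
    expect_equal(sum(block == "treatment"), 2)
  }
  # block size 6 carries 4 treatment / 2 control per block
  a6 <- blockedRandomization(subj[1:6, ], block_size = 6, seed = 7)$arm
  expect_equal(sum(a6 == "treatment"), 4)
  expect_error(blockedRandomization(subj, block_size = 4), "multiple")
})

test_that("randomization is reproducible and per-site independent", {
  subj <- data.frame(subject = sprintf("S%02d", 1:18),
                     site = rep(c("A", "B"), each = 9))
  r1 <- blockedRandomization(subj, seed = 11)
  r2 <- blockedRandomization(subj, seed = 11)
  expect_identical(r1$arm, r2$arm)
  expect_false(identical(r1$arm, blockedRandomization(subj, seed = 12)$arm))
  # enrolling more subjects at site B never perturbs site A's sequence
  more <- rbind(subj, data.frame(subject = sprintf("S%02d", 19:24),
                                 site = "B"))
  r3 <- blockedRandomization(more, seed = 11)
  expect_identical(r3$arm[more$site == "A"], r1$arm[subj$site == "A"])
  # marginal imbalance bounded by one incomplete block per site
  odd <- data.frame(subject = sprintf("S%02d", 1:11),
                    site = rep(c("A", "B"), c(7, 4)))
  ro <- blockedRandomization(odd, seed = 3)
  for (s in c("A", "B")) {
    t <- sum(ro$arm[ro$site == s] == "treatment")
    n <- sum(ro$site == s)
    expect_lte(abs(t - 2 / 3 * n), 2)
  }
})
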