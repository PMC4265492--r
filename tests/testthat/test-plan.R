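test_that("heterogeneity index is the lower-to-upper TAR ratio", {
  expect_equal(heterogeneityIndex(18, 9), 2.0)
  expect_equal(heterogeneityIndex(12, 10), 1.2)
  expect_gte(heterogeneityIndex(12, 10), 1.2)   # at the threshold: eligible
  expect_equal(heterogeneityIndex(10, 10), 1.0) # homogeneous: ineligible
  expect_error(heterogeneityIndex(0, 10), "positive")
  expect_error(heterogeneityIndex(12, -1), "positive")
})

test_that("combined TAR is the air-weighted aggregate of treated segments", {
  one <- data.frame(tissue_ml = 30, air_ml = 270)
  expect_equal(combinedTAR(one), 100 * 30 / 270)   # single segment: own TAR
  two <- data.frame(tissue_ml = c(30, 20), air_ml = c(270, 230))
  expect_equal(combinedTAR(two), 10.0)
  # equal air volumes: plain mean of the segmental TARs
  eq <- data.frame(tissue_ml = c(8, 12), air_ml = c(100, 100))
  expect_equal(combinedTAR(eq), 10.0)
  expect_error(combinedTAR(two[0, ]), "empty")
})

test_that("option enumeration is exhaustive and canonical", {
  m <- buildLungModel(f1Table())
  left <- enumerateOptions(m, "left")
  right <- enumerateOptions(m, "right")
  both <- enumerateOptions(m, "both")
  expect_equal(nrow(left), 24)    # 4 session-1 x 6 session-2 sets
  expect_equal(nrow(right), 21)   # 3 session-1 x 7 session-2 sets
  expect_equal(nrow(both), 45)
  expect_false(anyDuplicated(both$option_id) > 0)
  # lingula never appears; the {LB1, LB2} pair is always the merged segment
  treated <- paste(both$session1, both$session2)
  expect_false(any(grepl("LB4|LB5", treated)))
  expect_false(any(both$session2 == "LB1,LB2"))
  expect_true(all(vapply(strsplit(both$session2, ","), length,
                         1L) %in% 1:2))
})

test_that("constraint filtering applies every window, the cap and HI", {
  opts <- data.frame(option_id = sprintf("o%d", 1:4),
                     s1_fraction = c(50, 50, 50, 29.9),
                     s2_fraction = c(60, 38, 60, 60),
                     combined_fraction = c(96, 98, 110, 89.9),
                     s1_volume_ml = c(900, 900, 1750, 900),
                     s2_volume_ml = c(1000, 1000, 1000, 1000),
                     min_hi = c(1.3, 1.3, 1.3, 1.3))
  res <- applyConstraints(opts)
  expect_true(res$pass[1])               # combined 96 is inside [95, 130]
  expect_false(res$pass_s2_window[2])    # 38% below the 40% lower bound
  expect_false(res$pass_s1_cap[3])       # 1750 ml breaches the session cap
  expect_false(res$pass_s1_window[4])
  # boundary values are inclusive
  edge <- data.frame(option_id = "e", s1_fraction = 30, s2_fraction = 80,
                     combined_fraction = 110, s1_volume_ml = 1700,
                     s2_volume_ml = 1700, min_hi = 1.2)
  expect_true(applyConstraints(edge)$pass)
})

test_that("disease ranking honours the equal-disease tolerance", {
  r1 <- classifyDiseaseRank(c(a = 9.0, b = 10.5, c = 13.0))
  expect_equal(r1$rank[r1$segment_id == "c"], "least")  # 13 - 10.5 > 2
  r2 <- classifyDiseaseRank(c(a = 8.0, b = 8.3, c = 9.0))
  expect_false(any(r2$rank == "least"))                 # all pairwise <= 2
  r3 <- classifyDiseaseRank(c(a = 7.0, b = 8.5, c = 12.5))
  expect_equal(r3$rank[r3$segment_id == "c"], "least")
  expect_equal(r3$rank[r3$segment_id %in% c("a", "b")],
               c("tied", "tied"))                       # most-diseased tie
  r4 <- classifyDiseaseRank(c(a = 5, b = 10, c = 15))
  expect_equal(r4$rank, c("most", "intermediate", "least"))
  expect_error(classifyDiseaseRank(c(a = 5)), "two segments")
})

test_that("selection on F1 removes the least-diseased segment and breaks the TAR tie at the 110% target", {
  m <- buildLungModel(f1Table())
  sel <- selectPlan(m)
  expect_true(isFeasible(sel))
  audit <- planAudit(sel)
  ch <- chosenOption(sel)

  # LB3 is uniquely least diseased on the left: every feasible option
  # treating it is dominance-removed
  rk <- diseaseRank(sel)
  expect_equal(rk$segment_id[rk$rank == "least" & rk$side == "left"], "LB3")
  lb3 <- grepl("LB3", paste(audit$session1, audit$session2))
  expect_true(all(audit$removed_least_diseased[audit$pass & lb3]))

  # the minimum-combined-TAR option is within tolerance of the winner but
  # loses on distance to the 110% combined target
  surv <- audit[audit$pass & !audit$removed_least_diseased, ]
  expect_gt(nrow(surv), 1)
  minTar <- min(surv$combined_tar)
  expect_lte(ch$combined_tar - minTar, 0.30)
  expect_false(ch$option_id ==
                 surv$option_id[which.min(surv$combined_tar)])
  tie <- surv[surv$combined_tar - minTar <= 0.30, ]
  expect_equal(ch$target_distance, min(tie$target_distance))
  expect_identical(ch$option_id, "left:LB2|RB1,RB2")   # pinned via oracle
  expect_true(revalidatePlan(sel, m))
})

test_that("a clear combined-TAR gap decides without the target tie-break", {
  # shrink the tolerance so the F1 tie group collapses to the minimum
  m <- buildLungModel(f1Table())
  sel <- selectPlan(m, planConstraints(combined_tar_tol = 0.01))
  audit <- planAudit(sel)
  surv <- audit[audit$pass & !audit$removed_least_diseased, ]
  expect_equal(chosenOption(sel)$combined_tar, min(surv$combined_tar))
})

test_that("homogeneous lungs yield a no-feasible-plan outcome, not an error", {
  m <- generateLungFixture(seed = 5, strength = 0)   # HI = 1 everywhere
  sel <- selectPlan(m)
  expect_false(isFeasible(sel))
  expect_equal(nrow(chosenOption(sel)), 0)
  expect_equal(nrow(planAudit(sel)), 45)
  expect_false(any(planAudit(sel)$pass_hi))
})

test_that("relabeling segments consistently never changes the chosen tissue", {
  tab <- f1Table()
  m1 <- selectPlan(buildLungModel(tab))
  swap <- tab
  i <- match(c("RB1", "RB3"), swap$segment_id)
  swap$segment_id[i] <- c("RB3", "RB1")
  m2 <- selectPlan(buildLungModel(swap))
  # map the swapped ids back and compare the treated tissue as a set
  treatedSet <- function(sel, map = identity) {
    ch <- chosenOption(sel)
    sort(map(c(ch$session1, strsplit(ch$session2, ",")[[1]])))
  }
  unswap <- function(ids) ifelse(ids == "RB1", "RB3",
                                 ifelse(ids == "RB3", "RB1", ids))
  expect_identical(treatedSet(m2, unswap), treatedSet(m1))
  expect_equal(chosenOption(m1)$combined_tar,
               chosenOption(m2)$combined_tar)
  swapL <- tab
  j <- match(c("LB1", "LB2"), swapL$segment_id)
  swapL$segment_id[j] <- c("LB2", "LB1")
  m3 <- selectPlan(buildLungModel(swapL))
  expect_equal(chosenOption(m1)$combined_tar,
               chosenOption(m3)$combined_tar)
  expect_equal(chosenOption(m1)$combined_fraction,
               chosenOption(m3)$combined_fraction)
})

test_that("plans are scale invariant except through the volume cap", {
  tab <- f1Table()
  scaled <- tab
  scaled[, c("tissue_ml", "air_ml")] <-
    scaled[, c("tissue_ml", "air_ml")] * 0.5
  s1 <- selectPlan(buildLungModel(tab))
  s2 <- selectPlan(buildLungModel(scaled))
  expect_identical(chosenOption(s1)$option_id, chosenOption(s2)$option_id)
  # scaling up makes the large two-segment sessions breach 1700 ml
  big <- tab
  big[, c("tissue_ml", "air_ml")] <- big[, c("tissue_ml", "air_ml")] * 2
  sBig <- selectPlan(buildLungModel(big))
  audit <- planAudit(sBig)
  expect_true(any(!audit$pass_s2_cap))
  expect_false(identical(audit$pass, planAudit(s1)$pass))
})

test_that("least-diseased removal never empties a non-empty survivor set", {
  for (seed in 1:40) {
    m <- generateLungFixture(seed = seed, strength = (seed %% 5) / 4,
                             upper_volume_range = c(150, 900))
    sel <- selectPlan(m)
    audit <- planAudit(sel)
    if (any(audit$pass))
      expect_true(isFeasible(sel),
                  label = sprintf("seed %d keeps a survivor", seed))
  }
})
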