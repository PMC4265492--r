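.TREATMENT_PHONE  <- c(1, 4, 14, 17, 32, 45)
.TREATMENT_CLINIC <- c(2, 8, 12, 15, 21, 26, 39, 52)

#' Follow-up visit calendar for one arm
#'
#' Treatment-arm patients have telephone calls at weeks 1, 4, 14, 17, 32,
#' 45 and clinic visits at weeks 2, 8, 12, 15, 21, 26, 39, 52; the second
#' treatment session is scheduled 13 weeks after the first (nominal day 91
#' from study day 1, +/- 7 days), extendable by up to 4 weeks when healing
#' is incomplete (latest start day 126). Control patients skip the week 1,
#' 14 and 15 visits entirely, and their week-2 contact is a telephone call
#' rather than a clinic visit.
#'
#' @param arm \code{"treatment"} or \code{"control"}.
#' @return a \linkS4class{VisitSchedule}.
#' @examples
#' visitSchedule("control")
#' @export
visitSchedule <- function(arm = c("treatment", "control")) {
  arm <- match.arg(arm)
  if (arm == "treatment")
    new("VisitSchedule", arm = arm, phoneWeeks = .TREATMENT_PHONE,
        clinicWeeks = .TREATMENT_CLINIC,
        secondSession = list(nominalDay = 91, window = c(84, 98),
                             latestDelayedDay = 126))
  else
    new("VisitSchedule", arm = arm,
        phoneWeeks = sort(c(setdiff(.TREATMENT_PHONE, c(1, 14)), 2)),
        clinicWeeks = setdiff(.TREATMENT_CLINIC, c(2, 15)),
        secondSession = list())
}

setMethod("show", "VisitSchedule", function(object) {
  cat("VisitSchedule [", object@arm, "]\n", sep = "")
  cat("  phone weeks: ", paste(object@phoneWeeks, collapse = ", "), "\n",
      sep = "")
  cat("  clinic weeks: ", paste(object@clinicWeeks, collapse = ", "), "\n",
      sep = "")
  if (length(object@secondSession))
    cat(sprintf("  second session: day %d (window %d-%d, latest %d)\n",
                object@secondSession$nominalDay,
                object@secondSession$window[1],
                object@secondSession$window[2],
                object@secondSession$latestDelayedDay))
})

.ENDPOINT_BASELINES <- list(FEV1 = c(mean = 32, sd = 6),
                            SGRQ = c(mean = 60, sd = 10),
                            `6MWT` = c(mean = 300, sd = 60))

#' Generate a synthetic two-arm outcome cohort
#'
#' Outcomes follow the design's implicit normal model: for each endpoint
#' the 12-month change is normal with common standard deviation and a
#' between-arm mean difference equal to the assumed effect (control change
#' centred at zero). Follow-up values are generated at weeks 26, 39 and 52.
#' Missingness is simple Bernoulli: a dropping subject loses all visits
#' from a uniformly chosen follow-up onward, with the cause recorded as
#' \code{"sae"} or \code{"other"}, so that every branch of the missing-data
#' hierarchy occurs in a large cohort.
#'
#' @param effect treatment-minus-control mean difference at 12 months.
#' @param sd common outcome standard deviation.
#' @param n_treatment,n_control arm sizes.
#' @param endpoint \code{"FEV1"}, \code{"SGRQ"} or \code{"6MWT"};
#'   improvement direction is handled (SGRQ effects lower the score).
#' @param dropout_prob probability a subject's data are missing from some
#'   follow-up onward for non-SAE reasons.
#' @param sae_prob probability of SAE-caused missingness.
#' @param seed integer seed; the cohort is reproducible under it.
#' @return data.frame: \code{subject}, \code{arm}, \code{endpoint},
#'   \code{baseline}, \code{w26}, \code{w39}, \code{w52} (NA when
#'   missing), \code{missing_from} (first missing week or NA),
#'   \code{missing_cause}.
#' @export
generateCohort <- function(effect, sd, n_treatment = 40, n_control = 20,
                           endpoint = "FEV1", dropout_prob = 0.1,
                           sae_prob = 0.05, seed = NULL) {
  stopifnot(sd > 0, n_treatment >= 1, n_control >= 1,
            dropout_prob >= 0, dropout_prob <= 1,
            sae_prob >= 0, sae_prob <= 1, dropout_prob + sae_prob <= 1)
  endpoint <- match.arg(endpoint, names(.ENDPOINT_BASELINES))
  n <- n_treatment + n_control
  dirSign <- if (.higherBetter(endpoint)) 1 else -1
  bl <- .ENDPOINT_BASELINES[[endpoint]]
  withSeed(seed, {
    arm <- c(rep("treatment", n_treatment), rep("control", n_control))
    baseline <- rnorm(n, bl["mean"], bl["sd"])
    armShift <- dirSign * effect * (arm == "treatment")
    vals <- sapply(c(26, 39, 52), function(w)
      baseline + armShift * (w / 52) + rnorm(n, 0, sd))
    u <- runif(n)
    missFrom <- rep(NA_real_, n)
    cause <- rep(NA_character_, n)
    missing <- u < dropout_prob + sae_prob
    cause[missing] <- ifelse(u[missing] < sae_prob, "sae", "other")
    missFrom[missing] <- sample(c(26, 39, 52), sum(missing), replace = TRUE)
    for (j in seq_along(c(26, 39, 52))) {
      w <- c(26, 39, 52)[j]
      vals[missing & w >= missFrom, j] <- NA
    }
    data.frame(subject = sprintf("S%04d", seq_len(n)), arm = arm,
               endpoint = endpoint, baseline = baseline,
               w26 = vals[, 1], w39 = vals[, 2], w52 = vals[, 3],
               missing_from = missFrom, missing_cause = cause,
               stringsAsFactors = FALSE)
  })
}

#' Extract one subject's EndpointSeries from a generated cohort
#'
#' @param cohort data.frame from \code{\link{generateCohort}}.
#' @param subject subject id.
#' @return an \linkS4class{EndpointSeries}.
#' @export
cohortSeries <- function(cohort, subject) {
  row <- cohort[cohort$subject == subject, ]
  if (nrow(row) != 1L) stop("unknown subject: ", subject, call. = FALSE)
  weeks <- c(26, 39, 52)
  vals <- as.numeric(row[, c("w26", "w39", "w52")])
  cause <- rep(NA_character_, 3)
  cause[is.na(vals)] <- row$missing_cause
  endpointSeries(row$subject, row$endpoint, row$baseline, weeks, vals,
                 cause)
}

#' Monte-Carlo power of the two-sided two-sample t-test
#'
#' Simulates normal outcomes in both arms and applies the pooled-variance
#' two-sample t-test at the given level. The test statistic is computed
#' vectorised over replicates; a unit test pins it against
#' \code{stats::t.test}.
#'
#' @param effect true mean difference.
#' @param sd common standard deviation.
#' @param n_treatment,n_control arm sizes (each >= 2).
#' @param alpha two-sided level.
#' @param replicates number of simulated trials (>= 1000 recommended for
#'   reported estimates).
#' @param seed integer seed.
#' @return list: \code{power} (rejection fraction), \code{se} (Monte-Carlo
#'   standard error), \code{replicates}.
#' @examples
#' simulateTrialPower(11, 14, 40, 20, replicates = 2000, seed = 1)$power
#' @export
simulateTrialPower <- function(effect, sd, n_treatment = 40,
                               n_control = 20, alpha = 0.05,
                               replicates = 10000, seed = NULL) {
  stopifnot(n_treatment >= 2, n_control >= 2, sd > 0, replicates >= 1)
  df <- n_treatment + n_control - 2
  crit <- qt(1 - alpha / 2, df)
  withSeed(seed, {
    # chunked so memory stays modest at large replicate counts
    chunk <- 20000L
    reject <- 0
    done <- 0L
    while (done < replicates) {
      m <- min(chunk, replicates - done)
      xt <- matrix(rnorm(n_treatment * m, effect, sd), n_treatment, m)
      xc <- matrix(rnorm(n_control * m, 0, sd), n_control, m)
      mt <- colMeans(xt); mc <- colMeans(xc)
      vt <- colSums((xt - rep(mt, each = n_treatment))^2)
      vc <- colSums((xc - rep(mc, each = n_control))^2)
      sp2 <- (vt + vc) / df
      tstat <- (mt - mc) / sqrt(sp2 * (1 / n_treatment + 1 / n_control))
      reject <- reject + sum(abs(tstat) > crit)
      done <- done + m
    }
    p <- reject / replicates
    list(power = p, se = sqrt(p * (1 - p) / replicates),
         replicates = replicates)
  })
}

#' Generate a random virtual lung for the planner
#'
#' Emulates an upper-lobe-predominant emphysema pattern: lower-lobe TARs
#' are drawn first and each treatable upper segment's TAR is set to
#' \code{lower-lobe TAR / HI} with a per-segment heterogeneity index
#' \code{HI = 1 + strength * U(hi_jitter)}. At \code{strength = 1} every
#' upper segment satisfies HI >= 1.2 (default jitter starts at 0.3); at
#' \code{strength = 0} the upper lobes equal the lower lobes (HI = 1,
#' homogeneous disease). Segment volumes are drawn uniformly from the
#' stated ranges.
#'
#' @param seed integer seed; fixed seed gives a byte-identical table.
#' @param strength heterogeneity strength in [0, 1].
#' @param upper_volume_range,lingula_volume_range,lower_volume_range total
#'   segment/lobe volume ranges, ml.
#' @param lower_tar_range lower-lobe TAR range, percent.
#' @param hi_jitter range of the HI excess drawn per segment at
#'   \code{strength = 1}.
#' @param as_table return the raw segment table (data.frame) instead of
#'   the built \linkS4class{LungModel}.
#' @return a \linkS4class{LungModel} (or its segment table).
#' @examples
#' m <- generateLungFixture(seed = 1)
#' segmentTable(m)
#' @export
generateLungFixture <- function(seed = NULL, strength = 1,
                                upper_volume_range = c(250, 700),
                                lingula_volume_range = c(150, 350),
                                lower_volume_range = c(1100, 1900),
                                lower_tar_range = c(12, 20),
                                hi_jitter = c(0.3, 1.3),
                                as_table = FALSE) {
  stopifnot(strength >= 0, strength <= 1)
  for (rg in list(upper_volume_range, lingula_volume_range,
                  lower_volume_range, lower_tar_range))
    if (length(rg) != 2L || rg[1] <= 0 || rg[1] > rg[2])
      stop("ranges must be positive and ordered", call. = FALSE)
  withSeed(seed, {
    lowerTar <- c(left = runif(1, lower_tar_range[1], lower_tar_range[2]),
                  right = runif(1, lower_tar_range[1], lower_tar_range[2]))
    mk <- function(id, side, volRange, tar) {
      total <- runif(1, volRange[1], volRange[2])
      air <- total / (1 + tar / 100)
      data.frame(segment_id = id, tissue_ml = total - air, air_ml = air)
    }
    rows <- list()
    for (id in c(.LEFT_TREATABLE, .RIGHT_TREATABLE)) {
      side <- .sideOf(id)
      hi <- 1 + strength * runif(1, hi_jitter[1], hi_jitter[2])
      rows[[id]] <- mk(id, side, upper_volume_range, lowerTar[side] / hi)
    }
    for (id in .LEFT_LINGULA)
      rows[[id]] <- mk(id, "left", lingula_volume_range,
                       lowerTar["left"] / (1 + strength * 0.1))
    rows[["LLL"]] <- mk("LLL", "left", lower_volume_range,
                        lowerTar["left"])
    rows[["RLL"]] <- mk("RLL", "right", lower_volume_range,
                        lowerTar["right"])
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    if (as_table) tab else buildLungModel(tab)
  })
}
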