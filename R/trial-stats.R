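#' Design assumptions for the sample-size calculation
#'
#' @param mean_difference assumed between-arm mean difference at 12 months,
#'   endpoint units.
#' @param sd assumed common standard deviation, endpoint units.
#' @param power target power (default 0.80).
#' @param alpha two-sided type-I error level (default 0.05).
#' @param allocation_ratio treatment:control allocation (default 2).
#' @param dropout_rate anticipated loss to follow-up (default 0.15).
#' @return a \linkS4class{DesignAssumptions}.
#' @export
designAssumptions <- function(mean_difference, sd, power = 0.80,
                              alpha = 0.05, allocation_ratio = 2,
                              dropout_rate = 0.15) {
  new("DesignAssumptions", meanDifference = mean_difference, sd = sd,
      power = power, alpha = alpha, allocationRatio = allocation_ratio,
      dropoutRate = dropout_rate)
}

#' Exact power of the two-sided two-sample t-test
#'
#' Noncentral-t power with pooled degrees of freedom
#' \code{n_t + n_c - 2} and noncentrality
#' \code{delta / (sd * sqrt(1/n_t + 1/n_c))}.
#'
#' @param delta mean difference.
#' @param sd common standard deviation.
#' @param n_treatment,n_control group sizes (>= 2 total per group).
#' @param alpha two-sided level.
#' @return power, fraction.
#' @export
twoSampleTPower <- function(delta, sd, n_treatment, n_control,
                            alpha = 0.05) {
  stopifnot(sd > 0, n_treatment >= 1, n_control >= 1,
            n_treatment + n_control >= 3)
  df <- n_treatment + n_control - 2
  ncp <- delta / (sd * sqrt(1 / n_treatment + 1 / n_control))
  crit <- qt(1 - alpha / 2, df)
  1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
}

#' Sample size for a two-sample t-test with unequal allocation
#'
#' Finds the smallest control-group size \code{n_control >= 2} with
#' \code{n_treatment = ceiling(ratio * n_control)} whose two-sided
#' noncentral-t power reaches the target. With an exact integer ratio the
#' total is always a multiple of \code{ratio + 1}.
#'
#' @param assumptions a \linkS4class{DesignAssumptions}.
#' @param max_n_control search bound on the control-group size.
#' @return list: \code{n_control}, \code{n_treatment}, \code{n_total},
#'   \code{achieved_power}.
#' @examples
#' sampleSizeTwoSample(designAssumptions(11, 14))   # 20 / 40 / 60
#' @export
sampleSizeTwoSample <- function(assumptions, max_n_control = 100000L) {
  stopifnot(is(assumptions, "DesignAssumptions"))
  if (assumptions@meanDifference == 0)
    stop("power unreachable: zero mean difference", call. = FALSE)
  r <- assumptions@allocationRatio
  for (nc in 2:max_n_control) {
    nt <- as.integer(ceiling(r * nc - 1e-9))
    pw <- twoSampleTPower(assumptions@meanDifference, assumptions@sd,
                          nt, nc, assumptions@alpha)
    if (pw >= assumptions@power)
      return(list(n_control = nc, n_treatment = nt, n_total = nc + nt,
                  achieved_power = pw))
  }
  stop("power unreachable within the search bound", call. = FALSE)
}

#' Inflate a sample size for anticipated dropout
#'
#' @param n_total computed total sample size.
#' @param rate anticipated dropout fraction in [0, 1).
#' @return \code{ceiling(n_total * (1 + rate))}.
#' @examples
#' inflateForDropout(60, 0.15)   # 69
#' @export
inflateForDropout <- function(n_total, rate) {
  .assertNumber(n_total, "n_total", lower = 1)
  .assertNumber(rate, "rate", lower = 0)
  if (rate >= 1) stop("dropout rate must be < 1", call. = FALSE)
  # guard against float fuzz at exact products (e.g. 100 * 1.1)
  as.integer(ceiling(n_total * (1 + rate) - 1e-9))
}

#' Two-endpoint Hochberg decision rule
#'
#' The trial is positive when both co-primary endpoints reach significance
#' at the 0.05 level, or either one reaches significance at the 0.025
#' level: \code{max(p) <= 0.05 || min(p) <= 0.025}.
#'
#' @param p_fev1,p_sgrq two-sided p-values in [0, 1].
#' @param alpha overall two-sided level (default 0.05; the single-endpoint
#'   branch uses \code{alpha / 2}).
#' @return \code{"positive"} or \code{"negative"}.
#' @examples
#' hochbergDecision(0.03, 0.049)  # positive (both at 0.05)
#' hochbergDecision(0.02, 0.40)   # positive (one at 0.025)
#' hochbergDecision(0.03, 0.20)   # negative
#' @export
hochbergDecision <- function(p_fev1, p_sgrq, alpha = 0.05) {
  .assertNumber(p_fev1, "p_fev1", 0, 1)
  .assertNumber(p_sgrq, "p_sgrq", 0, 1)
  p <- c(p_fev1, p_sgrq)
  if (max(p) <= alpha || min(p) <= alpha / 2) "positive" else "negative"
}

#' Construct an EndpointSeries
#'
#' @param subject subject id.
#' @param endpoint \code{"FEV1"}, \code{"SGRQ"} or \code{"6MWT"}.
#' @param baseline baseline value.
#' @param weeks follow-up weeks, strictly increasing.
#' @param values values per week, NA when missing.
#' @param missing_cause per week: NA when observed, otherwise \code{"sae"}
#'   or \code{"other"}.
#' @return an \linkS4class{EndpointSeries}.
#' @export
endpointSeries <- function(subject, endpoint, baseline,
                           weeks = numeric(), values = numeric(),
                           missing_cause = rep(NA_character_,
                                               length(weeks))) {
  new("EndpointSeries", subject = as.character(subject),
      endpoint = endpoint, baseline = baseline, weeks = as.numeric(weeks),
      values = as.numeric(values),
      missingCause = as.character(missing_cause))
}

# higher values are better for FEV1 and 6MWT, lower for SGRQ
.higherBetter <- function(endpoint) endpoint != "SGRQ"

#' Responder flag at 12 months
#'
#' Responder definitions: FEV1 percent-predicted improvement of at least
#' 12% of the baseline value (relative-change convention; switch to
#' absolute percentage points with \code{fev1_rule = "absolute"}), SGRQ
#' decrease of at least 8 points, 6MWT increase of at least 30 meters.
#' Boundaries are inclusive.
#'
#' @param series an \linkS4class{EndpointSeries} (supplies the endpoint and
#'   baseline).
#' @param value_at_12m the (possibly imputed) 12-month value.
#' @param fev1_rule \code{"relative"} (default) or \code{"absolute"}.
#' @return logical responder flag.
#' @examples
#' s <- endpointSeries("s1", "FEV1", baseline = 30)
#' responderFlag(s, 34)   # TRUE: 4/30 = 13.3% >= 12%
#' @export
responderFlag <- function(series, value_at_12m,
                          fev1_rule = c("relative", "absolute")) {
  stopifnot(is(series, "EndpointSeries"))
  fev1_rule <- match.arg(fev1_rule)
  .assertNumber(value_at_12m, "value_at_12m")
  b <- series@baseline
  switch(series@endpoint,
    FEV1 = if (fev1_rule == "relative")
      (value_at_12m - b) / b >= 0.12 else value_at_12m - b >= 12,
    SGRQ = b - value_at_12m >= 8,
    `6MWT` = value_at_12m - b >= 30)
}

#' Assemble the primary-endpoint value under the missing-data hierarchy
#'
#' The primary analysis uses the 12-month (week 52) value when observed.
#' When it is missing because of a serious adverse event (including death),
#' the worst prior follow-up value is carried forward — direction-aware:
#' lowest prior FEV1/6MWT, highest prior SGRQ. When it is missing for any
#' other reason, the last available prior follow-up value is used. When no
#' follow-up data exist at all, the baseline value enters the
#' intent-to-treat analysis and the subject is flagged for the sensitivity
#' analysis that excludes such cases.
#'
#' @param series an \linkS4class{EndpointSeries}.
#' @param final_week the primary-analysis visit week (default 52).
#' @return list: \code{value}, \code{provenance} (one of
#'   \code{"observed"}, \code{"worst-prior"}, \code{"locf"},
#'   \code{"baseline-itt"}), \code{sensitivity_exclude}.
#' @export
assemblePrimaryEndpoint <- function(series, final_week = 52) {
  stopifnot(is(series, "EndpointSeries"))
  i <- match(final_week, series@weeks)
  finalValue <- if (!is.na(i)) series@values[i] else NA_real_
  if (!is.na(finalValue))
    return(list(value = finalValue, provenance = "observed",
                sensitivity_exclude = FALSE))
  prior <- series@weeks < final_week & !is.na(series@values)
  cause <- if (!is.na(i)) series@missingCause[i] else "other"
  if (!any(prior))
    return(list(value = series@baseline, provenance = "baseline-itt",
                sensitivity_exclude = TRUE))
  pv <- series@values[prior]
  if (identical(cause, "sae")) {
    worst <- if (.higherBetter(series@endpoint)) min(pv) else max(pv)
    return(list(value = worst, provenance = "worst-prior",
                sensitivity_exclude = FALSE))
  }
  list(value = pv[length(pv)], provenance = "locf",
       sensitivity_exclude = FALSE)
}

#' Site-stratified permuted-block randomization at a 2:1 ratio
#'
#' Within each site, subjects are assigned from independently generated
#' permuted blocks; every complete block carries arms in the exact
#' allocation ratio (block size 3 at 2:1 means 2 treatment, 1 control).
#' Marginal imbalance is therefore bounded by one incomplete block per
#' site. Per-site sequences are derived deterministically from the scheme
#' seed, so adding subjects at one site never perturbs another site's
#' sequence.
#'
#' @param subjects data.frame with columns \code{subject} and \code{site},
#'   in enrolment order.
#' @param ratio treatment:control ratio (integer, default 2).
#' @param block_size permuted-block size; must be a multiple of
#'   \code{ratio + 1} (default 3).
#' @param seed integer seed.
#' @return the \code{subjects} data.frame with an \code{arm} column
#'   (\code{"treatment"}/\code{"control"}).
#' @examples
#' subj <- data.frame(subject = sprintf("S%02d", 1:9), site = "A")
#' table(blockedRandomization(subj, seed = 1)$arm)   # 6 treatment, 3 control
#' @export
blockedRandomization <- function(subjects, ratio = 2L, block_size = 3L,
                                 seed = 1L) {
  stopifnot(is.data.frame(subjects),
            all(c("subject", "site") %in% names(subjects)))
  ratio <- as.integer(ratio); block_size <- as.integer(block_size)
  if (block_size %% (ratio + 1L) != 0L)
    stop("block size must be a multiple of ratio + 1", call. = FALSE)
  perBlock <- block_size %/% (ratio + 1L)
  arms <- c(rep("treatment", ratio * perBlock), rep("control", perBlock))
  out <- subjects
  out$arm <- NA_character_
  sites <- cSort(unique(as.character(subjects$site)))
  for (si in seq_along(sites)) {
    idx <- which(as.character(subjects$site) == sites[si])
    nBlocks <- ceiling(length(idx) / block_size)
    siteSeed <- (as.integer(seed) + 7919L * si) %% .Machine$integer.max
    seq <- withSeed(siteSeed,
      unlist(lapply(seq_len(nBlocks), function(b) sample(arms))))
    out$arm[idx] <- seq[seq_along(idx)]
  }
  out
}
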