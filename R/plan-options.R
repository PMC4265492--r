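#' Treatment-planning constraint set
#'
#' Constructor for \linkS4class{PlanConstraints} with the design defaults;
#' any threshold can be overridden. All windows and tolerances are compared
#' inclusively.
#'
#' @param session1_window percent window for the session-1 lobe fraction
#'   (default 50 +/- 20).
#' @param session2_window percent window for the session-2 lobe fraction
#'   (default 60 +/- 20).
#' @param combined_window percent window for the combined fraction on the
#'   200% two-lobe scale (default 110 +20/-15).
#' @param volume_cap_ml maximum volume treated per session, ml.
#' @param hi_min minimum heterogeneity index of every treated segment.
#' @param equal_disease_tol TAR points within which segments of a lobe are
#'   considered equally diseased.
#' @param combined_tar_tol TAR points within which options treat similar
#'   amounts of disease.
#' @param combined_target combined-fraction target, percent.
#' @return a \linkS4class{PlanConstraints}.
#' @export
planConstraints <- function(session1_window = c(30, 70),
                            session2_window = c(40, 80),
                            combined_window = c(95, 130),
                            volume_cap_ml = 1700,
                            hi_min = 1.2,
                            equal_disease_tol = 2.0,
                            combined_tar_tol = 0.30,
                            combined_target = 110) {
  new("PlanConstraints",
      session1Window = as.numeric(session1_window),
      session2Window = as.numeric(session2_window),
      combinedWindow = as.numeric(combined_window),
      volumeCap = volume_cap_ml, hiMin = hi_min,
      equalDiseaseTol = equal_disease_tol,
      combinedTarTol = combined_tar_tol,
      combinedTarget = combined_target)
}

#' Segmental heterogeneity index
#'
#' HI compares an upper-lobe segment's density with the ipsilateral lower
#' lobe: \code{HI = lower-lobe TAR / segmental TAR}. A more diseased (less
#' dense) upper segment has a lower TAR and therefore HI > 1; segments are
#' treatable when HI >= 1.2.
#'
#' @param lower_lobe_tar lower-lobe TAR, percent (> 0).
#' @param segment_tar segmental TAR, percent (> 0).
#' @return the HI ratio (vectorised).
#' @examples
#' heterogeneityIndex(18, 9)   # 2.0
#' heterogeneityIndex(12, 10)  # 1.2, at the eligibility threshold
#' @export
heterogeneityIndex <- function(lower_lobe_tar, segment_tar) {
  if (any(!is.finite(lower_lobe_tar)) || any(!is.finite(segment_tar)) ||
      any(lower_lobe_tar <= 0) || any(segment_tar <= 0))
    stop("TARs must be finite and positive", call. = FALSE)
  lower_lobe_tar / segment_tar
}

#' Combined TAR of a set of treated segments
#'
#' Aggregates the treated segments by summing tissue and air volumes before
#' taking the ratio: \code{100 * sum(tissue) / sum(air)} — an air-weighted
#' mean of the segmental TARs. The option with the lowest combined TAR
#' targets the most disease.
#'
#' @param segments data.frame with columns \code{tissue_ml} and
#'   \code{air_ml}, one row per treated segment; non-empty.
#' @return combined TAR, percent.
#' @examples
#' combinedTAR(data.frame(tissue_ml = c(30, 20), air_ml = c(270, 230)))
#' @export
combinedTAR <- function(segments) {
  stopifnot(is.data.frame(segments))
  if (!nrow(segments)) stop("empty segment set", call. = FALSE)
  air <- sum(segments$air_ml)
  if (air <= 0) stop("combined TAR undefined: zero total air", call. = FALSE)
  100 * sum(segments$tissue_ml) / air
}

# expand merged ids to base segments ("LB1+2" -> LB1, LB2)
.expandBase <- function(ids)
  unique(unlist(lapply(ids, function(i)
    if (i == .LEFT_MERGED) c("LB1", "LB2") else i)))

# session-2 choices of one lobe: singles and unordered pairs of distinct
# tissue; {LB1, LB2} is the merged LB1+2 and is deduplicated to it.
.session2Sets <- function(side) {
  if (side == "right") {
    singles <- as.list(.RIGHT_TREATABLE)
    pairs <- combn(.RIGHT_TREATABLE, 2, simplify = FALSE)
  } else {
    singles <- as.list(c(.LEFT_TREATABLE, .LEFT_MERGED))
    pairs <- list(c("LB1", "LB3"), c("LB2", "LB3"), c(.LEFT_MERGED, "LB3"))
  }
  c(singles, pairs)
}

.session1Ids <- function(side) .treatableIds(side)

.optionId <- function(primary_side, s1, s2)
  paste0(primary_side, ":", s1, "|", paste(cSort(s2), collapse = ","))

#' Enumerate all bilateral treatment options
#'
#' Generates the full matrix of candidate plans: one treatable segment of
#' the primary upper lobe in session 1, and one or two treatable segments
#' of the contralateral upper lobe in session 2. On the left, LB1 and LB2
#' may merge into the single segment LB1+2; the pair \{LB1, LB2\} is
#' deduplicated to it. Derived quantities (session volumes, lobe fractions,
#' combined fraction on the 200% scale, minimum HI over treated segments,
#' combined TAR) are attached to every option.
#'
#' @param model a \linkS4class{LungModel}.
#' @param primary_side \code{"both"} (default; enumerate either lobe as
#'   primary), \code{"left"} or \code{"right"}.
#' @return data.frame, one row per option: \code{option_id},
#'   \code{primary_side}, \code{session1}, \code{session2}
#'   (comma-separated, canonically sorted), \code{s1_volume_ml},
#'   \code{s2_volume_ml}, \code{s1_fraction}, \code{s2_fraction},
#'   \code{combined_fraction}, \code{min_hi}, \code{combined_tar}.
#' @examples
#' m <- generateLungFixture(seed = 1)
#' nrow(enumerateOptions(m, "left"))   # 24
#' nrow(enumerateOptions(m, "both"))   # 45
#' @export
enumerateOptions <- function(model,
                             primary_side = c("both", "left", "right")) {
  stopifnot(is(model, "LungModel"))
  primary_side <- match.arg(primary_side)
  sides <- if (primary_side == "both") c("left", "right") else primary_side

  # per-segment lookups, computed once per model
  seg <- model@segments
  tis <- setNames(seg$tissue_ml, seg$segment_id)
  air <- setNames(seg$air_ml, seg$segment_id)
  tot <- setNames(seg$total_ml, seg$segment_id)
  hiOf <- setNames(heterogeneityIndex(model@lowerLobeTAR[seg$side],
                                      seg$tar), seg$segment_id)

  n <- 0L
  for (ps in sides)
    n <- n + length(.session1Ids(ps)) * length(.session2Sets(.otherSide(ps)))
  id <- pside <- ses1 <- ses2 <- character(n)
  v1 <- v2 <- f1 <- f2 <- mh <- ct <- numeric(n)

  k <- 0L
  for (ps in sides) {
    ss <- .otherSide(ps)
    denom1 <- .lobeDenominator(model, ps)
    denom2 <- .lobeDenominator(model, ss)
    for (s1 in .session1Ids(ps)) {
      for (s2 in .session2Sets(ss)) {
        k <- k + 1L
        treated <- c(s1, s2)
        id[k] <- .optionId(ps, s1, s2)
        pside[k] <- ps
        ses1[k] <- s1
        ses2[k] <- paste(cSort(s2), collapse = ",")
        v1[k] <- tot[[s1]]
        v2[k] <- sum(tot[s2])
        f1[k] <- 100 * v1[k] / denom1
        f2[k] <- 100 * v2[k] / denom2
        mh[k] <- min(hiOf[treated])
        ct[k] <- 100 * sum(tis[treated]) / sum(air[treated])
      }
    }
  }
  opt <- data.frame(option_id = id, primary_side = pside, session1 = ses1,
                    session2 = ses2, s1_volume_ml = v1, s2_volume_ml = v2,
                    s1_fraction = f1, s2_fraction = f2,
                    combined_fraction = f1 + f2, min_hi = mh,
                    combined_tar = ct, stringsAsFactors = FALSE)
  opt <- opt[cOrder(opt$option_id), ]
  rownames(opt) <- NULL
  opt
}

#' Apply the treatment-volume and HI constraints to enumerated options
#'
#' An option survives iff its session-1 fraction lies in the session-1
#' window, its session-2 fraction in the session-2 window, its combined
#' fraction in the combined window, both session volumes do not exceed the
#' per-session cap, and every treated segment meets the minimum HI. All
#' comparisons are inclusive. Every evaluation is recorded per option.
#'
#' @param options data.frame from \code{\link{enumerateOptions}}.
#' @param constraints a \linkS4class{PlanConstraints}.
#' @return the \code{options} data.frame with logical columns
#'   \code{pass_s1_window}, \code{pass_s2_window}, \code{pass_combined},
#'   \code{pass_s1_cap}, \code{pass_s2_cap}, \code{pass_hi} and the
#'   conjunction \code{pass}.
#' @export
applyConstraints <- function(options, constraints = planConstraints()) {
  stopifnot(is.data.frame(options), is(constraints, "PlanConstraints"))
  w1 <- constraints@session1Window; w2 <- constraints@session2Window
  wc <- constraints@combinedWindow
  options$pass_s1_window <- options$s1_fraction >= w1[1] &
    options$s1_fraction <= w1[2]
  options$pass_s2_window <- options$s2_fraction >= w2[1] &
    options$s2_fraction <= w2[2]
  options$pass_combined <- options$combined_fraction >= wc[1] &
    options$combined_fraction <= wc[2]
  options$pass_s1_cap <- options$s1_volume_ml <= constraints@volumeCap
  options$pass_s2_cap <- options$s2_volume_ml <= constraints@volumeCap
  options$pass_hi <- options$min_hi >= constraints@hiMin
  options$pass <- options$pass_s1_window & options$pass_s2_window &
    options$pass_combined & options$pass_s1_cap & options$pass_s2_cap &
    options$pass_hi
  options
}
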