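#' VoxelPhantom: a synthetic CT volume with a segment label map
#'
#' Container for a voxel-level stand-in for a quantitative-CT study: a grid
#' of Hounsfield units, an integer label map of identical shape assigning
#' each voxel to a bronchopulmonary segment, the voxel volume in ml, and a
#' label table mapping integer labels to canonical segment identifiers
#' (\code{"LB1"}, \code{"RB3"}, \code{"LLL"}, ...).
#'
#' @slot hu 3-D numeric array of Hounsfield units.
#' @slot labels 3-D integer array, same shape as \code{hu}; 0 = background.
#' @slot voxelVolume volume of one voxel in ml (> 0).
#' @slot labelTable data.frame with columns \code{label} (integer) and
#'   \code{segment_id} (character); every nonzero label in \code{labels}
#'   must appear exactly once.
#' @exportClass VoxelPhantom
setClass("VoxelPhantom",
  representation(hu = "array", labels = "array", voxelVolume = "numeric",
                 labelTable = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@hu), dim(object@labels)))
      msg <- c(msg, "hu and label grids must share their shape")
    if (length(object@voxelVolume) != 1L || !is.finite(object@voxelVolume) ||
        object@voxelVolume <= 0)
      msg <- c(msg, "voxelVolume must be a single positive number")
    if (!all(c("label", "segment_id") %in% names(object@labelTable)))
      msg <- c(msg, "labelTable needs columns 'label' and 'segment_id'")
    else {
      present <- setdiff(unique(as.integer(object@labels)), 0L)
      missing <- setdiff(present, object@labelTable$label)
      if (length(missing))
        msg <- c(msg, paste0("labels without a labelTable entry: ",
                             paste(missing, collapse = ", ")))
      if (anyDuplicated(object@labelTable$label))
        msg <- c(msg, "duplicate labels in labelTable")
    }
    if (any(!is.finite(object@hu)))
      msg <- c(msg, "hu grid contains non-finite values")
    if (length(msg)) msg else TRUE
  })

#' LungModel: the planner's view of both lungs
#'
#' Per-segment densitometry for the treatable upper-lobe segments (left:
#' LB1, LB2, LB3 plus the merged LB1+2; right: RB1, RB2, RB3), the lingula
#' (LB4, LB5; never treatable), and per-side lower-lobe tissue-to-air ratios
#' (TAR, percent). The lobe-fraction denominator convention records whether
#' session fractions are taken over the treatable-segment volume only
#' (default) or over the whole anatomical lobe including the lingula.
#'
#' @slot segments data.frame with columns \code{segment_id}, \code{side},
#'   \code{region} (\code{"upper"}, \code{"lingula"}, \code{"lower"}),
#'   \code{tissue_ml}, \code{air_ml}, \code{total_ml}, \code{tar}.
#' @slot lowerLobeTAR named numeric, \code{c(left=, right=)}, percent.
#' @slot denominator \code{"treatable"} or \code{"anatomical"}.
#' @exportClass LungModel
setClass("LungModel",
  representation(segments = "data.frame", lowerLobeTAR = "numeric",
                 denominator = "character"),
  validity = function(object) {
    msg <- character()
    seg <- object@segments
    need <- c("segment_id", "side", "region", "tissue_ml", "air_ml",
              "total_ml", "tar")
    if (!all(need %in% names(seg)))
      return(paste("segments must have columns:", paste(need, collapse = ", ")))
    up <- seg[seg$region != "lower", ]
    leftIds <- up$segment_id[up$side == "left"]
    if (!setequal(setdiff(leftIds, .LEFT_MERGED),
                  c(.LEFT_TREATABLE, .LEFT_LINGULA)))
      msg <- c(msg, "left upper lobe must contain exactly LB1, LB2, LB3, LB4, LB5")
    if (!.LEFT_MERGED %in% leftIds)
      msg <- c(msg, "merged LB1+2 entry missing")
    if (!setequal(up$segment_id[up$side == "right"], .RIGHT_TREATABLE))
      msg <- c(msg, "right upper lobe must contain exactly RB1, RB2, RB3")
    if (anyDuplicated(seg$segment_id))
      msg <- c(msg, "duplicate segment ids")
    if (any(seg$tissue_ml < 0) || any(seg$air_ml <= 0))
      msg <- c(msg, "tissue volumes must be >= 0 and air volumes > 0")
    if (!all(c("left", "right") %in% names(object@lowerLobeTAR)) ||
        any(!is.finite(object@lowerLobeTAR)) || any(object@lowerLobeTAR <= 0))
      msg <- c(msg, "lowerLobeTAR must be positive for both sides")
    if (!object@denominator %in% c("treatable", "anatomical"))
      msg <- c(msg, "denominator must be 'treatable' or 'anatomical'")
    if (length(msg)) msg else TRUE
  })

#' PlanConstraints: the treatment-volume and disease constraints
#'
#' Defaults encode the design's treatment volume parameters: session 1
#' targets 50% (+/-20) of the primary upper lobe, session 2 targets 60%
#' (+/-20) of the contralateral upper lobe, the combination targets 110%
#' (+20/-15) of the two lobes (each lobe = 100%, both = 200%), no session
#' may treat more than 1700 ml, and every treated segment needs a
#' heterogeneity index of at least 1.2. Segmental TARs within 2 percentage
#' points are considered equally diseased; combined TARs within 0.30
#' percentage points are considered to treat similar amounts of disease.
#'
#' @slot session1Window,session2Window,combinedWindow numeric length-2
#'   percent windows (inclusive).
#' @slot volumeCap per-session cap in ml.
#' @slot hiMin minimum heterogeneity index for treated segments.
#' @slot equalDiseaseTol TAR points within which segments are equally diseased.
#' @slot combinedTarTol combined-TAR similarity tolerance, TAR points.
#' @slot combinedTarget combined-fraction target, percent of the 200% scale.
#' @exportClass PlanConstraints
setClass("PlanConstraints",
  representation(session1Window = "numeric", session2Window = "numeric",
                 combinedWindow = "numeric", volumeCap = "numeric",
                 hiMin = "numeric", equalDiseaseTol = "numeric",
                 combinedTarTol = "numeric", combinedTarget = "numeric"),
  validity = function(object) {
    msg <- character()
    for (w in c("session1Window", "session2Window", "combinedWindow")) {
      v <- slot(object, w)
      if (length(v) != 2L || v[1] > v[2] || any(!is.finite(v)))
        msg <- c(msg, paste(w, "must be a non-empty [lo, hi] window"))
    }
    for (s in c("volumeCap", "hiMin", "equalDiseaseTol", "combinedTarTol",
                "combinedTarget"))
      if (length(slot(object, s)) != 1L || slot(object, s) <= 0)
        msg <- c(msg, paste(s, "must be a single positive number"))
    if (length(msg)) msg else TRUE
  })

#' PlanSelection: a chosen treatment plan with its full decision trace
#'
#' @slot feasible TRUE when a plan passing every constraint exists.
#' @slot chosen one-row data.frame describing the preferred option (zero
#'   rows when no feasible plan exists).
#' @slot audit data.frame with one row per enumerated option: computed
#'   volumes, fractions, minimum HI, combined TAR, each constraint verdict,
#'   dominance removal and tie-group membership.
#' @slot diseaseRank per-lobe disease classification of the base segments.
#' @slot constraints the \linkS4class{PlanConstraints} applied.
#' @slot notes character vector narrating the selection stages.
#' @exportClass PlanSelection
setClass("PlanSelection",
  representation(feasible = "logical", chosen = "data.frame",
                 audit = "data.frame", diseaseRank = "data.frame",
                 constraints = "PlanConstraints", notes = "character"),
  validity = function(object) {
    if (object@feasible && nrow(object@chosen) != 1L)
      return("feasible selection must carry exactly one chosen option")
    if (!object@feasible && nrow(object@chosen) != 0L)
      return("infeasible selection must not carry a chosen option")
    TRUE
  })

#' PatientRecord: structured screening measurements
#'
#' Numeric measurements and boolean attestations needed to evaluate the
#' computable inclusion/exclusion criteria. Pulmonary-artery pressures may
#' come from echocardiography or right-heart catheter; catheter values are
#' definitive when both are present. History items that are not derivable
#' from numbers (bronchiectasis, exacerbation history, consent, ...) are
#' recorded as attestations.
#'
#' @slot measurements named numeric vector of the screening measurements
#'   (see \code{\link{patientRecord}} for the field list); optional fields
#'   may be NA.
#' @slot attestations named logical vector of history/imaging attestations.
#' @exportClass PatientRecord
setClass("PatientRecord",
  representation(measurements = "numeric", attestations = "logical"),
  validity = function(object) {
    m <- object@measurements
    need <- .REQUIRED_MEASUREMENTS
    missing <- setdiff(need, names(m))
    if (length(missing))
      return(paste0("missing measurements: ", paste(missing, collapse = ", ")))
    bad <- names(m)[!is.finite(m) & !names(m) %in% .OPTIONAL_MEASUREMENTS]
    if (length(bad))
      return(paste0("non-finite required measurements: ",
                    paste(bad, collapse = ", ")))
    if (!m[["mmrc"]] %in% 0:4) return("mmrc must be an integer in 0..4")
    f <- m[["largest_bulla_fraction_of_lobe"]]
    if (is.finite(f) && (f < 0 || f > 1))
      return("largest_bulla_fraction_of_lobe must lie in [0, 1]")
    missingAtt <- setdiff(.REQUIRED_ATTESTATIONS, names(object@attestations))
    if (length(missingAtt))
      return(paste0("missing attestations: ",
                    paste(missingAtt, collapse = ", ")))
    TRUE
  })

#' EligibilityDecision: per-criterion screening verdicts
#'
#' @slot eligible TRUE iff every criterion passes.
#' @slot criteria data.frame: criterion id, description, observed value,
#'   threshold, pass.
#' @slot failed ids of failed criteria.
#' @slot metadata list (e.g. which mMRC convention was applied).
#' @exportClass EligibilityDecision
setClass("EligibilityDecision",
  representation(eligible = "logical", criteria = "data.frame",
                 failed = "character", metadata = "list"),
  validity = function(object) {
    if (!identical(object@eligible, all(object@criteria$pass)))
      return("eligible must equal 'all criteria pass'")
    if (!setequal(object@failed,
                  object@criteria$criterion[!object@criteria$pass]))
      return("failed ids must match the failing criteria rows")
    TRUE
  })

#' DesignAssumptions: inputs to the sample-size calculation
#'
#' @slot meanDifference assumed between-arm mean difference, endpoint units.
#' @slot sd assumed common standard deviation, endpoint units.
#' @slot power target power, fraction in (0, 1).
#' @slot alpha two-sided type-I error level.
#' @slot allocationRatio treatment:control ratio (>= 1).
#' @slot dropoutRate anticipated loss to follow-up, fraction in [0, 1).
#' @exportClass DesignAssumptions
setClass("DesignAssumptions",
  representation(meanDifference = "numeric", sd = "numeric",
                 power = "numeric", alpha = "numeric",
                 allocationRatio = "numeric", dropoutRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@sd <= 0) msg <- c(msg, "sd must be > 0")
    if (object@power <= 0 || object@power >= 1)
      msg <- c(msg, "power must lie in (0, 1)")
    if (object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "alpha must lie in (0, 1)")
    if (object@allocationRatio < 1)
      msg <- c(msg, "allocationRatio must be >= 1 (treatment:control)")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      msg <- c(msg, "dropoutRate must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' EndpointSeries: one subject's longitudinal endpoint values
#'
#' @slot subject subject identifier.
#' @slot endpoint \code{"FEV1"} (percent predicted), \code{"SGRQ"} or
#'   \code{"6MWT"}; the improvement direction is implied (SGRQ lower-better).
#' @slot baseline baseline value (required).
#' @slot weeks follow-up visit weeks, strictly increasing.
#' @slot values observed values per week; NA when missing.
#' @slot missingCause per week: NA when observed, \code{"sae"} (serious
#'   adverse event or death) or \code{"other"} when missing.
#' @exportClass EndpointSeries
setClass("EndpointSeries",
  representation(subject = "character", endpoint = "character",
                 baseline = "numeric", weeks = "numeric",
                 values = "numeric", missingCause = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@endpoint %in% c("FEV1", "SGRQ", "6MWT"))
      msg <- c(msg, "endpoint must be one of FEV1, SGRQ, 6MWT")
    if (length(object@baseline) != 1L || !is.finite(object@baseline))
      msg <- c(msg, "baseline must be present and finite")
    if (is.unsorted(object@weeks, strictly = TRUE))
      msg <- c(msg, "weeks must be strictly increasing")
    if (length(object@values) != length(object@weeks) ||
        length(object@missingCause) != length(object@weeks))
      msg <- c(msg, "values and missingCause must align with weeks")
    bad <- !is.na(object@values) & !is.na(object@missingCause)
    if (any(bad)) msg <- c(msg, "observed visits cannot carry a missing cause")
    badCause <- is.na(object@values) &
      !object@missingCause %in% c("sae", "other")
    if (any(badCause))
      msg <- c(msg, "missing visits need cause 'sae' or 'other'")
    if (length(msg)) msg else TRUE
  })

#' VisitSchedule: the follow-up calendar for one arm
#'
#' @slot arm \code{"treatment"} or \code{"control"}.
#' @slot phoneWeeks telephone-call weeks.
#' @slot clinicWeeks in-person clinic-visit weeks.
#' @slot secondSession list with \code{nominalDay}, \code{window} (days) and
#'   \code{latestDelayedDay} for the treatment arm; empty list for control.
#' @exportClass VisitSchedule
setClass("VisitSchedule",
  representation(arm = "character", phoneWeeks = "numeric",
                 clinicWeeks = "numeric", secondSession = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@arm %in% c("treatment", "control"))
      msg <- c(msg, "arm must be 'treatment' or 'control'")
    if (length(intersect(object@phoneWeeks, object@clinicWeeks)))
      msg <- c(msg, "phone and clinic week sets must be disjoint")
    if (object@arm == "control") {
      if (any(c(1, 14, 15) %in% c(object@phoneWeeks, object@clinicWeeks)))
        msg <- c(msg, "control arm never has visits at weeks 1, 14, 15")
      if (!2 %in% object@phoneWeeks)
        msg <- c(msg, "control week 2 must be a telephone call")
      if (length(object@secondSession))
        msg <- c(msg, "control arm has no second treatment session")
    }
    if (length(msg)) msg else TRUE
  })
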