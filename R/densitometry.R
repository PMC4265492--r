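#' Tissue fraction from a Hounsfield unit value
#'
#' Standard two-compartment lung densitometry: a voxel is a linear mix of
#' air (-1000 HU) and tissue/water (0 HU), so the tissue fraction is
#' \code{(HU + 1000) / 1000}, clipped to [0, 1] outside that range.
#'
#' @param hu numeric vector of Hounsfield units; must be finite.
#' @return tissue fraction(s) in [0, 1].
#' @examples
#' tissueFractionFromHU(c(-1000, -890, 0))
#' @export
tissueFractionFromHU <- function(hu) {
  if (!is.numeric(hu) || any(!is.finite(hu)))
    stop("Hounsfield units must be finite numbers", call. = FALSE)
  pmin(pmax((hu + 1000) / 1000, 0), 1)
}

#' Tissue-to-air ratio in percent
#'
#' @param tissue_ml,air_ml tissue and air volumes in ml; \code{air_ml} > 0.
#' @return TAR = 100 * tissue / air, percent. Lower TAR means less dense,
#'   more emphysematous tissue.
#' @export
tarPercent <- function(tissue_ml, air_ml) {
  if (any(air_ml <= 0))
    stop("TAR undefined: air volume must be positive", call. = FALSE)
  if (any(tissue_ml < 0))
    stop("tissue volume must be non-negative", call. = FALSE)
  100 * tissue_ml / air_ml
}

#' Per-segment densitometry from a voxel phantom
#'
#' Sums the tissue and air content of every voxel carrying
#' \code{segment_label} (tissue = voxel volume x tissue fraction, air = the
#' remainder) and derives the segment's TAR.
#'
#' @param phantom a \linkS4class{VoxelPhantom}.
#' @param segment_label integer label to summarise; must be present in the
#'   phantom's label grid.
#' @return one-row data.frame: \code{segment_id}, \code{tissue_ml},
#'   \code{air_ml}, \code{total_ml}, \code{n_voxels}, \code{tar}.
#' @examples
#' ph <- generatePhantom(data.frame(segment_id = "RB1", target_tar = 11.11,
#'                                  volume_ml = 1), seed = 1)
#' summarizeSegment(ph, 1L)
#' @export
summarizeSegment <- function(phantom, segment_label) {
  stopifnot(is(phantom, "VoxelPhantom"))
  segment_label <- as.integer(segment_label)
  sel <- which(phantom@labels == segment_label)
  if (!length(sel))
    stop(sprintf("segment label %d not present in phantom", segment_label),
         call. = FALSE)
  frac <- tissueFractionFromHU(phantom@hu[sel])
  vv <- phantom@voxelVolume
  tissue <- sum(vv * frac)
  air <- sum(vv * (1 - frac))
  if (air <= 0)
    stop(sprintf("segment label %d has zero air volume; TAR undefined",
                 segment_label), call. = FALSE)
  id <- phantom@labelTable$segment_id[
    match(segment_label, phantom@labelTable$label)]
  data.frame(segment_id = id, tissue_ml = tissue, air_ml = air,
             total_ml = tissue + air, n_voxels = length(sel),
             tar = tarPercent(tissue, air), stringsAsFactors = FALSE)
}

#' Summarise every labelled segment of a phantom
#'
#' @param phantom a \linkS4class{VoxelPhantom}.
#' @return data.frame with one row per label, ordered by label.
#' @export
summarizePhantom <- function(phantom) {
  stopifnot(is(phantom, "VoxelPhantom"))
  labs <- sort(phantom@labelTable$label)
  do.call(rbind, lapply(labs, function(l) summarizeSegment(phantom, l)))
}
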