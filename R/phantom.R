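#' Generate a voxel phantom with prescribed per-segment TARs
#'
#' Builds a synthetic CT volume in which each requested segment occupies a
#' contiguous block of voxels whose mean Hounsfield value encodes the target
#' tissue-to-air ratio. A target TAR (percent) corresponds to a tissue
#' fraction \code{f = TAR / (100 + TAR)} and hence a mean of
#' \code{-1000 * (1 - f)} HU; zero-mean Gaussian noise (default sd 20 HU) is
#' added per voxel. Because the summed tissue/air volumes depend on the mean
#' fraction only, the recovered TAR matches the target up to clipping at the
#' [-1000, 0] HU bounds, which is negligible at physiological TARs.
#'
#' @param spec data.frame with columns \code{segment_id}, \code{target_tar}
#'   (percent, > 0) and \code{volume_ml} (> 0).
#' @param voxel_volume_ml ml per voxel (isotropic); anisotropic spacing may
#'   be supplied as \code{spacing_mm}, a length-3 vector whose product
#'   (in mm^3) overrides \code{voxel_volume_ml} (1 ml = 1000 mm^3).
#' @param noise_sd_hu per-voxel Gaussian noise, HU.
#' @param seed integer seed; the phantom is reproducible under it.
#' @param spacing_mm optional per-axis voxel spacing in mm.
#' @return a \linkS4class{VoxelPhantom}; labels are 1..nrow(spec) in spec
#'   order.
#' @examples
#' spec <- data.frame(segment_id = c("RB1", "RB2"),
#'                    target_tar = c(10, 12), volume_ml = c(2, 3))
#' ph <- generatePhantom(spec, seed = 7)
#' summarizePhantom(ph)
#' @export
generatePhantom <- function(spec, voxel_volume_ml = 0.01, noise_sd_hu = 20,
                            seed = NULL, spacing_mm = NULL) {
  stopifnot(is.data.frame(spec),
            all(c("segment_id", "target_tar", "volume_ml") %in% names(spec)))
  if (any(!is.finite(spec$target_tar)) || any(spec$target_tar <= 0))
    stop("target TARs must be finite and positive", call. = FALSE)
  if (any(spec$volume_ml <= 0))
    stop("segment volumes must be positive", call. = FALSE)
  if (!is.null(spacing_mm)) {
    stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
    voxel_volume_ml <- prod(spacing_mm) / 1000
  }
  .assertNumber(voxel_volume_ml, "voxel_volume_ml", lower = 1e-12)

  nvox <- pmax(1L, as.integer(round(spec$volume_ml / voxel_volume_ml)))
  total <- sum(nvox)
  # near-cubic grid holding all segment blocks consecutively
  nx <- max(1L, as.integer(ceiling(total^(1 / 3))))
  ny <- nx
  nz <- as.integer(ceiling(total / (nx * ny)))
  hu <- array(-1000, dim = c(nx, ny, nz))
  labels <- array(0L, dim = c(nx, ny, nz))

  frac <- spec$target_tar / (100 + spec$target_tar)   # TAR = 100 f / (1 - f)
  meanHU <- -1000 * (1 - frac)
  withSeed(seed, {
    at <- 0L
    for (i in seq_len(nrow(spec))) {
      idx <- at + seq_len(nvox[i])
      vals <- meanHU[i] + rnorm(nvox[i], sd = noise_sd_hu)
      hu[idx] <- pmin(pmax(vals, -1000), 0)
      labels[idx] <- i
      at <- at + nvox[i]
    }
  })
  new("VoxelPhantom", hu = hu, labels = labels,
      voxelVolume = voxel_volume_ml,
      labelTable = data.frame(label = seq_len(nrow(spec)),
                              segment_id = as.character(spec$segment_id),
                              stringsAsFactors = FALSE))
}

#' Write / read a phantom as a NIfTI pair plus JSON label table
#'
#' The HU volume is stored as float32 NIfTI, the label map as int16 NIfTI,
#' and the label table (with the voxel volume) as JSON.
#'
#' @param phantom a \linkS4class{VoxelPhantom}.
#' @param prefix path prefix; writes \code{<prefix>_hu.nii},
#'   \code{<prefix>_labels.nii} and \code{<prefix>_labels.json}.
#' @return \code{writePhantom}: the prefix, invisibly. \code{readPhantom}:
#'   the reconstructed \linkS4class{VoxelPhantom}.
#' @export
writePhantom <- function(phantom, prefix) {
  stopifnot(is(phantom, "VoxelPhantom"))
  RNifti::writeNifti(RNifti::asNifti(phantom@hu, datatype = "float"),
                     paste0(prefix, "_hu.nii"))
  RNifti::writeNifti(RNifti::asNifti(phantom@labels, datatype = "int16"),
                     paste0(prefix, "_labels.nii"))
  jsonlite::write_json(
    list(voxel_volume_ml = phantom@voxelVolume,
         labels = phantom@labelTable),
    paste0(prefix, "_labels.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(prefix) {
  hu <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_hu.nii"))),
              dim = dim(RNifti::readNifti(paste0(prefix, "_hu.nii"))))
  labn <- RNifti::readNifti(paste0(prefix, "_labels.nii"))
  labels <- array(as.integer(labn), dim = dim(labn))
  meta <- jsonlite::read_json(paste0(prefix, "_labels.json"),
                              simplifyVector = TRUE)
  new("VoxelPhantom", hu = hu, labels = labels,
      voxelVolume = as.numeric(meta$voxel_volume_ml),
      labelTable = data.frame(label = as.integer(meta$labels$label),
                              segment_id = as.character(meta$labels$segment_id),
                              stringsAsFactors = FALSE))
}
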