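.REQUIRED_TABLE_IDS <- c(.LEFT_TREATABLE, .LEFT_LINGULA, .RIGHT_TREATABLE,
                         .LOWER_IDS)

.sideOf <- function(id) ifelse(substr(id, 1, 1) == "L", "left", "right")

.regionOf <- function(id) {
  ifelse(id %in% .LOWER_IDS, "lower",
         ifelse(id %in% .LEFT_LINGULA, "lingula", "upper"))
}

#' Build a LungModel from a per-segment densitometry table
#'
#' Validates a table of per-segment tissue/air volumes (ml), derives total
#' volumes and TARs, adds the merged LB1+2 entry (sum of LB1 and LB2
#' volumes) when it is not supplied explicitly, and extracts the per-side
#' lower-lobe TARs from the \code{LLL}/\code{RLL} rows.
#'
#' @param segment_table data.frame with columns \code{segment_id},
#'   \code{tissue_ml}, \code{air_ml}; exactly one row for each of LB1-LB5,
#'   RB1-RB3, LLL, RLL (an explicit \code{LB1+2} row is optional).
#' @param denominator lobe-fraction denominator convention:
#'   \code{"treatable"} (default; left-lobe fractions are taken over the
#'   three treatable segments, excluding the lingula) or
#'   \code{"anatomical"} (whole upper lobe including LB4/LB5).
#' @return a validated \linkS4class{LungModel}.
#' @examples
#' tab <- data.frame(
#'   segment_id = c("LB1","LB2","LB3","LB4","LB5","RB1","RB2","RB3","LLL","RLL"),
#'   tissue_ml  = c( 30,  32,  35,  20,  18,  33,  31,  36, 180, 175),
#'   air_ml     = c(370, 368, 365, 180, 182, 367, 369, 364, 1100, 1075))
#' buildLungModel(tab)
#' @export
buildLungModel <- function(segment_table, denominator = c("treatable",
                                                          "anatomical")) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(segment_table))
  need <- c("segment_id", "tissue_ml", "air_ml")
  if (!all(need %in% names(segment_table)))
    stop("segment table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- segment_table
  tab$segment_id <- toupper(trimws(as.character(tab$segment_id)))

  unknown <- setdiff(tab$segment_id, .ALL_SEGMENT_IDS)
  if (length(unknown))
    stop("unknown segment id(s): ", paste(cSort(unknown), collapse = ", "),
         call. = FALSE)
  dup <- unique(tab$segment_id[duplicated(tab$segment_id)])
  if (length(dup))
    stop("duplicate segment id(s): ", paste(cSort(dup), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(.REQUIRED_TABLE_IDS, tab$segment_id)
  if (length(missing))
    stop("missing segment id(s): ", paste(cSort(missing), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(tab$tissue_ml)) || any(!is.finite(tab$air_ml)) ||
      any(tab$tissue_ml < 0))
    stop("volumes must be finite and tissue volumes non-negative",
         call. = FALSE)
  if (any(tab$air_ml <= 0))
    stop("air volumes must be positive (TAR undefined at zero air)",
         call. = FALSE)

  if (!.LEFT_MERGED %in% tab$segment_id) {
    lb1 <- tab[tab$segment_id == "LB1", ]
    lb2 <- tab[tab$segment_id == "LB2", ]
    tab <- rbind(tab[, need],
                 data.frame(segment_id = .LEFT_MERGED,
                            tissue_ml = lb1$tissue_ml + lb2$tissue_ml,
                            air_ml = lb1$air_ml + lb2$air_ml))
  } else tab <- tab[, need]

  lower <- tab[tab$segment_id %in% .LOWER_IDS, ]
  upper <- tab[!tab$segment_id %in% .LOWER_IDS, ]
  seg <- data.frame(segment_id = c(upper$segment_id, lower$segment_id),
                    stringsAsFactors = FALSE)
  seg$side <- .sideOf(seg$segment_id)
  seg$region <- .regionOf(seg$segment_id)
  all <- rbind(upper, lower)
  seg$tissue_ml <- all$tissue_ml
  seg$air_ml <- all$air_ml
  seg$total_ml <- seg$tissue_ml + seg$air_ml
  seg$tar <- tarPercent(seg$tissue_ml, seg$air_ml)
  seg <- seg[cOrder(match(seg$region, c("upper", "lingula", "lower")),
                    seg$segment_id), ]
  rownames(seg) <- NULL

  llt <- seg$tar[seg$segment_id == .LOWER_IDS["left"]]
  rlt <- seg$tar[seg$segment_id == .LOWER_IDS["right"]]
  new("LungModel", segments = seg,
      lowerLobeTAR = c(left = llt, right = rlt),
      denominator = denominator)
}

#' Lung model built directly from a voxel phantom
#'
#' Convenience wrapper: summarises every labelled segment of the phantom
#' and feeds the resulting table to \code{\link{buildLungModel}}.
#'
#' @param phantom a \linkS4class{VoxelPhantom} whose label table covers all
#'   required segments.
#' @inheritParams buildLungModel
#' @return a \linkS4class{LungModel}.
#' @export
lungModelFromPhantom <- function(phantom, denominator = "treatable") {
  buildLungModel(summarizePhantom(phantom)[, c("segment_id", "tissue_ml",
                                               "air_ml")],
                 denominator = denominator)
}

#' Read / write the CSV segment-table dialect
#'
#' Plain CSV with header \code{segment_id,tissue_ml,air_ml}; lower lobes
#' appear as \code{LLL} and \code{RLL} rows. A JSON equivalent (an array of
#' row objects) is accepted and produced with \code{format = "json"}.
#'
#' @param path file path.
#' @param format \code{"csv"} (default) or \code{"json"}; inferred from the
#'   file extension when missing.
#' @return \code{readSegmentTable}: a data.frame. \code{writeSegmentTable}:
#'   \code{path}, invisibly.
#' @export
readSegmentTable <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path, TRUE)) "json" else "csv"
  tab <- if (format == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment_id", "tissue_ml", "air_ml")
  if (!is.data.frame(tab) || !all(need %in% names(tab)))
    stop("segment table must provide columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  tab[, need]
}

#' @rdname readSegmentTable
#' @param table data.frame to write.
#' @export
writeSegmentTable <- function(table, path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path, TRUE)) "json" else "csv"
  need <- c("segment_id", "tissue_ml", "air_ml")
  stopifnot(all(need %in% names(table)))
  if (format == "json")
    jsonlite::write_json(table[, need], path, dataframe = "rows",
                         digits = NA)
  else write.csv(table[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname LungModel-class
#' @export
setMethod("segmentTable", "LungModel", function(x) x@segments)

#' @rdname LungModel-class
#' @export
setMethod("lowerLobeTAR", "LungModel", function(x) x@lowerLobeTAR)

#' @rdname LungModel-class
#' @export
setMethod("denominatorConvention", "LungModel", function(x) x@denominator)

# Treatable segment ids of one upper lobe, including the merged LB1+2 on
# the left.
.treatableIds <- function(side) {
  if (side == "left") c(.LEFT_TREATABLE, .LEFT_MERGED) else .RIGHT_TREATABLE
}

# Lobe-fraction denominator volume (ml) of one upper lobe under the model's
# convention. The merged LB1+2 duplicates LB1/LB2 tissue and is excluded.
.lobeDenominator <- function(model, side) {
  seg <- model@segments
  base <- seg[seg$side == side & seg$region == "upper" &
                seg$segment_id != .LEFT_MERGED, ]
  vol <- sum(base$total_ml)
  if (model@denominator == "anatomical" && side == "left")
    vol <- vol + sum(seg$total_ml[seg$region == "lingula"])
  vol
}

.segmentRow <- function(model, id) {
  row <- model@segments[model@segments$segment_id == id, ]
  if (!nrow(row)) stop("unknown segment id: ", id, call. = FALSE)
  row
}

setMethod("show", "LungModel", function(object) {
  seg <- object@segments
  up <- seg[seg$region == "upper" & seg$segment_id != .LEFT_MERGED, ]
  cat("LungModel (", nrow(seg), " segments, denominator = ",
      object@denominator, ")\n", sep = "")
  cat("  upper-lobe TAR range: ",
      sprintf("%.2f-%.2f%%", min(up$tar), max(up$tar)), "\n", sep = "")
  cat("  lower-lobe TAR: left ",
      sprintf("%.2f%%", object@lowerLobeTAR["left"]), ", right ",
      sprintf("%.2f%%", object@lowerLobeTAR["right"]), "\n", sep = "")
})
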