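# Vessel-segment tables are plain data.frames with one row per vessel
# segment. Native columns:
#   subject_id        opaque label of the source volume
#   segment_id        integer, unique within a subject
#   parent_id         integer or NA for a root segment
#   length_mm, volume_mm3, radius_mm
#   n_downstream_tips integer >= 1 (a tip counts itself)
#   well_segmented    logical quality flag (circularity + minimum volume)
#   in_loop           logical, segment lies on a cycle (reticulation)
# Optional measurement columns (n_voxels, far_fraction) survive a round-trip
# when present.

segmentTableColumns <- c("subject_id", "segment_id", "parent_id",
                         "length_mm", "volume_mm3", "radius_mm",
                         "n_downstream_tips", "well_segmented", "in_loop")

# header-name synonyms accepted when reading foreign (e.g. published raw
# angiography output) tables; matching is case-insensitive
segmentTableSynonyms <- list(
  subject_id = c("subject_id", "subject", "image", "source", "img"),
  segment_id = c("segment_id", "id", "name", "vessel_id", "seg"),
  parent_id = c("parent_id", "parent", "parent_name", "par"),
  length_mm = c("length_mm", "length", "len", "l"),
  volume_mm3 = c("volume_mm3", "volume", "vol", "v"),
  radius_mm = c("radius_mm", "radius", "rad", "r"),
  n_downstream_tips = c("n_downstream_tips", "tips", "n_tips", "ntips",
                        "nd", "n_d", "ndownstream"),
  well_segmented = c("well_segmented", "wellsegmented", "quality", "ok",
                     "good"),
  in_loop = c("in_loop", "loop", "reticulated"),
  n_voxels = c("n_voxels", "voxels", "nvox"),
  far_fraction = c("far_fraction", "farfrac"))

#' Validate a vessel-segment table
#'
#' Checks the segment-table invariants: mandatory columns present, segment
#' ids unique within each subject, and every non-missing parent id
#' referencing an existing segment of the same subject.
#'
#' @param tab data.frame in the native segment-table schema.
#' @return \code{tab}, invisibly; errors describe the first violation.
#' @export
validateSegmentTable <- function(tab) {
  mandatory <- c("segment_id", "radius_mm", "length_mm")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing))
    stop("segment table lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (!"subject_id" %in% names(tab)) tab$subject_id <- "subject1"
  for (sub in unique(tab$subject_id)) {
    rows <- tab[tab$subject_id == sub, ]
    if (anyDuplicated(rows$segment_id))
      stop("duplicate segment ids within subject '", sub, "'")
    par <- rows$parent_id
    if (!is.null(par)) {
      bad <- !is.na(par) & !(par %in% rows$segment_id)
      if (any(bad))
        stop("orphan parent id(s) in subject '", sub, "': ",
             paste(unique(par[bad]), collapse = ", "))
    }
  }
  invisible(tab)
}

#' Read a vessel-segment table (TSV)
#'
#' Reads a tab-separated segment table, mapping columns by header name.
#' Foreign headers are accepted through a synonym list (e.g. \code{radius}
#' for \code{radius_mm}); unknown columns are ignored. The mandatory columns
#' are segment id, radius and length.
#'
#' @param path TSV file with a header row.
#' @param validate check table invariants (default TRUE).
#' @return data.frame in the native schema described in
#'   \code{\link{writeSegmentTable}}.
#' @export
readSegmentTable <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("segment table does not exist: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  lower <- tolower(names(raw))
  out <- list()
  for (native in names(segmentTableSynonyms)) {
    hit <- which(lower %in% segmentTableSynonyms[[native]])
    if (length(hit)) out[[native]] <- raw[[hit[1]]]
  }
  missing <- setdiff(c("segment_id", "radius_mm", "length_mm"), names(out))
  if (length(missing))
    stop("segment table ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  tab <- as.data.frame(out, stringsAsFactors = FALSE)
  if (is.null(tab$subject_id)) tab$subject_id <- "subject1"
  if (is.null(tab$parent_id)) tab$parent_id <- NA
  # empty-string parents mark roots
  if (is.character(tab$parent_id)) tab$parent_id[tab$parent_id == ""] <- NA
  for (col in c("well_segmented", "in_loop")) {
    if (!is.null(tab[[col]]) && !is.logical(tab[[col]]))
      tab[[col]] <- as.logical(as.numeric(tab[[col]]) != 0)
  }
  if (is.null(tab$well_segmented)) tab$well_segmented <- TRUE
  if (is.null(tab$in_loop)) tab$in_loop <- FALSE
  if (validate) validateSegmentTable(tab)
  tab
}

#' Write a vessel-segment table (TSV)
#'
#' Writes the native tab-separated schema: \code{subject_id}, \code{segment_id},
#' \code{parent_id} (empty for a root), \code{length_mm}, \code{volume_mm3},
#' \code{radius_mm}, \code{n_downstream_tips}, \code{well_segmented} (0/1),
#' \code{in_loop} (0/1), plus any extra measurement columns present. Numbers
#' are printed with 8 significant digits so the round-trip is lossless at
#' measurement precision.
#'
#' @param tab segment table data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSegmentTable <- function(tab, path) {
  validateSegmentTable(tab)
  atomic <- names(tab)[vapply(tab, is.atomic, logical(1))]
  cols <- c(intersect(segmentTableColumns, atomic),
            setdiff(atomic, segmentTableColumns))
  out <- tab[, cols, drop = FALSE]
  for (col in c("well_segmented", "in_loop"))
    if (!is.null(out[[col]])) out[[col]] <- as.integer(out[[col]])
  if (!is.null(out$parent_id)) {
    p <- out$parent_id
    out$parent_id <- ifelse(is.na(p), "", as.character(p))
  }
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 8))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
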