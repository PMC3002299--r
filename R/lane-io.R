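# Gel image and trace I/O, lane extraction and quality filtering.

#' Write a gel image to disk
#'
#' 16-bit grayscale TIFF (or 8-bit PNG, by file extension). Values are
#' clamped to `[0, 1]` and quantized by the writer.
#'
#' @param image Numeric matrix in `[0, 1]` (rows = migration axis).
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @export
write_gel_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(image, path, bits.per.sample = 16, compression = "none")
  else if (ext == "png") png::writePNG(image, path)
  else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read a gel image from disk
#'
#' @param path TIFF or PNG file written by [write_gel_image()] (or any
#'   single-channel grayscale image).
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_gel_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else if (ext == "png") png::readPNG(path)
  else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Extract per-lane intensity traces from a gel image
#'
#' Each lane's trace is the mean greyscale intensity across the lane's
#' column span, one value per image row. Trace order equals metadata row
#' order.
#'
#' @param image Gel image matrix (rows = migration axis).
#' @param metadata Lane metadata with `col_start` / `col_end` columns (as
#'   produced by [render_gel_image()] or read from the metadata CSV).
#' @return List of `lane_trace` objects, one per metadata row.
#' @export
extract_lanes <- function(image, metadata) {
  stopifnot(all(c("col_start", "col_end") %in% names(metadata)))
  if (any(metadata$col_start < 1 | metadata$col_end > ncol(image)))
    stop("lane column span outside image")
  spans <- metadata[order(metadata$col_start), c("col_start", "col_end")]
  if (nrow(spans) > 1 && any(spans$col_start[-1] <= spans$col_end[-nrow(spans)]))
    stop("overlapping lane column spans")
  lapply(seq_len(nrow(metadata)), function(r) {
    v <- rowMeans(image[, metadata$col_start[r]:metadata$col_end[r],
                        drop = FALSE])
    structure(list(intensities = v, npix = nrow(image)), class = "lane_trace")
  })
}

#' Quality-filter lane traces
#'
#' Deterministic stand-in for the visual triage of poor-quality lanes:
#' a lane is kept only if (i) its dynamic range (max - min intensity)
#' reaches `min_dynamic_range`, (ii) at most `max_saturated_frac` of its
#' pixels sit at the detector ceiling, and (iii) for SS lanes, peak-picking
#' recovers the expected number of anchor bands. Every rejection is logged
#' with its reason; a warning names any sample that loses all of its lanes.
#'
#' @param traces List of `lane_trace` objects.
#' @param metadata Matching metadata data frame (same order).
#' @param min_dynamic_range Minimum max-min intensity (default 0.1).
#' @param max_saturated_frac Maximum fraction of pixels at >= 0.999
#'   (default 0.2).
#' @param expected_ss_bands Number of SS anchor bands (default 24).
#' @param ss_threshold Peak threshold (on the min-max scaled trace) used to
#'   count SS anchors (default 0.3).
#' @return List with `traces`, `metadata` (kept rows) and `log` (data frame
#'   of rejections: `replicate_id`, `reason`).
#' @export
quality_filter <- function(traces, metadata, min_dynamic_range = 0.1,
                           max_saturated_frac = 0.2,
                           expected_ss_bands = 24, ss_threshold = 0.3) {
  stopifnot(length(traces) == nrow(metadata))
  keep <- rep(TRUE, length(traces))
  reasons <- character(0); who <- character(0)
  for (i in seq_along(traces)) {
    v <- traces[[i]]$intensities
    if (diff(range(v)) < min_dynamic_range) {
      keep[i] <- FALSE; who <- c(who, metadata$replicate_id[i])
      reasons <- c(reasons, "dynamic range"); next
    }
    if (mean(v >= 0.999) > max_saturated_frac) {
      keep[i] <- FALSE; who <- c(who, metadata$replicate_id[i])
      reasons <- c(reasons, "saturation"); next
    }
    if (isTRUE(metadata$is_SS[i])) {
      sc <- (v - min(v)) / diff(range(v))
      bn <- nrow(pick_bands(sc, seq(0, 1, length.out = length(sc)),
                            threshold = ss_threshold, min_separation = 0.02))
      if (bn != expected_ss_bands) {
        keep[i] <- FALSE; who <- c(who, metadata$replicate_id[i])
        reasons <- c(reasons, "SS anchors")
      }
    }
  }
  kept_meta <- metadata[keep, , drop = FALSE]
  lost <- setdiff(metadata$sample_id[!metadata$is_SS],
                  kept_meta$sample_id[!kept_meta$is_SS])
  if (length(lost))
    warning("all lanes rejected for sample(s): ", paste(lost, collapse = ", "))
  list(traces = traces[keep], metadata = kept_meta,
       log = data.frame(replicate_id = who, reason = reasons,
                        stringsAsFactors = FALSE))
}

#' Write / read lane metadata CSV
#'
#' Fixed schema: `gel_id, lane_index, sample_id, replicate_id, group,
#' is_SS, channel` plus the pixel spans `col_start, col_end`.
#' @param metadata Metadata data frame.
#' @param path CSV path.
#' @export
write_lane_metadata <- function(metadata, path) {
  write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lane_metadata
#' @export
read_lane_metadata <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write / read lane traces as CSV
#'
#' Long format: one row per (lane, pixel), columns `replicate_id`,
#' `pixel_index`, `intensity`.
#' @param traces List of `lane_trace` objects.
#' @param metadata Matching metadata (same order, for `replicate_id`).
#' @param path CSV path.
#' @export
write_lane_traces <- function(traces, metadata, path) {
  df <- do.call(rbind, lapply(seq_along(traces), function(i) {
    data.frame(replicate_id = metadata$replicate_id[i],
               pixel_index = seq_len(traces[[i]]$npix),
               intensity = traces[[i]]$intensities)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lane_traces
#' @export
read_lane_traces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$replicate_id)
  lapply(ids, function(id) {
    v <- df$intensity[df$replicate_id == id]
    structure(list(intensities = v, npix = length(v)), class = "lane_trace")
  })
}

#' Write an aligned matrix as TSV
#'
#' Rows are lanes (named by `replicate_id`), columns the 731 retained Rf
#' grid values.
#' @param X Aligned matrix from [align_experiment()].
#' @param path TSV path.
#' @export
write_aligned_matrix <- function(X, path) {
  write.table(X, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_aligned_matrix
#' @export
read_aligned_matrix <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                       check.names = FALSE))
}
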