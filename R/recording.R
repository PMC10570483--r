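#' Construct a Recording
#'
#' The basic container for one subject's continuous multichannel EEG: a
#' channels x samples voltage matrix plus sampling rate, channel labels,
#' bad-segment annotations and a bad-channel list. All sample indices are
#' 0-based and intervals are half-open `[start, end)`; time in ms is
#' `sample * 1000 / sfreq`.
#'
#' @param data numeric matrix, channels x samples.
#' @param sfreq sampling rate in Hz (> 0).
#' @param labels channel labels; defaults to rownames of `data`.
#' @param subject subject identifier.
#' @param bad_segments two-column matrix (start, end) of 0-based half-open
#'   sample intervals marked as contaminated, or `NULL`.
#' @param bad_channels character vector of damaged channel labels.
#' @return An object of class `recording`.
#' @export
recording <- function(data, sfreq, labels = rownames(data),
                      subject = "S01", bad_segments = NULL,
                      bad_channels = character(0)) {
  data <- as.matrix(data)
  if (is.null(labels)) stop("channel labels are required")
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("number of labels (", length(labels),
         ") does not match number of channel rows (", nrow(data), ")")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0)
    stop("sfreq must be a single positive number")
  bad_segments <- normalize_segments(bad_segments, ncol(data))
  bad_channels <- as.character(bad_channels)
  if (length(bad_channels) && !all(bad_channels %in% labels))
    stop("bad_channels not in labels: ",
         paste(setdiff(bad_channels, labels), collapse = ", "))
  rownames(data) <- labels
  structure(list(data = data, sfreq = as.numeric(sfreq), labels = labels,
                 subject = as.character(subject),
                 bad_segments = bad_segments, bad_channels = bad_channels),
            class = "recording")
}

# Coerce to a sorted, merged, validated 2-column (start, end) matrix.
normalize_segments <- function(seg, n_samples) {
  if (is.null(seg) || NROW(seg) == 0L)
    return(matrix(numeric(0), 0L, 2L,
                  dimnames = list(NULL, c("start", "end"))))
  seg <- matrix(as.numeric(as.matrix(seg)), ncol = 2L)
  if (any(!is.finite(seg)) || any(seg < 0) || any(seg[, 2L] > n_samples) ||
      any(seg[, 1L] >= seg[, 2L]))
    stop("bad segments must satisfy 0 <= start < end <= n_samples")
  seg <- seg[order(seg[, 1L]), , drop = FALSE]
  merged <- seg[1L, , drop = FALSE]
  for (i in seq_len(nrow(seg))[-1L]) {
    j <- nrow(merged)
    if (seg[i, 1L] <= merged[j, 2L]) {
      merged[j, 2L] <- max(merged[j, 2L], seg[i, 2L])
    } else merged <- rbind(merged, seg[i, ])
  }
  dimnames(merged) <- list(NULL, c("start", "end"))
  merged
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> subject ", x$subject, ": ", nrow(x$data), " channels x ",
      ncol(x$data), " samples @ ", x$sfreq, " Hz (",
      signif(ncol(x$data) / x$sfreq, 4), " s)\n", sep = "")
  if (nrow(x$bad_segments))
    cat("  bad segments: ", nrow(x$bad_segments), " (",
        signif(sum(x$bad_segments[, 2] - x$bad_segments[, 1]) / x$sfreq, 3),
        " s)\n", sep = "")
  if (length(x$bad_channels))
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Good-sample mask of a recording
#'
#' Logical vector, one element per sample, `TRUE` where the sample lies
#' outside every bad-segment annotation. Bad segments are masked rather
#' than spliced out so that sample indices stay aligned with any ground
#' truth; downstream stages skip masked samples and never count microstate
#' runs or transitions across a mask boundary.
#'
#' @param rec a `recording`.
#' @return logical vector of length `n_samples`.
#' @export
good_mask <- function(rec) {
  ok <- rep(TRUE, n_samples(rec))
  seg <- rec$bad_segments
  for (i in seq_len(nrow(seg)))
    ok[seq.int(seg[i, 1L] + 1L, seg[i, 2L])] <- FALSE
  ok
}

#' Usable (unmasked) duration of a recording in seconds
#' @param rec a `recording`.
#' @export
usable_seconds <- function(rec) sum(good_mask(rec)) / rec$sfreq

#' Write / read a recording as a delimited matrix with JSON sidecar
#'
#' The matrix file is comma-separated with a header row listing the channel
#' labels (in row order); each subsequent row holds one channel's samples,
#' so the layout is channels x samples. A `<path>.json` sidecar stores the
#' sampling rate, subject id, bad segments and bad channels.
#'
#' @param rec a `recording`.
#' @param path path of the matrix file (sidecar is `<path>.json`).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$labels, collapse = ","), con)
  utils::write.table(format(rec$data, digits = 10, trim = TRUE,
                            scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  sidecar <- list(sfreq = rec$sfreq, subject = rec$subject,
                  bad_segments = rec$bad_segments,
                  bad_channels = rec$bad_channels)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty recording file: ", path)
  labels <- trimws(strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
  if (any(labels == ""))
    stop("missing channel label in header at position ",
         which(labels == "")[1L], " of ", path)
  body <- lines[-1L]
  if (length(body) != length(labels))
    stop(path, ": ", length(labels), " labels in header but ",
         length(body), " channel rows")
  data <- matrix(NA_real_, length(body), 0L)
  vals <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], ",", fixed = TRUE)[[1L]]))
    if (anyNA(v))
      stop(path, ": non-numeric cell in channel row ", i, " (", labels[i], ")")
    v
  })
  if (length(unique(lengths(vals))) != 1L)
    stop(path, ": channel rows differ in sample count")
  data <- do.call(rbind, vals)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar file: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  seg <- side$bad_segments
  if (!is.null(seg) && length(seg)) seg <- matrix(unlist(seg), ncol = 2L)
  recording(data, sfreq = side$sfreq, labels = labels,
            subject = side$subject %||% "S01",
            bad_segments = seg,
            bad_channels = side$bad_channels %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Replace the data matrix, keeping metadata consistent.
set_data <- function(rec, data, sfreq = rec$sfreq, labels = rec$labels,
                     bad_segments = rec$bad_segments) {
  recording(data, sfreq = sfreq, labels = labels, subject = rec$subject,
            bad_segments = bad_segments,
            bad_channels = intersect(rec$bad_channels, labels))
}
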