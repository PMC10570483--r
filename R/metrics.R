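#' Temporal microstate metrics of a label sequence
#'
#' Runs are maximal constant-label stretches within unmasked spans; no run
#' or transition is counted across a mask boundary. Per class the metrics
#' are:
#' \describe{
#'   \item{duration (ms)}{mean run length times `1000 / sfreq`}
#'   \item{occurrence (1/s)}{number of runs divided by unmasked seconds}
#'   \item{coverage (%)}{percentage of unmasked samples carrying the class}
#' }
#' plus the 12 off-diagonal transition percentages: `100 * count(i -> j) /
#' count(all transitions)`, which sum to 100 whenever at least one
#' transition exists. A sequence with zero transitions gets an all-zero
#' transition block and attribute `no_transitions = TRUE`.
#'
#' @param seq a `label_sequence` (from [backfit()]), or an integer/factor
#'   label vector when `sfreq` is given.
#' @param sfreq sampling rate, required for a bare label vector.
#' @param classes class names, for a bare vector (default A-D as needed).
#' @param subject subject id recorded in the output row.
#' @return A one-row data frame: `subject`, `dur_<class>`, `occ_<class>`,
#'   `cov_<class>`, and `tr_<ij>` for every ordered class pair.
#' @export
compute_metrics <- function(seq, sfreq = NULL, classes = NULL,
                            subject = NULL) {
  if (inherits(seq, "label_sequence")) {
    labels <- seq$labels
    sfreq <- seq$sfreq
    classes <- seq$classes
    subject <- subject %||% seq$subject
  } else {
    labels <- as.integer(seq)
    if (is.null(sfreq)) stop("sfreq required for a bare label vector")
    if (is.null(classes))
      classes <- LETTERS[seq_len(max(labels, na.rm = TRUE))]
    subject <- subject %||% "S01"
  }
  K <- length(classes)
  ok <- !is.na(labels)
  if (!any(ok)) stop("no unmasked samples")
  n_ok <- sum(ok)
  secs <- n_ok / sfreq

  # run-length encode with masked samples as sentinel 0, so no run or
  # transition ever crosses a mask boundary
  r <- rle(ifelse(ok, labels, 0L))
  keep <- r$values != 0L
  run_class <- r$values[keep]
  run_len <- r$lengths[keep]
  adj <- which(r$values[-length(r$values)] != 0L & r$values[-1L] != 0L)
  trans <- table(factor(r$values[adj], seq_len(K)),
                 factor(r$values[adj + 1L], seq_len(K)))
  trans <- matrix(as.integer(trans), K, K)
  dur <- occ <- cov <- numeric(K)
  for (kk in seq_len(K)) {
    rl <- run_len[run_class == kk]
    dur[kk] <- if (length(rl)) mean(rl) * 1000 / sfreq else 0
    occ[kk] <- length(rl) / secs
    cov[kk] <- 100 * sum(rl) / n_ok
  }
  n_trans <- sum(trans)
  tr_pct <- if (n_trans > 0) 100 * trans / n_trans else trans * 0
  pairs <- transition_pairs(classes)
  tr <- mapply(function(i, j) tr_pct[i, j], pairs$i, pairs$j)
  out <- data.frame(subject = subject,
                    as.list(stats::setNames(dur, paste0("dur_", classes))),
                    as.list(stats::setNames(occ, paste0("occ_", classes))),
                    as.list(stats::setNames(cov, paste0("cov_", classes))),
                    as.list(stats::setNames(tr, pairs$name)),
                    stringsAsFactors = FALSE)
  attr(out, "no_transitions") <- n_trans == 0L
  if (n_trans == 0L) warning("sequence contains no transitions")
  out
}

# Ordered off-diagonal class pairs and their column names (tr_AB, ...).
transition_pairs <- function(classes) {
  K <- length(classes)
  g <- expand.grid(j = seq_len(K), i = seq_len(K))[, 2:1]
  g <- g[g$i != g$j, ]
  g <- g[order(g$i, g$j), ]
  g$name <- paste0("tr_", classes[g$i], classes[g$j])
  g
}
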