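#' Zero-phase band-pass filter
#'
#' Butterworth filtering applied forward and backward (`signal::filtfilt`)
#' so the passband has zero phase shift. The band edges default to the
#' broadband resting-EEG band 0.1-80 Hz. For numerical stability with a
#' very low high-pass corner the band-pass is applied as a cascade of a
#' 2nd-order high-pass at `low` and a 4th-order low-pass at `high`; DC is
#' removed.
#'
#' @param rec a `recording`.
#' @param low,high band edges in Hz; `0 < low < high < sfreq/2`.
#' @return the filtered `recording`.
#' @export
pp_bandpass <- function(rec, low = 0.1, high = 80) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$sfreq / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyq) stop("high edge (", high, " Hz) must be below Nyquist (",
                        nyq, " Hz)")
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  out <- rec$data - rowMeans(rec$data)   # remove DC before the long-tailed HP
  out <- t(apply(out, 1L, function(ch)
    signal::filtfilt(lp, signal::filtfilt(hp, ch))))
  set_data(rec, out)
}

#' Zero-phase band-stop (notch) filter for power-line noise
#'
#' 4th-order Butterworth band-stop applied forward-backward. Defaults to
#' the 48-52 Hz band around 50 Hz mains.
#'
#' @param rec a `recording`.
#' @param lower,upper stop-band edges in Hz, inside `(0, sfreq/2)`.
#' @return the filtered `recording`.
#' @export
pp_notch <- function(rec, lower = 48, upper = 52) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$sfreq / 2
  if (!(lower > 0 && lower < upper && upper < nyq))
    stop("notch band must lie inside (0, Nyquist)")
  bs <- signal::butter(4, c(lower, upper) / nyq, type = "stop")
  out <- t(apply(rec$data, 1L, function(ch) signal::filtfilt(bs, ch)))
  set_data(rec, out)
}

#' Resample a recording to a lower sampling rate
#'
#' Polyphase anti-aliased resampling (`signal::resample`) of every channel.
#' Only downsampling (or the identity) is supported; bad-segment
#' annotations are rescaled by `target / sfreq`.
#'
#' @param rec a `recording`.
#' @param target new sampling rate in Hz, `<= sfreq`.
#' @return the resampled `recording`.
#' @export
pp_resample <- function(rec, target = 500) {
  stopifnot(inherits(rec, "recording"))
  if (target > rec$sfreq) stop("upsampling not supported (target ", target,
                               " > sfreq ", rec$sfreq, ")")
  if (target == rec$sfreq) return(rec)
  frac <- ratio_pq(target / rec$sfreq)
  out <- t(apply(rec$data, 1L, function(ch)
    signal::resample(ch, frac[1L], frac[2L])))
  n_new <- round(n_samples(rec) * target / rec$sfreq)
  out <- out[, seq_len(min(ncol(out), n_new)), drop = FALSE]
  seg <- rec$bad_segments
  if (nrow(seg)) {
    seg <- round(seg * target / rec$sfreq)
    seg[, 2L] <- pmin(seg[, 2L], ncol(out))
    seg <- seg[seg[, 1L] < seg[, 2L], , drop = FALSE]
  }
  set_data(rec, out, sfreq = target, bad_segments = seg)
}

# Small-integer rational approximation of a resampling ratio.
ratio_pq <- function(r, max_q = 1000L) {
  for (q in seq_len(max_q)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("resampling ratio ", r, " has no small rational form")
}

#' Re-reference to averaged mastoids
#'
#' Subtracts the mean of the two mastoid channels from every channel and
#' drops the mastoids from the scalp set used downstream. The removed
#' reference series is stored in attribute `"reference"` so the operation
#' is invertible.
#'
#' @param rec a `recording` containing both mastoid channels.
#' @param m1,m2 mastoid channel labels.
#' @return the re-referenced `recording` (without M1/M2).
#' @export
pp_rereference <- function(rec, m1 = "M1", m2 = "M2") {
  stopifnot(inherits(rec, "recording"))
  miss <- setdiff(c(m1, m2), rec$labels)
  if (length(miss)) stop("mastoid channel(s) missing: ",
                         paste(miss, collapse = ", "))
  ref <- colMeans(rec$data[c(m1, m2), , drop = FALSE])
  keep <- setdiff(rec$labels, c(m1, m2))
  out <- sweep(rec$data[keep, , drop = FALSE], 2L, ref)
  res <- set_data(rec, out, labels = keep)
  attr(res, "reference") <- ref
  res
}

#' Interpolate damaged channels
#'
#' Each bad channel is replaced by the inverse-distance-weighted mean of
#' its 4 nearest good channels (montage positions). Subjects with more
#' than `max_bad` damaged channels are excluded: the function signals a
#' condition of class `subject_excluded`.
#'
#' @param rec a `recording` with a `bad_channels` list.
#' @param montage a `montage` covering the recording's channels.
#' @param max_bad maximum number of interpolatable channels (default 3;
#'   more leads to exclusion).
#' @param k number of neighbors used for interpolation.
#' @return the repaired `recording` with `bad_channels` cleared.
#' @export
pp_interpolate_bad <- function(rec, montage = standard_montage(),
                               max_bad = 3L, k = 4L) {
  stopifnot(inherits(rec, "recording"))
  bad <- rec$bad_channels
  if (!length(bad)) return(rec)
  if (length(bad) > max_bad)
    stop(structure(class = c("subject_excluded", "error", "condition"),
                   list(message = paste0("subject ", rec$subject, " excluded: ",
                                         length(bad), " damaged channels (> ",
                                         max_bad, ")"),
                        call = sys.call())))
  validate_montage(montage)
  if (!all(rec$labels %in% montage$labels))
    stop("montage does not cover channels: ",
         paste(setdiff(rec$labels, montage$labels), collapse = ", "))
  pos <- montage$pos[rec$labels, , drop = FALSE]
  good <- setdiff(rec$labels, bad)
  out <- rec$data
  for (b in bad) {
    d <- sqrt(rowSums(sweep(pos[good, , drop = FALSE], 2L, pos[b, ])^2))
    nb <- good[order(d)][seq_len(min(k, length(good)))]
    w <- 1 / pmax(d[order(d)][seq_len(length(nb))], 1e-12)
    w <- w / sum(w)
    out[b, ] <- as.vector(w %*% rec$data[nb, , drop = FALSE])
  }
  res <- set_data(rec, out)
  res$bad_channels <- character(0)
  res
}

#' Full preprocessing chain
#'
#' Applies, in order: band-pass, notch, resampling to `target_sfreq`,
#' averaged-mastoid re-referencing (only when both mastoids are present),
#' and bad-channel interpolation. Bad segments are kept as annotations
#' (see [good_mask()]), never spliced out. Synthetic recordings carry no
#' mastoids and are already at the target rate, so those steps are no-ops
#' for them.
#'
#' @param rec a `recording`.
#' @param montage a `montage` for interpolation.
#' @param low,high band-pass edges (Hz).
#' @param notch_lower,notch_upper notch band (Hz), or `NULL` to skip.
#' @param target_sfreq resampling target (Hz).
#' @return the preprocessed `recording`.
#' @export
preprocess <- function(rec, montage = standard_montage(),
                       low = 0.1, high = 80,
                       notch_lower = 48, notch_upper = 52,
                       target_sfreq = 500) {
  rec <- pp_bandpass(rec, low, high)
  if (!is.null(notch_lower)) rec <- pp_notch(rec, notch_lower, notch_upper)
  if (rec$sfreq > target_sfreq) rec <- pp_resample(rec, target_sfreq)
  if (all(c("M1", "M2") %in% rec$labels)) rec <- pp_rereference(rec)
  pp_interpolate_bad(rec, montage)
}
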