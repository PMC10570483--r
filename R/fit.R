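#' Individual-level microstate clustering
#'
#' First-level segmentation of one preprocessed recording: the scalp data
#' are converted to common average reference, the GFP is computed, maps at
#' retained GFP peaks are extracted (masked samples contribute no peaks),
#' and polarity-invariant modified k-means is run on the peak maps.
#'
#' @param rec a preprocessed `recording`.
#' @param k number of microstate classes (default 4).
#' @param restarts k-means restarts (default 100).
#' @param peak_rule GFP-peak outlier rule, see [find_gfp_peaks()].
#' @param seed seed for the k-means restarts.
#' @return an unlabeled `template_set` (provenance = subject id).
#' @export
cluster_individual <- function(rec, k = 4L, restarts = 100L,
                               peak_rule = "mean+2sd", seed = NULL) {
  stopifnot(inherits(rec, "recording"))
  dat <- avg_reference(rec$data)
  g <- compute_gfp(dat, sfreq = rec$sfreq)
  g <- find_gfp_peaks(g, rule = peak_rule, mask = good_mask(rec))
  if (length(g$peaks) < k)
    stop("only ", length(g$peaks), " usable GFP peaks; need >= k = ", k)
  peak_maps <- dat[, g$peaks + 1L, drop = FALSE]
  ts <- modified_kmeans(peak_maps, k = k, restarts = restarts, seed = seed)
  ts$provenance <- rec$subject
  rownames(ts$maps) <- rec$labels
  ts
}

# Common average reference across channels, per sample.
avg_reference <- function(m) m - rep(colMeans(m), each = nrow(m))

#' Group-level microstate clustering and canonical labeling
#'
#' Second-level clustering: the individual template maps of all subjects
#' are pooled and re-clustered with polarity-invariant modified k-means,
#' then the resulting group maps are labeled A-D by the one-to-one
#' matching to the canonical templates that maximizes total
#' polarity-invariant similarity (exhaustive search over the k!
#' permutations). A mean matched similarity below 0.5 raises a warning
#' (non-canonical solution).
#'
#' @param sets list of individual `template_set`s (>= 2 subjects).
#' @param montage montage used to build the canonical reference maps.
#' @param k,restarts,seed as in [cluster_individual()].
#' @return a labeled `template_set` with columns ordered A-D
#'   (provenance = "group").
#' @export
cluster_group <- function(sets, montage = standard_montage(), k = 4L,
                          restarts = 100L, seed = NULL) {
  if (length(sets) < 2L) stop("group clustering needs >= 2 subjects")
  pooled <- do.call(cbind, lapply(sets, function(s) s$maps))
  ts <- modified_kmeans(pooled, k = k, restarts = restarts, seed = seed,
                        weights = rep(1, ncol(pooled)))
  rownames(ts$maps) <- rownames(sets[[1L]]$maps)
  label_templates(ts, canonical_templates(montage))
}

# Assign class labels to template columns by the permutation maximizing
# total |spatial correlation| with reference maps; reorders columns to the
# reference order and flips signs so matched correlation is positive.
label_templates <- function(ts, reference) {
  k <- ts$k
  if (ncol(reference) != k) stop("reference has wrong number of maps")
  sim <- abs(stats::cor(ts$maps, reference))          # k x k
  perms <- permutations(k)
  tot <- apply(perms, 1L, function(p) sum(sim[cbind(p, seq_len(k))]))
  p <- perms[which.max(tot), ]                        # template col for ref j
  mean_sim <- max(tot) / k
  if (mean_sim < 0.5)
    warning("non-canonical solution: mean matched similarity ",
            signif(mean_sim, 3), " < 0.5")
  maps <- ts$maps[, p, drop = FALSE]
  sgn <- sign(diag(stats::cor(maps, reference)))
  sgn[sgn == 0] <- 1
  maps <- sweep(maps, 2L, sgn, "*")
  colnames(maps) <- colnames(reference)
  relabel <- match(seq_len(k), p)
  ts$maps <- maps
  ts$labels <- relabel[ts$labels]
  ts$class_labels <- colnames(reference)
  ts$match_similarity <- sim[cbind(p, seq_len(k))]
  ts
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))))
}

#' Backfit group templates into a recording
#'
#' Assigns every unmasked sample the class of the template with maximal
#' absolute spatial correlation to the sample's (average-referenced)
#' topography. Ties go to the lowest class index (A < B < C < D).
#' Zero-variance samples inherit the previous valid label (or the next
#' one at the start of the sequence). Masked samples get `NA`.
#'
#' @param rec a preprocessed `recording`.
#' @param templates a labeled `template_set` (or a channels x K matrix of
#'   unit-norm zero-mean maps).
#' @return An object of class `label_sequence`: list with `labels`
#'   (integer per sample, `NA` where masked), `classes` (class names),
#'   `corr` (per-sample fitted |spatial correlation|), `sfreq`, `mask`,
#'   `gev` (GEV of the fit over unmasked samples) and `subject`.
#' @export
backfit <- function(rec, templates) {
  stopifnot(inherits(rec, "recording"))
  tm <- if (inherits(templates, "template_set")) templates$maps else templates
  classes <- colnames(tm)
  if (is.null(classes)) classes <- LETTERS[seq_len(ncol(tm))]
  mask <- good_mask(rec)
  if (!any(mask)) stop("no unmasked samples to backfit")
  dat <- avg_reference(rec$data)
  cc <- abs(map_template_corr(dat, tm))              # K x T
  lab <- max.col(t(cc), ties.method = "first")
  fit <- cc[cbind(lab, seq_along(lab))]
  zero_var <- colSums(dat^2) == 0
  lab[zero_var] <- NA_integer_
  lab <- fill_forward(lab)
  g <- sqrt(colMeans(dat^2))           # spatial SD; dat is already centered
  lab_m <- lab; lab_m[!mask] <- NA_integer_
  fit_m <- fit; fit_m[!mask | zero_var] <- NA_real_
  ok <- !is.na(lab_m) & g > 0
  ri <- cc[cbind(lab_m[ok], which(ok))]
  structure(list(labels = lab_m, classes = classes, corr = fit_m,
                 sfreq = rec$sfreq, mask = mask,
                 gev = sum((g[ok] * ri)^2) / sum(g^2),
                 subject = rec$subject),
            class = "label_sequence")
}

# Replace NA entries by the previous non-NA value (next one at the start).
fill_forward <- function(x) {
  if (!anyNA(x)) return(x)
  n <- length(x)
  last <- NA
  for (i in seq_len(n)) {
    if (is.na(x[i])) x[i] <- last else last <- x[i]
  }
  if (anyNA(x)) {
    nxt <- x[which(!is.na(x))[1L]]
    x[is.na(x)] <- nxt
  }
  x
}

#' @export
print.label_sequence <- function(x, ...) {
  cat("<label_sequence> subject ", x$subject, ": ", length(x$labels),
      " samples @ ", x$sfreq, " Hz, GEV = ", signif(x$gev, 4), "\n", sep = "")
  invisible(x)
}

#' Fit the two-level microstate model to a cohort of recordings
#'
#' The front end of the package: runs individual-level clustering for each
#' subject, pools the individual templates into the group-level clustering,
#' labels the group maps A-D against the canonical topographies, backfits
#' them into every recording, and computes the per-subject temporal
#' metrics.
#'
#' @param recordings a list of preprocessed `recording`s (or one
#'   `recording`).
#' @param k number of microstate classes (default 4).
#' @param restarts modified k-means restarts at both levels (default 100).
#' @param peak_rule GFP-peak outlier rule, see [find_gfp_peaks()].
#' @param montage montage providing the canonical reference maps.
#' @param seed integer seed controlling the k-means restarts.
#' @return An object of class `microstate_fit`: list with `templates`
#'   (labeled group `template_set`), `individual` (per-subject sets),
#'   `sequences` (per-subject `label_sequence`s), `metrics` (data frame,
#'   one row per subject: dur_A..dur_D ms, occ_A..occ_D per s,
#'   cov_A..cov_D %, tr_AB..tr_DC %), `gev` (mean backfit GEV), `k`,
#'   and `call`.
#' @examples
#' cfg <- sim_config(n_hp = 2, n_lp = 2, length_s = 10, seed = 7)
#' coh <- simulate_cohort(cfg)
#' fit <- fit_microstates(coh$recordings, restarts = 10, seed = 1)
#' fit
#' coef(fit)[1:3, ]
#' head(fit$metrics)
#' @export
fit_microstates <- function(recordings, k = 4L, restarts = 100L,
                            peak_rule = "mean+2sd",
                            montage = standard_montage(), seed = 1L) {
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1L,
            all(vapply(recordings, inherits, TRUE, "recording")))
  indiv <- lapply(seq_along(recordings), function(i)
    cluster_individual(recordings[[i]], k = k, restarts = restarts,
                       peak_rule = peak_rule, seed = seed + i))
  grp <- if (length(indiv) >= 2L)
    cluster_group(indiv, montage = montage, k = k, restarts = restarts,
                  seed = seed)
  else label_templates(indiv[[1L]], canonical_templates(montage))
  seqs <- lapply(recordings, backfit, templates = grp)
  metrics <- do.call(rbind, lapply(seqs, compute_metrics))
  rownames(metrics) <- NULL
  structure(list(templates = grp, individual = indiv, sequences = seqs,
                 metrics = metrics,
                 gev = mean(vapply(seqs, `[[`, 0, "gev")),
                 k = k, call = match.call()),
            class = "microstate_fit")
}

#' @export
print.microstate_fit <- function(x, ...) {
  cat("Two-level microstate segmentation (k = ", x$k, ")\n", sep = "")
  cat("  subjects: ", nrow(x$metrics), "\n", sep = "")
  cat("  mean backfit GEV: ", signif(x$gev, 4), "\n", sep = "")
  cat("  group template GEV (peak maps): ", signif(x$templates$gev, 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.microstate_fit <- function(object, ...) {
  m <- object$metrics
  cls <- object$templates$class_labels
  tab <- t(vapply(cls, function(cl) c(
    duration_ms = mean(m[[paste0("dur_", cl)]]),
    occurrence = mean(m[[paste0("occ_", cl)]]),
    coverage_pct = mean(m[[paste0("cov_", cl)]])), numeric(3)))
  res <- list(k = object$k, n = nrow(m), gev = object$gev,
              class_means = tab)
  class(res) <- "summary.microstate_fit"
  res
}

#' @export
print.summary.microstate_fit <- function(x, ...) {
  cat("Microstate fit: ", x$n, " subjects, k = ", x$k,
      ", mean GEV = ", signif(x$gev, 4), "\n\n", sep = "")
  cat("Mean temporal metrics per class:\n")
  print(round(x$class_means, 2))
  invisible(x)
}

#' @export
coef.microstate_fit <- function(object, ...) object$templates$maps

#' Backfit new data with a fitted microstate model
#'
#' @param object a `microstate_fit`.
#' @param newdata a `recording` (or list of recordings) on the same
#'   channel set.
#' @param ... unused.
#' @return a `label_sequence` (or list of them).
#' @export
predict.microstate_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "recording"))
    return(backfit(newdata, object$templates))
  lapply(newdata, backfit, templates = object$templates)
}

#' Plot fitted microstate templates
#'
#' Draws each group template as a color-coded electrode map on the head
#' circle (red positive, blue negative; polarity is conventional).
#'
#' @param x a `microstate_fit`.
#' @param montage the montage supplying electrode positions.
#' @param ... passed to `plot.default`.
#' @export
plot.microstate_fit <- function(x, montage = standard_montage(), ...) {
  tm <- x$templates$maps
  pos <- montage$pos[rownames(tm), , drop = FALSE]
  op <- graphics::par(mfrow = c(1, ncol(tm)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::colorRampPalette(c("blue3", "grey95", "red3"))(101)
  for (j in seq_len(ncol(tm))) {
    v <- tm[, j]
    idx <- 1 + round(50 * (1 + v / max(abs(v))))
    plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), axes = FALSE,
         asp = 1, xlab = "", ylab = "",
         main = paste0("MS-", colnames(tm)[j]), ...)
    graphics::symbols(0, 0, circles = 1.1, inches = FALSE, add = TRUE)
    graphics::points(pos[, 1], pos[, 2], pch = 21, cex = 2.2,
                     bg = pal[idx], col = "grey40")
  }
  invisible(x)
}
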