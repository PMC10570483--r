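#' Global field power
#'
#' GFP at each sample is the spatial standard deviation of the scalp
#' topography: `GFP(t) = sqrt(mean((v_c(t) - mean_c v_c(t))^2))` over the
#' channels (population form, divisor C). High-GFP moments are the moments
#' of highest topographic signal-to-noise and anchor microstate analysis.
#'
#' @param rec a `recording` (or a bare channels x samples matrix) with at
#'   least 2 channels.
#' @param sfreq sampling rate, required only when `rec` is a bare matrix.
#' @return An object of class `gfp_series`: list with `gfp` (numeric per
#'   sample), `sfreq`, and (after [find_gfp_peaks()]) `peaks` and
#'   `excluded` (0-based sample indices).
#' @export
compute_gfp <- function(rec, sfreq = NULL) {
  if (inherits(rec, "recording")) {
    m <- rec$data
    sfreq <- rec$sfreq
  } else {
    m <- as.matrix(rec)
    if (is.null(sfreq)) stop("sfreq required for a bare matrix")
  }
  if (nrow(m) < 2L) stop("GFP needs at least 2 channels")
  g <- sqrt(pmax(colMeans(m^2) - colMeans(m)^2, 0))
  structure(list(gfp = g, sfreq = sfreq, peaks = NULL, excluded = NULL),
            class = "gfp_series")
}

#' Locate and screen GFP peaks
#'
#' Peaks are strict local maxima of the GFP series. To keep high-amplitude
#' outliers (residual artifacts) out of the clustering, unusually large
#' peaks are excluded; with the default rule a peak is dropped when its GFP
#' exceeds `mean + 2 * SD` of all peak GFP values (`rule = "mean+2sd"`).
#' The literal alternative `rule = "2sd"` drops peaks whose GFP exceeds
#' twice the SD of all peak values. Peaks inside masked (bad) segments are
#' never returned.
#'
#' @param x a `gfp_series` (>= 3 samples).
#' @param rule outlier rule, `"mean+2sd"` (default) or `"2sd"`.
#' @param mask optional logical good-sample mask aligned with the series.
#' @return `x` with `peaks` (retained peak indices, 0-based) and
#'   `excluded` (outlier peak indices) filled in.
#' @export
find_gfp_peaks <- function(x, rule = c("mean+2sd", "2sd"), mask = NULL) {
  stopifnot(inherits(x, "gfp_series"))
  rule <- match.arg(rule)
  g <- x$gfp
  n <- length(g)
  if (n < 3L) stop("need at least 3 samples to find peaks")
  i <- 2:(n - 1L)
  is_peak <- g[i] > g[i - 1L] & g[i] > g[i + 1L]
  pk <- i[is_peak]                       # 1-based interior positions
  if (!is.null(mask)) pk <- pk[mask[pk]]
  if (!length(pk)) {
    warning("no GFP peaks found")
    x$peaks <- integer(0); x$excluded <- integer(0)
    return(x)
  }
  pv <- g[pk]
  thr <- if (rule == "mean+2sd") mean(pv) + 2 * stats::sd(pv)
         else 2 * stats::sd(pv)
  drop <- if (is.na(thr)) rep(FALSE, length(pk)) else pv > thr
  x$peaks <- pk[!drop] - 1L              # 0-based
  x$excluded <- pk[drop] - 1L
  x
}

#' Spatial correlation and polarity-invariant similarity of two maps
#'
#' The Pearson correlation of two topographies across channels, and its
#' absolute value. Microstate analysis disregards polarity: a map and its
#' sign-flipped copy are the same state, so similarity is `|correlation|`.
#'
#' @param u,v numeric vectors of equal length (one value per channel),
#'   each with non-zero variance.
#' @return list with `correlation` and `similarity`.
#' @export
spatial_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("maps differ in channel count")
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("spatial correlation undefined for a zero-variance map")
  r <- stats::cor(u, v)
  list(correlation = r, similarity = abs(r))
}

#' Global explained variance
#'
#' Fraction of GFP-weighted topographic variance explained by the assigned
#' templates: `GEV = sum_t (GFP_t * corr(v_t, a_L(t)))^2 / sum_t GFP_t^2`,
#' where `corr` is the spatial Pearson correlation between the sample map
#' and its assigned template.
#'
#' @param maps channels x T matrix of topographies.
#' @param templates channels x K matrix of unit-norm zero-mean templates.
#' @param labels integer template assignment per column of `maps` (`NA`
#'   columns are skipped).
#' @param gfp GFP value per column; defaults to the spatial SD of `maps`.
#' @return GEV in `[0, 1]`.
#' @export
gev <- function(maps, templates, labels, gfp = NULL) {
  maps <- as.matrix(maps)
  if (is.null(gfp))
    gfp <- sqrt(pmax(colMeans(maps^2) - colMeans(maps)^2, 0))
  if (all(gfp == 0)) stop("GEV undefined: all-zero GFP")
  ok <- !is.na(labels) & gfp > 0
  r <- map_template_corr(maps[, ok, drop = FALSE], templates)
  ri <- r[cbind(labels[ok], seq_len(sum(ok)))]
  sum((gfp[ok] * ri)^2) / sum(gfp^2)
}

# Spatial Pearson correlations between columns of `maps` (any scale) and
# unit-norm zero-mean template columns: K x T matrix. Zero-variance map
# columns get correlation 0.
map_template_corr <- function(maps, templates) {
  m <- maps - rep(colMeans(maps), each = nrow(maps))
  nrm <- sqrt(colSums(m^2))
  inv <- ifelse(nrm > 0, 1 / nrm, 0)
  m <- m * rep(inv, each = nrow(m))
  crossprod(templates, m)
}

#' Cross-validation criterion
#'
#' Residual-variance model-selection statistic penalizing the number of
#' templates K against the channel count C:
#' `sigma2 = sum_t (v_t' v_t - (a_L(t)' v_t)^2) / (T * (C - 1))`,
#' `CV = sigma2 * ((C - 1) / (C - K - 1))^2`. Smaller is better; it is 0
#' when every sample map is exactly proportional to its template.
#'
#' @inheritParams gev
#' @return the CV criterion value (voltage^2 scale).
#' @export
cv_criterion <- function(maps, templates, labels) {
  maps <- as.matrix(maps)
  C <- nrow(maps); K <- ncol(templates)
  if (C <= K + 1L) stop("CV criterion requires more channels than K + 1")
  ok <- !is.na(labels)
  v <- maps[, ok, drop = FALSE]
  v <- v - rep(colMeans(v), each = nrow(v))
  a <- templates[, labels[ok], drop = FALSE]
  resid <- colSums(v^2) - colSums(a * v)^2
  sigma2 <- sum(resid) / (sum(ok) * (C - 1))
  sigma2 * ((C - 1) / (C - K - 1))^2
}

#' Polarity-invariant modified k-means clustering of topographies
#'
#' The microstate clustering algorithm. Each restart draws `k` distinct
#' input maps as initial centers, then alternates: (1) assign every map to
#' the center with the largest absolute spatial correlation; (2) replace
#' each center by the sign-aligned mean of its members (members whose
#' correlation with the current center is negative are flipped before
#' averaging), re-centered to zero mean and re-normalized. Iteration stops
#' when the assignment stabilizes or the GEV gain falls below `tol`
#' (at most `max_iter` sweeps). The restart with the highest GEV wins.
#' An empty cluster is re-seeded from the currently worst-fitted map.
#'
#' @param maps channels x N matrix of topographies (N >= k). Columns are
#'   average-referenced and normalized internally; the GEV objective is
#'   weighted by each map's original GFP (or by `weights`).
#' @param k number of clusters (default 4).
#' @param restarts number of random restarts (default 100).
#' @param weights optional per-map GFP weights; defaults to the spatial SD
#'   of each input column.
#' @param seed optional integer seed making the restarts reproducible.
#' @param max_iter cap on update sweeps per restart.
#' @param tol minimum GEV gain to continue iterating.
#' @return An object of class `template_set`: list with `maps` (channels x
#'   k, zero-mean unit-norm), `labels` (assignment per input map), `gev`,
#'   `cv`, `k`, `restarts`, and `provenance`.
#' @export
modified_kmeans <- function(maps, k = 4L, restarts = 100L, weights = NULL,
                            seed = NULL, max_iter = 1000L, tol = 1e-6) {
  maps <- as.matrix(maps)
  n <- ncol(maps)
  if (n < k) stop("need at least k = ", k, " maps, got ", n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  w <- if (is.null(weights))
    sqrt(pmax(colMeans(maps^2) - colMeans(maps)^2, 0)) else weights
  keep <- w > 0
  if (!all(keep)) { maps <- maps[, keep, drop = FALSE]; w <- w[keep] }
  V <- normalize_maps(maps)              # zero-mean unit-norm columns
  w2 <- w^2; tot <- sum(w2)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- V[, sample.int(ncol(V), k), drop = FALSE]
    lab <- rep(0L, ncol(V)); g_prev <- -Inf
    for (it in seq_len(max_iter)) {
      cc <- crossprod(centers, V)              # k x N correlations
      lab_new <- max.col(t(abs(cc)), ties.method = "first")
      # re-seed empty clusters from the worst-fitted map
      fit <- abs(cc[cbind(lab_new, seq_len(ncol(V)))])
      for (j in seq_len(k)) {
        if (!any(lab_new == j)) {
          worst <- which.min(fit)
          centers[, j] <- V[, worst]
          lab_new[worst] <- j
          fit[worst] <- 1
        }
      }
      for (j in seq_len(k)) {
        mem <- which(lab_new == j)
        s <- sign(cc[j, mem]); s[s == 0] <- 1
        ctr <- V[, mem, drop = FALSE] %*% s
        ctr <- ctr - mean(ctr)
        nrm <- sqrt(sum(ctr^2))
        if (nrm > 0) centers[, j] <- ctr / nrm
      }
      cc <- crossprod(centers, V)
      ri <- abs(cc[cbind(lab_new, seq_len(ncol(V)))])
      g <- sum(w2 * ri^2) / tot
      if (identical(lab_new, lab) || g - g_prev < tol) { lab <- lab_new; break }
      lab <- lab_new; g_prev <- g
    }
    if (is.null(best) || g > best$gev)
      best <- list(centers = centers, labels = lab, gev = g)
  }
  lab_full <- rep(NA_integer_, n)
  lab_full[keep] <- best$labels
  cv <- if (nrow(maps) > k + 1L)
    cv_criterion(maps, best$centers, best$labels) else NA_real_
  structure(list(maps = best$centers, labels = lab_full, gev = best$gev,
                 cv = cv, k = k, restarts = restarts,
                 class_labels = NULL, provenance = "unlabeled"),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat("<template_set> k = ", x$k, ", ", nrow(x$maps), " channels",
      if (!is.null(x$class_labels))
        paste0(", classes ", paste(x$class_labels, collapse = "")),
      "\n  GEV = ", signif(x$gev, 4),
      if (!is.na(x$cv)) paste0(", CV = ", signif(x$cv, 4)),
      " (", x$restarts, " restarts; ", x$provenance, ")\n", sep = "")
  invisible(x)
}
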