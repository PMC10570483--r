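#' Standard 30-channel 10-20 montage
#'
#' Returns the scalp montage used throughout the package: the 10-20 / 10-10
#' channel set of a 32-channel cap with the two mastoids (M1, M2) set aside
#' as reference electrodes, leaving 30 scalp channels. Positions are 2-D
#' polar projections onto the unit head circle (x: left negative / right
#' positive; y: posterior negative / anterior positive).
#'
#' @param include_mastoids if `TRUE`, append M1 and M2 (placed below the
#'   ears, outside the head circle) to the channel set.
#' @return An object of class `montage`: a list with `labels` (character),
#'   `pos` (n x 2 numeric matrix, rownames = labels) and `mastoids`
#'   (character vector of mastoid labels present).
#' @export
standard_montage <- function(include_mastoids = FALSE) {
  ring <- function(deg) c(cospi(deg / 180), sinpi(deg / 180))
  pos <- rbind(
    Fp1 = ring(108), Fp2 = ring(72),
    F7  = ring(144), F3  = c(-0.40,  0.50), Fz = c(0,  0.50),
    F4  = c(0.40,  0.50), F8 = ring(36),
    FT7 = c(-0.87,  0.33), FC3 = c(-0.45,  0.25), FCz = c(0,  0.25),
    FC4 = c(0.45,  0.25), FT8 = c(0.87,  0.33),
    T3  = c(-1, 0), C3 = c(-0.50, 0), Cz = c(0, 0), C4 = c(0.50, 0),
    T4  = c(1, 0),
    TP7 = c(-0.87, -0.33), CP3 = c(-0.45, -0.25), CPz = c(0, -0.25),
    CP4 = c(0.45, -0.25), TP8 = c(0.87, -0.33),
    T5  = ring(216), P3 = c(-0.40, -0.50), Pz = c(0, -0.50),
    P4  = c(0.40, -0.50), T6 = ring(324),
    O1  = ring(252), Oz = c(0, -1), O2 = ring(288))
  mast <- character(0)
  if (include_mastoids) {
    pos <- rbind(pos, M1 = c(-1.15, -0.55), M2 = c(1.15, -0.55))
    mast <- c("M1", "M2")
  }
  colnames(pos) <- c("x", "y")
  structure(list(labels = rownames(pos), pos = pos, mastoids = mast),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$labels), " channels",
      if (length(x$mastoids)) paste0(" (mastoids: ",
                                     paste(x$mastoids, collapse = ", "), ")"),
      "\n", sep = "")
  cat(" ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

validate_montage <- function(montage, min_channels = 8L) {
  stopifnot(inherits(montage, "montage"))
  if (anyDuplicated(montage$labels))
    stop("montage labels must be unique")
  if (!all(is.finite(montage$pos)))
    stop("montage positions must be finite")
  if (length(montage$labels) < min_channels)
    stop("montage has fewer than ", min_channels, " channels")
  invisible(montage)
}

scalp_labels <- function(montage) setdiff(montage$labels, montage$mastoids)

#' Canonical microstate template maps
#'
#' Builds the four canonical resting-state microstate topographies on a
#' given montage, used to assign class labels A-D to group-level cluster
#' centers by polarity-invariant matching:
#' \describe{
#'   \item{A}{left-posterior / right-anterior diagonal gradient}
#'   \item{B}{the mirrored diagonal (right-posterior / left-anterior)}
#'   \item{C}{anterior-posterior gradient with an occipital extremum,
#'     symmetric about the midline}
#'   \item{D}{fronto-central extremum}
#' }
#' Each map is average-referenced (zero mean across channels) and scaled to
#' unit L2 norm; microstate analysis is polarity-invariant so the overall
#' sign of each map is a convention, not data.
#'
#' @param montage a `montage`; mastoid channels are ignored.
#' @return A channels x 4 numeric matrix with rownames = scalp channel
#'   labels and colnames `c("A","B","C","D")`. Pairwise absolute spatial
#'   correlations are below 0.7.
#' @export
canonical_templates <- function(montage = standard_montage()) {
  validate_montage(montage)
  sc <- scalp_labels(montage)
  p <- montage$pos[sc, , drop = FALSE]
  x <- p[, "x"]; y <- p[, "y"]
  bump <- function(cx, cy, s) exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
  maps <- cbind(
    A = -(x + y),
    B = x - y,
    C = bump(0, -0.70, 0.55),
    D = bump(0, 0.20, 0.40))
  maps <- normalize_maps(maps)
  rownames(maps) <- sc
  maps
}

# Center each column (average reference) and scale to unit L2 norm.
normalize_maps <- function(m) {
  m <- as.matrix(m)
  m <- m - rep(colMeans(m), each = nrow(m))
  nrm <- sqrt(colSums(m^2))
  if (any(nrm == 0)) stop("cannot normalize a zero map")
  m * rep(1 / nrm, each = nrow(m))
}
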