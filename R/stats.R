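#' Normality-routed two-group comparison
#'
#' The Shapiro-Wilk test is run in each group at alpha = .05; when both
#' groups pass, a two-sample pooled-variance Student t-test is used,
#' otherwise the Mann-Whitney U test (normal approximation with tie
#' correction). Cohen's d (pooled SD, sign convention HP - LP) is always
#' reported.
#'
#' @param x,y numeric metric values for the two groups (HP and LP), each
#'   with >= 3 observations.
#' @param name comparison name carried into the result.
#' @param var_equal use the pooled-variance t-test (default); `FALSE`
#'   switches to Welch.
#' @return a one-row `stats_result` data frame: `comparison`, `test`,
#'   `statistic`, `p`, `d`.
#' @export
route_and_compare <- function(x, y, name = "metric", var_equal = TRUE) {
  if (length(x) < 3L || length(y) < 3L) stop("need >= 3 subjects per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("degenerate comparison: zero variance in both groups")
  normal <- function(v) stats::sd(v) > 0 && stats::shapiro.test(v)$p.value > .05
  if (normal(x) && normal(y)) {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    test <- if (var_equal) "t" else "welch"
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    tt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    test <- "mann-whitney"
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  data.frame(comparison = name, test = test, statistic = stat, p = p,
             d = cohens_d(mean(x), stats::sd(x), length(x),
                          mean(y), stats::sd(y), length(y)),
             stringsAsFactors = FALSE)
}

#' Cohen's d from group summaries
#'
#' `d = (m1 - m2) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' Group 1 is conventionally HP, so a negative d means HP lower.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return Cohen's d.
#' @export
cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2L || n2 < 2L) stop("need n >= 2 per group")
  if (s1 == 0 && s2 == 0) stop("Cohen's d undefined: both SDs are zero")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m1 - m2) / sp
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction (df = 1), as used for the categorical
#' clinical comparisons.
#'
#' @param counts 2x2 matrix of nonnegative integer counts (groups x
#'   categories).
#' @param name comparison name.
#' @return a one-row data frame: `comparison`, `test`, `statistic`, `p`.
#' @export
chi_square_2x2 <- function(counts, name = "table") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stop("counts must be 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  ct <- stats::chisq.test(counts, correct = FALSE)
  data.frame(comparison = name, test = "chi-square",
             statistic = unname(ct$statistic), p = ct$p.value,
             stringsAsFactors = FALSE)
}

#' Mixed (between x within) ANOVA on a temporal microstate parameter
#'
#' 2 (group, between-subject) x K (microstate class, within-subject)
#' ANOVA via `aov` with an `Error(subject)` stratum, for one of the
#' temporal parameters. When the group main effect or the interaction is
#' significant at `alpha`, per-class post-hoc comparisons are run through
#' [route_and_compare()] and BH-corrected as one family.
#'
#' @param metrics metrics data frame ([compute_metrics()] rows, one per
#'   subject).
#' @param subjects subject metadata with `subject` and `group` columns.
#' @param parameter one of `"duration"`, `"occurrence"`, `"coverage"`.
#' @param alpha significance level gating the post-hoc tests.
#' @return list with `anova` (data frame: effect, F, df1, df2, p) and
#'   `posthoc` (per-class `stats_result` rows with `p_fdr`, or `NULL`).
#' @export
mixed_anova <- function(metrics, subjects, parameter = c("duration",
                        "occurrence", "coverage"), alpha = 0.05) {
  parameter <- match.arg(parameter)
  prefix <- c(duration = "dur_", occurrence = "occ_", coverage = "cov_")[parameter]
  cols <- grep(paste0("^", prefix), names(metrics), value = TRUE)
  if (length(cols) < 2L) stop("metrics lack per-class columns for ", parameter)
  if (anyNA(metrics[cols])) stop("missing class rows in metrics")
  idx <- match(metrics$subject, subjects$subject)
  if (anyNA(idx)) stop("subjects table does not cover all metric rows")
  long <- data.frame(
    subject = factor(rep(metrics$subject, length(cols))),
    group = factor(rep(subjects$group[idx], length(cols))),
    class = factor(rep(sub(prefix, "", cols), each = nrow(metrics))),
    value = unlist(metrics[cols], use.names = FALSE))
  if (stats::var(long$value) == 0) {
    warning("zero error variance in ", parameter, ": F undefined")
    an <- data.frame(effect = c("group", "class", "group:class"),
                     F = NaN, df1 = c(1L, length(cols) - 1L,
                                      length(cols) - 1L),
                     df2 = NA_integer_, p = NaN, stringsAsFactors = FALSE)
    return(list(anova = an, posthoc = NULL))
  }
  fit <- stats::aov(value ~ group * class + Error(subject), data = long)
  sm <- summary(fit)
  btw <- sm[["Error: subject"]][[1L]]
  wth <- sm[["Error: Within"]][[1L]]
  pull <- function(tab, term) {
    i <- grep(paste0("^", term, "\\s*$"), trimws(rownames(tab)))
    data.frame(effect = term, F = tab[i, "F value"], df1 = tab[i, "Df"],
               df2 = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"],
               stringsAsFactors = FALSE)
  }
  an <- rbind(pull(btw, "group"), pull(wth, "class"), pull(wth, "group:class"))
  posthoc <- NULL
  if (any(an$p[an$effect %in% c("group", "group:class")] < alpha,
          na.rm = TRUE)) {
    hp <- subjects$subject[subjects$group == "HP"]
    posthoc <- do.call(rbind, lapply(cols, function(cl) {
      route_and_compare(metrics[[cl]][metrics$subject %in% hp],
                        metrics[[cl]][!metrics$subject %in% hp],
                        name = cl)
    }))
    posthoc$p_fdr <- fdr_bh(posthoc$p)
  }
  list(anova = an, posthoc = posthoc)
}

#' Covariate-adjusted group effect (GLM sensitivity analysis)
#'
#' Gaussian identity-link linear model `metric ~ group + covariates`,
#' reporting the adjusted group coefficient (HP vs LP), its SE and p.
#' Used to check that group differences survive adjustment for age,
#' surgery type, BDI-II and ALND.
#'
#' @param metric numeric response, one value per subject.
#' @param subjects metadata with `group` and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param name comparison name.
#' @return a one-row data frame: `comparison`, `estimate`, `se`,
#'   `statistic`, `p`.
#' @export
glm_adjust <- function(metric, subjects,
                       covariates = c("age", "surgery", "bdi", "alnd"),
                       name = "metric") {
  df <- data.frame(y = metric,
                   group = factor(subjects$group, levels = c("LP", "HP")))
  for (cv in covariates) {
    v <- subjects[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv)
    if (!is.numeric(v)) v <- factor(v)
    if (length(unique(v)) > 1L) df[[cv]] <- v   # constant covariates drop out
  }
  fit <- stats::lm(y ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("singular design: aliased terms ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  co <- summary(fit)$coefficients["groupHP", ]
  data.frame(comparison = name, estimate = co[1L], se = co[2L],
             statistic = co[3L], p = co[4L], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p values for one family of tests (monotone, capped at
#' 1, never smaller than the raw p). Families follow the reporting
#' structure: the 4 classes of one temporal parameter form a family, the
#' 12 transition comparisons another.
#'
#' @param p vector of raw p values in `[0, 1]`.
#' @return vector of BH-adjusted p values, same order as the input.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson and Spearman correlation of a metric with NRS
#'
#' @param metric numeric metric values (n >= 4).
#' @param nrs numeric pain scores.
#' @return a list with `pearson` (r, p) and `spearman` (rho, p); Spearman
#'   is computed on ranks with tie handling.
#' @export
correlate_with_nrs <- function(metric, nrs) {
  if (length(metric) != length(nrs)) stop("length mismatch")
  if (length(metric) < 4L) stop("need n >= 4")
  if (stats::sd(metric) == 0 || stats::sd(nrs) == 0)
    stop("correlation undefined for zero-variance input")
  pe <- stats::cor.test(metric, nrs, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(metric, nrs, method = "spearman",
                                         exact = FALSE))
  list(pearson = c(r = unname(pe$estimate), p = pe$p.value),
       spearman = c(rho = unname(sp$estimate), p = sp$p.value))
}

#' Full group-statistics report for a fitted cohort
#'
#' Reproduces the statistical battery on a cohort: mixed ANOVA + post-hoc
#' per temporal parameter (BH family = 4 classes), the 12 transition
#' comparisons (BH family = 12), GLM covariate adjustment for the primary
#' MS-C metrics, and Pearson/Spearman correlations of C coverage with NRS.
#'
#' @param metrics metrics data frame (one row per subject).
#' @param subjects subject metadata (`subject`, `group`, `nrs`,
#'   covariates).
#' @param alpha significance level.
#' @return list with `anova` (per parameter), `transitions` (12-row data
#'   frame with `p_fdr`), `glm`, and `nrs_correlation`.
#' @export
microstate_stats <- function(metrics, subjects, alpha = 0.05) {
  anova <- lapply(c(duration = "duration", occurrence = "occurrence",
                    coverage = "coverage"),
                  function(p) mixed_anova(metrics, subjects, p, alpha))
  hp <- metrics$subject %in% subjects$subject[subjects$group == "HP"]
  tr_cols <- grep("^tr_", names(metrics), value = TRUE)
  transitions <- do.call(rbind, lapply(tr_cols, function(cl)
    route_and_compare(metrics[[cl]][hp], metrics[[cl]][!hp], name = cl)))
  transitions$p_fdr <- fdr_bh(transitions$p)
  idx <- match(metrics$subject, subjects$subject)
  glm <- tryCatch(
    rbind(glm_adjust(metrics$occ_C, subjects[idx, ], name = "occ_C"),
          glm_adjust(metrics$cov_C, subjects[idx, ], name = "cov_C")),
    error = function(e) {
      message("GLM adjustment skipped: ", conditionMessage(e))
      NULL
    })
  list(anova = anova, transitions = transitions, glm = glm,
       nrs_correlation = correlate_with_nrs(metrics$cov_C,
                                            subjects$nrs[idx]))
}
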