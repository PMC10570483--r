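# Independent brute-force oracles used to cross-check the wired paths.

# Benjamini-Hochberg step-up, written directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

oracle_chisq <- function(tab) {
  expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expct)^2 / expct)
}

oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

oracle_gfp <- function(m) {
  vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    sqrt(sum((v - mean(v))^2) / length(v))
  }, 0)
}

# Exhaustive best-GEV bipartition of maps (columns) into k = 2 clusters.
# Per cluster the GEV-optimal polarity-invariant center is the leading
# eigenvector of the GFP^2-weighted outer-product sum.
oracle_best_partition <- function(maps, gfp) {
  V <- maps
  V <- sweep(V, 2L, colMeans(V))
  nrm <- sqrt(colSums(V^2))
  V <- sweep(V, 2L, nrm, "/")
  n <- ncol(V)
  w2 <- gfp^2
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {          # non-empty, label-symmetric
    grp <- c(0L, as.integer(intToBits(code)[1:(n - 1)])) + 1L
    num <- 0
    for (g in 1:2) {
      idx <- which(grp == g)
      S <- matrix(0, nrow(V), nrow(V))
      for (i in idx) S <- S + w2[i] * tcrossprod(V[, i])
      ctr <- eigen(S, symmetric = TRUE)$vectors[, 1L]
      num <- num + sum(w2[idx] * (crossprod(ctr, V[, idx, drop = FALSE]))^2)
    }
    g <- num / sum(w2)
    if (is.null(best) || g > best$gev) best <- list(gev = g, grp = grp)
  }
  best
}

# Two-way mixed-design sums of squares decomposed by hand (balanced data).
oracle_mixed_ss <- function(value, subject, group, class) {
  gm <- mean(value)
  n_s <- length(unique(subject))
  n_c <- length(unique(class))
  subj_mean <- tapply(value, subject, mean)
  grp_of_subj <- tapply(as.character(group), subject, `[`, 1L)
  grp_mean <- tapply(value, group, mean)
  cls_mean <- tapply(value, class, mean)
  cell_mean <- tapply(value, list(group, class), mean)
  n_per_grp <- table(grp_of_subj)
  ss_group <- n_c * sum(n_per_grp * (grp_mean[names(n_per_grp)] - gm)^2)
  ss_subj_within <- n_c * sum((subj_mean - grp_mean[grp_of_subj])^2)
  ss_class <- n_s * sum((cls_mean - gm)^2)
  ss_int <- sum(outer(n_per_grp, rep(1, n_c)) *
                  (cell_mean[names(n_per_grp), ] -
                     outer(grp_mean[names(n_per_grp)], cls_mean, "+") + gm)^2)
  fitted <- cell_mean[cbind(as.character(group), as.character(class))] +
    subj_mean[as.character(subject)] - grp_mean[as.character(grp_of_subj[as.character(subject)])]
  ss_err <- sum((value - fitted)^2)
  list(group = ss_group, subj = ss_subj_within, class = ss_class,
       interaction = ss_int, error = ss_err)
}
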