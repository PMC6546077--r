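#' Permutation test for the genome-wide significance threshold
#'
#' Each permutation reshuffles the assignment of phenotype rows (trait
#' vectors together with their covariates) to genotype rows — equivalent
#' under the null to permuting genotypes, but it lets the conditional
#' genotype probabilities be computed once and cached. The genome-wide
#' maximum LR2 of each permuted scan forms the empirical null
#' distribution; the significance threshold is its \eqn{1-\alpha}
#' quantile (type-7 interpolation). The null-model likelihood is invariant
#' to row reshuffles, so the null fit is reused across permutations.
#'
#' @param ds An \code{fm_dataset}.
#' @param curve,cov Models or registered names.
#' @param n_perm Number of permutations (>= 100 recommended for a stable
#'   threshold; fewer triggers a warning).
#' @param seed Integer seed; per-permutation substreams are derived from
#'   it so results do not depend on worker scheduling.
#' @param filter If \code{TRUE}, permuted scans are restricted to the
#'   positions retained by \code{\link{prefilter_positions}} (cheap
#'   dosage-trait correlation screen; the observed per-chromosome peaks
#'   are always retained).
#' @param keep_fraction Fraction of positions kept per chromosome when
#'   \code{filter} is on.
#' @param sr Observed \code{qtl_scan} (required when \code{filter = TRUE};
#'   computed internally if missing).
#' @param step Scan grid spacing in cM.
#' @param n_workers Parallel workers (forked).
#' @param alpha Significance level for the reported threshold.
#' @param identity_first If \code{TRUE}, permutation #1 is the identity
#'   (diagnostic: its maximum equals the observed scan maximum).
#' @param control An \code{\link{fm_control}}.
#' @return A \code{perm_result}: \code{n_perm}, \code{max_lr2} (vector),
#'   \code{threshold}, \code{alpha}, \code{seed}, \code{filtered},
#'   \code{positions_used}.
#' @export
permute_scan <- function(ds, curve, cov, n_perm, seed, filter = FALSE,
                         keep_fraction = 0.2, sr = NULL, step = 1,
                         n_workers = 1L, alpha = 0.05,
                         identity_first = FALSE, control = fm_control()) {
  stopifnot(n_perm >= 1L)
  if (n_perm < 100L)
    warning("n_perm = ", n_perm, " < 100: threshold quantile is unstable")
  curve <- get_curve(curve); cov <- get_covariance(cov)

  grid <- scan_grid(ds$map, step)
  if (filter) {
    if (is.null(sr)) sr <- qtl_scan(ds, curve, cov, step, n_workers, control)
    keep <- prefilter_positions(ds, sr, keep_fraction)
    grid <- grid[keep, , drop = FALSE]
  }
  probs_list <- lapply(seq_len(nrow(grid)), function(k)
    conditional_probs(grid[k, ], ds$geno, ds$map, ds$cross))
  h0 <- if (!is.null(sr)) sr$h0 else fit_null(ds, curve, cov, control)

  n <- nrow(ds$pheno$values)
  perm_seeds <- with_local_seed(seed, sample.int(2147483646L, n_perm))
  one_perm <- function(k) {
    idx <- if (identity_first && k == 1L) seq_len(n)
           else with_local_seed(perm_seeds[k], sample.int(n))
    dsp <- ds
    dsp$pheno$values <- ds$pheno$values[idx, , drop = FALSE]
    if (!is.null(ds$pheno$covariates))
      dsp$pheno$covariates <- ds$pheno$covariates[idx, , drop = FALSE]
    res <- scan_core(dsp, h0, grid, probs_list, curve, cov, control)
    max(res$lr2, na.rm = TRUE)
  }
  mx <- if (n_workers > 1L) {
    unlist(parallel::mclapply(seq_len(n_perm), one_perm, mc.cores = n_workers))
  } else vapply(seq_len(n_perm), one_perm, 0)

  structure(list(n_perm = n_perm, max_lr2 = mx,
                 threshold = perm_threshold_value(mx, alpha),
                 alpha = alpha, seed = seed, filtered = filter,
                 positions_used = nrow(grid)),
            class = "perm_result")
}

perm_threshold_value <- function(max_lr2, alpha) {
  stats::quantile(max_lr2, probs = 1 - alpha, type = 7, names = FALSE)
}

#' Empirical significance threshold from a permutation result
#'
#' @param pr A \code{perm_result}.
#' @param alpha Significance level in (0, 1).
#' @return The \eqn{1-\alpha} type-7 empirical quantile of the
#'   genome-wide maximum LR2 over permutations.
#' @export
perm_threshold <- function(pr, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  perm_threshold_value(pr$max_lr2, alpha)
}

#' Correlation-based pre-filter of scan positions
#'
#' Ranks positions by the squared correlation between the expected
#' genotype dosage \eqn{\sum_j j \, p_{ij}} and the phenotype, maximised
#' over time points, and keeps the top fraction per chromosome. Each
#' chromosome's observed-scan peak is always retained, so the filtered
#' permutation scan can never miss the observed signal by construction.
#' This is a deliberately cheap stand-in for curve-clustering candidate
#' selection; its safety is covered by tests.
#'
#' @param ds An \code{fm_dataset}.
#' @param sr The observed \code{qtl_scan}.
#' @param keep_fraction Fraction in (0, 1] of positions kept per
#'   chromosome.
#' @return Integer indices into \code{sr$positions} (sorted).
#' @export
prefilter_positions <- function(ds, sr, keep_fraction) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  grid <- sr$positions
  if (keep_fraction == 1) return(seq_len(nrow(grid)))
  Y <- ds$pheno$values
  J <- ds$cross$n_classes
  score <- vapply(seq_len(nrow(grid)), function(k) {
    pr <- conditional_probs(grid[k, ], ds$geno, ds$map, ds$cross)
    dosage <- drop(pr %*% (seq_len(J) - 1))
    if (stats::sd(dosage) < 1e-12) return(0)
    max(vapply(seq_len(ncol(Y)), function(t) {
      y <- Y[, t]
      ok <- !is.na(y)
      if (sum(ok) < 3L || stats::sd(y[ok]) < 1e-12) return(0)
      stats::cor(dosage[ok], y[ok])^2
    }, 0))
  }, 0)
  keep <- integer(0)
  peaks <- sr$peaks
  for (ch in unique(grid$chr)) {
    idx <- which(grid$chr == ch)
    n_keep <- max(ceiling(keep_fraction * length(idx)), 1L)
    top <- idx[order(score[idx], decreasing = TRUE)[seq_len(n_keep)]]
    pk <- peaks[peaks$chr == ch, , drop = FALSE]
    if (nrow(pk))
      top <- union(top, idx[grid$pos[idx] == pk$pos[1L]])
    keep <- c(keep, top)
  }
  sort(unique(keep))
}

#' @export
print.perm_result <- function(x, ...) {
  cat("<perm_result>", x$n_perm, "permutations",
      if (x$filtered) "(filtered)" else "", "\n")
  cat("  threshold(alpha=", x$alpha, "): ", signif(x$threshold, 6), "\n", sep = "")
  invisible(x)
}
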