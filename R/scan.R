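# Core profile computation shared by qtl_scan and the permutation engine.
# `probs_list` is aligned to rows of `grid`; the null fit is supplied so
# permutations (which leave the null likelihood invariant) can reuse it.
scan_core <- function(ds, h0, grid, probs_list, curve, cov, control) {
  curve <- get_curve(curve); cov <- get_covariance(cov)
  npos <- nrow(grid)
  lr2 <- rep(NA_real_, npos)
  h1_params <- vector("list", npos)
  diagnostics <- character(0)
  prev <- NULL
  for (k in seq_len(npos)) {
    init <- prev %||% h0
    fit <- tryCatch(
      fit_alternative(ds, probs_list[[k]], curve, cov, init, control),
      error = function(e) NULL)
    if (!is.null(prev) && (is.null(fit) || fit$loglik < h0$loglik)) {
      # warm start failed or stalled below the null: fall back to the
      # null-replication initialisation (which bounds loglik at h0's)
      fit2 <- tryCatch(
        fit_alternative(ds, probs_list[[k]], curve, cov, h0, control),
        error = function(e) NULL)
      if (!is.null(fit2) &&
          (is.null(fit) || fit2$loglik > fit$loglik)) fit <- fit2
    }
    if (is.null(fit)) {
      diagnostics <- c(diagnostics, paste0(grid$chr[k], "@", grid$pos[k],
                                           ": fit failed"))
      prev <- NULL
      next
    }
    lr2[k] <- tryCatch(lr_statistic(h0, fit), error = function(e) {
      diagnostics <<- c(diagnostics, paste0(grid$chr[k], "@", grid$pos[k],
                                            ": ", conditionMessage(e)))
      NA_real_
    })
    h1_params[[k]] <- list(curve_params = fit$curve_params,
                           theta = fit$theta, alpha = fit$alpha)
    prev <- fit
  }
  list(lr2 = lr2, h1_params = h1_params, diagnostics = diagnostics)
}

#' Genome-wide likelihood-ratio scan
#'
#' Fits the null model once (it has no genotype term, hence no position
#' dependence), then at every grid position computes conditional genotype
#' probabilities from the flanking markers and fits the mixture model by
#' EM, warm-starting each position from the previous one on the same
#' chromosome. Chromosomes are independent units of work, so results are
#' identical for any \code{n_workers}.
#'
#' @param ds An \code{fm_dataset}.
#' @param curve Curve model or registered name.
#' @param cov Covariance model or registered name.
#' @param step Scan grid spacing in cM (default 1).
#' @param n_workers Number of parallel workers (forked; chromosomes are
#'   distributed, order of execution does not affect results).
#' @param control An \code{\link{fm_control}}.
#' @return A \code{qtl_scan} object: \code{positions} (grid data frame),
#'   \code{lr2}, \code{h1_params}, \code{h0}, \code{peaks},
#'   \code{threshold} (NULL until permutation).
#' @export
qtl_scan <- function(ds, curve, cov, step = 1, n_workers = 1L,
                     control = fm_control()) {
  curve <- get_curve(curve); cov <- get_covariance(cov)
  grid <- scan_grid(ds$map, step)
  h0 <- fit_null(ds, curve, cov, control)
  chrs <- unique(grid$chr)
  run_chr <- function(ch) {
    sub <- grid[grid$chr == ch, , drop = FALSE]
    probs <- lapply(seq_len(nrow(sub)), function(k)
      conditional_probs(sub[k, ], ds$geno, ds$map, ds$cross))
    scan_core(ds, h0, sub, probs, curve, cov, control)
  }
  res <- if (n_workers > 1L) {
    parallel::mclapply(chrs, run_chr, mc.cores = n_workers)
  } else lapply(chrs, run_chr)
  lr2 <- unlist(lapply(res, `[[`, "lr2"))
  h1_params <- do.call(c, lapply(res, `[[`, "h1_params"))
  diagnostics <- unlist(lapply(res, `[[`, "diagnostics"))
  n_failed <- sum(is.na(lr2))
  if (n_failed > 0.2 * length(lr2))
    stop("scan failed at ", n_failed, "/", length(lr2), " positions: ",
         paste(utils::head(diagnostics, 3L), collapse = "; "))
  sr <- structure(list(positions = grid, lr2 = lr2, h1_params = h1_params,
                       h0 = h0, threshold = NULL, curve = curve$name,
                       cov = cov$name, step = step,
                       diagnostics = diagnostics),
                  class = "qtl_scan")
  sr$peaks <- find_peaks(sr)
  sr
}

#' Per-chromosome scan peaks
#'
#' One row per chromosome at the position of its maximum LR2; ties are
#' broken by the smallest position.
#'
#' @param sr A \code{qtl_scan}.
#' @return Data frame with columns \code{chr}, \code{pos}, \code{lr2}.
#' @export
find_peaks <- function(sr) {
  grid <- sr$positions
  if (is.null(grid) || nrow(grid) == 0L) stop("empty scan result")
  out <- lapply(unique(grid$chr), function(ch) {
    idx <- which(grid$chr == ch)
    v <- sr$lr2[idx]
    if (all(is.na(v))) return(NULL)
    best <- idx[which(v == max(v, na.rm = TRUE))]
    best <- best[which.min(grid$pos[best])]   # tie-break: smallest position
    data.frame(chr = ch, pos = grid$pos[best], lr2 = sr$lr2[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1L))])
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("<qtl_scan>", nrow(x$positions), "positions,",
      length(unique(x$positions$chr)), "chromosome(s); curve:", x$curve,
      " cov:", x$cov, "\n")
  cat("  max LR2:", signif(max(x$lr2, na.rm = TRUE), 6))
  if (!is.null(x$threshold))
    cat("  (threshold:", signif(x$threshold, 6), ")")
  cat("\n")
  invisible(x)
}
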