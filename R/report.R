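# Pure rendering: serialises scan/permutation results to CSV and draws
# PNG figures. Never mutates the analysis objects.

scan_to_df <- function(sr) {
  grid <- sr$positions
  J <- max(vapply(sr$h1_params, function(h)
    if (is.null(h)) 0L else length(h$curve_params), 0L))
  base <- data.frame(chr = grid$chr, pos_cM = grid$pos, lr2 = sr$lr2,
                     stringsAsFactors = FALSE)
  if (J == 0L) return(base)
  np <- length(sr$h1_params[[which(!vapply(sr$h1_params, is.null,
                                           logical(1L)))[1L]]]$curve_params[[1L]])
  for (j in seq_len(J)) for (p in seq_len(np)) {
    base[[paste0("curve", j, "_p", p)]] <- vapply(sr$h1_params, function(h)
      if (is.null(h)) NA_real_ else h$curve_params[[j]][p], 0)
  }
  ntheta <- length(sr$h0$theta)
  for (p in seq_len(ntheta)) {
    base[[paste0("cov_p", p)]] <- vapply(sr$h1_params, function(h)
      if (is.null(h)) NA_real_ else h$theta[p], 0)
  }
  base
}

plot_lr_profile <- function(sr, file) {
  grid <- sr$positions
  chrs <- unique(grid$chr)
  nc <- length(chrs)
  grDevices::png(file, width = 1200, height = 300 * ceiling(nc / 2),
                 res = 110)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(ceiling(nc / 2), min(nc, 2L)),
                mar = c(4, 4, 2, 1))
  ylim <- c(0, max(c(sr$lr2, sr$threshold), na.rm = TRUE) * 1.05)
  for (ch in chrs) {
    idx <- grid$chr == ch
    graphics::plot(grid$pos[idx], sr$lr2[idx], type = "l",
                   xlab = "position (cM)", ylab = "LR2", main = ch,
                   ylim = ylim)
    mk <- unique(grid[idx & grid$pos == grid$left_pos,
                      c("left_marker", "left_pos")])
    graphics::axis(1, at = mk$left_pos, labels = FALSE, tcl = -0.8)
    graphics::mtext(mk$left_marker, side = 1, at = mk$left_pos, cex = 0.45,
                    line = 2.4, las = 2)
    if (!is.null(sr$threshold))
      graphics::abline(h = sr$threshold, lty = 2, col = "red")
  }
  invisible(file)
}

plot_trajectories <- function(ds, sr, file) {
  grDevices::png(file, width = 900, height = 600, res = 110)
  on.exit(grDevices::dev.off())
  Y <- ds$pheno$values
  times <- ds$pheno$times
  graphics::matplot(times, t(Y), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", alpha.f = 0.3),
                    xlab = "time", ylab = "trait",
                    main = "longitudinal trait trajectories")
  cf <- sr$h0$curve_params[[1L]]
  graphics::lines(times, get_curve(sr$curve)$fun(cf, times), col = "blue",
                  lwd = 2)
  invisible(file)
}

plot_qtl_curves <- function(ds, sr, row_idx, file) {
  grDevices::png(file, width = 700, height = 500, res = 110)
  on.exit(grDevices::dev.off())
  times <- ds$pheno$times
  h1 <- sr$h1_params[[row_idx]]
  cols <- c("#D55E00", "#0072B2", "#009E73")
  curvef <- get_curve(sr$curve)$fun
  vals <- lapply(h1$curve_params, curvef, times)
  graphics::plot(NULL, xlim = range(times), ylim = range(unlist(vals)),
                 xlab = "time", ylab = "trait",
                 main = paste0("QTL at ", sr$positions$chr[row_idx], " ",
                               sr$positions$pos[row_idx], " cM (LR2=",
                               signif(sr$lr2[row_idx], 4), ")"))
  for (j in seq_along(vals))
    graphics::lines(times, vals[[j]], col = cols[(j - 1L) %% 3L + 1L], lwd = 2)
  graphics::legend("bottomright", legend = ds$cross$labels,
                   col = cols[seq_along(vals)], lwd = 2, bty = "n")
  invisible(file)
}

#' Render the analysis report (CSV tables + PNG figures)
#'
#' Writes the scan profile table, per-chromosome peaks, permutation maxima
#' (when available), the trait-trajectory figure, the LR2 profile figure
#' (threshold line drawn when a permutation result is supplied), and one
#' genotype-specific curve figure per peak above the threshold. A report
#' is produced even when no peak is significant.
#'
#' @param sr A \code{qtl_scan}.
#' @param pr Optional \code{perm_result}.
#' @param ds The \code{fm_dataset} that was scanned.
#' @param out_dir Output directory.
#' @return Named character vector of files written, invisibly.
#' @export
report <- function(sr, pr = NULL, ds, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(pr)) sr$threshold <- perm_threshold(pr, pr$alpha)
  files <- c(scan = file.path(out_dir, "scan.csv"),
             peaks = file.path(out_dir, "peaks.csv"),
             profile = file.path(out_dir, "lr2_profile.png"),
             trajectories = file.path(out_dir, "trait_trajectories.png"))
  utils::write.csv(scan_to_df(sr), files["scan"], row.names = FALSE)
  peaks <- find_peaks(sr)
  peaks$significant <- if (is.null(sr$threshold)) NA else peaks$lr2 >= sr$threshold
  utils::write.csv(peaks, files["peaks"], row.names = FALSE)
  if (!is.null(pr)) {
    files["perm"] <- file.path(out_dir, "perm.csv")
    utils::write.csv(data.frame(perm_index = seq_len(pr$n_perm),
                                max_lr2 = pr$max_lr2),
                     files["perm"], row.names = FALSE)
  }
  plot_lr_profile(sr, files["profile"])
  plot_trajectories(ds, sr, files["trajectories"])
  if (!is.null(sr$threshold)) {
    sig <- peaks[!is.na(peaks$significant) & peaks$significant, , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      ridx <- which(sr$positions$chr == sig$chr[i] &
                    sr$positions$pos == sig$pos[i])[1L]
      if (is.null(sr$h1_params[[ridx]])) next
      f <- file.path(out_dir, paste0("qtl_curves_", sig$chr[i], "_",
                                     sig$pos[i], ".png"))
      files[paste0("qtl_", i)] <- f
      plot_qtl_curves(ds, sr, ridx, f)
    }
  }
  invisible(files)
}
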