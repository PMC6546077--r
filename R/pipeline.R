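#' End-to-end functional-mapping pipeline
#'
#' Runs the full analysis: load and validate data, select curve and
#' covariance models if requested (\code{"auto"}), scan the genome, run
#' the permutation test, and render the report bundle (CSV tables, PNG
#' figures and a JSON run manifest recording configuration, seeds and
#' selections so a rerun reproduces all outputs byte-identically).
#'
#' @param pheno_path,geno_path,marker_path Input CSV paths.
#' @param covar_path Optional covariate CSV path.
#' @param cross Cross type name.
#' @param curve Curve name or \code{"auto"} (AIC selection over the
#'   built-in registry).
#' @param covariance Covariance name or \code{"auto"} (AIC selection over
#'   \code{vc}, \code{cs}, \code{ar1}, \code{arma11}).
#' @param step Scan grid spacing (cM).
#' @param n_perm Number of permutations (0 skips the permutation stage).
#' @param alpha Significance level.
#' @param filter Use the correlation pre-filter in permutations.
#' @param keep_fraction Fraction of positions kept by the filter.
#' @param n_workers Parallel workers.
#' @param seed Root seed for all stochastic stages.
#' @param out_dir Report directory.
#' @param control An \code{\link{fm_control}}.
#' @return List with \code{ds}, \code{scan}, \code{perm} (or NULL),
#'   \code{manifest}, \code{files}.
#' @export
run_pipeline <- function(pheno_path, covar_path = NULL, geno_path,
                         marker_path, cross, curve = "auto",
                         covariance = "auto", step = 1, n_perm = 0L,
                         alpha = 0.05, filter = FALSE, keep_fraction = 0.2,
                         n_workers = 1L, seed = 1L, out_dir = ".",
                         control = fm_control()) {
  stopifnot(alpha > 0, alpha < 1)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  ds <- stage("load", load_dataset(pheno_path, covar_path, geno_path,
                                   marker_path, cross))
  diags <- validate_dataset(ds)
  if (length(diags))
    stop("[load] dataset invalid: ",
         paste(vapply(diags, `[[`, "", "code"), collapse = ", "))

  Y <- ds$pheno$values
  times <- ds$pheno$times
  curve_sel <- curve
  if (identical(curve, "auto")) {
    cf <- stage("estimate",
                select_curve(c("logistic", "double_logistic", "legendre",
                               "pharmacology"), times, Y))
    curve_sel <- cf$model$name
  }
  cov_sel <- covariance
  if (identical(covariance, "auto")) {
    cfit <- fit_curve_ls(curve_sel, times, Y)
    R <- sweep(Y, 2L, get_curve(curve_sel)$fun(cfit$params, times))
    cvf <- stage("estimate",
                 select_covariance(c("vc", "cs", "ar1", "arma11"), R, times))
    cov_sel <- cvf$model$name
  }

  sr <- stage("scan", qtl_scan(ds, curve_sel, cov_sel, step = step,
                               n_workers = n_workers, control = control))
  pr <- NULL
  if (n_perm > 0L)
    pr <- stage("permutation",
                permute_scan(ds, curve_sel, cov_sel, n_perm = n_perm,
                             seed = seed, filter = filter,
                             keep_fraction = keep_fraction, sr = sr,
                             step = step, n_workers = n_workers,
                             alpha = alpha, control = control))

  manifest <- list(
    package = "longqtl",
    version = as.character(utils::packageVersion("longqtl")),
    inputs = list(pheno = pheno_path, covar = covar_path, geno = geno_path,
                  marker = marker_path),
    cross = ds$cross$name,
    curve = list(requested = curve, used = curve_sel),
    covariance = list(requested = covariance, used = cov_sel),
    step_cM = step, n_perm = n_perm, alpha = alpha,
    filter = filter, keep_fraction = keep_fraction,
    seed = seed, n_workers = n_workers,
    n_individuals = length(ds$pheno$ids), n_markers = nrow(ds$map),
    n_positions = nrow(sr$positions),
    threshold = if (is.null(pr)) NULL else perm_threshold(pr, alpha))

  files <- stage("report", report(sr, pr, ds, out_dir))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files["manifest"] <- manifest_path

  list(ds = ds, scan = sr, perm = pr, manifest = manifest, files = files)
}
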