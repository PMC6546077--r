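#' Evenly spaced synthetic genetic map
#'
#' Convenience map builder for simulations: \code{n_chr} chromosomes each
#' carrying \code{n_markers} markers at \code{spacing} cM intervals
#' starting at 0.
#'
#' @param n_chr Number of chromosomes.
#' @param n_markers Markers per chromosome.
#' @param spacing Marker spacing in cM.
#' @return A \code{genetic_map}.
#' @export
sim_map <- function(n_chr = 5L, n_markers = 12L, spacing = 10) {
  genetic_map(data.frame(
    marker = paste0("m", rep(seq_len(n_chr), each = n_markers), "_",
                    rep(seq_len(n_markers), n_chr)),
    chr = paste0("chr", rep(seq_len(n_chr), each = n_markers)),
    pos_cM = rep((seq_len(n_markers) - 1) * spacing, n_chr),
    stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Describes the generative model: an inbred cross whose genotypes arise
#' by Haldane recombination along a map, and longitudinal phenotypes equal
#' to a genotype-specific parametric curve plus structured multivariate
#' normal noise (plus an optional time-constant covariate shift). The
#' defaults mirror a forest-tree backcross design: 11 yearly measurements
#' and a moderately dense map, at a size small enough for routine testing.
#'
#' @param cross Cross type name or object.
#' @param map A \code{genetic_map} (default \code{sim_map()}).
#' @param qtl List with \code{chr}, \code{pos} (cM) and \code{params}, a
#'   list of J curve-parameter vectors (one per genotype class). Use
#'   identical vectors for a null (no-QTL-effect) simulation.
#' @param curve Curve model name (default \code{"logistic"}).
#' @param cov Covariance model name (default \code{"ar1"}).
#' @param cov_theta Covariance parameters (default \code{c(1, 0.6)}:
#'   unit variance, lag-one correlation 0.6).
#' @param times Measurement times (default \code{1:11}).
#' @param n Number of individuals.
#' @param covariates Optional list \code{(p, alpha)}: \code{p} standard
#'   normal covariates with coefficient vector \code{alpha}.
#' @param seed Root RNG seed.
#' @return A \code{sim_config}.
#' @export
sim_config <- function(cross = "BC", map = sim_map(),
                       qtl = list(chr = "chr1", pos = 34,
                                  params = list(c(30, 5, 0.5), c(25, 5, 0.5))),
                       curve = "logistic", cov = "ar1",
                       cov_theta = c(1, 0.6), times = 1:11, n = 200L,
                       covariates = NULL, seed = 1L) {
  cross <- cross_type(cross)
  map <- as_genetic_map(map)
  if (n < 1L) stop("n must be >= 1")
  if (length(qtl$params) != cross$n_classes)
    stop("qtl$params must supply one curve-parameter vector per genotype (J = ",
         cross$n_classes, ")")
  if (!qtl$chr %in% map$chr) stop("QTL chromosome not in map")
  span <- range(map$pos_cM[map$chr == qtl$chr])
  if (qtl$pos < span[1L] || qtl$pos > span[2L])
    stop("QTL position outside its chromosome's map span")
  m <- length(times)
  # the generator is a stated world, not an estimator: validate theta by
  # positive-definiteness of the built matrix, not by estimation bounds
  # (e.g. a 1e-12 noiseless-limit variance is legal here)
  S <- get_covariance(cov)$build(cov_theta, m, times)
  tryCatch(chol(S), error = function(e)
    stop("cov_theta does not yield a positive-definite covariance"))
  structure(list(cross = cross, map = map, qtl = qtl, curve = curve,
                 cov = cov, cov_theta = cov_theta, times = times,
                 n = as.integer(n), covariates = covariates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# simulate a 2-state meiotic chain over loci with recombination fractions r
sim_chain <- function(n, rvec) {
  L <- length(rvec) + 1L
  g <- matrix(0L, n, L)
  g[, 1L] <- stats::rbinom(n, 1L, 0.5)
  for (k in seq_along(rvec)) {
    flip <- stats::rbinom(n, 1L, rvec[k])
    g[, k + 1L] <- ifelse(flip == 1L, 1L - g[, k], g[, k])
  }
  g
}

# one gamete per individual from parent haplotype pairs (H1, H2):
# start haplotype Bernoulli(1/2), switch between adjacent loci with the
# per-meiosis recombination fraction
sim_gamete <- function(H1, H2, rvec) {
  n <- nrow(H1); L <- ncol(H1)
  side <- matrix(0L, n, L)
  side[, 1L] <- stats::rbinom(n, 1L, 0.5)
  for (k in seq_along(rvec)) {
    flip <- stats::rbinom(n, 1L, rvec[k])
    side[, k + 1L] <- (side[, k] + flip) %% 2L
  }
  (1L - side) * H1 + side * H2
}

# selfed RIL: iterate single-seed descent from the F1 until fixation
# (residual heterozygosity after 30 generations ~ 2^-30, negligible);
# the multilocus fixation distribution is not Markov, so RIL genotypes
# are generated by the physical process rather than an expanded chain
sim_ril_chain <- function(n, rvec, generations = 30L) {
  L <- length(rvec) + 1L
  H1 <- matrix(1L, n, L)
  H2 <- matrix(0L, n, L)
  for (g in seq_len(generations)) {
    A <- sim_gamete(H1, H2, rvec)
    B <- sim_gamete(H1, H2, rvec)
    H1 <- A; H2 <- B
  }
  H1
}

#' Simulate genotypes along the map (with the hidden QTL genotype)
#'
#' Marker genotypes are generated chromosome by chromosome as a Markov
#' chain with Haldane recombination fractions between adjacent loci
#' (selfed-RIL intervals use the expansion \eqn{r^* = 2r/(1+2r)}; F2
#' genotypes compose two independent gametes). The QTL is inserted as a
#' pseudo-locus at its map position and returned separately — it is never
#' part of the observable marker data.
#'
#' @param cfg A \code{sim_config}.
#' @return List with \code{geno} (\code{ids}, \code{codes}) and
#'   \code{qtl_geno} (hidden integer classes \code{0..J-1}).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n
  ids <- sprintf("ind%03d", seq_len(n))
  chr_seeds <- with_local_seed(cfg$seed,
                               sample.int(2147483646L, length(unique(cfg$map$chr))))
  codes <- NULL
  qtl_geno <- NULL
  chrs <- unique(cfg$map$chr)
  for (ci in seq_along(chrs)) {
    ch <- chrs[ci]
    sub <- cfg$map[cfg$map$chr == ch, , drop = FALSE]
    pos <- sub$pos_cM
    qhere <- identical(ch, cfg$qtl$chr)
    qpos <- if (qhere) cfg$qtl$pos else NULL
    allpos <- if (qhere) sort(unique(c(pos, qpos))) else pos
    r <- haldane_r(diff(allpos))
    G <- with_local_seed(chr_seeds[ci], {
      switch(cfg$cross$name,
             F2 = sim_chain(n, r) + sim_chain(n, r),
             RIL = sim_ril_chain(n, r),
             sim_chain(n, r))
    })
    colnames(G) <- as.character(allpos)
    if (qhere) {
      qcol <- match(as.character(qpos), colnames(G))
      qtl_geno <- G[, qcol]
      keep <- match(as.character(pos), colnames(G))
      keep <- setdiff(keep, if (qpos %in% pos) integer(0) else qcol)
      G <- G[, match(as.character(pos), colnames(G)), drop = FALSE]
    }
    colnames(G) <- sub$marker
    codes <- if (is.null(codes)) G else cbind(codes, G)
  }
  rownames(codes) <- ids
  list(geno = list(ids = ids, codes = codes), qtl_geno = as.integer(qtl_geno))
}

#' Simulate longitudinal phenotypes given hidden QTL genotypes
#'
#' \eqn{y_i = \alpha X_i + g_{j(i)}(t) + \epsilon_i} with
#' \eqn{\epsilon_i \sim MVN(0, \Sigma(\theta))}.
#'
#' @param cfg A \code{sim_config}.
#' @param qtl_geno Hidden QTL genotype classes from
#'   \code{\link{simulate_genotypes}}.
#' @return List with \code{pheno} (\code{ids}, \code{times},
#'   \code{values}, \code{covariates}).
#' @export
simulate_phenotypes <- function(cfg, qtl_geno) {
  stopifnot(inherits(cfg, "sim_config"), length(qtl_geno) == cfg$n)
  curve <- get_curve(cfg$curve)
  m <- length(cfg$times)
  G <- do.call(rbind, lapply(cfg$qtl$params, function(p) curve$fun(p, cfg$times)))
  Sigma <- get_covariance(cfg$cov)$build(cfg$cov_theta, m, cfg$times)
  U <- chol(Sigma)
  pheno_seed <- with_local_seed(cfg$seed + 1L, sample.int(2147483646L, 1L))
  with_local_seed(pheno_seed, {
    E <- matrix(stats::rnorm(cfg$n * m), cfg$n, m) %*% U
    X <- NULL
    shift <- 0
    if (!is.null(cfg$covariates)) {
      X <- matrix(stats::rnorm(cfg$n * cfg$covariates$p), cfg$n)
      colnames(X) <- paste0("x", seq_len(cfg$covariates$p))
      shift <- drop(X %*% cfg$covariates$alpha)
    }
    Y <- G[qtl_geno + 1L, , drop = FALSE] + E + shift
    ids <- sprintf("ind%03d", seq_len(cfg$n))
    rownames(Y) <- ids
    colnames(Y) <- as.character(cfg$times)
    if (!is.null(X)) rownames(X) <- ids
    list(pheno = list(ids = ids, times = cfg$times, values = Y,
                      covariates = X))
  })
}

#' Simulate a complete dataset (with hidden truth)
#'
#' @param cfg A \code{sim_config}.
#' @return A \code{sim_data}: \code{ds} (an \code{fm_dataset}) plus
#'   \code{truth} (hidden QTL genotypes and all generating parameters).
#' @export
simulate_dataset <- function(cfg) {
  g <- simulate_genotypes(cfg)
  p <- simulate_phenotypes(cfg, g$qtl_geno)
  ds <- new_fm_dataset(cfg$cross, cfg$map, g$geno, p$pheno)
  structure(list(ds = ds,
                 truth = list(qtl_chr = cfg$qtl$chr, qtl_pos = cfg$qtl$pos,
                              qtl_geno = g$qtl_geno,
                              curve = cfg$curve, curve_params = cfg$qtl$params,
                              cov = cfg$cov, cov_theta = cfg$cov_theta,
                              alpha = cfg$covariates$alpha %||% numeric(0),
                              seed = cfg$seed)),
            class = "sim_data")
}

#' Write a simulated dataset as the package's CSV file set
#'
#' Emits \code{marker.csv}, \code{geno.csv}, \code{pheno.csv}, optionally
#' \code{covar.csv}, in the dialect read by \code{\link{load_dataset}},
#' plus \code{truth.json} (hidden QTL genotype and generating parameters)
#' when the input carries truth.
#'
#' @param sim A \code{sim_data} or \code{fm_dataset}.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(sim, out_dir) {
  ds <- if (inherits(sim, "sim_data")) sim$ds else sim
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(marker = file.path(out_dir, "marker.csv"),
             geno = file.path(out_dir, "geno.csv"),
             pheno = file.path(out_dir, "pheno.csv"))
  utils::write.csv(as.data.frame(ds$map), paths["marker"], row.names = FALSE)
  gdf <- data.frame(id = ds$geno$ids, ds$geno$codes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(gdf, paths["geno"], row.names = FALSE, na = "")
  pdf_ <- data.frame(id = ds$pheno$ids, ds$pheno$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  names(pdf_)[-1L] <- as.character(ds$pheno$times)
  utils::write.csv(pdf_, paths["pheno"], row.names = FALSE)
  if (!is.null(ds$pheno$covariates)) {
    paths["covar"] <- file.path(out_dir, "covar.csv")
    cdf <- data.frame(id = ds$pheno$ids, ds$pheno$covariates,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(cdf, paths["covar"], row.names = FALSE)
  }
  if (inherits(sim, "sim_data")) {
    paths["truth"] <- file.path(out_dir, "truth.json")
    jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}
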