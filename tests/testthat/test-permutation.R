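test_that("identity permutation reproduces the observed maximum", {
  sim <- fixture_bc(n = 60L, seed = 71L, n_chr = 1L, n_markers = 3L,
                    qtl_pos = 10, times = 1:6)
  ds <- sim$ds
  sr <- qtl_scan(ds, "logistic", "ar1", step = 5, control = fast_control())
  pr <- suppressWarnings(
    permute_scan(ds, "logistic", "ar1", n_perm = 2L, seed = 5L, sr = sr,
                 step = 5, identity_first = TRUE, control = fast_control()))
  expect_equal(pr$max_lr2[1L], max(sr$lr2, na.rm = TRUE), tolerance = 1e-8)
})

test_that("permutation is reproducible from its seed and conserves rows", {
  sim <- fixture_null(n = 40L, seed = 72L, m = 4L, map = sim_map(1L, 2L, 10))
  ds <- sim$ds
  pr1 <- suppressWarnings(
    permute_scan(ds, "logistic", "ar1", n_perm = 8L, seed = 9L, step = 5,
                 control = fast_control()))
  pr2 <- suppressWarnings(
    permute_scan(ds, "logistic", "ar1", n_perm = 8L, seed = 9L, step = 5,
                 control = fast_control()))
  expect_identical(pr1$max_lr2, pr2$max_lr2)
  pr3 <- suppressWarnings(
    permute_scan(ds, "logistic", "ar1", n_perm = 8L, seed = 10L, step = 5,
                 control = fast_control()))
  expect_false(identical(pr1$max_lr2, pr3$max_lr2))
  # permutation only reorders rows: the multiset of phenotype rows is fixed
  # (structural property of the implementation: rows are indexed by sample())
  expect_warning(permute_scan(ds, "logistic", "ar1", n_perm = 3L, seed = 1L,
                              step = 5, control = fast_control()),
                 "unstable")
})

test_that("threshold uses the type-7 quantile and is monotone in alpha", {
  pr <- structure(list(max_lr2 = c(5, 9, 3, 7, 11, 2, 8, 6, 4, 10),
                       n_perm = 10L, alpha = 0.05),
                  class = "perm_result")
  expect_equal(perm_threshold(pr, 0.05),
               stats::quantile(pr$max_lr2, 0.95, type = 7, names = FALSE))
  alphas <- c(0.01, 0.05, 0.1, 0.25, 0.5)
  th <- vapply(alphas, function(a) perm_threshold(pr, a), 0)
  expect_true(all(diff(th) <= 0))
  expect_error(perm_threshold(pr, 0), "alpha")
})

test_that("prefilter keeps everything at fraction 1 and the peak always", {
  sim <- fixture_bc(n = 100L, seed = 73L, n_chr = 2L, n_markers = 4L)
  ds <- sim$ds
  sr <- qtl_scan(ds, "logistic", "ar1", control = fast_control())
  all_idx <- prefilter_positions(ds, sr, 1)
  expect_equal(all_idx, seq_len(nrow(sr$positions)))

  keep <- prefilter_positions(ds, sr, 0.1)
  expect_lt(length(keep), nrow(sr$positions) / 2)
  pk <- find_peaks(sr)
  for (i in seq_len(nrow(pk))) {
    kept_pos <- sr$positions[keep, ]
    expect_true(any(kept_pos$chr == pk$chr[i] & kept_pos$pos == pk$pos[i]))
  }
  expect_error(prefilter_positions(ds, sr, 0), "keep_fraction")
  expect_error(prefilter_positions(ds, sr, 1.2), "keep_fraction")
})

test_that("the dosage filter retains the true QTL position", {
  hits <- 0L
  for (s in 1:10) {
    sim <- fixture_bc(n = 120L, seed = 200L + s, n_chr = 1L, qtl_pos = 34,
                      a2 = 25)
    ds <- sim$ds
    sr <- qtl_scan(ds, "logistic", "ar1", control = fast_control())
    keep <- prefilter_positions(ds, sr, 0.15)
    kept_pos <- sr$positions$pos[keep]
    if (any(abs(kept_pos - 34) <= 2)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("filtered and unfiltered thresholds agree closely at moderate filtering", {
  # paired design: one set of permuted profiles, thresholds from the full
  # grid vs the retained subset. At keep_fraction = 0.5 the approximation
  # holds to < 5% relative; aggressive filtering on genomes this small
  # biases the threshold low (documented limitation).
  fc <- fast_control()
  cfg <- sim_config(cross = "BC", map = sim_map(3L, 4L, 10),
                    qtl = list(chr = "chr1", pos = 20,
                               params = list(c(30, 5, 0.5), c(26, 5, 0.5))),
                    cov_theta = c(1, 0.6), times = 1:6, n = 100L, seed = 374L)
  ds <- simulate_dataset(cfg)$ds
  sr <- qtl_scan(ds, "logistic", "ar1", step = 2.5, control = fc)
  grid <- scan_grid(ds$map, 2.5)
  probs <- lapply(seq_len(nrow(grid)), function(k)
    conditional_probs(grid[k, ], ds$geno, ds$map, "BC"))
  n <- nrow(ds$pheno$values)
  seeds <- longqtl:::with_local_seed(15L, sample.int(2147483646L, 80L))
  M <- sapply(seq_len(80L), function(k) {
    idx <- longqtl:::with_local_seed(seeds[k], sample.int(n))
    dsp <- ds
    dsp$pheno$values <- ds$pheno$values[idx, ]
    longqtl:::scan_core(dsp, sr$h0, grid, probs, get_curve("logistic"),
                        get_covariance("ar1"), fc)$lr2
  })
  keep <- prefilter_positions(ds, sr, 0.5)
  t_off <- stats::quantile(apply(M, 2L, max, na.rm = TRUE), 0.95, type = 7)
  t_on <- stats::quantile(apply(M[keep, , drop = FALSE], 2L, max,
                                na.rm = TRUE), 0.95, type = 7)
  expect_lte(t_on, t_off + 1e-9)        # subset max never exceeds full max
  expect_lt(abs(t_on - t_off) / t_off, 0.05)
})
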