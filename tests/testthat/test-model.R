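test_that("genotype_density matches Eq.-style oracle and degenerate cases", {
  times <- 1:4
  g <- logistic_value(30, 5, 0.5, times)
  # y equal to the mean with identity covariance: zero quadratic form
  expect_equal(genotype_density(g, NULL, numeric(0), g, diag(4)),
               -2 * log(2 * pi), tolerance = 1e-12)
  # alpha = 0 reduces to the plain MVN density
  S <- build_covariance("ar1", c(1.3, 0.4), 4)
  y <- g + c(0.5, -0.2, 0.1, 0.3)
  expect_equal(genotype_density(y, c(1, 2), c(0, 0), g, S),
               mvn_logpdf(y, g, S), tolerance = 1e-12)
  # random instances against the independent dense oracle
  set.seed(21)
  for (k in 1:10) {
    X_i <- rnorm(2); alpha <- rnorm(2)
    y <- rnorm(4, g)
    expect_equal(genotype_density(y, X_i, alpha, g, S),
                 oracle_mvn_logpdf(y, g + sum(alpha * X_i), S),
                 tolerance = 1e-10)
  }
  expect_error(genotype_density(y[1:3], NULL, numeric(0), g, S), "mismatch")
})

make_toy <- function(n, m, J, seed, cross = if (J == 2) "BC" else "F2") {
  set.seed(seed)
  times <- seq_len(m)
  params <- lapply(seq_len(J), function(j) c(20 + 3 * j, 4, 0.5))
  theta <- c(1, 0.5)
  probs <- matrix(stats::rexp(n * J), n)
  probs <- probs / rowSums(probs)
  Y <- matrix(rnorm(n * m, 20), n)
  ds <- longqtl:::new_fm_dataset(cross, sim_map(1L, 2L, 10),
    geno = list(ids = as.character(seq_len(n)),
                codes = matrix(0L, n, 2L,
                               dimnames = list(NULL, c("m1_1", "m1_2")))),
    pheno = list(ids = as.character(seq_len(n)), times = times, values = Y,
                 covariates = NULL))
  list(ds = ds, probs = probs,
       params = list(curve_params = params, theta = theta, alpha = numeric(0)))
}

test_that("mixture_loglik matches the naive brute-force oracle", {
  for (seed in 1:5) {
    toy <- make_toy(n = 4L, m = 3L, J = 2L, seed = seed)
    expect_equal(
      mixture_loglik(toy$params, toy$probs, toy$ds, "logistic", "ar1"),
      oracle_mixture_loglik(toy$params$curve_params, toy$params$theta,
                            numeric(0), toy$probs, toy$ds$pheno$values,
                            NULL, toy$ds$pheno$times, "logistic", "ar1"),
      tolerance = 1e-12)
  }
  toy3 <- make_toy(n = 5L, m = 4L, J = 3L, seed = 6L)
  expect_equal(
    mixture_loglik(toy3$params, toy3$probs, toy3$ds, "logistic", "ar1"),
    oracle_mixture_loglik(toy3$params$curve_params, toy3$params$theta,
                          numeric(0), toy3$probs, toy3$ds$pheno$values,
                          NULL, toy3$ds$pheno$times, "logistic", "ar1"),
    tolerance = 1e-12)
})

test_that("degenerate mixtures reduce to single-class likelihoods", {
  toy <- make_toy(n = 6L, m = 4L, J = 2L, seed = 3L)
  p1 <- cbind(rep(1, 6), rep(0, 6))
  ll <- mixture_loglik(toy$params, p1, toy$ds, "logistic", "ar1")
  S <- build_covariance("ar1", toy$params$theta, 4)
  g1 <- logistic_value(23, 4, 0.5, 1:4)
  direct <- sum(vapply(seq_len(6), function(i)
    mvn_logpdf(toy$ds$pheno$values[i, ], g1, S), 0))
  expect_equal(ll, direct, tolerance = 1e-10)

  # identical curves for all classes: label-invariant, equals the null
  same <- toy$params
  same$curve_params <- list(c(23, 4, 0.5), c(23, 4, 0.5))
  expect_equal(mixture_loglik(same, toy$probs, toy$ds, "logistic", "ar1"),
               direct, tolerance = 1e-10)
})

test_that("fit_null recovers generating parameters on no-QTL data", {
  sims <- lapply(1:8, function(s) fixture_null(n = 150L, seed = 100L + s,
                                               m = 8L))
  ests <- sapply(sims, function(sim) {
    fit <- fit_null(sim$ds, "logistic", "ar1")
    c(fit$curve_params[[1L]], fit$theta)
  })
  truth <- c(30, 5, 0.5, 1, 0.6)
  mc_se <- apply(ests, 1L, sd) / sqrt(ncol(ests))
  expect_true(all(abs(rowMeans(ests) - truth) < 3 * mc_se + 0.02))
})

test_that("fit_null is deterministic", {
  sim <- fixture_bc(n = 50L, seed = 44L)
  f1 <- fit_null(sim$ds, "logistic", "ar1")
  f2 <- fit_null(sim$ds, "logistic", "ar1")
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$curve_params, f2$curve_params)
})

test_that("permuting individual order leaves logliks unchanged", {
  sim <- fixture_bc(n = 60L, seed = 45L)
  ds <- sim$ds
  set.seed(1); idx <- sample(60L)
  ds2 <- ds
  ds2$pheno$values <- ds$pheno$values[idx, ]
  ds2$pheno$ids <- ds$pheno$ids[idx]
  ds2$geno$codes <- ds$geno$codes[idx, ]
  ds2$geno$ids <- ds$geno$ids[idx]
  f1 <- fit_null(ds, "logistic", "ar1")
  f2 <- fit_null(ds2, "logistic", "ar1")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("EM at a degenerate fixed point leaves parameters unchanged", {
  sim <- fixture_bc(n = 80L, seed = 46L)
  ds <- sim$ds
  qtl_geno <- sim$truth$qtl_geno
  probs <- cbind(1 - qtl_geno, qtl_geno)   # exact class membership
  h1 <- fit_alternative(ds, probs, "logistic", "ar1",
                        control = fm_control(tol = 1e-8))
  # re-running EM from the solution must not move the likelihood
  h2 <- fit_alternative(ds, probs, "logistic", "ar1", init = h1,
                        control = fm_control(tol = 1e-8, max_iter = 3L))
  expect_equal(h2$loglik, h1$loglik, tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing and LR2 behaves", {
  sim <- fixture_bc(n = 100L, seed = 47L)
  ds <- sim$ds
  grid <- scan_grid(ds$map, 1)
  pos <- grid[grid$chr == "chr1" & grid$pos == 30, ]
  probs <- conditional_probs(pos, ds$geno, ds$map, ds$cross)
  h0 <- fit_null(ds, "logistic", "ar1")
  h1 <- fit_alternative(ds, probs, "logistic", "ar1", h0)
  expect_true(all(diff(h1$ll_trace) > -1e-8))
  expect_gte(lr_statistic(h0, h1), 0)
  expect_gte(h1$loglik, h0$loglik - 1e-6)

  # h1 forced to the replicated null parameters gives LR2 = 0
  h1_null <- h0
  h1_null$curve_params <- rep(h0$curve_params, 2L)
  expect_equal(lr_statistic(h0, h1_null), 0)

  # an h1 clearly below h0 signals optimiser failure
  h_bad <- h1; h_bad$loglik <- h0$loglik - 5
  expect_no_error(lr_statistic(h_bad, h0))    # positive LR is fine
  expect_error(lr_statistic(h0, h_bad), "failed")
})

test_that("alternative fit recovers genotype-specific curves (BC QTL at marker)", {
  sim <- fixture_bc(n = 200L, seed = 48L)
  ds <- sim$ds
  grid <- scan_grid(ds$map, 1)
  pos <- grid[grid$chr == "chr1" & grid$pos == 30, ]
  probs <- conditional_probs(pos, ds$geno, ds$map, ds$cross)
  h1 <- fit_alternative(ds, probs, "logistic", "ar1")
  a_hat <- sort(c(h1$curve_params[[1L]][1L], h1$curve_params[[2L]][1L]))
  expect_lt(abs(a_hat[1L] - 25) / 25, 0.05)
  expect_lt(abs(a_hat[2L] - 30) / 30, 0.05)
  expect_lt(abs(h1$theta[2L] - 0.6), 0.1)
})

test_that("covariate coefficients are estimated under both hypotheses", {
  cfg <- sim_config(n = 150L, seed = 9L, map = sim_map(1L, 4L, 10),
                    qtl = list(chr = "chr1", pos = 10,
                               params = list(c(30, 5, 0.5), c(26, 5, 0.5))),
                    covariates = list(p = 1L, alpha = 2))
  sim <- simulate_dataset(cfg)
  h0 <- fit_null(sim$ds, "logistic", "ar1")
  expect_equal(unname(h0$alpha), 2, tolerance = 0.3)
  grid <- scan_grid(sim$ds$map, 5)
  probs <- conditional_probs(grid[2L, ], sim$ds$geno, sim$ds$map, "BC")
  h1 <- fit_alternative(sim$ds, probs, "logistic", "ar1", h0)
  expect_equal(unname(h1$alpha), 2, tolerance = 0.3)
  expect_gte(lr_statistic(h0, h1), 0)
})

test_that("missing phenotype cells are marginalised, not dropped", {
  sim <- fixture_bc(n = 60L, seed = 50L, times = 1:6)
  ds <- sim$ds
  ds$pheno$values[cbind(1:10, rep(c(2L, 5L), 5L))] <- NA
  h0 <- fit_null(ds, "logistic", "ar1")
  expect_true(is.finite(h0$loglik))
  grid <- scan_grid(ds$map, 1)
  probs <- conditional_probs(grid[grid$chr == "chr1" & grid$pos == 30, ],
                             ds$geno, ds$map, ds$cross)
  h1 <- fit_alternative(ds, probs, "logistic", "ar1", h0,
                        control = fm_control(max_iter = 40L))
  expect_gte(lr_statistic(h0, h1), 0)
  expect_true(all(diff(h1$ll_trace) > -1e-8))
})
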