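test_that("AR(1) construction: identity limit and closed-form determinant", {
  S0 <- build_covariance("ar1", c(2, 0), 3)
  expect_equal(S0, 2 * diag(3))
  S <- build_covariance("ar1", c(1, 0.5), 3)
  expect_equal(det(S), (1 - 0.25)^2, tolerance = 1e-12)   # (1-rho^2)^(m-1)
  expect_equal(det(S), 0.5625, tolerance = 1e-12)
})

test_that("compound symmetry bounds exclude the singular boundary", {
  m <- 4
  b <- get_covariance("cs")$bounds(m)
  expect_gt(b$lower[2L], -1 / (m - 1))
  S <- build_covariance("cs", c(1, -1 / (m - 1) + 1e-6), m)
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(build_covariance("cs", c(1, -1 / (m - 1)), m), "bounds")
})

test_that("every built-in structure is symmetric and PD across its box", {
  set.seed(404)
  m <- 6
  times <- 1:m
  for (nm in cov_names()) {
    model <- get_covariance(nm)
    b <- model$bounds(m)
    np <- model$n_params(m)
    lo <- pmax(b$lower, c(0.05, rep(-3, np - 1L))[seq_len(np)])
    hi <- pmin(b$upper, c(5, rep(3, np - 1L))[seq_len(np)])
    for (k in seq_len(200L)) {
      th <- lo + stats::runif(np) * (hi - lo)
      S <- build_covariance(nm, th, m, times)
      expect_lt(max(abs(S - t(S))), 1e-12)
      expect_no_error(chol(S))
    }
  }
})

test_that("mvn_logpdf matches standard normal, factorisation and a dense oracle", {
  expect_equal(mvn_logpdf(0, 0, matrix(1)), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  expect_equal(mvn_logpdf(0, 0, matrix(1)), -0.918939, tolerance = 1e-6)

  # diagonal Sigma factorises into univariate normals
  y <- c(0.3, -1.2, 2.5); mu <- c(0, 1, -1); v <- c(1, 2, 0.5)
  expect_equal(mvn_logpdf(y, mu, diag(v)),
               sum(stats::dnorm(y, mu, sqrt(v), log = TRUE)),
               tolerance = 1e-12)

  set.seed(2)
  for (k in 1:10) {
    A <- matrix(rnorm(25), 5)
    S <- crossprod(A) + diag(5) * 0.1
    y <- rnorm(5); mu <- rnorm(5)
    expect_equal(mvn_logpdf(y, mu, S), oracle_mvn_logpdf(y, mu, S),
                 tolerance = 1e-10)
    y[2L] <- NA   # marginalisation over observed coordinates
    expect_equal(mvn_logpdf(y, mu, S), oracle_mvn_logpdf(y, mu, S),
                 tolerance = 1e-10)
  }
})

test_that("AR(1) density equals the closed-form tridiagonal likelihood", {
  set.seed(3)
  m <- 8; s2 <- 1.7; rho <- 0.55
  S <- build_covariance("ar1", c(s2, rho), m)
  for (k in 1:20) {
    y <- rnorm(m); mu <- rnorm(m, 1)
    expect_equal(mvn_logpdf(y, mu, S),
                 oracle_ar1_loglik(y, mu, s2, rho), tolerance = 1e-9)
  }
})

test_that("SAD(1) reproduces its generative recursion", {
  # y_t = phi_t y_{t-1} + e_t: sample covariance of simulated recursion
  set.seed(8)
  m <- 4; v <- c(1, 0.8, 1.2, 0.9); phi <- c(0.7, 0.5, 0.9)
  n <- 2e5
  E <- sapply(seq_len(m), function(t) rnorm(n, sd = sqrt(v[t])))
  Y <- E
  for (t in 2:m) Y[, t] <- phi[t - 1L] * Y[, t - 1L] + E[, t]
  S_emp <- crossprod(Y) / n
  S <- build_covariance("sad1", c(v, phi), m)
  expect_lt(max(abs(S - S_emp)), 0.05)
})

test_that("ARMA(1,1) matrix has the banded-geometric form", {
  th <- c(2, 0.6, 0.3)
  S <- build_covariance("arma11", th, 5)
  gam <- (1 + 0.6 * 0.3) * (0.6 + 0.3) / (1 + 2 * 0.6 * 0.3 + 0.09)
  expect_equal(diag(S), rep(2, 5))
  expect_equal(S[1, 2], 2 * gam, tolerance = 1e-12)
  expect_equal(S[1, 4], 2 * gam * 0.6^2, tolerance = 1e-12)  # rho = phi
})

test_that("covariance selection recovers AR(1) truth and is parsimonious", {
  set.seed(11)
  n <- 200; m <- 10
  S <- build_covariance("ar1", c(1, 0.6), m)
  R <- matrix(rnorm(n * m), n) %*% chol(S)
  sel <- select_covariance(list("vc", "ar1", "cs"), R, 1:m)
  expect_equal(sel$model$name, "ar1")
  # rho-hat within 3 SE of 0.6 (asymptotic SE ~ sqrt((1-rho^2)/(n*(m-1))))
  se_rho <- sqrt((1 - 0.36) / (n * (m - 1)))
  expect_lt(abs(sel$theta[2L] - 0.6), 3 * se_rho)

  # iid residuals: AIC picks the 1-parameter model at the analytic rate
  # P(pick vc) = P(chisq_1 <= 2) ~= 0.8427 (AIC penalty 2 per parameter),
  # so the win rate must sit within a 3-SE binomial band of that value
  wins <- 0L
  for (k in 1:40) {
    R0 <- matrix(rnorm(100 * 6), 100)
    s0 <- select_covariance(list("vc", "ar1"), R0, 1:6)
    if (s0$model$name == "vc") wins <- wins + 1L
  }
  p_vc <- stats::pchisq(2, df = 1)
  expect_lt(abs(wins / 40 - p_vc), 3 * sqrt(p_vc * (1 - p_vc) / 40))

  # single candidate comes back with its ML estimate
  one <- select_covariance(list("ar1"), R, 1:m)
  expect_equal(one$model$name, "ar1")
})

test_that("model nesting never decreases the maximised log-likelihood", {
  set.seed(12)
  R <- matrix(rnorm(150 * 6), 150) %*% chol(build_covariance("cs", c(1, 0.3), 6))
  ll_vc <- longqtl:::fit_cov_ml("vc", R, 1:6)$loglik
  ll_cs <- longqtl:::fit_cov_ml("cs", R, 1:6)$loglik
  ll_ar1 <- longqtl:::fit_cov_ml("ar1", R, 1:6)$loglik
  expect_gte(ll_cs, ll_vc - 1e-6)
  expect_gte(ll_ar1, ll_vc - 1e-6)
})

test_that("criterion = MLE picks the larger likelihood regardless of size", {
  set.seed(13)
  R <- matrix(rnorm(80 * 5), 80)
  aic_pick <- select_covariance(list("vc", "sad1"), R, 1:5, criterion = "AIC")
  mle_pick <- select_covariance(list("vc", "sad1"), R, 1:5, criterion = "MLE")
  expect_equal(mle_pick$model$name, "sad1")  # 9 free params always fit better
  expect_gte(mle_pick$loglik, aic_pick$loglik - 1e-6)
})
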