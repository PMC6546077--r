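# Independent oracles used to check the package's fast implementations.
# These are deliberately naive: explicit inverses/determinants, term-by-term
# sums and physical meiosis simulation, never sharing code with R/.

# dense MVN log-density via explicit inverse and determinant
oracle_mvn_logpdf <- function(y, mean, Sigma) {
  obs <- !is.na(y)
  d <- y[obs] - mean[obs]
  S <- Sigma[obs, obs, drop = FALSE]
  k <- sum(obs)
  -0.5 * (k * log(2 * pi) + log(det(S)) +
            drop(t(d) %*% solve(S) %*% d))
}

# naive mixture log-likelihood: double loop, densities on the raw scale
oracle_mixture_loglik <- function(curve_params, theta, alpha, probs, Y, X,
                                  times, curve_name, cov_name) {
  curve <- get_curve(curve_name)
  Sigma <- build_covariance(cov_name, theta, length(times), times)
  n <- nrow(Y)
  J <- ncol(probs)
  total <- 0
  for (i in seq_len(n)) {
    mix <- 0
    shift <- if (is.null(X)) 0 else sum(alpha * X[i, ])
    for (j in seq_len(J)) {
      g <- curve$fun(curve_params[[j]], times)
      mix <- mix + probs[i, j] * exp(oracle_mvn_logpdf(Y[i, ], g + shift, Sigma))
    }
    total <- total + log(mix)
  }
  total
}

# closed-form AR(1) log-likelihood (tridiagonal inverse), one row
oracle_ar1_loglik <- function(y, mean, s2, rho) {
  m <- length(y)
  d <- y - mean
  q <- d[1L]^2
  if (m >= 2L) q <- q + sum((d[-1L] - rho * d[-m])^2) / (1 - rho^2)
  logdet <- m * log(s2) + (m - 1) * log(1 - rho^2)
  -0.5 * (m * log(2 * pi) + logdet + q / s2)
}

# ---- physical meiosis simulator ----------------------------------------
# Crossovers are a Poisson process on the interval (Morgan scale); an odd
# crossover count between two loci swaps the contributing haplotype. This
# derives recombination from the process itself, independently of the
# Haldane formula under test.

# one gamete per row from parent haplotypes H1, H2 (n x 3 matrices),
# locus distances d1, d2 in cM
mc_gamete <- function(H1, H2, d1, d2) {
  n <- nrow(H1)
  h <- stats::rbinom(n, 1L, 0.5)                  # starting haplotype
  # map distance in Morgans = expected crossovers seen by one gamete
  x1 <- stats::rpois(n, d1 / 100) %% 2L           # odd crossovers 1->2
  x2 <- stats::rpois(n, d2 / 100) %% 2L
  h2 <- (h + x1) %% 2L
  h3 <- (h2 + x2) %% 2L
  cbind(ifelse(h  == 0L, H1[, 1L], H2[, 1L]),
        ifelse(h2 == 0L, H1[, 2L], H2[, 2L]),
        ifelse(h3 == 0L, H1[, 3L], H2[, 3L]))
}

# n individuals typed at (marker, QTL, marker) with distances d1, d2
mc_meiosis_trios <- function(cross, d1, d2, n) {
  ONE <- matrix(1L, n, 3L); ZERO <- matrix(0L, n, 3L)
  cross <- toupper(cross)
  if (cross == "BC") {
    mc_gamete(ONE, ZERO, d1, d2)                   # + 0 from recurrent parent
  } else if (cross == "DH") {
    mc_gamete(ONE, ZERO, d1, d2)                   # doubled gamete
  } else if (cross == "F2") {
    mc_gamete(ONE, ZERO, d1, d2) + mc_gamete(ONE, ZERO, d1, d2)
  } else if (cross == "RIL") {
    H1 <- ONE; H2 <- ZERO
    for (gen in 1:30) {                            # selfing to near-fixation
      A <- mc_gamete(H1, H2, d1, d2)
      B <- mc_gamete(H1, H2, d1, d2)
      H1 <- A; H2 <- B
    }
    H1                                             # residual het ~ 2^-30
  } else stop("unknown cross")
}

# empirical P(QTL class | flanking classes) with binomial 3-SE bands
mc_conditional_check <- function(cross, L, n = 1e6, frac = 0.5) {
  d1 <- frac * L; d2 <- (1 - frac) * L
  tri <- mc_meiosis_trios(cross, d1, d2, n)
  J <- cross_type(cross)$n_classes
  map <- genetic_map(data.frame(marker = c("mL", "mR"), chr = "c1",
                                pos_cM = c(0, L)))
  pos <- list(chr = "c1", pos = d1, left_marker = "mL", right_marker = "mR",
              left_pos = 0, right_pos = L)
  worst <- 0
  for (a in 0:(J - 1L)) for (b in 0:(J - 1L)) {
    sel <- tri[, 1L] == a & tri[, 3L] == b
    nab <- sum(sel)
    if (nab < 50L) next
    geno <- list(ids = "i", codes = matrix(c(a, b), 1L, 2L,
                                           dimnames = list("i", c("mL", "mR"))))
    p_model <- conditional_probs(pos, geno, map, cross)[1L, ]
    for (q in 0:(J - 1L)) {
      phat <- mean(tri[sel, 2L] == q)
      se <- sqrt(p_model[q + 1L] * (1 - p_model[q + 1L]) / nab)
      excess <- abs(phat - p_model[q + 1L]) - (3 * se + 2 / nab)
      worst <- max(worst, excess)
    }
  }
  worst       # <= 0 iff every cell is within 3 SE (+ continuity correction)
}
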