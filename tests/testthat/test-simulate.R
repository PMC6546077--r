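test_that("zero map distance gives identical genotype columns", {
  map <- genetic_map(data.frame(marker = c("a", "b", "c"), chr = "1",
                                pos_cM = c(0, 1e-9, 50)))
  cfg <- sim_config(map = map, qtl = list(chr = "1", pos = 25,
                                          params = list(c(30, 5, 0.5),
                                                        c(25, 5, 0.5))),
                    n = 500L, seed = 2L)
  g <- simulate_genotypes(cfg)
  expect_identical(g$geno$codes[, "a"], g$geno$codes[, "b"])
})

test_that("recombination fraction approaches 1/2 at large distance", {
  map <- genetic_map(data.frame(marker = c("a", "b"), chr = "1",
                                pos_cM = c(0, 1000)))
  cfg <- sim_config(map = map, qtl = list(chr = "1", pos = 500,
                                          params = list(c(30, 5, 0.5),
                                                        c(25, 5, 0.5))),
                    n = 10000L, seed = 3L)
  g <- simulate_genotypes(cfg)
  rec <- mean(g$geno$codes[, "a"] != g$geno$codes[, "b"])
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(rec - 0.5), 3 * se)
})

test_that("marker class frequencies match design expectations", {
  cfg <- sim_config(n = 10000L, seed = 4L, map = sim_map(1L, 3L, 10),
                    qtl = list(chr = "chr1", pos = 10,
                               params = list(c(30, 5, 0.5), c(25, 5, 0.5))))
  g <- simulate_genotypes(cfg)
  freq <- colMeans(g$geno$codes)
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 10000)))

  cfgf2 <- sim_config(cross = "F2", n = 8000L, seed = 5L,
                      map = sim_map(1L, 3L, 10),
                      qtl = list(chr = "chr1", pos = 10,
                                 params = list(c(25, 5, 0.5), c(28, 5, 0.5),
                                               c(30, 5, 0.5))))
  gf2 <- simulate_genotypes(cfgf2)
  het <- colMeans(gf2$geno$codes == 1L)
  expect_true(all(abs(het - 0.5) < 3 * sqrt(0.25 / 8000)))
})

test_that("short intervals recombine at the Haldane rate", {
  cfg <- sim_config(n = 20000L, seed = 6L, map = sim_map(1L, 2L, 20),
                    qtl = list(chr = "chr1", pos = 10,
                               params = list(c(30, 5, 0.5), c(25, 5, 0.5))))
  g <- simulate_genotypes(cfg)
  rec <- mean(g$geno$codes[, 1L] != g$geno$codes[, 2L])
  r <- haldane_r(20)
  expect_lt(abs(rec - r), 3 * sqrt(r * (1 - r) / 20000))
})

test_that("phenotypes collapse to the genotype curves in the zero-noise limit", {
  cfg <- sim_config(n = 30L, seed = 7L, map = sim_map(1L, 3L, 10),
                    qtl = list(chr = "chr1", pos = 10,
                               params = list(c(30, 5, 0.5), c(25, 5, 0.5))),
                    cov_theta = c(1e-12, 0))
  sim <- simulate_dataset(cfg)
  G <- rbind(logistic_value(30, 5, 0.5, 1:11), logistic_value(25, 5, 0.5, 1:11))
  expect_lt(max(abs(sim$ds$pheno$values - G[sim$truth$qtl_geno + 1L, ])), 1e-5)
})

test_that("residual sample covariance matches the generating structure", {
  cfg <- sim_config(n = 5000L, seed = 8L, map = sim_map(1L, 2L, 10),
                    qtl = list(chr = "chr1", pos = 0,
                               params = list(c(30, 5, 0.5), c(30, 5, 0.5))),
                    cov_theta = c(1, 0.6), times = 1:6)
  sim <- simulate_dataset(cfg)
  R <- sweep(sim$ds$pheno$values, 2L, logistic_value(30, 5, 0.5, 1:6))
  S_emp <- crossprod(R) / nrow(R)
  S <- build_covariance("ar1", c(1, 0.6), 6)
  # entrywise 3-SE band; var of sample covariance ~ (S_ss S_tt + S_st^2)/n
  se <- sqrt((outer(diag(S), diag(S)) + S^2) / 5000)
  expect_true(all(abs(S_emp - S) < 3 * se + 0.01))
})

test_that("simulation is reproducible from its seed", {
  s1 <- simulate_dataset(sim_config(n = 40L, seed = 99L))
  s2 <- simulate_dataset(sim_config(n = 40L, seed = 99L))
  expect_identical(s1$ds$pheno$values, s2$ds$pheno$values)
  expect_identical(s1$ds$geno$codes, s2$ds$geno$codes)
  s3 <- simulate_dataset(sim_config(n = 40L, seed = 100L))
  expect_false(identical(s1$ds$pheno$values, s3$ds$pheno$values))
})

test_that("invalid configurations are rejected before any generation", {
  expect_error(sim_config(n = 0L), ">= 1")
  expect_error(sim_config(qtl = list(chr = "chr9", pos = 10,
                                     params = list(c(1, 1, 1), c(1, 1, 1)))),
               "chromosome")
  expect_error(sim_config(qtl = list(chr = "chr1", pos = 500,
                                     params = list(c(1, 1, 1), c(1, 1, 1)))),
               "span")
  expect_error(sim_config(qtl = list(chr = "chr1", pos = 10,
                                     params = list(c(1, 1, 1)))),
               "per genotype")
})

test_that("hidden QTL genotypes are calibrated against conditional_probs", {
  cfg <- sim_config(n = 2000L, seed = 12L, map = sim_map(1L, 4L, 10),
                    qtl = list(chr = "chr1", pos = 17,
                               params = list(c(30, 5, 0.5), c(25, 5, 0.5))))
  g <- simulate_genotypes(cfg)
  grid <- scan_grid(cfg$map, 1)
  pos <- grid[grid$pos == 17, ]
  pr <- conditional_probs(pos, g$geno, cfg$map, "BC")
  p_true <- pr[cbind(seq_len(2000L), g$qtl_geno + 1L)]
  expect_gt(mean(p_true), mean(1 - p_true))
  expect_gt(mean(p_true), 0.8)   # flanking markers 7 and 3 cM away
})
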