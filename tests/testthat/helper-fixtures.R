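# Shared small fixtures, built in code at test time.

# quick backcross dataset with a strong QTL at 30 cM (a marker) on chr1
fixture_bc <- function(n = 120L, seed = 11L, n_chr = 2L, n_markers = 7L,
                       qtl_pos = min(30, (n_markers - 1L) * 10), a2 = 25,
                       cov_theta = c(1, 0.6), times = 1:11) {
  cfg <- sim_config(cross = "BC", map = sim_map(n_chr, n_markers, 10),
                    qtl = list(chr = "chr1", pos = qtl_pos,
                               params = list(c(30, 5, 0.5), c(a2, 5, 0.5))),
                    cov_theta = cov_theta, times = times, n = n, seed = seed)
  simulate_dataset(cfg)
}

# null dataset: both genotype classes share one curve
fixture_null <- function(n = 60L, seed = 21L, m = 5L,
                         map = sim_map(1L, 3L, 10)) {
  cfg <- sim_config(cross = "BC", map = map,
                    qtl = list(chr = "chr1", pos = 10,
                               params = list(c(30, 5, 0.5), c(30, 5, 0.5))),
                    cov_theta = c(1, 0.6), times = seq_len(m), n = n,
                    seed = seed)
  simulate_dataset(cfg)
}

# fast EM settings for scan-heavy tests
fast_control <- function() fm_control(tol = 1e-4, max_iter = 60L,
                                      inner_maxit = 80L)
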