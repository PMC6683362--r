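test_that("cohort simulation is deterministic under seed and varies across seeds", {
  cfg <- sim_config(n_per_class = c(LL = 3, RR = 3, LR = 4),
                    n_loci_total = 40, n_diagnostic = 15, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$genotypes$depth, b$genotypes$depth)
  expect_identical(a$panel, b$panel)
  cfg2 <- cfg; cfg2$seed <- 8L
  c2 <- simulate_cohort(cfg2)
  expect_false(identical(a$genotypes$depth, c2$genotypes$depth))
})

test_that("diploid hybrids at high depth have balanced allele depths", {
  # Poisson(1000) per locus, error-free: each allele depth concentrates
  # tightly around 500 in an LR diploid
  co <- simulate_cohort(sim_config(
    n_per_class = c(LR = 5), n_loci_total = 30, n_diagnostic = 30,
    depth_mean = 1000, depth_dispersion = "poisson", seq_error = 0,
    missing_rate = 0, seed = 7))
  for (s in co$genotypes$samples) {
    for (i in seq_len(nrow(co$panel))) {
      loc <- co$panel$locus[i]
      ad <- as.integer(strsplit(co$genotypes$depth[loc, s], ",")[[1]])
      expect_true(all(ad >= 400 & ad <= 600))
    }
  }
})

test_that("error-free parental individuals carry zero depth on the other genome", {
  co <- simulate_cohort(sim_config(
    n_per_class = c(LL = 4), n_loci_total = 25, n_diagnostic = 25,
    depth_mean = 50, seq_error = 0, missing_rate = 0, seed = 13))
  for (i in seq_len(nrow(co$panel))) {
    loc <- co$panel$locus[i]
    reg <- co$genotypes$alleles[[loc]]
    r_idx <- match(co$panel$R_allele[i], reg)
    for (s in co$genotypes$samples) {
      ad <- as.integer(strsplit(co$genotypes$depth[loc, s], ",")[[1]])
      expect_identical(ad[r_idx], 0L)
    }
  }
})

test_that("allele-depth fractions converge to the dosage proportions", {
  # law-of-large-numbers check at depth 1e4: pooled L fraction within 0.01
  # of 1/2 (LR), 2/3 (LLR), 1/3 (LRR)
  co <- simulate_cohort(sim_config(
    n_per_class = c(LR = 3, LLR = 3, LRR = 3), n_loci_total = 50,
    n_diagnostic = 50, depth_mean = 1e4, depth_dispersion = "poisson",
    seq_error = 0, missing_rate = 0, seed = 99))
  expected <- c(LR = 1 / 2, LLR = 2 / 3, LRR = 1 / 3)
  for (k in seq_along(co$genotypes$samples)) {
    s <- co$genotypes$samples[k]
    cls <- co$truth$class[co$truth$sample == s]
    sL <- 0; tot <- 0
    for (i in seq_len(nrow(co$panel))) {
      loc <- co$panel$locus[i]
      reg <- co$genotypes$alleles[[loc]]
      ad <- as.integer(strsplit(co$genotypes$depth[loc, s], ",")[[1]])
      sL <- sL + ad[match(co$panel$L_allele[i], reg)]
      tot <- tot + sum(ad)
    }
    expect_lt(abs(sL / tot - expected[[cls]]), 0.01)
  }
})

test_that("hemiclonal groups show far lower heterozygosity than hybrids", {
  co <- simulate_cohort(sim_config(
    n_per_class = c(RR = 6, LR = 6), n_loci_total = 400, n_diagnostic = 100,
    residual_het = 0.01, depth_mean = 30, seed = 31))
  ih <- individual_heterozygosity(co$genotypes)
  cls <- co$truth$class[match(ih$sample, co$truth$sample)]
  h_rr <- mean(ih$het[cls == "RR"])
  h_lr <- mean(ih$het[cls == "LR"])
  expect_lt(h_rr, 0.05)
  expect_gt(h_lr, h_rr + 0.2)
})

test_that("sim_config rejects out-of-domain parameters", {
  expect_error(sim_config(n_per_class = c(LL = 0, RR = 0, LR = 0)), "at least one")
  expect_error(sim_config(n_diagnostic = 100, n_loci_total = 50), "n_loci_total")
  expect_error(sim_config(seq_error = 0.5), "seq_error")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(depth_dispersion = -1), "dispersion")
})

test_that("peak heights follow copy number and efficiency exactly when noise-free", {
  cfg <- peak_sim_config(
    loci = list(M1 = list(L = 122L, R = 137L)),
    n_per_class = c(LR = 2, LLR = 2, LRR = 2),
    base_height = 1000, sigma = 0, seed = 4)
  sim <- simulate_peak_table(cfg)
  for (k in seq_len(nrow(sim$truth))) {
    pk <- sim$peaks[sim$peaks$sample == sim$truth$sample[k], ]
    hL <- pk$height[pk$allele == 122L]
    hR <- pk$height[pk$allele == 137L]
    expect_equal(hL, switch(sim$truth$class[k], LR = 1000, LLR = 2000, LRR = 1000))
    expect_equal(hR, switch(sim$truth$class[k], LR = 1000, LLR = 1000, LRR = 2000))
  }
  # allele-specific efficiency scales the peak
  sim2 <- simulate_peak_table(peak_sim_config(
    loci = list(M1 = list(L = 122L, R = 137L)), n_per_class = c(LR = 1),
    base_height = 1000, sigma = 0, efficiency = c("122" = 0.5), seed = 4))
  expect_equal(sim2$peaks$height[sim2$peaks$allele == 122L], 500)
})

test_that("LLR individuals with distinct L alleles emit tri-allelic patterns", {
  sim <- simulate_peak_table(peak_sim_config(
    loci = list(M1 = list(L = c(122L, 123L), R = 137L)),
    n_per_class = c(LLR = 30), sigma = 0, seed = 17))
  n_peaks <- table(sim$peaks$sample)
  expect_true(any(n_peaks == 3L))  # distinct L copies
  expect_true(all(n_peaks %in% c(2L, 3L)))
})

test_that("null alleles drop records rather than emitting zero heights", {
  sim <- simulate_peak_table(peak_sim_config(
    loci = list(M1 = list(L = 122L, R = 137L)),
    n_per_class = c(LR = 200), sigma = 0, null_prob = 0.3, seed = 8))
  expect_true(all(sim$peaks$height > 0))
  expect_lt(nrow(sim$peaks), 400L)   # some copies failed to amplify
  expect_error(peak_sim_config(sigma = -0.1), "sigma")
})
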