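slice <- function(alleles, heights, sample = "S1", locus = "RICA1b5") {
  data.frame(sample = sample, locus = locus, allele = alleles,
             height = heights, stringsAsFactors = FALSE)
}

test_that("PHR is the log10 ratio of R over L peak heights", {
  r <- compute_phr(slice(c(122L, 137L), c(1000, 1000)), 122L, 137L)
  expect_equal(r$phr, 0.0)
  expect_identical(r$pattern, "ok")
  r2 <- compute_phr(slice(c(122L, 137L), c(1000, 2000)), 122L, 137L)
  expect_equal(r2$phr, log10(2), tolerance = 1e-12)
  # antisymmetry: swapping the two heights negates the statistic exactly
  r3 <- compute_phr(slice(c(122L, 137L), c(2000, 1000)), 122L, 137L)
  expect_equal(r3$phr, -r2$phr)
})

test_that("non-quantifiable patterns are flagged, not quantified", {
  r1 <- compute_phr(slice(122L, 5000), 122L, 137L)
  expect_identical(r1$pattern, "single_peak")
  expect_true(is.na(r1$phr))
  r2 <- compute_phr(slice(c(122L, 123L, 137L), c(900, 1100, 950)),
                    c(122L, 123L), 137L)
  expect_true(r2$triallelic)
  expect_identical(r2$pattern, "triallelic")
  expect_true(is.na(r2$phr))
  r3 <- compute_phr(slice(c(122L, 123L), c(900, 1100)), c(122L, 123L), 137L)
  expect_identical(r3$pattern, "same_genome")
  expect_warning(compute_phr(slice(c(122L, 137L, 99L), c(1000, 1000, 10)),
                             122L, 137L), "ignored")
})

test_that("tri-allelic detection needs three distinct recorded alleles", {
  expect_false(detect_triallelic(slice(c(122L, 137L), c(1, 1))))
  expect_true(detect_triallelic(slice(c(122L, 123L, 137L), c(1, 1, 1))))
})

test_that("printed calibration values classify to their genotype classes", {
  cal <- phr_calibration()
  ranges <- cal[cal$genotype == "122/137", ]
  expect_identical(classify_phr(-0.22, ranges), "LR")
  expect_identical(classify_phr(-0.39, ranges), "LLR")
  expect_identical(classify_phr(0.17, ranges), "LRR")
  expect_identical(classify_phr(0.5, ranges), "OUT_OF_RANGE")
  expect_identical(classify_phr(-0.26, ranges), "OUT_OF_RANGE")
})

test_that("overlapping or inconsistent calibrations are rejected", {
  bad <- data.frame(locus = "M", genotype = "a/b",
                    class = c("LR", "LLR"),
                    phr_min = c(-0.2, -0.3), phr_max = c(0, -0.2),
                    stringsAsFactors = FALSE)
  expect_error(validate_phr_calibration(bad), "overlapping")
  bad2 <- data.frame(locus = "M", genotype = "a/b", class = "LR",
                     phr_min = 0.1, phr_max = -0.1)
  expect_error(validate_phr_calibration(bad2), "phr_min")
  bad3 <- data.frame(locus = "M", genotype = "a/b", class = "LR",
                     phr_min = -0.2, phr_max = 0, mean = 0.1)
  expect_error(validate_phr_calibration(bad3), "mean")
})

test_that("containment is exhaustive and exclusive for random disjoint ranges", {
  set.seed(404)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    edges <- sort(stats::runif(2 * k, -1, 1))
    ranges <- data.frame(
      locus = "M", genotype = "a/b", class = paste0("C", seq_len(k)),
      phr_min = edges[seq(1, 2 * k, 2)], phr_max = edges[seq(2, 2 * k, 2)] -
        1e-6, stringsAsFactors = FALSE)
    x <- stats::runif(60, -1.2, 1.2)
    got <- classify_phr(x, ranges)
    for (i in seq_along(x)) {
      inside <- which(ranges$phr_min <= x[i] & x[i] <= ranges$phr_max)
      expect_identical(got[i], if (length(inside)) ranges$class[inside]
                               else "OUT_OF_RANGE")
    }
  }
})

test_that("noise-free simulated classes give the exact copy-number PHR", {
  sim <- simulate_peak_table(peak_sim_config(
    loci = list(RICA1b5 = list(L = 122L, R = 137L)),
    n_per_class = c(LR = 3, LLR = 3, LRR = 3), sigma = 0, seed = 10))
  rep <- phr_report(sim$peaks, sim$markers)
  cls <- sim$truth$class[match(rep$sample, sim$truth$sample)]
  expect_equal(rep$phr[cls == "LR"], rep(0, 3))
  expect_equal(rep$phr[cls == "LLR"], rep(-log10(2), 3), tolerance = 1e-12)
  expect_equal(rep$phr[cls == "LRR"], rep(log10(2), 3), tolerance = 1e-12)
})

test_that("simulated tri-allelic LLR individuals are detected via truth", {
  sim <- simulate_peak_table(peak_sim_config(
    loci = list(RICA1b5 = list(L = c(122L, 123L), R = 137L)),
    n_per_class = c(LR = 10, LLR = 10), sigma = 0.1, seed = 15))
  rep <- phr_report(sim$peaks, sim$markers)
  cls <- sim$truth$class[match(rep$sample, sim$truth$sample)]
  expect_false(any(rep$triallelic[cls == "LR"]))
  # an LLR is tri-allelic exactly when its two L copies differ
  n3 <- tapply(sim$peaks$allele, sim$peaks$sample,
               function(a) length(unique(a)))
  expect_identical(unname(rep$triallelic),
                   as.vector(n3[rep$sample] >= 3L))
})

test_that("calibration files round-trip", {
  p <- tempfile(fileext = ".tsv")
  write_phr_calibration(phr_calibration(), p)
  expect_equal(read_phr_calibration(p), phr_calibration(), tolerance = 1e-12)
})
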