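# Build a one-sample genotype matrix with given L/R depths over n loci.
depth_fixture <- function(dL, dR, sample_id = "S1") {
  n <- length(dL)
  loci <- sprintf("t%03d:%d", seq_len(n), seq_len(n))
  geno <- matrix("A/G", n, 1, dimnames = list(loci, sample_id))
  depth <- matrix(sprintf("%d,%d", dL, dR), n, 1,
                  dimnames = list(loci, sample_id))
  alleles <- stats::setNames(rep(list(c("A", "G")), n), loci)
  gm <- genotype_matrix(geno, depth = depth, alleles = alleles)
  panel <- data.frame(locus = loci, L_allele = "A", R_allele = "G",
                      stringsAsFactors = FALSE)
  list(gm = gm, panel = panel)
}

test_that("locus coverage ratio is max over min", {
  expect_equal(locus_coverage_ratio(10, 10), 1.0)
  expect_equal(locus_coverage_ratio(20, 10), 2.0)
  expect_equal(locus_coverage_ratio(10, 12), 1.2)
  expect_error(locus_coverage_ratio(0, 10), "min-depth")
})

test_that("profiles aggregate usable loci and respect the depth floor", {
  fx <- depth_fixture(dL = c(10L, 30L, 2L, 15L), dR = c(10L, 10L, 50L, 0L))
  pr <- individual_dosage_profile(fx$gm, fx$panel, "S1",
                                  min_depth_per_allele = 3, min_loci = 2)
  # loci 3 and 4 fail the per-allele depth floor
  expect_equal(pr$n_loci_used, 2L)
  expect_equal(pr$mean_ratio, mean(c(1, 3)))
  expect_equal(pr$pooled_ratio, max(40, 20) / min(40, 20))
  expect_equal(pr$mean_log2_LR, mean(log2(c(10 / 10, 30 / 10))))
})

test_that("samples without usable panel loci are UNDETERMINED", {
  fx <- depth_fixture(dL = c(5L, 5L), dR = c(0L, 0L))
  pr <- individual_dosage_profile(fx$gm, fx$panel, "S1")
  expect_equal(pr$n_loci_used, 0L)
  expect_identical(pr$call, "UNDETERMINED")
  ml <- dosage_likelihood_call(pr)
  expect_true(is.na(ml$ml_class))
})

test_that("ploidy classification follows the threshold bands", {
  fake <- function(mean_ratio, mean_log2) {
    structure(list(n_loci_used = 100L, min_loci = 20L,
                   mean_ratio = mean_ratio, mean_log2_LR = mean_log2),
              class = "dosage_profile")
  }
  expect_identical(classify_ploidy(fake(1.1, -0.05)), "DIPLOID_LR")
  expect_identical(classify_ploidy(fake(2.05, 0.9)), "TRIPLOID_LLR")
  expect_identical(classify_ploidy(fake(2.05, -0.9)), "TRIPLOID_LRR")
  expect_identical(classify_ploidy(fake(1.55, 0.4)), "UNDETERMINED")
  expect_identical(classify_ploidy(fake(2.05, 0)), "UNDETERMINED")
  expect_error(classify_ploidy(fake(1.1, 0), diploid_max = 1.8,
                               triploid_min = 1.7), "configuration")
})

test_that("likelihood call identifies exact dosage patterns", {
  even <- depth_fixture(dL = rep(50L, 30), dR = rep(50L, 30))
  pr <- individual_dosage_profile(even$gm, even$panel, "S1")
  expect_identical(dosage_likelihood_call(pr)$ml_class, "DIPLOID_LR")
  twoone <- depth_fixture(dL = rep(40L, 30), dR = rep(20L, 30))
  pr2 <- individual_dosage_profile(twoone$gm, twoone$panel, "S1")
  expect_identical(dosage_likelihood_call(pr2)$ml_class, "TRIPLOID_LLR")
  expect_identical(dosage_likelihood_call(pr2, error = 0.01)$ml_class,
                   "TRIPLOID_LLR")
  expect_error(dosage_likelihood_call(pr2, error = 0.6), "error")
})

test_that("classification is symmetric under swapping the L and R labels", {
  co <- simulate_cohort(sim_config(
    n_per_class = c(LLR = 4, LRR = 4, LR = 4), n_loci_total = 60,
    n_diagnostic = 60, depth_mean = 100, seq_error = 0, missing_rate = 0,
    seed = 55))
  swapped <- co$panel
  swapped$L_allele <- co$panel$R_allele
  swapped$R_allele <- co$panel$L_allele
  flip <- c(DIPLOID_LR = "DIPLOID_LR", TRIPLOID_LLR = "TRIPLOID_LRR",
            TRIPLOID_LRR = "TRIPLOID_LLR", UNDETERMINED = "UNDETERMINED")
  for (s in co$genotypes$samples) {
    a <- individual_dosage_profile(co$genotypes, co$panel, s)
    b <- individual_dosage_profile(co$genotypes, swapped, s)
    expect_equal(b$mean_ratio, a$mean_ratio)
    expect_equal(b$mean_log2_LR, -a$mean_log2_LR)
    expect_identical(b$call, unname(flip[a$call]))
  }
})

test_that("ratio statistics converge to 1x for diploids and 2x for triploids", {
  co <- simulate_cohort(sim_config(
    n_per_class = c(LR = 3, LLR = 3, LRR = 3), n_loci_total = 50,
    n_diagnostic = 50, depth_mean = 1e4, depth_dispersion = "poisson",
    seq_error = 0, missing_rate = 0, seed = 21))
  for (k in seq_along(co$genotypes$samples)) {
    s <- co$genotypes$samples[k]
    cls <- co$truth$class[co$truth$sample == s]
    pr <- individual_dosage_profile(co$genotypes, co$panel, s)
    target <- if (cls == "LR") 1 else 2
    expect_equal(pr$pooled_ratio, target, tolerance = 0.02)
    expect_identical(pr$call,
                     c(LR = "DIPLOID_LR", LLR = "TRIPLOID_LLR",
                       LRR = "TRIPLOID_LRR")[[cls]])
  }
})

test_that("heuristic and likelihood calls agree at moderate depth", {
  co <- simulate_cohort(sim_config(
    n_per_class = c(LR = 6, LLR = 6, LRR = 6), n_loci_total = 150,
    n_diagnostic = 150, depth_mean = 50, depth_dispersion = "poisson",
    seq_error = 0.01, missing_rate = 0, seed = 88))
  rep <- dosage_report(co$genotypes, co$panel, error = 0.01)
  expect_true(all(rep$call == rep$ml_call))
  truth <- c(LR = "DIPLOID_LR", LLR = "TRIPLOID_LLR", LRR = "TRIPLOID_LRR")
  cls <- co$truth$class[match(rep$sample, co$truth$sample)]
  expect_true(all(rep$call == unname(truth[cls])))
})
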