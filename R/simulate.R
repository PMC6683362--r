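#' Configuration for the synthetic cohort simulator
#'
#' Defines a cohort with the statistical structure a hybridogenetic
#' *Pelophylax* RAD-seq survey assumes: parental `LL` and `RR` individuals,
#' diploid hybrids `LR` and triploid hybrids `LLR` / `LRR`; a SNP matrix in
#' which a subset of loci is fully species-diagnostic (fixed L/R difference);
#' and per-allele read depths drawn under the genome-dosage proportions
#' (1:1 for LR, 2:1 for LLR, 1:2 for LRR) with symmetric cross-allele
#' sequencing error.
#'
#' Read depth follows a negative binomial law parameterized by mean and
#' dispersion (`size`), with `"poisson"` as the equi-dispersed limit; RAD
#' libraries are typically overdispersed, hence the default. Hemiclonal /
#' parental individuals are heterozygous at a non-diagnostic locus with
#' probability `residual_het` (their near-clonal genomes carry little
#' diversity), hybrids with probability `hybrid_het` (two divergent genomes).
#'
#' @param n_per_class named integer vector of cohort sizes for (a subset of)
#'   the classes `LL`, `RR`, `LR`, `LLR`, `LRR`.
#' @param n_loci_total total number of SNP loci.
#' @param n_diagnostic number of fully diagnostic loci (`<= n_loci_total`).
#' @param depth_mean mean total read depth per locus and individual.
#' @param depth_dispersion negative-binomial `size`, or `"poisson"`.
#' @param seq_error per-read probability `[0, 0.5)` that a read at a
#'   diagnostic locus is attributed to the other genome's allele.
#' @param missing_rate probability `[0, 1)` that a genotype call is missing.
#' @param residual_het heterozygosity of LL/RR individuals at non-diagnostic
#'   loci.
#' @param hybrid_het heterozygosity of hybrid individuals at non-diagnostic
#'   loci.
#' @param ploidy_coding `"diploid"` writes triploid individuals with
#'   diploid-coded calls (heterozygous iff both alleles present), as real SNP
#'   callers do; `"true"` writes the full allele multiset (e.g. `L/L/R`) so
#'   truth files round-trip.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_per_class = c(LL = 5, RR = 5, LR = 10, LLR = 0, LRR = 0),
                       n_loci_total = 500L,
                       n_diagnostic = 150L,
                       depth_mean = 20,
                       depth_dispersion = 5,
                       seq_error = 0.005,
                       missing_rate = 0.1,
                       residual_het = 0.01,
                       hybrid_het = 0.2,
                       ploidy_coding = c("diploid", "true"),
                       seed = NULL) {
  classes <- c("LL", "RR", "LR", "LLR", "LRR")
  if (is.null(names(n_per_class)) || !all(names(n_per_class) %in% classes))
    stop("'n_per_class' must be named with classes among: ",
         paste(classes, collapse = ", "))
  n <- stats::setNames(integer(5), classes)
  n[names(n_per_class)] <- as.integer(n_per_class)
  if (any(n < 0)) stop("class counts must be non-negative")
  if (sum(n) == 0L) stop("cohort must contain at least one individual")
  n_loci_total <- as.integer(n_loci_total)
  n_diagnostic <- as.integer(n_diagnostic)
  if (n_loci_total < 1L) stop("'n_loci_total' must be >= 1")
  if (n_diagnostic < 0L || n_diagnostic > n_loci_total)
    stop("'n_diagnostic' must be in [0, n_loci_total]")
  if (depth_mean <= 0) stop("'depth_mean' must be positive")
  if (!identical(depth_dispersion, "poisson") &&
      (!is.numeric(depth_dispersion) || depth_dispersion <= 0))
    stop("'depth_dispersion' must be positive or \"poisson\"")
  if (seq_error < 0 || seq_error >= 0.5) stop("'seq_error' must be in [0, 0.5)")
  if (missing_rate < 0 || missing_rate >= 1) stop("'missing_rate' must be in [0, 1)")
  if (residual_het < 0 || residual_het > 1) stop("'residual_het' must be in [0, 1]")
  if (hybrid_het < 0 || hybrid_het > 1) stop("'hybrid_het' must be in [0, 1]")
  structure(
    list(n_per_class = n, n_loci_total = n_loci_total,
         n_diagnostic = n_diagnostic, depth_mean = depth_mean,
         depth_dispersion = depth_dispersion, seq_error = seq_error,
         missing_rate = missing_rate, residual_het = residual_het,
         hybrid_het = hybrid_het,
         ploidy_coding = match.arg(ploidy_coding),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

# Run expr with a locally scoped RNG seed (global .Random.seed restored).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.draw_total_depth <- function(n, mean, dispersion) {
  if (identical(dispersion, "poisson")) stats::rpois(n, mean)
  else stats::rnbinom(n, mu = mean, size = dispersion)
}

# Dosage proportion of the L allele per class.
.p_L <- c(LL = 1, RR = 0, LR = 1 / 2, LLR = 2 / 3, LRR = 1 / 3)

#' Simulate a genotyped cohort with ground truth
#'
#' Generates a [genotype_matrix()] (with per-allele depths), a population map
#' marking the parental individuals as reference panels, a truth table and the
#' planted diagnostic panel. At each diagnostic locus the L and R genomes are
#' fixed for different alleles; allele depths are multinomial over the two
#' alleles with probabilities proportional to genome dosage, perturbed by the
#' configured sequencing error. Genotype calls reflect the true genome
#' composition (heterozygous iff both genomes contribute), so the error rate
#' perturbs depths only — mimicking a caller that does not call an allele on
#' stray reads.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_cohort` with elements `genotypes`
#'   ([genotype_matrix()]), `popmap`, `truth`
#'   (`sample`, `class`, `sex`, `population`), `panel` (the planted
#'   diagnostic loci with their L/R alleles) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n <- config$n_per_class
    cls <- rep(names(n), n)
    ids <- sprintf("%s%03d", cls, unlist(lapply(n, seq_len), use.names = FALSE))
    ns <- length(ids)
    nl <- config$n_loci_total
    loci <- sprintf("tag%05d:%d", seq_len(nl), seq_len(nl))
    diag_idx <- sort(sample.int(nl, config$n_diagnostic))
    is_diag <- seq_len(nl) %in% diag_idx

    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, nl, replace = TRUE)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))
    # registered alleles per locus; at diagnostic loci orientation is random
    L_is_ref <- stats::runif(nl) < 0.5
    ref <- ifelse(L_is_ref, a1, a2)
    alt <- ifelse(L_is_ref, a2, a1)
    L_al <- a1
    R_al <- a2
    alleles <- mapply(function(r, a) c(r, a), ref, alt, SIMPLIFY = FALSE)
    names(alleles) <- loci

    geno <- matrix(NA_character_, nl, ns, dimnames = list(loci, ids))
    depth <- matrix(NA_character_, nl, ns, dimnames = list(loci, ids))
    eps <- config$seq_error
    pL_eff <- .p_L * (1 - eps) + (1 - .p_L) * eps

    het_p <- ifelse(cls %in% c("LL", "RR"), config$residual_het,
                    config$hybrid_het)

    for (i in seq_len(nl)) {
      tot <- .draw_total_depth(ns, config$depth_mean, config$depth_dispersion)
      if (is_diag[i]) {
        dL <- stats::rbinom(ns, tot, pL_eff[cls])
        dR <- tot - dL
        call_by_class <- vapply(
          names(n), function(cl)
            .dosage_call(cl, L_al[i], R_al[i], config$ploidy_coding),
          character(1))
        geno[i, ] <- call_by_class[cls]
        depth[i, ] <- if (L_is_ref[i]) sprintf("%d,%d", dL, dR)
                      else sprintf("%d,%d", dR, dL)
      } else {
        het <- stats::runif(ns) < het_p
        g <- ifelse(het,
                    paste(pmin(a1[i], a2[i]), pmax(a1[i], a2[i]), sep = "/"),
                    paste(a1[i], a1[i], sep = "/"))
        d1 <- ifelse(het, stats::rbinom(ns, tot, 0.5), tot)
        d2 <- tot - d1
        geno[i, ] <- g
        dref <- if (ref[i] == a1[i]) d1 else d2
        dalt <- tot - dref
        depth[i, ] <- sprintf("%d,%d", dref, dalt)
      }
    }

    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(nl * ns) < config$missing_rate, nl, ns)
      geno[drop] <- NA_character_
      depth[drop] <- NA_character_
    }

    gm <- genotype_matrix(geno, depth = depth, alleles = alleles,
                          validate = FALSE)
    popmap <- data.frame(
      sample = ids, population = "SIM1",
      taxon_hint = ifelse(cls == "LL", "LL_REF",
                          ifelse(cls == "RR", "RR_REF", "UNKNOWN")),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      sample = ids, class = cls,
      sex = sample(c("F", "M"), ns, replace = TRUE),
      population = "SIM1", stringsAsFactors = FALSE)
    panel <- data.frame(
      locus = loci[diag_idx], L_allele = L_al[diag_idx],
      R_allele = R_al[diag_idx], stringsAsFactors = FALSE)
    panel <- panel[order(panel$locus), , drop = FALSE]
    rownames(panel) <- NULL
    structure(list(genotypes = gm, popmap = popmap, truth = truth,
                   panel = panel, config = config),
              class = "sim_cohort")
  })
}

# Genotype-call string for a class at a diagnostic locus.
.dosage_call <- function(class, L, R, coding) {
  copies <- switch(class,
    LL = c(L, L), RR = c(R, R), LR = c(L, R),
    LLR = c(L, L, R), LRR = c(L, R, R))
  if (coding == "diploid") copies <- unique(copies)
  if (length(copies) == 1L) copies <- c(copies, copies)
  paste(sort(copies), collapse = "/")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>\n")
  print(table(class = x$truth$class))
  cat("loci:", length(x$genotypes$loci),
      "(diagnostic:", nrow(x$panel), ")\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the cohort in the package's interchange formats: a VCF with `GT`/`AD`,
#' a population-map TSV, a truth TSV and the planted diagnostic panel TSV.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_sim_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    popmap = file.path(dir, "popmap.tsv"),
    truth = file.path(dir, "truth.tsv"),
    panel = file.path(dir, "panel_truth.tsv"))
  write_vcf_with_depths(cohort$genotypes, paths["vcf"])
  write_population_map(cohort$popmap, paths["popmap"])
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$panel, paths["panel"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
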