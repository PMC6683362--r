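#' Per-locus allele coverage ratio
#'
#' The dosage statistic of the RAD approach: the ratio of the highest
#' per-allele read depth over the lowest at a diagnostic locus. It tends
#' towards 1 in diploid LR hybrids (alleles present in equal copy) and
#' towards 2 in LLR/LRR triploids (one genome present in double copy).
#'
#' @param depth_a,depth_b integer read depths of the two alleles (both >= 1).
#' @return `max / min` as a numeric >= 1 (vectorized).
#' @export
locus_coverage_ratio <- function(depth_a, depth_b) {
  if (any(depth_a < 1) || any(depth_b < 1))
    stop("locus_coverage_ratio needs both depths >= 1; ",
         "zero-depth loci are excluded upstream by the min-depth policy")
  pmax(depth_a, depth_b) / pmin(depth_a, depth_b)
}

#' Dosage profile of one individual over a diagnostic panel
#'
#' Collects, for one sample, every panel locus where (i) the genotype is
#' called and contains both the panel's L and R alleles, and (ii) both allele
#' depths are recorded and at least `min_depth_per_allele` (a heterozygote
#' with a zero-depth allele is indistinguishable from allelic dropout, so
#' such loci are excluded rather than imputed). Three summary statistics are
#' computed: `mean_ratio`, the arithmetic mean of per-locus max/min ratios
#' (the statistic the field reports); `pooled_ratio`, the max/min ratio of
#' depths summed over loci (lower variance); and `mean_log2_LR`, the mean of
#' `log2(depth_L / depth_R)`, whose sign separates LLR (positive) from LRR
#' (negative).
#'
#' @param gm a [genotype_matrix()] with depths.
#' @param panel panel from [find_diagnostic_loci()] (columns `locus`,
#'   `L_allele`, `R_allele`).
#' @param sample_id one sample identifier present in `gm`.
#' @param min_depth_per_allele minimum depth per allele for a locus to be
#'   used.
#' @param min_loci minimum usable loci for a ploidy call; below the floor the
#'   call is `UNDETERMINED`.
#' @param diploid_max,triploid_min classification thresholds, see
#'   [classify_ploidy()].
#' @return an object of class `dosage_profile`: a list with `sample_id`,
#'   `loci` (per-locus data.frame `locus`, `depth_L`, `depth_R`, `ratio`),
#'   `n_loci_used`, `mean_ratio`, `pooled_ratio`, `mean_log2_LR`, `call`.
#' @export
individual_dosage_profile <- function(gm, panel, sample_id,
                                      min_depth_per_allele = 3L,
                                      min_loci = 20L,
                                      diploid_max = 1.4,
                                      triploid_min = 1.7) {
  if (!nrow(panel)) stop("panel is empty")
  if (!sample_id %in% gm$samples) stop("unknown sample: ", sample_id)
  if (is.null(gm$depth))
    stop("genotype matrix carries no allele depths; dosage needs AD")
  loci <- panel$locus
  if (!all(loci %in% gm$loci)) stop("panel loci absent from genotype matrix")
  g <- gm$geno[loci, sample_id]
  d <- gm$depth[loci, sample_id]
  parts <- .split_calls(g)
  dL <- dR <- rep(NA_integer_, length(loci))
  for (i in seq_along(loci)) {
    if (is.na(g[i]) || is.na(d[i])) next
    p <- parts[[i]]
    if (!(panel$L_allele[i] %in% p) || !(panel$R_allele[i] %in% p)) next
    reg <- gm$alleles[[loci[i]]]
    ad <- .parse_depth_cell(d[i], reg)
    dL[i] <- ad[[panel$L_allele[i]]]
    dR[i] <- ad[[panel$R_allele[i]]]
  }
  usable <- !is.na(dL) & !is.na(dR) &
    dL >= min_depth_per_allele & dR >= min_depth_per_allele
  per_locus <- data.frame(
    locus = loci[usable], depth_L = dL[usable], depth_R = dR[usable],
    stringsAsFactors = FALSE)
  per_locus$ratio <- if (nrow(per_locus))
    locus_coverage_ratio(per_locus$depth_L, per_locus$depth_R) else numeric(0)
  n_used <- nrow(per_locus)
  prof <- structure(list(
    sample_id = sample_id,
    loci = per_locus,
    n_loci_used = n_used,
    mean_ratio = if (n_used) mean(per_locus$ratio) else NA_real_,
    pooled_ratio = if (n_used) {
      sL <- sum(per_locus$depth_L); sR <- sum(per_locus$depth_R)
      max(sL, sR) / min(sL, sR)
    } else NA_real_,
    mean_log2_LR = if (n_used)
      mean(log2(per_locus$depth_L / per_locus$depth_R)) else NA_real_,
    min_loci = as.integer(min_loci),
    call = "UNDETERMINED"), class = "dosage_profile")
  prof$call <- classify_ploidy(prof, diploid_max = diploid_max,
                               triploid_min = triploid_min)
  prof
}

#' Classify ploidy from a dosage profile
#'
#' Rule-based call on the mean per-locus coverage ratio: `DIPLOID_LR` when
#' `mean_ratio <= diploid_max`; a triploid call when
#' `mean_ratio >= triploid_min`, directed by the sign of `mean_log2_LR`
#' (`TRIPLOID_LLR` when positive, `TRIPLOID_LRR` when negative);
#' `UNDETERMINED` otherwise, including profiles below the usable-locus floor
#' and an exactly zero `mean_log2_LR` in the triploid band. The band between
#' the thresholds avoids forcing borderline calls: observed diploids span
#' roughly 1.0–1.3 while the triploid expectation is 2.
#'
#' @param profile a [individual_dosage_profile()] result.
#' @param diploid_max upper mean-ratio bound for a diploid call.
#' @param triploid_min lower mean-ratio bound for a triploid call; must
#'   exceed `diploid_max`.
#' @return one of `"DIPLOID_LR"`, `"TRIPLOID_LLR"`, `"TRIPLOID_LRR"`,
#'   `"UNDETERMINED"`.
#' @export
classify_ploidy <- function(profile, diploid_max = 1.4, triploid_min = 1.7) {
  if (diploid_max >= triploid_min)
    stop("configuration error: 'diploid_max' must be < 'triploid_min'")
  stopifnot(inherits(profile, "dosage_profile"))
  if (profile$n_loci_used < profile$min_loci) return("UNDETERMINED")
  m <- profile$mean_ratio
  if (m <= diploid_max) return("DIPLOID_LR")
  if (m >= triploid_min) {
    s <- profile$mean_log2_LR
    if (s > 0) return("TRIPLOID_LLR")
    if (s < 0) return("TRIPLOID_LRR")
  }
  "UNDETERMINED"
}

#' Likelihood-based ploidy call from allele depths
#'
#' Model-based companion to the ratio heuristic: under genome dosage the
#' L-allele depth at a diagnostic locus is binomial with success probability
#' 1/2 (LR), 2/3 (LLR) or 1/3 (LRR) of the total, adjusted for a symmetric
#' per-read error `error` (`p' = p (1 - error) + (1 - p) error`). Per-class
#' log-likelihoods sum the binomial log-pmf over the profile's usable loci.
#' The maximum-likelihood class is reported alongside — never overriding —
#' the heuristic call.
#'
#' @param profile a [individual_dosage_profile()] result.
#' @param error per-read cross-allele error rate in `[0, 0.5)`.
#' @return a list of class `dosage_likelihood` with `loglik` (named numeric
#'   over `DIPLOID_LR`, `TRIPLOID_LLR`, `TRIPLOID_LRR`) and `ml_class`
#'   (`NA` when the profile has no usable loci).
#' @export
dosage_likelihood_call <- function(profile, error = 0) {
  stopifnot(inherits(profile, "dosage_profile"))
  if (error < 0 || error >= 0.5) stop("'error' must be in [0, 0.5)")
  p <- c(DIPLOID_LR = 1 / 2, TRIPLOID_LLR = 2 / 3, TRIPLOID_LRR = 1 / 3)
  padj <- p * (1 - error) + (1 - p) * error
  if (!profile$n_loci_used) {
    return(structure(list(loglik = stats::setNames(rep(NA_real_, 3), names(p)),
                          ml_class = NA_character_),
                     class = "dosage_likelihood"))
  }
  dL <- profile$loci$depth_L
  tot <- dL + profile$loci$depth_R
  ll <- vapply(padj, function(pp) sum(stats::dbinom(dL, tot, pp, log = TRUE)),
               numeric(1))
  structure(list(loglik = ll, ml_class = names(ll)[which.max(ll)]),
            class = "dosage_likelihood")
}

#' @export
print.dosage_profile <- function(x, ...) {
  cat("<dosage_profile> ", x$sample_id, "\n", sep = "")
  cat(sprintf("  loci used: %d | mean ratio: %.3f | pooled ratio: %.3f | mean log2(L/R): %+.3f\n",
              x$n_loci_used,
              ifelse(is.na(x$mean_ratio), NaN, x$mean_ratio),
              ifelse(is.na(x$pooled_ratio), NaN, x$pooled_ratio),
              ifelse(is.na(x$mean_log2_LR), NaN, x$mean_log2_LR)))
  cat("  call:", x$call, "\n")
  invisible(x)
}

#' Dosage report for a set of samples
#'
#' Convenience wrapper running [individual_dosage_profile()] and
#' [dosage_likelihood_call()] over samples and assembling the per-sample
#' summary table the pipeline writes.
#'
#' @inheritParams individual_dosage_profile
#' @param samples sample identifiers (default: all samples of `gm`).
#' @param error error rate passed to [dosage_likelihood_call()].
#' @return data.frame with columns `sample`, `n_loci_used`, `mean_ratio`,
#'   `pooled_ratio`, `mean_log2_LR`, `call`, `ml_call`.
#' @export
dosage_report <- function(gm, panel, samples = gm$samples,
                          min_depth_per_allele = 3L, min_loci = 20L,
                          diploid_max = 1.4, triploid_min = 1.7,
                          error = 0.01) {
  rows <- lapply(samples, function(s) {
    pr <- individual_dosage_profile(gm, panel, s,
                                    min_depth_per_allele = min_depth_per_allele,
                                    min_loci = min_loci,
                                    diploid_max = diploid_max,
                                    triploid_min = triploid_min)
    ml <- dosage_likelihood_call(pr, error = error)
    data.frame(sample = s, n_loci_used = pr$n_loci_used,
               mean_ratio = pr$mean_ratio, pooled_ratio = pr$pooled_ratio,
               mean_log2_LR = pr$mean_log2_LR, call = pr$call,
               ml_call = ifelse(is.na(ml$ml_class), "UNDETERMINED",
                                ml$ml_class),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
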