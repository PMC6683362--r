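#' Discover species-diagnostic loci from parental reference panels
#'
#' A locus is diagnostic when the two parental reference groups are fixed for
#' different alleles — an allele frequency difference of 1.0 between the
#' `LL_REF` (*P. lessonae*-type) and `RR_REF` (*P. ridibundus*-type) samples.
#' Fixation is evaluated on non-missing reference genotypes only: all called
#' LL references must be homozygous for one allele `a`, all called RR
#' references homozygous for a different allele `b`, and each group must
#' contribute at least `min_ref_called` called samples. The locus is then
#' oriented `L_allele = a`, `R_allele = b`. Hybrid and `UNKNOWN` samples are
#' ignored during discovery (they are the inference targets).
#'
#' @param gm a [genotype_matrix()].
#' @param pm a population map (see [read_population_map()]) with at least one
#'   `LL_REF` and one `RR_REF` sample present in `gm`.
#' @param min_ref_called minimum called reference samples per group.
#' @param require_biallelic admit only loci with at most two registered
#'   alleles (SNP-matrix practice); with `FALSE`, multiallelic sites qualify
#'   whenever the two groups are each fixed for distinct alleles.
#' @return a data.frame of class `diagnostic_panel` with columns `locus`,
#'   `L_allele`, `R_allele`, `n_LL_called`, `n_RR_called`, sorted by locus id.
#'   An empty panel is returned with a warning, not an error.
#' @export
find_diagnostic_loci <- function(gm, pm, min_ref_called = 3L,
                                 require_biallelic = TRUE) {
  pm <- validate_population_map(pm)
  ll <- intersect(pm$sample[pm$taxon_hint == "LL_REF"], gm$samples)
  rr <- intersect(pm$sample[pm$taxon_hint == "RR_REF"], gm$samples)
  if (!length(ll) || !length(rr))
    stop("diagnostic discovery needs at least one LL_REF and one RR_REF ",
         "sample present in the genotype matrix")
  keep <- logical(length(gm$loci))
  La <- Ra <- character(length(gm$loci))
  nL <- nR <- integer(length(gm$loci))
  for (i in seq_along(gm$loci)) {
    if (require_biallelic && length(gm$alleles[[i]]) > 2L) next
    gl <- gm$geno[i, ll]
    gl <- gl[!is.na(gl)]
    if (length(gl) < min_ref_called) next
    gr <- gm$geno[i, rr]
    gr <- gr[!is.na(gr)]
    if (length(gr) < min_ref_called) next
    a <- .fixed_hom_allele(gl)
    if (is.na(a)) next
    b <- .fixed_hom_allele(gr)
    if (is.na(b) || a == b) next
    keep[i] <- TRUE
    La[i] <- a; Ra[i] <- b
    nL[i] <- length(gl); nR[i] <- length(gr)
  }
  panel <- data.frame(locus = gm$loci[keep], L_allele = La[keep],
                      R_allele = Ra[keep], n_LL_called = nL[keep],
                      n_RR_called = nR[keep], stringsAsFactors = FALSE)
  panel <- panel[order(panel$locus), , drop = FALSE]
  rownames(panel) <- NULL
  if (!nrow(panel))
    warning("no diagnostic loci found; panel is empty")
  class(panel) <- c("diagnostic_panel", "data.frame")
  panel
}

# Unique allele if all calls in 'g' are homozygous for the same allele,
# else NA.
.fixed_hom_allele <- function(g) {
  u <- unique(unlist(.split_calls(g)))
  if (length(u) == 1L) u else NA_character_
}

#' Per-sample coverage of a diagnostic panel
#'
#' Counts, for every sample, the panel loci with a called genotype and those
#' whose call also has recorded allele depths — used to flag samples too
#' sparse for a dosage call.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a non-empty panel from [find_diagnostic_loci()].
#' @return data.frame with columns `sample`, `n_called`, `n_with_depth`.
#' @export
panel_coverage_report <- function(gm, panel) {
  if (!nrow(panel)) stop("panel is empty")
  if (!all(panel$locus %in% gm$loci))
    stop("panel loci absent from the genotype matrix")
  sub <- gm$geno[panel$locus, , drop = FALSE]
  called <- !is.na(sub)
  n_called <- colSums(called)
  n_depth <- if (is.null(gm$depth)) rep(0L, length(gm$samples)) else {
    d <- gm$depth[panel$locus, , drop = FALSE]
    colSums(called & !is.na(d))
  }
  data.frame(sample = gm$samples, n_called = as.integer(n_called),
             n_with_depth = as.integer(n_depth), row.names = NULL,
             stringsAsFactors = FALSE)
}
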