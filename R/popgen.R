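#' Per-individual observed heterozygosity
#'
#' Fraction of called loci at which an individual's genotype contains at
#' least two distinct alleles. Computed on genotype calls (not depths); loci
#' monomorphic within a group are included.
#'
#' @param gm a [genotype_matrix()].
#' @param loci optional character vector restricting the computation (e.g. a
#'   diagnostic panel's loci); default all loci.
#' @return data.frame `sample`, `n_called`, `n_het`, `het` (`NA` when no
#'   locus is called).
#' @export
individual_heterozygosity <- function(gm, loci = NULL) {
  if (is.null(loci)) loci <- gm$loci
  if (!all(loci %in% gm$loci)) stop("unknown locus identifier(s)")
  sub <- gm$geno[loci, , drop = FALSE]
  n_called <- integer(length(gm$samples))
  n_het <- integer(length(gm$samples))
  for (j in seq_along(gm$samples)) {
    g <- sub[, j]
    called <- !is.na(g)
    n_called[j] <- sum(called)
    if (n_called[j]) {
      parts <- .split_calls(g[called])
      n_het[j] <- sum(vapply(parts, function(p) length(unique(p)) > 1L,
                             logical(1)))
    }
  }
  data.frame(sample = gm$samples, n_called = n_called, n_het = n_het,
             het = ifelse(n_called > 0, n_het / n_called, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Average observed heterozygosity per population and taxon
#'
#' Mirrors the standard population summary: per-individual observed
#' heterozygosity (heterozygous called loci / called loci) averaged within
#' each `(population, taxon)` group, reported only for groups of at least
#' `min_n` individuals — smaller groups are omitted with a message, never
#' silently.
#'
#' @param gm a [genotype_matrix()].
#' @param groups data.frame with columns `sample`, `population`, `taxon`
#'   (taxon from [hybrid_index()] calls or user labels).
#' @param min_n minimum group size.
#' @param loci optional locus restriction (default: all loci, the
#'   genome-wide scope).
#' @return data.frame `population`, `taxon`, `n`, `H_o`.
#' @export
observed_heterozygosity <- function(gm, groups, min_n = 5L, loci = NULL) {
  if (!length(gm$loci) || !length(gm$samples)) stop("empty genotype matrix")
  need <- c("sample", "population", "taxon")
  if (!all(need %in% names(groups)))
    stop("groups must have columns: ", paste(need, collapse = ", "))
  ih <- individual_heterozygosity(gm, loci = loci)
  df <- merge(groups[, need], ih, by = "sample")
  df <- df[!is.na(df$het), , drop = FALSE]
  if (!nrow(df)) stop("no individuals with called genotypes")
  agg <- stats::aggregate(het ~ population + taxon, data = df,
                          FUN = function(x) c(n = length(x), H_o = mean(x)))
  out <- data.frame(population = agg$population, taxon = agg$taxon,
                    n = as.integer(agg$het[, "n"]), H_o = agg$het[, "H_o"],
                    stringsAsFactors = FALSE)
  small <- out$n < min_n
  if (any(small))
    message("omitting ", sum(small), " group(s) with n < ", min_n, ": ",
            paste(paste0(out$population[small], "/", out$taxon[small]),
                  collapse = ", "))
  out <- out[!small, , drop = FALSE]
  out <- out[order(out$population, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diagnostic-locus hybrid index and taxon assignment
#'
#' For each sample, the fractions of called panel loci that are heterozygous
#' L/R, homozygous for the L allele, and homozygous for the R allele (they
#' sum to 1). Taxon calls follow simple thresholds: `LL` when
#' `frac_homL >= pure_min`, `RR` when `frac_homR >= pure_min`, `LR` when
#' `frac_het >= het_min`, otherwise `AMBIGUOUS` — a deliberately transparent
#' stand-in for Bayesian ancestry clustering, sufficient because diagnostic
#' loci are fixed between the parental genomes. The thresholds are working
#' constants chosen to tolerate genotyping error and missing data, not
#' published values.
#'
#' @param gm a [genotype_matrix()].
#' @param panel panel from [find_diagnostic_loci()].
#' @param samples sample identifiers (default all).
#' @param pure_min minimum homozygous fraction for a parental call.
#' @param het_min minimum heterozygous fraction for a hybrid call.
#' @return data.frame `sample`, `n_panel_called`, `frac_het`, `frac_homL`,
#'   `frac_homR`, `taxon_call`.
#' @export
hybrid_index <- function(gm, panel, samples = gm$samples,
                         pure_min = 0.9, het_min = 0.9) {
  if (!nrow(panel)) stop("panel is empty")
  if (!all(samples %in% gm$samples)) stop("unknown sample identifier(s)")
  loci <- panel$locus
  rows <- lapply(samples, function(s) {
    g <- gm$geno[loci, s]
    parts <- .split_calls(g)
    hasL <- hasR <- logical(length(loci))
    for (i in seq_along(loci)) {
      if (is.na(g[i])) next
      hasL[i] <- panel$L_allele[i] %in% parts[[i]]
      hasR[i] <- panel$R_allele[i] %in% parts[[i]]
    }
    informative <- hasL | hasR
    n <- sum(informative)
    if (!n) {
      return(data.frame(sample = s, n_panel_called = 0L, frac_het = NA_real_,
                        frac_homL = NA_real_, frac_homR = NA_real_,
                        taxon_call = "AMBIGUOUS", stringsAsFactors = FALSE))
    }
    fh <- sum(hasL & hasR) / n
    fl <- sum(hasL & !hasR) / n
    fr <- sum(hasR & !hasL) / n
    call <- if (fl >= pure_min) "LL"
            else if (fr >= pure_min) "RR"
            else if (fh >= het_min) "LR"
            else "AMBIGUOUS"
    data.frame(sample = s, n_panel_called = n, frac_het = fh,
               frac_homL = fl, frac_homR = fr, taxon_call = call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
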