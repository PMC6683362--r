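# Independent oracles and fixture builders shared by the test files.

# Brute-force diagnostic scan: per locus, tabulate allele frequencies in each
# reference group directly and require a frequency difference of exactly 1.0
# (each group monomorphic, for different alleles). Deliberately written via
# frequency tables, not the package's homozygosity short-cut.
oracle_panel <- function(gm, pm, min_ref_called = 3L, require_biallelic = TRUE) {
  ll <- pm$sample[pm$taxon_hint == "LL_REF"]
  rr <- pm$sample[pm$taxon_hint == "RR_REF"]
  hits <- character(0)
  ori <- list()
  for (loc in gm$loci) {
    if (require_biallelic && length(gm$alleles[[loc]]) > 2L) next
    freqs <- function(samples) {
      g <- gm$geno[loc, samples]
      g <- g[!is.na(g)]
      if (!length(g)) return(list(n = 0L, tab = table(character(0))))
      list(n = length(g), tab = table(unlist(strsplit(g, "/", fixed = TRUE))))
    }
    fl <- freqs(ll); fr <- freqs(rr)
    if (fl$n < min_ref_called || fr$n < min_ref_called) next
    pl <- fl$tab / sum(fl$tab)
    pr <- fr$tab / sum(fr$tab)
    fixed_l <- names(pl)[pl == 1]
    fixed_r <- names(pr)[pr == 1]
    if (length(fixed_l) == 1L && length(fixed_r) == 1L &&
        fixed_l != fixed_r) {
      hits <- c(hits, loc)
      ori[[loc]] <- c(L = fixed_l, R = fixed_r)
    }
  }
  hits <- sort(hits)
  data.frame(locus = hits,
             L_allele = vapply(hits, function(l) ori[[l]][["L"]], character(1)),
             R_allele = vapply(hits, function(l) ori[[l]][["R"]], character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Random small genotype matrix + popmap for oracle-equivalence testing.
# Plants a few truly fixed loci in half the draws so both outcomes occur.
random_ref_matrix <- function(n_loci = 30L, n_ll = 4L, n_rr = 4L,
                              plant = TRUE, missing_rate = 0.15) {
  bases <- c("A", "C", "G", "T")
  loci <- sprintf("loc%03d:%d", seq_len(n_loci), seq_len(n_loci))
  samples <- c(sprintf("LLs%02d", seq_len(n_ll)),
               sprintf("RRs%02d", seq_len(n_rr)))
  alleles <- list()
  geno <- matrix(NA_character_, n_loci, n_ll + n_rr,
                 dimnames = list(loci, samples))
  for (i in seq_len(n_loci)) {
    al <- sample(bases, 2L)
    alleles[[loci[i]]] <- al
    if (plant && stats::runif(1) < 0.2) {
      geno[i, ] <- c(rep(paste(al[1L], al[1L], sep = "/"), n_ll),
                     rep(paste(al[2L], al[2L], sep = "/"), n_rr))
    } else {
      draw <- function() {
        g <- sample(al, 2L, replace = TRUE)
        paste(sort(g), collapse = "/")
      }
      geno[i, ] <- replicate(n_ll + n_rr, draw())
    }
    drop <- stats::runif(n_ll + n_rr) < missing_rate
    geno[i, drop] <- NA_character_
  }
  pm <- data.frame(sample = samples, population = "POP1",
                   taxon_hint = rep(c("LL_REF", "RR_REF"), c(n_ll, n_rr)),
                   stringsAsFactors = FALSE)
  list(gm = genotype_matrix(geno, alleles = alleles), pm = pm)
}

# Independent enumeration of a cross: expand every (egg, sperm) pair from the
# two gamete distributions by hand and tabulate offspring compositions.
oracle_cross_pre <- function(egg_dist, sperm_dist) {
  out <- list()
  for (e in names(egg_dist)) {
    for (s in names(sperm_dist)) {
      toks <- sort(c(regmatches(e, gregexpr("[LR][xy]", e))[[1L]],
                     regmatches(s, gregexpr("[LR][xy]", s))[[1L]]))
      key <- paste(toks, collapse = "")
      out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) +
        unname(egg_dist[[e]] * sperm_dist[[s]])
    }
  }
  v <- unlist(out)
  v[sort(names(v))]
}

# Tiny hand-written VCF fixture.
write_tiny_vcf <- function(path, body_lines,
                           samples = c("S1", "S2"),
                           format = "GT:AD") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}
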