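#' Construct a genotype matrix with per-allele read depths
#'
#' The central container of the package: a loci-by-samples matrix of genotype
#' calls together with (optional) per-allele read depths, as exported from a
#' RAD-seq SNP-calling pipeline. Genotype calls are unordered allele lists
#' written `"A/G"` (any ploidy); depths are comma-joined integers aligned with
#' the locus's registered allele vector (reference allele first), exactly as a
#' VCF `AD` field.
#'
#' @param geno character matrix, loci in rows, samples in columns; entries are
#'   allele identifiers joined by `"/"` (e.g. `"A/G"`, `"A/A/G"`) or `NA` for
#'   a missing call. Must have unique row and column names.
#' @param depth optional character matrix of the same shape; entries are
#'   comma-joined non-negative integer depths, one per registered allele of
#'   the locus, or `NA` when no depth was recorded for the cell.
#' @param alleles named list, one character vector of registered allele
#'   identifiers per locus (first element is the reference allele). Names must
#'   equal `rownames(geno)`.
#' @param validate check the container invariants (uniqueness of identifiers,
#'   every called allele registered, depth vectors aligned with allele sets).
#'
#' @return an object of class `genotype_matrix`: a list with elements
#'   `samples`, `loci`, `alleles`, `geno`, `depth`.
#' @seealso [read_vcf_with_depths()], [simulate_cohort()]
#' @export
genotype_matrix <- function(geno, depth = NULL, alleles, validate = TRUE) {
  if (!is.matrix(geno) || !is.character(geno))
    stop("'geno' must be a character matrix (loci x samples)")
  loci <- rownames(geno)
  samples <- colnames(geno)
  if (is.null(loci) || is.null(samples))
    stop("'geno' must have locus rownames and sample colnames")
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(loci))
    stop("duplicate locus identifiers: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  if (!is.list(alleles) || !identical(sort(names(alleles)), sort(loci)))
    stop("'alleles' must be a named list covering exactly the loci of 'geno'")
  alleles <- alleles[loci]
  if (!is.null(depth)) {
    if (!is.matrix(depth) || !identical(dim(depth), dim(geno)))
      stop("'depth' must be a character matrix with the same shape as 'geno'")
    dimnames(depth) <- dimnames(geno)
    if (!is.character(depth)) storage.mode(depth) <- "character"
  }
  gm <- structure(
    list(samples = samples, loci = loci, alleles = alleles,
         geno = geno, depth = depth),
    class = "genotype_matrix")
  if (validate) validate_genotype_matrix(gm)
  gm
}

#' Validate the invariants of a genotype matrix
#'
#' Checks that every allele appearing in a genotype call is registered for its
#' locus, and that depth entries, where present, carry one integer per
#' registered allele. Missing genotypes impose no depth requirement.
#'
#' @param gm a [genotype_matrix()].
#' @return `gm`, invisibly; stops with an informative error on violation.
#' @export
validate_genotype_matrix <- function(gm) {
  for (i in seq_along(gm$loci)) {
    loc <- gm$loci[i]
    reg <- gm$alleles[[i]]
    g <- gm$geno[i, ]
    called <- !is.na(g)
    if (any(called)) {
      used <- unique(unlist(strsplit(g[called], "/", fixed = TRUE)))
      bad <- setdiff(used, reg)
      if (length(bad))
        stop("locus ", loc, ": allele(s) ", paste(bad, collapse = ", "),
             " appear in genotype calls but are not registered")
    }
    if (!is.null(gm$depth)) {
      d <- gm$depth[i, ]
      has <- !is.na(d)
      if (any(has)) {
        parsed <- strsplit(d[has], ",", fixed = TRUE)
        if (any(lengths(parsed) != length(reg)))
          stop("locus ", loc, ": depth entries must list one value per ",
               "registered allele (", length(reg), ")")
        vals <- suppressWarnings(as.integer(unlist(parsed)))
        if (anyNA(vals) || any(vals < 0))
          stop("locus ", loc, ": depths must be non-negative integers")
      }
    }
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$samples), " samples x ",
      length(x$loci), " loci", sep = "")
  cat(if (is.null(x$depth)) " (no depths)\n" else " (with allele depths)\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$loci), length(x$samples))

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm a [genotype_matrix()].
#' @param samples,loci character vectors of identifiers to keep (default all).
#' @return a [genotype_matrix()] restricted to the requested cells.
#' @export
gm_subset <- function(gm, samples = gm$samples, loci = gm$loci) {
  if (!all(samples %in% gm$samples)) stop("unknown sample identifier(s)")
  if (!all(loci %in% gm$loci)) stop("unknown locus identifier(s)")
  genotype_matrix(
    geno = gm$geno[loci, samples, drop = FALSE],
    depth = if (!is.null(gm$depth)) gm$depth[loci, samples, drop = FALSE],
    alleles = gm$alleles[loci],
    validate = FALSE)
}

# Parse one depth cell ("10,12") into a named integer vector over the locus's
# registered alleles; NA cell -> NULL.
.parse_depth_cell <- function(d, reg) {
  if (is.na(d)) return(NULL)
  v <- suppressWarnings(as.integer(strsplit(d, ",", fixed = TRUE)[[1L]]))
  names(v) <- reg
  v
}

# Split genotype calls into allele vectors; NA stays NA element.
.split_calls <- function(g) strsplit(g, "/", fixed = TRUE)
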