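#' Read a VCF file into a genotype matrix with allele depths
#'
#' Ingests the `GT` and `AD` fields of a VCF 4.x file (the usual export of a
#' RAD-seq SNP caller) into a [genotype_matrix()]. Both biallelic and
#' multiallelic sites are accepted; genotype ploidy is taken as written in the
#' `GT` string, so diploid (`0/1`) and triploid (`0/0/1`) calls both round-trip
#' — the latter matter for simulated truth files. Missing calls (`./.`) are
#' stored as missing and impose no depth requirement. Locus identifiers are
#' `CHROM:POS` (1-based, as in the VCF standard).
#'
#' Parsing itself is delegated to \pkg{vcfR}; a light structural pre-scan runs
#' first so that a malformed data line is reported with its line number.
#'
#' @param path path to a VCF text file (plain or gzipped).
#' @param require_depths error if the file carries no `AD` field; with
#'   `FALSE`, files without depths load with `depth = NULL` and depth-based
#'   analyses will skip.
#' @return a [genotype_matrix()].
#' @export
read_vcf_with_depths <- function(path, require_depths = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L)
    stop("not a VCF file (expected exactly one #CHROM header line): ", path)
  ncol_expect <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]])
  if (ncol_expect < 10L)
    stop("VCF has no sample columns: ", path)
  body <- seq(hdr + 1L, length.out = length(lines) - hdr)
  if (length(body)) {
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nf != ncol_expect & nzchar(trimws(lines[body]))]
    if (length(bad))
      stop("malformed VCF line ", bad[1L], " in ", path,
           ": expected ", ncol_expect, " tab-separated fields")
  }
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("VCF format error: GT field absent in ", path)
  has_ad <- all(grepl("(^|:)AD(:|$)", fmt))
  if (require_depths && !has_ad)
    stop("VCF format error: AD field required but absent in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- if (has_ad) vcfR::extract.gt(vcf, element = "AD") else NULL
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))   # single-variant files come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  loci <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  if (anyDuplicated(loci))
    stop("duplicate CHROM:POS in ", path, ": ",
         loci[duplicated(loci)][1L])
  alleles <- vector("list", length(loci))
  names(alleles) <- loci
  geno <- matrix(NA_character_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = list(loci, colnames(gt)))
  for (i in seq_along(loci)) {
    alt <- fix[i, "ALT"]
    alts <- if (is.na(alt) || alt == ".") character(0)
            else strsplit(alt, ",", fixed = TRUE)[[1L]]
    al <- unname(c(fix[i, "REF"], alts))
    alleles[[i]] <- al
    g <- gt[i, ]
    ok <- !is.na(g) & !grepl(".", g, fixed = TRUE)
    if (any(ok)) {
      idx <- .split_calls(gsub("|", "/", g[ok], fixed = TRUE))
      geno[i, ok] <- vapply(idx, function(p) {
        j <- as.integer(p) + 1L
        if (anyNA(j) || any(j < 1L) || any(j > length(al)))
          stop("allele index out of range at locus ", loci[i])
        paste(al[j], collapse = "/")
      }, character(1))
    }
  }
  if (!is.null(ad)) {
    ad[ad == "." | ad == ""] <- NA_character_
    ad[is.na(geno)] <- NA_character_
    dimnames(ad) <- dimnames(geno)
  }
  genotype_matrix(geno, depth = ad, alleles = alleles)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Inverse of [read_vcf_with_depths()]: emits VCF 4.2 with `GT` (and `AD`
#' when depths are stored). Locus identifiers of the form `CHROM:POS` are
#' split back into their coordinates; other identifiers are written as a
#' contig name with `POS = 1`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_with_depths <- function(gm, path) {
  fmt <- if (is.null(gm$depth)) "GT" else "GT:AD"
  meta <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=hybridogen_", as.character(utils::packageVersion("hybridogen"))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(gm$depth))
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  has_pos <- grepl(":[0-9]+$", gm$loci)
  chrom <- ifelse(has_pos, sub(":[0-9]+$", "", gm$loci), gm$loci)
  pos <- ifelse(has_pos, sub("^.*:", "", gm$loci), "1")
  rows <- character(length(gm$loci))
  for (i in seq_along(gm$loci)) {
    al <- gm$alleles[[i]]
    ref <- al[1L]
    alt <- if (length(al) > 1L) paste(al[-1L], collapse = ",") else "."
    g <- gm$geno[i, ]
    gt <- rep("./.", length(g))
    ok <- !is.na(g)
    if (any(ok)) {
      gt[ok] <- vapply(.split_calls(g[ok]), function(p)
        paste(match(p, al) - 1L, collapse = "/"), character(1))
    }
    cells <- gt
    if (!is.null(gm$depth)) {
      d <- gm$depth[i, ]
      d[is.na(d)] <- "."
      cells <- paste(gt, d, sep = ":")
    }
    rows[i] <- paste(c(chrom[i], pos[i], ".", ref, alt, ".", "PASS", ".",
                       fmt, cells), collapse = "\t")
  }
  writeLines(c(meta, rows), path)
  invisible(path)
}
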