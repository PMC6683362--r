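#' Calibrated peak-height-ratio ranges for triploid detection
#'
#' Genotype-specific calibration of the microsatellite peak-height ratio
#' (PHR), `log10(H_R / H_L)`: published ranges at a RICA1b5-analogous
#' genotype place diploid LR hybrids in `[-0.23, 0.00]`, LLR triploids at a
#' mean of -0.39 (range `[-0.54, -0.29]`, the duplicated L genome doubling
#' the L peak) and LRR triploids at 0.17 (range `[0.09, 0.25]`). The default
#' set applies those ranges to the 122/137 and 123/137 genotypes, the
#' near-identical profiles a Ticino-style survey compares; users may supply
#' their own calibration via [read_phr_calibration()].
#'
#' @return data.frame with columns `locus`, `genotype`, `class`, `phr_min`,
#'   `phr_max`, `mean`.
#' @export
phr_calibration <- function() {
  data.frame(
    locus = "RICA1b5",
    genotype = rep(c("122/137", "123/137"), each = 3),
    class = rep(c("LLR", "LR", "LRR"), 2),
    phr_min = rep(c(-0.54, -0.23, 0.09), 2),
    phr_max = rep(c(-0.29, 0.00, 0.25), 2),
    mean = rep(c(-0.39, NA, 0.17), 2),
    stringsAsFactors = FALSE)
}

#' Validate a PHR calibration table
#'
#' Ranges must satisfy `phr_min <= phr_max`, contain their mean when one is
#' given, and be pairwise disjoint within each `(locus, genotype)` set —
#' closed intervals, so even touching ranges are rejected: a boundary value
#' could not be classified uniquely.
#'
#' @param cal data.frame with columns `locus`, `genotype`, `class`,
#'   `phr_min`, `phr_max` and optionally `mean`.
#' @return the validated data.frame.
#' @export
validate_phr_calibration <- function(cal) {
  need <- c("locus", "genotype", "class", "phr_min", "phr_max")
  if (!all(need %in% names(cal)))
    stop("calibration must have columns: ", paste(need, collapse = ", "))
  if (is.null(cal$mean)) cal$mean <- NA_real_
  if (any(cal$phr_min > cal$phr_max))
    stop("calibration error: phr_min > phr_max")
  given <- !is.na(cal$mean)
  if (any(given & (cal$mean < cal$phr_min | cal$mean > cal$phr_max)))
    stop("calibration error: mean outside [phr_min, phr_max]")
  for (key in unique(paste(cal$locus, cal$genotype, sep = "\r"))) {
    sub <- cal[paste(cal$locus, cal$genotype, sep = "\r") == key, ]
    sub <- sub[order(sub$phr_min), ]
    if (nrow(sub) > 1L &&
        any(sub$phr_min[-1L] <= sub$phr_max[-nrow(sub)]))
      stop("configuration error: overlapping PHR calibration ranges for ",
           sub$locus[1L], " ", sub$genotype[1L])
  }
  cal
}

#' @rdname phr_calibration
#' @param path TSV with columns `locus`, `genotype`, `class`, `phr_min`,
#'   `phr_max`, `mean`.
#' @export
read_phr_calibration <- function(path) {
  cal <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  validate_phr_calibration(cal)
}

#' @rdname phr_calibration
#' @param cal calibration data.frame.
#' @export
write_phr_calibration <- function(cal, path) {
  cal <- validate_phr_calibration(cal)
  utils::write.table(cal, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect a tri-allelic microsatellite genotype
#'
#' A triploid carrying three distinct alleles at a co-amplifying locus shows
#' three peaks; with the strong L-allele diversity of these markers, LLR
#' individuals are expected to be caught this way.
#'
#' @param peaks data.frame slice for one sample at one locus, with columns
#'   `allele` and `height`.
#' @return `TRUE` iff at least 3 distinct allele sizes have recorded peaks.
#' @export
detect_triallelic <- function(peaks) {
  length(unique(peaks$allele)) >= 3L
}

#' Compute the peak-height ratio for one sample at one locus
#'
#' The PHR is `log10(H_R / H_L)` where `H_R` is the height of the R-specific
#' peak and `H_L` the height of the L-specific peak, computed only when the
#' pattern carries exactly one peak from each genome. Other patterns are
#' flagged instead of quantified: a single visible peak may hide a null
#' allele (`"single_peak"`), three or more peaks indicate a triploid
#' (`"triallelic"`), and two peaks from the same genome cannot be oriented
#' (`"same_genome"`). Peaks whose allele belongs to neither set are ignored
#' and reported.
#'
#' @param peaks data.frame slice for one sample at one locus, with columns
#'   `allele`, `height` (and optionally `sample`, `locus`, carried through).
#' @param L_alleles,R_alleles integer vectors of L- and R-specific allele
#'   sizes.
#' @param log_base base of the logarithm; base 10 keeps the copy-number-2
#'   signal at +/- 0.301, commensurate with the published calibration ranges.
#' @return an object of class `phr_result`: list with `sample`, `locus`,
#'   `L_allele`, `R_allele`, `H_L`, `H_R`, `phr`, `triallelic`, `pattern`,
#'   `ignored_alleles`.
#' @export
compute_phr <- function(peaks, L_alleles, R_alleles, log_base = 10) {
  if (!nrow(peaks)) stop("empty peaks slice")
  if (length(intersect(L_alleles, R_alleles)))
    stop("L and R allele sets must be disjoint")
  known <- peaks$allele %in% c(L_alleles, R_alleles)
  ignored <- unique(peaks$allele[!known])
  if (length(ignored))
    warning("peak allele(s) in neither genome set ignored: ",
            paste(ignored, collapse = ", "))
  tri <- detect_triallelic(peaks)
  pk <- peaks[known, , drop = FALSE]
  isL <- pk$allele %in% L_alleles
  isR <- pk$allele %in% R_alleles
  res <- list(
    sample = if ("sample" %in% names(peaks)) unique(peaks$sample)[1L] else NA,
    locus = if ("locus" %in% names(peaks)) unique(peaks$locus)[1L] else NA,
    L_allele = NA_integer_, R_allele = NA_integer_,
    H_L = NA_real_, H_R = NA_real_, phr = NA_real_,
    triallelic = tri, pattern = NA_character_,
    ignored_alleles = ignored)
  if (tri) {
    res$pattern <- "triallelic"
  } else if (sum(isL) == 1L && sum(isR) == 1L) {
    res$L_allele <- pk$allele[isL]
    res$R_allele <- pk$allele[isR]
    res$H_L <- pk$height[isL]
    res$H_R <- pk$height[isR]
    res$phr <- log(res$H_R / res$H_L, base = log_base)
    res$pattern <- "ok"
  } else if (nrow(pk) <= 1L) {
    res$pattern <- "single_peak"
  } else {
    res$pattern <- "same_genome"
  }
  structure(res, class = "phr_result")
}

#' @export
print.phr_result <- function(x, ...) {
  cat("<phr_result> ", x$sample, " @ ", x$locus, ": ", sep = "")
  if (identical(x$pattern, "ok"))
    cat(sprintf("PHR = %.4f (H_R %s=%.0f / H_L %s=%.0f)\n",
                x$phr, x$R_allele, x$H_R, x$L_allele, x$H_L))
  else cat(x$pattern, "- no PHR\n")
  invisible(x)
}

#' Classify a PHR value against calibrated ranges
#'
#' Returns the unique class whose closed interval `[phr_min, phr_max]`
#' contains the value, or `OUT_OF_RANGE` when none does. Calibration ranges
#' are validated for disjointness first, so containment is exclusive.
#'
#' @param phr numeric vector of PHR values.
#' @param ranges calibration rows (one `(locus, genotype)` set) with columns
#'   `class`, `phr_min`, `phr_max`.
#' @return character vector of classes.
#' @export
classify_phr <- function(phr, ranges) {
  if (!all(c("class", "phr_min", "phr_max") %in% names(ranges)))
    stop("ranges must have columns class, phr_min, phr_max")
  if (is.null(ranges$locus)) ranges$locus <- "any"
  if (is.null(ranges$genotype)) ranges$genotype <- "any"
  validate_phr_calibration(ranges)
  vapply(phr, function(v) {
    if (is.na(v)) return(NA_character_)
    hit <- which(ranges$phr_min <= v & v <= ranges$phr_max)
    if (length(hit) == 1L) ranges$class[hit] else "OUT_OF_RANGE"
  }, character(1))
}

#' PHR report over a peak table
#'
#' Runs [compute_phr()] for every `(sample, locus)` pair of a peak table,
#' using a marker definition mapping allele sizes to their genome of origin,
#' and classifies computable PHR values against the calibration rows matching
#' the locus and observed genotype (`"L/R"` allele sizes). Pairs without a
#' matching calibration keep `class = NA`.
#'
#' @param peaks a peak table (see [read_peak_table()]).
#' @param markers data.frame `locus`, `allele`, `genome` (`"L"` or `"R"`).
#' @param calibration calibration data.frame (default [phr_calibration()]).
#' @param log_base logarithm base (see [compute_phr()]).
#' @return data.frame with one row per sample-locus pair: `sample`, `locus`,
#'   `L_allele`, `R_allele`, `H_L`, `H_R`, `phr`, `pattern`, `triallelic`,
#'   `class`.
#' @export
phr_report <- function(peaks, markers, calibration = phr_calibration(),
                       log_base = 10) {
  peaks <- validate_peak_table(peaks)
  calibration <- validate_phr_calibration(calibration)
  keys <- unique(peaks[, c("sample", "locus")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sl <- peaks[peaks$sample == keys$sample[i] & peaks$locus == keys$locus[i], ]
    mk <- markers[markers$locus == keys$locus[i], ]
    r <- suppressWarnings(
      compute_phr(sl, mk$allele[mk$genome == "L"],
                  mk$allele[mk$genome == "R"], log_base = log_base))
    cls <- NA_character_
    if (!is.na(r$phr)) {
      gkey <- paste(r$L_allele, r$R_allele, sep = "/")
      cal <- calibration[calibration$locus == keys$locus[i] &
                           calibration$genotype == gkey, ]
      if (nrow(cal)) cls <- classify_phr(r$phr, cal)
    }
    data.frame(sample = keys$sample[i], locus = keys$locus[i],
               L_allele = r$L_allele, R_allele = r$R_allele,
               H_L = r$H_L, H_R = r$H_R, phr = r$phr,
               pattern = r$pattern, triallelic = r$triallelic,
               class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
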