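#' Configuration for the microsatellite peak-height simulator
#'
#' Emulates GeneMapper-style peak tables for loci that co-amplify L- and
#' R-specific alleles of hybrid water frogs. Each genome copy carrying allele
#' `a` contributes `base_height * efficiency[a]` to the allele's peak; the
#' aggregated peak is perturbed by lognormal noise, so
#' `H = base * e_a * copy_number * exp(N(0, sigma^2))`. Allele copies can fail
#' to amplify entirely (null alleles), in which case no record is emitted —
#' absent peaks are absent rows, not zeros.
#'
#' @param loci named list; each element a list with components `L` (vector of
#'   L-specific allele sizes) and `R` (vector of R-specific allele sizes).
#'   Defaults to the RICA1b5-style marker with L alleles 122/123/127/145 and
#'   the R-fixed allele 137.
#' @param n_per_class named counts of individuals per class among
#'   `LR`, `LLR`, `LRR`.
#' @param base_height expected height contributed by one genome copy at unit
#'   efficiency.
#' @param sigma standard deviation of the lognormal noise (0 = noise-free).
#' @param efficiency named numeric vector of per-allele amplification
#'   efficiencies (names are allele sizes as character); unnamed alleles
#'   default to 1.
#' @param null_prob probability that a genome copy's allele fails to amplify.
#' @param seed integer seed.
#' @return an object of class `peak_sim_config`.
#' @export
peak_sim_config <- function(loci = list(RICA1b5 = list(L = c(122L, 123L, 127L, 145L),
                                                       R = 137L)),
                            n_per_class = c(LR = 10, LLR = 0, LRR = 0),
                            base_height = 1000,
                            sigma = 0.15,
                            efficiency = NULL,
                            null_prob = 0,
                            seed = NULL) {
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (null_prob < 0 || null_prob >= 1) stop("'null_prob' must be in [0, 1)")
  if (base_height <= 0) stop("'base_height' must be positive")
  classes <- c("LR", "LLR", "LRR")
  if (is.null(names(n_per_class)) || !all(names(n_per_class) %in% classes))
    stop("'n_per_class' must be named with classes among: ",
         paste(classes, collapse = ", "))
  n <- stats::setNames(integer(3), classes)
  n[names(n_per_class)] <- as.integer(n_per_class)
  if (sum(n) == 0L) stop("cohort must contain at least one individual")
  for (nm in names(loci)) {
    if (!all(c("L", "R") %in% names(loci[[nm]])))
      stop("locus '", nm, "' must define L and R allele sizes")
  }
  structure(list(loci = loci, n_per_class = n, base_height = base_height,
                 sigma = sigma, efficiency = efficiency,
                 null_prob = null_prob,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "peak_sim_config")
}

#' Simulate a microsatellite peak table with ground truth
#'
#' For each individual, L-genome copies draw their allele from the locus's
#' L-specific sizes and R-genome copies from the R-specific sizes (LLR
#' individuals whose two L copies carry distinct alleles therefore produce
#' tri-allelic patterns). Peak heights follow the model described in
#' [peak_sim_config()].
#'
#' @param config a [peak_sim_config()].
#' @return a list of class `peak_sim` with elements `peaks` (a peak-table
#'   data.frame), `truth` (`sample`, `class`, `sex`, `population`) and
#'   `markers` (a data.frame `locus`, `allele`, `genome` mapping each allele
#'   size to its genome of origin, for use with [phr_report()]).
#' @export
simulate_peak_table <- function(config) {
  stopifnot(inherits(config, "peak_sim_config"))
  .with_seed(config$seed, {
    n <- config$n_per_class
    cls <- rep(names(n), n)
    ids <- sprintf("%s%03d", cls, unlist(lapply(n, seq_len), use.names = FALSE))
    nL <- c(LR = 1L, LLR = 2L, LRR = 1L)
    nR <- c(LR = 1L, LLR = 1L, LRR = 2L)
    eff <- function(a) {
      if (is.null(config$efficiency)) return(rep(1, length(a)))
      e <- config$efficiency[as.character(a)]
      e[is.na(e)] <- 1
      unname(e)
    }
    pick <- function(v, n) {
      v <- as.integer(v)
      v[sample.int(length(v), n, replace = TRUE)]
    }
    rows <- list()
    for (k in seq_along(ids)) {
      for (nm in names(config$loci)) {
        def <- config$loci[[nm]]
        copies <- c(pick(def$L, nL[cls[k]]), pick(def$R, nR[cls[k]]))
        amplified <- copies[stats::runif(length(copies)) >= config$null_prob]
        if (!length(amplified)) next
        tab <- table(amplified)
        al <- as.integer(names(tab))
        h <- config$base_height * eff(al) * as.integer(tab) *
          exp(stats::rnorm(length(al), 0, config$sigma))
        rows[[length(rows) + 1L]] <- data.frame(
          sample = ids[k], locus = nm, allele = al, height = h,
          stringsAsFactors = FALSE)
      }
    }
    peaks <- if (length(rows)) do.call(rbind, rows)
             else data.frame(sample = character(), locus = character(),
                             allele = integer(), height = numeric())
    rownames(peaks) <- NULL
    truth <- data.frame(
      sample = ids, class = cls,
      sex = sample(c("F", "M"), length(ids), replace = TRUE),
      population = "SIM1", stringsAsFactors = FALSE)
    markers <- do.call(rbind, lapply(names(config$loci), function(nm) {
      def <- config$loci[[nm]]
      data.frame(locus = nm,
                 allele = c(as.integer(def$L), as.integer(def$R)),
                 genome = rep(c("L", "R"), c(length(def$L), length(def$R))),
                 stringsAsFactors = FALSE)
    }))
    structure(list(peaks = validate_peak_table(peaks), truth = truth,
                   markers = markers, config = config),
              class = "peak_sim")
  })
}
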