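#' Frog genotypes with sex-chromosome-annotated genome copies
#'
#' A genome copy is a lineage (`L`, the *P. lessonae*-derived genome, or `R`,
#' the *P. ridibundus*-derived genome) annotated with a sex chromosome
#' (`x` or `y`), written `"Lx"`, `"Ly"`, `"Rx"`, `"Ry"`. Under the default
#' model the R genome is strictly X-linked (primary hybridizations involve
#' L-lineage males with R-lineage females), so `"Ry"` is rejected unless
#' `allow_Ry = TRUE`; relaxing the validator is reported with a message.
#' Sex is a pure function of the copies: male iff any Y is present, hence
#' hybrid males are `LyRx` and hybrid females `LxRx`.
#'
#' @param copies character vector of 2 or 3 genome-copy tokens.
#' @param allow_Ry admit the hypothetical Y-bearing R genome.
#' @return an object of class `frog_genotype`.
#' @export
frog_genotype <- function(copies, allow_Ry = FALSE) {
  valid <- c("Lx", "Ly", "Rx", "Ry")
  if (!all(copies %in% valid))
    stop("unknown genome copy token(s): ",
         paste(setdiff(copies, valid), collapse = ", "),
         " (expected Lx, Ly, Rx, Ry)")
  if (!length(copies) %in% c(2L, 3L))
    stop("a frog genotype has 2 or 3 genome copies, got ", length(copies))
  if ("Ry" %in% copies) {
    if (!allow_Ry)
      stop("the R genome is strictly X-linked under the default model; ",
           "'Ry' requires allow_Ry = TRUE")
    message("note: X-linkage of the R genome relaxed (Ry admitted)")
  }
  structure(list(copies = sort(copies)), class = "frog_genotype")
}

#' Parse a compact genotype string like "LxRx" or "LxLyRx"
#' @param s character scalar of concatenated genome-copy tokens.
#' @param allow_Ry see [frog_genotype()].
#' @return a [frog_genotype()].
#' @export
parse_genotype <- function(s, allow_Ry = FALSE) {
  toks <- regmatches(s, gregexpr("[LR][xy]", s))[[1L]]
  if (!nchar(gsub("[LR][xy]", "", s)) == 0 || !length(toks))
    stop("cannot parse genotype string: ", s)
  frog_genotype(toks, allow_Ry = allow_Ry)
}

#' @export
format.frog_genotype <- function(x, ...) paste(x$copies, collapse = "")

#' @export
print.frog_genotype <- function(x, ...) {
  cat("<frog_genotype> ", format(x), " (", genotype_class(x), ", ",
      frog_sex(x), ")\n", sep = "")
  invisible(x)
}

#' Sex of a genotype: male iff any Y-bearing copy
#' @param g a [frog_genotype()] or copies vector.
#' @return `"M"` or `"F"`.
#' @export
frog_sex <- function(g) {
  copies <- if (inherits(g, "frog_genotype")) g$copies else g
  if (any(grepl("y", copies, fixed = TRUE))) "M" else "F"
}

#' Genome composition class of a genotype
#' @param g a [frog_genotype()] or copies vector.
#' @return lineage string with copies sorted, e.g. `"LR"`, `"LLR"`, `"RR"`.
#' @export
genotype_class <- function(g) {
  copies <- if (inherits(g, "frog_genotype")) g$copies else g
  paste(sort(substr(copies, 1L, 1L)), collapse = "")
}

# canonical key of a copy multiset
.copies_key <- function(copies) paste(sort(copies), collapse = "")
.key_to_copies <- function(key) regmatches(key, gregexpr("[LR][xy]", key))[[1L]]

#' Gametogenesis rules
#'
#' The modes of hybridogenetic gamete production:
#' * `ELIMINATE_L` — the hybrid excludes its L genome and transmits the R
#'   hemiclone clonally (the classic L-E behaviour).
#' * `ELIMINATE_R` — the reverse (R-E behaviour): the L genome is transmitted.
#' * `AMPHI` — hybrid amphigamy: a diploid LR individual transmits its L copy
#'   with probability `q` and its R copy with `1 - q`.
#' * `DIPLOID_LR` — unreduced bivalent LR gametes (the eggs that found
#'   triploids in mixed-ploidy all-hybrid systems).
#' * `MENDELIAN` — ordinary segregation for a diploid with two same-lineage
#'   copies (parental LL / RR): each copy with probability 1/2.
#' * `TRIPLOID_RULE` — per-composition table for triploids; each entry is a
#'   named probability vector over the gamete kinds `L_haploid`, `R_haploid`
#'   (a recombined haploid of the duplicated lineage, each copy equally
#'   likely), `LL_unreduced`, `RR_unreduced`, `LR_unreduced`.
#'
#' @param mode one of the modes above.
#' @param q L-transmission probability for `AMPHI`.
#' @param triploid_table named list of probability vectors for
#'   `TRIPLOID_RULE`, keyed by composition class (`"LLR"`, `"LRR"`).
#' @return an object of class `gamete_rule`.
#' @export
gamete_rule <- function(mode = c("ELIMINATE_L", "ELIMINATE_R", "AMPHI",
                                 "DIPLOID_LR", "MENDELIAN", "TRIPLOID_RULE"),
                        q = 0.5, triploid_table = NULL) {
  mode <- match.arg(mode)
  if (q < 0 || q > 1) stop("'q' must be in [0, 1]")
  if (mode == "TRIPLOID_RULE") {
    if (is.null(triploid_table)) stop("TRIPLOID_RULE needs a triploid_table")
    for (cls in names(triploid_table)) {
      p <- triploid_table[[cls]]
      if (abs(sum(p) - 1) > 1e-9)
        stop("triploid_table entry '", cls, "' must sum to 1")
    }
  }
  structure(list(mode = mode, q = q, triploid_table = triploid_table),
            class = "gamete_rule")
}

#' Gamete distribution of a genotype under a rule
#'
#' Enumerates the gametes a genotype produces under a gametogenesis rule,
#' with their probabilities. Gametes carry their genome copies (and thus sex
#' chromosomes); when a parent holds two copies of the transmitted lineage,
#' Mendelian 1/2-1/2 segregation applies between them.
#'
#' @param g a [frog_genotype()].
#' @param rule a [gamete_rule()].
#' @return named numeric vector: names are canonical gamete strings (e.g.
#'   `"Rx"`, `"LxRx"`), values are probabilities summing to 1.
#' @export
gamete_distribution <- function(g, rule) {
  stopifnot(inherits(g, "frog_genotype"), inherits(rule, "gamete_rule"))
  copies <- g$copies
  lin <- substr(copies, 1L, 1L)
  Ls <- copies[lin == "L"]
  Rs <- copies[lin == "R"]
  fail <- function() stop("rule ", rule$mode, " is not applicable to ",
                          "genotype ", .copies_key(copies))
  dist <- switch(
    rule$mode,
    ELIMINATE_L = {
      if (!length(Rs)) fail()
      .haploid_dist(Rs)
    },
    ELIMINATE_R = {
      if (!length(Ls)) fail()
      .haploid_dist(Ls)
    },
    AMPHI = {
      if (length(copies) != 2L || length(Ls) != 1L || length(Rs) != 1L) fail()
      stats::setNames(c(rule$q, 1 - rule$q), c(Ls, Rs))
    },
    DIPLOID_LR = {
      if (length(Ls) != 1L || length(Rs) != 1L) fail()
      stats::setNames(1, .copies_key(copies))
    },
    MENDELIAN = {
      if (length(copies) != 2L) fail()
      .haploid_dist(copies)
    },
    TRIPLOID_RULE = {
      cls <- genotype_class(g)
      entry <- rule$triploid_table[[cls]]
      if (is.null(entry)) fail()
      out <- numeric(0)
      add <- function(d, keys, p) {
        for (i in seq_along(keys)) d[keys[i]] <- (if (keys[i] %in% names(d))
          d[[keys[i]]] else 0) + p[i]
        d
      }
      for (kind in names(entry)) {
        p <- entry[[kind]]
        sub <- switch(kind,
          L_haploid = { if (!length(Ls)) fail(); .haploid_dist(Ls) },
          R_haploid = { if (!length(Rs)) fail(); .haploid_dist(Rs) },
          LL_unreduced = { if (length(Ls) != 2L) fail()
            stats::setNames(1, .copies_key(Ls)) },
          RR_unreduced = { if (length(Rs) != 2L) fail()
            stats::setNames(1, .copies_key(Rs)) },
          LR_unreduced = { if (!length(Ls) || !length(Rs)) fail()
            pairs <- expand.grid(Ls, Rs, stringsAsFactors = FALSE)
            keys <- mapply(function(a, b) .copies_key(c(a, b)),
                           pairs[[1L]], pairs[[2L]])
            d <- tapply(rep(1 / nrow(pairs), nrow(pairs)), keys, sum)
            stats::setNames(as.numeric(d), names(d)) },
          stop("unknown triploid gamete kind: ", kind))
        out <- add(out, names(sub), as.numeric(sub) * p)
      }
      out
    })
  dist <- tapply(as.numeric(dist), names(dist), sum)
  dist <- stats::setNames(as.numeric(dist), names(dist))
  if (abs(sum(dist) - 1) > 1e-9)
    stop("internal error: gamete distribution does not sum to 1")
  dist
}

# equal-probability haploid transmission among the given copies
.haploid_dist <- function(copies) {
  d <- tapply(rep(1 / length(copies), length(copies)), copies, sum)
  stats::setNames(as.numeric(d), names(d))
}

#' Cross two frogs under gametogenesis rules
#'
#' Offspring distribution as the product of the parents' gamete
#' distributions, gametes unioned into offspring genotypes. Two
#' distributions are reported: pre-viability (the zygotes) and
#' post-viability, where class weights model hybridogenetic load —
#' homotypic `LL` / `RR` zygotes produced from hemiclonal genomes carry
#' accumulated deleterious mutations and default to weight 0, all other
#' (hybrid) compositions to 1. The post-viability distribution is
#' renormalized when any class survives.
#'
#' @param mother,father [frog_genotype()]s; the mother must be female and
#'   the father male (sex is derived from the copies).
#' @param mother_rule,father_rule [gamete_rule()]s; alternatively supply
#'   `system` and both are derived from the preset.
#' @param system optional [system_preset()] supplying rules and viability.
#' @param viability named weights for `LL`, `RR` and `hybrid` classes.
#' @return an object of class `cross_result`: data.frame with columns
#'   `genotype`, `class`, `sex`, `p_pre`, `p_post`.
#' @export
cross <- function(mother, father, mother_rule = NULL, father_rule = NULL,
                  system = NULL,
                  viability = c(LL = 0, RR = 0, hybrid = 1)) {
  stopifnot(inherits(mother, "frog_genotype"),
            inherits(father, "frog_genotype"))
  if (frog_sex(mother) != "F")
    stop("mother must be female (no Y-bearing copy), got ", format(mother))
  if (frog_sex(father) != "M")
    stop("father must be male (at least one Y-bearing copy), got ",
         format(father))
  if (!is.null(system)) {
    stopifnot(inherits(system, "cross_system"))
    if (is.null(mother_rule)) mother_rule <- rule_for(system, mother)
    if (is.null(father_rule)) father_rule <- rule_for(system, father)
    if (missing(viability)) viability <- system$viability
  }
  if (is.null(mother_rule) || is.null(father_rule))
    stop("supply mother_rule and father_rule, or a system preset")
  gm <- gamete_distribution(mother, mother_rule)
  gf <- gamete_distribution(father, father_rule)
  acc <- list()
  for (i in seq_along(gm)) {
    for (j in seq_along(gf)) {
      copies <- c(.key_to_copies(names(gm)[i]), .key_to_copies(names(gf)[j]))
      key <- .copies_key(copies)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        gm[[i]] * gf[[j]]
    }
  }
  keys <- sort(names(acc))
  p_pre <- vapply(keys, function(k) acc[[k]], numeric(1))
  cls <- vapply(keys, function(k) genotype_class(.key_to_copies(k)),
                character(1))
  sex <- vapply(keys, function(k) frog_sex(.key_to_copies(k)), character(1))
  w <- vapply(cls, function(cl)
    if (cl %in% names(viability)) viability[[cl]] else viability[["hybrid"]],
    numeric(1))
  post_raw <- p_pre * w
  p_post <- if (sum(post_raw) > 0) post_raw / sum(post_raw) else post_raw
  out <- data.frame(genotype = keys, class = cls, sex = sex,
                    p_pre = as.numeric(p_pre), p_post = as.numeric(p_post),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cross_result", "data.frame")
  out
}

#' @export
print.cross_result <- function(x, ...) {
  cat("<cross_result>\n")
  df <- as.data.frame(x)
  df$p_pre <- sprintf("%.4f", df$p_pre)
  df$p_post <- sprintf("%.4f", df$p_post)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Preset hybridogenetic breeding systems
#'
#' * `L_E` — the *lessonae-esculentus* system: LR hybrids of both sexes
#'   exclude their L genome and transmit clonal R gametes; parental LL
#'   reproduces sexually. Hemiclone-derived RR offspring (from inter-hybrid
#'   crosses) are unviable; the host species LL is viable.
#' * `R_E` — the reverse system: hybrids transmit L gametes; RR is the
#'   viable host, LL offspring are unviable.
#' * `E_E_TRIPLOID` — the classic all-hybrid system with mixed ploidy:
#'   LR females lay unreduced bivalent LR eggs, LR males give hemiclonal R
#'   sperm, and triploids feed haploids back (LLR males give recombined L
#'   sperm, LRR individuals give R). LL and RR are unviable.
#' * `E_E_DIPLOID_AMPHIGAMY` — the hypothesized diploid all-hybrid system:
#'   both sexes produce gametes among which both genomes are represented
#'   (`AMPHI`, `q = 0.5` as the symmetric case). LL and RR arise but are
#'   unviable (hybridogenetic load); mixtures of L- and R-eliminating
#'   lineages can be expressed by setting `q` to 0 or 1 per individual.
#'
#' @param name preset name.
#' @param q amphigamy L-transmission probability (used by
#'   `E_E_DIPLOID_AMPHIGAMY`).
#' @param triploid_table override for the triploid gametogenesis table (see
#'   [gamete_rule()]); the `E_E_TRIPLOID` default encodes `LLR` giving
#'   recombined L haploids and `LRR` giving R haploids, with unreduced `LL`
#'   sperm available as a documented table entry.
#' @return an object of class `cross_system`.
#' @export
system_preset <- function(name = c("L_E", "R_E", "E_E_TRIPLOID",
                                   "E_E_DIPLOID_AMPHIGAMY"),
                          q = 0.5, triploid_table = NULL) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1L], "'; available: L_E, R_E, ",
         "E_E_TRIPLOID, E_E_DIPLOID_AMPHIGAMY"))
  sys <- switch(
    name,
    L_E = list(
      hybrid_female = gamete_rule("ELIMINATE_L"),
      hybrid_male = gamete_rule("ELIMINATE_L"),
      triploid_table = NULL,
      viability = c(LL = 1, RR = 0, hybrid = 1)),
    R_E = list(
      hybrid_female = gamete_rule("ELIMINATE_R"),
      hybrid_male = gamete_rule("ELIMINATE_R"),
      triploid_table = NULL,
      viability = c(LL = 0, RR = 1, hybrid = 1)),
    E_E_TRIPLOID = list(
      hybrid_female = gamete_rule("DIPLOID_LR"),
      hybrid_male = gamete_rule("ELIMINATE_L"),
      triploid_table = if (is.null(triploid_table))
        list(LLR = c(L_haploid = 1), LRR = c(R_haploid = 1))
        else triploid_table,
      viability = c(LL = 0, RR = 0, hybrid = 1)),
    E_E_DIPLOID_AMPHIGAMY = list(
      hybrid_female = gamete_rule("AMPHI", q = q),
      hybrid_male = gamete_rule("AMPHI", q = q),
      triploid_table = NULL,
      viability = c(LL = 0, RR = 0, hybrid = 1)))
  structure(c(list(name = name), sys), class = "cross_system")
}

#' @export
print.cross_system <- function(x, ...) {
  cat("<cross_system> ", x$name, "\n", sep = "")
  cat("  hybrid female rule:", x$hybrid_female$mode, "\n")
  cat("  hybrid male rule:  ", x$hybrid_male$mode, "\n")
  cat("  viability: ", paste(names(x$viability), x$viability, sep = "=",
                             collapse = ", "), "\n")
  invisible(x)
}

#' Gametogenesis rule a preset assigns to a genotype
#'
#' Parental (`LL` / `RR`) genotypes segregate Mendelian everywhere; diploid
#' hybrids follow the preset's sex-specific hybrid rule; triploids follow the
#' preset's triploid table where one is defined.
#'
#' @param system a [system_preset()].
#' @param g a [frog_genotype()].
#' @return a [gamete_rule()].
#' @export
rule_for <- function(system, g) {
  stopifnot(inherits(system, "cross_system"), inherits(g, "frog_genotype"))
  cls <- genotype_class(g)
  if (cls %in% c("LL", "RR")) return(gamete_rule("MENDELIAN"))
  if (cls == "LR") {
    return(if (frog_sex(g) == "F") system$hybrid_female else system$hybrid_male)
  }
  if (cls %in% c("LLR", "LRR")) {
    if (is.null(system$triploid_table))
      stop("preset ", system$name, " defines no gametogenesis rule for ",
           "triploid genotype ", format(g))
    return(gamete_rule("TRIPLOID_RULE", triploid_table = system$triploid_table))
  }
  stop("no rule for genotype class ", cls, " under preset ", system$name)
}

#' Deterministic generation-to-generation recursion of a breeding system
#'
#' Iterates genotype frequencies under random mating within sex: every
#' female genotype is mated with every male genotype in proportion to their
#' frequencies, the pre-viability offspring distributions are pooled,
#' viability weights applied, and the surviving pool renormalized. This is a
#' frequency recursion (no drift, no ecology), provided as an extension of
#' the single-cross model to study system closure.
#'
#' @param system a [system_preset()].
#' @param init named numeric vector of genotype frequencies (names are
#'   genotype strings like `"LxRx"`).
#' @param n_gen number of generations.
#' @param on_missing_rule `"error"` (default) or `"drop"`: what to do with a
#'   genotype the preset has no rule for.
#' @return list of named frequency vectors, one per generation (including
#'   the renormalized initial state), each summing to 1.
#' @export
iterate_generations <- function(system, init, n_gen,
                                on_missing_rule = c("error", "drop")) {
  stopifnot(inherits(system, "cross_system"))
  on_missing_rule <- match.arg(on_missing_rule)
  freq <- init / sum(init)
  traj <- vector("list", n_gen + 1L)
  traj[[1L]] <- freq
  for (gen in seq_len(n_gen)) {
    gts <- lapply(names(freq), function(k)
      frog_genotype(.key_to_copies(k)))
    sex <- vapply(gts, frog_sex, character(1))
    fem <- which(sex == "F" & freq > 0)
    mal <- which(sex == "M" & freq > 0)
    if (!length(fem) || !length(mal))
      stop("population lost one sex entirely at generation ", gen)
    wf <- freq[fem] / sum(freq[fem])
    wm <- freq[mal] / sum(freq[mal])
    pool <- list()
    for (i in seq_along(fem)) {
      for (j in seq_along(mal)) {
        mr <- tryCatch(rule_for(system, gts[[fem[i]]]), error = identity)
        fr <- tryCatch(rule_for(system, gts[[mal[j]]]), error = identity)
        if (inherits(mr, "error") || inherits(fr, "error")) {
          if (on_missing_rule == "drop") next else stop(
            conditionMessage(if (inherits(mr, "error")) mr else fr))
        }
        cr <- cross(gts[[fem[i]]], gts[[mal[j]]], mother_rule = mr,
                    father_rule = fr, viability = system$viability)
        wpair <- unname(wf[i] * wm[j])
        for (k in seq_len(nrow(cr))) {
          key <- cr$genotype[k]
          pool[[key]] <- (if (is.null(pool[[key]])) 0 else pool[[key]]) +
            wpair * cr$p_pre[k] *
            (if (cr$class[k] %in% names(system$viability))
               system$viability[[cr$class[k]]]
             else system$viability[["hybrid"]])
        }
      }
    }
    v <- unlist(pool)
    if (is.null(v) || sum(v) <= 0)
      stop("no viable offspring at generation ", gen)
    freq <- sort(v / sum(v), decreasing = TRUE)
    traj[[gen + 1L]] <- freq
  }
  traj
}
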