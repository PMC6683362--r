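#' Pipeline run configuration
#'
#' Bundles input paths and every stage parameter into a validated
#' configuration. Configurations can also be loaded from a JSON or YAML file
#' with [read_pipeline_config()]; unspecified fields take the defaults below.
#'
#' @param vcf path to the genotype VCF (GT + AD).
#' @param popmap path to the population-map TSV.
#' @param out_dir output directory for the report bundle.
#' @param peaks optional path to a microsatellite peak-table TSV.
#' @param markers optional path to a marker-definition TSV (`locus`,
#'   `allele`, `genome`); required when `peaks` is given.
#' @param calibration optional path to a PHR calibration TSV (default: the
#'   built-in [phr_calibration()]).
#' @param min_ref_called,require_biallelic see [find_diagnostic_loci()].
#' @param min_depth_per_allele,min_loci,diploid_max,triploid_min see
#'   [individual_dosage_profile()] and [classify_ploidy()].
#' @param likelihood_error see [dosage_likelihood_call()].
#' @param pure_min,het_min see [hybrid_index()].
#' @param min_n see [observed_heterozygosity()].
#' @param log_base see [compute_phr()].
#' @param seed integer seed recorded in every output header (the analysis
#'   stages are deterministic; the seed matters when the pipeline is pointed
#'   at simulated inputs and for provenance).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, popmap, out_dir,
                            peaks = NULL, markers = NULL, calibration = NULL,
                            min_ref_called = 3L, require_biallelic = TRUE,
                            min_depth_per_allele = 3L, min_loci = 20L,
                            diploid_max = 1.4, triploid_min = 1.7,
                            likelihood_error = 0.01,
                            pure_min = 0.9, het_min = 0.9,
                            min_n = 5L, log_base = 10, seed = 1L) {
  for (p in c(vcf, popmap, peaks, markers, calibration)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  if (!is.null(peaks) && is.null(markers))
    stop("'markers' is required when 'peaks' is given")
  structure(list(
    vcf = vcf, popmap = popmap, out_dir = out_dir, peaks = peaks,
    markers = markers, calibration = calibration,
    min_ref_called = as.integer(min_ref_called),
    require_biallelic = isTRUE(require_biallelic),
    min_depth_per_allele = as.integer(min_depth_per_allele),
    min_loci = as.integer(min_loci), diploid_max = diploid_max,
    triploid_min = triploid_min, likelihood_error = likelihood_error,
    pure_min = pure_min, het_min = het_min, min_n = as.integer(min_n),
    log_base = log_base, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Load a pipeline configuration from JSON or YAML
#' @param path configuration file; the extension (`.json` vs `.yml`/`.yaml`)
#'   selects the parser.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, lst)
}

#' Run the full analysis pipeline
#'
#' Executes the survey's analysis flow on one cohort: read the genotype
#' matrix and population map, discover the diagnostic panel from the
#' parental reference samples, profile allele-depth dosage and call ploidy
#' per hybrid sample, assign taxa by the diagnostic-locus hybrid index,
#' summarize observed heterozygosity per population and taxon, and (when a
#' peak table is supplied) compute and classify microsatellite peak-height
#' ratios. Writes a report bundle to `out_dir`: `panel.tsv`, `dosage.tsv`,
#' `hybrid_index.tsv`, `heterozygosity.tsv`, optional `phr.tsv`,
#' `summary.json`, `config.json` and `run.log`. Every TSV carries a header
#' comment with the tool version, seed and configuration hash, and reruns
#' with the same inputs are byte-identical.
#'
#' If the diagnostic panel comes out empty, the dosage and hybrid-index
#' stages are skipped with an explicit notice (and recorded in the log);
#' heterozygosity is then grouped by the population map's taxon hints.
#'
#' @param config a [pipeline_config()] or path to a JSON/YAML file.
#' @return invisibly, a list with the panel, dosage table, hybrid-index
#'   table, heterozygosity table, optional PHR table, and the summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message("[hybridogen] ", msg)
  }
  ver <- as.character(utils::packageVersion("hybridogen"))
  note("hybridogen ", ver, " pipeline starting")
  note("parameters: ", paste(
    vapply(setdiff(names(config), c("vcf", "popmap", "peaks", "markers",
                                    "calibration", "out_dir")),
           function(k) paste0(k, "=", config[[k]]), character(1)),
    collapse = " "))

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config[order(names(config))], cfg_path,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  # hash the analysis parameters, not the destination, so reruns into a
  # different directory remain comparable
  hash_src <- tempfile(fileext = ".json")
  jsonlite::write_json(config[sort(setdiff(names(config), "out_dir"))],
                       hash_src, auto_unbox = TRUE, null = "null")
  cfg_hash <- unname(tools::md5sum(hash_src))
  unlink(hash_src)
  hdr <- c(paste0("hybridogen ", ver), paste0("seed=", config$seed),
           paste0("config_md5=", cfg_hash))

  gm <- read_vcf_with_depths(config$vcf, require_depths = TRUE)
  pm <- read_population_map(config$popmap)
  note("inputs: ", length(gm$samples), " samples, ", length(gm$loci), " loci")

  panel <- withCallingHandlers(
    find_diagnostic_loci(gm, pm, min_ref_called = config$min_ref_called,
                         require_biallelic = config$require_biallelic),
    warning = function(w) {
      note("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  note("diagnostic panel: ", nrow(panel), " loci")
  write_diagnostic_panel(as.data.frame(panel),
                         file.path(config$out_dir, "panel.tsv"), hdr)

  dosage <- NULL
  hi <- NULL
  if (nrow(panel)) {
    dosage <- dosage_report(gm, panel,
                            min_depth_per_allele = config$min_depth_per_allele,
                            min_loci = config$min_loci,
                            diploid_max = config$diploid_max,
                            triploid_min = config$triploid_min,
                            error = config$likelihood_error)
    write_report_tsv(dosage, file.path(config$out_dir, "dosage.tsv"), hdr)
    hi <- hybrid_index(gm, panel, pure_min = config$pure_min,
                       het_min = config$het_min)
    write_report_tsv(hi, file.path(config$out_dir, "hybrid_index.tsv"), hdr)
  } else {
    note("empty panel: dosage and hybrid-index stages skipped")
  }

  taxon <- if (!is.null(hi)) hi$taxon_call[match(pm$sample, hi$sample)]
           else pm$taxon_hint
  groups <- data.frame(sample = pm$sample, population = pm$population,
                       taxon = taxon, stringsAsFactors = FALSE)
  het <- withCallingHandlers(
    observed_heterozygosity(gm, groups, min_n = config$min_n),
    message = function(m) {
      note(sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  write_report_tsv(het, file.path(config$out_dir, "heterozygosity.tsv"), hdr)

  phr_tab <- NULL
  if (!is.null(config$peaks)) {
    peaks <- read_peak_table(config$peaks)
    markers <- utils::read.delim(config$markers, header = TRUE, sep = "\t",
                                 comment.char = "#",
                                 stringsAsFactors = FALSE)
    cal <- if (is.null(config$calibration)) phr_calibration()
           else read_phr_calibration(config$calibration)
    phr_tab <- phr_report(peaks, markers, calibration = cal,
                          log_base = config$log_base)
    write_report_tsv(phr_tab, file.path(config$out_dir, "phr.tsv"), hdr)
    note("phr: ", nrow(phr_tab), " sample-locus pairs")
  }

  count_of <- function(x) as.list(table(x))
  summary <- list(
    tool = "hybridogen", version = ver, seed = config$seed,
    config_md5 = unname(cfg_hash),
    n_samples = length(gm$samples), n_loci = length(gm$loci),
    n_panel_loci = nrow(panel),
    taxon_counts = if (!is.null(hi)) count_of(hi$taxon_call) else NULL,
    ploidy_counts = if (!is.null(dosage)) count_of(dosage$call) else NULL,
    ml_ploidy_counts = if (!is.null(dosage)) count_of(dosage$ml_call) else NULL,
    phr_class_counts = if (!is.null(phr_tab))
      count_of(phr_tab$class[!is.na(phr_tab$class)]) else NULL)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  note("pipeline finished")
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(panel = panel, dosage = dosage, hybrid_index = hi,
                 heterozygosity = het, phr = phr_tab, summary = summary))
}
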