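# End-to-end orchestration: run configuration, the full landscape pipeline,
# and the deterministic landscape-map layout.

CONFIG_NUMERIC <- c("evalue_cutoff", "lfdr_threshold", "min_length",
                    "prevalence_threshold", "min_regions", "seed")
CONFIG_FIELDS <- c("mutation_file", "protein_file", "domain_file",
                   "exclusion_file", "mutation_dialect", "domain_dialect",
                   "protein_format", "cohort_name", "out_dir", "z_form",
                   CONFIG_NUMERIC)

#' Build a run configuration
#'
#' Collects the input paths, dialects and thresholds of one pipeline run.
#' Defaults are the method's standard constants: E-value cutoff 0.001 for
#' domain placements, local-fdr threshold 0.1, minimum region length 150 aa,
#' high-prevalence threshold 0.04.
#'
#' @param mutation_file,protein_file,domain_file Input paths.
#' @param out_dir Output directory (created if absent).
#' @param exclusion_file Optional path to a file of dbSNP-style ids, one per
#'   line.
#' @param mutation_dialect,domain_dialect,protein_format Reader dialects.
#' @param cohort_name Cohort label.
#' @param evalue_cutoff,lfdr_threshold,min_length,prevalence_threshold,min_regions
#'   Method constants (see [read_domain_map()], [call_peaks()],
#'   [mutation_prevalence()], [fit_local_fdr()]).
#' @param z_form Score form, see [bernoulli_z()].
#' @param seed Seed for the layout shuffle.
#' @return A `landscape_config` object (named list).
#' @export
landscape_config <- function(mutation_file, protein_file, domain_file,
                             out_dir, exclusion_file = NA_character_,
                             mutation_dialect = "simple_tsv",
                             domain_dialect = "simple_tsv",
                             protein_format = "tsv",
                             cohort_name = "cohort",
                             evalue_cutoff = 0.001, lfdr_threshold = 0.1,
                             min_length = 150, prevalence_threshold = 0.04,
                             min_regions = 200,
                             z_form = c("binomial", "snr"), seed = 1) {
  z_form <- match.arg(z_form)
  stopifnot(lfdr_threshold >= 0, min_length > 0, prevalence_threshold > 0,
            evalue_cutoff >= 0, min_regions > 0)
  cfg <- mget(CONFIG_FIELDS)
  structure(cfg, class = "landscape_config")
}

#' Write a configuration as key=value text
#'
#' @param config A `landscape_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "landscape_config"))
  vals <- vapply(CONFIG_FIELDS, function(f) {
    v <- config[[f]]
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE)
  }, character(1))
  writeLines(paste0(CONFIG_FIELDS, "=", vals), path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' @param path Path to the key=value file.
#' @return A `landscape_config` identical to the one written.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- stringr::str_match(lines, "^([^=]+)=(.*)$")
  if (any(is.na(kv[, 1]))) stop("malformed config line(s)", call. = FALSE)
  vals <- setNames(as.list(kv[, 3]), trimws(kv[, 2]))
  miss <- setdiff(CONFIG_FIELDS, names(vals))
  if (length(miss)) {
    stop("config is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cfg <- vals[CONFIG_FIELDS]
  for (f in CONFIG_NUMERIC) cfg[[f]] <- as.numeric(cfg[[f]])
  cfg$seed <- as.integer(cfg$seed)
  cfg$min_length <- as.integer(cfg$min_length) # stored integral
  cfg$min_regions <- as.integer(cfg$min_regions)
  if (identical(cfg$exclusion_file, "NA")) cfg$exclusion_file <- NA_character_
  structure(cfg, class = "landscape_config")
}

#' Run the full landscape pipeline from a configuration
#'
#' Reads the inputs, applies the somatic filters, assembles the cohort,
#' computes the gene and domain landscapes, classifies peak origins, re-tests
#' domains after gene-peak removal, and writes six TSVs into `out_dir`:
#' `filter_report.tsv`, `gene_landscape.tsv`, `domain_landscape.tsv`,
#' `peak_origins.tsv`, `domain_recall.tsv`, `run_log.tsv`.  Output is
#' byte-identical across reruns with the same configuration and inputs.
#'
#' @param config A `landscape_config`.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `gene_landscape`, `domain_landscape`, `origins`, `recall`, `summary`)
#'   and `files` (the written paths).
#' @export
run_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  proteins <- read_protein_set(config$protein_file,
                               format = config$protein_format)
  domains <- read_domain_map(config$domain_file,
                             dialect = config$domain_dialect,
                             evalue_cutoff = config$evalue_cutoff,
                             proteins = proteins)
  mutations <- read_mutation_table(config$mutation_file,
                                   dialect = config$mutation_dialect)
  exclusion <- if (!is.na(config$exclusion_file)) {
    readLines(config$exclusion_file, warn = FALSE)
  } else character()
  filtered <- filter_cohort(mutations, exclusion_ids = exclusion)
  cohort <- build_cohort(filtered, proteins, domains,
                         name = config$cohort_name)

  gl <- gene_landscape(cohort, lfdr_threshold = config$lfdr_threshold,
                       min_length = config$min_length,
                       z_form = config$z_form,
                       min_regions = config$min_regions)
  dl <- domain_landscape(cohort, lfdr_threshold = config$lfdr_threshold,
                         min_length = config$min_length,
                         z_form = config$z_form,
                         min_regions = config$min_regions)
  origins <- classify_peak_origins(dl, gl)
  recall <- recall_after_gene_peak_removal(cohort, gl, dl)

  files <- c(
    filter_report = file.path(config$out_dir, "filter_report.tsv"),
    gene_landscape = file.path(config$out_dir, "gene_landscape.tsv"),
    domain_landscape = file.path(config$out_dir, "domain_landscape.tsv"),
    peak_origins = file.path(config$out_dir, "peak_origins.tsv"),
    domain_recall = file.path(config$out_dir, "domain_recall.tsv"),
    run_log = file.path(config$out_dir, "run_log.tsv")
  )
  write_filter_report(filtered, files[["filter_report"]])
  write_landscape_table(gl, files[["gene_landscape"]])
  write_landscape_table(dl, files[["domain_landscape"]])
  readr::write_tsv(origins, files[["peak_origins"]], na = "NA")
  readr::write_tsv(
    dplyr::select(recall, -dplyr::any_of("landscape_after")),
    files[["domain_recall"]], na = "NA")
  log <- dplyr::bind_rows(
    cohort$log,
    tibble::tibble(stage = c("gene_regions", "gene_significant",
                             "domain_regions", "domain_significant"),
                   n = c(nrow(gl$stats), sum(gl$stats$significant),
                         nrow(dl$stats), sum(dl$stats$significant))))
  readr::write_tsv(log, files[["run_log"]])
  invisible(list(cohort = cohort, gene_landscape = gl, domain_landscape = dl,
                 origins = origins, recall = recall, files = files))
}

#' Deterministic grid layout of a mutational landscape map
#'
#' Places each region on a ceiling(sqrt(N)) x ceiling(sqrt(N)) grid — each
#' gene or domain one point, position arbitrary by construction — by a
#' seeded shuffle of a deterministic ordering (descending frequency, ties by
#' id), with height proportional to the length-normalized frequency.
#' Identical stats and seed give identical placements.
#'
#' @param stats A `landscape` object or its statistics tibble.
#' @param grid_seed Integer seed for the cell shuffle.
#' @param cap Optional height cap (tall peaks are clipped to `cap` and
#'   flagged, so the rest of the relief stays visible).
#' @return Tibble `region_id`, `x`, `y`, `height`, `capped`.
#' @export
layout_landscape <- function(stats, grid_seed = 1, cap = NULL) {
  if (inherits(stats, "landscape")) stats <- stats$stats
  n <- nrow(stats)
  side <- ceiling(sqrt(n))
  ord <- order(-stats$p_hat, stats$region_id)
  cells <- tidyr::expand_grid(x = seq_len(side), y = seq_len(side))[seq_len(n), ]
  idx <- with_seed(grid_seed, sample.int(n))
  height <- stats$p_hat[ord]
  capped <- rep(FALSE, n)
  if (!is.null(cap)) {
    capped <- height > cap
    height <- pmin(height, cap)
  }
  tibble::tibble(region_id = stats$region_id[ord],
                 x = cells$x[idx], y = cells$y[idx],
                 height = height, capped = capped)
}
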