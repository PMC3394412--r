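# Cohort assembly: filtering rules, recurrence counting, representative
# isoform selection, and mutation-to-domain assignment.

#' Filter a mutation table down to the analyzable somatic set
#'
#' Applies the four standard exclusion rules: germline calls (`is_somatic`
#' FALSE), quality-control failures (`passed_qc` FALSE), known polymorphisms
#' (dbSNP id in `exclusion_ids`), and synonymous SNVs (assumed unlikely to
#' affect tumor development).  Retention is the conjunction of the four
#' predicates, so the result is independent of rule order; the per-rule
#' removal counts in the report are attributed sequentially in the order
#' given.
#'
#' @param mutations Mutation tibble (see [read_mutation_table()]).
#' @param exclusion_ids Character vector of dbSNP-style ids to exclude
#'   (possibly empty).
#' @param rules Order in which removals are attributed in the report; a
#'   permutation of `c("germline", "qc", "dbsnp", "synonymous")`.
#' @return The retained mutation tibble, with a `"filter_report"` attribute
#'   (tibble `rule`, `removed`, `remaining`) retrievable via
#'   [filter_report()].
#' @export
filter_cohort <- function(mutations, exclusion_ids = character(),
                          rules = c("germline", "qc", "dbsnp", "synonymous")) {
  stopifnot(setequal(rules, c("germline", "qc", "dbsnp", "synonymous")))
  predicates <- list(
    germline   = function(m) m$is_somatic,
    qc         = function(m) m$passed_qc,
    dbsnp      = function(m) is.na(m$dbsnp_id) | !(m$dbsnp_id %in% exclusion_ids),
    synonymous = function(m) m$variant_class != "synonymous_SNV"
  )
  keep <- rep(TRUE, nrow(mutations))
  report <- tibble::tibble(rule = character(), removed = integer(),
                           remaining = integer())
  for (rule in rules) {
    pass <- predicates[[rule]](mutations)
    removed <- sum(keep & !pass)
    keep <- keep & pass
    report <- dplyr::bind_rows(report, tibble::tibble(
      rule = rule, removed = removed, remaining = sum(keep)))
  }
  out <- mutations[keep, ]
  attr(out, "filter_report") <- report
  out
}

#' Per-rule removal counts from [filter_cohort()]
#'
#' @param mutations A filtered mutation tibble.
#' @return Tibble with columns `rule`, `removed`, `remaining`.
#' @export
filter_report <- function(mutations) {
  attr(mutations, "filter_report") %||%
    tibble::tibble(rule = character(), removed = integer(), remaining = integer())
}

#' Write the filtering report as a TSV
#'
#' @param mutations A filtered mutation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(mutations, path) {
  readr::write_tsv(filter_report(mutations), path)
  invisible(path)
}

#' Count per-variant somatic recurrence across the patient population
#'
#' A variant observed in m distinct patients contributes m occurrences to
#' downstream counts; duplicate (sample, variant) rows — e.g. the same call
#' reported by two sequencing centers — count once.
#'
#' @param mutations Mutation tibble.
#' @return Tibble keyed by (`protein_acc`, `protein_pos`, `ref_res`,
#'   `alt_res`, `variant_class`) with the host `gene` and `n_patients`, the
#'   number of distinct patients carrying the variant.
#' @export
count_recurrence <- function(mutations) {
  mutations |>
    dplyr::distinct(.data$sample_id, .data$protein_acc, .data$protein_pos,
                    .data$ref_res, .data$alt_res, .data$variant_class,
                    .keep_all = TRUE) |>
    dplyr::group_by(.data$protein_acc, .data$protein_pos, .data$ref_res,
                    .data$alt_res, .data$variant_class) |>
    dplyr::summarise(gene = dplyr::first(.data$gene),
                     n_patients = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop")
}

#' Choose one representative protein isoform per gene
#'
#' The representative is the longest isoform; ties are broken by the
#' lexicographically smallest accession so the choice is reproducible.
#'
#' @param proteins Protein tibble (`gene`, `protein_acc`, `length`).
#' @return The same tibble with `is_representative` set: exactly one TRUE per
#'   gene.
#' @export
select_representative_proteins <- function(proteins) {
  if (!nrow(proteins)) stop("protein set is empty", call. = FALSE)
  reps <- proteins |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(dplyr::desc(.data$length), .data$protein_acc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  dplyr::mutate(proteins,
                is_representative = .data$protein_acc %in% reps$protein_acc)
}

#' Assemble a validated cohort
#'
#' Selects representative isoforms, deduplicates (sample, variant) rows,
#' drops mutations on non-representative isoforms or unknown proteins (with
#' counts in the assembly log), and validates that every retained mutation
#' position lies within its protein.  Domain instances on unknown proteins or
#' extending past the protein end are dropped with a warning.
#'
#' @param mutations Filtered mutation tibble.
#' @param proteins Protein tibble; representatives are (re)selected with
#'   [select_representative_proteins()].
#' @param domains Domain-instance tibble.
#' @param name Cohort label used in reports.
#' @param n_patients Number of patients in the cohort; defaults to the number
#'   of distinct sample ids observed (override when some patients carry no
#'   retained mutation).
#' @return A `cohort` object: list with `name`, `patients`, `n_patients`,
#'   `mutations` (with a `mutation_id` key and the representative gene
#'   symbol), `proteins`, `domains`, `log`.
#' @export
build_cohort <- function(mutations, proteins, domains, name = "cohort",
                         n_patients = NULL) {
  proteins <- select_representative_proteins(proteins)
  log <- tibble::tibble(stage = character(), n = integer())
  note <- function(stage, n) {
    log <<- dplyr::bind_rows(log, tibble::tibble(stage = stage, n = as.integer(n)))
  }
  note("input_mutations", nrow(mutations))

  n0 <- nrow(mutations)
  mutations <- dplyr::distinct(
    mutations, .data$sample_id, .data$protein_acc, .data$protein_pos,
    .data$ref_res, .data$alt_res, .data$variant_class, .keep_all = TRUE)
  note("duplicate_rows_removed", n0 - nrow(mutations))

  unknown <- !(mutations$protein_acc %in% proteins$protein_acc)
  if (any(unknown)) {
    warning(sum(unknown), " mutation(s) on unknown proteins dropped",
            call. = FALSE)
    mutations <- mutations[!unknown, ]
  }
  note("unknown_protein_removed", sum(unknown))

  reps <- proteins[proteins$is_representative, ]
  off_rep <- !(mutations$protein_acc %in% reps$protein_acc)
  mutations <- mutations[!off_rep, ]
  note("non_representative_isoform_removed", sum(off_rep))

  lens <- reps$length[match(mutations$protein_acc, reps$protein_acc)]
  if (any(mutations$protein_pos > lens)) {
    stop("mutation position exceeds protein length for ",
         sum(mutations$protein_pos > lens), " record(s)", call. = FALSE)
  }
  # carry the representative gene symbol so counts key on the protein set
  mutations$gene <- reps$gene[match(mutations$protein_acc, reps$protein_acc)]
  mutations <- dplyr::mutate(mutations, mutation_id = dplyr::row_number())

  dom_unknown <- !(domains$protein_acc %in% proteins$protein_acc)
  if (any(dom_unknown)) {
    warning(sum(dom_unknown), " domain instance(s) on unknown proteins dropped",
            call. = FALSE)
    domains <- domains[!dom_unknown, ]
  }
  dlen <- proteins$length[match(domains$protein_acc, proteins$protein_acc)]
  dom_over <- domains$end > dlen
  if (any(dom_over)) {
    warning(sum(dom_over), " domain instance(s) exceeding protein length dropped",
            call. = FALSE)
    domains <- domains[!dom_over, ]
  }
  note("retained_mutations", nrow(mutations))

  structure(
    list(name = name,
         patients = sort(unique(mutations$sample_id)),
         n_patients = n_patients %||% dplyr::n_distinct(mutations$sample_id),
         mutations = mutations, proteins = proteins, domains = domains,
         log = log),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", x$name, ": ", nrow(x$mutations), " mutations, ",
      x$n_patients, " patients, ",
      sum(x$proteins$is_representative), " genes, ",
      dplyr::n_distinct(x$domains$domain_acc), " domains\n", sep = "")
  invisible(x)
}

#' Assign mutations to the domain instances covering them
#'
#' A mutation at residue p is assigned to every domain instance with
#' start <= p <= end on its protein (indels by their start residue, so a
#' deletion beginning inside an instance is assigned to it even if it extends
#' past the instance end).  Overlapping instances of different domains yield
#' one assignment each; mutations in inter-domain linkers yield none.
#'
#' @param cohort A `cohort` object.
#' @return Tibble with one row per (mutation, covering instance):
#'   `mutation_id`, `sample_id`, `gene`, `protein_acc`, `protein_pos`,
#'   `domain_acc`, `domain_name`, `start`, `end`.  The
#'   `"fraction_in_domain"` attribute gives the fraction of mutations covered
#'   by at least one instance.
#' @export
assign_mutations_to_domains <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  muts <- cohort$mutations
  reps <- cohort$proteins[cohort$proteins$is_representative, ]
  lens <- reps$length[match(muts$protein_acc, reps$protein_acc)]
  if (any(is.na(lens)) || any(muts$protein_pos > lens)) {
    stop("mutation position exceeds protein length: cohort invariant violated",
         call. = FALSE)
  }
  doms <- dplyr::semi_join(cohort$domains, reps, by = "protein_acc")
  out <- muts |>
    dplyr::select("mutation_id", "sample_id", "gene", "protein_acc",
                  "protein_pos") |>
    dplyr::inner_join(
      dplyr::select(doms, "protein_acc", "domain_acc", "domain_name",
                    "start", "end"),
      by = "protein_acc", relationship = "many-to-many") |>
    dplyr::filter(.data$start <= .data$protein_pos,
                  .data$protein_pos <= .data$end)
  attr(out, "fraction_in_domain") <-
    if (nrow(muts)) dplyr::n_distinct(out$mutation_id) / nrow(muts) else NA_real_
  out
}

#' Classify an insertion or deletion by reading-frame effect
#'
#' @param nt_length Nucleotide length(s) of the inserted or deleted sequence;
#'   integers >= 1.
#' @return `"frameshift"` when the length is not a multiple of three,
#'   `"nonframeshift"` otherwise (vectorized).
#' @export
classify_indel <- function(nt_length) {
  if (any(is.na(nt_length)) || any(nt_length < 1) ||
      any(nt_length != round(nt_length))) {
    stop("indel length must be an integer >= 1", call. = FALSE)
  }
  ifelse(nt_length %% 3 == 0, "nonframeshift", "frameshift")
}
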