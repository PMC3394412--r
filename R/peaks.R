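# Relating domain peaks to gene peaks, and comparing landscapes across
# cohorts.

#' Classify how each significant domain peak arose from the gene landscape
#'
#' A domain peak whose contributing genes are all themselves significant gene
#' peaks is classed `from_gene_peaks`; one whose contributors are all
#' non-significant is `aggregated` (the signature of cross-gene aggregation:
#' the domain reaches significance although no host gene does); anything in
#' between is `mixed`.
#'
#' @param domain_landscape Domain `landscape` (with breakdown).
#' @param gene_landscape Gene `landscape` of the same cohort.
#' @return Tibble with one row per significant domain: `domain_acc`,
#'   `origin_class`, `n_genes`, `n_significant_genes`, `genes` (collapsed
#'   `gene(k)` string, descending by count).
#' @export
classify_peak_origins <- function(domain_landscape, gene_landscape) {
  stopifnot(inherits(domain_landscape, "landscape"),
            inherits(gene_landscape, "landscape"),
            identical(domain_landscape$kind, "domain"),
            identical(gene_landscape$kind, "gene"))
  sig_domains <- significant_regions(domain_landscape)
  if (!length(sig_domains)) {
    return(tibble::tibble(domain_acc = character(), origin_class = character(),
                          n_genes = integer(), n_significant_genes = integer(),
                          genes = character()))
  }
  breakdown <- domain_landscape$breakdown
  sig_genes <- significant_regions(gene_landscape)
  purrr::map_dfr(sig_domains, function(d) {
    bd <- breakdown[breakdown$domain_acc == d & breakdown$k > 0, ]
    if (!nrow(bd)) {
      stop("significant domain ", d, " has an empty per-gene breakdown",
           call. = FALSE)
    }
    gene_sig <- bd$gene %in% sig_genes
    origin <- if (all(gene_sig)) "from_gene_peaks"
      else if (!any(gene_sig)) "aggregated" else "mixed"
    tibble::tibble(
      domain_acc = d, origin_class = origin,
      n_genes = nrow(bd), n_significant_genes = sum(gene_sig),
      genes = paste0(bd$gene, " (", bd$k, ")", collapse = ", ")
    )
  })
}

#' Re-test domain peaks after removing mutations from significant gene peaks
#'
#' Removes every mutation occurring in a significant gene (whole-gene "node
#' removal", not just the in-domain ones), then recomputes the domain
#' landscape from scratch — counts, background rate, z scores and a fresh
#' lfdr fit.  A previously significant domain that stays significant on the
#' reduced data "retained mutations after gene-peak removal": its signal does
#' not just piggyback on one dominant gene.  With no significant genes the
#' landscape is unchanged.
#'
#' @param cohort A `cohort` object.
#' @param gene_ls The called gene `landscape`.
#' @param domain_ls The called domain `landscape` (supplies the
#'   before-removal flags and the calling parameters, which are reused).
#' @return Tibble with one row per domain: `domain_acc`, `k_before`,
#'   `k_after`, `significant_before`, `significant_after`,
#'   `retained_after_removal` (significant both before and after).  The
#'   re-called landscape is attached as the `"landscape_after"` attribute.
#' @export
recall_after_gene_peak_removal <- function(cohort, gene_ls, domain_ls) {
  stopifnot(inherits(cohort, "cohort"),
            identical(gene_ls$kind, "gene"),
            identical(domain_ls$kind, "domain"))
  sig_genes <- significant_regions(gene_ls)
  reduced <- cohort
  reduced$mutations <- cohort$mutations[!(cohort$mutations$gene %in% sig_genes), ]
  p <- domain_ls$params
  after <- if (sum(gene_counts(reduced)$k) == 0) NULL else {
    domain_landscape(reduced, lfdr_threshold = p$lfdr_threshold,
                     min_length = p$min_length, z_form = p$z_form,
                     min_regions = p$min_regions)
  }
  before <- domain_ls$stats
  after_stats <- if (is.null(after)) {
    dplyr::mutate(before[, c("region_id", "L")], k = 0L, significant = FALSE)
  } else after$stats
  out <- before |>
    dplyr::select(domain_acc = "region_id", k_before = "k",
                  significant_before = "significant") |>
    dplyr::left_join(
      dplyr::select(after_stats, domain_acc = "region_id", k_after = "k",
                    significant_after = "significant"),
      by = "domain_acc") |>
    dplyr::mutate(
      k_after = tidyr::replace_na(.data$k_after, 0L),
      significant_after = tidyr::replace_na(.data$significant_after, FALSE),
      retained_after_removal = .data$significant_before & .data$significant_after
    ) |>
    dplyr::relocate("domain_acc", "k_before", "k_after",
                    "significant_before", "significant_after",
                    "retained_after_removal")
  attr(out, "landscape_after") <- after
  out
}

#' Compare the significant peaks of two cohort landscapes
#'
#' Computes the shared and exclusive significant regions of two landscapes of
#' the same kind and the shared percentages (one decimal), the numbers behind
#' a two-set Venn diagram of peak overlap.
#'
#' @param a,b `landscape` objects of the same kind.
#' @return A `landscape_comparison` object: list with `kind`, `name_a`,
#'   `name_b`, `significant_a`, `significant_b`, `shared`, `exclusive_a`,
#'   `exclusive_b`, `shared_percent_a`, `shared_percent_b`.
#' @export
compare_cohorts <- function(a, b) {
  stopifnot(inherits(a, "landscape"), inherits(b, "landscape"))
  if (!identical(a$kind, b$kind)) {
    stop("cannot compare landscapes of different kinds: ",
         a$kind, " vs ", b$kind, call. = FALSE)
  }
  sa <- significant_regions(a)
  sb <- significant_regions(b)
  shared <- sort(intersect(sa, sb))
  structure(
    list(kind = a$kind, name_a = a$cohort_name, name_b = b$cohort_name,
         significant_a = sa, significant_b = sb, shared = shared,
         exclusive_a = sort(setdiff(sa, sb)),
         exclusive_b = sort(setdiff(sb, sa)),
         shared_percent_a = round(100 * length(shared) / max(1L, length(sa)), 1),
         shared_percent_b = round(100 * length(shared) / max(1L, length(sb)), 1)),
    class = "landscape_comparison"
  )
}

#' @export
print.landscape_comparison <- function(x, ...) {
  cat("<landscape_comparison> ", x$kind, ": ", x$name_a, " (",
      length(x$significant_a), ") vs ", x$name_b, " (",
      length(x$significant_b), "), shared ", length(x$shared),
      " (", x$shared_percent_a, "% / ", x$shared_percent_b, "%)\n", sep = "")
  invisible(x)
}

#' Shared domain peaks hosted inside shared gene peaks
#'
#' Of the domain peaks shared between two cohorts, returns those whose host
#' genes intersect the shared gene peaks — the (typically rare) case where
#' gene-level and domain-level agreement coincide.
#'
#' @param gene_comparison `landscape_comparison` of kind `"gene"`.
#' @param domain_comparison `landscape_comparison` of kind `"domain"`.
#' @param domain_genes Tibble `domain_acc`, `gene` mapping domains to host
#'   genes (e.g. a domain-landscape breakdown or an instance map joined to a
#'   protein set).
#' @return Character vector of qualifying domain accessions.
#' @export
shared_domain_in_shared_gene <- function(gene_comparison, domain_comparison,
                                         domain_genes) {
  stopifnot(identical(gene_comparison$kind, "gene"),
            identical(domain_comparison$kind, "domain"))
  shared_genes <- gene_comparison$shared
  hosts <- domain_genes[domain_genes$domain_acc %in% domain_comparison$shared, ]
  sort(unique(hosts$domain_acc[hosts$gene %in% shared_genes]))
}
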