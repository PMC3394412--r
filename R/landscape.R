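# Length-normalized mutation frequencies, the Bernoulli-standardized z score,
# and peak calling for gene and domain landscapes.  Genes and domains are
# fitted as separate landscapes: separate background rates and separate
# local-fdr fits.

#' Occurrence-weighted mutation counts per gene
#'
#' Counts retained mutation occurrences (one per patient carrying the
#' variant) falling in each gene's representative protein.  Genes with at
#' least one retained mutation form the landscape universe (the "cancer gene
#' set").
#'
#' @param cohort A `cohort` object.
#' @return Tibble `gene`, `k`, sorted by gene.
#' @export
gene_counts <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  dplyr::count(cohort$mutations, .data$gene, name = "k") |>
    dplyr::arrange(.data$gene)
}

#' Cumulative length of each domain across a protein set
#'
#' The normalizing length of a domain is the summed residue length of all of
#' its placements (end - start + 1), so a domain repeated seven times in one
#' protein contributes all seven copies.
#'
#' @param domains Domain-instance tibble.
#' @param proteins Optional protein tibble; when given, instances are
#'   restricted to representative proteins first.
#' @return Tibble `domain_acc`, `domain_name`, `L`.
#' @export
cumulative_domain_length <- function(domains, proteins = NULL) {
  if (!is.null(proteins)) {
    reps <- proteins[proteins$is_representative, ]
    domains <- dplyr::semi_join(domains, reps, by = "protein_acc")
  }
  domains |>
    dplyr::group_by(.data$domain_acc) |>
    dplyr::summarise(domain_name = dplyr::first(.data$domain_name),
                     L = as.integer(sum(.data$end - .data$start + 1L)),
                     .groups = "drop") |>
    dplyr::arrange(.data$domain_acc)
}

#' Occurrence-weighted mutation counts per domain, with per-gene breakdown
#'
#' A mutation assigned to a domain counts once toward that domain no matter
#' how many instances of the same domain cover it; the breakdown lists the
#' contributing genes with their counts (the structure behind aggregated
#' domain peaks).
#'
#' @param assignments Assignment tibble from [assign_mutations_to_domains()].
#' @return List with `counts` (tibble `domain_acc`, `k`) and `breakdown`
#'   (tibble `domain_acc`, `gene`, `k`).
#' @export
domain_counts <- function(assignments) {
  hits <- dplyr::distinct(assignments, .data$mutation_id, .data$domain_acc,
                          .data$gene)
  counts <- hits |>
    dplyr::distinct(.data$mutation_id, .data$domain_acc) |>
    dplyr::count(.data$domain_acc, name = "k") |>
    dplyr::arrange(.data$domain_acc)
  breakdown <- hits |>
    dplyr::count(.data$domain_acc, .data$gene, name = "k") |>
    dplyr::arrange(.data$domain_acc, dplyr::desc(.data$k), .data$gene)
  list(counts = counts, breakdown = breakdown)
}

#' Length-normalized mutation frequency
#'
#' @param k Mutation count(s), >= 0.
#' @param L Normalizing length(s) in amino acids, >= 1.
#' @return `k / L` (vectorized).
#' @export
normalized_frequency <- function(k, L) {
  if (any(L < 1)) stop("normalizing length must be >= 1", call. = FALSE)
  if (any(k < 0)) stop("mutation count must be >= 0", call. = FALSE)
  k / L
}

#' Pooled background mutation rate
#'
#' Under the uniform-passenger assumption the background per-residue success
#' probability is the pooled rate over all regions being tested:
#' `p0 = sum(k) / sum(L)`.
#'
#' @param k Region mutation counts.
#' @param L Region normalizing lengths.
#' @return The pooled rate `p0`.
#' @export
background_rate <- function(k, L) {
  if (length(L) == 0 || sum(L) == 0) {
    stop("total normalizing length is zero", call. = FALSE)
  }
  sum(k) / sum(L)
}

#' Bernoulli-standardized mutation-frequency score
#'
#' Default form standardizes the observed per-residue frequency against the
#' pooled background under a binomial model,
#' `z = (k/L - p0) / sqrt(p0 (1 - p0) / L)`, which is approximately N(0,1)
#' for passenger-only regions and strictly increasing in `k` at fixed `L`.
#' The `"snr"` form is the literal signal-to-noise ratio of a Bernoulli
#' variable with success probability `p = k/L`, `z = sqrt(p / (1 - p))`.
#'
#' @param k Mutation count(s).
#' @param L Normalizing length(s), >= 1.
#' @param p0 Pooled background rate, strictly inside (0, 1) (unused by the
#'   `"snr"` form).
#' @param form `"binomial"` (default) or `"snr"`.
#' @return Numeric z score(s).
#' @export
bernoulli_z <- function(k, L, p0, form = c("binomial", "snr")) {
  form <- match.arg(form)
  if (any(L < 1)) stop("normalizing length must be >= 1", call. = FALSE)
  if (form == "binomial") {
    if (!is.finite(p0) || p0 <= 0 || p0 >= 1) {
      stop("background rate p0 must lie strictly between 0 and 1",
           call. = FALSE)
    }
    (k / L - p0) / sqrt(p0 * (1 - p0) / L)
  } else {
    p <- k / L
    ifelse(p >= 1, Inf, sqrt(p / (1 - p)))
  }
}

#' Call significantly mutated regions from counts and lengths
#'
#' The peak-calling pipeline: regions shorter than `min_length` are excluded
#' before fitting (flagged `excluded_short`; the heuristic guards against
#' unstable frequencies on very short regions), the pooled background rate is
#' computed over the tested regions, each region is scored with
#' [bernoulli_z()], the local false discovery rate is fitted over the score
#' ensemble with [fit_local_fdr()], and a region is significant iff
#' `lfdr < lfdr_threshold` (strict), it was not excluded for length, it
#' carries at least one mutation, and its frequency is elevated (`z > 0`;
#' the lfdr is small in both tails, but a depleted region is not a peak).
#' Zero-count regions participate in the null fit but can never be
#' significant.
#'
#' @param regions Tibble with columns `region_id`, `region_kind`, `k`, `L`.
#' @param lfdr_threshold Strict local-fdr cutoff for significance
#'   (default 0.1).
#' @param min_length Minimum region length in amino acids (default 150).
#' @param z_form Passed to [bernoulli_z()].
#' @param min_regions Passed to [fit_local_fdr()].
#' @param kind Landscape kind label (`"gene"` or `"domain"`).
#' @param cohort_name Cohort label carried into comparisons.
#' @return A `landscape` object: list with `stats` (tibble adding `p_hat`,
#'   `z`, `lfdr`, `significant`, `excluded_short`), `p0`, `fit` (an
#'   `lfdr_fit` or NULL), `kind`, `cohort_name`, `params`, and optionally
#'   `breakdown`.
#' @export
call_peaks <- function(regions, lfdr_threshold = 0.1, min_length = 150,
                       z_form = c("binomial", "snr"), min_regions = 200,
                       kind = NULL, cohort_name = "cohort") {
  z_form <- match.arg(z_form)
  stopifnot(all(c("region_id", "region_kind", "k", "L") %in% names(regions)))
  if (lfdr_threshold < 0) stop("lfdr_threshold must be >= 0", call. = FALSE)
  stats <- regions |>
    dplyr::mutate(p_hat = normalized_frequency(.data$k, .data$L),
                  excluded_short = .data$L < min_length,
                  z = NA_real_, lfdr = NA_real_, significant = FALSE)
  inc <- !stats$excluded_short
  p0 <- NA_real_
  fit <- NULL
  if (any(inc)) {
    p0 <- background_rate(stats$k[inc], stats$L[inc])
    stats$z[inc] <- bernoulli_z(stats$k[inc], stats$L[inc], p0, form = z_form)
    z_inc <- stats$z[inc]
    if (length(z_inc) < 2 ||
        diff(range(z_inc)) < sqrt(.Machine$double.eps)) {
      warning("fewer than two distinct scores: no lfdr fit, ",
              "no region called significant", call. = FALSE)
    } else {
      fit <- fit_local_fdr(z_inc, min_regions = min_regions)
      stats$lfdr[inc] <- fit$lfdr
      # peaks are elevated frequencies: the lfdr is small in both tails, but
      # a depleted region (z < 0) is not a mutation peak
      stats$significant <- !stats$excluded_short &
        !is.na(stats$lfdr) & stats$lfdr < lfdr_threshold &
        stats$k > 0 & !is.na(stats$z) & stats$z > 0
    }
  }
  structure(
    list(stats = dplyr::as_tibble(stats), p0 = p0, fit = fit,
         kind = kind %||% stats$region_kind[1], cohort_name = cohort_name,
         params = list(lfdr_threshold = lfdr_threshold,
                       min_length = min_length, z_form = z_form,
                       min_regions = min_regions)),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", x$kind, " (", x$cohort_name, "): ",
      nrow(x$stats), " regions, ",
      sum(x$stats$significant), " significant, ",
      sum(x$stats$excluded_short), " excluded (< ",
      x$params$min_length, " aa), p0 = ", signif(x$p0, 4), "\n", sep = "")
  invisible(x)
}

#' Gene mutation landscape of a cohort
#'
#' Builds the per-gene region table (occurrence-weighted counts, normalized
#' by representative-protein length) and calls peaks with [call_peaks()].
#'
#' @inheritParams call_peaks
#' @param cohort A `cohort` object.
#' @return A `landscape` object with `kind = "gene"`.
#' @export
gene_landscape <- function(cohort, lfdr_threshold = 0.1, min_length = 150,
                           z_form = c("binomial", "snr"), min_regions = 200) {
  z_form <- match.arg(z_form)
  reps <- cohort$proteins[cohort$proteins$is_representative, ]
  regions <- gene_counts(cohort) |>
    dplyr::inner_join(dplyr::select(reps, "gene", L = "length"), by = "gene") |>
    dplyr::transmute(region_id = .data$gene, region_kind = "gene",
                     k = .data$k, L = .data$L)
  call_peaks(regions, lfdr_threshold, min_length, z_form, min_regions,
             kind = "gene", cohort_name = cohort$name)
}

#' Domain mutation landscape of a cohort
#'
#' Aggregates mutations from all genes containing each domain: the region
#' universe is every domain with at least one instance on a representative
#' protein (zero-count domains enter the null fit), counts come from
#' [domain_counts()] and normalizing lengths from
#' [cumulative_domain_length()].
#'
#' @inheritParams call_peaks
#' @param cohort A `cohort` object.
#' @return A `landscape` object with `kind = "domain"` and a `breakdown`
#'   element (per-gene contribution counts per domain).
#' @export
domain_landscape <- function(cohort, lfdr_threshold = 0.1, min_length = 150,
                             z_form = c("binomial", "snr"), min_regions = 200) {
  z_form <- match.arg(z_form)
  lens <- cumulative_domain_length(cohort$domains, cohort$proteins)
  dc <- domain_counts(assign_mutations_to_domains(cohort))
  regions <- lens |>
    dplyr::left_join(dc$counts, by = "domain_acc") |>
    dplyr::mutate(k = tidyr::replace_na(.data$k, 0L)) |>
    dplyr::transmute(region_id = .data$domain_acc, region_kind = "domain",
                     k = .data$k, L = .data$L)
  ls <- call_peaks(regions, lfdr_threshold, min_length, z_form, min_regions,
                   kind = "domain", cohort_name = cohort$name)
  ls$breakdown <- dc$breakdown
  ls
}

#' Significant region ids of a landscape
#'
#' @param landscape A `landscape` object.
#' @return Character vector of significant region ids.
#' @export
significant_regions <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  sort(landscape$stats$region_id[landscape$stats$significant])
}

#' Mutation prevalence of a region in the patient population
#'
#' Prevalence is the region's mutation count divided by the number of
#' patients in the cohort; regions at or above `high_threshold` (default
#' 0.04) are flagged as high-prevalence.  Prevalence and length-normalized
#' frequency capture different things: a short domain can be a significant
#' frequency peak at low prevalence and vice versa.
#'
#' @param k Mutation count(s).
#' @param n_patients Number of patients, >= 1.
#' @param high_threshold Inclusive high-prevalence cutoff.
#' @return Tibble `k`, `prevalence`, `high`.
#' @export
mutation_prevalence <- function(k, n_patients, high_threshold = 0.04) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  prevalence <- k / n_patients
  tibble::tibble(k = k, prevalence = prevalence,
                 high = prevalence >= high_threshold)
}

#' Cohort mutation-count report
#'
#' The standard descriptive summary of a cohort's mutation burden: per-class
#' counts with percentages (one decimal), the in-domain percentage, and
#' per-patient statistics (mean rounded to integer, SD as the spread
#' measure).
#'
#' @param class_counts Tibble `variant_class`, `n` of retained mutation
#'   counts per class.
#' @param n_patients Number of patients.
#' @param n_in_domain Number of mutations inside annotated domain regions
#'   (optional).
#' @param per_patient Optional integer vector of per-patient totals (enables
#'   SD and range).
#' @return A one-row tibble of totals plus a `per_class` tibble attribute
#'   with the per-class percentages.
#' @export
mutation_report <- function(class_counts, n_patients, n_in_domain = NA,
                            per_patient = NULL) {
  total <- sum(class_counts$n)
  per_class <- class_counts |>
    dplyr::mutate(percent = round(100 * .data$n / total, 1)) |>
    dplyr::arrange(dplyr::desc(.data$n))
  out <- tibble::tibble(
    n_patients = n_patients,
    total_mutations = total,
    in_domain = n_in_domain,
    in_domain_percent = round(100 * n_in_domain / total, 1),
    mean_per_patient = round(total / n_patients),
    sd_per_patient = if (!is.null(per_patient)) round(sd(per_patient)) else NA_real_,
    min_per_patient = if (!is.null(per_patient)) min(per_patient) else NA_integer_,
    max_per_patient = if (!is.null(per_patient)) max(per_patient) else NA_integer_
  )
  attr(out, "per_class") <- per_class
  out
}

#' Summarize a cohort's mutation burden
#'
#' Convenience wrapper computing [mutation_report()] inputs from a cohort:
#' per-class retained counts, the in-domain count (mutations covered by at
#' least one domain instance), and per-patient totals.
#'
#' @param cohort A `cohort` object.
#' @return See [mutation_report()].
#' @export
cohort_summary <- function(cohort) {
  class_counts <- dplyr::count(cohort$mutations, .data$variant_class, name = "n")
  asn <- assign_mutations_to_domains(cohort)
  per_patient <- dplyr::count(cohort$mutations, .data$sample_id)$n
  mutation_report(class_counts, cohort$n_patients,
                  n_in_domain = dplyr::n_distinct(asn$mutation_id),
                  per_patient = per_patient)
}
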