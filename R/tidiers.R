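# broom-style accessors for the fitted objects.

#' Tidy a landscape into its per-region statistics
#'
#' @param x A `landscape` object.
#' @param ... Unused.
#' @return The statistics tibble (one row per region).
#' @method tidy landscape
#' @export
tidy.landscape <- function(x, ...) x$stats

#' One-row summary of a landscape
#'
#' @param x A `landscape` object.
#' @param ... Unused.
#' @return Tibble with region counts, the pooled background rate, and the
#'   null-fit parameters.
#' @method glance landscape
#' @export
glance.landscape <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, cohort = x$cohort_name,
    n_regions = nrow(x$stats),
    n_excluded_short = sum(x$stats$excluded_short),
    n_significant = sum(x$stats$significant),
    p0 = x$p0,
    pi0 = if (!is.null(x$fit)) x$fit$pi0 else NA_real_,
    null_mean = if (!is.null(x$fit)) x$fit$null_mean else NA_real_,
    null_sd = if (!is.null(x$fit)) x$fit$null_sd else NA_real_,
    null_type = if (!is.null(x$fit)) x$fit$null_type else NA_character_
  )
}

#' Tidy an lfdr fit into per-score rows
#'
#' @param x An `lfdr_fit` object.
#' @param ... Unused.
#' @return Tibble `z`, `lfdr`.
#' @method tidy lfdr_fit
#' @export
tidy.lfdr_fit <- function(x, ...) tibble::tibble(z = x$z, lfdr = x$lfdr)

#' One-row summary of an lfdr fit
#'
#' @param x An `lfdr_fit` object.
#' @param ... Unused.
#' @return Tibble `n`, `null_type`, `null_mean`, `null_sd`, `pi0`.
#' @method glance lfdr_fit
#' @export
glance.lfdr_fit <- function(x, ...) {
  tibble::tibble(n = x$n, null_type = x$null_type, null_mean = x$null_mean,
                 null_sd = x$null_sd, pi0 = x$pi0)
}

#' Tidy a landscape comparison into Venn counts
#'
#' @param x A `landscape_comparison` object.
#' @param ... Unused.
#' @return Tibble with one row per Venn compartment (`exclusive_a`,
#'   `shared`, `exclusive_b`) plus the set sizes.
#' @method tidy landscape_comparison
#' @export
tidy.landscape_comparison <- function(x, ...) {
  tibble::tibble(
    compartment = c("exclusive_a", "shared", "exclusive_b"),
    cohort = c(x$name_a, paste(x$name_a, x$name_b, sep = " & "), x$name_b),
    n = c(length(x$exclusive_a), length(x$shared), length(x$exclusive_b))
  )
}

#' One-row summary of a landscape comparison
#'
#' @param x A `landscape_comparison` object.
#' @param ... Unused.
#' @return Tibble with set sizes and shared percentages.
#' @method glance landscape_comparison
#' @export
glance.landscape_comparison <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, name_a = x$name_a, name_b = x$name_b,
    n_a = length(x$significant_a), n_b = length(x$significant_b),
    n_shared = length(x$shared),
    shared_percent_a = x$shared_percent_a,
    shared_percent_b = x$shared_percent_b
  )
}

#' Write a comparison report (Venn counts + shared ids) as TSV
#'
#' @param comparison A `landscape_comparison` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(comparison, path) {
  stopifnot(inherits(comparison, "landscape_comparison"))
  readr::write_tsv(tidy(comparison), path)
  invisible(path)
}
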