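# GO-term overrepresentation of significant entities versus non-significant
# mutated entities, with ancestor propagation over the ontology DAG.

# all ancestors of `term` (excluding the term itself), memoized in `env`
ancestors_of <- function(term, parents, env) {
  if (!is.null(env[[term]])) return(env[[term]])
  ps <- parents[[term]] %||% character()
  anc <- ps
  for (p in ps) anc <- c(anc, ancestors_of(p, parents, env))
  anc <- unique(anc)
  env[[term]] <- anc
  anc
}

#' Propagate annotations up the ontology
#'
#' Expands each entity's term set to include every ancestor along every path
#' to the root (the true-path rule), excluding the root terms themselves.
#' Annotations to terms absent from the graph are dropped with a warning.
#' Propagation is idempotent.
#'
#' @param graph An `ontology_graph` from [read_obo()].
#' @param annotations Tibble `entity`, `term`.
#' @return Expanded tibble `entity`, `term` (distinct, sorted).
#' @export
propagate_annotations <- function(graph, annotations) {
  stopifnot(inherits(graph, "ontology_graph"))
  known <- annotations$term %in% graph$terms$id
  if (!all(known)) {
    warning(sum(!known), " annotation(s) to unknown terms dropped",
            call. = FALSE)
    annotations <- annotations[known, ]
  }
  env <- new.env(parent = emptyenv())
  closure <- lapply(
    setNames(unique(annotations$term), unique(annotations$term)),
    function(t) setdiff(unique(c(t, ancestors_of(t, graph$parents, env))),
                        graph$roots)
  )
  annotations |>
    dplyr::distinct(.data$entity, .data$term) |>
    dplyr::mutate(term = unname(closure[.data$term])) |>
    tidyr::unnest("term") |>
    dplyr::distinct(.data$entity, .data$term) |>
    dplyr::arrange(.data$entity, .data$term)
}

#' Right-tail Fisher exact p-value of a 2x2 table
#'
#' The one-sided p-value for overrepresentation: the probability, under the
#' hypergeometric null with the table's margins fixed, of `a` or more
#' significant-and-annotated entities.  Computed through the hypergeometric
#' tail identity (vectorized).
#'
#' @param a,b,c,d Cell counts: significant/annotated, significant/not,
#'   non-significant/annotated, non-significant/not.
#' @return Right-tail p-value(s) in (0, 1].
#' @export
fisher_right_tail <- function(a, b, c, d) {
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Term overrepresentation in significant versus non-significant entities
#'
#' For each term, builds the 2x2 table of (significant vs not) x (annotated
#' vs not) over the background — the entities carrying at least one somatic
#' mutation — and computes the right-tail (one-sided) Fisher exact p-value.
#' Terms annotated to no background entity are skipped.  No multiple-testing
#' correction is applied to the ranking; a Benjamini-Hochberg `q` column is
#' emitted for convenience.
#'
#' @param significant Character vector of significant entity ids, a subset of
#'   `background`.
#' @param background Character vector of mutated entity ids.
#' @param annotations Tibble `entity`, `term` (typically
#'   [propagate_annotations()] output).
#' @param graph Optional `ontology_graph` used to attach term names and to
#'   restrict testing to `namespaces`.
#' @param namespaces Namespaces tested when `graph` is given (default
#'   biological process and molecular function; cellular component is
#'   excluded).
#' @return Tibble `term`, `name`, `a`, `b`, `c`, `d`, `p`, `q`, sorted by
#'   ascending p with ties broken by term id.  `a` counts
#'   significant-and-annotated entities; `a + b` equals the number of
#'   significant entities.
#' @export
enrich <- function(significant, background, annotations, graph = NULL,
                   namespaces = c("biological_process", "molecular_function")) {
  significant <- unique(significant)
  background <- unique(background)
  if (!all(significant %in% background)) {
    stop("significant set must be a subset of the background", call. = FALSE)
  }
  empty <- tibble::tibble(term = character(), name = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), p = double(), q = double())
  if (!length(significant)) return(empty)
  ann <- annotations[annotations$entity %in% background, ]
  if (!is.null(graph)) {
    keep_terms <- graph$terms$id[graph$terms$namespace %in% namespaces]
    ann <- ann[ann$term %in% keep_terms, ]
  }
  if (!nrow(ann)) return(empty)
  n_sig <- length(significant)
  n_bg <- length(background)
  counts <- ann |>
    dplyr::distinct(.data$entity, .data$term) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      a = sum(.data$entity %in% significant),
      annotated = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(b = n_sig - .data$a,
                  c = .data$annotated - .data$a,
                  d = (n_bg - n_sig) - .data$c,
                  p = fisher_right_tail(.data$a, .data$b, .data$c, .data$d),
                  q = p.adjust(.data$p, method = "BH"))
  out <- counts |>
    dplyr::select("term", "a", "b", "c", "d", "p", "q") |>
    dplyr::arrange(.data$p, .data$term)
  out$name <- if (!is.null(graph)) {
    graph$terms$name[match(out$term, graph$terms$id)]
  } else NA_character_
  dplyr::relocate(out, "term", "name")
}

#' Write enrichment results as a TSV
#'
#' @param results Tibble from [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(results, path) {
  readr::write_tsv(results, path, na = "NA")
  invisible(path)
}
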