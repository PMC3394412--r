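# Readers and writers for every external format the pipeline touches.
# All tables come back as tibbles; rejected rows are never silently dropped —
# they are enumerated in the "parse_report" attribute (see parse_report()).

#' Read a per-patient somatic mutation table
#'
#' Parses a MAF-like TSV of somatic variant observations into the canonical
#' mutation tibble used throughout the package.  Coordinates are protein-space:
#' `protein_pos` is the 1-based residue index (for indels, the start residue).
#'
#' Two dialects are supported. `"simple_tsv"` uses the canonical column names
#' directly (`sample_id`, `gene`, `protein_acc`, `protein_pos`, `ref_res`,
#' `alt_res`, `variant_class`, `dbsnp_id`, `is_somatic`, `passed_qc`; the last
#' four are optional).  `"maf_subset"` consumes the subset of MAF columns that
#' map onto those fields (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Protein_Accession`, `Protein_Position`, `Variant_Classification`,
#' `dbSNP_RS`, `Mutation_Status`, optional `Ref_Residue`/`Alt_Residue`/
#' `Quality_Filter`); MAF consequence labels (`Missense_Mutation`, `Silent`,
#' `Nonsense_Mutation`, `Nonstop_Mutation`, `Frame_Shift_Ins`,
#' `Frame_Shift_Del`, `In_Frame_Ins`, `In_Frame_Del`) are translated to the
#' [MUTATION_CLASSES] vocabulary.  Extra columns are ignored in both dialects.
#'
#' Rows with an unparseable or non-positive position, an unknown variant
#' class, or an empty sample id are rejected (with row number and reason in
#' the parse report); all other rows are kept in input order.
#'
#' @param path Path to a tab-separated file.
#' @param dialect `"simple_tsv"` (default) or `"maf_subset"`.
#' @return A tibble with one row per (sample, variant) observation and columns
#'   `sample_id`, `gene`, `protein_acc`, `protein_pos` (integer), `ref_res`,
#'   `alt_res` (NA for indels), `variant_class`, `dbsnp_id`, `is_somatic`,
#'   `passed_qc`.  The `"parse_report"` attribute lists rejected rows.
#' @seealso [write_mutation_table()], [filter_cohort()]
#' @export
read_mutation_table <- function(path, dialect = c("simple_tsv", "maf_subset")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", comment = "#", progress = FALSE)
  if (dialect == "maf_subset") raw <- maf_to_simple(raw)

  required <- c("sample_id", "gene", "protein_acc", "protein_pos", "variant_class")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("mutation table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("ref_res", "alt_res", "dbsnp_id")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  if (!"is_somatic" %in% names(raw)) raw$is_somatic <- "TRUE"
  if (!"passed_qc" %in% names(raw)) raw$passed_qc <- "TRUE"

  pos <- suppressWarnings(as.integer(raw$protein_pos))
  reason <- dplyr::case_when(
    is.na(pos) | pos < 1L ~ "unparseable or non-positive protein_pos",
    !(raw$variant_class %in% MUTATION_CLASSES) ~ "unknown variant_class",
    is.na(raw$sample_id) | raw$sample_id == "" ~ "empty sample_id",
    .default = NA_character_
  )
  keep <- is.na(reason)
  out <- tibble::tibble(
    sample_id     = raw$sample_id[keep],
    gene          = raw$gene[keep],
    protein_acc   = raw$protein_acc[keep],
    protein_pos   = pos[keep],
    ref_res       = raw$ref_res[keep],
    alt_res       = raw$alt_res[keep],
    variant_class = raw$variant_class[keep],
    dbsnp_id      = raw$dbsnp_id[keep],
    is_somatic    = parse_flag(raw$is_somatic[keep]),
    passed_qc     = parse_flag(raw$passed_qc[keep])
  )
  report <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  if (nrow(report)) {
    warning(nrow(report), " mutation row(s) rejected; see parse_report()",
            call. = FALSE)
  }
  attr(out, "parse_report") <- report
  out
}

#' Write a mutation table in the simple TSV dialect
#'
#' @param mutations Mutation tibble as returned by [read_mutation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(mutations, path) {
  cols <- c("sample_id", "gene", "protein_acc", "protein_pos", "ref_res",
            "alt_res", "variant_class", "dbsnp_id", "is_somatic", "passed_qc")
  readr::write_tsv(mutations[, cols], path, na = "NA")
  invisible(path)
}

# TRUE/FALSE flags with permissive spellings; absent values count as TRUE
parse_flag <- function(x) {
  u <- toupper(trimws(x))
  out <- u %in% c("TRUE", "T", "1", "YES", "Y")
  out[is.na(x)] <- TRUE
  out
}

# translate the consumed MAF columns onto the simple dialect
maf_to_simple <- function(raw) {
  class_map <- c(
    Missense_Mutation = "nsSNV",           Silent = "synonymous_SNV",
    Nonsense_Mutation = "stopgain_SNV",    Nonstop_Mutation = "stoploss_SNV",
    Frame_Shift_Ins = "frameshift_ins",    Frame_Shift_Del = "frameshift_del",
    In_Frame_Ins = "nonframeshift_ins",    In_Frame_Del = "nonframeshift_del"
  )
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Protein_Accession",
            "Protein_Position", "Variant_Classification")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("maf_subset table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  vc <- raw$Variant_Classification
  mapped <- unname(class_map[vc])
  mapped[is.na(mapped)] <- vc[is.na(mapped)]  # unknowns rejected downstream
  dbsnp <- if ("dbSNP_RS" %in% names(raw)) raw$dbSNP_RS else NA_character_
  dbsnp[!is.na(dbsnp) & tolower(dbsnp) == "novel"] <- NA_character_
  tibble::tibble(
    sample_id = raw$Tumor_Sample_Barcode,
    gene = raw$Hugo_Symbol,
    protein_acc = raw$Protein_Accession,
    protein_pos = raw$Protein_Position,
    ref_res = if ("Ref_Residue" %in% names(raw)) raw$Ref_Residue else NA_character_,
    alt_res = if ("Alt_Residue" %in% names(raw)) raw$Alt_Residue else NA_character_,
    variant_class = mapped,
    dbsnp_id = dbsnp,
    is_somatic = if ("Mutation_Status" %in% names(raw)) {
      ifelse(tolower(raw$Mutation_Status) == "somatic", "TRUE", "FALSE")
    } else "TRUE",
    passed_qc = if ("Quality_Filter" %in% names(raw)) {
      ifelse(toupper(raw$Quality_Filter) %in% c("PASS", "PASSED"), "TRUE", "FALSE")
    } else "TRUE"
  )
}

#' Report of rows rejected or dropped by a reader
#'
#' @param x A tibble returned by one of the readers.
#' @return A tibble with columns `row` and `reason` (empty when nothing was
#'   rejected).
#' @export
parse_report <- function(x) {
  attr(x, "parse_report") %||% tibble::tibble(row = integer(), reason = character())
}

#' Read a protein-to-domain instance map
#'
#' Each row places one domain model on one protein as a 1-based inclusive
#' interval with an E-value.  Instances with E-value above `evalue_cutoff`
#' (default 0.001, the conventional threshold for trusting a complete-domain
#' hit) are dropped and counted.  When a protein set is supplied, instances on
#' unknown proteins are dropped with a warning and instances extending past
#' the protein end are rejected.
#'
#' The `"hmmscan_domtbl"` dialect parses HMMER3 `--domtblout` output: the
#' domain accession is the target accession (version suffix stripped), the
#' interval is `ali_from`..`ali_to`, and the E-value is the per-domain
#' independent E-value (`i-Evalue`) column.
#'
#' @param path Path to the map file.
#' @param dialect `"simple_tsv"` (columns `domain_acc`, `domain_name`
#'   (optional), `protein_acc`, `start`, `end`, `evalue`) or
#'   `"hmmscan_domtbl"`.
#' @param evalue_cutoff Maximum E-value retained; use `Inf` to keep all rows.
#' @param proteins Optional protein tibble (see [read_protein_set()]) used to
#'   validate accessions and coordinates.
#' @return Tibble with columns `domain_acc`, `domain_name`, `protein_acc`,
#'   `start`, `end`, `evalue`.  Attributes: `"parse_report"` (rejected rows),
#'   `"n_evalue_filtered"`, `"n_unknown_protein"`.
#' @export
read_domain_map <- function(path, dialect = c("simple_tsv", "hmmscan_domtbl"),
                            evalue_cutoff = 0.001, proteins = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "simple_tsv") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           na = "NA", comment = "#", progress = FALSE)
    req <- c("domain_acc", "protein_acc", "start", "end", "evalue")
    miss <- setdiff(req, names(raw))
    if (length(miss)) {
      stop("domain map is missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (!"domain_name" %in% names(raw)) raw$domain_name <- raw$domain_acc
    pre_rejected <- tibble::tibble(row = integer(), reason = character())
  } else {
    parsed <- parse_domtbl(path)
    raw <- parsed$rows
    pre_rejected <- parsed$rejected
  }

  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  evalue <- suppressWarnings(as.numeric(raw$evalue))
  reason <- dplyr::case_when(
    is.na(start) | is.na(end) | start < 1L ~ "unparseable or non-positive coordinates",
    start > end ~ "start greater than end",
    is.na(evalue) | evalue < 0 ~ "unparseable or negative evalue",
    .default = NA_character_
  )
  keep <- is.na(reason)
  out <- tibble::tibble(
    domain_acc = raw$domain_acc[keep],
    domain_name = raw$domain_name[keep],
    protein_acc = raw$protein_acc[keep],
    start = start[keep], end = end[keep], evalue = evalue[keep]
  )
  rejected <- dplyr::bind_rows(
    pre_rejected,
    tibble::tibble(row = which(!keep), reason = reason[!keep])
  )

  n_eval <- sum(out$evalue > evalue_cutoff)
  out <- out[out$evalue <= evalue_cutoff, ]

  n_unknown <- 0L
  if (!is.null(proteins)) {
    unknown <- !(out$protein_acc %in% proteins$protein_acc)
    n_unknown <- sum(unknown)
    if (n_unknown > 0) {
      warning(n_unknown, " domain instance(s) on unknown proteins dropped",
              call. = FALSE)
      out <- out[!unknown, ]
    }
    lens <- proteins$length[match(out$protein_acc, proteins$protein_acc)]
    over <- out$end > lens
    if (any(over)) {
      rejected <- dplyr::bind_rows(
        rejected,
        tibble::tibble(row = which(over), reason = "interval exceeds protein length")
      )
      out <- out[!over, ]
    }
  }
  if (nrow(rejected)) {
    warning(nrow(rejected), " domain map row(s) rejected; see parse_report()",
            call. = FALSE)
  }
  attr(out, "parse_report") <- rejected
  attr(out, "n_evalue_filtered") <- n_eval
  attr(out, "n_unknown_protein") <- n_unknown
  out
}

#' Write a domain map in the simple TSV dialect
#'
#' @param domains Domain-instance tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_map <- function(domains, path) {
  cols <- c("domain_acc", "domain_name", "protein_acc", "start", "end", "evalue")
  readr::write_tsv(domains[, cols], path, na = "NA")
  invisible(path)
}

# HMMER3 --domtblout: whitespace-delimited, 23 columns, '#' comments
parse_domtbl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  fields <- strsplit(trimws(lines[data]), "\\s+")
  short <- vapply(fields, length, integer(1)) < 19L
  rejected <- tibble::tibble(
    row = which(short),
    reason = rep("fewer than 19 whitespace-separated fields", sum(short))
  )
  fields <- fields[!short]
  rows <- tibble::tibble(
    domain_name = vapply(fields, `[`, "", 1L),
    domain_acc = sub("\\.\\d+$", "", vapply(fields, `[`, "", 2L)),
    protein_acc = vapply(fields, `[`, "", 4L),
    evalue = vapply(fields, `[`, "", 13L),   # i-Evalue
    start = vapply(fields, `[`, "", 18L),    # ali_from
    end = vapply(fields, `[`, "", 19L)       # ali_to
  )
  list(rows = rows, rejected = rejected)
}

#' Read a protein set with lengths
#'
#' `"tsv"` expects columns `gene`, `protein_acc`, `length` (and optionally
#' `is_representative`).  `"fasta"` derives lengths from the sequences; the
#' accession is the first header token and the gene symbol is taken from a
#' `gene=SYMBOL` token when present (otherwise the accession is reused).
#' Reading FASTA requires the Biostrings package.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"fasta"`.
#' @return Tibble with columns `gene`, `protein_acc`, `length`,
#'   `is_representative`.
#' @seealso [select_representative_proteins()]
#' @export
read_protein_set <- function(path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           na = "NA", comment = "#", progress = FALSE)
    miss <- setdiff(c("gene", "protein_acc", "length"), names(raw))
    if (length(miss)) {
      stop("protein set is missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    len <- suppressWarnings(as.integer(raw$length))
    if (any(is.na(len) | len < 1L)) {
      stop("protein lengths must be integers >= 1", call. = FALSE)
    }
    rep <- if ("is_representative" %in% names(raw)) {
      parse_flag(raw$is_representative) & !is.na(raw$is_representative)
    } else FALSE
    tibble::tibble(gene = raw$gene, protein_acc = raw$protein_acc,
                   length = len, is_representative = rep)
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA protein sets requires the Biostrings package",
           call. = FALSE)
    }
    seqs <- Biostrings::readAAStringSet(path)
    headers <- names(seqs)
    acc <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
    gene <- stringr::str_match(headers, "gene=(\\S+)")[, 2]
    gene[is.na(gene)] <- acc[is.na(gene)]
    tibble::tibble(gene = gene, protein_acc = acc,
                   length = Biostrings::width(seqs), is_representative = FALSE)
  }
}

#' Read a GO ontology in OBO v1.2 format
#'
#' Parses `[Term]` stanzas into a DAG.  Obsolete terms are excluded at parse
#' time; both `is_a` and `relationship: part_of` count as parent edges.  A
#' cyclic parent chain is a hard error.  Roots are the terms without parents
#' (the three namespace roots in the full Gene Ontology).
#'
#' @param path Path to an OBO v1.2 file.
#' @return An `ontology_graph` object: list with `terms` (tibble `id`, `name`,
#'   `namespace`), `parents` (named list of parent-id character vectors) and
#'   `roots` (character vector).
#' @seealso [propagate_annotations()], [read_term_annotations()]
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(trimws(lines) == "[Term]")
  stanza_heads <- which(grepl("^\\[", trimws(lines)))
  ids <- character(0); nms <- character(0); ns <- character(0)
  parents <- list()
  for (s in starts) {
    nxt <- stanza_heads[stanza_heads > s]
    block <- lines[(s + 1):(if (length(nxt)) nxt[1] - 1 else length(lines))]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (!length(hit)) return(NA_character_)
      trimws(sub(paste0("^", key, ":"), "", hit[1]))
    }
    id <- get1("id")
    if (is.na(id)) next
    if (identical(get1("is_obsolete"), "true")) next
    isa <- sub("\\s*!.*$", "", trimws(sub("^is_a:", "", grep("^is_a:", block, value = TRUE))))
    rel <- grep("^relationship:\\s*part_of", block, value = TRUE)
    po <- stringr::str_match(rel, "part_of\\s+(\\S+)")[, 2]
    ids <- c(ids, id)
    nms <- c(nms, get1("name"))
    ns <- c(ns, get1("namespace"))
    parents[[id]] <- unique(c(isa, po[!is.na(po)]))
  }
  if (anyDuplicated(ids)) stop("duplicate term ids in OBO file", call. = FALSE)
  # keep only edges to terms that exist (drops edges to obsolete terms)
  parents <- lapply(parents, function(p) p[p %in% ids])
  check_acyclic(ids, parents)
  roots <- ids[vapply(parents[ids], length, integer(1)) == 0L]
  structure(
    list(terms = tibble::tibble(id = ids, name = nms, namespace = ns),
         parents = parents, roots = roots),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", nrow(x$terms), " terms, ",
      length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

# Kahn-style elimination: peel terms whose parents are all peeled; leftovers
# imply a cycle
check_acyclic <- function(ids, parents) {
  remaining <- ids
  repeat {
    if (!length(remaining)) return(invisible(TRUE))
    free <- vapply(parents[remaining],
                   function(p) !any(p %in% remaining), logical(1))
    if (!any(free)) {
      stop("cyclic parent chain in ontology involving: ",
           paste(head(remaining, 5), collapse = ", "), call. = FALSE)
    }
    remaining <- remaining[!free]
  }
}

#' Read entity-to-GO-term annotations
#'
#' `"tsv"` expects two columns (entity id, GO id), with or without a header
#' row.  `"pfam2go"` parses the GO Consortium's pfam2go mapping
#' (`Pfam:PFxxxxx name > GO:description ; GO:nnnnnnn` lines, `!` comments).
#'
#' @param path Path to the annotation file.
#' @param dialect `"tsv"` or `"pfam2go"`.
#' @return Tibble with columns `entity`, `term` (duplicates removed).
#' @export
read_term_annotations <- function(path, dialect = c("tsv", "pfam2go")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    raw <- readr::read_tsv(path, col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           comment = "#", progress = FALSE)
    if (ncol(raw) < 2) stop("annotation TSV needs two columns", call. = FALSE)
    out <- tibble::tibble(entity = raw[[1]], term = raw[[2]])
    # tolerate a header row
    if (nrow(out) && !grepl("^GO:\\d+$", out$term[1])) out <- out[-1, ]
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^!", lines) & nzchar(trimws(lines))]
    m <- stringr::str_match(lines, "^Pfam:(\\S+)\\s+\\S+\\s*>\\s*GO:.*;\\s*(GO:\\d+)\\s*$")
    ok <- !is.na(m[, 1])
    if (!all(ok)) {
      warning(sum(!ok), " unparseable pfam2go line(s) skipped", call. = FALSE)
    }
    out <- tibble::tibble(entity = sub("\\.\\d+$", "", m[ok, 2]), term = m[ok, 3])
  }
  dplyr::distinct(out)
}

#' Write a landscape statistics table
#'
#' Emits a TSV with the fixed columns `region_id`, `region_kind`, `k`, `L`,
#' `p_hat`, `z`, `lfdr`, `significant`, `excluded_short`, sorted by descending
#' normalized frequency with ties broken by region id, so output is bit-stable
#' for identical inputs.
#'
#' @param stats A `landscape` object or its statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_landscape_table()]
#' @export
write_landscape_table <- function(stats, path) {
  if (inherits(stats, "landscape")) stats <- stats$stats
  cols <- c("region_id", "region_kind", "k", "L", "p_hat", "z", "lfdr",
            "significant", "excluded_short")
  miss <- setdiff(cols, names(stats))
  if (length(miss)) {
    stop("landscape table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::arrange(stats[, cols], dplyr::desc(.data$p_hat), .data$region_id)
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read a landscape statistics table written by [write_landscape_table()]
#'
#' @param path Path to the TSV.
#' @return Statistics tibble with typed columns.
#' @export
read_landscape_table <- function(path) {
  readr::read_tsv(path, col_types = "cciidddll", na = "NA", progress = FALSE)
}
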