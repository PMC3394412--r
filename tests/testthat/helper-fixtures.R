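# Fixtures built in code, and the independent oracles used across files.

# minimal well-formed mutation tibble
toy_mutations <- function() {
  tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    gene = c("GA", "GA", "GB"),
    protein_acc = c("NP_1", "NP_1", "NP_2"),
    protein_pos = c(10L, 20L, 5L),
    ref_res = c("A", "R", NA),
    alt_res = c("V", "H", NA),
    variant_class = c("nsSNV", "stopgain_SNV", "frameshift_del"),
    dbsnp_id = c(NA, "rs123", NA),
    is_somatic = TRUE, passed_qc = TRUE
  )
}

toy_proteins <- function() {
  tibble::tibble(
    gene = c("GA", "GA", "GB"),
    protein_acc = c("NP_1", "NP_1b", "NP_2"),
    length = c(400L, 200L, 300L),
    is_representative = FALSE
  )
}

toy_domains <- function() {
  tibble::tibble(
    domain_acc = c("PF001", "PF001", "PF002"),
    domain_name = c("domA", "domA", "domB"),
    protein_acc = c("NP_1", "NP_2", "NP_2"),
    start = c(5L, 100L, 1L),
    end = c(60L, 180L, 50L),
    evalue = c(1e-10, 1e-5, 0)
  )
}

toy_cohort <- function() {
  build_cohort(toy_mutations(), toy_proteins(), toy_domains(), name = "toy")
}

# a small linear + diamond ontology written as OBO v1.2 text
write_toy_obo <- function(path, obsolete = FALSE, cyclic = FALSE) {
  lines <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: level1", "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: level2", "namespace: biological_process",
    "is_a: GO:0000002 ! level1", "",
    "[Term]", "id: GO:0000004", "name: level3", "namespace: biological_process",
    "is_a: GO:0000003 ! level2", "",
    "[Term]", "id: GO:0000005", "name: second parent",
    "namespace: molecular_function", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000006", "name: diamond child",
    "namespace: biological_process",
    "is_a: GO:0000003 ! level2",
    "relationship: part_of GO:0000005 ! second parent", ""
  )
  if (obsolete) {
    lines <- c(lines, "[Term]", "id: GO:0000099", "name: dead",
               "namespace: biological_process", "is_obsolete: true", "")
  }
  if (cyclic) {
    lines <- c(lines, "[Term]", "id: GO:0000010", "name: cyc1",
               "namespace: biological_process", "is_a: GO:0000011 ! cyc2", "",
               "[Term]", "id: GO:0000011", "name: cyc2",
               "namespace: biological_process", "is_a: GO:0000010 ! cyc1", "")
  }
  writeLines(lines, path)
  path
}

# independent right-tail oracle: explicit sum of hypergeometric terms
hyper_right_tail_oracle <- function(a, b, c, d) {
  m <- a + c          # annotated
  n_draws <- a + b    # significant
  N <- a + b + c + d
  xs <- a:min(n_draws, m)
  if (!length(xs)) return(0)
  sum(exp(lchoose(m, xs) + lchoose(N - m, n_draws - xs) - lchoose(N, n_draws)))
}

# brute-force interval-membership oracle for domain assignment
assignment_oracle <- function(cohort) {
  reps <- cohort$proteins[cohort$proteins$is_representative, ]
  doms <- cohort$domains[cohort$domains$protein_acc %in% reps$protein_acc, ]
  out <- list()
  for (i in seq_len(nrow(cohort$mutations))) {
    m <- cohort$mutations[i, ]
    for (j in seq_len(nrow(doms))) {
      d <- doms[j, ]
      if (m$protein_acc == d$protein_acc &&
          d$start <= m$protein_pos && m$protein_pos <= d$end) {
        out[[length(out) + 1]] <- tibble::tibble(
          mutation_id = m$mutation_id, domain_acc = d$domain_acc,
          start = d$start, end = d$end)
      }
    }
  }
  dplyr::bind_rows(out)
}

# standard driver layout used by the power/recovery checks
standard_drivers <- function() {
  tibble::tibble(
    region_kind = c("gene", "gene", "domain", "domain", "domain"),
    region_id = c("G005", "G010", "DM0002", "DM0003", "DM0004"),
    multiplier = 10
  )
}

extdata <- function(file) {
  system.file("extdata", file, package = "domainscape", mustWork = TRUE)
}
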