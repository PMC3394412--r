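# Filtering rules, recurrence counting, representative selection, and
# mutation-to-domain assignment.

test_that("the four filter rules remove exactly the right records", {
  muts <- tibble::tibble(
    sample_id = sprintf("S%d", 1:5), gene = "GA", protein_acc = "NP_1",
    protein_pos = 1:5, ref_res = "A", alt_res = "V",
    variant_class = c("synonymous_SNV", "nsSNV", "nsSNV", "nsSNV",
                      "frameshift_ins"),
    dbsnp_id = c(NA, "rs1", NA, NA, NA),
    is_somatic = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    passed_qc = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  got <- filter_cohort(muts, exclusion_ids = "rs1")
  # synonymous somatic SNV removed; excluded dbSNP id removed; germline and
  # QC-fail removed; the clean frameshift insertion retained
  expect_equal(got$sample_id, "S5")
  report <- filter_report(got)
  expect_equal(report$removed[report$rule == "synonymous"], 1L)
  expect_equal(report$removed[report$rule == "dbsnp"], 1L)
  expect_equal(sum(report$removed), 4L)
  expect_equal(report$remaining[nrow(report)], 1L)
})

test_that("filter composition is order-independent", {
  sim <- suppressWarnings(simulate_cohort(
    seed = 11, spec = proteome_spec(n_genes = 40, n_domains = 10)))
  muts <- sim$mutations
  excl <- sim$truth$dbsnp_exclusion_ids
  base <- filter_cohort(muts, excl)
  perms <- list(c("qc", "synonymous", "germline", "dbsnp"),
                c("dbsnp", "germline", "synonymous", "qc"),
                c("synonymous", "dbsnp", "qc", "germline"))
  for (p in perms) {
    got <- filter_cohort(muts, excl, rules = p)
    expect_equal(got, base, ignore_attr = TRUE)
  }
})

test_that("recurrence counts occurrences per distinct patient, deduplicating rows", {
  muts <- tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S1", "S4", "S5"),
    gene = "GA", protein_acc = "NP_1",
    protein_pos = c(10L, 10L, 10L, 10L, 50L, 60L),
    ref_res = "A", alt_res = "V", variant_class = "nsSNV",
    dbsnp_id = NA_character_, is_somatic = TRUE, passed_qc = TRUE)
  got <- count_recurrence(muts)
  # same substitution in 3 patients (S1 listed twice counts once)
  expect_equal(got$n_patients[got$protein_pos == 10], 3L)
  # disjoint variants in disjoint patients each count once
  expect_equal(got$n_patients[got$protein_pos %in% c(50, 60)], c(1L, 1L))
})

test_that("representative selection takes the longest isoform, ties by accession", {
  prot <- tibble::tibble(
    gene = c("GA", "GA", "GB", "GB", "GC"),
    protein_acc = c("NP_10", "NP_11", "NP_2", "NP_1", "NP_solo"),
    length = c(2843L, 1200L, 400L, 400L, 100L))
  got <- select_representative_proteins(prot)
  reps <- got$protein_acc[got$is_representative]
  expect_setequal(reps, c("NP_10", "NP_1", "NP_solo"))  # tie -> NP_1
  expect_equal(sum(got$is_representative[got$gene == "GA"]), 1L)
})

test_that("cohort assembly drops non-representative mutations and validates positions", {
  muts <- dplyr::bind_rows(
    toy_mutations(),
    tibble::tibble(sample_id = "S9", gene = "GA", protein_acc = "NP_1b",
                   protein_pos = 5L, ref_res = "A", alt_res = "V",
                   variant_class = "nsSNV", dbsnp_id = NA_character_,
                   is_somatic = TRUE, passed_qc = TRUE))
  ch <- build_cohort(muts, toy_proteins(), toy_domains())
  expect_equal(nrow(ch$mutations), 3)  # isoform NP_1b mutation dropped
  expect_equal(
    ch$log$n[ch$log$stage == "non_representative_isoform_removed"], 1L)
  bad <- toy_mutations()
  bad$protein_pos[1] <- 999L
  expect_error(build_cohort(bad, toy_proteins(), toy_domains()),
               "exceeds protein length")
})

test_that("domain assignment covers exactly the instances containing the position", {
  ch <- toy_cohort()
  asn <- assign_mutations_to_domains(ch)
  # S1 at NP_1:10 inside PF001 (5-60); S2 at NP_1:20 inside PF001;
  # S3 (a deletion) at NP_2:5 inside PF002 (1-50) only
  expect_equal(nrow(asn), 3)
  expect_equal(sort(unique(asn$domain_acc)), c("PF001", "PF002"))
  expect_equal(attr(asn, "fraction_in_domain"), 1)
  # a position in a linker yields no assignment
  ch2 <- ch
  ch2$mutations$protein_pos <- c(70L, 200L, 70L)
  asn2 <- assign_mutations_to_domains(ch2)
  expect_equal(nrow(asn2), 0)
})

test_that("overlapping instances of different domains each receive the mutation", {
  prot <- tibble::tibble(gene = "GX", protein_acc = "NP_X", length = 200L,
                         is_representative = TRUE)
  doms <- tibble::tibble(
    domain_acc = c("PFa", "PFb"), domain_name = c("a", "b"),
    protein_acc = "NP_X", start = c(10L, 40L), end = c(60L, 90L),
    evalue = 0)
  muts <- tibble::tibble(
    sample_id = "S1", gene = "GX", protein_acc = "NP_X", protein_pos = 50L,
    ref_res = "A", alt_res = "V", variant_class = "nsSNV",
    dbsnp_id = NA_character_, is_somatic = TRUE, passed_qc = TRUE)
  asn <- assign_mutations_to_domains(build_cohort(muts, prot, doms))
  expect_setequal(asn$domain_acc, c("PFa", "PFb"))
})

test_that("assignment agrees with the brute-force membership oracle", {
  for (seed in c(5, 17)) {
    sim <- suppressWarnings(simulate_cohort(
      seed = seed, spec = proteome_spec(n_genes = 25, n_domains = 10)))
    asn <- assign_mutations_to_domains(sim$cohort) |>
      dplyr::select("mutation_id", "domain_acc", "start", "end") |>
      dplyr::arrange(mutation_id, domain_acc, start)
    oracle <- assignment_oracle(sim$cohort) |>
      dplyr::arrange(mutation_id, domain_acc, start)
    expect_equal(asn, oracle, ignore_attr = TRUE)
    expect_true(all(asn$start <= asn$end))
  }
})

test_that("indel classification follows length mod 3", {
  expect_equal(classify_indel(c(3, 1, 9, 2, 6)),
               c("nonframeshift", "frameshift", "nonframeshift",
                 "frameshift", "nonframeshift"))
  expect_error(classify_indel(0), "length")
})
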