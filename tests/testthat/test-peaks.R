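# Peak-origin classification, gene-peak removal, and cross-cohort
# comparison.

# a hand-built pair of landscapes with controllable significance flags
fake_landscape <- function(kind, ids, significant, cohort_name = "A",
                           breakdown = NULL) {
  stats <- tibble::tibble(
    region_id = ids, region_kind = kind, k = 5L, L = 200L,
    p_hat = 5 / 200, z = 1, lfdr = ifelse(significant, 0.01, 0.9),
    significant = significant, excluded_short = FALSE)
  structure(list(stats = stats, p0 = 0.005, fit = NULL, kind = kind,
                 cohort_name = cohort_name,
                 params = list(lfdr_threshold = 0.1, min_length = 150,
                               z_form = "binomial", min_regions = 200),
                 breakdown = breakdown),
            class = "landscape")
}

test_that("peak origins split into from_gene_peaks, aggregated, and mixed", {
  breakdown <- tibble::tibble(
    domain_acc = c("PFp53", "PFp53", "PFcenpb", "PFcenpb", "PFall", "PFall"),
    gene = c("TP53", "TP63", "TIGD7", "JRKL", "KRAS", "NRAS"),
    k = c(27L, 1L, 3L, 2L, 20L, 7L))
  dl <- fake_landscape("domain", c("PFp53", "PFcenpb", "PFall"),
                       significant = c(TRUE, TRUE, TRUE),
                       breakdown = breakdown)
  gl <- fake_landscape("gene", c("TP53", "TP63", "TIGD7", "JRKL", "KRAS",
                                 "NRAS"),
                       significant = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  got <- classify_peak_origins(dl, gl)
  origin <- setNames(got$origin_class, got$domain_acc)
  # dominant significant gene plus one non-significant contributor -> mixed
  expect_equal(origin[["PFp53"]], "mixed")
  # aggregation from genes that are not themselves peaks
  expect_equal(origin[["PFcenpb"]], "aggregated")
  expect_equal(origin[["PFall"]], "from_gene_peaks")
  # a significant domain with no breakdown violates the invariant
  dl2 <- fake_landscape("domain", "PFghost", TRUE,
                        breakdown = breakdown[0, ])
  expect_error(classify_peak_origins(dl2, gl), "breakdown")
})

test_that("gene-peak removal re-tests domains on the reduced cohort", {
  # WAP-style fixture: one dominant contributor plus three aggregating genes
  bd <- tibble::tibble(
    domain_acc = rep("PFwap", 4),
    gene = c("WFDC8", "SLPI", "WFDC5", "KAL1"),
    k = c(3L, 1L, 1L, 1L))
  ch <- cohort_from_breakdown(bd, instance_length = 160)
  gl <- suppressWarnings(gene_landscape(ch))
  dl <- suppressWarnings(domain_landscape(ch))
  # force the dominant gene significant to exercise the removal
  gl$stats$significant <- gl$stats$region_id == "WFDC8"
  got <- suppressWarnings(recall_after_gene_peak_removal(ch, gl, dl))
  expect_equal(got$k_before[got$domain_acc == "PFwap"], 6L)
  expect_equal(got$k_after[got$domain_acc == "PFwap"], 3L)  # WFDC8's 3 removed
  expect_true(all(got$k_after <= got$k_before))
})

test_that("removal with no significant genes is the identity on domain stats", {
  sim <- suppressWarnings(simulate_cohort(
    seed = 19, spec = proteome_spec(n_genes = 50, n_domains = 12)))
  gl <- suppressWarnings(gene_landscape(sim$cohort))
  dl <- suppressWarnings(domain_landscape(sim$cohort))
  gl$stats$significant <- FALSE
  got <- suppressWarnings(recall_after_gene_peak_removal(sim$cohort, gl, dl))
  expect_equal(got$k_after, got$k_before)
  expect_equal(got$significant_after, got$significant_before)
})

test_that("a domain fed solely by one significant gene is not retained", {
  bd <- tibble::tibble(domain_acc = "PFsolo", gene = "ONLY", k = 8L)
  ch <- cohort_from_breakdown(bd, instance_length = 160)
  gl <- suppressWarnings(gene_landscape(ch))
  dl <- suppressWarnings(domain_landscape(ch))
  gl$stats$significant <- TRUE
  dl$stats$significant <- TRUE
  got <- recall_after_gene_peak_removal(ch, gl, dl)
  expect_equal(got$k_after, 0L)
  expect_false(got$retained_after_removal)
})

test_that("cohort comparison computes shared percentages and the Venn identity", {
  a <- fake_landscape("gene", sprintf("g%03d", 1:154),
                      significant = rep(TRUE, 154), cohort_name = "colon")
  b <- fake_landscape("gene", c(sprintf("g%03d", 1:7), sprintf("h%03d", 1:144)),
                      significant = rep(TRUE, 151), cohort_name = "breast")
  cmp <- compare_cohorts(a, b)
  expect_equal(length(cmp$shared), 7)
  expect_equal(length(cmp$exclusive_a), 147)
  expect_equal(length(cmp$exclusive_b), 144)
  expect_equal(cmp$shared_percent_a, 4.5)   # 7 of 154
  # Venn identity
  expect_equal(length(cmp$shared) + length(cmp$exclusive_a),
               length(cmp$significant_a))
  expect_equal(length(cmp$shared) + length(cmp$exclusive_b),
               length(cmp$significant_b))
  # identical landscapes share everything; disjoint share nothing
  expect_equal(compare_cohorts(a, a)$shared_percent_a, 100)
  c0 <- fake_landscape("gene", sprintf("x%03d", 1:10), rep(TRUE, 10))
  expect_equal(length(compare_cohorts(a, c0)$shared), 0)
  expect_error(compare_cohorts(a, fake_landscape("domain", "d1", TRUE)),
               "kind")
})

test_that("shared domains hosted in shared genes are identified", {
  gcmp <- compare_cohorts(
    fake_landscape("gene", c("TP53", "KRAS"), c(TRUE, TRUE), "colon"),
    fake_landscape("gene", c("TP53", "BRCA1"), c(TRUE, TRUE), "breast"))
  dcmp <- compare_cohorts(
    fake_landscape("domain", c("PFp53", "PFlsm"), c(TRUE, TRUE), "colon"),
    fake_landscape("domain", c("PFp53", "PFlsm"), c(TRUE, TRUE), "breast"))
  hosts <- tibble::tibble(domain_acc = c("PFp53", "PFlsm"),
                          gene = c("TP53", "SNRPB"))
  expect_equal(shared_domain_in_shared_gene(gcmp, dcmp, hosts), "PFp53")
  # empty shared sets -> empty result
  gcmp0 <- compare_cohorts(
    fake_landscape("gene", "A", TRUE, "x"),
    fake_landscape("gene", "B", TRUE, "y"))
  expect_equal(shared_domain_in_shared_gene(gcmp0, dcmp, hosts), character())
})
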