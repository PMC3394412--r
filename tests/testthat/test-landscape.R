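# Counts, normalizing lengths, frequencies, the z score, prevalence, and the
# cohort report arithmetic.

test_that("gene counts recover planted per-gene totals and sum to the retained set", {
  ch <- toy_cohort()
  gc <- gene_counts(ch)
  expect_equal(gc$k[gc$gene == "GA"], 2L)
  expect_equal(gc$k[gc$gene == "GB"], 1L)
  expect_equal(sum(gc$k), nrow(ch$mutations))
  # empty cohort -> empty mapping
  ch$mutations <- ch$mutations[0, ]
  expect_equal(nrow(gene_counts(ch)), 0)
})

test_that("cumulative domain length sums all instances, including tandem repeats", {
  # two instances of lengths 50 and 60
  d <- tibble::tibble(domain_acc = "PFx", domain_name = "x",
                      protein_acc = c("NP_1", "NP_2"),
                      start = c(1L, 11L), end = c(50L, 70L), evalue = 0)
  expect_equal(cumulative_domain_length(d)$L, 110L)
  # DNA-binding-domain-style fixture: instances 193 + 197 = 390
  p53 <- tibble::tibble(domain_acc = "PF00870", domain_name = "P53",
                        protein_acc = c("NP_tp53", "NP_tp63"),
                        start = c(101L, 151L), end = c(293L, 347L), evalue = 0)
  expect_equal(cumulative_domain_length(p53)$L, 390L)
  # armadillo-repeat-style fixture: 7 tandem copies of 22 aa plus one
  # 22-aa instance elsewhere = 176
  starts <- (0:6) * 22L + 1L
  crr <- tibble::tibble(domain_acc = "PF05923", domain_name = "APC_crr",
                        protein_acc = c(rep("NP_apc", 7), "NP_other"),
                        start = c(starts, 10L),
                        end = c(starts + 21L, 31L), evalue = 0)
  expect_equal(cumulative_domain_length(crr)$L, 176L)
})

test_that("domain counts aggregate per-gene breakdowns to the printed totals", {
  bd <- readr::read_tsv(extdata("coad_domain_breakdown.tsv"),
                        comment = "#", show_col_types = FALSE)
  ch <- cohort_from_breakdown(bd)
  dc <- domain_counts(assign_mutations_to_domains(ch))
  totals <- setNames(dc$counts$k, dc$counts$domain_acc)
  expect_equal(totals[["PF03166"]], 14L)   # MH2 across five SMAD-family genes
  expect_equal(totals[["PF00095"]], 6L)    # WAP across four genes
  # breakdown totals equal the sum of their per-gene parts for every domain
  sums <- dc$breakdown |>
    dplyr::group_by(domain_acc) |>
    dplyr::summarise(k = sum(k))
  expect_equal(totals[sums$domain_acc], setNames(sums$k, sums$domain_acc))
})

test_that("a mutation under two instances of the same domain counts once", {
  prot <- tibble::tibble(gene = "GX", protein_acc = "NP_X", length = 200L,
                         is_representative = TRUE)
  doms <- tibble::tibble(domain_acc = "PFa", domain_name = "a",
                         protein_acc = "NP_X", start = c(10L, 40L),
                         end = c(60L, 90L), evalue = 0)
  muts <- tibble::tibble(
    sample_id = "S1", gene = "GX", protein_acc = "NP_X", protein_pos = 50L,
    ref_res = "A", alt_res = "V", variant_class = "nsSNV",
    dbsnp_id = NA_character_, is_somatic = TRUE, passed_qc = TRUE)
  dc <- domain_counts(assign_mutations_to_domains(build_cohort(muts, prot, doms)))
  expect_equal(dc$counts$k, 1L)
})

test_that("normalized frequency is k/L and scale-invariant", {
  expect_equal(normalized_frequency(30, 189), 30 / 189)  # 0.158730...
  expect_equal(normalized_frequency(28, 390), 28 / 390)  # 0.071794...
  expect_equal(normalized_frequency(0, 500), 0)
  # multiplying every k and L by the same integer leaves p_hat unchanged
  k <- c(2, 5, 0, 11); L <- c(200, 350, 151, 800)
  for (m in c(2L, 7L)) {
    expect_equal(normalized_frequency(k * m, L * m), normalized_frequency(k, L))
  }
  expect_error(normalized_frequency(1, 0), "length")
})

test_that("background rate pools counts over lengths", {
  expect_equal(background_rate(c(2, 1), c(100, 200)), 0.01)
  expect_equal(background_rate(c(0, 0), c(100, 200)), 0)
  expect_error(background_rate(numeric(), numeric()), "length")
  # a synthetic uniform cohort pools close to the generated occurrence rate
  sim <- suppressWarnings(simulate_cohort(seed = 2))
  gl <- suppressWarnings(gene_landscape(sim$cohort))
  expected <- sim$truth$background_rate * sim$truth$n_patients
  expect_lt(abs(gl$p0 - expected) / expected, 0.25)
})

test_that("the z score is centered, monotone, and matches independent arithmetic", {
  expect_equal(bernoulli_z(5, 500, 0.01), 0)           # k/L = p0 -> 0
  expect_lt(bernoulli_z(0, 500, 0.01), 0)              # k = 0 -> negative
  zs <- bernoulli_z(0:20, 300, 0.005)
  expect_true(all(diff(zs) > 0))                       # increasing in k
  # independently coded arithmetic oracle
  k <- 30; L <- 189; p0 <- 0.002
  oracle <- (k / L - p0) * sqrt(L) / sqrt(p0 * (1 - p0))
  expect_equal(bernoulli_z(k, L, p0), oracle, tolerance = 1e-12)
  expect_error(bernoulli_z(1, 100, 0), "p0")
  expect_error(bernoulli_z(1, 100, 1), "p0")
  # literal Bernoulli signal-to-noise variant
  expect_equal(bernoulli_z(30, 189, 0.002, form = "snr"),
               sqrt((30 / 189) / (1 - 30 / 189)), tolerance = 1e-12)
})

test_that("peak calling applies the length cutoff and the strict lfdr threshold", {
  set.seed(31)
  n <- 300
  regions <- tibble::tibble(
    region_id = sprintf("R%03d", 1:n), region_kind = "gene",
    L = c(100L, rep(c(200L, 400L, 800L), length.out = n - 1)),
    k = rbinom(n, L, 0.005))
  regions$k[2] <- 60L  # a blatant peak on L = 200
  ls <- call_peaks(regions)
  st <- ls$stats
  expect_true(st$excluded_short[1])            # L = 100 < 150
  expect_false(st$significant[1])              # excluded can never be significant
  expect_true(is.na(st$lfdr[1]))
  expect_true(st$significant[2])
  expect_equal(st$p_hat, st$k / st$L)
  expect_true(all(st$lfdr[!st$excluded_short] >= 0 &
                    st$lfdr[!st$excluded_short] <= 1))
  # significance is strict: lfdr exactly at the threshold does not qualify
  expect_true(all(st$lfdr[st$significant] < 0.1))
  at <- call_peaks(regions, lfdr_threshold = min(st$lfdr, na.rm = TRUE))
  expect_false(any(at$stats$significant))
})

test_that("zero-count regions join the null fit but are never significant", {
  set.seed(13)
  n <- 250
  regions <- tibble::tibble(
    region_id = sprintf("D%03d", 1:n), region_kind = "domain",
    L = rep(c(200L, 400L), length.out = n), k = rbinom(n, 200, 0.004))
  regions$k[1:40] <- 0L
  ls <- suppressWarnings(call_peaks(regions))
  expect_false(any(ls$stats$significant[ls$stats$k == 0]))
  expect_false(any(is.na(ls$stats$lfdr)))  # all fitted (none short)
})

test_that("mutation prevalence divides count by patients with the 0.04 high flag", {
  got <- mutation_prevalence(c(4, 0, 132), 100)
  expect_equal(got$prevalence, c(0.04, 0, 1.32))
  expect_equal(got$high, c(TRUE, FALSE, TRUE))  # 0.04 is high (inclusive)
  expect_error(mutation_prevalence(1, 0), "n_patients")
})

test_that("the cohort report reproduces composition percentages from counts", {
  counts <- readr::read_tsv(extdata("coad_mutation_class_counts.tsv"),
                            comment = "#", show_col_types = FALSE)
  classes <- counts[counts$item %in% MUTATION_CLASSES, ]
  rep <- mutation_report(
    tibble::tibble(variant_class = classes$item, n = classes$n),
    n_patients = counts$n[counts$item == "n_patients"],
    n_in_domain = counts$n[counts$item == "in_domain"])
  expect_equal(rep$total_mutations, 21572)
  per_class <- attr(rep, "per_class")
  expect_equal(per_class$percent[per_class$variant_class == "nsSNV"], 79.6)
  expect_equal(rep$in_domain_percent, 49.4)
  expect_equal(rep$mean_per_patient, 216)
})
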