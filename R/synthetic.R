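# Synthetic proteomes and cohorts with known ground truth.  The generator
# emulates the structure the pipeline is built for: multi-isoform genes,
# domain instances shared across genes and repeated within one protein, and
# per-patient mutations drawn residue-by-residue from a uniform background
# rate with planted elevated-rate driver regions.

#' Describe a synthetic proteome
#'
#' Gene lengths are log-normal (clamped), a fraction of genes carry a second,
#' shorter isoform (exercising representative selection), and each domain is
#' placed on a Poisson-distributed number of host genes.  Two structural
#' features are always included because the method leans on them: the first
#' domain is laid down as a tandem repeat (several copies in one protein, so
#' its cumulative length sums over copies) and the second is shared across
#' many genes (the substrate for aggregated domain peaks).
#'
#' @param n_genes Number of genes (default 200).
#' @param n_domains Number of distinct domains (default 40).
#' @param length_meanlog,length_sdlog Log-normal parameters for
#'   representative protein lengths (defaults log(500), 0.4).
#' @param min_length,max_length Clamp for protein lengths (defaults 200,
#'   3000 aa).
#' @param extra_isoform_fraction Fraction of genes with a second, shorter
#'   isoform (default 0.3).
#' @param domain_length_range Instance length range in aa (default 40-200).
#' @param mean_hosts_per_domain Mean number of host genes per domain
#'   (default 3).
#' @param tandem_copies Copies of the tandem-repeat domain (default 7).
#' @param shared_hosts Host-gene count of the widely shared domain
#'   (default 8).
#' @return A `proteome_spec` object (validated list).
#' @export
proteome_spec <- function(n_genes = 200, n_domains = 40,
                          length_meanlog = log(500), length_sdlog = 0.4,
                          min_length = 200, max_length = 3000,
                          extra_isoform_fraction = 0.3,
                          domain_length_range = c(40, 200),
                          mean_hosts_per_domain = 3,
                          tandem_copies = 7, shared_hosts = 8) {
  stopifnot(n_genes >= 2, n_domains >= 1, min_length >= 1,
            max_length >= min_length,
            extra_isoform_fraction >= 0, extra_isoform_fraction <= 1,
            length(domain_length_range) == 2,
            domain_length_range[1] >= 1,
            domain_length_range[2] >= domain_length_range[1],
            domain_length_range[2] <= min_length,
            tandem_copies >= 1, shared_hosts >= 1, shared_hosts <= n_genes)
  structure(as.list(environment()), class = "proteome_spec")
}

#' Generate a synthetic proteome and domain map
#'
#' Deterministic under `seed`.  Every instance fits inside its host protein;
#' E-values are sampled far below the conventional 0.001 cutoff so the whole
#' map survives reading back through [read_domain_map()].
#'
#' @param spec A [proteome_spec()].
#' @param seed Integer seed.
#' @return List with `proteins` (tibble, representatives flagged) and
#'   `domains` (instance tibble).
#' @export
generate_proteome <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "proteome_spec"))
  with_seed(seed, {
    genes <- sprintf("G%03d", seq_len(spec$n_genes))
    lens <- pmin(spec$max_length, pmax(spec$min_length, round(
      rlnorm(spec$n_genes, spec$length_meanlog, spec$length_sdlog))))
    proteins <- tibble::tibble(
      gene = genes, protein_acc = sprintf("NP_%04d", seq_len(spec$n_genes)),
      length = as.integer(lens), is_representative = TRUE)
    n_extra <- round(spec$extra_isoform_fraction * spec$n_genes)
    if (n_extra > 0) {
      which_extra <- sort(sample.int(spec$n_genes, n_extra))
      proteins <- dplyr::bind_rows(proteins, tibble::tibble(
        gene = genes[which_extra],
        protein_acc = sprintf("NP_%04d", spec$n_genes + seq_len(n_extra)),
        length = pmax(1L, as.integer(round(0.6 * lens[which_extra]))),
        is_representative = FALSE))
    }
    rep_len <- setNames(as.integer(lens), genes)
    gene_acc <- setNames(proteins$protein_acc[proteins$is_representative],
                         proteins$gene[proteins$is_representative])

    place <- function(domain_acc, domain_name, gene, dlen) {
      len <- rep_len[[gene]]
      start <- sample.int(len - dlen + 1L, 1L)
      tibble::tibble(domain_acc = domain_acc, domain_name = domain_name,
                     protein_acc = gene_acc[[gene]],
                     start = start, end = start + dlen - 1L,
                     evalue = signif(10^(-stats::runif(1, 5, 30)), 3))
    }

    inst <- list()
    for (j in seq_len(spec$n_domains)) {
      acc <- sprintf("DM%04d", j)
      nm <- sprintf("dom%03d", j)
      dlen <- sample(seq(spec$domain_length_range[1],
                         spec$domain_length_range[2]), 1L)
      if (j == 1) {
        # tandem-repeat domain: several copies tiled in one protein
        host <- genes[which.max(lens)]
        copy_len <- min(dlen, rep_len[[host]] %/% spec$tandem_copies)
        starts <- (seq_len(spec$tandem_copies) - 1L) * copy_len + 1L
        inst[[j]] <- tibble::tibble(
          domain_acc = acc, domain_name = nm, protein_acc = gene_acc[[host]],
          start = starts, end = starts + copy_len - 1L,
          evalue = signif(10^(-stats::runif(spec$tandem_copies, 5, 30)), 3))
      } else if (j == 2) {
        hosts <- sample(genes, spec$shared_hosts)
        inst[[j]] <- purrr::map_dfr(hosts, place,
                                    domain_acc = acc, domain_name = nm,
                                    dlen = dlen)
      } else {
        n_hosts <- 1L + rpois(1, spec$mean_hosts_per_domain - 1)
        hosts <- sample(genes, min(n_hosts, spec$n_genes))
        inst[[j]] <- purrr::map_dfr(hosts, place,
                                    domain_acc = acc, domain_name = nm,
                                    dlen = dlen)
      }
    }
    list(proteins = proteins, domains = dplyr::bind_rows(inst))
  })
}

#' Ground truth for a synthetic cohort
#'
#' Captures everything needed to simulate and to score recovery: the
#' proteome, the per-residue per-patient background mutation probability, the
#' planted driver regions with their rate multipliers, the variant-class mix,
#' and the decoy fractions that exercise the filters.
#'
#' The default class mix follows the composition typical of a colon tumor
#' exome: roughly 80% nonsynonymous SNVs, 12% frameshift insertions, 7%
#' stop-gains, and a sliver of the remaining classes.
#'
#' @param proteome Output of [generate_proteome()].
#' @param drivers Tibble `region_kind` (`"gene"` or `"domain"`),
#'   `region_id`, `multiplier` (>= 1).  A gene driver elevates the whole
#'   protein; a domain driver elevates every instance of the domain.  May be
#'   empty (pure-null cohort).
#' @param background_rate Per-residue per-patient mutation probability r in
#'   (0, 1); default 5e-5.
#' @param n_patients Number of patients (default 100).
#' @param seed Integer seed.
#' @param class_probs Named probabilities over the non-synonymous
#'   [MUTATION_CLASSES] (normalized internally).
#' @param decoys Named fractions (relative to the core somatic count) of
#'   planted filter decoys: `synonymous`, `dbsnp`, `germline`, `qc_fail`.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(proteome,
                            drivers = tibble::tibble(region_kind = character(),
                                                     region_id = character(),
                                                     multiplier = double()),
                            background_rate = 5e-5, n_patients = 100,
                            seed = 1,
                            class_probs = c(nsSNV = 0.796,
                                            frameshift_ins = 0.117,
                                            stopgain_SNV = 0.074,
                                            nonframeshift_ins = 0.011,
                                            stoploss_SNV = 0.0015,
                                            frameshift_del = 0.0005),
                            decoys = c(synonymous = 0.08, dbsnp = 0.05,
                                       germline = 0.05, qc_fail = 0.02)) {
  stopifnot(background_rate > 0, background_rate < 1, n_patients >= 1,
            all(drivers$multiplier >= 1),
            all(drivers$region_kind %in% c("gene", "domain")),
            all(names(class_probs) %in% MUTATION_CLASSES),
            !("synonymous_SNV" %in% names(class_probs)),
            all(decoys >= 0))
  max_rate <- background_rate * max(c(1, drivers$multiplier))
  if (max_rate >= 1) {
    stop("background_rate times the largest multiplier must stay below 1",
         call. = FALSE)
  }
  structure(
    list(proteome = proteome, drivers = drivers,
         background_rate = background_rate, n_patients = n_patients,
         seed = seed, class_probs = class_probs / sum(class_probs),
         decoys = decoys),
    class = "synthetic_truth"
  )
}

# uniform-rate segments of one protein given driver intervals with multipliers
rate_segments <- function(len, ivals) {
  if (!nrow(ivals)) {
    return(tibble::tibble(start = 1L, end = len, multiplier = 1))
  }
  bp <- sort(unique(c(1L, ivals$start, ivals$end + 1L, len + 1L)))
  bp <- bp[bp >= 1L & bp <= len + 1L]
  segs <- tibble::tibble(start = head(bp, -1L), end = tail(bp, -1L) - 1L)
  segs$multiplier <- vapply(seq_len(nrow(segs)), function(i) {
    cover <- ivals$start <= segs$start[i] & segs$end[i] <= ivals$end
    if (any(cover)) max(ivals$multiplier[cover]) else 1
  }, double(1))
  segs
}

#' Simulate a per-patient mutation table from a synthetic truth
#'
#' Per patient and per residue, a mutation occurs independently with
#' probability r (times the driver multiplier inside driver regions; nested
#' or overlapping drivers take the maximum).  Variant classes are drawn from
#' the truth's class mix; SNV classes get distinct ref/alt residues, indel
#' classes NA.  Decoy rows — synonymous SNVs, dbSNP-flagged variants (their
#' ids are recorded in the truth as the matching exclusion list), germline
#' calls and QC failures — are appended at the configured fractions so the
#' filter rules have something to remove.  Fully deterministic under the
#' truth's seed.
#'
#' @param truth A [synthetic_truth()] object.
#' @return Mutation tibble (same shape as [read_mutation_table()] output),
#'   with attributes `"truth"` (the input, with `dbsnp_exclusion_ids`
#'   filled) and `"n_core"` (count of non-decoy rows).
#' @export
generate_cohort <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  proteome <- truth$proteome
  reps <- proteome$proteins[proteome$proteins$is_representative, ]
  doms <- dplyr::semi_join(proteome$domains, reps, by = "protein_acc")
  samples <- sprintf("P%03d", seq_len(truth$n_patients))

  # driver intervals per protein
  drv <- truth$drivers
  gene_ivals <- if (nrow(drv)) {
    drv |>
      dplyr::filter(.data$region_kind == "gene") |>
      dplyr::inner_join(reps, by = c(region_id = "gene")) |>
      dplyr::transmute(.data$protein_acc, start = 1L, end = .data$length,
                       multiplier = .data$multiplier)
  } else tibble::tibble(protein_acc = character(), start = integer(),
                        end = integer(), multiplier = double())
  dom_ivals <- if (nrow(drv)) {
    drv |>
      dplyr::filter(.data$region_kind == "domain") |>
      dplyr::inner_join(doms, by = c(region_id = "domain_acc"),
                        relationship = "many-to-many") |>
      dplyr::select("protein_acc", "start", "end", "multiplier")
  } else gene_ivals[0, ]
  ivals <- dplyr::bind_rows(gene_ivals, dom_ivals)

  with_seed(truth$seed, {
    rows <- purrr::map_dfr(seq_len(nrow(reps)), function(i) {
      acc <- reps$protein_acc[i]
      segs <- rate_segments(reps$length[i],
                            ivals[ivals$protein_acc == acc, ])
      purrr::map_dfr(seq_len(nrow(segs)), function(s) {
        seg_len <- segs$end[s] - segs$start[s] + 1L
        rate <- truth$background_rate * segs$multiplier[s]
        counts <- rbinom(truth$n_patients, seg_len, rate)
        hit <- which(counts > 0)
        if (!length(hit)) return(NULL)
        # one Bernoulli trial per residue: positions unique within a patient
        pos <- unlist(lapply(hit, function(p) {
          segs$start[s] - 1L + sample.int(seg_len, counts[p])
        }))
        tibble::tibble(
          sample_id = rep(samples[hit], counts[hit]),
          gene = reps$gene[i], protein_acc = acc, protein_pos = pos)
      })
    })
    if (!nrow(rows)) {
      rows <- tibble::tibble(sample_id = character(), gene = character(),
                             protein_acc = character(),
                             protein_pos = integer())
    }
    n_core <- nrow(rows)
    cls <- sample(names(truth$class_probs), n_core, replace = TRUE,
                  prob = truth$class_probs)
    is_snv <- cls %in% c("nsSNV", "stopgain_SNV", "stoploss_SNV")
    ref <- sample(AA_ALPHABET, n_core, replace = TRUE)
    shift <- sample.int(length(AA_ALPHABET) - 1L, n_core, replace = TRUE)
    alt <- AA_ALPHABET[(match(ref, AA_ALPHABET) - 1L + shift) %%
                         length(AA_ALPHABET) + 1L]
    core <- dplyr::mutate(rows,
      ref_res = ifelse(is_snv, ref, NA_character_),
      alt_res = ifelse(is_snv, alt, NA_character_),
      variant_class = cls, dbsnp_id = NA_character_,
      is_somatic = TRUE, passed_qc = TRUE)

    decoy_rows <- function(n, class, dbsnp_id = NA_character_,
                           is_somatic = TRUE, passed_qc = TRUE) {
      if (n == 0) return(NULL)
      prot <- sample.int(nrow(reps), n, replace = TRUE,
                         prob = reps$length)
      pos <- vapply(reps$length[prot],
                    function(l) sample.int(l, 1L), integer(1))
      ref <- sample(AA_ALPHABET, n, replace = TRUE)
      shift <- sample.int(length(AA_ALPHABET) - 1L, n, replace = TRUE)
      tibble::tibble(
        sample_id = sample(samples, n, replace = TRUE),
        gene = reps$gene[prot], protein_acc = reps$protein_acc[prot],
        protein_pos = pos, ref_res = ref,
        alt_res = AA_ALPHABET[(match(ref, AA_ALPHABET) - 1L + shift) %%
                                length(AA_ALPHABET) + 1L],
        variant_class = class, dbsnp_id = dbsnp_id,
        is_somatic = is_somatic, passed_qc = passed_qc)
    }
    n_of <- function(what) {
      frac <- unname(truth$decoys[what])
      if (length(frac) != 1 || is.na(frac)) frac <- 0
      as.integer(round(frac * n_core))
    }
    n_db <- n_of("dbsnp")
    db_ids <- if (n_db) sprintf("rs%06d", seq_len(n_db)) else character()
    decoys <- dplyr::bind_rows(
      decoy_rows(n_of("synonymous"), "synonymous_SNV"),
      decoy_rows(n_db, "nsSNV", dbsnp_id = db_ids),
      decoy_rows(n_of("germline"), "nsSNV", is_somatic = FALSE),
      decoy_rows(n_of("qc_fail"), "nsSNV", passed_qc = FALSE)
    )
    out <- dplyr::bind_rows(core, decoys) |>
      dplyr::arrange(.data$sample_id, .data$protein_acc, .data$protein_pos,
                     .data$variant_class)
    truth$dbsnp_exclusion_ids <- db_ids
    attr(out, "truth") <- truth
    attr(out, "n_core") <- n_core
    out
  })
}

#' One-call synthetic cohort: proteome + mutations + filtering + assembly
#'
#' Generates a proteome from `spec`, simulates mutations under `truth`
#' parameters, applies [filter_cohort()] with the generated exclusion list,
#' and assembles the [build_cohort()] object.
#'
#' @param seed Integer seed driving both the proteome and the cohort.
#' @param spec A [proteome_spec()].
#' @param drivers,background_rate,n_patients,... Passed to
#'   [synthetic_truth()].
#' @return List with `cohort` (a `cohort` object), `truth`, and `mutations`
#'   (the raw pre-filter table).
#' @export
simulate_cohort <- function(seed = 1, spec = proteome_spec(),
                            drivers = NULL, background_rate = 5e-5,
                            n_patients = 100, ...) {
  proteome <- generate_proteome(spec, seed = seed)
  truth <- synthetic_truth(
    proteome,
    drivers = drivers %||% tibble::tibble(region_kind = character(),
                                          region_id = character(),
                                          multiplier = double()),
    background_rate = background_rate, n_patients = n_patients,
    seed = seed + 1L, ...)
  mutations <- generate_cohort(truth)
  truth <- attr(mutations, "truth")
  filtered <- filter_cohort(mutations, exclusion_ids = truth$dbsnp_exclusion_ids)
  cohort <- build_cohort(filtered, proteome$proteins, proteome$domains,
                         name = sprintf("synthetic_%d", seed),
                         n_patients = n_patients)
  list(cohort = cohort, truth = truth, mutations = mutations)
}

#' Reconstruct a minimal cohort realizing a per-gene domain breakdown
#'
#' Builds the smallest cohort in which each listed gene contributes exactly
#' `k` mutations to each listed domain: one representative protein per gene,
#' one instance per (gene, domain) pair laid out side by side, and `k`
#' distinct-patient nonsynonymous mutations placed inside the instance.
#' Useful for verifying aggregation arithmetic against published per-gene
#' contribution tables.
#'
#' @param breakdown Tibble `domain_acc`, `gene`, `k` (optionally
#'   `domain_name`).
#' @param instance_length Residue length of each instance (default 60; must
#'   be >= the largest `k`).
#' @return A `cohort` object.
#' @export
cohort_from_breakdown <- function(breakdown, instance_length = 60) {
  stopifnot(all(c("domain_acc", "gene", "k") %in% names(breakdown)))
  if (max(breakdown$k) > instance_length) {
    stop("instance_length must be >= the largest per-gene count",
         call. = FALSE)
  }
  if (!"domain_name" %in% names(breakdown)) {
    breakdown$domain_name <- breakdown$domain_acc
  }
  # one instance per (gene, domain), tiled left to right on the protein
  inst <- breakdown |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(slot = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(protein_acc = paste0("NP_", .data$gene),
                  start = (.data$slot - 1L) * as.integer(instance_length) + 1L,
                  end = .data$slot * as.integer(instance_length),
                  evalue = 1e-10)
  proteins <- inst |>
    dplyr::group_by(.data$gene, .data$protein_acc) |>
    dplyr::summarise(length = max(.data$end) + 20L, .groups = "drop") |>
    dplyr::mutate(is_representative = TRUE)
  mutations <- inst[inst$k > 0, ] |>
    dplyr::rowwise() |>
    dplyr::reframe(
      sample_id = sprintf("S%03d", seq_len(.data$k)),
      gene = .data$gene, protein_acc = .data$protein_acc,
      protein_pos = .data$start - 1L +
        (seq_len(.data$k) - 1L) %% as.integer(instance_length) + 1L,
      ref_res = "A", alt_res = "V", variant_class = "nsSNV",
      dbsnp_id = NA_character_, is_somatic = TRUE, passed_qc = TRUE)
  build_cohort(mutations, proteins,
               dplyr::select(inst, "domain_acc", "domain_name",
                             "protein_acc", "start", "end", "evalue"),
               name = "breakdown_fixture")
}

#' Write the planted ground truth as a TSV (for recovery scoring)
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  header <- tibble::tibble(
    region_kind = "param", region_id = c("background_rate", "n_patients", "seed"),
    multiplier = c(truth$background_rate, truth$n_patients, truth$seed))
  readr::write_tsv(dplyr::bind_rows(truth$drivers, header), path)
  invisible(path)
}
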