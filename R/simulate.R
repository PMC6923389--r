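#' Position-specific sequencing-error profile
#'
#' Substitution noise in deep amplicon sequencing is position- and
#' allele-specific. The generator draws an error VAF for every
#' (position, alternative allele) pair from a beta distribution and caps
#' it; a matched lesion/control pair shares these per-position rates, so
#' their VAF difference reflects sampling noise around a common,
#' position-local floor. Defaults are anchored to the scale of a negative
#' endometrium panel (per-hotspot VAF mean ~0.065%, SD ~0.09%): beta mean
#' `6.5e-4` with shape `0.57` (coefficient of variation ~1.3), capped at
#' 0.01.
#'
#' @param rate_mean Mean per-allele error VAF (default `6.5e-4`).
#' @param rate_shape Beta shape1; smaller values give stronger
#'   position-to-position heterogeneity (default 0.57).
#' @param max_rate Upper cap on any single error rate (default 0.01).
#' @return An `error_profile` list.
#' @export
error_profile <- function(rate_mean = 6.5e-4, rate_shape = 0.57, max_rate = 0.01) {
  stopifnot(rate_mean >= 0, rate_mean < max_rate, rate_shape > 0, max_rate <= 0.01)
  structure(
    list(rate_mean = rate_mean, rate_shape = rate_shape, max_rate = max_rate),
    class = "error_profile"
  )
}

# beta draw with given mean/shape, capped; a zero-mean profile is noise-free
.draw_rates <- function(n, profile) {
  if (profile$rate_mean == 0) {
    return(numeric(n))
  }
  shape1 <- profile$rate_shape
  shape2 <- shape1 * (1 / profile$rate_mean - 1)
  pmin(rbeta(n, shape1, shape2), profile$max_rate)
}

#' Simulate an amplicon allele-count table
#'
#' Per-position multinomial read draws over \{A, C, G, T\} at the given
#' depth, with per-allele error probabilities from the error profile and
#' optional spiked somatic variants; strand counts are split binomially.
#' Pure function of its arguments and the seed.
#'
#' @param target One-row target tibble ([target_region()]).
#' @param depth Reads per position.
#' @param profile An [error_profile()].
#' @param spikes Optional tibble `pos` (0-based), `alt`, `vaf` of somatic
#'   variants to spike in.
#' @param seed Integer seed; same seed, same table.
#' @param sample_id Sample name recorded in the output.
#' @param ref Optional character vector of reference bases (length of the
#'   region); drawn uniformly when `NULL`.
#' @param rates Optional pre-drawn error-rate matrix (positions x 3
#'   non-reference alleles), used to share the noise floor between a
#'   lesion and its matched control; drawn from `profile` when `NULL`.
#' @return A validated allele-count tibble. The realised `ref` and `rates`
#'   are attached as attributes so a matched sample can reuse them.
#' @export
simulate_amplicon <- function(target, depth, profile = error_profile(),
                              spikes = NULL, seed = 1, sample_id = "sim",
                              ref = NULL, rates = NULL) {
  stopifnot(nrow(target) == 1, depth > 0)
  len <- target$end - target$start
  pos <- seq.int(target$start, target$end - 1L)
  if (!is.null(spikes) && nrow(spikes) > 0) {
    if (any(!spikes$pos %in% pos)) {
      abort("spike position outside the target region")
    }
    if (any(spikes$vaf < 0 | spikes$vaf > 1)) {
      abort("spike VAFs must lie in [0, 1]")
    }
    if (!all(spikes$alt %in% ALLELES)) {
      abort("spike alleles must be one of A, C, G, T")
    }
  }
  withr::with_seed(seed, {
    if (is.null(ref)) ref <- sample(ALLELES, len, replace = TRUE)
    if (is.null(rates)) {
      rates <- matrix(.draw_rates(len * 3L, profile), nrow = len)
    }
    counts <- matrix(0L, len, 8, dimnames = list(NULL, COUNT_COLS))
    for (i in seq_len(len)) {
      p <- setNames(numeric(4), ALLELES)
      p[setdiff(ALLELES, ref[i])] <- rates[i, ]
      if (!is.null(spikes) && nrow(spikes) > 0) {
        here <- spikes$pos == pos[i]
        if (any(here)) {
          if (any(spikes$alt[here] == ref[i])) {
            abort("spike allele equals the reference base at its position")
          }
          p[spikes$alt[here]] <- p[spikes$alt[here]] + spikes$vaf[here]
        }
      }
      p[ref[i]] <- 1 - sum(p[setdiff(ALLELES, ref[i])])
      if (p[ref[i]] < 0) abort("spike + error probabilities exceed 1")
      tot <- rmultinom(1, depth, p)[, 1]
      fwd <- rbinom(4, tot, 0.5)
      # column order: A_fwd, A_rev, C_fwd, C_rev, ...
      counts[i, ] <- as.integer(t(cbind(fwd, tot - fwd)))
    }
    out <- tibble(
      sample_id = sample_id, region_id = target$region_id,
      pos = pos, ref = ref
    )
    for (k in seq_along(COUNT_COLS)) out[[COUNT_COLS[k]]] <- counts[, k]
    out <- validate_allele_counts(out)
    attr(out, "ref") <- ref
    attr(out, "rates") <- rates
    out
  })
}

#' Simulate a multi-region patient with known clonal structure
#'
#' Generates matched allele-count tables for every sample of a
#' multi-region design (lesion regions, optional normal tissues, and a
#' blood germline control drawn from the pure noise process), given a set
#' of clones, their mutations and their per-sample cell fractions.
#' Heterozygous autosomal variants contribute `cell_fraction / 2 * purity`
#' to the VAF. All samples of the patient share the same per-position
#' error-rate floor. Ground truth (expected VAF matrix and sharing
#' classes) is returned alongside the data so downstream inference can be
#' scored without re-derivation.
#'
#' @param mutations Tibble `clone_id`, `pos` (0-based), `alt`, optional
#'   `gene`.
#' @param placement Tibble `clone_id`, `sample_id`, `cell_fraction` in
#'   `[0, 1]`; omitted pairs mean the clone is absent.
#' @param meta Sample metadata tibble ([build_matrix()] schema) including
#'   one `blood` sample used as the matched control.
#' @param target One-row target tibble.
#' @param depth Reads per position.
#' @param profile An [error_profile()].
#' @param purity Epithelial-content multiplier on all cell fractions
#'   (default 1; bulk tissue dilution shrinks it).
#' @param seed Integer seed.
#' @return A list: `counts` (named list of allele-count tibbles, one per
#'   sample), `truth` (list with `vaf` - the expected mutation x sample
#'   VAF tibble -, `sharing` - per-mutation true sharing class and flags),
#'   `meta`, `target`.
#' @export
simulate_patient <- function(mutations, placement, meta, target, depth,
                             profile = error_profile(), purity = 1, seed = 1) {
  validate_meta(meta)
  stopifnot(all(placement$cell_fraction >= 0), all(placement$cell_fraction <= 1))
  if (!all(placement$sample_id %in% meta$sample_id)) {
    abort("placement refers to samples missing from meta")
  }
  if (!all(mutations$clone_id %in% placement$clone_id)) {
    abort("mutations refer to clones with no placement")
  }
  if (!"gene" %in% names(mutations)) mutations$gene <- NA_character_
  inside <- mutations$pos >= target$start & mutations$pos < target$end
  if (!all(inside)) {
    abort(paste0(
      "mutation position(s) outside the target region: ",
      paste(mutations$pos[!inside], collapse = ", ")
    ))
  }
  blood <- meta$sample_id[meta$tissue_class == "blood"]
  if (length(blood) != 1) {
    abort("meta must contain exactly one blood sample as germline control")
  }

  # expected VAF per mutation x sample
  truth_vaf <- tidyr::expand_grid(
    mutations %>% mutate(mutation_idx = row_number()),
    sample_id = meta$sample_id
  ) %>%
    left_join(placement, by = c("clone_id", "sample_id")) %>%
    mutate(
      cell_fraction = if_else(is.na(.data$cell_fraction) |
        .data$sample_id == blood, 0, .data$cell_fraction),
      true_vaf = .data$cell_fraction / 2 * purity,
      present = .data$true_vaf > 0
    ) %>%
    select(all_of(c(
      "clone_id", "mutation_idx", "pos", "alt", "gene",
      "sample_id", "true_vaf", "present"
    )))

  # draw the shared noise floor once, then each sample on a derived seed
  base <- simulate_amplicon(target, depth,
    profile = profile, seed = seed,
    sample_id = ".floor"
  )
  ref <- attr(base, "ref")
  rates <- attr(base, "rates")
  # spiked alleles must differ from the reference base
  mut_ref <- ref[mutations$pos - target$start + 1L]
  clash <- mutations$alt == mut_ref
  if (any(clash)) {
    ref[mutations$pos[clash] - target$start + 1L] <-
      purrr::map_chr(mutations$alt[clash], function(a) setdiff(ALLELES, a)[1])
  }
  counts <- purrr::imap(
    setNames(meta$sample_id, meta$sample_id),
    function(sid, nm) {
      spikes <- truth_vaf %>%
        filter(.data$sample_id == sid, .data$true_vaf > 0) %>%
        group_by(.data$pos, .data$alt) %>%
        summarise(vaf = sum(.data$true_vaf), .groups = "drop")
      simulate_amplicon(
        target, depth,
        profile = profile,
        spikes = if (nrow(spikes) > 0) spikes else NULL,
        seed = seed + 7919L * match(sid, meta$sample_id),
        sample_id = sid, ref = ref, rates = rates
      )
    }
  )

  truth_sharing <- .truth_sharing(truth_vaf, meta)
  list(
    counts = counts,
    truth = list(vaf = truth_vaf, sharing = truth_sharing),
    meta = meta, target = target
  )
}

# direct bookkeeping of the generator's sharing structure
.truth_sharing <- function(truth_vaf, meta) {
  lesion <- meta %>% filter(.data$tissue_class %in% LESION_CLASSES)
  dom_counts <- table(lesion$tissue_class)
  dominant <- names(dom_counts)[order(-dom_counts, match(names(dom_counts), LESION_CLASSES))][1]
  truth_vaf %>%
    left_join(meta %>% select(all_of(c("sample_id", "tissue_class"))), by = "sample_id") %>%
    group_by(.data$mutation_idx, .data$clone_id, .data$pos, .data$alt, .data$gene) %>%
    summarise(
      n_dom = sum(.data$present[.data$tissue_class == dominant]),
      n_dom_total = sum(.data$tissue_class == dominant),
      n_lesion = sum(.data$present[.data$tissue_class %in% LESION_CLASSES]),
      cross_lesion_shared = any(.data$present[.data$tissue_class == "adenomyosis"]) &&
        any(.data$present[.data$tissue_class == "endometriosis"]),
      normal_shared = any(.data$present[.data$tissue_class == "normal_endometrium"]),
      .groups = "drop"
    ) %>%
    mutate(
      basis = if_else(.data$n_dom > 0, .data$n_dom, .data$n_lesion),
      sharing_class = case_when(
        .data$n_dom >= 2 & .data$n_dom == .data$n_dom_total ~ "ubiquitous",
        .data$basis == 1 ~ "private",
        .data$basis > 1 ~ "restricted",
        TRUE ~ "private"
      )
    ) %>%
    select(-"basis")
}

#' Simulate a negative-panel VAF table for hotspot cutoff estimation
#'
#' Draws null per-hotspot VAFs (in percent) for a panel of
#' mutation-negative samples: each sample x hotspot gets an error rate
#' from the profile and a binomial read draw at the given depth. Feeding
#' the result to [estimate_cutoff()] yields detection cutoffs on the
#' sub-percent scale.
#'
#' @param n_samples Panel size (>= 2).
#' @param hotspot_ids Character vector of hotspot class names.
#' @param profile An [error_profile()].
#' @param depth Reads per hotspot (default 10000).
#' @param seed Integer seed.
#' @return A tibble `sample_id`, `hotspot_id`, `vaf_pct`.
#' @export
simulate_negative_panel <- function(n_samples, hotspot_ids,
                                    profile = error_profile(), depth = 10000,
                                    seed = 1) {
  stopifnot(n_samples >= 2)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      sample_id = sprintf("NE%02d", seq_len(n_samples)),
      hotspot_id = hotspot_ids
    )
    rate <- .draw_rates(nrow(grid), profile)
    grid %>% mutate(vaf_pct = 100 * rbinom(nrow(grid), depth, rate) / depth)
  })
}

#' Simulate bisulfite read counts over an amplicon
#'
#' Per CpG site, reads are truly methylated with the site's methylation
#' probability; unmethylated cytosines convert with probability
#' `conversion_rate`, so incomplete conversion inflates apparent
#' methylation by `(1 - conversion_rate)` at unmethylated sites. Non-CpG
#' cytosines (always unmethylated) are included for conversion QC.
#'
#' @param meth_prob Numeric vector: per-CpG methylation probability (its
#'   length sets the number of CpG sites).
#' @param read_depth Reads per site.
#' @param conversion_rate Bisulfite conversion efficiency (default 0.995).
#' @param n_noncpg Number of non-CpG cytosine sites (default 10).
#' @param error_rate Probability of an uncallable base at a site
#'   (default 0.002).
#' @param sample_id,amplicon_id Identifiers for the output.
#' @param seed Integer seed.
#' @return A bisulfite count tibble: `sample_id`, `amplicon_id`,
#'   `site_index`, `context` ("CpG"/"CHH"), `retained`, `converted`,
#'   `other`.
#' @export
simulate_bisulfite <- function(meth_prob, read_depth, conversion_rate = 0.995,
                               n_noncpg = 10, error_rate = 0.002,
                               sample_id = "sim", amplicon_id = "PR-A",
                               seed = 1) {
  stopifnot(all(meth_prob >= 0), all(meth_prob <= 1),
    conversion_rate >= 0, conversion_rate <= 1
  )
  withr::with_seed(seed, {
    n_cpg <- length(meth_prob)
    p_retained <- meth_prob + (1 - meth_prob) * (1 - conversion_rate)
    other_cpg <- rbinom(n_cpg, read_depth, error_rate)
    callable <- read_depth - other_cpg
    meth <- rbinom(n_cpg, callable, p_retained)
    cpg <- tibble(
      sample_id = sample_id, amplicon_id = amplicon_id,
      site_index = seq_len(n_cpg), context = "CpG",
      retained = meth, converted = callable - meth, other = other_cpg
    )
    other_nc <- rbinom(n_noncpg, read_depth, error_rate)
    callable_nc <- read_depth - other_nc
    conv <- rbinom(n_noncpg, callable_nc, conversion_rate)
    noncpg <- tibble(
      sample_id = sample_id, amplicon_id = amplicon_id,
      site_index = n_cpg + seq_len(n_noncpg), context = "CHH",
      retained = callable_nc - conv, converted = conv, other = other_nc
    )
    bind_rows(cpg, noncpg)
  })
}

#' Simulate cohort metadata with designed characteristic associations
#'
#' Generates a patient table consumable by [table1_battery()]: mutation
#' status is Bernoulli, and each characteristic is Bernoulli with a
#' probability depending on mutation status, so the true odds ratio per
#' characteristic is known.
#'
#' @param n_patients Cohort size.
#' @param kras_prob Probability a patient is mutation-positive
#'   (default 0.371).
#' @param associations Tibble `characteristic`, `prob_given_mut`,
#'   `prob_given_wt`.
#' @param seed Integer seed.
#' @return A list: `meta` (patient tibble) and `truth` (per characteristic
#'   the generating probabilities and true odds ratio).
#' @export
simulate_cohort_metadata <- function(n_patients, kras_prob = 0.371,
                                     associations, seed = 1) {
  stopifnot(
    all(associations$prob_given_mut >= 0), all(associations$prob_given_mut <= 1),
    all(associations$prob_given_wt >= 0), all(associations$prob_given_wt <= 1)
  )
  withr::with_seed(seed, {
    meta <- tibble(
      patient_id = sprintf("P%03d", seq_len(n_patients)),
      kras_mutated = runif(n_patients) < kras_prob
    )
    for (i in seq_len(nrow(associations))) {
      p <- if_else(
        meta$kras_mutated,
        associations$prob_given_mut[i], associations$prob_given_wt[i]
      )
      meta[[associations$characteristic[i]]] <- runif(n_patients) < p
    }
    odds <- function(p) p / (1 - p)
    truth <- associations %>%
      mutate(true_odds_ratio = odds(.data$prob_given_mut) / odds(.data$prob_given_wt))
    list(meta = meta, truth = truth)
  })
}
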