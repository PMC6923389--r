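#' Configuration for the exome candidate-SNV hard filters
#'
#' Defaults are the discard rules used for exome candidate curation: a
#' candidate is discarded when total reads < 100, mutant reads < 7, disease
#' VAF < 0.024, germline VAF > 0.01, the mutant allele is seen on only one
#' strand, or the variant is present in a population database. (The
#' mutant-read rule is sometimes paraphrased as "< 8"; the formal threshold
#' of 7 is the default here and is configurable.)
#'
#' @param min_total_reads Discard below this total depth (default 100).
#' @param min_mutant_reads Discard below this mutant read count (default 7).
#' @param min_vaf_disease Discard below this disease VAF (default 0.024).
#' @param max_vaf_germline Discard above this germline VAF (default 0.01).
#' @param require_both_strands Discard single-strand support (default TRUE).
#' @param exclude_population_db Discard known population variants (default TRUE).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_total_reads = 100, min_mutant_reads = 7,
                          min_vaf_disease = 0.024, max_vaf_germline = 0.01,
                          require_both_strands = TRUE,
                          exclude_population_db = TRUE) {
  stopifnot(
    min_total_reads >= 0, min_mutant_reads >= 0,
    min_vaf_disease >= 0, max_vaf_germline >= 0
  )
  structure(
    list(
      min_total_reads = min_total_reads,
      min_mutant_reads = min_mutant_reads,
      min_vaf_disease = min_vaf_disease,
      max_vaf_germline = max_vaf_germline,
      require_both_strands = isTRUE(require_both_strands),
      exclude_population_db = isTRUE(exclude_population_db)
    ),
    class = "filter_config"
  )
}

validate_candidates <- function(candidates) {
  need <- c(
    "chrom", "pos", "ref", "alt", "total_reads", "mutant_reads",
    "mutant_reads_fwd", "mutant_reads_rev", "vaf_disease", "vaf_germline",
    "in_population_db"
  )
  miss <- setdiff(need, names(candidates))
  if (length(miss) > 0) {
    abort(paste0("candidate table missing column(s): ", paste(miss, collapse = ", ")))
  }
  with(candidates, {
    if (any(mutant_reads_fwd + mutant_reads_rev != mutant_reads)) {
      abort("mutant_reads must equal mutant_reads_fwd + mutant_reads_rev")
    }
    if (any(mutant_reads > total_reads)) {
      abort("mutant_reads must not exceed total_reads")
    }
    if (any(vaf_disease < 0 | vaf_disease > 1 | vaf_germline < 0 | vaf_germline > 1)) {
      abort("VAFs must lie in [0, 1]")
    }
  })
  invisible(candidates)
}

#' Apply the hard-filter battery to exome candidate SNVs
#'
#' A candidate is discarded if *any* rule fires; every violated rule is
#' recorded, so the discard log is complete rather than first-hit. The
#' retained and discarded sets partition the input.
#'
#' @param candidates Tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `total_reads`, `mutant_reads`, `mutant_reads_fwd`, `mutant_reads_rev`,
#'   `vaf_disease`, `vaf_germline`, `in_population_db` (logical).
#' @param config A [filter_config()].
#' @return A list with tibbles `retained` (input columns, in input order)
#'   and `discarded` (input columns plus `filter_reasons`, a
#'   semicolon-joined rule list).
#' @export
filter_candidates <- function(candidates, config = filter_config()) {
  validate_candidates(candidates)
  rules <- tibble(
    total_reads = candidates$total_reads < config$min_total_reads,
    mutant_reads = candidates$mutant_reads < config$min_mutant_reads,
    vaf_disease = candidates$vaf_disease < config$min_vaf_disease,
    vaf_germline = candidates$vaf_germline > config$max_vaf_germline,
    single_strand = config$require_both_strands &
      (candidates$mutant_reads_fwd == 0 | candidates$mutant_reads_rev == 0),
    population_db = config$exclude_population_db & candidates$in_population_db
  )
  reasons <- apply(as.matrix(rules), 1, function(r) {
    paste(names(rules)[r], collapse = ";")
  })
  drop <- reasons != ""
  list(
    retained = candidates[!drop, , drop = FALSE],
    discarded = candidates[drop, , drop = FALSE] %>%
      mutate(filter_reasons = reasons[drop])
  )
}

#' Summarise retained SNVs across a cohort
#'
#' @param retained_by_patient A named list of retained-candidate tibbles
#'   (one per patient, possibly empty), or a single tibble with a
#'   `patient_id` column.
#' @return A one-row tibble: `n_patients`, `n_mutated` (patients with at
#'   least one retained SNV), `frac_mutated`, `n_snvs`,
#'   `mean_snvs_per_patient`, and the VAF summaries `vaf_mean`, `vaf_min`,
#'   `vaf_max` (NA for an empty cohort).
#' @export
summarize_cohort <- function(retained_by_patient) {
  if (is.data.frame(retained_by_patient)) {
    stopifnot("patient_id" %in% names(retained_by_patient))
    retained_by_patient <- split(
      retained_by_patient,
      retained_by_patient$patient_id
    )
  }
  n_per <- purrr::map_int(retained_by_patient, nrow)
  vafs <- purrr::map(retained_by_patient, function(x) x$vaf_disease) %>%
    purrr::flatten_dbl()
  tibble(
    n_patients = length(n_per),
    n_mutated = sum(n_per > 0),
    frac_mutated = if (length(n_per) > 0) sum(n_per > 0) / length(n_per) else NA_real_,
    n_snvs = sum(n_per),
    mean_snvs_per_patient = if (length(n_per) > 0) mean(n_per) else NA_real_,
    vaf_mean = if (length(vafs) > 0) mean(vafs) else NA_real_,
    vaf_min = if (length(vafs) > 0) min(vafs) else NA_real_,
    vaf_max = if (length(vafs) > 0) max(vafs) else NA_real_
  )
}
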