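#' Define a mutation hotspot class
#'
#' A hotspot class pools the codon positions and alternative alleles that
#' are scored together against a single detection cutoff (for example
#' "KRAS p.G12/G13" pools the codon-12 and codon-13 substitutions).
#'
#' @param hotspot_id Identifier, e.g. `"KRAS p.G12/G13"`.
#' @param gene Gene symbol.
#' @param positions Integer vector of genomic positions in the class.
#' @param alleles Character vector of allowed alternative alleles (recycled
#'   against positions if length 1).
#' @return A one-row `hotspot_def` tibble with list-columns `positions`
#'   and `alleles`.
#' @export
hotspot_def <- function(hotspot_id, gene, positions, alleles = c("A", "C", "G", "T")) {
  if (length(positions) == 0) {
    abort("a hotspot class needs at least one position")
  }
  tibble(
    hotspot_id = hotspot_id, gene = gene,
    positions = list(as.integer(positions)),
    alleles = list(as.character(alleles))
  )
}

#' Read hotspot definitions from JSON
#'
#' The file is an array of objects with fields `hotspot_id`, `gene`,
#' `positions`, `alleles`.
#'
#' @param path Path to the JSON file.
#' @return A `hotspot_def` tibble, one row per class.
#' @export
read_hotspot_defs <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  purrr::map_dfr(x, function(h) {
    hotspot_def(h$hotspot_id, h$gene, unlist(h$positions), unlist(h$alleles))
  })
}

#' Estimate a hotspot detection cutoff from a negative panel
#'
#' The cutoff is `panel mean + 3 x panel SD` of the hotspot VAFs observed
#' in a panel of negative (histologically normal endometrium) samples.
#' Percent is the canonical unit throughout this module.
#'
#' @param panel_vafs Numeric vector of per-sample hotspot VAFs, in percent.
#' @param hotspot_id Identifier carried into the result.
#' @param sd_ddof 0 for the population SD (default) or 1 for the sample SD.
#' @param leave_out Optional sample index to exclude (leave-one-out cutoff
#'   estimation when the tested sample is itself a panel member).
#' @return A one-row tibble: `hotspot_id`, `panel_mean`, `panel_sd`,
#'   `cutoff` (`= panel_mean + 3 * panel_sd`), `panel_n`.
#' @examples
#' # a panel standardised to mean 0.065 / SD 0.09 gives cutoff 0.335
#' v <- c(0.065 - 0.09, 0.065, 0.065 + 0.09)
#' estimate_cutoff(v, "KRAS p.G12/G13")
#' @export
estimate_cutoff <- function(panel_vafs, hotspot_id = NA_character_,
                            sd_ddof = 0, leave_out = NULL) {
  if (!is.null(leave_out)) panel_vafs <- panel_vafs[-leave_out]
  n <- length(panel_vafs)
  if (n < 2) {
    abort("cutoff estimation needs a panel of at least 2 samples")
  }
  if (any(panel_vafs < 0)) {
    abort("panel VAFs must be non-negative")
  }
  m <- mean(panel_vafs)
  s <- if (sd_ddof == 1) stats::sd(panel_vafs) else sqrt(mean((panel_vafs - m)^2))
  tibble(
    hotspot_id = hotspot_id, panel_mean = m, panel_sd = s,
    cutoff = m + 3 * s, panel_n = n
  )
}

#' Call a hotspot mutation against a panel-derived cutoff
#'
#' Positive iff the sample VAF strictly exceeds the cutoff; a VAF exactly
#' at the cutoff is negative.
#'
#' @param sample_vaf Numeric vector of sample hotspot VAFs, in percent.
#' @param cutoff A cutoff tibble from [estimate_cutoff()] (or a bare
#'   number, in percent).
#' @return Logical vector of calls.
#' @export
call_hotspot <- function(sample_vaf, cutoff) {
  if (is.data.frame(cutoff)) cutoff <- cutoff$cutoff
  if (any(is.na(sample_vaf)) || any(sample_vaf < 0)) {
    abort("sample VAFs must be non-negative and non-missing")
  }
  sample_vaf > cutoff
}

#' Aggregate a sample's VAFs within a hotspot class
#'
#' A class pools several codons; the sample-level hotspot VAF is the
#' maximum single alt-allele VAF within the class (a conservative pooling
#' for detection: one real mutant codon suffices).
#'
#' @param vafs Tibble with columns `pos`, `alt`, `vaf` (percent).
#' @param hotspot One-row [hotspot_def()] tibble.
#' @return The pooled VAF in percent (0 when no class position is present).
#' @export
pool_hotspot_vaf <- function(vafs, hotspot) {
  sel <- vafs$pos %in% hotspot$positions[[1]] & vafs$alt %in% hotspot$alleles[[1]]
  if (!any(sel)) {
    return(0)
  }
  max(vafs$vaf[sel])
}

#' Per-group hotspot mutation frequencies
#'
#' Groups are the macro-dissection design labels: patients with
#' adenomyosis ("A"), with endometriosis only ("E"), and with neither
#' ("Non-A/E"). Per group the fraction of hotspot-positive samples is
#' reported, plus the VAF vectors of positive samples for downstream Welch
#' comparisons.
#'
#' @param samples Tibble with columns `sample_id`, `group`, `vaf`
#'   (percent) for one hotspot class; every sample must carry exactly one
#'   non-missing group label.
#' @param cutoff A cutoff tibble from [estimate_cutoff()] or a number.
#' @return A tibble per group: `group`, `n`, `n_positive`, `frac_positive`
#'   (NA-flagged for empty groups), `vafs` (list-column of all VAFs) and
#'   `positive_vafs` (list-column of VAFs above cutoff).
#' @export
group_mutation_table <- function(samples, cutoff) {
  if (anyNA(samples$group)) {
    abort("every sample must carry a group label")
  }
  # factor groups keep empty levels, which come back undefined-flagged
  samples %>%
    mutate(positive = call_hotspot(.data$vaf, cutoff)) %>%
    group_by(.data$group, .drop = FALSE) %>%
    summarise(
      n = n(),
      n_positive = sum(.data$positive),
      frac_positive = if_else(n() > 0, sum(.data$positive) / n(), NA_real_),
      vafs = list(.data$vaf),
      positive_vafs = list(.data$vaf[.data$positive]),
      .groups = "drop"
    )
}
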