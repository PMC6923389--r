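validate_bisulfite <- function(counts) {
  need <- c("sample_id", "amplicon_id", "site_index", "context", "retained", "converted")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    abort(paste0("bisulfite count table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"other" %in% names(counts)) counts$other <- 0
  if (any(counts$retained < 0 | counts$converted < 0 | counts$other < 0)) {
    abort("bisulfite counts must be non-negative")
  }
  counts
}

#' Per-CpG methylation frequency
#'
#' At a CpG site, reads retaining the cytosine are methylated and reads
#' converted to T are unmethylated; anything else is uncallable and
#' excluded from the denominator. `freq = methylated / callable`, with
#' zero-callable sites flagged `NA` rather than erroring.
#'
#' @param counts Tibble with columns `sample_id`, `amplicon_id`,
#'   `site_index`, `context` (`"CpG"` rows are used), `retained`,
#'   `converted`, and optional `other`.
#' @return A tibble per CpG: the id columns plus `methylated`,
#'   `unmethylated`, `callable`, `freq`, `defined`.
#' @export
methylation_frequency <- function(counts) {
  counts <- validate_bisulfite(counts)
  counts %>%
    filter(.data$context == "CpG") %>%
    mutate(
      methylated = .data$retained,
      unmethylated = .data$converted,
      callable = .data$retained + .data$converted,
      defined = .data$callable > 0,
      freq = if_else(.data$defined, .data$methylated / .data$callable, NA_real_)
    ) %>%
    select(all_of(c(
      "sample_id", "amplicon_id", "site_index",
      "methylated", "unmethylated", "callable", "freq", "defined"
    )))
}

#' Per-sample amplicon methylation summary
#'
#' The per-sample summary is the unweighted mean frequency over defined
#' CpG sites of the amplicon (matching per-region reporting granularity);
#' set `depth_weighted = TRUE` to weight sites by callable depth instead.
#'
#' @param profile Per-CpG tibble from [methylation_frequency()].
#' @param depth_weighted Weight CpGs by callable reads (default FALSE).
#' @return A tibble per `sample_id` x `amplicon_id`: `n_cpg`, `mean_freq`.
#' @export
summarize_methylation <- function(profile, depth_weighted = FALSE) {
  profile %>%
    filter(.data$defined) %>%
    group_by(.data$sample_id, .data$amplicon_id) %>%
    summarise(
      n_cpg = n(),
      mean_freq = if (depth_weighted) {
        sum(.data$freq * .data$callable) / sum(.data$callable)
      } else {
        mean(.data$freq)
      },
      .groups = "drop"
    )
}

#' Bisulfite conversion-rate QC
#'
#' Cytosines outside CpG context are essentially unmethylated, so the
#' fraction converted at non-CpG C's estimates the bisulfite conversion
#' efficiency; incomplete conversion inflates apparent CpG methylation.
#'
#' @param counts Bisulfite count tibble (rows with `context != "CpG"` are
#'   used).
#' @param min_rate Warn below this conversion rate (default 0.98).
#' @return A tibble per `sample_id` x `amplicon_id`: `n_sites`,
#'   `conversion_rate`, `flag` (TRUE when below `min_rate`).
#' @export
conversion_qc <- function(counts, min_rate = 0.98) {
  counts <- validate_bisulfite(counts)
  out <- counts %>%
    filter(.data$context != "CpG") %>%
    group_by(.data$sample_id, .data$amplicon_id) %>%
    summarise(
      n_sites = n(),
      conversion_rate = sum(.data$converted) /
        pmax(sum(.data$converted) + sum(.data$retained), 1),
      .groups = "drop"
    ) %>%
    mutate(flag = .data$conversion_rate < min_rate)
  if (any(out$flag)) {
    warn(paste0(
      "low bisulfite conversion rate (< ", min_rate, ") in: ",
      paste(paste0(out$sample_id[out$flag], "/", out$amplicon_id[out$flag]),
        collapse = ", "
      )
    ))
  }
  out
}

#' Compare promoter methylation between mutation groups
#'
#' Per amplicon, Welch's t-test on the per-sample mean CpG methylation
#' frequencies of two groups (e.g. KRAS wild-type vs KRAS-mutated
#' lesions).
#'
#' @param summary Per-sample summary from [summarize_methylation()].
#' @param groups Tibble `sample_id`, `group` with exactly two group
#'   levels.
#' @return A tibble per amplicon: group means/SDs/sizes, `t`, `df`,
#'   `p_value` (two-sided).
#' @export
compare_methylation_groups <- function(summary, groups) {
  lv <- sort(unique(groups$group))
  if (length(lv) != 2) {
    abort("compare_methylation_groups() needs exactly two groups")
  }
  df <- summary %>% inner_join(groups, by = "sample_id")
  df %>%
    group_by(.data$amplicon_id) %>%
    summarise(
      {
        x <- .data$mean_freq[.data$group == lv[1]]
        y <- .data$mean_freq[.data$group == lv[2]]
        if (length(x) < 2 || length(y) < 2) {
          abort("each group needs at least 2 samples per amplicon")
        }
        wt <- welch_t(x, y)
        tibble(
          group_1 = lv[1], n_1 = length(x), mean_1 = mean(x), sd_1 = stats::sd(x),
          group_2 = lv[2], n_2 = length(y), mean_2 = mean(y), sd_2 = stats::sd(y),
          t = wt$t, df = wt$df, p_value = wt$p_value
        )
      },
      .groups = "drop"
    )
}
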