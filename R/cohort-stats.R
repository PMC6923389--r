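#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by the point-probability rule: with margins fixed, the p-value
#' is the sum of hypergeometric probabilities of all tables whose point
#' probability does not exceed that of the observed table (the convention
#' of mainstream implementations, reproduced here in vectorisable form).
#' The odds ratio returned is the sample (cross-product) estimate
#' `(a*d)/(b*c)`, NA-flagged when a margin is empty.
#'
#' @param a,b,c,d The 2x2 cell counts, row-wise: `a` exposed & positive,
#'   `b` exposed & negative, `c` unexposed & positive, `d` unexposed &
#'   negative. Alternatively `a` may be a 2x2 matrix.
#' @return A one-row tibble: `odds_ratio`, `p_value`.
#' @examples
#' fisher_exact(11, 2, 15, 42) # p ~ 2e-4
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    b <- a[1, 2]
    c <- a[2, 1]
    d <- a[2, 2]
    a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("2x2 cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) {
    abort("2x2 table must have a positive grand total")
  }
  p <- .fisher_p(a, b, c, d)
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
  tibble(odds_ratio = or, p_value = p)
}

# bare-numeric point-probability p; kept separate so sweeps over many
# tables avoid per-call tibble overhead
.fisher_p <- function(a, b, c, d) {
  m <- a + c # column-1 total
  n_ <- b + d # column-2 total
  k <- a + b # row-1 total
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  # tolerance keeps ties (tables with the same probability) in the sum
  p_obs <- probs[support == a]
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t with Satterthwaite degrees of freedom, as used for
#' all VAF and methylation group comparisons. The degenerate
#' zero-variance case is resolved deterministically: equal means give
#' `t = 0, p = 1`, different means give infinite `t` and `p = 0`.
#'
#' @param x,y Numeric vectors, each of length >= 2, finite.
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("welch_t() needs at least 2 observations per group")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("welch_t() requires finite observations")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble(
      t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
      df = length(x) + length(y) - 2,
      p_value = if (eq) 1 else 0,
      mean_x = mean(x), mean_y = mean(y)
    ))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y)
  )
}

#' Fisher tests of every patient characteristic against mutation status
#'
#' Builds, for each logical characteristic column, the 2x2 table of
#' characteristic x KRAS mutation status and runs [fisher_exact()] -
#' the cohort-table battery relating clinical variables (pretreatment,
#' endometriosis subtypes, PR immunostaining, ...) to mutation status.
#'
#' @param meta Tibble with one row per patient: a logical `kras_mutated`
#'   column plus one logical column per characteristic (all non-id logical
#'   columns are tested).
#' @param characteristics Optional character vector naming the columns to
#'   test; default is every logical column except `kras_mutated`.
#' @return A tidy tibble per characteristic: counts in each arm
#'   (`n_mut_pos`, `n_mut`, `n_wt_pos`, `n_wt`), `odds_ratio`, `p_value`.
#' @export
table1_battery <- function(meta, characteristics = NULL) {
  if (!"kras_mutated" %in% names(meta) || anyNA(meta$kras_mutated)) {
    abort("meta must carry a complete logical 'kras_mutated' column")
  }
  if (is.null(characteristics)) {
    characteristics <- setdiff(
      names(meta)[purrr::map_lgl(meta, is.logical)],
      "kras_mutated"
    )
  }
  purrr::map_dfr(characteristics, function(ch) {
    v <- meta[[ch]]
    mut <- meta$kras_mutated
    a <- sum(v & mut)
    b <- sum(!v & mut)
    c <- sum(v & !mut)
    d <- sum(!v & !mut)
    fe <- fisher_exact(a, b, c, d)
    tibble(
      characteristic = ch,
      n_mut_pos = a, n_mut = sum(mut),
      n_wt_pos = c, n_wt = sum(!mut),
      odds_ratio = fe$odds_ratio, p_value = fe$p_value
    )
  })
}

#' Relative expression by the comparative-Ct method
#'
#' `dCt = Ct_target - Ct_reference` per sample; `ddCt` subtracts the mean
#' `dCt` of the control condition; fold change is `2^(-ddCt)` (the
#' housekeeping-normalised relative expression).
#'
#' @param measurements Tibble with columns `sample_id`, `ct_target`,
#'   `ct_reference`, `condition`.
#' @param control_condition The condition serving as calibrator
#'   (default `"control"`).
#' @return The input plus `dct`, `ddct`, `fold_change`.
#' @examples
#' qpcr_fold_change(tibble::tibble(
#'   sample_id = c("c1", "c2", "t1"),
#'   ct_target = c(25, 25.4, 27.2), ct_reference = c(20, 20.4, 20.2),
#'   condition = c("control", "control", "treated")
#' ))
#' @export
qpcr_fold_change <- function(measurements, control_condition = "control") {
  need <- c("sample_id", "ct_target", "ct_reference", "condition")
  miss <- setdiff(need, names(measurements))
  if (length(miss) > 0) {
    abort(paste0("qPCR table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyNA(measurements$ct_target) || anyNA(measurements$ct_reference)) {
    abort("missing Ct values")
  }
  if (!any(measurements$condition == control_condition)) {
    abort(paste0("no samples in control condition '", control_condition, "'"))
  }
  measurements %>%
    mutate(dct = .data$ct_target - .data$ct_reference) %>%
    mutate(
      ddct = .data$dct - mean(.data$dct[.data$condition == control_condition]),
      fold_change = 2^(-.data$ddct)
    )
}
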