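#' Configuration for the position-local noise caller
#'
#' The caller tests, at each position `j`, whether the lesion-vs-control
#' VAF difference `d_j` exceeds the local background noise. A call requires
#' all three of: `P(X > d_j) < alpha` for `X ~ N(mu_j, sigma_j^2)` fitted on
#' the surrounding window, `d_j > d_min`, and every non-reference allele in
#' the control staying below `control_vaf_max`.
#'
#' @param alpha One-sided significance level (default 0.05).
#' @param d_min Minimum VAF difference, as a fraction (default 0.001).
#' @param control_vaf_max Maximum control VAF for any non-reference allele
#'   at the tested position (default 0.01).
#' @param K Window half-width in positions. `NULL` (default) uses the full
#'   region length, so the background is estimated from every other defined
#'   position of the amplicon.
#' @param sd_ddof Degrees-of-freedom correction for the window SD: 0
#'   (population SD, default) or 1 (sample SD).
#' @param bonferroni If `TRUE`, Bonferroni-correct p-values across the
#'   tested positions of a region before applying `alpha`. Off by default;
#'   the per-position test is reported uncorrected.
#' @return A `caller_config` list.
#' @export
caller_config <- function(alpha = 0.05, d_min = 0.001, control_vaf_max = 0.01,
                          K = NULL, sd_ddof = 0, bonferroni = FALSE) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
    is.numeric(d_min), d_min >= 0,
    is.numeric(control_vaf_max), control_vaf_max > 0, control_vaf_max < 1,
    is.null(K) || (is.numeric(K) && K >= 1),
    sd_ddof %in% c(0, 1),
    is.logical(bonferroni)
  )
  structure(
    list(
      alpha = alpha, d_min = d_min, control_vaf_max = control_vaf_max,
      K = if (is.null(K)) NULL else as.integer(K),
      sd_ddof = sd_ddof, bonferroni = isTRUE(bonferroni)
    ),
    class = "caller_config"
  )
}

#' Per-position VAF difference track between lesion and control
#'
#' For each position `i` the statistic is
#' `d_i = max over alleles y of |a_{y,i} - n_{y,i}|`, where `a` and `n` are
#' the lesion and control VAF profiles. The maximising allele is recorded;
#' ties break alphabetically. Positions where either sample has zero depth
#' are flagged undefined.
#'
#' @param lesion,control Long VAF tibbles from [compute_vaf()], covering the
#'   same region and positions.
#' @return A tibble with one row per position: `region_id`, `pos`, `ref`,
#'   `d`, `allele` (argmax over the full alphabet), `alt` (argmax among
#'   non-reference alleles), `defined`, `lesion_depth`, `control_depth`.
#' @export
difference_track <- function(lesion, control) {
  if (!setequal(unique(lesion$region_id), unique(control$region_id))) {
    abort("lesion and control VAF profiles cover different regions")
  }
  j <- inner_join(
    lesion %>% select(all_of(c("region_id", "pos", "ref", "allele", "vaf", "depth"))),
    control %>% select(all_of(c("region_id", "pos", "allele", "vaf", "depth"))),
    by = c("region_id", "pos", "allele"), suffix = c("_lesion", "_control")
  )
  if (nrow(j) != nrow(lesion) || nrow(j) != nrow(control)) {
    abort("lesion and control VAF profiles cover different positions")
  }
  j %>%
    mutate(absdiff = abs(.data$vaf_lesion - .data$vaf_control)) %>%
    arrange(.data$region_id, .data$pos, .data$allele) %>%
    group_by(.data$region_id, .data$pos, .data$ref) %>%
    summarise(
      is_defined = all(!is.na(.data$absdiff)),
      d = if (.data$is_defined[1]) max(.data$absdiff) else NA_real_,
      best_allele = if (.data$is_defined[1]) {
        .data$allele[which.max(.data$absdiff)]
      } else {
        NA_character_
      },
      best_alt = if (.data$is_defined[1]) {
        nonref <- which(.data$allele != .data$ref[1])
        .data$allele[nonref][which.max(.data$absdiff[nonref])]
      } else {
        NA_character_
      },
      lesion_depth = .data$depth_lesion[1],
      control_depth = .data$depth_control[1],
      .groups = "drop"
    ) %>%
    rename(
      defined = "is_defined", allele = "best_allele", alt = "best_alt"
    ) %>%
    select(all_of(c(
      "region_id", "pos", "ref", "d", "allele", "alt", "defined",
      "lesion_depth", "control_depth"
    ))) %>%
    arrange(.data$region_id, .data$pos)
}

#' Fit the windowed background-noise model
#'
#' For position `j`, the null is `N(mu_j, sigma_j^2)` where `mu_j` and
#' `sigma_j` are the mean and SD of the difference track over the window
#' `{j-K, ..., j-1, j+1, ..., j+K}` - position `j` itself is always
#' excluded from its own background. The window is truncated at region
#' boundaries and restricted to defined positions; no padding is invented.
#'
#' @param track Difference track from [difference_track()] (one region).
#' @param j Position(s) to fit, 0-based; `NULL` fits every defined position.
#' @param config A [caller_config()].
#' @return A tibble `region_id`, `pos`, `mu`, `sigma`, `n_window`. When `j`
#'   is given explicitly, a window with fewer than 2 usable positions is an
#'   error; when scanning, such positions are returned with `NA` model.
#' @export
fit_background <- function(track, j = NULL, config = caller_config()) {
  if (length(unique(track$region_id)) != 1) {
    abort("fit_background() expects a single-region track")
  }
  track <- arrange(track, .data$pos)
  pos <- track$pos
  if (any(diff(pos) != 1)) {
    abort("difference track positions must be contiguous")
  }
  n <- length(pos)
  K <- if (is.null(config$K)) n else min(config$K, n)

  dv <- track$d
  ok <- as.numeric(!is.na(dv))
  d0 <- if_else(is.na(dv), 0, dv)
  cs <- cumsum(d0)
  cs2 <- cumsum(d0^2)
  cn <- cumsum(ok)
  idx <- seq_len(n)
  lo <- pmax(idx - K, 1L)
  hi <- pmin(idx + K, n)
  prev <- pmax(lo - 1L, 1L)
  before <- lo > 1 # zero-width prefix when the window starts at row 1
  wsum <- cs[hi] - ifelse(before, cs[prev], 0)
  wsum2 <- cs2[hi] - ifelse(before, cs2[prev], 0)
  wn <- cn[hi] - ifelse(before, cn[prev], 0)
  # drop j itself from its own window
  wsum <- wsum - d0
  wsum2 <- wsum2 - d0^2
  wn <- wn - ok

  mu <- if_else(wn >= 1, wsum / wn, NA_real_)
  v0 <- pmax(wsum2 / wn - mu^2, 0)
  v <- if (config$sd_ddof == 1) v0 * wn / pmax(wn - 1, 1) else v0
  sigma <- if_else(wn >= 2, sqrt(v), NA_real_)
  mu[wn < 2] <- NA_real_

  out <- tibble(
    region_id = track$region_id, pos = pos,
    mu = mu, sigma = sigma, n_window = as.integer(wn)
  )
  if (!is.null(j)) {
    out <- out[match(j, out$pos), , drop = FALSE]
    if (anyNA(out$pos)) {
      abort(paste0("position(s) not on track: ", paste(setdiff(j, pos), collapse = ", ")))
    }
    degen <- out$n_window < 2
    if (any(degen)) {
      abort(paste0(
        "degenerate background (fewer than 2 window positions) at position(s): ",
        paste(out$pos[degen], collapse = ", ")
      ))
    }
  }
  out
}

# upper-tail p under N(mu, sigma^2); sigma = 0 collapses to a point mass
.noise_pvalue <- function(d, mu, sigma) {
  n <- max(length(d), length(mu), length(sigma))
  d <- rep_len(d, n)
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  p <- numeric(n)
  spread <- sigma > 0
  p[spread] <- pnorm(d[spread], mean = mu[spread], sd = sigma[spread],
    lower.tail = FALSE
  )
  p[!spread] <- ifelse(d[!spread] > mu[!spread], 0, 1)
  p
}

#' Test a single position against its background model
#'
#' @param track Difference track (one region).
#' @param background Background tibble from [fit_background()] containing
#'   the tested position.
#' @param lesion,control Long VAF tibbles from [compute_vaf()].
#' @param j Position to test (0-based).
#' @param config A [caller_config()].
#' @return A one-row call tibble (see [call_region()] for the columns).
#' @export
test_position <- function(track, background, lesion, control, j,
                          config = caller_config()) {
  bg <- background %>% filter(.data$pos == j)
  if (nrow(bg) != 1 || is.na(bg$sigma)) {
    abort(paste0("background model undefined at position ", j))
  }
  row <- track %>% filter(.data$pos == j)
  if (nrow(row) != 1 || !row$defined) {
    abort(paste0("difference track undefined at position ", j))
  }
  ctrl_j <- control %>% filter(.data$pos == j)
  les_j <- lesion %>% filter(.data$pos == j)
  assemble_calls(
    track = row, background = bg,
    lesion_alt_vaf = les_j$vaf[match(row$alt, les_j$allele)],
    control_alt_vaf = ctrl_j$vaf[match(row$alt, ctrl_j$allele)],
    control_nonref_max = max(ctrl_j$vaf[ctrl_j$allele != row$ref], 0),
    config = config, n_tested = 1L
  )
}

assemble_calls <- function(track, background, lesion_alt_vaf, control_alt_vaf,
                           control_nonref_max, config, n_tested) {
  p <- .noise_pvalue(track$d, background$mu, background$sigma)
  p_eff <- if (config$bonferroni) pmin(1, p * n_tested) else p
  tibble(
    region_id = track$region_id,
    pos = track$pos,
    ref = track$ref,
    alt = track$alt,
    d = track$d,
    mu = background$mu,
    sigma = background$sigma,
    n_window = background$n_window,
    p_value = p,
    lesion_vaf = lesion_alt_vaf,
    control_vaf = control_alt_vaf,
    p_pass = p_eff < config$alpha,
    d_pass = track$d > config$d_min,
    control_pass = control_nonref_max < config$control_vaf_max,
    verdict = .data$p_pass & .data$d_pass & .data$control_pass
  )
}

#' Call somatic SNVs across a target region
#'
#' Runs the full position-local noise test: VAF profiles for lesion and
#' control, the per-position difference track, the windowed background
#' model, and the three-way decision rule at every testable position (or a
#' supplied candidate subset). Deterministic for fixed input.
#'
#' @param lesion,control Allele-count tibbles for the lesion and matched
#'   control sample.
#' @param target One-row target tibble ([target_region()]); counts are
#'   restricted to `[start, end)`.
#' @param config A [caller_config()].
#' @param positions Optional integer vector of candidate positions to test
#'   (0-based); default tests every position with a defined background.
#' @return A `tds_calls` object: use [tidy()] for the per-position call
#'   table, [glance()] for a one-row summary, `autoplot()` to draw the
#'   difference track, and [write_calls()] to export VCF.
#' @export
call_region <- function(lesion, control, target, config = caller_config(),
                        positions = NULL) {
  stopifnot(nrow(target) == 1)
  lesion <- validate_allele_counts(lesion) %>%
    filter(.data$region_id == target$region_id)
  control <- validate_allele_counts(control) %>%
    filter(.data$region_id == target$region_id)
  if (nrow(lesion) == 0 || nrow(control) == 0) {
    abort(paste0("no counts overlap target region ", target$region_id))
  }
  lv <- compute_vaf(lesion)
  cv <- compute_vaf(control)
  track <- difference_track(lv, cv)
  bg <- fit_background(track, j = NULL, config = config)

  tb <- track %>%
    left_join(bg, by = c("region_id", "pos")) %>%
    filter(.data$defined, !is.na(.data$sigma), !is.na(.data$alt))
  if (!is.null(positions)) {
    tb <- tb %>% filter(.data$pos %in% positions)
  }
  ctrl_stats <- cv %>%
    filter(.data$allele != .data$ref) %>%
    group_by(.data$pos) %>%
    summarise(control_nonref_max = max(.data$vaf), .groups = "drop")
  les_alt <- lv %>% select(all_of(c("pos", "allele", "vaf")))
  ctl_alt <- cv %>% select(all_of(c("pos", "allele", "vaf")))
  tb <- tb %>%
    left_join(ctrl_stats, by = "pos") %>%
    left_join(les_alt, by = c("pos", "alt" = "allele")) %>%
    rename(lesion_vaf = "vaf") %>%
    left_join(ctl_alt, by = c("pos", "alt" = "allele")) %>%
    rename(control_vaf = "vaf")

  calls <- assemble_calls(
    track = tb,
    background = tb,
    lesion_alt_vaf = tb$lesion_vaf,
    control_alt_vaf = tb$control_vaf,
    control_nonref_max = tb$control_nonref_max,
    config = config, n_tested = nrow(tb)
  ) %>%
    mutate(chrom = target$chrom, .before = 1)

  structure(
    list(
      calls = calls, target = target, config = config,
      track = track, background = bg,
      sample_id = unique(lesion$sample_id)[1],
      control_id = unique(control$sample_id)[1]
    ),
    class = "tds_calls"
  )
}

#' @export
print.tds_calls <- function(x, ...) {
  cat(
    "<tds_calls> region ", x$target$region_id, " (", x$target$chrom, ":",
    x$target$start, "-", x$target$end, ")\n",
    "  sample ", x$sample_id, " vs control ", x$control_id, "\n",
    "  ", nrow(x$calls), " tested positions, ",
    sum(x$calls$verdict), " somatic calls\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname call_region
#' @param x A `tds_calls` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tds_calls <- function(x, ...) {
  x$calls
}

#' @rdname call_region
#' @exportS3Method generics::glance
glance.tds_calls <- function(x, ...) {
  tibble(
    region_id = x$target$region_id,
    n_positions = nrow(x$track),
    n_tested = nrow(x$calls),
    n_calls = sum(x$calls$verdict),
    alpha = x$config$alpha,
    d_min = x$config$d_min,
    control_vaf_max = x$config$control_vaf_max,
    median_background_mu = stats::median(x$background$mu, na.rm = TRUE)
  )
}

#' Plot the per-position difference track of a region call
#'
#' Draws `d_i` along the amplicon with the fitted local background mean and
#' highlights positions passing the full decision rule.
#'
#' @param object A `tds_calls` object from [call_region()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tds_calls <- function(object, ...) {
  df <- object$track %>%
    left_join(object$background, by = c("region_id", "pos"))
  hits <- object$calls %>% filter(.data$verdict)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$d), colour = "grey30", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu),
      colour = "steelblue", linetype = 2, na.rm = TRUE
    ) +
    ggplot2::geom_point(
      data = hits, ggplot2::aes(y = .data$d),
      colour = "firebrick", size = 2
    ) +
    ggplot2::labs(
      x = "position (0-based)", y = "VAF difference d",
      title = paste0(
        object$target$region_id, ": ", object$sample_id,
        " vs ", object$control_id
      ),
      subtitle = "dashed line: windowed background mean; points: somatic calls"
    ) +
    ggplot2::theme_minimal()
}
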