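#' Write somatic calls to a minimal VCF 4.2 file
#'
#' Emits the fixed VCF columns plus INFO keys `DJ` (VAF difference), `MU`
#' and `SIGMA` (windowed background model), `PVAL` (one-sided normal tail
#' probability), `VAF_LESION` and `VAF_CONTROL`. `FILTER` is `PASS` for
#' verdict-true calls, otherwise the semicolon-joined names of the failed
#' rules (`p_value`, `d_min`, `control_vaf`). Positions are converted from
#' the internal 0-based convention to VCF's 1-based one.
#'
#' @param calls A `tds_calls` object or its [tidy()] call tibble (must
#'   carry `chrom`).
#' @param path Output path.
#' @param which Which rows to write: `"verdict"` (default) writes only
#'   verdict-true calls, `"all"` writes every tested position.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, which = c("verdict", "all")) {
  which <- match.arg(which)
  if (inherits(calls, "tds_calls")) calls <- tidy(calls)
  if (which == "verdict") calls <- calls %>% filter(.data$verdict)
  calls <- calls %>% filter(.data$alt != .data$ref)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=adenoclone",
    "##INFO=<ID=DJ,Number=1,Type=Float,Description=\"Max absolute lesion-control VAF difference\">",
    "##INFO=<ID=MU,Number=1,Type=Float,Description=\"Windowed background mean of the difference track\">",
    "##INFO=<ID=SIGMA,Number=1,Type=Float,Description=\"Windowed background SD of the difference track\">",
    "##INFO=<ID=PVAL,Number=1,Type=Float,Description=\"Upper-tail normal probability P(X > DJ)\">",
    "##INFO=<ID=VAF_LESION,Number=1,Type=Float,Description=\"Alt allele VAF in the lesion sample\">",
    "##INFO=<ID=VAF_CONTROL,Number=1,Type=Float,Description=\"Alt allele VAF in the control sample\">",
    "##FILTER=<ID=p_value,Description=\"Background tail probability >= alpha\">",
    "##FILTER=<ID=d_min,Description=\"VAF difference below minimum\">",
    "##FILTER=<ID=control_vaf,Description=\"Non-reference allele too frequent in control\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  fmt <- function(x) formatC(x, digits = 6, format = "g")
  lines <- character(0)
  if (nrow(calls) > 0) {
    filt <- purrr::pmap_chr(
      calls %>% select(all_of(c("p_pass", "d_pass", "control_pass"))),
      function(p_pass, d_pass, control_pass) {
        failed <- c("p_value", "d_min", "control_vaf")[!c(p_pass, d_pass, control_pass)]
        if (length(failed) == 0) "PASS" else paste(failed, collapse = ";")
      }
    )
    info <- paste0(
      "DJ=", fmt(calls$d), ";MU=", fmt(calls$mu), ";SIGMA=", fmt(calls$sigma),
      ";PVAL=", fmt(calls$p_value), ";VAF_LESION=", fmt(calls$lesion_vaf),
      ";VAF_CONTROL=", fmt(calls$control_vaf)
    )
    lines <- paste(
      calls$chrom, calls$pos + 1L, ".", calls$ref, calls$alt, ".", filt, info,
      sep = "\t"
    )
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot open ", path, " for writing: ", conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

#' Read back a VCF written by [write_calls()]
#'
#' Minimal reader for round-tripping the caller's own output; not a general
#' VCF parser.
#'
#' @param path Path to a VCF written by [write_calls()].
#' @return A tibble with `chrom`, `pos` (0-based again), `ref`, `alt`,
#'   `filter`, and the numeric INFO fields `d`, `mu`, `sigma`, `p_value`,
#'   `lesion_vaf`, `control_vaf`.
#' @export
read_calls <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), filter = character(), d = double(), mu = double(),
      sigma = double(), p_value = double(), lesion_vaf = double(),
      control_vaf = double()
    ))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info_val <- function(info, key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    as.numeric(m)
  }
  tibble(
    chrom = f[, 1], pos = as.integer(f[, 2]) - 1L, ref = f[, 4], alt = f[, 5],
    filter = f[, 7],
    d = info_val(f[, 8], "DJ"), mu = info_val(f[, 8], "MU"),
    sigma = info_val(f[, 8], "SIGMA"), p_value = info_val(f[, 8], "PVAL"),
    lesion_vaf = info_val(f[, 8], "VAF_LESION"),
    control_vaf = info_val(f[, 8], "VAF_CONTROL")
  )
}
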