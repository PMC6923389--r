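#' Read amplicon target regions from a BED file
#'
#' Targets are the ~250 bp PCR amplicons that deep sequencing interrogates.
#' Coordinates follow the BED convention (0-based, half-open) and are kept
#' that way internally; only VCF output converts to 1-based.
#'
#' @param path Path to a BED file with at least three columns
#'   (chrom, start, end); a fourth column, when present, supplies the
#'   region identifier. Regions without a name are labelled
#'   `region_<chrom>_<start>`.
#' @param max_length Maximum permitted region length in bp. Amplicons are
#'   short by construction; the default guards against malformed rows.
#'
#' @return A tibble with columns `region_id`, `chrom`, `start`, `end`
#'   (one row per BED row, input order preserved).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr12\t25245346\t25245596\tKRAS_G12", bed)
#' read_targets(bed)
#' @export
read_targets <- function(path, max_length = 10000) {
  if (!file.exists(path)) {
    abort(paste0("BED file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  if (!any(keep)) {
    return(tibble(
      region_id = character(), chrom = character(),
      start = integer(), end = integer()
    ))
  }
  # field-by-field so parse failures can name the offending line; BED rows
  # may freely mix 3 and 4+ columns
  rows <- purrr::map(which(keep), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || anyNA(suppressWarnings(as.integer(f[2:3])))) {
      abort(paste0("malformed BED row at line ", i, ": ", lines[[i]]))
    }
    tibble(
      region_id = if (length(f) >= 4) f[4] else NA_character_,
      chrom = f[1],
      start = as.integer(f[2]),
      end = as.integer(f[3])
    )
  })
  out <- bind_rows(rows) %>%
    mutate(region_id = if_else(
      is.na(.data$region_id) | .data$region_id == "",
      paste0("region_", .data$chrom, "_", .data$start),
      .data$region_id
    ))
  validate_targets(out, max_length = max_length)
  out
}

validate_targets <- function(targets, max_length = 10000) {
  bad <- targets$end <= targets$start
  if (any(bad)) {
    abort(paste0(
      "target region with end <= start: ",
      paste(targets$region_id[bad], collapse = ", ")
    ))
  }
  long <- (targets$end - targets$start) > max_length
  if (any(long)) {
    abort(paste0(
      "target region longer than ", max_length, " bp: ",
      paste(targets$region_id[long], collapse = ", ")
    ))
  }
  invisible(targets)
}

#' Construct a target-region tibble directly
#'
#' Convenience constructor used by the simulators and in tests; applies the
#' same validation as [read_targets()].
#'
#' @param region_id Region identifier.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @return A one-row (or vectorised) target tibble.
#' @export
target_region <- function(region_id, chrom, start, end) {
  out <- tibble(
    region_id = as.character(region_id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end)
  )
  validate_targets(out)
  out
}
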