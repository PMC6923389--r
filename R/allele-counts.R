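COUNT_COLS <- as.vector(t(outer(c("A", "C", "G", "T"), c("fwd", "rev"), paste, sep = "_")))

#' Read a per-position allele-count table
#'
#' The allele-count table is the pipeline's pileup representation: one row
#' per target position with strand-split read counts for each nucleotide.
#' Depth at a position is the sum over the eight count columns; N bases and
#' deletions are never counted.
#'
#' @param path Path to a TSV with columns `sample_id`, `region_id`, `pos`
#'   (0-based), `ref`, and `A_fwd`, `A_rev`, `C_fwd`, `C_rev`, `G_fwd`,
#'   `G_rev`, `T_fwd`, `T_rev`.
#' @return A validated tibble with the columns above plus `depth`.
#' @seealso [write_allele_counts()], [compute_vaf()]
#' @export
read_allele_counts <- function(path) {
  counts <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      region_id = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_allele_counts(counts)
}

#' Validate (and finalise) an allele-count tibble
#'
#' Checks the schema, non-negativity and position uniqueness, and computes
#' the `depth` column. Called by every reader and simulator so that all
#' downstream code can rely on the invariants.
#'
#' @param counts A tibble in the [read_allele_counts()] schema.
#' @return The tibble with `depth` added, positions sorted within region.
#' @export
validate_allele_counts <- function(counts) {
  need <- c("sample_id", "region_id", "pos", "ref", COUNT_COLS)
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    abort(paste0("allele-count table missing column(s): ", paste(miss, collapse = ", ")))
  }
  cnt <- as.matrix(counts[COUNT_COLS])
  if (anyNA(cnt) || any(cnt < 0)) {
    abort("allele counts must be non-negative and non-missing")
  }
  if (any(cnt != round(cnt))) {
    abort("allele counts must be integers")
  }
  dup <- counts %>%
    dplyr::count(.data$sample_id, .data$region_id, .data$pos) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "duplicated position(s) in allele-count table: ",
      paste(utils::head(paste0(dup$region_id, ":", dup$pos), 5), collapse = ", ")
    ))
  }
  if (!all(counts$ref %in% ALLELES)) {
    abort("ref must be one of A, C, G, T")
  }
  counts %>%
    mutate(depth = rowSums(cnt)) %>%
    arrange(.data$sample_id, .data$region_id, .data$pos)
}

#' Write an allele-count table to TSV
#'
#' @param counts Allele-count tibble (see [read_allele_counts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  counts %>%
    select(all_of(c("sample_id", "region_id", "pos", "ref", COUNT_COLS))) %>%
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Compute per-position, per-allele variant allele fractions
#'
#' VAF pools the two strands: `vaf(y, i) = (fwd + rev count of y) / depth(i)`.
#' Zero-depth positions are retained but flagged: their `vaf` is `NA` and
#' they are excluded from all downstream statistics.
#'
#' @param counts Allele-count tibble.
#' @return A long tibble with one row per position and allele:
#'   `sample_id`, `region_id`, `pos`, `ref`, `allele`, `count`, `depth`,
#'   `vaf`, `defined` (logical; `FALSE` where depth is zero).
#' @examples
#' counts <- tibble::tibble(
#'   sample_id = "s1", region_id = "r", pos = 0L, ref = "A",
#'   A_fwd = 45, A_rev = 45, C_fwd = 0, C_rev = 0,
#'   G_fwd = 5, G_rev = 5, T_fwd = 0, T_rev = 0
#' )
#' compute_vaf(counts) # vaf(G) = 0.10
#' @export
compute_vaf <- function(counts) {
  counts <- validate_allele_counts(counts)
  long <- counts %>%
    tidyr::pivot_longer(
      cols = all_of(COUNT_COLS),
      names_to = c("allele", "strand"), names_sep = "_",
      values_to = "count"
    ) %>%
    group_by(.data$sample_id, .data$region_id, .data$pos, .data$ref,
      .data$depth, .data$allele
    ) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(
      defined = .data$depth > 0,
      vaf = if_else(.data$defined, .data$count / .data$depth, NA_real_)
    ) %>%
    select(all_of(c(
      "sample_id", "region_id", "pos", "ref", "allele",
      "count", "depth", "vaf", "defined"
    ))) %>%
    arrange(.data$sample_id, .data$region_id, .data$pos, .data$allele)
  long
}

#' Compute allele counts from a coordinate-sorted BAM file
#'
#' Thin wrapper around `Rsamtools::pileup()` restricted to the target
#' regions. Only A/C/G/T base calls passing the quality thresholds are
#' counted; deletions and reference skips are excluded, so `depth` matches
#' the package-wide definition.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param targets Target tibble from [read_targets()].
#' @param reference Path to the reference FASTA (used to fill the `ref`
#'   column), or a named character vector of reference sequences.
#' @param sample_id Sample identifier recorded in the output.
#' @param min_base_quality,min_mapping_quality Phred thresholds; read
#'   bases/alignments below them are ignored (defaults 20/20).
#' @return An allele-count tibble covering every position of every target
#'   (zero rows of coverage appear as all-zero counts).
#' @export
counts_from_alignments <- function(bam, targets, reference, sample_id,
                                   min_base_quality = 20,
                                   min_mapping_quality = 20) {
  for (pkg in c("Rsamtools", "GenomicRanges", "IRanges")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(paste0("package '", pkg, "' is required for counts_from_alignments()"))
    }
  }
  validate_targets(targets)
  if (!file.exists(paste0(bam, ".bai")) && !file.exists(sub("\\.bam$", ".bai", bam))) {
    abort(paste0("BAM index not found for ", bam))
  }
  refseq <- load_reference(reference)
  absent <- setdiff(unique(targets$chrom), names(refseq))
  if (length(absent) > 0) {
    abort(paste0("target chrom absent from reference: ", paste(absent, collapse = ", ")))
  }
  bf <- Rsamtools::BamFile(bam)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  absent <- setdiff(unique(targets$chrom), names(hdr))
  if (length(absent) > 0) {
    abort(paste0("target chrom absent from BAM header: ", paste(absent, collapse = ", ")))
  }
  which <- GenomicRanges::GRanges(
    targets$chrom,
    IRanges::IRanges(start = targets$start + 1L, end = targets$end)
  )
  pu <- Rsamtools::pileup(
    bf,
    scanBamParam = Rsamtools::ScanBamParam(which = which),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 10000000L,
      min_base_quality = as.integer(min_base_quality),
      min_mapq = as.integer(min_mapping_quality),
      min_nucleotide_depth = 0L, min_minor_allele_depth = 0L,
      distinguish_strands = TRUE, distinguish_nucleotides = TRUE,
      ignore_query_Ns = TRUE,
      include_deletions = FALSE, include_insertions = FALSE
    )
  )
  pu <- as_tibble(pu) %>%
    mutate(
      seqnames = as.character(.data$seqnames),
      nucleotide = as.character(.data$nucleotide),
      strand = as.character(.data$strand)
    ) %>%
    filter(.data$nucleotide %in% ALLELES)

  # scaffold of every target position, then join observed counts onto it
  per_target <- purrr::pmap(targets, function(region_id, chrom, start, end, ...) {
    pos <- seq.int(start, end - 1L)
    scaffold <- tibble(
      sample_id = sample_id, region_id = region_id, pos = pos,
      ref = strsplit(substr(refseq[[chrom]], start + 1L, end), "")[[1]]
    )
    obs <- pu %>%
      filter(.data$seqnames == chrom, .data$pos >= start + 1L, .data$pos <= end) %>%
      mutate(
        pos = .data$pos - 1L,
        col = paste0(.data$nucleotide, if_else(.data$strand == "+", "_fwd", "_rev"))
      ) %>%
      select(all_of(c("pos", "col", "count"))) %>%
      tidyr::pivot_wider(names_from = "col", values_from = "count", values_fill = 0)
    out <- left_join(scaffold, obs, by = "pos")
    for (cc in COUNT_COLS) {
      if (!cc %in% names(out)) out[[cc]] <- 0
      out[[cc]][is.na(out[[cc]])] <- 0
    }
    out %>% select(all_of(c("sample_id", "region_id", "pos", "ref", COUNT_COLS)))
  })
  validate_allele_counts(bind_rows(per_target))
}

load_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("package 'Biostrings' is required to read a reference FASTA")
    }
    seqs <- Biostrings::readDNAStringSet(reference)
    out <- as.character(seqs)
    names(out) <- sub("\\s.*$", "", names(seqs))
    return(out)
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(reference)
  }
  abort("reference must be a FASTA path or a named character vector of sequences")
}
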