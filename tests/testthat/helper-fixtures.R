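library(tibble)
library(dplyr)

# build an allele-count tibble from a strand-pooled count matrix
# (counts: positions x 4, columns A/C/G/T); strand split deterministically
toy_counts <- function(counts, ref, start = 0L, sample_id = "s",
                       region_id = "r") {
  counts <- as.matrix(counts)
  colnames(counts) <- c("A", "C", "G", "T")
  fwd <- floor(counts / 2)
  rev <- counts - fwd
  out <- tibble(
    sample_id = sample_id, region_id = region_id,
    pos = start + seq_len(nrow(counts)) - 1L, ref = ref
  )
  for (al in c("A", "C", "G", "T")) {
    out[[paste0(al, "_fwd")]] <- fwd[, al]
    out[[paste0(al, "_rev")]] <- rev[, al]
  }
  validate_allele_counts(out)
}

# random valid allele-count table for property tests
random_counts <- function(n_pos, max_count = 200, sample_id = "s",
                          region_id = "r", start = 0L) {
  counts <- matrix(rpois(n_pos * 4, lambda = runif(1, 5, max_count / 4)),
    nrow = n_pos
  )
  toy_counts(counts,
    ref = sample(c("A", "C", "G", "T"), n_pos, replace = TRUE),
    start = start, sample_id = sample_id, region_id = region_id
  )
}

# matched lesion/control pair over a shared noise floor, optional spikes
# (an all-A reference keeps spike alleles C/G/T always valid)
sim_pair <- function(target, depth = 10000, profile = error_profile(),
                     spikes = NULL, seed = 1,
                     ref = rep("A", target$end - target$start)) {
  lesion <- simulate_amplicon(target, depth,
    profile = profile, spikes = spikes,
    seed = seed, sample_id = "lesion", ref = ref
  )
  control <- simulate_amplicon(target, depth,
    profile = profile, seed = seed + 1000003L, sample_id = "control",
    ref = attr(lesion, "ref"), rates = attr(lesion, "rates")
  )
  list(lesion = lesion, control = control)
}

# a six-region adenomyosis patient with trunk/restricted/private/cross
# clonal structure used by the recovery experiments
example_patient_design <- function() {
  meta <- tibble(
    sample_id = c(paste0("A", 1:6), "EN", "B"),
    patient_id = "P1",
    tissue_class = c(rep("adenomyosis", 6), "endometriosis", "blood"),
    region_label = c(as.character(1:6), "EN", "B")
  )
  mutations <- tibble(
    clone_id = c("trunk", "restricted", "private", "cross"),
    pos = c(20L, 60L, 100L, 140L),
    alt = c("C", "G", "T", "C"),
    gene = c("ZNF672", "C1QTNF", "MSS51", "KRAS")
  )
  placement <- bind_rows(
    tibble(clone_id = "trunk", sample_id = paste0("A", 1:6), cell_fraction = 0.2),
    tibble(clone_id = "restricted", sample_id = paste0("A", 1:3), cell_fraction = 0.12),
    tibble(clone_id = "private", sample_id = "A4", cell_fraction = 0.1),
    tibble(clone_id = "cross", sample_id = c("A2", "EN"), cell_fraction = 0.16)
  )
  list(meta = meta, mutations = mutations, placement = placement)
}

# run the caller on every lesion sample of a simulated patient and return
# the long call table build_matrix() consumes
patient_calls <- function(sim, config = caller_config()) {
  blood <- sim$meta$sample_id[sim$meta$tissue_class == "blood"]
  lesions <- setdiff(sim$meta$sample_id, blood)
  purrr::map_dfr(lesions, function(sid) {
    res <- call_region(sim$counts[[sid]], sim$counts[[blood]], sim$target,
      config = config
    )
    tidy(res) %>%
      filter(.data$verdict) %>%
      mutate(sample_id = sid, vaf = .data$lesion_vaf, present = TRUE) %>%
      select(sample_id, chrom, pos, ref, alt, vaf, present)
  })
}

# construct a non-negative panel whose mean and population SD are exactly
# the target (two-point construction: sub-percent noise panels are skewed,
# with SD often exceeding the mean, so a symmetric construction would go
# negative)
standardized_panel <- function(n, m, s, k = max(2L, n %/% 5L)) {
  z <- c(rep(0, n - k), rep(1, k))
  mz <- mean(z)
  sz <- sqrt(mean((z - mz)^2))
  b <- s / sz
  a <- m - b * mz
  stopifnot(a >= 0)
  a + b * z
}

# minimal SAM + FASTA pair for alignment-counting tests; all reads are
# full-length matches (CIGAR <n>M) so the naive oracle stays trivial
write_toy_alignments <- function(dir, refseq, reads, chrom = "amp") {
  fa <- file.path(dir, "ref.fa")
  writeLines(c(paste0(">", chrom), refseq), fa)
  sam <- file.path(dir, "toy.sam")
  n <- nchar(refseq)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", chrom, "\tLN:", n)
  )
  body <- purrr::imap_chr(reads, function(r, i) {
    paste(
      paste0("read", i), r$flag, chrom, r$pos1, r$mapq,
      paste0(nchar(r$seq), "M"), "*", 0, 0, r$seq,
      strrep(r$qual, nchar(r$seq)),
      sep = "\t"
    )
  })
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam,
    destination = file.path(dir, "toy"),
    overwrite = TRUE, indexDestination = TRUE
  )
  list(bam = bam, fasta = fa, chrom = chrom)
}
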