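simple_meta <- function(n_adeno = 6, endo = FALSE, ne = FALSE, lm = FALSE) {
  rows <- tibble(
    sample_id = paste0("A", seq_len(n_adeno)), patient_id = "P1",
    tissue_class = "adenomyosis", region_label = as.character(seq_len(n_adeno))
  )
  if (endo) {
    rows <- bind_rows(rows, tibble(
      sample_id = "EN", patient_id = "P1",
      tissue_class = "endometriosis", region_label = "EN"
    ))
  }
  if (ne) {
    rows <- bind_rows(rows, tibble(
      sample_id = "NE", patient_id = "P1",
      tissue_class = "normal_endometrium", region_label = "NE"
    ))
  }
  if (lm) {
    rows <- bind_rows(rows, tibble(
      sample_id = "LM", patient_id = "P1",
      tissue_class = "leiomyoma", region_label = "LM"
    ))
  }
  bind_rows(rows, tibble(
    sample_id = "B", patient_id = "P1",
    tissue_class = "blood", region_label = "B"
  ))
}

mut_call <- function(sample_id, pos, alt = "C", vaf = 0.05, gene = NA_character_) {
  tibble(
    sample_id = sample_id, chrom = "chr1", pos = pos, ref = "A", alt = alt,
    vaf = vaf, gene = gene
  )
}

test_that("the matrix is the union of mutations with zero-fill for absent calls", {
  meta <- simple_meta(2)
  calls <- bind_rows(mut_call("A1", 10L), mut_call("A2", 20L, alt = "G"))
  m <- build_matrix(calls, meta)
  wide <- matrix_wide(m)
  expect_equal(nrow(wide), 2)
  expect_equal(sort(colnames(wide)), sort(c("mutation_id", "gene", "A1", "A2", "B")))
  expect_equal(wide$A1[wide$mutation_id == "chr1:10:A>C"], 0.05)
  expect_equal(wide$A2[wide$mutation_id == "chr1:10:A>C"], 0)
  expect_equal(wide$A1[wide$mutation_id == "chr1:20:A>G"], 0)
})

test_that("sharing classes follow presence counts in the dominant tissue class", {
  meta <- simple_meta(6, endo = TRUE, ne = TRUE)
  calls <- bind_rows(
    mut_call(paste0("A", 1:6), 10L, gene = "ZNF672"), # all regions: trunk
    mut_call(paste0("A", 1:3), 20L, alt = "G"), # some regions
    mut_call("A3", 30L, alt = "T"), # one region
    mut_call(c("A2", "EN"), 40L, gene = "KRAS"), # adeno + endo
    mut_call(c("A1", "A2", "NE"), 50L, alt = "G") # also in NE
  )
  sh <- classify_sharing(build_matrix(calls, meta))
  cls <- setNames(sh$sharing_class, sh$mutation_id)
  expect_equal(unname(cls["chr1:10:A>C"]), "ubiquitous")
  expect_equal(unname(cls["chr1:20:A>G"]), "restricted")
  expect_equal(unname(cls["chr1:30:A>T"]), "private")
  expect_equal(unname(cls["chr1:40:A>C"]), "private") # one adenomyosis region
  expect_true(sh$cross_lesion_shared[sh$mutation_id == "chr1:40:A>C"])
  expect_true(sh$normal_shared[sh$mutation_id == "chr1:50:A>G"])
  expect_false(any(sh$cross_lesion_shared[sh$mutation_id != "chr1:40:A>C"]))
  # flags never contradict counts: a cross-lesion mutation sits in >= 2 samples
  flagged <- sh %>% filter(cross_lesion_shared)
  present_n <- tidy(build_matrix(calls, meta)) %>%
    filter(tissue_class != "blood", present) %>%
    dplyr::count(mutation_id)
  expect_true(all(present_n$n[present_n$mutation_id %in% flagged$mutation_id] >= 2))
})

test_that("sharing classification is invariant to sample column order", {
  meta <- simple_meta(4, endo = TRUE)
  calls <- bind_rows(
    mut_call(paste0("A", 1:4), 10L),
    mut_call(c("A2", "A3"), 20L, alt = "G"),
    mut_call("EN", 30L, alt = "T")
  )
  sh1 <- classify_sharing(build_matrix(calls, meta))
  perm <- meta[c(5, 3, 1, 6, 2, 4), ]
  sh2 <- classify_sharing(build_matrix(calls[sample(nrow(calls)), ], perm))
  expect_equal(
    sh1 %>% arrange(mutation_id),
    sh2 %>% arrange(mutation_id)
  )
})

test_that("unassayed cells are missing-flagged and excluded from sharing", {
  meta <- simple_meta(3)
  calls <- bind_rows(mut_call(c("A1", "A2"), 10L))
  assayed <- tidyr::expand_grid(
    sample_id = c("A1", "A2"), chrom = "chr1", pos = 10L
  ) # A3 never assayed at this site
  m <- build_matrix(calls, meta, assayed = assayed)
  td <- tidy(m)
  expect_true(is.na(td$vaf[td$sample_id == "A3"]))
  expect_false(td$assayed[td$sample_id == "A3"])
  # present in all *assayed* dominant-class samples -> ubiquitous
  sh <- classify_sharing(m)
  expect_equal(sh$sharing_class, "ubiquitous")
  expect_equal(sh$n_assayed, 2L)
})

test_that("mutual exclusivity is the Jaccard overlap of presence sets", {
  meta <- simple_meta(3, lm = TRUE)
  disjoint <- bind_rows(
    mut_call(c("A1", "A2"), 10L),
    mut_call("LM", 20L, alt = "G", gene = "MED12")
  )
  m <- build_matrix(disjoint, meta)
  me <- mutual_exclusivity(m, "adenomyosis", "leiomyoma")
  expect_equal(me$fraction_shared, 0)
  expect_equal(me$shared, character(0))

  identical_sets <- bind_rows(mut_call(c("A1", "LM"), 10L))
  me2 <- mutual_exclusivity(build_matrix(identical_sets, meta), "adenomyosis", "leiomyoma")
  expect_equal(me2$fraction_shared, 1)

  expect_error(mutual_exclusivity(m, "adenomyosis", "endometriosis"), "absent")
})

test_that("matrix construction rejects invalid designs", {
  meta <- simple_meta(2)
  calls <- mut_call("A1", 10L)
  expect_error(
    build_matrix(calls, meta %>% mutate(patient_id = c("P1", "P2", "P1"))),
    "single patient"
  )
  expect_error(
    build_matrix(mut_call("ghost", 10L), meta),
    "not in metadata"
  )
  expect_error(
    build_matrix(calls, meta[c(1, 3), ]),
    "at least 2 non-blood"
  )
  m <- build_matrix(calls, meta)
  m$mutations <- m$mutations[0, ]
  expect_error(classify_sharing(m), "empty")
  expect_error(autoplot(m), "empty")
})

test_that("a truth-fed matrix reproduces the generator's VAF table and trunk set", {
  design <- example_patient_design()
  sim <- simulate_patient(
    design$mutations, design$placement, design$meta,
    target = target_region("amp", "chr1", 0, 160), depth = 2000, seed = 42
  )
  truth_calls <- sim$truth$vaf %>%
    mutate(
      chrom = "chr1", ref = "A",
      vaf = true_vaf
    ) %>%
    select(sample_id, chrom, pos, ref, alt, gene, vaf, present)
  m <- build_matrix(truth_calls, design$meta)
  td <- tidy(m) %>% filter(sample_id != "B")
  joined <- td %>%
    left_join(
      sim$truth$vaf %>% mutate(mutation_id = paste0("chr1:", pos, ":A>", alt)),
      by = c("mutation_id", "sample_id")
    )
  expect_equal(joined$vaf, joined$true_vaf)
  sh <- classify_sharing(m) %>%
    left_join(
      sim$truth$sharing %>% mutate(mutation_id = paste0("chr1:", pos, ":A>", alt)),
      by = "mutation_id"
    )
  expect_equal(sh$sharing_class.x, sh$sharing_class.y)
  trunk <- sh$mutation_id[sh$sharing_class.x == "ubiquitous"]
  expect_equal(trunk, "chr1:20:A>C")
})

test_that("heatmaps render deterministically and refuse empty input", {
  meta <- simple_meta(3, endo = TRUE)
  calls <- bind_rows(
    mut_call(paste0("A", 1:3), 10L, gene = "KRAS"),
    mut_call("EN", 20L, alt = "G")
  )
  m <- build_matrix(calls, meta)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
  b1 <- ggplot2::ggplot_build(p)$data[[1]]
  b2 <- ggplot2::ggplot_build(autoplot(m))$data[[1]]
  expect_identical(b1, b2)
  path <- withr::local_tempfile(fileext = ".png")
  render_heatmap(m, path, width = 4, height = 3)
  expect_true(file.exists(path) && file.size(path) > 0)
})
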