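LESION_CLASSES <- c("adenomyosis", "endometriosis", "leiomyoma")
TISSUE_CLASSES <- c(
  LESION_CLASSES, "normal_endometrium", "normal_myometrium", "blood"
)

validate_meta <- function(meta) {
  need <- c("sample_id", "patient_id", "tissue_class", "region_label")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort(paste0("sample metadata missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(meta$tissue_class), TISSUE_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("unknown tissue_class: ", paste(bad, collapse = ", ")))
  }
  invisible(meta)
}

#' Build a multi-region mutation-by-sample VAF matrix
#'
#' Takes per-sample mutation calls for one patient and assembles the union
#' of mutations across samples into a mutations x samples matrix of VAFs
#' with presence booleans. A mutation absent from an assayed sample gets
#' VAF 0; samples in which a mutation was not assayed are missing-flagged
#' and excluded from sharing computations. Blood is carried as a germline
#' reference column but never participates in sharing.
#'
#' @param calls Long tibble with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `vaf` (fraction), optional `gene`, and optional logical
#'   `present` (e.g. the noise-caller verdict). When `present` is absent,
#'   presence falls back to `vaf > presence_threshold`.
#' @param meta Sample metadata tibble: `sample_id`, `patient_id`,
#'   `tissue_class` (one of adenomyosis, endometriosis, leiomyoma,
#'   normal_endometrium, normal_myometrium, blood), `region_label`.
#' @param presence_threshold Absolute VAF presence threshold used when no
#'   `present` column is supplied (default 0.01, i.e. 1%).
#' @param assayed Optional tibble `sample_id`, `chrom`, `pos` marking which
#'   positions each sample was assayed at; `NULL` (default) treats every
#'   sample as assayed for every mutation.
#' @return A `multiregion_matrix` object; see [classify_sharing()],
#'   [mutual_exclusivity()], `autoplot()`, [render_heatmap()], [tidy()].
#' @export
build_matrix <- function(calls, meta, presence_threshold = 0.01, assayed = NULL) {
  validate_meta(meta)
  if (length(unique(meta$patient_id)) != 1) {
    abort("build_matrix() expects samples from a single patient")
  }
  if (sum(meta$tissue_class != "blood") < 2) {
    abort("need at least 2 non-blood samples for a multi-region matrix")
  }
  unknown <- setdiff(unique(calls$sample_id), meta$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("calls from sample(s) not in metadata: ", paste(unknown, collapse = ", ")))
  }
  if (!"gene" %in% names(calls)) calls$gene <- NA_character_
  muts <- calls %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$gene) %>%
    arrange(.data$chrom, .data$pos, .data$alt) %>%
    mutate(mutation_id = paste0(.data$chrom, ":", .data$pos, ":", .data$ref, ">", .data$alt))
  grid <- tidyr::expand_grid(
    mutation_id = muts$mutation_id,
    sample_id = meta$sample_id
  ) %>%
    left_join(muts, by = "mutation_id")
  obs <- calls %>%
    mutate(mutation_id = paste0(.data$chrom, ":", .data$pos, ":", .data$ref, ">", .data$alt)) %>%
    select(any_of(c("mutation_id", "sample_id", "vaf", "present")))
  data <- grid %>%
    left_join(obs, by = c("mutation_id", "sample_id")) %>%
    mutate(vaf = if_else(is.na(.data$vaf), 0, .data$vaf))
  if ("present" %in% names(data)) {
    data <- data %>%
      mutate(present = if_else(is.na(.data$present), FALSE, .data$present))
  } else {
    data <- data %>% mutate(present = .data$vaf > presence_threshold)
  }
  data <- data %>% mutate(assayed = TRUE)
  if (!is.null(assayed)) {
    amap <- assayed %>%
      left_join(muts, by = c("chrom", "pos")) %>%
      filter(!is.na(.data$mutation_id)) %>%
      distinct(.data$sample_id, .data$mutation_id) %>%
      mutate(assayed = TRUE)
    data <- data %>%
      select(-"assayed") %>%
      left_join(amap, by = c("mutation_id", "sample_id")) %>%
      mutate(
        assayed = !is.na(.data$assayed),
        vaf = if_else(.data$assayed, .data$vaf, NA_real_),
        present = .data$assayed & .data$present
      )
  }
  data <- data %>% left_join(meta, by = "sample_id")
  orphan <- data %>%
    group_by(.data$mutation_id) %>%
    summarise(
      ok = any(.data$present[.data$tissue_class != "blood"]),
      .groups = "drop"
    ) %>%
    filter(!.data$ok)
  if (nrow(orphan) > 0) {
    warn(paste0(
      "mutation(s) present in no non-blood sample: ",
      paste(orphan$mutation_id, collapse = ", ")
    ))
  }
  structure(
    list(
      patient_id = meta$patient_id[1],
      mutations = muts, meta = meta, data = data,
      presence_threshold = presence_threshold
    ),
    class = "multiregion_matrix"
  )
}

#' @export
print.multiregion_matrix <- function(x, ...) {
  cat(
    "<multiregion_matrix> patient ", x$patient_id, ": ",
    nrow(x$mutations), " mutations x ", nrow(x$meta), " samples\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname build_matrix
#' @param x A `multiregion_matrix`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.multiregion_matrix <- function(x, ...) {
  x$data %>%
    select(all_of(c(
      "mutation_id", "gene", "sample_id", "tissue_class", "region_label",
      "vaf", "present", "assayed"
    )))
}

#' Export a multi-region matrix as a wide VAF table
#'
#' @param x A `multiregion_matrix`.
#' @return A tibble, one row per mutation, one VAF column per sample.
#' @export
matrix_wide <- function(x) {
  x$data %>%
    select(all_of(c("mutation_id", "gene", "sample_id", "vaf"))) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "vaf")
}

#' Classify mutation sharing across multi-region samples
#'
#' The count-based class is assigned from presence among the assayed
#' lesion samples of the patient's dominant lesion tissue class (the class
#' with most samples, typically adenomyosis): present in all of them (and
#' at least 2) is `ubiquitous` - the early-acquired, trunk-like pattern;
#' present in exactly one lesion sample is `private`; anything in between
#' is `restricted`. Two orthogonal flags sit on top: `cross_lesion_shared`
#' when the mutation is present in both an adenomyosis and an
#' endometriosis sample, and `normal_shared` when it is also present in
#' normal endometrium. Blood never counts.
#'
#' @param x A `multiregion_matrix` from [build_matrix()].
#' @return A tibble per mutation: `mutation_id`, `gene`, `n_present`
#'   (dominant-class presences), `n_assayed` (assayed dominant-class
#'   samples), `sharing_class`, `cross_lesion_shared`, `normal_shared`.
#' @export
classify_sharing <- function(x) {
  if (nrow(x$mutations) == 0) {
    abort("cannot classify sharing of an empty matrix")
  }
  lesion_meta <- x$meta %>% filter(.data$tissue_class %in% LESION_CLASSES)
  if (nrow(lesion_meta) == 0) {
    abort("no lesion samples in matrix")
  }
  dominant <- lesion_meta %>%
    dplyr::count(.data$tissue_class) %>%
    arrange(desc(.data$n), match(.data$tissue_class, LESION_CLASSES)) %>%
    pull(.data$tissue_class) %>%
    first()

  x$data %>%
    filter(.data$tissue_class != "blood") %>%
    group_by(.data$mutation_id, .data$gene) %>%
    summarise(
      n_present = sum(.data$present[.data$tissue_class == dominant]),
      n_assayed = sum(.data$assayed[.data$tissue_class == dominant]),
      n_lesion_present = sum(.data$present[.data$tissue_class %in% LESION_CLASSES]),
      cross_lesion_shared = any(.data$present[.data$tissue_class == "adenomyosis"]) &&
        any(.data$present[.data$tissue_class == "endometriosis"]),
      normal_shared = any(.data$present[.data$tissue_class == "normal_endometrium"]),
      .groups = "drop"
    ) %>%
    mutate(
      basis = if_else(.data$n_present > 0, .data$n_present, .data$n_lesion_present),
      sharing_class = case_when(
        .data$n_present >= 2 & .data$n_present == .data$n_assayed ~ "ubiquitous",
        .data$basis == 1 ~ "private",
        .data$basis > 1 ~ "restricted",
        TRUE ~ "private"
      )
    ) %>%
    select(all_of(c(
      "mutation_id", "gene", "n_present", "n_assayed",
      "sharing_class", "cross_lesion_shared", "normal_shared"
    )))
}

#' Fraction of mutations shared between two tissue classes
#'
#' Computes `|shared| / |union|` of the mutations present in each class; a
#' value of 0 is full mutual exclusivity (the pattern seen between
#' adenomyosis and co-existing leiomyoma).
#'
#' @param x A `multiregion_matrix`.
#' @param class_a,class_b Tissue classes to compare.
#' @return A list: `fraction_shared`, `shared` (mutation ids), `union_n`.
#' @export
mutual_exclusivity <- function(x, class_a, class_b) {
  present_in <- function(cl) {
    if (!cl %in% x$meta$tissue_class) {
      abort(paste0("tissue class absent from matrix: ", cl))
    }
    x$data %>%
      filter(.data$tissue_class == cl, .data$present) %>%
      pull(.data$mutation_id) %>%
      unique()
  }
  a <- present_in(class_a)
  b <- present_in(class_b)
  u <- union(a, b)
  s <- intersect(a, b)
  list(
    fraction_shared = if (length(u) > 0) length(s) / length(u) else NA_real_,
    shared = sort(s),
    union_n = length(u)
  )
}

#' Heatmap of a multi-region VAF matrix
#'
#' Mutations x samples tile plot with a VAF colour scale and tissue-class
#' column annotation, mirroring the standard multi-region display. Layout
#' is deterministic: mutations ordered by coordinate, samples by tissue
#' class then region label.
#'
#' @param object A `multiregion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.multiregion_matrix <- function(object, ...) {
  if (nrow(object$mutations) == 0) {
    abort("cannot plot an empty matrix")
  }
  df <- object$data %>%
    mutate(
      mutation_id = factor(.data$mutation_id, levels = rev(object$mutations$mutation_id)),
      sample_id = factor(
        .data$sample_id,
        levels = object$meta %>%
          arrange(match(.data$tissue_class, TISSUE_CLASSES), .data$region_label) %>%
          pull(.data$sample_id)
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$mutation_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$vaf), colour = "grey80") +
    ggplot2::scale_fill_gradient(
      low = "white", high = "firebrick",
      na.value = "grey60", name = "VAF"
    ) +
    ggplot2::facet_grid(. ~ tissue_class, scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = paste0("Patient ", object$patient_id, ": multi-region VAF matrix")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Render a multi-region heatmap to file
#'
#' @param x A `multiregion_matrix`.
#' @param path Output path; format from the extension (png, pdf, svg).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(x, path, width = 7, height = 5) {
  p <- autoplot(x)
  ggplot2::ggsave(path, plot = p, width = width, height = height)
  invisible(path)
}
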