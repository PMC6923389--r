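vaf_pair_from_matrices <- function(lesion_vafs, control_vafs, ref, depth = 10000) {
  # turn VAF matrices (positions x 4 alleles A/C/G/T) into count tables
  to_counts <- function(vafs, id) {
    toy_counts(round(vafs * depth), ref = ref, sample_id = id)
  }
  list(
    lesion = compute_vaf(to_counts(lesion_vafs, "L")),
    control = compute_vaf(to_counts(control_vafs, "N"))
  )
}

test_that("difference track is the per-allele max absolute VAF difference", {
  ref <- c("A", "A", "A")
  les <- rbind(c(0.90, 0.10, 0, 0), c(0.95, 0.03, 0.02, 0), c(1, 0, 0, 0))
  ctl <- rbind(c(0.99, 0.01, 0, 0), c(0.95, 0.03, 0.02, 0), c(1, 0, 0, 0))
  pair <- vaf_pair_from_matrices(les, ctl, ref)
  tr <- difference_track(pair$lesion, pair$control)
  expect_equal(tr$d, c(0.09, 0, 0))
  expect_equal(tr$allele[1], "C")
  # identical profiles give an all-zero track
  same <- difference_track(pair$control, pair$control)
  expect_true(all(same$d == 0))
})

test_that("difference track matches a brute-force per-allele oracle and is symmetric", {
  withr::local_seed(42)
  for (rep in 1:5) {
    a <- random_counts(25, sample_id = "L")
    b <- random_counts(25, sample_id = "N")
    b$ref <- a$ref
    va <- compute_vaf(a)
    vb <- compute_vaf(b)
    tr <- difference_track(va, vb)

    # oracle: loop positions and alleles explicitly
    for (p in unique(tr$pos)) {
      diffs <- sapply(c("A", "C", "G", "T"), function(al) {
        abs(
          va$vaf[va$pos == p & va$allele == al] -
            vb$vaf[vb$pos == p & vb$allele == al]
        )
      })
      expect_equal(tr$d[tr$pos == p], max(diffs))
    }
    # |a - n| is symmetric under swapping the samples
    rev <- difference_track(vb, va)
    expect_equal(tr$d, rev$d)
  }
})

test_that("windowed background mean and SD follow the direct formulas", {
  # four positions; testing j = pos 3 with the window {0.001, 0.002, 0.003}
  tr <- tibble(
    region_id = "r", pos = 0:3, ref = "A",
    d = c(0.001, 0.002, 0.003, 0.01),
    allele = "C", alt = "C", defined = TRUE,
    lesion_depth = 1e4, control_depth = 1e4
  )
  bg <- fit_background(tr, j = 3, config = caller_config(K = 10))
  expect_equal(bg$mu, 0.002)
  expect_equal(bg$sigma, sqrt(2 / 3) * 0.001, tolerance = 1e-12)
  expect_equal(bg$n_window, 3L)

  # ddof = 1 switches to the sample SD
  bg1 <- fit_background(tr, j = 3, config = caller_config(K = 10, sd_ddof = 1))
  expect_equal(bg1$sigma, sd(c(0.001, 0.002, 0.003)))

  # constant window collapses to sigma = 0
  trc <- tr %>% mutate(d = c(0.002, 0.002, 0.002, 0.05))
  bgc <- fit_background(trc, j = 3)
  expect_equal(bgc$mu, 0.002)
  expect_equal(bgc$sigma, 0)
})

test_that("background windows truncate at region edges and exclude j", {
  withr::local_seed(7)
  n <- 60
  tr <- tibble(
    region_id = "r", pos = seq_len(n) - 1L, ref = "A",
    d = abs(rnorm(n, 1e-3, 3e-4)), allele = "C", alt = "C",
    defined = TRUE, lesion_depth = 1e4, control_depth = 1e4
  )
  K <- 10
  bg <- fit_background(tr, config = caller_config(K = K))
  # naive recomputation position by position
  for (j in c(0, 1, 5, 29, 58, 59)) {
    w <- setdiff(max(0, j - K):min(n - 1, j + K), j)
    dw <- tr$d[tr$pos %in% w]
    expect_equal(bg$mu[bg$pos == j], mean(dw), tolerance = 1e-12)
    expect_equal(bg$sigma[bg$pos == j], sqrt(mean((dw - mean(dw))^2)),
      tolerance = 1e-10
    )
    expect_equal(bg$n_window[bg$pos == j], length(w))
  }
  expect_lt(bg$n_window[bg$pos == 0], 2 * K)

  # degenerate window errors when requested explicitly
  tiny <- tr[1:2, ] %>% mutate(d = c(1e-3, NA), defined = c(TRUE, FALSE))
  expect_error(fit_background(tiny, j = 0), "degenerate")
})

test_that("background model matches naive recomputation on random tracks", {
  withr::local_seed(99)
  for (rep in 1:4) {
    n <- sample(30:80, 1)
    K <- sample(c(3, 7, 15, n), 1)
    d <- abs(rnorm(n, 8e-4, 4e-4))
    miss <- sample(n, floor(n / 10))
    d[miss] <- NA
    tr <- tibble(
      region_id = "r", pos = seq_len(n) - 1L, ref = "A", d = d,
      allele = "C", alt = "C", defined = !is.na(d),
      lesion_depth = 1e4, control_depth = 1e4
    )
    bg <- fit_background(tr, config = caller_config(K = K))
    for (j in tr$pos) {
      w <- setdiff(max(0, j - K):min(n - 1, j + K), j)
      dw <- d[w + 1]
      dw <- dw[!is.na(dw)]
      if (length(dw) >= 2) {
        expect_equal(bg$mu[bg$pos == j], mean(dw), tolerance = 1e-12)
        expect_equal(bg$sigma[bg$pos == j],
          sqrt(mean((dw - mean(dw))^2)),
          tolerance = 1e-9
        )
      } else {
        expect_true(is.na(bg$sigma[bg$pos == j]))
      }
    }
  }
})

test_that("the position test applies the normal tail and all three flags", {
  ref <- rep("A", 5)
  les <- matrix(rep(c(0.999, 0.001, 0, 0), each = 5), 5)
  ctl <- les
  # position 2 carries d = 0.002 over a flat 0.001 background in C
  les[3, 2] <- 0.003
  les[3, 1] <- 0.997
  pair <- vaf_pair_from_matrices(les, ctl, ref, depth = 1e5)
  tr <- difference_track(pair$lesion, pair$control)
  # hand-crafted background: mu 0.001, sigma 0.0005
  bg <- tibble(region_id = "r", pos = 2L, mu = 0.001, sigma = 5e-4, n_window = 4L)
  call <- test_position(tr, bg, pair$lesion, pair$control, j = 2)
  # z = (0.002 - 0.001) / 0.0005 = 2
  expect_equal(call$p_value, pnorm(2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(call$p_value, 5), 0.02275)
  expect_true(call$p_pass && call$d_pass && call$control_pass && call$verdict)

  # below d_min the verdict fails even with a tiny p
  call2 <- test_position(tr, bg, pair$lesion, pair$control,
    j = 2,
    config = caller_config(d_min = 0.005)
  )
  expect_false(call2$d_pass)
  expect_false(call2$verdict)
  expect_true(call2$p_pass)

  # a contaminated control kills control_pass
  ctl2 <- ctl
  ctl2[3, 2] <- 0.02
  ctl2[3, 1] <- 0.98
  pair2 <- vaf_pair_from_matrices(les, ctl2, ref, depth = 1e5)
  tr2 <- difference_track(pair2$lesion, pair2$control)
  call3 <- test_position(tr2, bg, pair2$lesion, pair2$control, j = 2)
  expect_false(call3$control_pass)
  expect_false(call3$verdict)

  # sigma = 0 point-mass rule
  bg0 <- bg %>% mutate(sigma = 0)
  expect_equal(test_position(tr, bg0, pair$lesion, pair$control, j = 2)$p_value, 0)
  bg0$mu <- 0.01
  expect_equal(test_position(tr, bg0, pair$lesion, pair$control, j = 2)$p_value, 1)
})

test_that("p-values are monotone non-increasing in d", {
  d <- seq(0, 0.01, length.out = 50)
  p <- adenoclone:::.noise_pvalue(d, mu = 1e-3, sigma = 4e-4)
  expect_true(all(diff(p) <= 0))
})

test_that("call_region is deterministic and its verdicts shrink as thresholds tighten", {
  tg <- target_region("amp", "chr1", 0, 150)
  pair <- sim_pair(tg,
    spikes = tibble(pos = c(40L, 90L), alt = c("C", "G"), vaf = c(0.03, 0.004)),
    seed = 77
  )
  res <- call_region(pair$lesion, pair$control, tg)
  res2 <- call_region(pair$lesion, pair$control, tg)
  expect_identical(tidy(res), tidy(res2))

  base <- tidy(res)$verdict
  strict_alpha <- tidy(call_region(pair$lesion, pair$control, tg,
    config = caller_config(alpha = 0.001)
  ))$verdict
  strict_dmin <- tidy(call_region(pair$lesion, pair$control, tg,
    config = caller_config(d_min = 0.01)
  ))$verdict
  strict_ctrl <- tidy(call_region(pair$lesion, pair$control, tg,
    config = caller_config(control_vaf_max = 1e-4)
  ))$verdict
  expect_true(all(strict_alpha <= base))
  expect_true(all(strict_dmin <= base))
  expect_true(all(strict_ctrl <= base))

  # candidate-restricted mode tests only the requested positions
  cand <- call_region(pair$lesion, pair$control, tg, positions = c(40L, 90L))
  expect_equal(sort(tidy(cand)$pos), c(40L, 90L))
})

test_that("type-I error is near nominal when the difference track is Gaussian", {
  # the tail test assumes the d-track is normal; generate it that way
  # (noise floor mean >> its spread, so folding at zero is negligible)
  withr::local_seed(314)
  n <- 250
  hits <- 0
  total <- 0
  for (r in 1:40) {
    tr <- tibble(
      region_id = "r", pos = seq_len(n) - 1L, ref = "A",
      d = abs(rnorm(n, 8e-4, 2e-4)), allele = "C", alt = "C",
      defined = TRUE, lesion_depth = 1e4, control_depth = 1e4
    )
    bg <- fit_background(tr)
    p <- adenoclone:::.noise_pvalue(tr$d, bg$mu, bg$sigma)
    hits <- hits + sum(p < 0.05)
    total <- total + n
  }
  rate <- hits / total
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("a typical low-VAF somatic variant is detected with high power", {
  # VAF 2.47% (the bottom of the observed lesion VAF range) at depth 10,000
  hits <- 0
  n_rep <- 40
  tg <- target_region("amp", "chr1", 0, 150)
  for (r in seq_len(n_rep)) {
    pair <- sim_pair(tg,
      spikes = tibble(pos = 75L, alt = "C", vaf = 0.0247),
      seed = 5000 + r
    )
    calls <- tidy(call_region(pair$lesion, pair$control, tg))
    hits <- hits + any(calls$verdict[calls$pos == 75])
  }
  expect_gt(hits / n_rep, 0.9)
})
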