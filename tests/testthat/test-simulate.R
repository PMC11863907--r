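# The synthetic cohort generator: determinism, calibration, truth tables and
# round trips.

small_cfg <- function(...) {
  sim_config(
    chrom_sizes = tibble::tibble(chrom = c("c1", "c2"), size = 2e6),
    samples = tibble::tibble(
      sample_id = sprintf("S%d", 1:6),
      condition = rep(c("pre", "post"), each = 3),
      platinum_status = rep(c("sensitive", "resistant"), 3),
      tumor_fraction = rep(c(0.3, 0.4, 0.5), 2),
      target_coverage = 0.1
    ),
    n_gained = 5, n_lost = 5,
    tfs = tibble::tibble(
      tf_name = "TF_A", n_sites = 100L, activity_pre = 0.8,
      activity_post = 0.2, activity_progression = 0.2,
      footprint_half_width = 25L, site_width = 20L
    ),
    ...
  )
}

test_that("a fixed seed reproduces the cohort byte-for-byte", {
  cfg <- small_cfg()
  s1 <- simulate_cohort(cfg, seed = 5)
  s2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(s1$fragments, s2$fragments)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$truth$planted, s2$truth$planted)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(s1, d1)
  write_cohort(s2, d2)
  f1 <- file.path(d1, "S1.bed"); f2 <- file.path(d2, "S1.bed")
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(s1$fragments, s3$fragments))
})

test_that("realized coverage is within 5% of each sample's target", {
  sim <- simulate_cohort(small_cfg(), seed = 9)
  smp <- sim$truth$samples
  expect_true(all(abs(smp$realized_coverage - smp$target_coverage) /
                    smp$target_coverage < 0.05))
  # recompute from the fragments themselves
  bp <- sim$fragments |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(cov = sum(length) / 4e6)
  expect_equal(sort(bp$cov), sort(smp$realized_coverage), tolerance = 1e-12)
})

test_that("fragment lengths reproduce the configured mixture modes", {
  set.seed(123)
  lens <- simulate_fragment_lengths(3e5)
  h <- size_histogram(lens)
  m <- peak_ratio_metrics(h)
  expect_equal(m$chromatosome_peak_bp, 165L)
  expect_equal(m$nucleosome_peak_bp, 150L)
  expect_equal(m$tf_peak_bp, 50L)
  expect_true(all(lens >= 30 & lens <= 400))
})

test_that("planted windows are recovered and the truth table is consistent", {
  cfg <- small_cfg()
  sim <- simulate_cohort(cfg, seed = 21)
  tr <- sim$truth
  expect_equal(nrow(tr$planted), 10)
  expect_setequal(tr$planted$direction[tr$planted$effect > 0], "gained")
  expect_equal(sort(c(tr$gained_bins, tr$lost_bins)), sort(tr$planted$bin_id))

  bins <- tile_genome(cfg$chrom_sizes, cfg$bin_size)
  occ <- sim$fragments |>
    filter_by_length() |>
    compute_occupancy(bins) |>
    normalize_track()
  d <- call_differential(occ)
  td <- tidy(d)
  hit <- dplyr::inner_join(td, tr$planted, by = "bin_id")
  expect_gte(sum(hit$direction.x == hit$direction.y), 9)
  expect_equal(sum(!td$bin_id %in% tr$planted$bin_id), 0)
})

test_that("per-sample child streams keep existing samples fixed when one is
           appended", {
  cfg <- small_cfg()
  cfg2 <- small_cfg()
  cfg2$samples <- dplyr::bind_rows(
    cfg$samples,
    tibble::tibble(sample_id = "S7", condition = "progression",
                   platinum_status = "sensitive", tumor_fraction = 0.4,
                   target_coverage = 0.1)
  )
  a <- simulate_cohort(cfg, seed = 3)
  b <- simulate_cohort(cfg2, seed = 3)
  for (sid in cfg$samples$sample_id) {
    expect_identical(
      a$fragments[a$fragments$sample_id == sid, ],
      b$fragments[b$fragments$sample_id == sid, ]
    )
  }
})

test_that("footprint dips deepen with tumor fraction and activity", {
  base <- small_cfg()
  depth_at <- function(tf_frac, activity) {
    cfg <- small_cfg()
    cfg$samples <- tibble::tibble(
      sample_id = sprintf("S%d", 1:2), condition = "pre",
      platinum_status = "sensitive", tumor_fraction = tf_frac,
      target_coverage = 0.2
    )
    cfg$tfs$activity_pre <- activity
    cfg$n_gained <- 0; cfg$n_lost <- 0
    cfg$planted_windows <- tibble::tibble(bin_id = integer(),
                                          effect = double())
    sim <- simulate_cohort(cfg, seed = 40)
    sc <- tfbs_center_depth(sim$fragments, sim$sites, cfg$chrom_sizes,
                            half_width = 10)
    mean(sc$score)
  }
  # 3-point grids in each knob
  d_tf <- c(depth_at(0.0, 0.9), depth_at(0.4, 0.9), depth_at(0.9, 0.9))
  expect_true(all(diff(d_tf) < 0))
  d_act <- c(depth_at(0.6, 0.1), depth_at(0.6, 0.5), depth_at(0.6, 0.9))
  expect_true(all(diff(d_act) < 0))
})

test_that("expression follows the negative link to expected center depth", {
  cfg <- small_cfg()
  sim <- simulate_cohort(cfg, seed = 2)
  # noiseless link: strictly decreasing in expected depth
  sim$truth$expression_link$noise_sd <- 0
  ex0 <- simulate_expression(sim, seed = 2)
  j <- dplyr::inner_join(ex0, sim$truth$expected_center_depth,
                         by = "sample_id")
  o <- order(j$expected_center_depth)
  expect_true(all(diff(j$expression[o]) <= 0))

  # zero slope: expression carries no depth signal (checked on a wide
  # synthetic truth table so the null correlation is well resolved)
  fake <- structure(list(truth = list(
    expected_center_depth = tibble::tibble(
      tf_name = "T", open_fraction = 0.5,
      sample_id = sprintf("F%03d", 1:200),
      expected_center_depth = seq(0.2, 1, length.out = 200)
    ),
    expression_link = list(intercept = 5, slope = 0, noise_sd = 0.5)
  )), class = "cfdna_sim")
  ex_null <- simulate_expression(fake, seed = 2)
  j0 <- dplyr::inner_join(ex_null, fake$truth$expected_center_depth,
                          by = "sample_id")
  expect_lt(abs(cor(j0$expression, j0$expected_center_depth,
                    method = "spearman")), 0.2)
})

test_that("written cohorts round-trip through the fragment reader and list
           every sample once", {
  cfg <- small_cfg()
  sim <- simulate_cohort(cfg, seed = 14)
  ex <- simulate_expression(sim, seed = 14)
  dir <- tempfile()
  paths <- write_cohort(sim, dir, expression = ex)
  sheet <- read_sample_sheet(paths$sample_sheet)
  expect_setequal(sheet$sample_id, cfg$samples$sample_id)
  expect_equal(anyDuplicated(sheet$sample_id), 0)
  for (i in seq_len(nrow(sheet))) {
    back <- read_fragments(sheet$path[i], sample_id = sheet$sample_id[i],
                           condition = sheet$condition[i])
    orig <- sim$fragments[sim$fragments$sample_id == sheet$sample_id[i], ]
    expect_equal(back$start, orig$start)
    expect_equal(back$end, orig$end)
    expect_equal(back$chrom, orig$chrom)
  }
  truth <- jsonlite::fromJSON(paths$truth)
  expect_equal(nrow(truth$planted), 10)
  expect_equal(truth$seed, 14)
  ex_back <- read_expression(paths$expression)
  expect_equal(
    dplyr::arrange(ex_back, gene, sample_id)$expression,
    dplyr::arrange(ex, gene, sample_id)$expression,
    tolerance = 1e-9
  )
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(sim_config(samples = dplyr::mutate(
    .default <- sim_config()$samples, tumor_fraction = 1.5
  )), "tumor_fraction")
  bad_mix <- sim_config()$size_mixture
  bad_mix$weight <- c(0.5, 0.5, 0.5)
  expect_error(sim_config(size_mixture = bad_mix), "sum to 1")
  bad_tfs <- sim_config()$tfs
  bad_tfs$activity_pre <- c(2, 0.5)
  expect_error(sim_config(tfs = bad_tfs), "activities")
})
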