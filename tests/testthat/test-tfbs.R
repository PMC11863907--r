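# Binding-site handling, aggregate profiles, center-depth activity scores
# and the downstream statistics.

test_that("BED sites are parsed with centers, strengths and strands", {
  p <- write_lines_tmp(c(
    "chr1\t100\t120\tsite1\t9.5\t+",
    "chr1\t500\t521\tsite2\t3\t-",
    "chr2\t40\t60"
  ))
  s <- load_sites(p, "REST")
  expect_equal(s$center, c(110, 510, 50))
  expect_equal(s$strength, c(9.5, 3, NA))
  expect_equal(s$strand, c("+", "-", "."))
  expect_equal(s$tf_name, rep("REST", 3))
  expect_equal(nrow(load_sites(write_lines_tmp(character(0)), "X")), 0)
  expect_error(load_sites(write_lines_tmp("chr1\t100\t90"), "X"), "line 1")
  expect_error(load_sites(write_lines_tmp("chr1\t100\t120\ts\tNaNope\t+"), "X"),
               "line 1")
})

test_that("site BED export/import round-trips all fields", {
  p <- write_lines_tmp(c(
    "chr1\t100\t120\tsite1\t9.5\t+",
    "chr2\t40\t60\tsite3\t2.25\t-"
  ))
  s <- load_sites(p, "A")
  out <- tempfile(fileext = ".bed")
  write_sites_bed(s, out)
  s2 <- load_sites(out, "A")
  expect_equal(s2, s)
})

test_that("top-fraction selection uses the ceiling rule, deterministic ties,
           and nests across fractions", {
  mk <- function(n, strength) {
    tibble::tibble(
      chrom = "c1", start = seq_len(n) * 100, end = seq_len(n) * 100 + 20,
      name = paste0("s", seq_len(n)), strength = strength,
      strand = ".", center = seq_len(n) * 100 + 10, tf_name = "T"
    )
  }
  four <- mk(4, 1:4)
  top2 <- select_top_fraction(four, 0.5)
  expect_equal(sort(top2$strength), c(3, 4))
  expect_equal(nrow(select_top_fraction(mk(5, 1:5), 0.5)), 3)  # ceil(2.5)

  # duplicate strengths: exactly half kept, byte-identical across calls
  dup <- mk(100, rep(1, 100))
  a <- select_top_fraction(dup, 0.5)
  b <- select_top_fraction(dup, 0.5)
  expect_equal(nrow(a), 50)
  expect_identical(a, b)

  # idempotent at the same fraction; top 25% nested in top 50%
  set.seed(2)
  rnd <- mk(40, runif(40))
  t50 <- select_top_fraction(rnd, 0.5)
  expect_identical(select_top_fraction(t50, 1), t50)
  t25 <- select_top_fraction(rnd, 0.25)
  expect_true(all(t25$name %in% t50$name))

  expect_error(select_top_fraction(mk(3, c(1, NA, 2))), "strength")
  expect_error(select_top_fraction(four, 0), "fraction")
})

test_that("a single fragment produces its indicator profile around one site", {
  cs <- tibble::tibble(chrom = "c1", size = 10000)
  # fragment covering offsets [-75, 75) around center 5000
  fr <- make_fragments("c1", 5000 - 75, 5000 + 75, condition = "pre")
  sites <- tibble::tibble(chrom = "c1", start = 4990, end = 5010,
                          name = "s", strength = 1, strand = "+",
                          center = 5000, tf_name = "T")
  p <- aggregate_profile(fr, sites, cs, flank = 100, step = 1,
                         min_len = NULL)
  prof <- tidy(p)
  gmean <- 150 / 10000
  inside <- prof$offset >= -75 & prof$offset < 75
  expect_equal(prof$occupancy[inside], rep(1 / gmean, sum(inside)))
  expect_equal(prof$occupancy[!inside], rep(0, sum(!inside)))
  expect_equal(p$n_sites, 1)
})

test_that("uniform coverage yields a flat profile at 1 and sites truncated at
           chromosome ends are dropped", {
  cs <- tibble::tibble(chrom = "c1", size = 19950)
  # perfect tiling coverage: depth exactly 1 everywhere (133 x 150 bp)
  fr <- make_fragments("c1", seq(0, 19800, by = 150),
                       seq(150, 19950, by = 150), condition = "pre")
  sites <- tibble::tibble(
    chrom = "c1", start = c(5000, 10000, 50),
    end = c(5020, 10020, 70), name = paste0("s", 1:3), strength = 1,
    strand = c("+", "-", "+"),
    center = c(5010, 10010, 60), tf_name = "T"
  )
  p <- aggregate_profile(fr, sites, cs, flank = 500, step = 10,
                         min_len = NULL)
  expect_equal(p$n_sites, 2)  # the site at 60 cannot host a 500-bp flank
  expect_equal(tidy(p)$occupancy, rep(1, nrow(tidy(p))), tolerance = 1e-12)
})

test_that("strand-randomized symmetric sites match an all-plus profile", {
  cs <- toy_chrom_sizes()
  fr <- random_fragments(4000, cs, len_range = c(120, 180), seed = 31,
                         condition = "pre")
  set.seed(32)
  sites <- tibble::tibble(
    chrom = sample(cs$chrom, 40, replace = TRUE),
    center = sample(5000:45000, 40)
  ) |>
    dplyr::mutate(start = center - 10, end = center + 10, name = "s",
                  strength = 1, strand = sample(c("+", "-"), 40, TRUE),
                  tf_name = "T")
  p_mix <- aggregate_profile(fr, sites, cs, flank = 300, step = 300)
  p_plus <- aggregate_profile(fr, dplyr::mutate(sites, strand = "+"),
                              cs, flank = 300, step = 300)
  # coarse bins symmetric about 0: strand flips only permute bp within bins
  expect_equal(mean(tidy(p_mix)$occupancy), mean(tidy(p_plus)$occupancy),
               tolerance = 0.05)
})

test_that("center-depth scores match the brute-force oracle and the uniform
           and zeroed-center limits", {
  cs <- tibble::tibble(chrom = "c1", size = 19950)
  fr <- make_fragments("c1", seq(0, 19800, by = 150),
                       seq(150, 19950, by = 150), condition = "pre")
  sites <- tibble::tibble(chrom = "c1", start = c(3000, 8000),
                          end = c(3020, 8020), name = c("a", "b"),
                          strength = 1, strand = "+",
                          center = c(3010, 8010), tf_name = "T")
  sc <- tfbs_center_depth(fr, sites, cs, half_width = 15, min_len = NULL)
  expect_equal(sc$score, 1)  # uniform track scores exactly 1

  # random fragments: equality with the per-bp oracle to 1e-9
  cs2 <- toy_chrom_sizes()
  fr2 <- random_fragments(500, cs2, seed = 77, condition = "pre")
  set.seed(78)
  sites2 <- tibble::tibble(
    chrom = sample(cs2$chrom, 25, replace = TRUE),
    center = sample(1000:49000, 25)
  ) |>
    dplyr::mutate(start = center - 10, end = center + 10, name = "s",
                  strength = 1, strand = "+", tf_name = "T")
  sc2 <- tfbs_center_depth(fr2, sites2, cs2, half_width = 15, min_len = NULL)
  expect_equal(sc2$score, oracle_center_depth(fr2, sites2, cs2, 15),
               tolerance = 1e-9)

  # coverage zeroed at all centers with half_width 0 -> score 0
  gap <- make_fragments("c1", c(0, 3500), c(3000, 8000), condition = "pre")
  sc3 <- tfbs_center_depth(gap, sites, cs, half_width = 0, min_len = NULL)
  expect_equal(sc3$score, 0)

  expect_error(tfbs_center_depth(fr, sites[0, ], cs), "sites")
})

test_that("correlations agree with closed forms and guard degenerate input", {
  scores <- tibble::tibble(sample_id = c("a", "b", "c"),
                           condition = "pre", tf_name = "T",
                           score = c(1, 2, 3), n_sites = 10)
  expr <- tibble::tibble(gene = "T", sample_id = c("a", "b", "c"),
                         expression = c(3, 2, 1))
  ce <- correlate_activity_expression(scores, expr, "T")
  expect_equal(ce$estimate, -1)
  expect_equal(ce$n, 3)

  # shuffling both vectors together leaves rho unchanged
  perm <- c(3, 1, 2)
  ce2 <- correlate_activity_expression(scores[perm, ], expr[perm, ], "T")
  expect_equal(ce2$estimate, ce$estimate)

  # Pearson on a perfect decreasing line
  tf_tab <- tibble::tibble(sample_id = c("a", "b", "c"),
                           tumor_fraction = c(0.9, 0.5, 0.1))
  ct <- correlate_with_tumor_fraction(scores, tf_tab)
  expect_equal(ct$estimate, -1, tolerance = 1e-12)

  # constant vector -> undefined estimate, not an error
  const <- dplyr::mutate(scores, score = 2)
  expect_true(is.na(correlate_with_tumor_fraction(const, tf_tab)$estimate))

  # fewer than 3 pairs -> error
  expect_error(correlate_with_tumor_fraction(scores[1:2, ], tf_tab), ">= 3")
  expect_error(correlate_activity_expression(scores, expr, "missing_gene"),
               "not found")
})

test_that("group comparison reproduces the exact rank-sum case and its
           symmetries", {
  sc <- tibble::tibble(
    sample_id = paste0("s", 1:6), condition = "pre", tf_name = "T",
    score = c(1, 2, 3, 4, 5, 6),
    platinum_status = rep(c("resistant", "sensitive"), each = 3)
  )
  mw <- compare_groups(sc)
  expect_equal(mw$u_statistic, 0)        # resistant (1,2,3) vs sensitive (4,5,6)
  expect_equal(mw$p.value, 0.1)          # exact two-sided enumeration
  expect_equal(mw$median1, 2)
  expect_equal(mw$median2, 5)

  # label swap: p unchanged, medians exchanged
  swapped <- dplyr::mutate(sc, platinum_status = ifelse(
    platinum_status == "resistant", "sensitive", "resistant"
  ))
  mw2 <- compare_groups(swapped)
  expect_equal(mw2$p.value, mw$p.value)
  expect_equal(c(mw2$median1, mw2$median2), c(mw$median2, mw$median1))

  # identical groups -> no evidence
  same <- dplyr::mutate(sc, score = rep(c(1, 2, 3), 2))
  expect_gt(suppressWarnings(compare_groups(same))$p.value, 0.99)

  expect_error(compare_groups(sc[1:3, ]), "2 non-empty groups")
  expect_error(compare_groups(dplyr::select(sc, -platinum_status)),
               "grouping column")
})
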