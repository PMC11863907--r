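# Synthetic cfDNA cohort generator. Emulates the statistical structure the
# analysis assumes -- nucleosome-protected fragment sizes (modes near
# 165/150/50 bp), per-sample sequencing depth, condition-dependent occupancy
# shifts in planted 10-kb windows, TFBS footprint dips scaled by
# tumor fraction x per-TF activity, and expression negatively linked to
# center read depth -- and emits a truth table for every downstream check.

.default_samples <- function() {
  tibble(
    sample_id = sprintf("S%02d", 1:12),
    condition = rep(c("pre", "post"), each = 6),
    platinum_status = rep(rep(c("sensitive", "resistant"), each = 3), 2),
    tumor_fraction = rep(seq(0.3, 0.5, length.out = 6), 2),
    target_coverage = 0.1
  )
}

.default_mixture <- function() {
  tibble(
    component = c("chromatosome", "core", "tf_footprint"),
    weight = c(0.55, 0.35, 0.10),
    mean = c(165, 150, 50),
    sd = c(5, 5, 10)
  )
}

.default_tfs <- function() {
  tibble(
    tf_name = c("TF_A", "TF_B"),
    n_sites = 1000L,
    activity_pre = c(0.8, 0.5),
    activity_post = c(0.3, 0.5),
    activity_progression = c(0.3, 0.5),
    footprint_half_width = 25L,
    site_width = 20L
  )
}

#' Configuration for a synthetic cfDNA cohort
#'
#' Assembles and validates the generator configuration. Defaults describe the
#' reference study conditions used throughout the test suite: a 2 x 10 Mb
#' genome, 6 pre-treatment and 6 post-treatment samples at 0.1x coverage with
#' tumor fractions 0.3-0.5, a three-component fragment-size mixture peaking
#' at 165/150/50 bp, 30 gained and 30 lost windows planted at relative effect
#' +/-0.6, two TFs with 1000 sites each, and expression linked negatively to
#' expected center depth.
#'
#' @param chrom_sizes Chromosome-sizes tibble (default two 10-Mb chromosomes).
#' @param bin_size Window size used to place planted effects (default 10,000).
#' @param samples Sample tibble: `sample_id`, `condition`, `platinum_status`,
#'   `tumor_fraction` in `[0,1]`, `target_coverage` (mean per-bp coverage).
#' @param size_mixture Fragment-length mixture: `component`, `weight`
#'   (summing to 1), `mean`, `sd` in bp.
#' @param length_range Truncation range for fragment lengths (default 30-400).
#' @param n_gained,n_lost Number of windows planted with positive/negative
#'   condition effects (ignored when `planted_windows` is given).
#' @param effect_size Magnitude of the planted relative occupancy change
#'   post-treatment (default 0.6; must be > -1 when negative).
#' @param planted_windows Optional explicit tibble (`bin_id`, `effect`);
#'   `NULL` draws `n_gained + n_lost` windows at simulation time.
#' @param window_noise_rsd Multiplicative between-sample noise on per-window
#'   fragment intensity, as a relative standard deviation (default 0.1).
#' @param dilute_by_tumor_fraction If `TRUE`, planted window effects act only
#'   on the tumor-derived compartment, so the observable shift is diluted to
#'   `tumor_fraction * effect` (and vanishes at tumor fraction 0). The
#'   default `FALSE` plants effects at the cohort level, i.e., `effect` IS
#'   the expected observable relative change. TFBS footprint dips always
#'   scale with tumor fraction regardless of this switch.
#' @param tfs TF tibble: `tf_name`, `n_sites`, per-condition activities in
#'   `[0,1]` (probability a site is bound in the tumor compartment),
#'   `footprint_half_width`, `site_width` (bp).
#' @param expression_link List `intercept`, `slope`, `noise_sd` for
#'   `expression = max(0, intercept - slope * expected_center_depth + noise)`.
#' @return A validated list of class `cfdna_sim_config`.
#' @export
sim_config <- function(chrom_sizes = tibble(chrom = c("chr1", "chr2"),
                                            size = 1e7),
                       bin_size = 10000,
                       samples = .default_samples(),
                       size_mixture = .default_mixture(),
                       length_range = c(30, 400),
                       n_gained = 30, n_lost = 30, effect_size = 0.6,
                       planted_windows = NULL,
                       window_noise_rsd = 0.1,
                       dilute_by_tumor_fraction = FALSE,
                       tfs = .default_tfs(),
                       expression_link = list(intercept = 10, slope = 10,
                                              noise_sd = 0.5)) {
  .check_chrom_sizes(chrom_sizes)
  .check_condition(samples$condition)
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in samples")
  if (any(samples$tumor_fraction < 0 | samples$tumor_fraction > 1)) {
    abort("tumor_fraction must lie in [0, 1]")
  }
  if (any(samples$target_coverage <= 0)) abort("target_coverage must be > 0")
  if (abs(sum(size_mixture$weight) - 1) > 1e-8) {
    abort("size-mixture weights must sum to 1")
  }
  if (any(size_mixture$weight < 0)) abort("size-mixture weights must be >= 0")
  if (!is.null(planted_windows)) {
    stopifnot(all(c("bin_id", "effect") %in% names(planted_windows)))
    if (any(planted_windows$effect <= -1)) abort("planted effect must be > -1")
  } else if (effect_size <= -1) {
    abort("effect_size must be > -1")
  }
  if (window_noise_rsd < 0) abort("window_noise_rsd must be >= 0")
  if (nrow(tfs) > 0) {
    act <- unlist(tfs[c("activity_pre", "activity_post", "activity_progression")])
    if (any(act < 0 | act > 1)) abort("TF activities must lie in [0, 1]")
  }
  structure(
    list(
      chrom_sizes = chrom_sizes, bin_size = bin_size, samples = samples,
      size_mixture = size_mixture, length_range = length_range,
      n_gained = n_gained, n_lost = n_lost, effect_size = effect_size,
      planted_windows = planted_windows,
      window_noise_rsd = window_noise_rsd,
      dilute_by_tumor_fraction = dilute_by_tumor_fraction,
      tfs = tfs, expression_link = expression_link
    ),
    class = "cfdna_sim_config"
  )
}

#' Draw fragment lengths from the protection-mode mixture
#'
#' Truncated-normal mixture over the chromatosome (~165 bp), nucleosome core
#' (~150 bp) and TF-footprint (~50 bp) protection modes; lengths are rounded
#' to integer bp and redrawn while outside `length_range`.
#'
#' @param n Number of lengths.
#' @param size_mixture Mixture tibble (see [sim_config()]).
#' @param length_range Truncation range in bp.
#' @return An integer vector of `n` fragment lengths.
#' @export
simulate_fragment_lengths <- function(n, size_mixture = .default_mixture(),
                                      length_range = c(30, 400)) {
  if (n == 0) return(integer(0))
  comp <- sample.int(nrow(size_mixture), n, replace = TRUE,
                     prob = size_mixture$weight)
  .draw_lengths(comp, size_mixture, length_range)
}

# Truncated-normal integer lengths for a given component assignment, by
# stratified inverse-CDF sampling: within each component the unit interval is
# split into equal strata, one jittered draw per stratum, in random order.
# The marginal distribution of every draw is the exact truncated normal; the
# stratification removes histogram-level Monte Carlo noise so the realized
# size distribution tracks the configured mixture closely at any n.
.draw_lengths <- function(comp, size_mixture, length_range) {
  len <- integer(length(comp))
  for (ci in seq_len(nrow(size_mixture))) {
    idx <- which(comp == ci)
    n <- length(idx)
    if (n == 0) next
    mu <- size_mixture$mean[ci]
    sg <- size_mixture$sd[ci]
    plo <- stats::pnorm(length_range[1], mu, sg)
    phi <- stats::pnorm(length_range[2], mu, sg)
    u <- (sample.int(n) - runif(n)) / n
    len[idx] <- as.integer(round(stats::qnorm(plo + u * (phi - plo), mu, sg)))
  }
  pmin(pmax(len, length_range[1]), length_range[2])
}

# Stochastic rounding: floor(x) + Bernoulli(frac(x)). Keeps per-window
# fragment counts within one unit of their expectation (variance-controlled
# allocation; see the methods vignette).
.stochastic_round <- function(x) {
  fl <- floor(x)
  as.integer(fl + rbinom(length(x), 1L, x - fl))
}

# Largest-remainder rounding: integer vector summing to round(sum(x)), each
# element floor(x) or floor(x)+1. Deterministic; keeps allocation noise at
# the sub-fragment level.
.lr_round <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  k <- as.integer(round(total - sum(fl)))
  out <- as.integer(fl)
  if (k > 0) {
    add <- order(x - fl, decreasing = TRUE)[seq_len(k)]
    out[add] <- out[add] + 1L
  }
  out
}

# Per-window protection-mode composition by largest remainder: a counts
# matrix (windows x components) whose rows sum to n_w and whose columns track
# the mixture weights, so window coverage is not inflated by multinomial
# variance in the component mix.
.stratify_components <- function(n_w, weights) {
  k <- length(weights)
  e <- outer(n_w, weights)
  fl <- floor(e)
  rem <- e - fl
  need <- as.integer(n_w - rowSums(fl))
  out <- fl
  for (j in seq_len(max(need, 0))) {
    pick <- max.col(rem, ties.method = "first")
    sel <- need >= j
    out[cbind(which(sel), pick[sel])] <- out[cbind(which(sel), pick[sel])] + 1
    rem[cbind(seq_along(pick), pick)] <- -1
  }
  storage.mode(out) <- "integer"
  out
}

.site_positions <- function(cfg, tf_row, margin = 5000) {
  sizes <- cfg$chrom_sizes$size
  usable <- pmax(sizes - 2 * margin, 0)
  n_per <- .stochastic_round(tf_row$n_sites * usable / sum(usable))
  # fix total deterministically
  while (sum(n_per) != tf_row$n_sites) {
    i <- which.max(usable)
    n_per[i] <- n_per[i] + sign(tf_row$n_sites - sum(n_per))
  }
  purrr::map2(seq_along(sizes), n_per, function(i, k) {
    if (k == 0) return(NULL)
    # evenly spaced slots with uniform jitter: well-separated sites
    slot <- usable[i] / k
    centers <- floor(margin + (seq_len(k) - 1) * slot + runif(k) * slot)
    tibble(chrom = cfg$chrom_sizes$chrom[i], center = centers)
  }) |>
    bind_rows()
}

.activity_of <- function(tfs, tf_name, condition) {
  row <- tfs[tfs$tf_name == tf_name, ]
  switch(condition,
    pre = row$activity_pre,
    post = row$activity_post,
    progression = row$activity_progression,
    unknown = row$activity_pre
  )
}

#' Simulate a cfDNA cohort with planted truth
#'
#' Generates per-sample fragment sets under the configured model and returns
#' them with a truth table for every downstream assertion. Per sample,
#' fragment midpoints are allocated to 10-kb windows in proportion to a base
#' intensity (uniform, times `1 + effect` in planted windows for
#' post-treatment and progression samples, times multiplicative window
#' noise), with fragment counts set by the sample's target coverage and
#' lengths drawn from the protection-mode mixture. A fraction
#' `tumor_fraction` of fragments is tumor-derived; at each TF site that is
#' bound ("open") in the tumor of the sample's condition, tumor-derived
#' fragments covering the site center are replaced by short TF-protected
#' fragments placed beside the center -- producing a footprint dip whose
#' depth scales with `tumor_fraction x activity` and, at the same time, the
#' ~50 bp component of the size distribution.
#'
#' All randomness flows from `seed` through one child stream per sample
#' (derived from the sample's position in the sample table), so appending a
#' sample does not perturb the others.
#'
#' @param cfg A [sim_config()] object.
#' @param seed Integer master seed.
#' @return A list of class `cfdna_sim`: `fragments` (all samples, one
#'   tibble), `sites` (all TFs, one tibble with `tf_name`), `truth` (planted
#'   windows, per-sample tumor fractions and realized coverage, per-TF
#'   per-condition activities and realized open fractions, per-site open
#'   status, expected center depths, generator parameters), and `config`.
#' @export
simulate_cohort <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cfdna_sim_config"))
  seed <- as.integer(seed)
  bins <- tile_genome(cfg$chrom_sizes, cfg$bin_size)
  genome_size <- sum(cfg$chrom_sizes$size)

  set.seed(seed)
  # planted windows
  planted <- cfg$planted_windows
  if (is.null(planted)) {
    n_pl <- cfg$n_gained + cfg$n_lost
    full <- bins$bin_id[bins$width == cfg$bin_size]
    ids <- sort(sample(full, n_pl))
    eff <- rep(c(cfg$effect_size, -cfg$effect_size),
               c(cfg$n_gained, cfg$n_lost))
    planted <- tibble(bin_id = ids, effect = sample(eff))
  }
  planted <- planted |>
    inner_join(bins, by = "bin_id") |>
    mutate(direction = ifelse(.data$effect > 0, "gained", "lost")) |>
    select("bin_id", "chrom", "start", "end", "effect", "direction")

  # TF sites, strengths, and per-condition open status
  sites <- NULL
  open_status <- NULL
  if (nrow(cfg$tfs) > 0) {
    sites <- purrr::map(seq_len(nrow(cfg$tfs)), function(i) {
      tf <- cfg$tfs[i, ]
      pos <- .site_positions(cfg, tf)
      hw <- floor(tf$site_width / 2)
      pos |>
        mutate(
          start = .data$center - hw,
          end = .data$center + (tf$site_width - hw),
          center = floor((.data$start + .data$end) / 2),
          name = sprintf("%s_site%04d", tf$tf_name, dplyr::row_number()),
          strength = runif(dplyr::n()),
          strand = sample(c("+", "-"), dplyr::n(), replace = TRUE),
          tf_name = tf$tf_name
        )
    }) |>
      bind_rows() |>
      select("chrom", "start", "end", "name", "strength", "strand",
             "center", "tf_name")
    open_status <- purrr::map(c("pre", "post", "progression"), function(cond) {
      sites |>
        group_by(.data$tf_name) |>
        mutate(
          condition = cond,
          open = runif(dplyr::n()) <
            .activity_of(cfg$tfs, .data$tf_name[1], cond)
        ) |>
        ungroup() |>
        select("tf_name", "name", "chrom", "center", "condition", "open")
    }) |>
      bind_rows()
  }

  mean_len <- sum(cfg$size_mixture$weight * cfg$size_mixture$mean)
  frag_list <- vector("list", nrow(cfg$samples))
  realized <- numeric(nrow(cfg$samples))
  expected_depth <- list()

  for (i in seq_len(nrow(cfg$samples))) {
    smp <- cfg$samples[i, ]
    set.seed(seed + 100003L * i)
    theta <- smp$tumor_fraction

    # per-window intensity
    intensity <- rep(1, nrow(bins))
    if (smp$condition %in% c("post", "progression") && nrow(planted) > 0) {
      eff <- if (cfg$dilute_by_tumor_fraction) theta * planted$effect
             else planted$effect
      intensity[planted$bin_id] <- 1 + eff
    }
    if (cfg$window_noise_rsd > 0) {
      s2 <- log(1 + cfg$window_noise_rsd^2)
      intensity <- intensity *
        stats::rlnorm(nrow(bins), meanlog = -s2 / 2, sdlog = sqrt(s2))
    }
    w <- intensity * bins$width
    n_target <- smp$target_coverage * genome_size / mean_len
    counts <- .lr_round(n_target * w / sum(w))

    idx <- rep.int(seq_len(nrow(bins)), counts)
    n_fr <- length(idx)
    mids <- bins$start[idx] +
      floor(runif(n_fr) * (bins$end[idx] - bins$start[idx]))
    cmat <- .stratify_components(counts, cfg$size_mixture$weight)
    comp <- rep.int(rep(seq_len(ncol(cmat)), times = nrow(cmat)),
                    times = as.vector(t(cmat)))
    lens <- .draw_lengths(comp, cfg$size_mixture, cfg$length_range)
    start <- mids - lens %/% 2L
    end <- start + lens
    chrom <- bins$chrom[idx]
    # shift fragments overhanging chromosome ends back inside
    csize <- setNames(cfg$chrom_sizes$size, cfg$chrom_sizes$chrom)[chrom]
    shift <- pmax(0, -start) - pmax(0, end - csize)
    start <- start + shift
    end <- end + shift
    tumor <- runif(n_fr) < theta

    # TF footprints: replace tumor fragments covering open site centers
    if (!is.null(sites) && any(tumor)) {
      op <- open_status[open_status$condition ==
                          (if (smp$condition == "unknown") "pre"
                           else smp$condition) & open_status$open, ]
      for (ch in unique(op$chrom)) {
        ctr <- op$center[op$chrom == ch]
        if (length(ctr) == 0) next
        cand <- which(chrom == ch & tumor)
        if (length(cand) == 0) next
        hits <- IRanges::findOverlaps(
          IRanges::IRanges(start = ctr + 1, width = 1),
          IRanges::IRanges(start = start[cand] + 1, end = end[cand])
        )
        if (length(hits) == 0) next
        fi <- cand[S4Vectors::subjectHits(hits)]
        ci <- ctr[S4Vectors::queryHits(hits)]
        keep <- !duplicated(fi)  # replace each fragment once
        fi <- fi[keep]; ci <- ci[keep]
        k <- length(fi)
        flen <- pmin(pmax(as.integer(round(rnorm(k, 50, 10))), 30L), 80L)
        side <- sample(c(-1L, 1L), k, replace = TRUE)
        gap <- sample.int(8L, k, replace = TRUE) + 2L
        ns <- ifelse(side > 0, ci + gap, ci - gap - flen)
        ne <- ns + flen
        sz <- csize[fi]
        sh <- pmax(0, -ns) - pmax(0, ne - sz)
        start[fi] <- ns + sh
        end[fi] <- ne + sh
        lens[fi] <- flen
      }
    }

    frag_list[[i]] <- tibble(
      chrom = chrom, start = as.double(start), end = as.double(end),
      length = as.integer(end - start),
      sample_id = smp$sample_id, condition = smp$condition
    ) |>
      .sort_genomic(cfg$chrom_sizes)
    realized[i] <- sum(as.numeric(lens)) / genome_size

    # expected normalized center depth per TF: 1 - theta * open fraction
    if (!is.null(sites)) {
      expected_depth[[i]] <- open_status |>
        filter(.data$condition ==
                 (if (smp$condition == "unknown") "pre" else smp$condition)) |>
        group_by(.data$tf_name) |>
        summarise(open_fraction = mean(.data$open), .groups = "drop") |>
        mutate(sample_id = smp$sample_id,
               expected_center_depth = 1 - theta * .data$open_fraction)
    }
  }

  truth <- list(
    seed = seed,
    planted = planted,
    gained_bins = planted$bin_id[planted$effect > 0],
    lost_bins = planted$bin_id[planted$effect < 0],
    samples = cfg$samples |> mutate(realized_coverage = realized),
    tfs = cfg$tfs,
    site_open_status = open_status,
    expected_center_depth = if (length(expected_depth) > 0)
      bind_rows(expected_depth) else NULL,
    dilute_by_tumor_fraction = cfg$dilute_by_tumor_fraction,
    expression_link = cfg$expression_link
  )
  structure(
    list(fragments = bind_rows(frag_list), sites = sites, truth = truth,
         config = cfg),
    class = "cfdna_sim"
  )
}

#' Simulate expression linked to TF center depth
#'
#' Generates one expression row per TF ("gene") across the cohort's samples:
#' `expression = max(0, intercept - slope * expected_center_depth + noise)`,
#' emulating the observation that higher read depth at a TF's binding sites
#' (less binding) predicts less expression of the TF's gene.
#'
#' @param sim A `cfdna_sim` object from [simulate_cohort()].
#' @param seed Integer seed for the expression noise stream.
#' @return A long expression tibble: `gene`, `sample_id`, `expression`.
#' @export
simulate_expression <- function(sim, seed = 1L) {
  stopifnot(inherits(sim, "cfdna_sim"))
  ed <- sim$truth$expected_center_depth
  if (is.null(ed)) abort("cohort was simulated without TFs")
  link <- sim$truth$expression_link
  set.seed(as.integer(seed) + 577L)
  ed |>
    arrange(.data$tf_name, .data$sample_id) |>
    mutate(
      gene = .data$tf_name,
      expression = pmax(0, link$intercept -
                          link$slope * .data$expected_center_depth +
                          rnorm(dplyr::n(), 0, link$noise_sd))
    ) |>
    select("gene", "sample_id", "expression")
}

#' Write a simulated cohort to disk
#'
#' Writes one fragment BED per sample, one BED6 per TF (strength in the score
#' column), a sample sheet TSV (with fragment paths), a gene-by-sample
#' expression TSV when supplied, the truth table as JSON and the
#' configuration as YAML.
#'
#' @param sim A `cfdna_sim` object.
#' @param out_dir Output directory (created if needed).
#' @param expression Optional expression tibble from [simulate_expression()].
#' @return The paths written, invisibly (named list).
#' @export
write_cohort <- function(sim, out_dir, expression = NULL) {
  stopifnot(inherits(sim, "cfdna_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  smp <- sim$truth$samples
  frag_paths <- vapply(smp$sample_id, function(sid) {
    p <- file.path(out_dir, paste0(sid, ".bed"))
    write_fragments_bed(
      sim$fragments[sim$fragments$sample_id == sid, , drop = FALSE], p
    )
    p
  }, "")
  site_paths <- character(0)
  if (!is.null(sim$sites)) {
    site_paths <- vapply(unique(sim$sites$tf_name), function(tf) {
      p <- file.path(out_dir, paste0("sites_", tf, ".bed"))
      write_sites_bed(sim$sites[sim$sites$tf_name == tf, , drop = FALSE], p)
      p
    }, "")
  }
  sheet <- smp |> mutate(path = unname(frag_paths))
  sheet_path <- file.path(out_dir, "sample_sheet.tsv")
  readr::write_tsv(sheet, sheet_path, progress = FALSE)
  sizes_path <- file.path(out_dir, "chrom_sizes.tsv")
  readr::write_tsv(sim$config$chrom_sizes, sizes_path, col_names = FALSE,
                   progress = FALSE)
  expr_path <- NULL
  if (!is.null(expression)) {
    expr_path <- file.path(out_dir, "expression.tsv")
    wide <- tidyr::pivot_wider(expression, names_from = "sample_id",
                               values_from = "expression")
    readr::write_tsv(wide, expr_path, progress = FALSE)
  }
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  cfg_plain <- purrr::map(unclass(sim$config), function(x) {
    if (is.data.frame(x)) lapply(as.list(x), unname) else x
  })
  yaml::write_yaml(cfg_plain, cfg_path)
  invisible(list(fragments = frag_paths, sites = site_paths,
                 sample_sheet = sheet_path, chrom_sizes = sizes_path,
                 expression = expr_path, truth = truth_path,
                 config = cfg_path))
}
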