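# Stability-filtered differential-occupancy calling between treatment
# conditions: the two-threshold procedure (within-condition relative
# deviation < rsd_max, between-condition relative change > change_min).

#' Relative deviation of normalized occupancies
#'
#' Sample standard deviation (n-1 denominator) divided by the arithmetic
#' mean. The stability criterion for a window is that this quantity, computed
#' across all samples of one condition, stays below a threshold (default 0.5).
#' Returns `NA` when the mean is zero (stability undefined).
#'
#' @param values Numeric vector of per-sample normalized occupancies at one
#'   window (length >= 2).
#' @return A single numeric value, or `NA` for a zero mean.
#' @export
relative_deviation <- function(values) {
  if (length(values) < 2) abort("relative deviation needs >= 2 values")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  sd(values) / m
}

.rsd_by_bin <- function(occupancy) {
  occupancy |>
    group_by(.data$bin_id, .data$chrom, .data$start, .data$end) |>
    summarise(
      n_samples = dplyr::n(),
      mean = mean(.data$value),
      rsd = ifelse(mean(.data$value) == 0, NA_real_,
                   sd(.data$value) / mean(.data$value)),
      .groups = "drop"
    ) |>
    arrange(.data$bin_id)
}

#' Windows with stable occupancy within one condition
#'
#' A window is stable when its relative deviation across the condition's
#' samples is defined and strictly below `rsd_max`, and its mean occupancy is
#' positive. Windows with zero coverage are retained but marked unstable.
#'
#' @param occupancy Normalized occupancy tibble for the samples of ONE
#'   condition (>= 2 samples on identical windows).
#' @param rsd_max Stability threshold on the relative deviation (strict `<`,
#'   default 0.5).
#' @return A tibble per window: `bin_id`, `chrom`, `start`, `end`,
#'   `n_samples`, `mean`, `rsd`, `stable`.
#' @export
stable_bins <- function(occupancy, rsd_max = 0.5) {
  if (length(unique(occupancy$condition)) > 1) {
    abort("stable_bins() expects samples of a single condition")
  }
  n_samp <- length(unique(occupancy$sample_id))
  if (n_samp < 2) abort("stability needs >= 2 samples per condition")
  counts <- dplyr::count(occupancy, .data$sample_id)
  if (length(unique(counts$n)) != 1) {
    abort("samples are not on identical windows")
  }
  .rsd_by_bin(occupancy) |>
    mutate(stable = !is.na(.data$rsd) & .data$rsd < rsd_max & .data$mean > 0)
}

#' Call gained- and lost-nucleosome regions between conditions
#'
#' Implements the two-threshold differential-occupancy procedure on 10-kb
#' windows: (1) keep windows whose occupancy is stable (relative deviation
#' strictly `< rsd_max`) in both the pre-treatment and post-treatment groups;
#' (2) among those, call a window *gained* when the relative change of the
#' averaged normalized occupancy, `(mean_post - mean_pre) / mean_pre`, is
#' strictly `> change_min`, and *lost* when it is strictly `< -change_min`.
#' Windows are single bins; no merging of adjacent calls is performed.
#' Progression samples are never used for calling.
#'
#' @param occupancy Normalized occupancy tibble containing >= 2 samples each
#'   with condition `"pre"` and `"post"` on identical windows. Samples with
#'   other condition labels are ignored.
#' @param rsd_max Within-condition stability threshold (default 0.5).
#' @param change_min Between-condition relative-change threshold (default 0.4).
#' @param denominator `"pre"` (default) divides the change by the
#'   pre-treatment mean; `"mean"` divides by the average of the two condition
#'   means (symmetric alternative).
#' @return An object of class `cfdna_diff` with components `regions` (called
#'   windows: means, `rel_change`, `direction`), `stats` (per-window means,
#'   RSDs, stability and change for every window), `n_gained`, `n_lost`, the
#'   thresholds used, and `no_stable` (TRUE when no window was stable in both
#'   conditions, in which case an empty set is returned with a warning).
#'   Use [tidy()] for the regions and [glance()] for the summary.
#' @export
call_differential <- function(occupancy, rsd_max = 0.5, change_min = 0.4,
                              denominator = c("pre", "mean")) {
  denominator <- match.arg(denominator)
  if (rsd_max <= 0 || change_min <= 0) {
    abort("rsd_max and change_min must be positive")
  }
  pre <- filter(occupancy, .data$condition == "pre")
  post <- filter(occupancy, .data$condition == "post")
  if (length(unique(pre$sample_id)) < 2 || length(unique(post$sample_id)) < 2) {
    abort("need >= 2 samples in each of the pre and post conditions")
  }
  s_pre <- stable_bins(pre, rsd_max)
  s_post <- stable_bins(post, rsd_max)
  if (!identical(s_pre$bin_id, s_post$bin_id)) {
    abort("pre and post groups are not on identical windows")
  }
  stats <- s_pre |>
    select("bin_id", "chrom", "start", "end",
           mean_pre = "mean", rsd_pre = "rsd", stable_pre = "stable") |>
    inner_join(
      s_post |> select("bin_id", mean_post = "mean", rsd_post = "rsd",
                       stable_post = "stable"),
      by = "bin_id"
    ) |>
    mutate(
      stable_both = .data$stable_pre & .data$stable_post,
      denom = if (denominator == "pre") .data$mean_pre
              else (.data$mean_pre + .data$mean_post) / 2,
      rel_change = ifelse(.data$stable_both & .data$denom > 0,
                          (.data$mean_post - .data$mean_pre) / .data$denom,
                          NA_real_)
    ) |>
    select(-"denom")
  no_stable <- !any(stats$stable_both)
  if (no_stable) {
    warn("no window is stable in both conditions; returning an empty region set")
  }
  regions <- stats |>
    filter(.data$stable_both, abs(.data$rel_change) > change_min) |>
    mutate(direction = ifelse(.data$rel_change > 0, "gained", "lost")) |>
    select("bin_id", "chrom", "start", "end", "mean_pre", "mean_post",
           "rel_change", "direction") |>
    arrange(.data$bin_id)
  structure(
    list(
      regions = regions,
      stats = stats,
      n_gained = sum(regions$direction == "gained"),
      n_lost = sum(regions$direction == "lost"),
      rsd_max = rsd_max,
      change_min = change_min,
      denominator = denominator,
      no_stable = no_stable
    ),
    class = "cfdna_diff"
  )
}

#' @export
print.cfdna_diff <- function(x, ...) {
  cat(sprintf(
    "Differential cfDNA occupancy (RSD < %g, |rel change| > %g, denominator = %s)\n",
    x$rsd_max, x$change_min, x$denominator
  ))
  cat(sprintf("  windows stable in both conditions: %d of %d\n",
              sum(x$stats$stable_both), nrow(x$stats)))
  cat(sprintf("  gained-nucleosome regions: %d\n", x$n_gained))
  cat(sprintf("  lost-nucleosome regions:   %d\n", x$n_lost))
  invisible(x)
}

#' Export differential regions as BED6
#'
#' BED6 with `name` = direction (gained/lost) and
#' `score = round(1000 * min(|rel_change|, 1))`, deterministic genomic order.
#'
#' @param x A `cfdna_diff` object.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
export_regions <- function(x, path) {
  stopifnot(inherits(x, "cfdna_diff"))
  bed <- x$regions |>
    mutate(
      score = round(1000 * pmin(abs(.data$rel_change), 1)),
      strand = ".",
      start = format(.data$start, scientific = FALSE, trim = TRUE),
      end = format(.data$end, scientific = FALSE, trim = TRUE)
    ) |>
    select("chrom", "start", "end", name = "direction", "score", "strand")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
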