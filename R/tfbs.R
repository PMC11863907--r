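# Aggregate cfDNA occupancy profiles around TF binding sites, center-depth
# activity scores, and their relation to expression, tumor fraction and
# clinical groups. Higher read depth at site centers indicates less TF
# binding, predicting less gene expression.

#' Load transcription factor binding sites from BED
#'
#' BED3+ with optional name (column 4), strength score (column
#' `strength_col`, default the BED score column 5) and strand (column 6).
#' The site center is `floor((start + end) / 2)`.
#'
#' @param path BED file of binding sites.
#' @param tf_name Transcription factor name attached to every site.
#' @param strength_col 1-based column index holding the site strength (motif
#'   or peak score); `NULL` to ignore strengths.
#' @return A tibble of sites: `chrom`, `start`, `end`, `name`, `strength`,
#'   `strand`, `center`, `tf_name`, sorted genomically.
#' @export
load_sites <- function(path, tf_name, strength_col = 5) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tl <- .split_table_lines(path)
  if (length(tl$fields) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  name = character(), strength = double(), strand = character(),
                  center = double(), tf_name = character()))
  }
  nf <- lengths(tl$fields)
  if (any(nf < 3)) {
    abort(sprintf("line %d: expected >= 3 BED fields, found %d",
                  tl$lineno[which(nf < 3)[1]], min(nf)))
  }
  getcol <- function(i, default = NA_character_) {
    ifelse(nf >= i, vapply(tl$fields, function(f) f[min(i, length(f))], ""), default)
  }
  start <- .parse_coord(vapply(tl$fields, `[[`, "", 2), tl$lineno, "start")
  end <- .parse_coord(vapply(tl$fields, `[[`, "", 3), tl$lineno, "end")
  if (any(end <= start)) {
    i <- which(end <= start)[1]
    abort(sprintf("line %d: site end <= start", tl$lineno[i]))
  }
  strength <- rep(NA_real_, length(start))
  if (!is.null(strength_col) && any(nf >= strength_col)) {
    raw <- getcol(strength_col)
    has <- nf >= strength_col & !is.na(raw) & raw != "."
    val <- suppressWarnings(as.numeric(raw[has]))
    if (anyNA(val)) {
      bad <- tl$lineno[has][which(is.na(val))[1]]
      abort(sprintf("line %d: non-numeric strength field", bad))
    }
    strength[has] <- val
  }
  strand <- getcol(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  tibble(
    chrom = vapply(tl$fields, `[[`, "", 1),
    start = start, end = end,
    name = getcol(4),
    strength = strength,
    strand = strand,
    center = floor((start + end) / 2),
    tf_name = tf_name
  ) |>
    .sort_genomic()
}

#' Write binding sites as BED6
#'
#' The strength is written in the BED score column (column 5).
#'
#' @param sites Site tibble from [load_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- sites |>
    mutate(
      name = ifelse(is.na(.data$name), ".", .data$name),
      score = ifelse(is.na(.data$strength), ".",
                     format(.data$strength, scientific = FALSE, trim = TRUE)),
      start = format(.data$start, scientific = FALSE, trim = TRUE),
      end = format(.data$end, scientific = FALSE, trim = TRUE)
    ) |>
    select("chrom", "start", "end", "name", "score", "strand")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Select the strongest fraction of binding sites
#'
#' Keeps the `ceiling(fraction * n)` highest-strength sites (e.g., the top
#' 50% of database-derived sites). Ties are broken deterministically by
#' genomic position (chrom, start ascending); output is sorted genomically.
#'
#' @param sites Site tibble; every site must carry a strength.
#' @param fraction Fraction to keep, in `(0, 1]` (default 0.5).
#' @return The selected site tibble.
#' @export
select_top_fraction <- function(sites, fraction = 0.5) {
  if (anyNA(sites$strength)) abort("all sites must have a strength score")
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  n_keep <- ceiling(fraction * nrow(sites))
  lev <- .chrom_levels(sites$chrom)
  sites |>
    arrange(dplyr::desc(.data$strength), match(.data$chrom, lev), .data$start) |>
    dplyr::slice_head(n = n_keep) |>
    .sort_genomic()
}

# Normalized per-chrom coverage for one sample: coverage Rle divided by the
# genome-wide per-bp mean. Errors on zero total coverage.
.normalized_coverage <- function(fragments, sizes, sample_id) {
  covs <- .coverage_rle(fragments, sizes)
  total <- sum(vapply(covs, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                              S4Vectors::runLength(r)), 0))
  gmean <- total / sum(as.numeric(sizes))
  if (gmean <= 0) abort(paste0("no coverage for sample ", sample_id))
  list(covs = covs, gmean = gmean)
}

#' Aggregate cfDNA occupancy profile around binding sites
#'
#' For each sample, extracts depth-normalized per-bp coverage of
#' nucleosome-protected fragments in a window of `+/- flank` bp around every
#' site center (offsets are negated for minus-strand sites so profiles are
#' strand-oriented), averages over sites with equal weight, and bins offsets
#' to `step`-bp resolution. Per condition, sample curves are averaged with
#' equal weight. Sites whose window would extend past a chromosome end are
#' dropped. A dip at offset 0 relative to the flanks indicates TF binding.
#'
#' @param fragments Fragment tibble (one or more samples, with conditions).
#' @param sites Site tibble from [load_sites()].
#' @param chrom_sizes Chromosome-sizes tibble.
#' @param flank Half-width of the profile window in bp (default 2000).
#' @param step Offset bin width in bp (default 10).
#' @param min_len,max_len Nucleosome-protection length filter applied before
#'   profiling (defaults 120/180); `NULL` to skip.
#' @return An object of class `cfdna_profile`: a list with `profile`
#'   (tibble: `offset`, `condition`, `occupancy`, `n_samples`), `by_sample`
#'   (per-sample curves), `n_sites`, `flank`, `step`, `tf_name`.
#' @export
aggregate_profile <- function(fragments, sites, chrom_sizes, flank = 2000,
                              step = 10, min_len = 120, max_len = 180) {
  .check_fragments(fragments)
  .check_chrom_sizes(chrom_sizes)
  if (nrow(sites) == 0) abort("no binding sites supplied")
  if (!is.null(min_len)) {
    fragments <- filter_by_length(fragments, min_len, max_len %||% Inf)
  }
  sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  st <- sites |>
    mutate(.size = sizes[.data$chrom]) |>
    filter(.data$center - flank >= 0, .data$center + flank < .data$.size)
  if (nrow(st) == 0) abort("no usable sites: all windows extend past chromosome ends")
  key <- distinct(fragments, .data$sample_id, .data$condition)
  width <- 2L * flank + 1L
  # offset bins: offset o -> bin centered at round-to-step position
  offs <- seq(-flank, flank)
  bin_of <- floor((offs + step / 2) / step)
  curves <- purrr::map2(key$sample_id, key$condition, function(sid, cond) {
    fr <- fragments[fragments$sample_id == sid, , drop = FALSE]
    nc <- .normalized_coverage(fr, sizes, sid)
    acc <- numeric(width)
    for (ch in unique(st$chrom)) {
      s <- st[st$chrom == ch, , drop = FALSE]
      v <- IRanges::Views(nc$covs[[ch]],
                          start = s$center - flank + 1,
                          end = s$center + flank + 1)
      m <- as.matrix(v)
      neg <- s$strand == "-"
      if (any(neg)) m[neg, ] <- m[neg, width:1, drop = FALSE]
      acc <- acc + colSums(m)
    }
    site_mean <- acc / nrow(st) / nc$gmean
    ub <- sort(unique(bin_of))
    tibble(
      sample_id = sid, condition = cond,
      offset = as.double(ub * step),
      occupancy = vapply(ub, function(b) mean(site_mean[bin_of == b]), 0)
    )
  })
  by_sample <- bind_rows(curves)
  profile <- by_sample |>
    group_by(.data$condition, .data$offset) |>
    summarise(occupancy = mean(.data$occupancy),
              n_samples = dplyr::n(), .groups = "drop") |>
    arrange(.data$condition, .data$offset)
  structure(
    list(profile = profile, by_sample = by_sample, n_sites = nrow(st),
         flank = flank, step = step,
         tf_name = unique(sites$tf_name)[1] %||% NA_character_),
    class = "cfdna_profile"
  )
}

#' @export
print.cfdna_profile <- function(x, ...) {
  cat(sprintf(
    "Aggregate cfDNA occupancy profile: %s, %d sites, flank %d bp, step %d bp\n",
    x$tf_name, x$n_sites, x$flank, x$step
  ))
  print(x$profile, ...)
  invisible(x)
}

#' TF activity scores from binding-site center read depth
#'
#' For each sample, the activity score is the mean depth-normalized coverage
#' of nucleosome-protected fragments in a `+/- half_width` bp window around
#' the site center, averaged over sites with equal weight. Coverage is
#' normalized to a genome-wide mean of 1, so a uniform track scores exactly
#' 1. Higher center read depth indicates less TF binding (and predicts less
#' expression of the TF's program); an active TF leaves a footprint dip, so
#' the score decreases with TF activity.
#'
#' @param fragments Fragment tibble (one or more samples).
#' @param sites Site tibble.
#' @param chrom_sizes Chromosome-sizes tibble.
#' @param half_width Half-width of the center window in bp (default 15; 0
#'   scores the single center base).
#' @param min_len,max_len Length filter applied before scoring (defaults
#'   120/180); `NULL` to skip.
#' @return A tibble: `sample_id`, `condition`, `tf_name`, `score`, `n_sites`.
#' @export
tfbs_center_depth <- function(fragments, sites, chrom_sizes, half_width = 15,
                              min_len = 120, max_len = 180) {
  .check_fragments(fragments)
  .check_chrom_sizes(chrom_sizes)
  if (nrow(sites) == 0) abort("no binding sites supplied")
  if (!is.null(min_len)) {
    fragments <- filter_by_length(fragments, min_len, max_len %||% Inf)
  }
  sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  st <- sites |>
    mutate(.size = sizes[.data$chrom]) |>
    filter(.data$center - half_width >= 0,
           .data$center + half_width < .data$.size)
  if (nrow(st) == 0) abort("no usable sites after clipping at chromosome ends")
  key <- distinct(fragments, .data$sample_id, .data$condition)
  rows <- purrr::map2(key$sample_id, key$condition, function(sid, cond) {
    fr <- fragments[fragments$sample_id == sid, , drop = FALSE]
    nc <- .normalized_coverage(fr, sizes, sid)
    means <- purrr::map(unique(st$chrom), function(ch) {
      s <- st[st$chrom == ch, , drop = FALSE]
      v <- IRanges::Views(nc$covs[[ch]],
                          start = s$center - half_width + 1,
                          end = s$center + half_width + 1)
      IRanges::viewMeans(v)
    })
    tibble(sample_id = sid, condition = cond,
           tf_name = unique(st$tf_name)[1] %||% NA_character_,
           score = mean(unlist(means)) / nc$gmean,
           n_sites = nrow(st))
  })
  bind_rows(rows)
}

#' Read a gene-by-sample expression table
#'
#' TSV whose first column is the gene identifier and remaining columns are
#' samples (TMM-FPKM semantics; values are consumed as provided, never
#' re-normalized here).
#'
#' @param path Expression TSV.
#' @return A long tibble: `gene`, `sample_id`, `expression`.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(df)[1] <- "gene"
  df <- mutate(df, across(-"gene", as.numeric))
  tidyr::pivot_longer(df, -"gene", names_to = "sample_id",
                      values_to = "expression")
}

.cor_row <- function(x, y, method, extra = list()) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need >= 3 paired samples")
  if (sd(x) == 0 || sd(y) == 0) {
    est <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = method,
                                    alternative = "two.sided"))
    est <- unname(ct$estimate); p <- ct$p.value
  }
  as_tibble(c(extra, list(method = method, estimate = est, p.value = p, n = n)))
}

#' Correlate TF activity scores with gene expression
#'
#' Relates per-sample center-depth activity scores of a TF to the expression
#' of a gene (typically the TF's own gene) in timepoint-matched tumors. With
#' the convention that higher center read depth means less TF binding, an
#' informative TF shows a negative correlation.
#'
#' @param scores Activity-score tibble from [tfbs_center_depth()].
#' @param expression Long expression tibble from [read_expression()].
#' @param gene Gene to correlate against; defaults to the TF name in `scores`.
#' @param method `"spearman"` (rank, default) or `"pearson"` (linear).
#' @return A one-row tibble: `tf_name`, `gene`, `method`, `estimate`,
#'   `p.value`, `n`. The estimate is `NA` when either vector is constant.
#' @export
correlate_activity_expression <- function(scores, expression, gene = NULL,
                                          method = c("spearman", "pearson")) {
  method <- match.arg(method)
  gene <- gene %||% unique(scores$tf_name)[1]
  ex <- filter(expression, .data$gene == !!gene)
  if (nrow(ex) == 0) abort(paste0("gene not found in expression table: ", gene))
  d <- inner_join(scores, ex, by = "sample_id")
  .cor_row(d$score, d$expression, method,
           extra = list(tf_name = unique(scores$tf_name)[1], gene = gene))
}

#' Correlate TF activity scores with cfDNA tumor fraction
#'
#' Pearson correlation between per-sample center-depth scores and externally
#' estimated tumor fractions, optionally restricted to one timepoint. A TF
#' whose program is active in the tumor shows anticorrelation (deeper
#' footprint, hence lower center depth, at higher tumor fraction).
#'
#' @param scores Activity-score tibble.
#' @param tumor_fractions Tibble with `sample_id` and `tumor_fraction`.
#' @param timepoint Optional condition label to subset scores to.
#' @return A one-row tibble: `tf_name`, `timepoint`, `method`, `estimate`,
#'   `p.value`, `n`.
#' @export
correlate_with_tumor_fraction <- function(scores, tumor_fractions,
                                          timepoint = NULL) {
  if (!is.null(timepoint)) {
    scores <- filter(scores, .data$condition == timepoint)
  }
  d <- inner_join(scores, tumor_fractions, by = "sample_id")
  .cor_row(d$score, d$tumor_fraction, "pearson",
           extra = list(tf_name = unique(scores$tf_name)[1],
                        timepoint = timepoint %||% "all"))
}

#' Compare TF activity between clinical groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test of activity scores
#' between two groups (e.g., platinum-sensitive vs platinum-resistant),
#' optionally restricted to one timepoint. The exact distribution is used for
#' small, tie-free samples; the normal approximation with tie correction
#' otherwise.
#'
#' @param scores Activity-score tibble carrying a grouping column.
#' @param group Name of the grouping column (default `"platinum_status"`).
#' @param timepoint Optional condition label to subset to.
#' @return A one-row tibble: the two group labels and sizes, group medians,
#'   the U statistic (for the first group, in label sort order) and the
#'   two-sided p-value.
#' @export
compare_groups <- function(scores, group = "platinum_status",
                           timepoint = NULL) {
  if (!group %in% names(scores)) {
    abort(paste0("grouping column not found: ", group))
  }
  if (!is.null(timepoint)) {
    scores <- filter(scores, .data$condition == timepoint)
  }
  g <- as.character(scores[[group]])
  lv <- sort(unique(g))
  if (length(lv) != 2) abort("need exactly 2 non-empty groups")
  x <- scores$score[g == lv[1]]
  y <- scores$score[g == lv[2]]
  if (length(x) == 0 || length(y) == 0) abort("a group is empty")
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  tibble(
    group1 = lv[1], group2 = lv[2],
    n1 = length(x), n2 = length(y),
    median1 = median(x), median2 = median(y),
    u_statistic = unname(wt$statistic),
    p.value = wt$p.value
  )
}
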