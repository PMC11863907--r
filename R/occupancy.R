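# Genome tiling, depth-normalized occupancy tracks, and region-level
# GC / copy-number confounder checks.

#' Tile the genome into fixed windows
#'
#' Partitions each chromosome into consecutive non-overlapping windows of
#' `bin_size` bp (the final window of a chromosome may be shorter).
#'
#' @param chrom_sizes Tibble with columns `chrom`, `size`.
#' @param bin_size Window width in bp (default 10,000).
#' @return A tibble of windows: `bin_id` (1-based ordinal over the whole
#'   genome), `chrom`, `start`, `end` (0-based half-open) and `width`.
#' @export
tile_genome <- function(chrom_sizes, bin_size = 10000) {
  .check_chrom_sizes(chrom_sizes)
  if (bin_size < 1) abort("bin_size must be >= 1")
  per <- purrr::map2(chrom_sizes$chrom, chrom_sizes$size, function(ch, sz) {
    starts <- seq(0, sz - 1, by = bin_size)
    tibble(chrom = ch, start = starts, end = pmin(starts + bin_size, sz))
  })
  bind_rows(per) |>
    mutate(bin_id = dplyr::row_number(), width = .data$end - .data$start) |>
    select("bin_id", "chrom", "start", "end", "width")
}

# Per-chromosome coverage Rle over full chromosome length for one sample's
# fragments. `sizes` is a named vector chrom -> length.
.coverage_rle <- function(fragments, sizes) {
  covs <- lapply(names(sizes), function(ch) {
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(fr) == 0) {
      S4Vectors::Rle(0L, sizes[[ch]])
    } else {
      IRanges::coverage(IRanges::IRanges(start = fr$start + 1, end = fr$end),
                        width = sizes[[ch]])
    }
  })
  names(covs) <- names(sizes)
  covs
}

.bin_sizes <- function(bins) {
  s <- bins |>
    group_by(.data$chrom) |>
    summarise(size = max(.data$end), .groups = "drop")
  setNames(s$size, s$chrom)
}

#' Compute a windowed cfDNA occupancy track
#'
#' For every sample present in `fragments`, computes mean per-bp fragment
#' coverage within each window: the sum over fragments of their overlap with
#' the window, divided by window width. Fragments spanning window boundaries
#' contribute to each window in proportion to the overlap. Values are
#' unnormalized; see [normalize_track()]. For nucleosome-occupancy analyses
#' the input should already be length-filtered to 120-180 bp.
#'
#' @param fragments Fragment tibble (may contain several samples).
#' @param bins Window tibble from [tile_genome()].
#' @return A long tibble: `sample_id`, `condition`, `bin_id`, `chrom`,
#'   `start`, `end`, `width`, `value`.
#' @export
compute_occupancy <- function(fragments, bins) {
  .check_fragments(fragments)
  sizes <- .bin_sizes(bins)
  bad <- setdiff(unique(fragments$chrom), names(sizes))
  if (length(bad) > 0) {
    abort(paste0("fragments on chromosome(s) not covered by bins: ",
                 paste(bad, collapse = ", ")))
  }
  key <- distinct(fragments, .data$sample_id, .data$condition)
  if (anyDuplicated(key$sample_id)) {
    abort("a sample_id appears with more than one condition label")
  }
  per_sample <- purrr::map2(key$sample_id, key$condition, function(sid, cond) {
    fr <- fragments[fragments$sample_id == sid, , drop = FALSE]
    covs <- .coverage_rle(fr, sizes)
    vals <- purrr::map(names(sizes), function(ch) {
      b <- bins[bins$chrom == ch, , drop = FALSE]
      v <- IRanges::Views(covs[[ch]], start = b$start + 1, end = b$end)
      tibble(bin_id = b$bin_id, value = IRanges::viewMeans(v))
    })
    bind_rows(vals) |>
      mutate(sample_id = sid, condition = cond)
  })
  bind_rows(per_sample) |>
    inner_join(bins, by = "bin_id") |>
    select("sample_id", "condition", "bin_id", "chrom", "start", "end",
           "width", "value") |>
    arrange(.data$sample_id, .data$bin_id)
}

#' Normalize an occupancy track by sequencing depth
#'
#' Divides every window value of a sample by that sample's width-weighted
#' genome-wide mean coverage (the depth constant), so the normalized track
#' has width-weighted mean exactly 1 and is comparable across samples of
#' different sequencing depth.
#'
#' @param occupancy Unnormalized occupancy tibble from [compute_occupancy()].
#' @return The occupancy tibble with `value` depth-normalized and a new
#'   `depth_constant` column (the divisor, per sample).
#' @export
normalize_track <- function(occupancy) {
  if ("depth_constant" %in% names(occupancy)) {
    abort("track appears to be normalized already (depth_constant present)")
  }
  out <- occupancy |>
    group_by(.data$sample_id) |>
    mutate(depth_constant = weighted.mean(.data$value, .data$width)) |>
    ungroup()
  if (any(out$depth_constant <= 0)) {
    bad <- unique(out$sample_id[out$depth_constant <= 0])
    abort(paste0("no coverage for sample(s): ", paste(bad, collapse = ", ")))
  }
  mutate(out, value = .data$value / .data$depth_constant)
}

#' Write a normalized occupancy track as bedGraph
#'
#' @param occupancy Occupancy tibble for one sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(occupancy, path) {
  if (length(unique(occupancy$sample_id)) > 1) {
    abort("write_bedgraph() takes a single sample's track")
  }
  readr::write_tsv(
    occupancy |>
      select("chrom", "start", "end", "value") |>
      mutate(start = format(.data$start, scientific = FALSE, trim = TRUE),
             end = format(.data$end, scientific = FALSE, trim = TRUE)),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read a bedGraph occupancy track
#'
#' Rebuilds an occupancy tibble from a bedGraph written by
#' [write_bedgraph()], re-deriving window ordinals from genomic order.
#'
#' @param path bedGraph file.
#' @param sample_id,condition Labels to attach.
#' @return An occupancy tibble (without `depth_constant`).
#' @export
read_bedgraph <- function(path, sample_id = "sample", condition = "unknown") {
  .check_condition(condition)
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "cddd", progress = FALSE)
  df |>
    .sort_genomic() |>
    mutate(bin_id = dplyr::row_number(), width = .data$end - .data$start,
           sample_id = sample_id, condition = condition) |>
    select("sample_id", "condition", "bin_id", "chrom", "start", "end",
           "width", "value")
}

#' Per-region GC content from a genome FASTA
#'
#' GC fraction of each region as (G + C) / (A + C + G + T),
#' case-insensitive; ambiguous bases (N) are excluded from the denominator.
#' Used as a post-hoc confounder check on differential-occupancy regions.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param fasta Path to a genome FASTA.
#' @return `regions` with a `gc` column added; attribute `mean_gc` holds the
#'   width-weighted region-set mean.
#' @export
gc_content <- function(regions, fasta) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  bad <- setdiff(unique(regions$chrom), names(genome))
  if (length(bad) > 0) {
    abort(paste0("region chromosome(s) absent from FASTA: ",
                 paste(bad, collapse = ", ")))
  }
  lens <- Biostrings::width(genome)[match(regions$chrom, names(genome))]
  over <- which(regions$end > lens | regions$start < 0)
  if (length(over) > 0) {
    i <- over[1]
    abort(sprintf("region %s:%d-%d extends beyond sequence end (%d)",
                  regions$chrom[i], regions$start[i], regions$end[i], lens[i]))
  }
  seqs <- Biostrings::DNAStringSet(genome[regions$chrom],
                                   start = regions$start + 1,
                                   end = regions$end)
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  acgt <- rowSums(freq)
  gc <- ifelse(acgt > 0, (freq[, "C"] + freq[, "G"]) / acgt, NA_real_)
  out <- mutate(regions, gc = as.double(gc))
  w <- regions$end - regions$start
  attr(out, "mean_gc") <- weighted.mean(gc, w, na.rm = TRUE)
  out
}

#' Read CNV segments
#'
#' Tab-separated with required header `chrom`, `start`, `end`, `log2_ratio`
#' (0-based half-open coordinates).
#'
#' @param path Segments TSV.
#' @return A tibble of segments.
#' @export
read_cnv_segments <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "d", end = "d", log2_ratio = "d"
  ), progress = FALSE)
  need <- c("chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(df))) {
    abort("CNV segment file must have header columns chrom, start, end, log2_ratio")
  }
  if (any(df$end <= df$start)) abort("CNV segment with end <= start")
  as_tibble(df[need])
}

#' Fraction of regions overlapping amplified CNV segments
#'
#' Fraction of regions that overlap, by at least 1 bp, any copy-number
#' segment with `log2_ratio` strictly greater than `log2_min`. Reported in
#' the source analysis as a confounder check (differential-occupancy regions
#' vs amplifications with log2 fold change > 1).
#'
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @param segments CNV segment tibble from [read_cnv_segments()].
#' @param log2_min Amplification threshold (strict `>`; default 1).
#' @return A single numeric fraction in `[0, 1]`.
#' @export
region_cnv_overlap <- function(regions, segments, log2_min = 1.0) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) == 0) abort("no regions supplied")
  amp <- segments[segments$log2_ratio > log2_min, , drop = FALSE]
  if (nrow(amp) == 0) return(0)
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1, regions$end))
  sg <- GenomicRanges::GRanges(amp$chrom,
                               IRanges::IRanges(amp$start + 1, amp$end))
  # segments on chromosomes absent from the regions are a valid input
  hits <- suppressWarnings(GenomicRanges::countOverlaps(rg, sg)) > 0
  mean(hits)
}
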