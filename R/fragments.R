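# Fragment input, nucleosome-protection length filtering and
# fragment-size-distribution metrics.

#' Read aligned cfDNA fragments
#'
#' Reads one plasma sample's sequenced fragments from a fragment BED file
#' (3+ columns, 0-based half-open, no header), a headered TSV with columns
#' `chrom`, `start`, `end`, or a coordinate-sorted BAM of paired reads. cfDNA
#' is double-stranded, so fragments are strand-agnostic and any strand column
#' is ignored.
#'
#' For BAM input one fragment is emitted per properly-paired template
#' (read 1 of each pair), spanning from the leftmost mate start over the
#' absolute template length. Duplicate, secondary, supplementary and
#' low-mapping-quality reads are excluded.
#'
#' @param path Input file.
#' @param format One of `"bed"`, `"tsv"`, `"bam"`. Default guesses from the
#'   file extension.
#' @param sample_id Sample identifier attached to every record.
#' @param condition Treatment timepoint: `"pre"`, `"post"`, `"progression"`
#'   or `"unknown"`.
#' @param chrom_sizes Optional chromosome-sizes tibble (`chrom`, `size`); when
#'   supplied, a fragment on an unlisted chromosome is an error.
#' @param min_mapq Minimum mapping quality for BAM reads (default 20).
#' @return A tibble with columns `chrom`, `start`, `end`, `length`,
#'   `sample_id`, `condition`, sorted by (chrom, start). Coordinates are
#'   0-based half-open; `length = end - start`.
#' @export
read_fragments <- function(path, format = NULL, sample_id = "sample",
                           condition = "unknown", chrom_sizes = NULL,
                           min_mapq = 20) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  .check_condition(condition)
  format <- format %||% switch(tolower(tools::file_ext(path)),
    bam = "bam", tsv = "tsv", "bed"
  )
  format <- match.arg(format, c("bed", "tsv", "bam"))
  df <- switch(format,
    bed = .read_fragments_bed(path),
    tsv = .read_fragments_tsv(path),
    bam = .read_fragments_bam(path, min_mapq)
  )
  if (!is.null(chrom_sizes)) {
    .check_chrom_sizes(chrom_sizes)
    bad <- setdiff(unique(df$chrom), chrom_sizes$chrom)
    if (length(bad) > 0) {
      abort(sprintf(
        "fragment chromosome(s) absent from chromosome-sizes table: %s",
        paste(bad, collapse = ", ")
      ))
    }
  }
  if (nrow(df) > 0 && any(df$end <= df$start)) {
    i <- which(df$end <= df$start)[1]
    abort(sprintf("fragment %d has end <= start (%s:%d-%d)",
                  i, df$chrom[i], df$start[i], df$end[i]))
  }
  df |>
    mutate(
      length = .data$end - .data$start,
      sample_id = sample_id,
      condition = condition
    ) |>
    .sort_genomic(chrom_sizes)
}

.split_table_lines <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  list(fields = strsplit(trimws(lines[keep]), "[ \t]+"), lineno = which(keep))
}

.parse_coord <- function(x, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v < 0 | v != floor(v))
  if (length(bad) > 0) {
    abort(sprintf("line %d: unparseable %s field '%s'",
                  lineno[bad[1]], what, x[bad[1]]))
  }
  v
}

.read_fragments_bed <- function(path) {
  tl <- .split_table_lines(path)
  if (length(tl$fields) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  nf <- lengths(tl$fields)
  if (any(nf < 3)) {
    abort(sprintf("line %d: expected >= 3 BED fields, found %d",
                  tl$lineno[which(nf < 3)[1]], min(nf)))
  }
  tibble(
    chrom = vapply(tl$fields, `[[`, "", 1),
    start = .parse_coord(vapply(tl$fields, `[[`, "", 2), tl$lineno, "start"),
    end   = .parse_coord(vapply(tl$fields, `[[`, "", 3), tl$lineno, "end")
  )
}

.read_fragments_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    abort("TSV fragment input must have header columns chrom, start, end")
  }
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  lineno <- seq_len(nrow(df)) + 1L  # header is line 1
  tibble(
    chrom = df$chrom,
    start = .parse_coord(df$start, lineno, "start"),
    end   = .parse_coord(df$end, lineno, "end")
  )
}

.read_fragments_bam <- function(path, min_mapq) {
  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE, isUnmappedQuery = FALSE,
    hasUnmappedMate = FALSE, isSecondaryAlignment = FALSE,
    isDuplicate = FALSE, isSupplementaryAlignment = FALSE,
    isFirstMateRead = TRUE
  )
  p <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "pos", "mpos", "isize", "mapq")
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$isize) & b$isize != 0 &
    (!is.na(b$mapq) & b$mapq >= min_mapq)
  if (!any(keep)) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  left <- pmin(b$pos[keep], b$mpos[keep])
  tibble(
    chrom = as.character(b$rname[keep]),
    start = as.double(left - 1L),
    end = as.double(left - 1L + abs(b$isize[keep]))
  )
}

#' Filter fragments by nucleosome-protection length
#'
#' Retains fragments whose length lies in `[min_len, max_len]`, bounds
#' inclusive. The 120-180 bp default selects nucleosome-protected cfDNA for
#' occupancy analysis.
#'
#' @param fragments Fragment tibble from [read_fragments()].
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The filtered fragment tibble, original order preserved.
#' @export
filter_by_length <- function(fragments, min_len = 120, max_len = 180) {
  .check_fragments(fragments)
  if (min_len > max_len) abort("min_len must be <= max_len")
  filter(fragments, .data$length >= min_len, .data$length <= max_len)
}

#' Fragment-size distribution
#'
#' Counts fragments per integer length over 1-bp bins with support
#' `[1, max_len]`. Fragments longer than `max_len` accumulate in a single
#' open overflow bin reported as length `max_len + 1`; that bin lies outside
#' every peak-search window and is excluded from peak detection, but it is
#' included in the count total so the histogram always conserves mass.
#'
#' @param fragments Fragment tibble, or an integer vector of lengths.
#' @param max_len Upper end of the 1-bp support (default 500).
#' @return A tibble with columns `length` (`1:(max_len + 1)`) and `count`;
#'   attribute `n` holds the total number of fragments.
#' @export
size_histogram <- function(fragments, max_len = 500L) {
  lens <- if (is.data.frame(fragments)) {
    .check_fragments(fragments)
    fragments$length
  } else {
    fragments
  }
  if (length(lens) > 0 && any(lens < 1)) abort("fragment lengths must be >= 1")
  counts <- tabulate(pmin(as.integer(lens), max_len + 1L), nbins = max_len + 1L)
  out <- tibble(length = seq_len(max_len + 1L), count = counts)
  attr(out, "n") <- length(lens)
  out
}

.window_peak <- function(hist, window) {
  sub <- hist[hist$length >= window[1] & hist$length <= window[2], ]
  if (nrow(sub) == 0 || all(sub$count == 0)) {
    return(list(peak = NA_integer_, height = NA_real_))
  }
  i <- which.max(sub$count)  # first maximum = smallest length on ties
  list(peak = sub$length[i], height = as.double(sub$count[i]))
}

#' Fragment-size peak positions and peak-height ratios
#'
#' Locates the modal fragment length inside three disjoint search windows --
#' transcription-factor protection (~50 bp), nucleosome core particle
#' (~150 bp) and chromatosome (~165 bp) -- and reports the
#' chromatosome/nucleosome and chromatosome/TF peak-height ratios used as
#' tumor-burden metrics. Ties within a window resolve to the smallest length.
#' A window with no counts yields `NA` for its peak and for every ratio that
#' depends on it.
#'
#' @param hist Size-distribution tibble from [size_histogram()].
#' @param tf_window,core_window,chromatosome_window Integer length-range
#'   `c(lo, hi)` (bp) searched for each peak. Defaults isolate the three
#'   protection modes; all are configurable because real peak positions are
#'   only approximate.
#' @return A one-row tibble: `chromatosome_peak_bp`, `nucleosome_peak_bp`,
#'   `tf_peak_bp`, the three peak heights, `ratio_chromatosome_nucleosome`
#'   and `ratio_chromatosome_tf`.
#' @export
peak_ratio_metrics <- function(hist, tf_window = c(30, 80),
                               core_window = c(140, 157),
                               chromatosome_window = c(158, 180)) {
  stopifnot(all(c("length", "count") %in% names(hist)))
  wins <- list(tf = tf_window, core = core_window, chromatosome = chromatosome_window)
  for (w in wins) {
    if (length(w) != 2 || w[1] > w[2]) abort("each window must be c(lo, hi) with lo <= hi")
  }
  ivs <- do.call(rbind, wins)
  o <- order(ivs[, 1])
  if (any(ivs[o, 1][-1] <= ivs[o, 2][-length(wins)])) {
    abort("peak search windows must be disjoint")
  }
  tfp <- .window_peak(hist, tf_window)
  cor_ <- .window_peak(hist, core_window)
  chr <- .window_peak(hist, chromatosome_window)
  ratio <- function(a, b) {
    if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
  }
  tibble(
    chromatosome_peak_bp = chr$peak,
    nucleosome_peak_bp = cor_$peak,
    tf_peak_bp = tfp$peak,
    chromatosome_height = chr$height,
    nucleosome_height = cor_$height,
    tf_height = tfp$height,
    ratio_chromatosome_nucleosome = ratio(chr$height, cor_$height),
    ratio_chromatosome_tf = ratio(chr$height, tfp$height)
  )
}

#' Write fragments as BED3
#'
#' @param fragments Fragment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  .check_fragments(fragments)
  readr::write_tsv(
    fragments |>
      select("chrom", "start", "end") |>
      mutate(start = format(.data$start, scientific = FALSE, trim = TRUE),
             end = format(.data$end, scientific = FALSE, trim = TRUE)),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Write fragments as paired-end SAM
#'
#' Emits one proper read pair per fragment (fixed-length reads anchored at
#' the fragment ends, template length equal to the fragment length) so that
#' simulated cohorts can exercise the BAM input path after conversion with
#' `Rsamtools::asBam()` or `samtools`.
#'
#' @param fragments Fragment tibble.
#' @param path Output SAM path.
#' @param chrom_sizes Chromosome-sizes tibble for the SAM header.
#' @param read_len Read length; capped at the fragment length.
#' @return `path`, invisibly.
#' @export
write_fragments_sam <- function(fragments, path, chrom_sizes, read_len = 50L) {
  .check_fragments(fragments)
  .check_chrom_sizes(chrom_sizes)
  fr <- .sort_genomic(fragments, chrom_sizes)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom_sizes$chrom, as.integer(chrom_sizes$size))
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(fr) > 0) {
    rl <- pmin(as.integer(read_len), fr$length)
    pos1 <- as.integer(fr$start + 1L)        # leftmost mate, 1-based
    pos2 <- as.integer(fr$end - rl)          # rightmost mate start - 1 (0-based)
    qn <- sprintf("frag%06d", seq_len(nrow(fr)))
    seqs <- strrep("A", rl)
    quals <- strrep("I", rl)
    cig <- sprintf("%dM", rl)
    r1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                  qn, fr$chrom, pos1, cig, pos2 + 1L, fr$length, seqs, quals)
    r2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                  qn, fr$chrom, pos2 + 1L, cig, pos1, -fr$length, seqs, quals)
    # interleave, then re-sort lines by coordinate for SO:coordinate
    recs <- c(rbind(r1, r2))
    ord <- order(rep(match(fr$chrom, chrom_sizes$chrom), each = 2),
                 c(rbind(pos1, pos2 + 1L)))
    writeLines(recs[ord], con)
  }
  invisible(path)
}
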