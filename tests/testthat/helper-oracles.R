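# Independent brute-force oracles and in-code fixtures shared by the tests.

# Per-bp coverage vector for one chromosome: position i (1..size) counts the
# fragments whose half-open interval covers base i-1.
oracle_coverage_vector <- function(fragments, chrom, size) {
  v <- numeric(size)
  fr <- fragments[fragments$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(fr))) {
    a <- fr$start[i] + 1
    b <- fr$end[i]
    v[a:b] <- v[a:b] + 1
  }
  v
}

# Window-mean coverage by brute force over the per-bp vector.
oracle_bin_means <- function(fragments, bins) {
  vapply(seq_len(nrow(bins)), function(i) {
    v <- oracle_coverage_vector(fragments, bins$chrom[i],
                                max(bins$end[bins$chrom == bins$chrom[i]]))
    mean(v[(bins$start[i] + 1):bins$end[i]])
  }, 0)
}

# Center-depth score by brute force: per-bp coverage averaged in
# [center - hw, center + hw], normalized by the genome-wide per-bp mean,
# averaged over sites.
oracle_center_depth <- function(fragments, sites, chrom_sizes, hw) {
  covs <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    oracle_coverage_vector(fragments, chrom_sizes$chrom[i], chrom_sizes$size[i])
  })
  names(covs) <- chrom_sizes$chrom
  gmean <- sum(unlist(lapply(covs, sum))) / sum(chrom_sizes$size)
  per_site <- vapply(seq_len(nrow(sites)), function(i) {
    v <- covs[[sites$chrom[i]]]
    mean(v[(sites$center[i] - hw + 1):(sites$center[i] + hw + 1)])
  }, 0)
  mean(per_site) / gmean
}

# A small fragment tibble built in code.
make_fragments <- function(chrom, start, end, sample_id = "s1",
                           condition = "unknown") {
  tibble::tibble(
    chrom = chrom, start = as.double(start), end = as.double(end),
    length = as.integer(end - start),
    sample_id = sample_id, condition = condition
  )
}

# Random fragments on a toy genome, reproducibly.
random_fragments <- function(n, chrom_sizes, len_range = c(50, 300),
                             sample_id = "s1", condition = "unknown",
                             seed = 1) {
  set.seed(seed)
  ch <- sample(chrom_sizes$chrom, n, replace = TRUE,
               prob = chrom_sizes$size)
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  size <- chrom_sizes$size[match(ch, chrom_sizes$chrom)]
  start <- floor(runif(n) * (size - len))
  make_fragments(ch, start, start + len, sample_id, condition) |>
    dplyr::arrange(chrom, start)
}

write_lines_tmp <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_chrom_sizes <- function() {
  tibble::tibble(chrom = c("chrA", "chrB"), size = c(50000, 50000))
}
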