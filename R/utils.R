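#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data abort warn
#' @importFrom dplyr filter mutate arrange group_by summarise ungroup select
#'   left_join inner_join bind_rows n across all_of distinct pull rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rbinom sd cor.test wilcox.test weighted.mean
#'   setNames median
NULL

# Condition labels used throughout: treatment timepoints of a plasma sample.
.conditions <- c("pre", "post", "progression", "unknown")

.check_condition <- function(condition) {
  bad <- setdiff(unique(condition), .conditions)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown condition label(s): %s (expected one of %s)",
      paste(bad, collapse = ", "), paste(.conditions, collapse = ", ")
    ))
  }
  invisible(condition)
}

.check_chrom_sizes <- function(chrom_sizes) {
  stopifnot(is.data.frame(chrom_sizes), all(c("chrom", "size") %in% names(chrom_sizes)))
  if (any(chrom_sizes$size < 1)) abort("chromosome sizes must be >= 1")
  if (anyDuplicated(chrom_sizes$chrom)) abort("duplicated chromosome names in chrom_sizes")
  chrom_sizes
}

.check_fragments <- function(fragments) {
  need <- c("chrom", "start", "end", "length", "sample_id", "condition")
  miss <- setdiff(need, names(fragments))
  if (length(miss) > 0) {
    abort(paste0("fragment table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(fragments)
}

# Order chromosomes by their order in a sizes table when available, else
# alphanumerically; keeps genomic sorting deterministic.
.chrom_levels <- function(chroms, chrom_sizes = NULL) {
  if (!is.null(chrom_sizes)) {
    lev <- chrom_sizes$chrom
    extra <- setdiff(unique(chroms), lev)
    c(lev, sort(extra))
  } else {
    sort(unique(as.character(chroms)))
  }
}

.sort_genomic <- function(df, chrom_sizes = NULL) {
  lev <- .chrom_levels(df$chrom, chrom_sizes)
  df |>
    mutate(.ord = match(.data$chrom, lev)) |>
    arrange(.data$.ord, .data$start) |>
    select(-".ord")
}

#' Read a chromosome-sizes table
#'
#' Two-column headerless TSV in the standard `.chrom.sizes` dialect:
#' chromosome name and length in bp.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = readr::cols(chrom = "c", size = "d"),
                        progress = FALSE)
  .check_chrom_sizes(df)
  as_tibble(df)
}
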