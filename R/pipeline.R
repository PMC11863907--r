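# End-to-end orchestration: fragments -> occupancy -> differential regions
# -> TFBS profiles and activity scores -> machine-readable report.

#' Read a sample sheet
#'
#' TSV with header; required columns `sample_id`, `condition`, `path`
#' (fragment file per sample); optional `platinum_status`, `tumor_fraction`,
#' `target_coverage`, `format`.
#'
#' @param path Sample sheet TSV.
#' @param base_dir Directory against which relative fragment paths are
#'   resolved (default: the sheet's directory).
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path, base_dir = dirname(path)) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("sample_id", "condition", "path")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("duplicate sample_id in sample sheet: ",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]),
                       collapse = ", ")))
  }
  .check_condition(df$condition)
  df$path <- ifelse(file.exists(df$path), df$path,
                    file.path(base_dir, df$path))
  as_tibble(df)
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML run configuration (or takes an equivalent list), fills in the
#' published analysis defaults -- 10-kb windows, 120-180 bp fragment filter,
#' stability threshold 0.5, relative-change threshold 0.4 -- and checks every
#' field, naming the offending field in each error.
#'
#' Recognized fields: `sample_sheet` (required), `chrom_sizes` (required),
#' `bin_size`, `min_len`, `max_len`, `rsd_max`, `change_min`, `tfs` (list of
#' `name`, `sites`, optional `top_fraction`, `half_width`, `flank`, `step`),
#' `expression`, `cnv_segments`, `fasta`, `out_dir`, `seed`.
#'
#' @param config Path to a YAML file, or a named list.
#' @param base_dir Directory for resolving relative paths (default: the
#'   config file's directory, or the working directory for a list).
#' @return A validated list of class `cfdna_run_config`.
#' @export
validate_config <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    base_dir <- base_dir %||% dirname(config)
    config <- yaml::read_yaml(config)
  }
  base_dir <- base_dir %||% "."
  stopifnot(is.list(config))
  defaults <- list(bin_size = 10000, min_len = 120, max_len = 180,
                   rsd_max = 0.5, change_min = 0.4, tfs = list(),
                   expression = NULL, cnv_segments = NULL, fasta = NULL,
                   out_dir = "cfdnafoot_out", seed = 1L)
  for (nm in names(defaults)) {
    config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  }
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base_dir, p)
  }
  for (nm in c("sample_sheet", "chrom_sizes", "expression", "cnv_segments",
               "fasta")) {
    config[[nm]] <- resolve(config[[nm]])
  }
  if (is.null(config$sample_sheet)) abort("config field 'sample_sheet' is required")
  if (is.null(config$chrom_sizes)) abort("config field 'chrom_sizes' is required")
  for (nm in c("sample_sheet", "chrom_sizes", "expression", "cnv_segments",
               "fasta")) {
    p <- config[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("config field '%s': file not found: %s", nm, p))
    }
  }
  for (nm in c("bin_size", "min_len", "max_len", "rsd_max", "change_min")) {
    v <- config[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0) {
      abort(sprintf("config field '%s' must be a positive number", nm))
    }
  }
  if (config$min_len > config$max_len) {
    abort("config field 'min_len' must be <= 'max_len'")
  }
  config$tfs <- purrr::map(config$tfs, function(tf) {
    if (is.null(tf$name)) abort("config field 'tfs': each entry needs a 'name'")
    if (is.null(tf$sites)) {
      abort(sprintf("config field 'tfs' (%s): 'sites' BED path required", tf$name))
    }
    tf$sites <- resolve(tf$sites)
    if (!file.exists(tf$sites)) {
      abort(sprintf("config field 'tfs' (%s): file not found: %s",
                    tf$name, tf$sites))
    }
    tf$half_width <- tf$half_width %||% 15
    tf$flank <- tf$flank %||% 2000
    tf$step <- tf$step %||% 10
    if (!is.null(tf$top_fraction) &&
        (tf$top_fraction <= 0 || tf$top_fraction > 1)) {
      abort(sprintf("config field 'tfs' (%s): top_fraction must be in (0, 1]",
                    tf$name))
    }
    tf
  })
  # sample sheet is validated now so errors surface at config time
  sheet <- read_sample_sheet(config$sample_sheet)
  missing_frag <- sheet$path[!file.exists(sheet$path)]
  if (length(missing_frag) > 0) {
    abort(paste0("fragment file(s) not found: ",
                 paste(missing_frag, collapse = ", ")))
  }
  config$sheet <- sheet
  structure(config, class = "cfdna_run_config")
}

.log_stage <- function(stage, ...) {
  message(sprintf("[cfdnafoot] %s: %s", stage, sprintf(...)))
}

.md5 <- function(paths) {
  h <- tools::md5sum(unlist(paths))
  as.list(setNames(unname(h), basename(names(h))))
}

#' Run the full cfDNA footprint analysis
#'
#' Executes the pipeline stages in order -- fragment input and length
#' filtering, fragment-size peak metrics, windowed depth-normalized
#' occupancy, differential-occupancy calling (pre vs post; progression
#' samples are profiled but never used for calling), confounder checks (GC
#' content, CNV overlap) when a FASTA / segment file is configured, and
#' per-TF binding-site analysis (aggregate profiles, center-depth activity
#' scores, expression / tumor-fraction correlations and platinum-group
#' comparison when the inputs are available) -- writing every intermediate
#' artifact plus a machine-readable JSON report. The report contains no
#' timestamps, so identical inputs reproduce an identical report.
#'
#' @param config A `cfdna_run_config` from [validate_config()], a YAML path,
#'   or a named list.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return The run report (named list), invisibly; written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "cfdna_run_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = list(
    bin_size = config$bin_size, min_len = config$min_len,
    max_len = config$max_len, rsd_max = config$rsd_max,
    change_min = config$change_min, seed = config$seed
  ), stages = list())

  run_stage <- function(name, fn) {
    .log_stage(name, "started")
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    .log_stage(name, "done")
    res
  }

  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  sheet <- config$sheet

  fragments <- run_stage("fragments", function() {
    purrr::pmap(sheet, function(sample_id, condition, path, ...) {
      dots <- list(...)
      read_fragments(path, format = dots$format %||% NULL,
                     sample_id = sample_id, condition = condition,
                     chrom_sizes = chrom_sizes)
    }) |> bind_rows()
  })
  report$stages$fragments <- list(
    n_samples = nrow(sheet),
    n_fragments = nrow(fragments),
    inputs = .md5(sheet$path)
  )

  peaks <- run_stage("size_metrics", function() {
    sheet$sample_id |>
      purrr::map(function(sid) {
        h <- size_histogram(fragments[fragments$sample_id == sid, ])
        peak_ratio_metrics(h) |> mutate(sample_id = sid, .before = 1)
      }) |>
      bind_rows()
  })
  peaks_path <- file.path(out_dir, "peak_ratios.tsv")
  readr::write_tsv(peaks, peaks_path, progress = FALSE)
  report$stages$size_metrics <- list(
    table = basename(peaks_path),
    mean_ratio_chromatosome_nucleosome =
      mean(peaks$ratio_chromatosome_nucleosome, na.rm = TRUE),
    mean_ratio_chromatosome_tf =
      mean(peaks$ratio_chromatosome_tf, na.rm = TRUE),
    outputs = .md5(peaks_path)
  )

  occ <- run_stage("occupancy", function() {
    bins <- tile_genome(chrom_sizes, config$bin_size)
    fragments |>
      filter_by_length(config$min_len, config$max_len) |>
      compute_occupancy(bins) |>
      normalize_track()
  })
  bg_paths <- vapply(sheet$sample_id, function(sid) {
    p <- file.path(out_dir, paste0(sid, ".occupancy.bedGraph"))
    write_bedgraph(occ[occ$sample_id == sid, ], p)
    p
  }, "")
  report$stages$occupancy <- list(
    n_windows = length(unique(occ$bin_id)),
    depth_constants = as.list(setNames(
      unique(occ[c("sample_id", "depth_constant")])$depth_constant,
      unique(occ[c("sample_id", "depth_constant")])$sample_id
    )),
    outputs = .md5(bg_paths)
  )

  n_pre <- length(unique(occ$sample_id[occ$condition == "pre"]))
  n_post <- length(unique(occ$sample_id[occ$condition == "post"]))
  diff <- NULL
  if (n_pre >= 2 && n_post >= 2) {
    diff <- run_stage("differential", function() {
      call_differential(occ, rsd_max = config$rsd_max,
                        change_min = config$change_min)
    })
    regions_path <- file.path(out_dir, "differential_regions.bed")
    export_regions(diff, regions_path)
    stats_path <- file.path(out_dir, "window_stats.tsv")
    readr::write_tsv(diff$stats, stats_path, progress = FALSE)
    report$stages$differential <- list(
      n_gained = diff$n_gained, n_lost = diff$n_lost,
      n_stable_both = sum(diff$stats$stable_both),
      outputs = .md5(c(regions_path, stats_path))
    )
  } else {
    .log_stage("differential", "skipped (need >= 2 pre and >= 2 post samples)")
    report$stages$differential <- list(skipped = TRUE)
  }

  if (!is.null(config$fasta) && !is.null(diff) && nrow(diff$regions) > 0) {
    gc_check <- run_stage("gc_check", function() {
      reg <- gc_content(diff$regions, config$fasta)
      gw <- gc_content(
        diff$stats |> select("chrom", "start", "end"), config$fasta
      )
      list(regions = attr(reg, "mean_gc"), genome = attr(gw, "mean_gc"))
    })
    report$stages$gc_check <- list(
      mean_gc_differential_regions = gc_check$regions,
      mean_gc_genome_windows = gc_check$genome
    )
  }

  if (!is.null(config$cnv_segments) && !is.null(diff) &&
      nrow(diff$regions) > 0) {
    cnv <- run_stage("cnv_check", function() {
      region_cnv_overlap(diff$regions, read_cnv_segments(config$cnv_segments))
    })
    report$stages$cnv_check <- list(amplified_overlap_fraction = cnv)
  }

  if (length(config$tfs) > 0) {
    expression <- if (!is.null(config$expression)) {
      read_expression(config$expression)
    }
    tf_reports <- run_stage("tfbs", function() {
      purrr::map(config$tfs, function(tf) {
        sites <- load_sites(tf$sites, tf$name)
        if (!is.null(tf$top_fraction)) {
          sites <- select_top_fraction(sites, tf$top_fraction)
          write_sites_bed(
            sites, file.path(out_dir, paste0(tf$name, ".top_sites.bed"))
          )
        }
        prof <- aggregate_profile(fragments, sites, chrom_sizes,
                                  flank = tf$flank, step = tf$step,
                                  min_len = config$min_len,
                                  max_len = config$max_len)
        prof_path <- file.path(out_dir, paste0(tf$name, ".profile.tsv"))
        readr::write_tsv(prof$profile, prof_path, progress = FALSE)
        scores <- tfbs_center_depth(fragments, sites, chrom_sizes,
                                    half_width = tf$half_width,
                                    min_len = config$min_len,
                                    max_len = config$max_len)
        scores_path <- file.path(out_dir, paste0(tf$name, ".scores.tsv"))
        readr::write_tsv(scores, scores_path, progress = FALSE)
        out <- list(tf_name = tf$name, n_sites = prof$n_sites,
                    mean_score = mean(scores$score),
                    outputs = .md5(c(prof_path, scores_path)))
        if (!is.null(expression) && tf$name %in% expression$gene) {
          ce <- correlate_activity_expression(scores, expression, tf$name)
          out$expression_spearman <- list(estimate = ce$estimate,
                                          p.value = ce$p.value, n = ce$n)
        }
        if ("tumor_fraction" %in% names(sheet)) {
          tfr <- inner_join(
            scores, sheet |> select("sample_id", "tumor_fraction"),
            by = "sample_id"
          )
          if (sum(is.finite(tfr$tumor_fraction)) >= 3) {
            ct <- correlate_with_tumor_fraction(
              scores, sheet |> select("sample_id", "tumor_fraction")
            )
            out$tumor_fraction_pearson <- list(estimate = ct$estimate,
                                               p.value = ct$p.value, n = ct$n)
          }
        }
        if ("platinum_status" %in% names(sheet)) {
          sc2 <- inner_join(
            scores, sheet |> select("sample_id", "platinum_status"),
            by = "sample_id"
          )
          if (length(unique(sc2$platinum_status)) == 2) {
            mw <- compare_groups(sc2, "platinum_status")
            out$platinum_mann_whitney <- list(
              u_statistic = mw$u_statistic, p.value = mw$p.value,
              medians = list(mw$median1, mw$median2)
            )
          }
        }
        out
      })
    })
    report$stages$tfbs <- tf_reports
  } else {
    .log_stage("tfbs", "skipped (no TF site files configured)")
    report$stages$tfbs <- list(skipped = TRUE)
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .log_stage("report", "written to %s", report_path)
  invisible(report)
}
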