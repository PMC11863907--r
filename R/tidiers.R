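# broom-style accessors for fitted/called objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-occupancy call
#'
#' @param x A `cfdna_diff` object.
#' @param ... Unused.
#' @return The called regions as a tibble (one row per window): `bin_id`,
#'   `chrom`, `start`, `end`, `mean_pre`, `mean_post`, `rel_change`,
#'   `direction`.
#' @export
tidy.cfdna_diff <- function(x, ...) {
  x$regions
}

#' One-row summary of a differential-occupancy call
#'
#' @param x A `cfdna_diff` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_windows`, `n_stable_both`, `n_gained`,
#'   `n_lost`, `rsd_max`, `change_min`, `denominator`.
#' @export
glance.cfdna_diff <- function(x, ...) {
  tibble(
    n_windows = nrow(x$stats),
    n_stable_both = sum(x$stats$stable_both),
    n_gained = x$n_gained,
    n_lost = x$n_lost,
    rsd_max = x$rsd_max,
    change_min = x$change_min,
    denominator = x$denominator
  )
}

#' Tidy an aggregate binding-site profile
#'
#' @param x A `cfdna_profile` object.
#' @param ... Unused.
#' @return The per-condition profile tibble: `offset`, `condition`,
#'   `occupancy`, `n_samples`.
#' @export
tidy.cfdna_profile <- function(x, ...) {
  x$profile
}
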