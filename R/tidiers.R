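#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn mantel_test one-row tibble with `r_observed`, `p_value`,
#'   `n_permutations`, `seed`.
#' @param x a `mantel_result`.
#' @param ... unused.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(r_observed = x$r_observed, p_value = x$p_value,
         n_permutations = x$n_permutations, seed = x$seed)
}

#' @describeIn mantel_test alias of `tidy()` (the test has a single row of
#'   fit statistics).
#' @export
glance.mantel_result <- function(x, ...) tidy.mantel_result(x)

#' @describeIn ssr_summary per-region counts and densities as a tibble.
#' @param x an `ssr_summary`.
#' @param ... unused.
#' @export
tidy.ssr_summary <- function(x, ...) as_tibble(x$by_region)

#' @describeIn ssr_summary one-row genome-level overview.
#' @export
glance.ssr_summary <- function(x, ...) {
  dplyr::bind_cols(
    tibble(total = x$total, genome_length = x$genome_length,
           density_per_kb = x$density_per_kb$rounded),
    x$mono_composition
  )
}

#' @describeIn identity_matrix unique pairs as a tibble (`taxon_1`,
#'   `taxon_2`, `percent`, `compared_length`).
#' @param x an `identity_matrix`.
#' @param ... unused.
#' @export
tidy.identity_matrix <- function(x, ...) {
  taxa <- rownames(x$percent)
  pairs <- utils::combn(length(taxa), 2L)
  tibble(taxon_1 = taxa[pairs[1, ]], taxon_2 = taxa[pairs[2, ]],
         percent = x$percent[t(pairs)],
         compared_length = x$compared_length[t(pairs)])
}

#' @describeIn regional_variability_summary the category-by-region counts
#'   as a tibble.
#' @param x a `regional_variability`.
#' @param ... unused.
#' @export
tidy.regional_variability <- function(x, ...) as_tibble(x$counts)

#' @describeIn regional_variability_summary the `Pi >= 0.024` shares as a
#'   tibble.
#' @export
glance.regional_variability <- function(x, ...) {
  as_tibble(x$variable_share)
}

#' @describeIn build_motif_matrix long-format presence records (`species`,
#'   `motif`, `present`).
#' @param x a `motif_matrix`.
#' @param ... unused.
#' @export
tidy.motif_matrix <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(unclass(x)), -"species",
                      names_to = "motif", values_to = "present")
}
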