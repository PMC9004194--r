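#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a density tensor into long form
#'
#' @param x A `density_tensor`.
#' @param ... Unused.
#' @return A tibble with columns `pseudomolecule`, `level`, `identity`,
#'   `window`, `gene`, `direction`, `density` — one row per tensor cell.
#' @export
tidy.density_tensor <- function(x, ...) {
  long <- as.data.frame.table(x$values, responseName = "density",
                              stringsAsFactors = FALSE)
  tibble(
    pseudomolecule = x$pseudomolecule,
    level = x$level,
    identity = long$identity,
    window = as.integer(long$window),
    gene = long$gene,
    direction = long$direction,
    density = long$density
  )
}

#' @rdname tidy.density_tensor
#' @export
tidy.density_data <- function(x, ...) {
  dplyr::bind_rows(tidy(x$order), tidy(x$superfamily))
}

#' One-row summaries of density objects
#'
#' @param x A `density_tensor` or `density_data`.
#' @param ... Unused.
#' @return A one-row tibble with axis sizes and density range/mean; for
#'   `density_data`, the mean of the total-TE upstream slice at the smallest
#'   window is included as `mean_total_upstream`.
#' @export
glance.density_tensor <- function(x, ...) {
  tibble(
    pseudomolecule = x$pseudomolecule,
    level = x$level,
    n_identities = length(x$identities),
    n_windows = length(x$windows),
    n_genes = length(x$genes),
    min_density = min(x$values),
    max_density = max(x$values),
    mean_density = mean(x$values)
  )
}

#' @rdname glance.density_tensor
#' @export
glance.density_data <- function(x, ...) {
  up <- x$order$values[.TOTAL_LABEL, 1, , 1]
  tibble(
    genome_id = x$genome_id,
    pseudomolecule = x$pseudomolecule,
    n_genes = length(x$genes),
    n_windows = length(x$windows),
    n_orders = length(x$order$identities),
    n_superfamilies = length(x$superfamily$identities),
    min_density = min(x$order$values, x$superfamily$values),
    max_density = max(x$order$values, x$superfamily$values),
    mean_total_upstream = mean(up)
  )
}

#' @rdname tidy.density_tensor
#' @export
tidy.syntelog_differences <- function(x, ...) {
  as_tibble(x)
}

#' @rdname glance.density_tensor
#' @export
glance.syntelog_differences <- function(x, ...) {
  tibble(
    n_nonzero = attr(x, "n_nonzero"),
    n_zero = attr(x, "n_zero"),
    n_skipped = attr(x, "n_skipped"),
    max_abs_difference = if (nrow(x) > 0) max(abs(x$difference)) else NA_real_
  )
}

#' @rdname glance.density_tensor
#' @export
glance.density_binning <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    bin_width = attr(x, "bin_width"),
    n_genes = sum(x$n),
    n_excluded = attr(x, "n_excluded")
  )
}
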