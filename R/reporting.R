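#' Per-gene top-N density table
#'
#' Summarises one gene at one window: for each level (order, superfamily) and
#' each strand-aware direction, the N densest TE groupings in descending
#' density (ties broken alphabetically). `"Total_TE_Density"` participates as
#' an identity, so it ranks first whenever any TE is present. When fewer than
#' N groupings have density > 0 the table is padded with `"No TE"` rows at
#' density 0 — a gene with no TEs anywhere yields an all-`"No TE"`, all-zero
#' table.
#'
#' @param x A `density_data` accessor from [read_density_store()].
#' @param gene Gene name.
#' @param window Window length in bp (intragenic rows ignore it).
#' @param n Number of entries per (level, direction) section; default 5.
#' @return A tibble with columns `gene`, `window`, `level`, `direction`,
#'   `rank` (1 = densest), `identity`, `density`.
#' @export
info_of_gene <- function(x, gene, window, n = 5L) {
  stopifnot(inherits(x, "density_data"))
  gi <- match(gene, x$genes)
  if (is.na(gi)) {
    cli::cli_abort(c("Unknown gene {.val {gene}}.",
                     "i" = "Valid options: {.val {x$genes}}."))
  }
  wi <- match(as.integer(window), x$windows)
  if (is.na(wi)) {
    cli::cli_abort(c("Unknown window {.val {window}}.",
                     "i" = "Valid options: {.val {x$windows}}."))
  }
  one_section <- function(level, di) {
    tensor <- x[[level]]
    rho <- tensor$values[, wi, gi, di]
    ids <- tensor$identities
    pos <- rho > 0
    ord <- order(-rho[pos], ids[pos])
    top <- tibble(identity = ids[pos][ord], density = unname(rho[pos][ord]))
    top <- head(top, n)
    if (nrow(top) < n) {
      pad <- tibble(identity = rep("No TE", n - nrow(top)), density = 0)
      top <- dplyr::bind_rows(top, pad)
    }
    top |>
      dplyr::mutate(
        gene = gene, window = as.integer(window), level = level,
        direction = .DIRECTIONS_SWAPPED[di], rank = dplyr::row_number(),
        .before = 1
      )
  }
  purrr::map_dfr(.LEVELS, function(level) {
    purrr::map_dfr(seq_along(.DIRECTIONS_SWAPPED), function(di) one_section(level, di))
  }) |>
    dplyr::select("gene", "window", "level", "direction", "rank", "identity", "density")
}

# Pool one (level, identity, window, direction) density vector across one or
# more pseudomolecule accessors. Returns a tibble (pseudomolecule, gene, density).
pooled_density <- function(accessors, level, identity, window, direction) {
  if (inherits(accessors, "density_data")) accessors <- list(accessors)
  purrr::map_dfr(accessors, function(x) {
    tensor <- x[[level]]
    ii <- match(identity, tensor$identities)
    wi <- match(as.integer(window), x$windows)
    di <- match(direction, .DIRECTIONS_SWAPPED)
    if (is.na(ii) || is.na(wi) || is.na(di)) {
      cli::cli_abort(c(
        "Identity, window or direction not present in store {.val {x$pseudomolecule}}.",
        "i" = "Identities: {.val {tensor$identities}}",
        "i" = "Windows: {.val {x$windows}}"
      ))
    }
    tibble(
      pseudomolecule = x$pseudomolecule, gene = x$genes,
      density = unname(tensor$values[ii, wi, , di])
    )
  })
}

#' Percentile-cutoff gene list
#'
#' Pools one density slice (level, identity, window, direction) over all
#' genes of a genome, computes the requested percentile of the pooled vector
#' (linear interpolation between order statistics), and returns the genes at
#' or above that cutoff — e.g. the genes whose 1-kb upstream LTR density is
#' within the 99th percentile, a list suitable for GO-enrichment screens.
#'
#' @param accessors A `density_data` accessor or a list of them (one per
#'   pseudomolecule of the genome).
#' @param level,identity,window,direction Slice selectors as in
#'   [density_of()].
#' @param percentile Percentile in (0, 100); default 99.
#' @return A list with `cutoff` (the percentile value) and `genes`, a tibble
#'   (`pseudomolecule`, `gene`, `density`) of genes with density >= cutoff,
#'   sorted by density descending then gene name. When every density is zero
#'   the cutoff is 0 and all genes are returned, with a warning.
#' @export
percentile_gene_list <- function(accessors, level = c("order", "superfamily"),
                                 identity, window,
                                 direction = c("upstream", "intragenic", "downstream"),
                                 percentile = 99) {
  level <- rlang::arg_match(level)
  direction <- rlang::arg_match(direction)
  if (percentile <= 0 || percentile >= 100) {
    cli::cli_abort("{.arg percentile} must lie strictly between 0 and 100.")
  }
  pooled <- pooled_density(accessors, level, identity, window, direction)
  if (all(pooled$density == 0)) {
    cli::cli_warn("All densities are zero for this slice; cutoff is 0 and every gene is returned.")
    cutoff <- 0
  } else {
    cutoff <- unname(quantile(pooled$density, percentile / 100, type = 7))
  }
  genes <- pooled |>
    dplyr::filter(.data$density >= cutoff) |>
    dplyr::arrange(dplyr::desc(.data$density), .data$gene)
  list(cutoff = cutoff, genes = genes)
}

#' Bin genes by density, carrying a companion value
#'
#' Partitions \[0, 1\] into equal-width bins — half-open `[a, b)` except the
#' last bin, which is closed at 1.0 — and assigns each gene to a bin by its
#' density, keeping a companion scalar (typically expression in TPM/FPKM,
#' treated as an opaque number) alongside. Genes whose companion value falls
#' below `expressed_cutoff` (e.g. lowly expressed genes under 0.1 TPM) are
#' excluded before binning.
#'
#' @param data A data frame with columns `density` (in \[0, 1\]) and,
#'   optionally, `value` (companion scalar) and `gene`.
#' @param bin_width Bin width; must divide 1 evenly. Default 0.1.
#' @param expressed_cutoff Optional companion-value cutoff; rows with
#'   `value < expressed_cutoff` are dropped before binning.
#' @return A `density_binning` tibble with one row per bin: `bin`,
#'   `bin_low`, `bin_high`, `right_closed`, `n`, and a list-column `values`
#'   of the member genes' companion values (densities when no `value` column
#'   is present). Attributes `n_excluded` and `bin_width` record the
#'   exclusion tally and width; bin counts always sum to the number of genes
#'   that survived exclusion.
#' @export
bin_genes_by_density <- function(data, bin_width = 0.1, expressed_cutoff = NULL) {
  if (!"density" %in% names(data)) {
    cli::cli_abort("{.arg data} must have a {.field density} column.")
  }
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9) {
    cli::cli_abort("{.arg bin_width} must divide 1 evenly (e.g. 0.1, 0.05, 0.2).")
  }
  nb <- as.integer(round(nb))
  if (any(data$density < 0 | data$density > 1)) {
    cli::cli_abort("Densities must lie in [0, 1].")
  }
  n_excluded <- 0L
  if (!is.null(expressed_cutoff) && "value" %in% names(data)) {
    keep <- data$value >= expressed_cutoff
    n_excluded <- sum(!keep)
    data <- data[keep, , drop = FALSE]
  }
  companion <- if ("value" %in% names(data)) data$value else data$density
  # Half-open bins [a, b); density exactly 1 belongs to the final closed bin.
  # Bin edges are resolved to within 1e-9 so that e.g. 0.3 / 0.1 lands in
  # [0.3, 0.4) despite binary floating point.
  idx <- pmin(as.integer(floor(data$density / bin_width + 1e-9)) + 1L, nb)
  out <- tibble(
    bin = seq_len(nb),
    bin_low = (seq_len(nb) - 1L) * bin_width,
    bin_high = seq_len(nb) * bin_width,
    right_closed = seq_len(nb) == nb,
    n = vapply(seq_len(nb), function(b) sum(idx == b), integer(1)),
    values = lapply(seq_len(nb), function(b) companion[idx == b])
  )
  structure(out, n_excluded = n_excluded, bin_width = bin_width,
            class = c("density_binning", class(out)))
}

#' Read syntelog pairs from TSV
#'
#' Expects columns `Gene_A`, `Gene_B`, `E_Value` (case-insensitive; the
#' E-value column is optional). Pairs with E-value above `max_e_value` are
#' filtered out.
#'
#' @param path TSV file of syntelog pairs.
#' @param max_e_value Maximum pairing E-value retained; default 0.05.
#' @return A tibble with columns `gene_a`, `gene_b`, `e_value`.
#' @export
read_syntelog_pairs <- function(path, max_e_value = 0.05) {
  check_file_exists(path)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    cli::cli_abort("Syntelog file {.file {path}} needs columns {.field Gene_A} and {.field Gene_B}.")
  }
  out <- tibble(
    gene_a = as.character(df$gene_a),
    gene_b = as.character(df$gene_b),
    e_value = if ("e_value" %in% names(df)) as.numeric(df$e_value) else 0
  )
  out[out$e_value <= max_e_value, , drop = FALSE]
}

#' Per-syntelog-pair density differences between two genomes
#'
#' For each syntelog pair, looks up the chosen density slice in both genomes
#' and reports the signed difference `density_a - density_b` (genome A first;
#' a difference of +1 means the grouping fully occupies the window around the
#' genome-A copy and is absent around the genome-B copy). Pairs with a gene
#' name missing from its genome's stores are skipped with a warning.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b` (see
#'   [read_syntelog_pairs()]).
#' @param accessors_a,accessors_b `density_data` accessor(s) for genome A and
#'   genome B.
#' @inheritParams percentile_gene_list
#' @return A `syntelog_differences` tibble with columns `gene_a`, `gene_b`,
#'   `density_a`, `density_b`, `difference` (in \[-1, 1\]). Attributes
#'   `n_zero`, `n_nonzero` and `n_skipped` hold the zero-difference,
#'   nonzero-difference and skipped-pair tallies (the zero and nonzero sets
#'   are reported separately: zero-difference pairs usually dominate and
#'   would otherwise swamp a histogram).
#' @export
syntelog_density_difference <- function(pairs, accessors_a, accessors_b,
                                        level = c("order", "superfamily"),
                                        identity, window,
                                        direction = c("upstream", "intragenic", "downstream")) {
  level <- rlang::arg_match(level)
  direction <- rlang::arg_match(direction)
  a <- pooled_density(accessors_a, level, identity, window, direction)
  b <- pooled_density(accessors_b, level, identity, window, direction)
  rho_a <- a$density[match(pairs$gene_a, a$gene)]
  rho_b <- b$density[match(pairs$gene_b, b$gene)]
  ok <- !is.na(rho_a) & !is.na(rho_b)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    cli::cli_warn("Skipped {n_skipped} syntelog pair{?s} with gene name{?s} missing from the stores.")
  }
  out <- tibble(
    gene_a = pairs$gene_a[ok], gene_b = pairs$gene_b[ok],
    density_a = rho_a[ok], density_b = rho_b[ok],
    difference = rho_a[ok] - rho_b[ok]
  )
  structure(out,
            n_zero = sum(out$difference == 0),
            n_nonzero = sum(out$difference != 0),
            n_skipped = n_skipped,
            class = c("syntelog_differences", class(out)))
}

#' Write a reporting tibble to TSV
#'
#' Thin wrapper used by all report types (gene-info tables, percentile gene
#' lists, bin summaries, syntelog differences); list-columns are dropped.
#'
#' @param report A tibble (or the list returned by [percentile_gene_list()],
#'   in which case its `genes` element is written).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  if (is.list(report) && !is.data.frame(report) && "genes" %in% names(report)) {
    report <- report$genes
  }
  report <- report[, !vapply(report, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}
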