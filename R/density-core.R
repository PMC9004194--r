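#' Base-pair overlap between a TE and a gene's flank window or body
#'
#' The elementary overlap counts, in 0-based inclusive coordinates. A flank
#' window of length `w` spans `w + 1` base pairs: the left window runs over
#' `[g0 - 1 - w, g0 - 1]` (clipped at 0) and the right window over
#' `[g1 + 1, g1 + 1 + w]`. The intragenic overlap is the intersection of the
#' TE with the gene body `[g0, g1]` and does not depend on the window.
#'
#' All arguments are vectorised and recycled.
#'
#' @param w Window length in base pairs (>= 1).
#' @param g0,g1 Gene start/stop, 0-based inclusive.
#' @param t0,t1 TE start/stop, 0-based inclusive.
#' @return Integer overlap in base pairs; `overlap_left()` and
#'   `overlap_right()` are bounded by `w + 1`, `overlap_intra()` by the gene
#'   length. A gene starting at position 0 has an empty left window, so its
#'   left overlap is 0.
#' @export
#' @examples
#' overlap_left(500, 1000, 400, 999)   # TE tiles the whole window: 501
#' overlap_intra(1000, 1999, 1200, 1499)
overlap_left <- function(w, g0, t0, t1) {
  w1 <- g0 - 1
  w0 <- pmax(w1 - w, 0)
  pmax(0, pmin(w1, t1) - pmax(w0, t0) + 1)
}

#' @rdname overlap_left
#' @export
overlap_intra <- function(g0, g1, t0, t1) {
  pmax(0, pmin(g1, t1) - pmax(g0, t0) + 1)
}

#' @rdname overlap_left
#' @export
overlap_right <- function(w, g1, t0, t1) {
  w0 <- g1 + 1
  w1 <- w0 + w
  pmax(0, pmin(w1, t1) - pmax(w0, t0) + 1)
}

#' Normalise summed overlaps into densities
#'
#' Flank densities divide the summed overlap by `w + 1` (the number of base
#' pairs a window of length `w` actually spans); intragenic densities divide
#' by the gene length `g1 - g0 + 1`. Both are proportions in \[0, 1\] as long
#' as the overlaps were summed over disjoint (revised) intervals.
#'
#' @param overlap_sum Summed overlap base pairs across one grouping's
#'   (disjoint) intervals.
#' @inheritParams overlap_left
#' @return Density in \[0, 1\]. `density_flank()` raises an internal
#'   consistency error if `overlap_sum > w + 1`, which can only happen when
#'   the input intervals were not merged.
#' @export
#' @examples
#' density_flank(501, 500) # fully tiled window: exactly 1
#' density_intra(300, 1000, 1999)
density_flank <- function(overlap_sum, w) {
  if (any(overlap_sum > w + 1)) {
    cli::cli_abort(
      "Summed flank overlap exceeds window span (w + 1): the TE intervals overlap each other. Revise the annotation first."
    )
  }
  overlap_sum / (w + 1)
}

#' @rdname density_flank
#' @export
density_intra <- function(overlap_sum, g0, g1) {
  len <- g1 - g0 + 1
  if (any(overlap_sum > len)) {
    cli::cli_abort(
      "Summed intragenic overlap exceeds gene length: the TE intervals overlap each other. Revise the annotation first."
    )
  }
  overlap_sum / len
}

#' Compute the density tensor for one pseudomolecule
#'
#' For every combination of TE grouping (the chosen level's labels plus
#' `"Total_TE_Density"`), window length, gene, and direction (left, intra,
#' right), sums the base-pair overlaps of the grouping's revised intervals
#' and normalises them into densities. Intragenic values do not depend on the
#' window and are replicated across the window axis.
#'
#' @param genes Gene tibble (one pseudomolecule) from
#'   [read_gene_annotation()].
#' @param revised Revised TE tibble from [revise_te_annotation()]; rows for
#'   other pseudomolecules are ignored.
#' @param level `"order"` or `"superfamily"`.
#' @param windows Integer vector of strictly increasing window lengths.
#' @param identities Optional fixed identity axis (so that every
#'   pseudomolecule of a genome shares one axis); defaults to the labels
#'   present in `revised` at this level, sorted, with `"Total_TE_Density"`
#'   appended. Labels without intervals on this pseudomolecule yield all-zero
#'   slices.
#' @return A `density_tensor`: values indexed
#'   (identity, window, gene, direction) with the direction axis fixed as
#'   (left, intra, right), plus the axis labels, gene strands, the
#'   pseudomolecule id and a `swapped = FALSE` flag.
#' @export
compute_pseudomolecule_density <- function(genes, revised,
                                           level = c("order", "superfamily"),
                                           windows = default_windows(),
                                           identities = NULL) {
  level <- rlang::arg_match(level)
  windows <- validate_windows(windows)
  pm <- unique(genes$pseudomolecule)
  if (length(pm) != 1) {
    cli::cli_abort("{.arg genes} must contain exactly one pseudomolecule; found {length(pm)}.")
  }
  rev_pm <- revised[revised$pseudomolecule == pm, , drop = FALSE]
  if (nrow(rev_pm) == 0) {
    cli::cli_warn("Pseudomolecule {.val {pm}} has no TE intervals; densities are all zero.")
  }
  if (is.null(identities)) {
    identities <- identity_axis(rev_pm$label[rev_pm$level == level])
  }

  n_i <- length(identities); n_w <- length(windows); n_g <- nrow(genes)
  values <- array(
    0, dim = c(n_i, n_w, n_g, 3L),
    dimnames = list(
      identity = identities, window = as.character(windows),
      gene = genes$name, direction = .DIRECTIONS_RAW
    )
  )

  for (ii in seq_len(n_i)) {
    id <- identities[ii]
    iv <- if (id == .TOTAL_LABEL) {
      rev_pm[rev_pm$level == "total", , drop = FALSE]
    } else {
      rev_pm[rev_pm$level == level & rev_pm$label == id, , drop = FALSE]
    }
    if (nrow(iv) == 0) next
    for (gi in seq_len(n_g)) {
      g0 <- genes$g0[gi]; g1 <- genes$g1[gi]
      o_i <- sum(overlap_intra(g0, g1, iv$t0, iv$t1))
      rho_i <- density_intra(o_i, g0, g1)
      for (wi in seq_len(n_w)) {
        w <- windows[wi]
        o_l <- sum(overlap_left(w, g0, iv$t0, iv$t1))
        o_r <- sum(overlap_right(w, g1, iv$t0, iv$t1))
        values[ii, wi, gi, 1L] <- density_flank(o_l, w)
        values[ii, wi, gi, 2L] <- rho_i
        values[ii, wi, gi, 3L] <- density_flank(o_r, w)
      }
    }
  }

  new_density_tensor(
    values = values, identities = identities, windows = windows,
    genes = genes$name, strands = genes$strand,
    pseudomolecule = pm, level = level, swapped = FALSE
  )
}

new_density_tensor <- function(values, identities, windows, genes, strands,
                               pseudomolecule, level, swapped) {
  structure(
    list(
      values = values, identities = identities, windows = as.integer(windows),
      genes = genes, strands = strands, pseudomolecule = pseudomolecule,
      level = level, swapped = swapped
    ),
    class = "density_tensor"
  )
}

#' @export
print.density_tensor <- function(x, ...) {
  cli::cli_text(
    "<density_tensor> {x$level}-level, pseudomolecule {.val {x$pseudomolecule}}: ",
    "{length(x$identities)} identit{?y/ies} x {length(x$windows)} window{?s} x ",
    "{length(x$genes)} gene{?s} x 3 directions ",
    "({if (x$swapped) 'upstream/intragenic/downstream' else 'left/intra/right'})"
  )
  invisible(x)
}

#' Run the full density pipeline over a genome
#'
#' Splits the annotations by pseudomolecule, revises the TEs, computes the
#' order- and superfamily-level tensors for every pseudomolecule (sharing one
#' genome-wide identity axis per level) and writes one HDF5 store per
#' pseudomolecule. Pseudomolecules are independent, so they may be processed
#' in parallel; results are identical for any worker count.
#'
#' @param genes Gene tibble from [read_gene_annotation()].
#' @param tes TE tibble from [read_te_annotation()].
#' @param genome_id Short genome identifier used in store file names
#'   (`{genome_id}_{pseudomolecule}.h5`).
#' @param output_dir Directory for the stores; created if needed.
#' @param windows Window lengths; default [default_windows()].
#' @param identity_maps Optional identity map or list of maps applied via
#'   [reclassify_identities()] before revision.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @param overwrite Overwrite existing store files? Default `FALSE`.
#' @return A tibble with one row per pseudomolecule: `pseudomolecule`,
#'   `path`, `n_genes`.
#' @export
process_genome <- function(genes, tes, genome_id, output_dir,
                           windows = default_windows(),
                           identity_maps = NULL,
                           workers = 1L, overwrite = FALSE) {
  windows <- validate_windows(windows)
  if (!is.null(identity_maps)) {
    if (inherits(identity_maps, "te_identity_map")) identity_maps <- list(identity_maps)
    for (m in identity_maps) tes <- reclassify_identities(tes, m)
  }
  gene_pm <- unique(genes$pseudomolecule)
  te_pm <- unique(tes$pseudomolecule)
  if (!setequal(gene_pm, te_pm)) {
    cli::cli_abort(c(
      "Pseudomolecule names differ between the gene and TE annotations.",
      "x" = "In genes only: {.val {setdiff(gene_pm, te_pm)}}",
      "x" = "In TEs only: {.val {setdiff(te_pm, gene_pm)}}"
    ))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  revised <- revise_te_annotation(tes)
  axes <- list(
    order = identity_axis(revised$label[revised$level == "order"]),
    superfamily = identity_axis(revised$label[revised$level == "superfamily"])
  )
  pms <- sort(gene_pm)
  paths <- file.path(output_dir, paste0(genome_id, "_", pms, ".h5"))
  if (!overwrite) {
    clash <- paths[file.exists(paths)]
    if (length(clash) > 0) {
      cli::cli_abort("Store file{?s} {.file {clash}} already exist{?s/}; use {.code overwrite = TRUE}.")
    }
  }

  run_one <- function(k) {
    pm <- pms[k]
    g <- genes[genes$pseudomolecule == pm, , drop = FALSE]
    ord <- compute_pseudomolecule_density(g, revised, "order", windows,
                                          identities = axes$order)
    sup <- compute_pseudomolecule_density(g, revised, "superfamily", windows,
                                          identities = axes$superfamily)
    write_density_store(ord, sup, paths[k], genome_id = genome_id,
                        overwrite = overwrite)
    nrow(g)
  }
  n_genes <- if (workers > 1L) {
    unlist(parallel::mclapply(seq_along(pms), run_one, mc.cores = workers))
  } else {
    vapply(seq_along(pms), run_one, integer(1))
  }
  tibble(pseudomolecule = pms, path = paths, n_genes = as.integer(n_genes))
}
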