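#' Default TE identity alphabet for synthetic genomes
#'
#' A small plant-style hierarchy: orders mapping to their superfamilies.
#'
#' @return Named list; names are orders, elements are superfamily vectors.
#' @export
default_identity_alphabet <- function() {
  list(
    LTR = c("Copia", "Gypsy"),
    TIR = c("Mutator", "CACTA"),
    LINE = "L1",
    Helitron = "Helitron"
  )
}

#' Generate a synthetic gene/TE annotation pair
#'
#' Produces a deterministic (seeded) pair of annotations with controlled
#' overlap structure so every pipeline stage can be exercised without real
#' data: genes are placed without mutual overlap; each TE is, with the stated
#' probabilities, anchored to overlap an existing same-identity TE (so the
#' revision merge has work to do) or a gene (so intragenic densities are
#' nonzero), and is otherwise placed uniformly. When
#' `te_te_overlap_prob = 1` and there are at least two TEs, at least one
#' same-superfamily overlapping pair is guaranteed.
#'
#' @param n_pseudomolecules Number of pseudomolecules.
#' @param pseudomolecule_length Length of each pseudomolecule in bp.
#' @param n_genes,n_tes Feature counts (split round-robin across
#'   pseudomolecules).
#' @param gene_length,te_length Length ranges `c(min, max)` in bp.
#' @param identities Identity alphabet as in [default_identity_alphabet()].
#' @param te_te_overlap_prob Probability a TE is placed overlapping an
#'   earlier TE of the same order and superfamily.
#' @param te_gene_overlap_prob Probability a TE is placed overlapping a gene.
#' @param antisense_fraction Expected fraction of antisense genes.
#' @param first_gene_at_zero Force the first gene of each pseudomolecule to
#'   start at position 0 (exercises the empty-left-window edge case).
#' @param seed Optional integer seed; the same seed always yields the same
#'   annotations.
#' @return A list with tibbles `genes` and `tes` in the internal model (the
#'   same schemas as [read_gene_annotation()] / [read_te_annotation()]).
#' @export
generate_synthetic_genome <- function(n_pseudomolecules = 1,
                                      pseudomolecule_length = 100000,
                                      n_genes = 10,
                                      gene_length = c(500, 3000),
                                      n_tes = 50,
                                      te_length = c(100, 2000),
                                      identities = default_identity_alphabet(),
                                      te_te_overlap_prob = 0.3,
                                      te_gene_overlap_prob = 0.3,
                                      antisense_fraction = 0.5,
                                      first_gene_at_zero = FALSE,
                                      seed = NULL) {
  stopifnot(n_pseudomolecules >= 1, pseudomolecule_length >= 1,
            n_genes >= 0, n_tes >= 0,
            gene_length[1] >= 1, te_length[1] >= 1,
            te_te_overlap_prob >= 0, te_te_overlap_prob <= 1,
            te_gene_overlap_prob >= 0, te_gene_overlap_prob <= 1,
            antisense_fraction >= 0, antisense_fraction <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))

  pms <- sprintf("pm%02d", seq_len(n_pseudomolecules))
  gene_pm <- pms[(seq_len(n_genes) - 1L) %% n_pseudomolecules + 1L]
  te_pm <- pms[(seq_len(n_tes) - 1L) %% n_pseudomolecules + 1L]

  per_pm_genes <- max(table(factor(gene_pm, levels = pms)), 0)
  if (per_pm_genes * gene_length[2] > 0.9 * pseudomolecule_length) {
    cli::cli_abort(
      "Infeasible packing: up to {per_pm_genes} genes of <= {gene_length[2]} bp cannot fit without overlap on a {pseudomolecule_length} bp pseudomolecule."
    )
  }

  flat_ids <- purrr::imap_dfr(identities, function(sups, ord) {
    tibble(order = ord, superfamily = sups)
  })

  genes_list <- list(); tes_list <- list()
  for (pm in pms) {
    ng <- sum(gene_pm == pm)
    g <- if (ng > 0) {
      lens <- sample(gene_length[1]:gene_length[2], ng, replace = TRUE)
      slack <- pseudomolecule_length - sum(lens)
      # random gaps before each gene summing to at most the slack
      gaps <- floor(diff(sort(c(0, runif(ng, 0, 1), 1))) * slack)[seq_len(ng)]
      if (first_gene_at_zero) gaps[1] <- 0L
      starts <- cumsum(gaps) + c(0L, cumsum(lens[-ng] + 1L))
      tibble(
        pseudomolecule = pm,
        name = sprintf("%s_gene%03d", pm, seq_len(ng)),
        g0 = as.integer(starts),
        g1 = as.integer(starts + lens - 1L),
        strand = ifelse(runif(ng) < antisense_fraction, "antisense", "sense")
      ) |>
        dplyr::mutate(length = .data$g1 - .data$g0 + 1L)
    } else {
      tibble(pseudomolecule = character(), name = character(), g0 = integer(),
             g1 = integer(), strand = character(), length = integer())
    }
    genes_list[[pm]] <- g

    nt <- sum(te_pm == pm)
    if (nt > 0) {
      t0 <- integer(nt); t1 <- integer(nt)
      ord <- character(nt); sup <- character(nt)
      for (j in seq_len(nt)) {
        len <- sample(te_length[1]:te_length[2], 1)
        u <- runif(1)
        placed <- FALSE
        if (j > 1 && u < te_te_overlap_prob) {
          # overlap an earlier TE, inheriting its identity so the revision
          # merge is guaranteed to trigger
          k <- sample(j - 1L, 1)
          start <- sample(t0[k]:t1[k], 1)
          ord[j] <- ord[k]; sup[j] <- sup[k]
          placed <- TRUE
        } else if (nrow(g) > 0 && u < te_te_overlap_prob + te_gene_overlap_prob) {
          k <- sample(nrow(g), 1)
          start <- sample(max(g$g0[k] - len + 1L, 0L):g$g1[k], 1)
        } else {
          start <- sample(0:max(pseudomolecule_length - len, 0), 1)
        }
        if (!placed) {
          row <- flat_ids[sample(nrow(flat_ids), 1), ]
          ord[j] <- row$order; sup[j] <- row$superfamily
        }
        t0[j] <- start
        t1[j] <- start + len - 1L
      }
      tes_list[[pm]] <- tibble(
        pseudomolecule = pm, t0 = t0, t1 = t1,
        order = ord, superfamily = sup
      ) |>
        dplyr::mutate(length = .data$t1 - .data$t0 + 1L)
    }
  }

  genes <- dplyr::bind_rows(genes_list) |>
    dplyr::arrange(.data$pseudomolecule, .data$g0)
  tes <- dplyr::bind_rows(tes_list)
  if (nrow(tes) > 0) tes <- dplyr::arrange(tes, .data$pseudomolecule, .data$t0)
  list(genes = genes, tes = tes)
}

#' Per-base occupancy-mask density oracle
#'
#' An independent reference for the whole pipeline: for each grouping label
#' it builds an explicit boolean occupancy vector over the pseudomolecule
#' (the union of the raw, unrevised TE intervals — union semantics make a
#' separate merge step unnecessary, and shared base pairs of nested TEs are
#' inherently counted once) and reads densities straight off the mask:
#' left = occupied bases in `[max(g0 - 1 - w, 0), g0 - 1]` over `w + 1`,
#' right analogously over `[g1 + 1, g1 + 1 + w]`, intragenic = occupied bases
#' in `[g0, g1]` over the gene length. It deliberately shares no code with
#' the revision or overlap modules, so agreement checks revision, overlap and
#' summation together.
#'
#' @param genes,tes Annotation tibbles restricted to one pseudomolecule.
#' @param windows Window lengths.
#' @param level `"order"` or `"superfamily"`.
#' @param identities Optional fixed identity axis, as in
#'   [compute_pseudomolecule_density()].
#' @return A `density_tensor` in raw left/intra/right orientation, directly
#'   comparable to [compute_pseudomolecule_density()] output.
#' @export
oracle_density <- function(genes, tes, windows, level = c("order", "superfamily"),
                           identities = NULL) {
  level <- rlang::arg_match(level)
  windows <- validate_windows(windows)
  pm <- unique(c(genes$pseudomolecule, tes$pseudomolecule))
  if (length(pm) != 1) {
    cli::cli_abort("Oracle operates on a single pseudomolecule; found {.val {pm}}.")
  }
  span <- max(c(genes$g1, tes$t1, 0)) + max(windows) + 2L
  if (span > 2e6) {
    cli::cli_abort("Instance too large for the explicit-mask oracle ({span} bp); use the main pipeline.")
  }
  labels <- tes[[level]]
  if (is.null(identities)) identities <- identity_axis(labels)

  masks <- lapply(identities, function(id) {
    m <- logical(span)
    rows <- if (id == .TOTAL_LABEL) seq_len(nrow(tes)) else which(labels == id)
    for (r in rows) m[(tes$t0[r]:tes$t1[r]) + 1L] <- TRUE
    m
  })

  n_i <- length(identities); n_w <- length(windows); n_g <- nrow(genes)
  values <- array(
    0, dim = c(n_i, n_w, n_g, 3L),
    dimnames = list(identity = identities, window = as.character(windows),
                    gene = genes$name, direction = .DIRECTIONS_RAW)
  )
  count_range <- function(m, lo, hi) {
    if (hi < lo || hi < 0) return(0L)
    lo <- max(lo, 0L)
    sum(m[(lo:hi) + 1L])
  }
  for (ii in seq_len(n_i)) {
    m <- masks[[ii]]
    for (gi in seq_len(n_g)) {
      g0 <- genes$g0[gi]; g1 <- genes$g1[gi]
      values[ii, , gi, 2L] <- count_range(m, g0, g1) / (g1 - g0 + 1)
      for (wi in seq_len(n_w)) {
        w <- windows[wi]
        values[ii, wi, gi, 1L] <- count_range(m, g0 - 1L - w, g0 - 1L) / (w + 1)
        values[ii, wi, gi, 3L] <- count_range(m, g1 + 1L, g1 + 1L + w) / (w + 1)
      }
    }
  }
  new_density_tensor(
    values = values, identities = identities, windows = windows,
    genes = genes$name, strands = genes$strand,
    pseudomolecule = pm, level = level, swapped = FALSE
  )
}
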