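# Small constructors used throughout the suite; all coordinates are the
# internal 0-based inclusive model.

make_genes <- function(pm, name, g0, g1, strand = "sense") {
  tibble::tibble(
    pseudomolecule = pm, name = name, g0 = as.integer(g0), g1 = as.integer(g1),
    strand = strand, length = as.integer(g1 - g0 + 1)
  )
}

make_tes <- function(pm, t0, t1, order, superfamily) {
  tibble::tibble(
    pseudomolecule = pm, t0 = as.integer(t0), t1 = as.integer(t1),
    order = order, superfamily = superfamily,
    length = as.integer(t1 - t0 + 1)
  )
}

empty_revised <- function() {
  tibble::tibble(pseudomolecule = character(), level = character(),
                 label = character(), t0 = integer(), t1 = integer())
}

# Full pipeline for one pseudomolecule: revise then compute.
pipeline_tensor <- function(genes, tes, windows, level, identities = NULL) {
  compute_pseudomolecule_density(genes, revise_te_annotation(tes),
                                 level = level, windows = windows,
                                 identities = identities)
}

# Draw a small random single-pseudomolecule instance; deterministic per seed.
random_instance <- function(seed, windows = c(100L, 500L, 1000L)) {
  set.seed(seed)
  alphabet <- default_identity_alphabet()
  orders <- sample(names(alphabet), sample(2:4, 1))
  generate_synthetic_genome(
    n_pseudomolecules = 1,
    pseudomolecule_length = 100000L,
    n_genes = sample(3:10, 1),
    n_tes = sample(5:50, 1),
    identities = alphabet[orders],
    te_te_overlap_prob = runif(1, 0, 0.8),
    te_gene_overlap_prob = runif(1, 0, 0.8),
    antisense_fraction = 0.5,
    first_gene_at_zero = runif(1) < 0.2,
    seed = seed
  )
}

# Per-base occupancy of a set of intervals over [0, span): independent of
# both the revision module and the oracle tensor builder.
coverage_mask <- function(t0, t1, span) {
  m <- logical(span)
  for (i in seq_along(t0)) m[(t0[i]:t1[i]) + 1L] <- TRUE
  m
}
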