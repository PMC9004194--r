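test_that("flank and intragenic overlaps clip their bounds exactly", {
  # left window of w=500 before g0=1000 spans [499, 999]
  expect_equal(overlap_left(500, 1000, 400, 999), 501)   # full coverage = w + 1
  expect_equal(overlap_left(500, 1000, 2000, 2500), 0)   # TE right of window
  expect_equal(overlap_left(500, 100, 0, 99), 100)       # clipped at 0: [0, 99]
  expect_equal(overlap_left(500, 0, 0, 99), 0)           # gene at origin: empty window

  expect_equal(overlap_intra(1000, 1999, 1200, 1499), 300)
  expect_equal(overlap_intra(1000, 1999, 500, 2500), 1000) # clipped both sides
  expect_equal(overlap_intra(1000, 1999, 100, 200), 0)

  # right window of w=500 after g1=1999 spans [2000, 2500]
  expect_equal(overlap_right(500, 1999, 2000, 2500), 501)
  expect_equal(overlap_right(500, 1999, 0, 1999), 0)
  expect_equal(overlap_right(500, 1999, 2400, 2700), 101)
})

test_that("densities normalise by w + 1 (flank) and gene length (intra)", {
  expect_identical(density_flank(501, 500), 1)
  expect_identical(density_flank(0, 500), 0)
  expect_equal(density_flank(100, 500), 100 / 501)
  expect_identical(density_intra(1000, 1000, 1999), 1)
  expect_identical(density_intra(0, 1000, 1999), 0)
  expect_equal(density_intra(300, 1000, 1999), 0.3)
  # the unmerged-input guard
  expect_error(density_flank(502, 500), "Revise")
  expect_error(density_intra(1001, 1000, 1999), "Revise")
})

test_that("a tensor cell equals the mask oracle on a hand-checkable instance", {
  genes <- make_genes("Chr1", c("gA", "gB", "gC"),
                      g0 = c(0, 3000, 7000), g1 = c(999, 4499, 7999),
                      strand = c("sense", "antisense", "sense"))
  tes <- make_tes("Chr1",
                  t0 = c(1500, 2800, 2900, 4600, 5000, 6950),
                  t1 = c(2500, 3100, 3050, 5599, 5099, 7049),
                  order = c("LTR", "LTR", "LTR", "TIR", "TIR", "LINE"),
                  superfamily = c("Copia", "Copia", "Gypsy", "Mutator", "Mutator", "L1"))
  windows <- c(100L, 500L, 1000L)
  for (lvl in c("order", "superfamily")) {
    got <- pipeline_tensor(genes, tes, windows, lvl)
    want <- oracle_density(genes, tes, windows, lvl, identities = got$identities)
    expect_equal(got$values, want$values, tolerance = 1e-15)
  }
  # spot value: gB left 500-window [2499, 2999] vs merged LTR intervals
  # [1500, 2500] and [2800, 3100]: 2 + 200 bp -> 202/501
  ord <- pipeline_tensor(genes, tes, windows, "order")
  expect_equal(ord$values["LTR", "500", "gB", "left"], 202 / 501)
  # gB intra [3000, 4499] overlaps merged LTR [2800, 3100] by 101 bp
  expect_equal(ord$values["LTR", "500", "gB", "intra"], 101 / 1500)
})

test_that("identities with no intervals yield zero slices; full tiling yields exactly 1", {
  genes <- make_genes("Chr1", "g1", 2000, 2999)
  tes <- make_tes("Chr1", 0, 10000, "LTR", "Copia")
  got <- pipeline_tensor(genes, tes, c(100L, 500L), "order",
                         identities = c("Helitron", "LTR", "Total_TE_Density"))
  expect_true(all(got$values["Helitron", , , ] == 0))
  expect_true(all(got$values["LTR", , , ] == 1))
  expect_true(all(got$values["Total_TE_Density", , , ] == 1))
})

test_that("a pseudomolecule without TE intervals warns and returns all zeros", {
  genes <- make_genes("Chr1", "g1", 100, 199)
  expect_warning(t <- compute_pseudomolecule_density(genes, empty_revised(),
                                                     "order", c(100L)),
                 "no TE intervals")
  expect_true(all(t$values == 0))
  expect_equal(t$identities, "Total_TE_Density")
})

test_that("tensor invariants hold on random instances", {
  for (seed in 1:12) {
    syn <- random_instance(seed)
    windows <- c(100L, 500L, 1000L)
    tensor <- pipeline_tensor(syn$genes, syn$tes, windows, "order")
    v <- tensor$values
    expect_gte(min(v), 0)
    expect_lte(max(v), 1)
    # intra invariance across the window axis
    intra <- v[, , , 2, drop = FALSE]
    for (wi in seq_along(windows)) {
      expect_identical(intra[, wi, , 1], intra[, 1, , 1])
    }
    # coverage mass rho * (w + 1) is non-decreasing in w for flanks
    for (d in c(1, 3)) {
      for (wi in seq_along(windows)[-1]) {
        mass_hi <- v[, wi, , d] * (windows[wi] + 1)
        mass_lo <- v[, wi - 1, , d] * (windows[wi - 1] + 1)
        expect_true(all(mass_hi - mass_lo >= -1e-9))
      }
    }
    # total dominance: total >= max single identity, <= sum of identities
    singles <- v[tensor$identities != "Total_TE_Density", , , , drop = FALSE]
    total <- v["Total_TE_Density", , , ]
    expect_true(all(total - apply(singles, c(2, 3, 4), max) >= -1e-12))
    expect_true(all(total - pmin(1, apply(singles, c(2, 3, 4), sum)) <= 1e-12))
  }
})

test_that("densities are invariant under a constant coordinate shift", {
  syn <- random_instance(99)
  windows <- c(100L, 500L)
  base <- pipeline_tensor(syn$genes, syn$tes, windows, "superfamily")
  shift <- 5000L
  genes2 <- dplyr::mutate(syn$genes, g0 = g0 + shift, g1 = g1 + shift)
  tes2 <- dplyr::mutate(syn$tes, t0 = t0 + shift, t1 = t1 + shift)
  shifted <- pipeline_tensor(genes2, tes2, windows, "superfamily",
                             identities = base$identities)
  expect_equal(shifted$values, base$values, tolerance = 1e-15)
})

test_that("process_genome is deterministic across worker counts and splits per pseudomolecule", {
  syn <- generate_synthetic_genome(n_pseudomolecules = 3, n_genes = 9, n_tes = 30, seed = 11)
  windows <- c(500L, 1000L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- process_genome(syn$genes, syn$tes, "syn", d1, windows = windows, workers = 1)
  r2 <- process_genome(syn$genes, syn$tes, "syn", d2, windows = windows, workers = 2)
  expect_equal(nrow(r1), 3)
  expect_true(all(file.exists(r1$path)))
  expect_equal(basename(r1$path), paste0("syn_", sort(unique(syn$genes$pseudomolecule)), ".h5"))
  expect_identical(unname(tools::md5sum(r1$path)), unname(tools::md5sum(r2$path)))

  # each store matches an independent single-pseudomolecule run
  pm <- r1$pseudomolecule[2]
  solo_dir <- withr::local_tempdir()
  solo <- process_genome(dplyr::filter(syn$genes, pseudomolecule == pm),
                         dplyr::filter(syn$tes, pseudomolecule == pm),
                         "solo", solo_dir, windows = windows)
  full <- read_density_store(r1$path[2])
  alone <- read_density_store(solo$path)
  # identity axes are genome-wide in the full run; compare the shared labels
  shared <- intersect(full$order$identities, alone$order$identities)
  expect_equal(full$order$values[shared, , , ], alone$order$values[shared, , , ])
})

test_that("process_genome rejects mismatched pseudomolecule sets, naming the difference", {
  syn <- generate_synthetic_genome(n_pseudomolecules = 2, n_genes = 4, n_tes = 10, seed = 3)
  tes_wrong <- dplyr::mutate(syn$tes, pseudomolecule = sub("pm02", "pmXX", pseudomolecule))
  expect_error(
    process_genome(syn$genes, tes_wrong, "syn", withr::local_tempdir()),
    "pmXX"
  )
})
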