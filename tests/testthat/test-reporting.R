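# A genome where one gene has a single Copia upstream and another has no TEs
# at all, so the report layout can be checked by hand.
reporting_fixture <- function(env = parent.frame()) {
  genes <- make_genes("Chr1", c("gene_te", "gene_bare"),
                      g0 = c(5000, 20000), g1 = c(5999, 20999))
  tes <- make_tes("Chr1", 4000, 4999, "LTR", "Copia")
  dir <- withr::local_tempdir(.local_envir = env)
  res <- process_genome(genes, tes, "rep", dir, windows = c(500L, 1000L))
  read_density_store(res$path)
}

test_that("info_of_gene reports an all-'No TE' zero layout for a TE-free gene", {
  x <- reporting_fixture()
  info <- info_of_gene(x, "gene_bare", 1000)
  expect_equal(nrow(info), 2 * 3 * 5) # levels x directions x top-5
  expect_true(all(info$identity == "No TE"))
  expect_true(all(info$density == 0))
})

test_that("info_of_gene ranks the upstream Copia with Total equal to it, ties alphabetical", {
  x <- reporting_fixture()
  info <- info_of_gene(x, "gene_te", 1000)
  up_sup <- info[info$level == "superfamily" & info$direction == "upstream", ]
  # Copia fully fills the 1 kb upstream window minus one base: 1000/1001.
  # Total equals Copia (only one TE); alphabetical tie-break puts Copia first.
  expect_equal(up_sup$identity[1:2], c("Copia", "Total_TE_Density"))
  expect_equal(up_sup$density[1:2], rep(1000 / 1001, 2))
  expect_equal(up_sup$identity[3:5], rep("No TE", 3))
  # top-1 Total is >= every other entry within each section
  for (lvl in c("order", "superfamily")) {
    for (d in unique(info$direction)) {
      sec <- info[info$level == lvl & info$direction == d, ]
      tot <- sec$density[sec$identity == "Total_TE_Density"]
      if (length(tot) > 0) expect_true(all(sec$density <= max(tot)))
    }
  }
  expect_error(info_of_gene(x, "missing_gene", 1000), "Valid options")
})

test_that("percentile cutoffs follow the linear-interpolation rule and inclusive membership", {
  # build an accessor whose pooled upstream vector is known exactly
  syn <- generate_synthetic_genome(n_genes = 8, n_tes = 40, seed = 31)
  dir <- withr::local_tempdir()
  res <- process_genome(syn$genes, syn$tes, "pct", dir, windows = c(500L, 1000L))
  x <- read_density_store(res$path)
  pooled <- x$order$values["Total_TE_Density", "1000", , "upstream"]

  out <- percentile_gene_list(x, "order", "Total_TE_Density", 1000, "upstream",
                              percentile = 50)
  expect_equal(out$cutoff, unname(quantile(pooled, 0.5, type = 7)))
  expect_setequal(out$genes$gene, names(pooled)[pooled >= out$cutoff])
  expect_false(is.unsorted(rev(out$genes$density)))
  # roughly half the genes (plus ties) sit at or above the median
  expect_gte(nrow(out$genes), length(pooled) / 2 - 1)

  # constant vector: cutoff equals the constant and every gene is returned
  const <- x
  const$order$values["Total_TE_Density", "1000", , "upstream"] <- 0.25
  out2 <- percentile_gene_list(const, "order", "Total_TE_Density", 1000, "upstream", 99)
  expect_equal(out2$cutoff, 0.25)
  expect_setequal(out2$genes$gene, x$genes)

  # all-zero slice: warning, cutoff 0, all genes
  zero <- x
  zero$order$values["Total_TE_Density", "1000", , "upstream"] <- 0
  expect_warning(out3 <- percentile_gene_list(zero, "order", "Total_TE_Density",
                                              1000, "upstream", 99),
                 "zero")
  expect_equal(out3$cutoff, 0)
  expect_equal(nrow(out3$genes), length(x$genes))
})

test_that("binning is half-open except the last bin, conserves counts, and honours the expression cutoff", {
  df <- tibble::tibble(
    gene = sprintf("g%02d", 1:6),
    density = c(0, 0.3, 0.1, 0.999, 1.0, 0.95),
    value = c(5, 0.05, 2, 1, 3, 0.2)
  )
  bins <- bin_genes_by_density(df, bin_width = 0.1)
  expect_equal(sum(bins$n), 6)
  expect_equal(bins$n[4], 1)   # 0.3 lands in [0.3, 0.4)
  expect_equal(bins$n[2], 1)   # 0.1 in [0.1, 0.2)
  expect_equal(bins$n[10], 3)  # 0.999, 0.95 and the closed boundary 1.0
  expect_true(bins$right_closed[10] && !any(bins$right_closed[1:9]))

  # excluding lowly expressed genes removes exactly those below the cutoff
  bins2 <- bin_genes_by_density(df, bin_width = 0.1, expressed_cutoff = 0.1)
  expect_equal(attr(bins2, "n_excluded"), 1)
  expect_equal(sum(bins2$n), 5)
  # cutoff 0 excludes nothing
  bins3 <- bin_genes_by_density(df, bin_width = 0.1, expressed_cutoff = 0)
  expect_equal(attr(bins3, "n_excluded"), 0)
  expect_equal(sum(bins3$n), 6)

  expect_error(bin_genes_by_density(df, bin_width = 0.3), "divide 1 evenly")
  expect_error(bin_genes_by_density(tibble::tibble(density = 1.2)), "0, 1")

  # counting property on uniform random densities
  set.seed(5)
  big <- tibble::tibble(density = runif(100), value = runif(100))
  bb <- bin_genes_by_density(big, 0.1, expressed_cutoff = 0.5)
  expect_equal(sum(bb$n) + attr(bb, "n_excluded"), 100)
  expect_equal(glance(bb)$n_genes, sum(bb$n))
})

test_that("syntelog differences are signed A minus B, antisymmetric, with separate zero/nonzero tallies", {
  syn_a <- generate_synthetic_genome(n_genes = 5, n_tes = 25, seed = 41)
  syn_b <- generate_synthetic_genome(n_genes = 5, n_tes = 25, seed = 42)
  dir <- withr::local_tempdir()
  pa <- process_genome(syn_a$genes, syn_a$tes, "A", dir, windows = c(500L))
  pb <- process_genome(syn_b$genes, syn_b$tes, "B", dir, windows = c(500L))
  a <- read_density_store(pa$path); b <- read_density_store(pb$path)
  pairs <- tibble::tibble(gene_a = a$genes, gene_b = b$genes, e_value = 0)

  d_ab <- syntelog_density_difference(pairs, a, b, "order", "Total_TE_Density",
                                      500, "upstream")
  expect_true(all(abs(d_ab$difference) <= 1))
  expect_equal(d_ab$difference, d_ab$density_a - d_ab$density_b)
  # antisymmetry under swapping genomes
  rev_pairs <- tibble::tibble(gene_a = pairs$gene_b, gene_b = pairs$gene_a)
  d_ba <- syntelog_density_difference(rev_pairs, b, a, "order", "Total_TE_Density",
                                      500, "upstream")
  expect_equal(d_ba$difference, -d_ab$difference)

  # identical genomes: every difference is zero
  d_aa <- syntelog_density_difference(
    tibble::tibble(gene_a = a$genes, gene_b = a$genes), a, a,
    "order", "Total_TE_Density", 500, "upstream")
  expect_true(all(d_aa$difference == 0))
  expect_equal(glance(d_aa)$n_zero, length(a$genes))
  expect_equal(glance(d_aa)$n_nonzero, 0)

  # zero/nonzero/skip bookkeeping on a crafted pair set
  mixed <- tibble::tibble(
    gene_a = c(a$genes[1:3], a$genes[1:2], "ghost"),
    gene_b = c(b$genes[1:3], b$genes[1:2], b$genes[1])
  )
  expect_warning(
    d_mix <- syntelog_density_difference(mixed, a, b, "order",
                                         "Total_TE_Density", 500, "upstream"),
    "Skipped 1"
  )
  expect_equal(nrow(d_mix), 5)
  expect_equal(glance(d_mix)$n_skipped, 1)
  expect_equal(glance(d_mix)$n_zero + glance(d_mix)$n_nonzero, 5)
})

test_that("syntelog pair files filter on E-value; reports write as TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene_A\tGene_B\tE_Value",
               "a1\tb1\t0.001", "a2\tb2\t0.2", "a3\tb3\t0.05"), path)
  pairs <- read_syntelog_pairs(path)
  expect_equal(pairs$gene_a, c("a1", "a3")) # 0.2 > 0.05 filtered out

  x <- reporting_fixture()
  out <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(info_of_gene(x, "gene_te", 1000), out)
  back <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(nrow(back), 30)
  pct <- percentile_gene_list(x, "order", "Total_TE_Density", 1000, "upstream", 50)
  write_report_tsv(pct, out)
  expect_equal(nrow(readr::read_tsv(out, show_col_types = FALSE)), nrow(pct$genes))
})
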