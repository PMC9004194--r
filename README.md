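# tedensity

Transposable elements (TEs) shape gene regulation: an LTR retrotransposon
parked just upstream of a promoter, an Alu inside an intron, a Helitron
downstream of the terminator can each change how a gene behaves. **tedensity**
quantifies this gene-centric TE presence for *every* gene in a genome, for
*every* TE grouping, over a sweep of measurement windows — giving plant and
animal genomicists a reproducible, annotation-driven alternative to ad-hoc
"count the TEs near my gene" scripts.

## The statistic

For a gene with 0-based inclusive bounds (g0, g1) and a window length *w*,
TE density is the proportion of base pairs occupied by a TE grouping within
a region anchored on the gene:

- **upstream/left**: the window spans [g0 − 1 − w, g0 − 1] (clipped at 0),
  i.e. `w + 1` base pairs; the overlap of a TE (t0, t1) with it is
  `O_l = max(0, min(g0 − 1, t1) − max(g0 − 1 − w, t0) + 1)`;
- **intragenic**: the intersection with the gene body,
  `O_i = max(0, min(g1, t1) − max(g0, t0) + 1)` — window-independent;
- **downstream/right**: symmetric over [g1 + 1, g1 + 1 + w].

Overlaps are summed across all intervals of a grouping and normalised:

    rho_flank = sum(O) / (w + 1)        rho_intra = sum(O) / (g1 - g0 + 1)

Summation only stays bounded in [0, 1] because overlapping TEs are first
**revised**: merged into disjoint intervals in three independent passes —
within each order, within each superfamily, and across all TEs to form the
synthetic `Total_TE_Density` grouping. Without this step, nested or
double-annotated TEs would inflate densities past 100 %.

Each pseudomolecule yields a 4-D tensor over
(identity × window × gene × direction), persisted in one HDF5 store. Because
annotations list every gene's start as its smaller coordinate regardless of
strand, tensors are stored in left/intra/right orientation; on reading, the
flank slices of antisense genes are swapped so results are reported as
upstream/intragenic/downstream.

## Worked example

```r
library(tedensity)
library(dplyr)

syn <- generate_synthetic_genome(n_pseudomolecules = 1, n_genes = 10,
                                 n_tes = 50, seed = 42)
stores <- process_genome(syn$genes, syn$tes, "demo", tempfile("stores"),
                         windows = c(500L, 1000L, 5000L))
x <- read_density_store(stores$path)
x
#> <density_data> genome "demo", pseudomolecule "pm01": 10 genes, 3 windows,
#> 5 orders, 7 superfamilies (swap applied)

info_of_gene(x, "pm01_gene004", 1000) |>
  filter(level == "superfamily", direction == "upstream")
#> # A tibble: 5 × 7
#>   gene         window level       direction  rank identity         density
#> 1 pm01_gene004   1000 superfamily upstream      1 L1                 0.372
#> 2 pm01_gene004   1000 superfamily upstream      2 Total_TE_Density   0.372
#> 3 pm01_gene004   1000 superfamily upstream      3 No TE              0
#> 4 pm01_gene004   1000 superfamily upstream      4 No TE              0
#> 5 pm01_gene004   1000 superfamily upstream      5 No TE              0
```

Read: 37.2 % of the 1001 bp upstream of `pm01_gene004` is covered by L1
LINEs, and since the total-TE density equals the L1 density, L1 is the only
TE grouping there; the `No TE` rows pad the top-5 layout. A percentile
screen over the same slice:

```r
pct <- percentile_gene_list(x, "order", "Total_TE_Density", 1000,
                            "upstream", percentile = 75)
pct$cutoff
#> [1] 0.8936064
pct$genes
#> # A tibble: 3 × 3
#>   pseudomolecule gene         density
#> 1 pm01           pm01_gene008       1
#> 2 pm01           pm01_gene009       1
#> 3 pm01           pm01_gene010       1
```

i.e. the 75th percentile of pooled upstream total-TE density is 0.894, and
three genes sit at or above it (all with fully TE-covered upstream
windows). Downstream analyses: `bin_genes_by_density()` (density vs
expression), `syntelog_density_difference()` (presence/absence variation
between genomes), `tidy()`/`glance()` for data-frame access, `autoplot()`
for quick figures. Real annotations come in through
`read_gene_annotation()` / `read_te_annotation()` (cleaned TSV or GFF3) and
`identity_map()` handles grouping renames such as `EnSpm_Cacta → CACTA`.

A thin command-line front end wrapping these functions ships at
`system.file("cli", "tedensity", package = "tedensity")` with subcommands
`process`, `info-gene`, `percentile`, `bins` and `syntelog-diff`.

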