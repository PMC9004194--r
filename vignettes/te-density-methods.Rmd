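---
title: "Gene-centric TE density: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric TE density: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tedensity)
```

## The quantity being measured

Transposable-element density is the fraction of base pairs occupied by a TE
grouping in a region anchored on a gene. It is computed for every
combination of

* **identity** — a TE order (LTR, TIR, LINE, SINE, Helitron, ...) or
  superfamily (Copia, Gypsy, Mutator, Alu, ...), plus the synthetic
  `Total_TE_Density` grouping that ignores identity;
* **window** — a flank distance $w$ in base pairs, swept over a user-chosen
  grid;
* **gene** — one interval per gene, from the first-exon start to the
  last-exon stop. This deliberately coarse definition means "intragenic"
  cannot distinguish a truly intronic TE from one overlapping an exon; that
  is a modelling choice, not an oversight, and it keeps the method
  independent of transcript structure;
* **direction** — upstream, intragenic, downstream.

All internal coordinates are 0-based and inclusive on both ends, so a
feature's length is `stop - start + 1`. The two supported input formats
(cleaned TSV and GFF3) are 1-based inclusive on disk and are shifted by
−1 on both bounds at ingestion; the shift is an exact bijection, and writing
an annotation back restores the original numbers.

### Windows span w + 1 base pairs

For a gene starting at $g_0$, the left window of length $w$ is
$[\max(g_0 - 1 - w,\, 0),\; g_0 - 1]$ and the right window of a gene ending
at $g_1$ is $[g_1 + 1,\; g_1 + 1 + w]$. Both span $w + 1$ base pairs, and
flank densities are normalised by $w + 1$, not $w$ — the off-by-one is a
property of inclusive bounds and is preserved deliberately so that a TE
exactly tiling a window gives a density of exactly 1. Intragenic densities
are normalised by the gene length $g_1 - g_0 + 1$ and are replicated across
the window axis (they do not depend on $w$).

Two boundary conventions matter:

* windows are clipped at position 0 on the left, but **not** at the
  pseudomolecule end on the right — pseudomolecule length is not an input
  to the model, and the denominator stays $w + 1$ even when the window runs
  past the last annotated feature. Densities near the right end are thus
  conservative (biased toward 0) rather than inflated;
* a gene starting at position 0 has an empty left window and left density 0
  for every $w$.

The intragenic overlap is the *intersection* of the TE with the gene body:
$b_0 = \max(g_0, t_0)$, $b_1 = \min(g_1, t_1)$,
$O_i = \max(0, b_1 - b_0 + 1)$. Intersection bounds are the only choice
consistent with the normalisation by gene length and with densities bounded
by 1 (union-span bounds would let $O_i$ exceed the gene length whenever a
TE pokes past either gene edge).

## Why revision must precede summation

Real TE annotations contain overlapping entries — nested insertions and
annotation-software artifacts. Summing raw per-TE overlaps would count
shared base pairs twice and push densities past 100 %. The revision step
merges overlapping TEs *within matching groupings* in three independent
passes: per order, per superfamily, and across all TEs (producing
`Total_TE_Density`). After revision, every (pseudomolecule, level, label)
subset is a disjoint interval set whose union of covered base pairs equals
the input's, so summation is exact and bounded.

Two deliberate choices:

* **adjacent intervals are not merged.** Touching-but-not-overlapping
  intervals cover the same base pairs merged or not, so densities are
  provably identical either way; keeping them separate makes the merge a
  pure interval-union operation with an easily testable contract. The merge
  itself is delegated to `IRanges::reduce(min.gapwidth = 0)` — a sorted
  linear sweep — rather than a recursive per-seed search; the output
  contract (sorted, disjoint, union-preserving) is what the rest of the
  pipeline relies on.
* **TE strand is ignored.** Density is a coverage statistic; the model
  never conditions on which strand a TE was annotated on.

`density_flank()` still guards against unmerged input (a summed overlap
above $w + 1$ raises an internal-consistency error), but with revision in
place that code path is structurally unreachable.

Revision only needs to run once per annotation;
`write_revised_annotation()` caches it as a TSV carrying the source file's
MD5 digest, and reloading refuses a stale cache.

## Left/right versus upstream/downstream

Annotation files list every gene's start as its smaller coordinate
regardless of strand, so the tensors are computed and stored in
left/intra/right orientation. `read_density_store()` applies the biological
relabelling at initialisation: for antisense genes the left and right
slices are exchanged, so the accessor exposes upstream / intragenic /
downstream. The swap is an involution, touches only antisense flanks, never
touches intragenic slices, and never modifies the file; a `SWAPPED`
attribute in the store (always false on disk) plus a refusal to persist
swapped views prevents accidental double application.

## Storage layout

One HDF5 file per pseudomolecule (`{genome}_{pseudomolecule}.h5`) holds
both the order-level and superfamily-level tensors (`ORDER_DENSITY`,
`SUPERFAMILY_DENSITY`; axes identity × window × gene × direction, double
precision) together with their label vectors and scalar attributes.
Co-locating the two levels keeps per-gene reporting a single-file
operation. Identity axes are fixed genome-wide at write time: the sorted
unique label set with `Total_TE_Density` appended last, so every
pseudomolecule of a genome shares one axis and labels absent from a
pseudomolecule simply carry all-zero slices. Pseudomolecules are
computationally independent, so `process_genome()` can fork one worker per
pseudomolecule; stores are byte-identical for any worker count.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `windows` | 500–10 000 bp in 500-bp steps (20 windows) | flank sweep grid; each window spans `w + 1` bp |
| `identity_maps` | none | rename/drop rules applied before revision (e.g. `EnSpm_Cacta → CACTA`, or isolating Penelope elements from LINEs into their own PLE order) |
| `info_of_gene(n)` | 5 | entries per report section, padded with `No TE` at 0 |
| `percentile` | 99 | cutoff percentile; computed by linear interpolation between order statistics (`stats::quantile` type 7), with membership inclusive (density ≥ cutoff). The interpolation rule is a convention — published percentile-based gene lists rarely state theirs, so reproductions should fix and report it as done here |
| `bin_width` | 0.1 | density bins partition [0, 1]; all bins half-open `[a, b)` except the last, closed at 1.0, so fully covered genes are counted. Bin edges are resolved to within 1e-9 to sidestep binary floating point at boundaries such as 0.3 |
| `max_e_value` | 0.05 | syntelog pairs with a worse pairing E-value are discarded |

Unclassified TEs are retained under sentinel labels (`Unknown_Order`,
`Unknown_Superfam`) rather than dropped: unknown elements are often the
decayed, inactive fraction and excluding them would bias intragenic
densities. Genes without a strand symbol are treated as sense, with a
warning.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_genome()` produces seeded annotation pairs under the
package's default study conditions: one 100-kb pseudomolecule, 10 genes of
500–3000 bp placed without mutual overlap, 50 TEs of 100–2000 bp, a
plant-style identity alphabet (LTR/Copia, LTR/Gypsy, TIR/Mutator,
TIR/CACTA, LINE/L1, Helitron/Helitron), a 0.3 probability that a TE is
dropped onto an earlier TE of the same identity (guaranteeing the revision
merge real work), a 0.3 probability that it overlaps a gene, and half the
genes antisense. These sizes keep the exhaustive per-base checks below fast
while covering every edge case the arithmetic has: nested TEs, TEs
straddling window and gene boundaries, genes at position 0, antisense
genes, identities absent from a pseudomolecule.

What it does **not** emulate: realistic TE length distributions (LTR
elements are not an order of magnitude longer than SINEs here),
insertion-site preference, pericentromeric clustering, family-level
structure, or any correlation between TE presence and the opaque companion
scalars used in binning. Passing tests therefore demonstrate that the
*arithmetic* — merge, overlap, normalisation, swap, storage — is exact on
any annotation, not that biological conclusions drawn from real genomes are
correct; those still depend on annotation quality, which this method
inherits entirely from its inputs.

## The independent oracle

`oracle_density()` recomputes every tensor cell from an explicit per-base
boolean occupancy mask per grouping (union semantics make a merge step
unnecessary; nested TEs are inherently counted once) and reads densities
off the mask by counting. It shares no code with revision, overlap or
summation, so pipeline-equals-oracle — asserted cell-for-cell at an
absolute tolerance of 1e-12 over 100 seeded genomes in the test suite — is
a genuine end-to-end check of the whole chain. All densities are exact
ratios of small integers, so observed deviations are exactly zero; the
1e-12 tolerance is slack, not a rounding allowance. The oracle's explicit
masks cap it at roughly megabase instances; it refuses anything larger and
points to the main pipeline.

## Known limitations

* Gene = first-exon-start to last-exon-stop; no intron/exon resolution.
* Order and superfamily aggregate potentially disparate TE families;
  family-level densities are out of scope.
* Short-TE versus long-TE interpretation: several SINEs and one LTR element
  can produce the same density value.
* Density attribution is per-grouping, not per-TE: the method reports how
  much of a window is covered, not which element covers it.
* Right-edge windows are not clipped to the pseudomolecule, so genes at the
  extreme right report conservative flank densities (see above).
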