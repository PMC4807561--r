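# compactr

Comparative pattern counts for time-series differential expression.

## What it does and for whom

When a transcriptomics time course contrasts two conditions — an ethanol
diet versus its isocaloric control, disease versus normal — the comparative
question is not just *which genes respond* but *which genes respond the same
way in both conditions, only in one, or differently in each*. `compactr` is
for analysts of such designs (bulk or single-cell, microarray or RNA-seq
summaries, any log2 expression matrix with a baseline).

The method: per gene, compute the average log2 differential versus baseline
at each post-perturbation time point, then discretize at a fold-change
threshold θ into regulation levels

    ℓ = +1  if d ≥ log2 θ;   ℓ = −1  if d ≤ −log2 θ;   ℓ = 0  otherwise

(ternary by default; L = 2k+1 levels for k thresholds). A gene's length-T
level vector is its **pattern**, indexed canonically as a base-L integer
with the all-null pattern centered. Cross-tabulating pattern pairs between
the two conditions over all genes gives the **comparative pattern-count
matrix**: an L^T × L^T two-way histogram (27 × 27 = 729 cells for the
ternary, three-time-point case) whose cell (i, j) counts genes with pattern
i in the reference condition and pattern j in the comparison. The diagonal
is the common response; off-diagonal cells are altered responses; the null
row/column hold the *novel* and *missing* responses. The matrix supports
partitioning into sections by first-time-point regulation, masking for
layered exploration, threshold sweeps, two-proportion z-tests of pattern
membership, and chord-diagram layouts with a Circos Table-Viewer-compatible
export. A planted-pattern simulator makes the whole pipeline testable with
known ground truth.

## Worked example

```r
library(compactr)

sim <- simulate_compact_data(simulation_config(n_genes = 500, seed = 1))
m <- compact(sim$expression, reference = "carbohydrate",
             comparison = "ethanol", threshold = 1.5)
summary(m)
```

```
COMPACT matrix, 27 x 27 cells, 500 genes
  diagonal (common response): 13; off-diagonal (altered): 487
  non-zero cells: 374; masked: 0
  classification:
      common        novel      missing      altered unresponsive
          12           20           14          453            1
  genes per section (basis time):
 a  b  c  d  e  f  g  h  i
56 61 62 53 41 59 57 44 67
```

The 500 simulated genes carry uniformly random planted pattern pairs, so
mass spreads across the matrix: 13 genes sit on the diagonal (12 with a
common non-null response plus 1 unresponsive in both groups), 20 respond
only in the ethanol group (novel), 14 only in the control (missing), and
the 9 sections `a`–`i` partition all 729 cells by the two groups' 1 h
regulation (`e` is the no-early-response block). Recovery against the
planted truth is exact here:

```r
score_recovery(sim$truth, m)$fraction
#> [1] 1

proportion_ztest(30, 1000, 60, 1000)
#> two-proportion z-test: 30/1000 vs 60/1000  z = -3.236, p = 0.001212
```

Layered exploration and exports:

```r
m2 <- mask_cells(m, sections = "e")          # hide the 81-cell central block
cell_genes(m2, ref = 0, cmp = 0)             # genes up at all times in both
export_circos_table(m2, "circos_table.tsv", include_masked = FALSE)
render_compact_heatmap(m2, "compact.png")
```

A command-line wrapper with `build`, `sweep`, and `simulate` subcommands is
installed at `inst/cli/compact-cli.R` (see `?compact_cli`).

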