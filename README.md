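# bcrlineage

Paired single-cell BCR repertoire + transcriptome lineage analysis in R.

In tumors such as triple-negative breast cancer (TNBC), the infiltrating
B-cell compartment differs sharply from matched peripheral blood (PBMC):
more and larger clones, higher somatic hypermutation (SHM), and a larger
class-switched fraction. Linking each cell's rearranged immunoglobulin
heavy chain (IGH) to its expression cluster makes clonal lineages traceable
across transcriptional states. `bcrlineage` implements that analysis as a
tested, tidyverse-style pipeline for anyone working with 10x-style paired
V(D)J + gene-expression data:

- **Chain/cell QC** — the cell-count-dependent doublet budget
  `X = (0.000879·N + 0.702)·0.01·N` (floored); top-scored doublet
  exclusion; gene-count (200–5000) and mitochondrial (≤50%) filters;
  single-productive-IGH selection with the strict 10-fold UMI dominance
  rule; removal of BCR/TCR double-positive barcodes (TCR-positive = both
  TRA and TRB assembled).
- **Clone calling** — two cells share a clone iff they have the same V, D,
  J gene usage and the same junction length (inferred common germline);
  SHM number/frequency over V and J segments only; isotype class,
  class-switch and germline status; clonal-fraction and clone-size
  summaries; public-clonotype matching (shared (V, J, CDRH3-aa) triples)
  with a 2×2 chi-square contrast.
- **Lineage sharing across clusters** — same-germline and same-sequence
  cell-pair events counted within/between expression clusters, split into
  TNBC / PBMC / mixed compartment groups and normalized per 10,000:
  `N_norm = (N/N_A)·(N/N_B)·10⁴`.
- **Expression scoring** — library-size normalization, gene-signature
  scores with per-cluster mean z-scores, UMI-fraction cell-cycle score,
  S/G2M module scores with the strict `>0.1 and > other` phase rule, and
  top/bottom-33% tertile stratification for survival analysis
  (`floor(n·fraction)` per tail; 279 patients → 92 + 92).
- **Synthetic data** — a generator for paired multi-sample tumor/blood
  repertoires and expression matrices with full ground truth (planted
  clones, SHM rates, switch probabilities, doublets, planted signature and
  cell-cycle effects), so the whole pipeline is testable without patient
  data.

## Worked example

```r
library(bcrlineage)
library(dplyr)

sim <- simulate_paired(sim_config(n_cells_per_sample = 300, seed = 42))
qc  <- repertoire_qc(sim$records, sim$meta)
rec <- qc$records |> assign_clones() |> add_shm_stats() |> add_bcr_status()
repertoire_summary(rec, group_by = "compartment")
#> # A tibble: 2 × 6
#>   compartment n_cells clonal_fraction germline_fraction switched_fraction
#>   <chr>         <int>           <dbl>             <dbl>             <dbl>
#> 1 blood          1369          0.0665           0.0584              0.306
#> 2 tumor          1368          0.183            0.00219             0.588
```

The tumor repertoire recovers the planted contrasts: ~18% of tumor B cells
sit in clones of size ≥2 versus ~7% in blood, germline (zero-SHM) receptors
are rare in tumor, and the switched fraction is about twice the blood
value.

```r
ev <- count_sharing_events(rec, qc$meta, "same_germline", "low") |>
  normalize_sharing()
sharing_matrix(ev, "TNBC")
#>          atypical memory  naive plasma
#> atypical     3.70    166  26.99   1.21
#> memory     165.94    263 127.92 150.75
#> naive       26.99    128   6.93   4.97
#> plasma       1.21    151   4.97   6.33
autoplot(ev)   # heatmap facets per compartment group

doublet_exclusion_count(c(2000, 10000))
#>   n_cells x_exact x_exclude
#> 1    2000    49.2        49
#> 2   10000   949.        949

cohort <- tibble::tibble(patient_id = sprintf("P%03d", 1:279),
                         score = rnorm(279))
table(stratify_patients(cohort)$group)
#> bottom middle    top
#>     92     95     92
```

Each matrix cell is the per-10,000 normalized count of same-germline cell
pairs linking two clusters; the diagonal is within-cluster clonal
expansion. The doublet budget and the 92/92 tertile split are the two fixed
numerical anchors of the pipeline.

## Package tour

| area | functions |
| --- | --- |
| simulation | `sim_config()`, `simulate_repertoire()`, `simulate_expression()`, `simulate_paired()`, `simulate_reference_clonotypes()` |
| QC | `doublet_exclusion_count()`, `exclude_top_scored()`, `qc_filter_cells()`, `select_single_productive_igh()`, `flag_bcr_tcr_doublets()`, `repertoire_qc()` |
| clones | `assign_clones()`, `clone_table()`, `add_shm_stats()`, `add_bcr_status()`, `repertoire_summary()`, `clone_size_distribution()`, `extract_clonotypes()`, `public_clone_fraction()` |
| sharing | `count_sharing_events()`, `normalize_sharing()`, `sharing_matrix()`, `autoplot()` |
| scoring | `normalize_library()`, `score_signature()`, `cluster_signature_means()`, `cell_cycle_score()`, `module_score()`, `assign_phase()`, `score_cell_cycle()`, `stratify_patients()` |
| IO | `read_rearrangements()`, `write_rearrangements()`, `read_cell_meta()`, `write_cell_meta()`, `read_expression_mtx()`, `write_expression_mtx()`, `read_gene_list()` |

See `vignettes/bcr-lineage-methods.Rmd` for the modelling choices,
parameter meanings and known limitations.
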