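# cardiolinc

Single-cell RNA-seq analysis of coding transcripts, long non-coding RNAs
(lncRNAs) and positionally conserved lncRNAs (pcRNAs) across heart
compartments and developmental stages — packaged as a tested, reusable R
pipeline for transcriptomics researchers who want each stage of such an
analysis as an inspectable, reproducible function rather than a one-off
script.

The pipeline covers, per dataset (one heart compartment at one developmental
stage):

1. **Preprocessing** — FPKM normalisation
   (`FPKM = counts / ((L/10³)·(N/10⁶))`) and prevalence filtering
   (transcript kept iff expressed in ≥ 5% of cells, boundary inclusive).
2. **Clustering** — Pearson dissimilarity `d = 1 − r` on log₂(FPKM+1) over
   dropout-selected variable genes, Ward agglomeration, and selection of the
   number of clusters K by maximising the mean silhouette
   `s(i) = (b − a)/max(a, b)` over K ∈ 2..10.
3. **Variable genes by dropout modelling** — dropout probability modelled as
   Michaelis–Menten in the mean, `P = 1 − S/(K_M + S)`; the global `K_M` is
   fitted by least squares, each gene's own constant
   `K_j = S_j P_j/(1 − P_j)` is tested (right tail, delta-method normal
   approximation, Benjamini–Hochberg) against it.
4. **Cell-type assignment** — each cluster's elevated variable genes are
   overlapped with a heart cell marker database; the adherence (chi-squared
   goodness-of-fit) statistic `X² = Σ_t (O_t − E_t)²/E_t` with expectations
   proportional to marker-set size assigns the type with the largest
   standardised residual, or `Unknown`; marker counts are stratified by
   biotype and compared across compartments as Venn region counts.
5. **Subpopulation differential expression** — when two clusters share an
   assigned type (the two-cardiomyocyte case), a negative-binomial Wald test
   ("DESeq2-lite": median-of-ratios size factors, moment dispersions under
   `Var = μ + φμ²`, `z = log(μ̂₂/μ̂₁)/SE`) with volcano counts per biotype at
   fold-change/significance cut-offs 1.5/0.05, and subpopulation naming
   `<TopCodingGene>-CM`.
6. **Enrichment** — hypergeometric over-representation with gene ratio
   observed/expected `k/(n_q K_s/N)`, and cell-label-permutation GSEA
   (signal-to-noise ranking, running-sum enrichment score, NES).
7. **Co-expression modules** — soft power β by scale-free topology fit
   (signed R² ≥ 0.8 with a mean-connectivity floor), topological overlap
   `TOM_ij = (L_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`, average-linkage tree
   cut, hub genes by intramodular connectivity, per-module ORA and
   per-cell-type GSEA — including the explicit `no-modules` outcome for
   datasets without modular patterns.

Because the original data require controlled access, the package ships a
first-class **synthetic-data generator** (`generate_dataset()`) that plants
every structure the pipeline is supposed to find — cell types with
marker-elevated genes, two cardiomyocyte-like subpopulations with known fold
changes, co-expression modules with known membership, Michaelis–Menten
dropout with known constant — so every stage is benchmarked against ground
truth. See the methods vignette (`vignettes/cardiolinc-methods.Rmd`) for the
models, defaults and design decisions.

## Worked example

```r
library(cardiolinc)

ds <- generate_dataset(generator_config(seed = 1))   # 2000 genes x 500 cells
report <- run_pipeline(
  run_config(seed = 1),
  data = list(counts = ds$counts, annotation = ds$annotation,
              markers = ds$markers,
              gene_sets = gene_set_collection(ds$truth$modules_of)))
print(report)
```

```
RunReport (cardiolinc 0.1.0 )
  expressed transcripts: coding=1182, lncRNA=592, pcRNA=194
  clustering: K = 5, mean silhouette = 0.467
  assignments: 1->cardiomyocyte, 2->endothelial, 3->fibroblast, 4->macrophage, 5->myoblast
  modules: 1 (sizes 1476)
```

The report says: after the 5% prevalence filter, 1182 coding, 592 lncRNA and
194 pcRNA transcripts remain; the silhouette criterion selects K = 5
clusters (mean silhouette 0.467), and each cluster is assigned its planted
cell type by the adherence test. On this heterogeneous dataset module
discovery returns one dominant co-expression component — the cell-type
structure correlates many genes at the small selected power (the methods
vignette discusses this, and the module benchmark that recovers planted
modules on homogeneous cells).

The stage objects are attached for inspection:

```r
st <- attr(report, "stages")
st$dropout_fit$K        # fitted Michaelis-Menten constant: 11.32 (se 0.095)
length(st$variable_genes)  # 96 dropout-variable genes
st$assignment           # per-cluster chi-squared, p, q, overlaps
```

```
 cluster assigned_type chi2            p            q top_overlap
       1 cardiomyocyte   64 4.179175e-13 5.223968e-13          16
       2   endothelial   72 8.582234e-15 2.145559e-14          18
       3    fibroblast   64 4.179175e-13 5.223968e-13          16
       4    macrophage   56 2.005176e-11 2.005176e-11          14
       5      myoblast   72 8.582234e-15 2.145559e-14          18
```

With `outdir` set in `run_config()`, every intermediate is written as a
deterministic TSV (clusters, silhouette table, assignments, DE tables,
volcano counts, module membership, hubs) plus a JSON report; re-running with
the same configuration and seed reproduces the files byte for byte.

A thin command-line wrapper with subcommands
`simulate | preprocess | cluster | celltype | de | ora | modules | run`
is installed at `inst/scripts/cardiolinc.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/cardiolinc.R", package="cardiolinc"))')" \
  simulate --outdir data/sim --seed 1
```

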