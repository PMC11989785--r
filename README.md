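# cocultalk

Bulk RNA-seq analysis for two-cell-type co-culture experiments, built for
the question: *when two cell populations share a medium, which genes
change, and which ligand–receptor pairs carry the conversation?* The
motivating system is a transwell co-culture of intramuscular
preadipocytes (IMAdCs) and skeletal muscle satellite cells (SMSCs) —
four groups (each cell type, mono- and co-cultured) with three
biological replicates — but the pipeline applies to any such design.

The package provides, end to end:

- **Normalization & QC** — FPKM, log10(FPKM + 1), per-sample Pearson
  correlation, PCA (samples as observations, gene-centered), and
  average-linkage hierarchical clustering on correlation distance.
- **Differential expression** — a negative-binomial Wald test on
  median-of-ratios-normalized counts. With group means
  $\bar{m}_1, \bar{m}_2$, the statistic is

  $$\log_2\!FC = \log_2\frac{\bar{m}_1}{\bar{m}_2},\qquad
    z = \frac{\log_2\!FC}{\widehat{SE}},$$

  where the standard error comes from the delta method applied to the
  NB variance $\mu + \alpha\mu^2$ (dispersion $\alpha$ estimated by
  method of moments, shrunk halfway toward a loess mean–dispersion
  trend). DEGs are called at BH-adjusted $p < 0.05$ and
  $|\log_2 FC| > 1$ (strict), and multi-contrast overlaps are
  partitioned into UP / DOWN / CONFLICT.
- **Over-representation analysis** — exact upper-tail hypergeometric
  tests of DEG lists against a GMT collection, BH-corrected, with
  Sankey-ready gene–term incidence tables.
- **Network analysis** — DEG-induced subgraphs, degree-ranked hubs, and
  module detection (default k = 3) by spectral embedding of the
  symmetric normalized Laplacian followed by k-means.
- **Ligand–receptor crosstalk** — the core analysis. DE ligands and
  receptors (screened against a CellTalkDB-dialect database) are paired
  under direction rules covering two methods (method 1: mono-vs-co
  contrasts; method 2: the co-vs-co contrast) and two modes (autocrine
  within a population, paracrine across populations). Each pair is
  scored by its **communication score**

  $$CS = 2^{|\log_2 FC_L|}\cdot 2^{|\log_2 FC_R|},$$

  the product of the members' fold-change magnitudes, and ranked within
  its (mode, method, source, target) stratum.
- **Synthetic data with planted truth** — seeded generators for NB
  counts with planted effects, LR scenarios with decoys, and
  stochastic-block-model networks, so every stage's recovery is
  measurable.

## Worked example

Simulate the study design with two planted paracrine SMSC→IMAdC pairs
(ligand up in SMSC mono-vs-co, receptor down in IMAdC mono-vs-co, planted
|log2FC| = 2) and five decoy database pairs, then run the inference:

```r
library(cocultalk)

cfg  <- simConfig(nGenes = 500, nRepsPerGroup = 3,
                  baselineLog2Mean = c(7, 0.5), dispersion = 0.05,
                  seed = 42)
scen <- simulateLRScenario(cfg, nTruePairs = 2, nDecoys = 5)
scen$db
#> LRDatabase: 7 pairs, 7 ligands, 7 receptors
#> provenance: synthetic LR scenario

results <- lapply(studyContrasts(), function(cs)
    nbWaldContrast(scen$experiment,
                   contrastSpec(cs$name, cs$first, cs$second)))
results$IMAdC_mono_vs_co
#> ContrastResult 'IMAdC_mono_vs_co': IMAdC/mono vs IMAdC/co
#>   500 genes; 0 UP, 2 DOWN at padj < 0.05 and |log2FC| > 1

pairs <- runCrosstalk(results, scen$db)
pairs[, c("rule", "ligand", "receptor", "ligand_log2fc",
          "receptor_log2fc", "cs", "rank")]
#>                    rule ligand receptor ligand_log2fc receptor_log2fc    cs rank
#> 1 m1_para_SMSC_to_IMAdC  G0001    G0003         1.885          -1.947 14.23    1
#> 2 m1_para_SMSC_to_IMAdC  G0002    G0004         1.795          -1.783 11.94    2
```

Both planted pairs — and only they — are recovered in the correct
stratum. The two DOWN calls in the IMAdC contrast are the planted
receptors; the estimated log2 fold changes (±1.8–1.9) recover the
planted ±2 within sampling error, and each CS is the product of the two
fold-change magnitudes ($2^{1.885}\cdot2^{1.947}\approx14.2$).

`runPipeline()` (or `inst/scripts/run_pipeline.R` with a YAML config)
chains every stage and writes a deterministic output tree —
`qc/`, `de/<contrast>/`, `enrichment/<contrast>/<direction>/`,
`network/`, `crosstalk/` — plus a `manifest.json` that suffices to
re-execute the run.

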