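# metaBSH

Quantification of metal-dependent bile salt hydrolase (BSH) gene families
in metagenomes and metatranscriptomes.

Gut bacteria deconjugate bile salts with BSH enzymes. Alongside the
classical cysteine-dependent BSHs, a family of metal-dependent
amidohydrolases with a dinuclear zinc active site ("metalloBSHs") carries
this activity in taurine-respiring organisms. Assessing such a family in
microbiome data takes a chain of steps, and this package implements all
of them as tested R functions:

* **Family delineation** — affine-gap global/local protein alignment
  (BLOSUM62, C++ core), sequence similarity networks with
  connected-component extraction (`buildSSN()`, `extractCluster()`),
  greedy 65%-identity clustering with score-sum representatives
  (`greedyCluster()`), and a conserved active-site residue filter that
  rejects sequences lacking a complete dinuclear metal centre
  (`checkKeyResidues()`).
* **Quantification** — a target+decoy reference database
  (`assembleReferenceDB()`), six-frame translated read search with a
  shared-k-mer prefilter (`searchReads()`), strict >90%-identity
  filtering with highest-identity best-hit assignment and decoy
  exclusion (`assignBest()`), RPKM and average-genome-size normalization
  with presence calls at a 1e-4 threshold (`abundanceTable()`).
* **Statistics** — Spearman correlation of summed family abundance
  against metabolite panels with Benjamini–Hochberg adjustment
  (`correlateMultiomics()`), chi-square prevalence comparisons
  (`prevalenceTest()`), half-minimum pseudo-count log transforms for
  plotting layers (`halfMinPseudocount()`).
* **Transcripts** — TPM quantification and median-log10 ranking with
  top-decile/centile flags (`tpm()`, `rankGenes()`).
* **Assay analytics** — Michaelis–Menten fitting with kcat/Km
  (`fitMM()`), end-point activity percentages, exact ESI adduct masses
  (`adductMz()`), and dinuclear metal-site distances from PDB
  coordinates (`metalPairDistance()`).
* **Synthetic data** — seed-reproducible generators for homolog
  families, metagenomic reads with recorded provenance, coupled
  metabolomes with closed-form Spearman calibration, transcript counts
  and kinetics datasets (`simulateCommunityStudy()` and friends), so the
  whole pipeline validates against known ground truth.

## Worked example

Simulate a small multi-omic study with a planted negative gene–metabolite
coupling, run the full pipeline, and inspect the association table:

```r
library(metaBSH)

study <- simulateCommunityStudy(seed = 42, nSamples = 30, nReads = 250,
                                readLen = 105, nTargets = 3, nDecoys = 6,
                                targetLen = 180, decoyLenRange = c(150, 210))
res <- runCommunityPipeline(study)

res$mappings[[1]]
#> MappingResult: 24/250 reads assigned (identity > 90%); 223 decoy-best discarded, 3 below identity

res$associations
#>   gene_set_id metabolite_id  n         rho        p_raw        p_adj
#> 1      family       coupled 30 -0.64360400 0.0001245915 0.0004983659
#> 2      family        null_1 30 -0.01446051 0.9395449586 0.9395449586
#> 3      family        null_2 30 -0.13548387 0.4753226726 0.8278146555
#> 4      family        null_3 30  0.09410456 0.6208609916 0.8278146555
```

Each sample's reads were translated in six frames, aligned to the
target+decoy database, filtered at strict >90% amino-acid identity and
assigned to their highest-identity protein; reads whose best hit is a
decoy are discarded (here most reads, since 90% of the simulated
community is decoy background). Counts become RPKM, are divided by each
sample's average genome size in Mb, and the summed family abundance is
correlated against the metabolite panel. The planted coupling
(Spearman rho −0.45 on the `coupled` metabolite) is recovered with the
expected sampling noise at n = 30, while the null metabolites stay
non-significant after BH adjustment.

Single-purpose utilities work standalone:

```r
adductMz("C24H41NO5", "M+H")
#> [1] 424.3057
fitMM(S = c(10, 50, 200, 1000, 5000, 20000),
      v = c(0.066, 0.28, 0.8, 1.71, 2.23, 2.37), enzymeNM = 5)
#> MMFit: Vmax = 2.412, Km = 403.6, kcat = 482.4 1/s, kcat/Km = 1.2e+06 1/(M s)
```

## Package layout

S4 classes (`AlignmentResult`, `SSNGraph`, `ReferenceDB`,
`MappingResult`, `MMFit`) carry the pipeline's central objects; abundance
and expression tables are `SummarizedExperiment`s with assays
`raw_count`, `rpkm`, `ags_norm` and `presence`. The methods vignette
(`vignettes/metaBSH-methods.Rmd`) documents the models, parameter
defaults, numerical conventions and the limits of what the synthetic
validation shows.
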