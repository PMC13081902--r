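---
title: "Quantifying a metalloenzyme gene family in metagenomes: methods and design"
author: "metaBSH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a metalloenzyme gene family in metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaBSH)
```

## The problem

Bile salt hydrolases (BSHs) deconjugate glycine- and taurine-conjugated
bile acids in the gut. Beyond the long-known cysteine-dependent
N-terminal-nucleophile BSHs, a class of metal-dependent amidohydrolases
with BSH activity (dinuclear zinc active site, here "metalloBSH") has been
described in taurine-respiring gut bacteria such as *Bilophila
wadsworthia*. Asking whether such a family matters *in vivo* requires a
chain of computational steps: delineate the family from protein sequences,
quantify its genes in shotgun metagenomes and metatranscriptomes, and
correlate the abundances with bile-acid metabolomes. **metaBSH**
implements that chain as a tested, reusable pipeline and ships a
synthetic-data generator with known ground truth, so each stage - and the
pipeline end to end - can be validated against planted answers.

## Pairwise alignment

All sequence comparison rests on affine-gap pairwise protein alignment
(`globalAlign()`, `localAlign()`), implemented in C++ with BLOSUM62
scoring. A gap of length $L$ costs $g_o + L \cdot g_e$. Defaults are
$g_o = 10$, $g_e = 0.5$ for global alignment and $g_o = 11$, $g_e = 1$ for
the local alignments of the translated search, emulating common
pairwise-aligner and translated-search defaults; the literature rarely
states which aligner produced a printed "percent identity", so these
defaults are a documented convention, not a reproduction of any one tool.

Three conventions are fixed deliberately:

* **Identity denominator.** Percent identity divides the number of
  identical columns by *all* alignment columns, gap columns included
  (`denominator = "columns"`); dividing by the shorter sequence length is
  available via `denominator = "shorter"` because reporting conventions
  differ between tools and neither is canonical.
* **Ambiguity.** `X` scores 0 against every residue, and neither `X` nor
  the stop symbol `*` ever counts as identical. Ambiguous translated
  codons therefore neither reward nor punish an alignment.
* **Tie-breaks.** Co-optimal tracebacks resolve deterministically
  (diagonal over up over left), so identical inputs always give identical
  alignments.

Correctness is established against two independent routes: an exhaustive
recursive enumeration of every alignment path (no dynamic programming)
for short sequences, and `Biostrings::pairwiseAlignment()` on random
pairs. The enumeration is exponential, so the tests run it for global
alignments up to length 8 and local alignments up to length 5; beyond
that the recursion tree (which grows like the Delannoy numbers times gap
states) stops being a reasonable test-time oracle.

## Family delineation

`buildSSN()` computes an all-vs-all sequence similarity network: an edge
joins two proteins when their global alignment passes both a score cutoff
and a minimum percent identity (default 31%). Connected components
approximate isofunctional families, and `extractCluster()` returns the
component containing a seed enzyme. The score cutoff is expressed on this
package's raw alignment-score scale and is a free parameter: published
SSN cutoffs are tool-specific (typically $-\log_{10} E$-value styled) and
do not transfer between aligners, so the package expects the user to
calibrate the cutoff such that known within-family pairs connect and
unrelated pairs do not - which is exactly how the tests choose it for
synthetic families.

`greedyCluster()` reduces redundancy at a 65% identity threshold using a
deterministic greedy pass in descending length order; after assignment
the representative of each cluster is the member with the highest summed
alignment score to its co-members (ties: longest, then lexicographic id).
The internals of any particular published clustering tool are not
reproduced - only the contract above, which the tests verify against an
exhaustive score-sum computation.

`checkKeyResidues()` guards the family against partial or truncated
sequences: a candidate is globally aligned to the full-length reference
enzyme and must show the expected residue in every column corresponding
to the dinuclear-metal ligands (H110, H112, K373, H441, H474, D583 in
reference coordinates) and, by default, the substrate-recognition set
(S194, H196, Q381, N443, H544). The carboxylated lysine at 373 is matched
as plain K, because post-translational carboxylation is invisible in
primary sequence. A gap at any profile column means the site is absent.
`assembleReferenceDB()` then splits the input into targets (cluster
members passing the filter) and decoys (everything else, including
failed cluster members), preserving the total count.

## Translated search and best-hit assignment

`searchReads()` translates each read in six frames (stops as `*`,
N-containing codons as `X`, trailing partial codons dropped) and locally
aligns frames against database entries. A shared amino-acid k-mer
prefilter (default $k = 4$, at least one shared k-mer) limits the
alignment work; disabling it (`prefilter = FALSE`) gives the exhaustive
search the tests compare against. Reporting is score-based with a minimum
reported score of 50 by default: a local alignment can be very short yet
100% identical, and the threshold is set so that such chance alignments -
seeded by random k-mer collisions between unrelated sequences - fall
below it, while any genuine read-length match (which scores in the
hundreds) passes. No E-value is computed; the downstream quantification
depends on the identity filter and the best-hit rule, not on E-value
calibration, and this is a deliberate divergence from translated-search
tools.

`assignBest()` applies the quantification rules: hits at or below 90%
identity are dropped (the filter is strict `>`), the surviving hit with
the highest identity wins (ties: score, then smallest target id), and a
read whose winner is a decoy is discarded and counted. Identity is
computed over the local alignment length by default; the read-length
convention is available through the alignment's identity denominator.

## Abundance, presence, association

Counts are normalized per sample as

$$\mathrm{RPKM} = \frac{c}{\left(3 L_{aa}/1000\right)\,\left(N/10^6\right)},$$

with $L_{aa}$ the protein length (converted to coding-nucleotide
kilobases; an amino-acid-kilounit alternative is available) and $N$ the
sample's total read count, then divided by the sample's average genome
size in Mb (`agsNormalize()`). AGS is a supplied per-sample input - this
package does not estimate it. Because every downstream statistic is
rank-based, any consistent AGS unit yields identical conclusions. A gene
is called present when its AGS-normalized abundance strictly exceeds
$10^{-4}$; the synthetic spike-ins are calibrated to straddle this
default rather than asserting unit equivalence with any particular real
dataset.

Family-level association uses the summed family abundance per sample.
`correlateMultiomics()` intersects sample ids with the metabolite table
(paired design only), computes Spearman's $\rho$ on untransformed values
per metabolite, and adjusts p-values across the metabolite panel with
Benjamini-Hochberg. The Spearman p-value uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, adequate for the tens-to-hundreds of
samples this pipeline targets; an exact permutation option exists for
$n < 10$. Perfect monotone association would give $p = 0$ under the t
approximation, which is clamped to the smallest positive double so that
the BH domain contract $p \in (0,1]$ holds. Missing metabolite values are
dropped pairwise, never imputed. For plotting layers,
`halfMinPseudocount()` adds half of the dataset-wide minimum non-zero
value before log transform (log2 for gene abundances, log10 for
metabolites); one pseudo-count per dataset is the default reading of
"each respective dataset", with a per-column mode available. Since
Spearman is invariant under strictly monotone transforms, correlating
transformed or untransformed layers gives identical $\rho$ - the tests
assert this directly.

Prevalence differences between groups use the Pearson chi-square on the
groups-by-detection contingency table without continuity correction
(none is standard for this use); a Yates flag exists for the corrected
2-group variant.

## Transcript ranking

`tpm()` computes transcripts per million per replicate
($10^6 \cdot (c_g/L_g) / \sum_h (c_h/L_h)$; each column sums to $10^6$).
`rankGenes()` takes the per-gene median of $\log_{10}(TPM+1)$ across
replicates (transform before median, matching the stated sequence; with
an odd replicate count both orders agree, and both are exposed), sorts
descending with lexicographic tie-breaks, and flags the top decile and
centile with a ceiling boundary: rank $\le \lceil 0.10\,n \rceil$ and
$\le \lceil 0.01\,n \rceil$. The boundary rule is a package convention -
percentile edges are rarely defined in publications.

## Kinetics and chemistry utilities

`fitMM()` fits $v = V_{max} S/(K_m + S)$ by unweighted Levenberg-
Marquardt least squares (via minpack.lm), initialized at
$V_{max,0} = \max v$ and $K_{m,0} = S$ at half-maximal rate, with up to
500 iterations and a $10^{-10}$ relative tolerance. With the enzyme
concentration supplied, $k_{cat} = V_{max}/[E]$ and $k_{cat}/K_m$ is
reported in $M^{-1}s^{-1}$. Non-convergence returns a flagged result
rather than an error. Published catalytic efficiencies for this family
(order $10^5\ M^{-1}s^{-1}$) serve only as magnitude guidance for the
simulator, never as asserted values - they cannot be reproduced without
the raw assay data. End-point assays are summarized by
`relativeActivity()` (vs a no-variant control under initial-rate
conditions) and `conversionRate()` (vs wild type after extended
incubation); dose-response and pH profiles are reported as tables of
these percentages, not fitted to 4PL curves.

`adductMz()` computes exact electrospray adduct masses from monoisotopic
atomic masses (IUPAC values, 8 decimals) including the electron mass -
high-resolution "calculated" values include it. `metalPairDistance()`
reads ATOM/HETATM records (via bio3d) and reports the closest distinct
pair of atoms of a requested element, preferring pairs within one chain,
as a check on dinuclear metal sites in predicted structures.

## The synthetic-data generator

`simulateCommunityStudy()` generates everything the pipeline consumes,
with all randomness flowing from one seed (the same seed regenerates the
study byte-identically):

* **Protein families**: one ancestral target protein, homologs mutated to
  a target identity band (60-85% by default, spanning realistic
  within-family divergence) with the key active-site residues protected,
  plus unrelated random decoys. `mutateToIdentity()` re-measures identity
  with the package's own `globalAlign()` until it lands within +/-2
  points of the target.
* **Coding sequences**: deterministic reverse translation using the most
  frequent *E. coli* codon per residue, so frame +1 of a CDS
  round-trips exactly to the protein.
* **Reads**: drawn from genes proportional to abundance times length,
  uniform start and strand, independent per-base substitution errors
  (1% by default; indels are deliberately excluded from the default
  error model so that per-read identity stays analytically predictable).
  Every read's source is recorded.
* **Per-sample truth**: family relative abundance is log-normal across
  samples (median about 10% of the community), average genome size
  uniform on 2.5-5.5 Mb, total reads as stated.
* **Metabolome**: the coupled metabolite is built through a Gaussian
  copula on the abundance ranks. For a bivariate normal with Pearson
  correlation $\rho_P$, the population Spearman correlation is
  $\rho_S = (6/\pi)\arcsin(\rho_P/2)$; inverting this gives the noise
  standard deviation in closed form, so the realized Spearman
  correlation is on target ($-0.45$ by default) in expectation, with no
  iterative tuning. A monotone log-normal mapping then produces a
  plausible concentration scale without touching the ranks. Independent
  null metabolites are appended.

What the generator does *not* emulate: real genome backgrounds and
shared domains between families, quality-score-dependent error profiles,
indels, paired-end structure, compositional effects, or longitudinal
repeated measures. Passing the end-to-end tests therefore demonstrates
that the pipeline's logic is correct under its stated model - exact
provenance, substitution-only noise, monotone coupling - not that any
particular biological dataset would yield a given effect size.

## Problem sizes used in validation

The generator's reference scale (10 samples, 10^4 reads per sample, 10
targets plus 50 decoys) runs in minutes on one CPU. The end-to-end
coupling-recovery study uses 209 paired samples - the intestinal
sample size the association analysis is designed around - and chooses
compact per-sample sequencing (250 reads of 105 nt against 3 targets and
8 decoys) so that 20 replicate studies complete in a few minutes while
leaving per-sample family counts (tens of reads) informative enough for
rank statistics. With the family's across-sample abundance spread much
larger than its counting noise, the estimated abundance tracks the
planted truth at rank correlation above 0.95, and the estimated
gene-metabolite correlation recovers the planted $\rho = -0.45$ with a
small attenuation (about 0.02) plus the sampling variability of a
Spearman coefficient at $n = 209$ (s.d. about 0.06 per study).

## Known limitations

* The SSN score cutoff is not portable to or from other aligners; only
  the identity threshold is comparable across tools.
* The translated search is exact within its reporting threshold but has
  no E-value model; sensitivity at very low identity is governed by the
  k-mer prefilter.
* The Spearman t-approximation is asymptotic; for very small panels at
  $n < 10$ use the permutation option.
* `fitMM()` assumes initial-rate data; it does not model substrate
  depletion or product inhibition.
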