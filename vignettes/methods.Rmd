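---
title: "Models and methods in ribopost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ribopost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopost)
```

# Scope

`ribopost` implements an integrative post-transcriptional analysis of
matched ribosome-profiling (Ribo-seq), mRNA-seq and small-RNA-seq count
data: quality control of ribosome-protected fragments (RPFs), negative-
binomial differential expression, translational-efficiency (TE) testing,
regulatory-mode classification, sequence-feature stratification, and
miRNA/tRNA-derived small RNA target analysis. Because the questions the
pipeline answers are statistical (is a change real? is an offset
recoverable? does repression scale with site count?), the package ships a
synthetic-data generator that plants known regulatory structure, and every
estimator is validated against that recorded truth. This vignette explains
the models, the defaults and why they were chosen, and what the synthetic
validation does and does not establish.

# The synthetic experiment

The generator emulates a repeated-depolarization design: three conditions
(resting `control`, immediately post-stimulus `t0h`, and `t2h` after a 2-h
rest phase) in biological quadruplicate, assayed by mRNA-seq, Ribo-seq and
small-RNA-seq.

**Transcriptome.** `make_transcriptome()` emits single-isoform models in
transcript space (no genome, no isoforms): 5'UTR + CDS + 3'UTR with
0-based half-open coordinates. The CDS starts with ATG, ends with one stop
codon, and internal in-frame stops are rejection-sampled away. Bases are
i.i.d. with per-region GC targets (defaults 0.60/0.52/0.44 for
5'UTR/CDS/3'UTR, mirroring the GC gradient of human transcripts); default
region lengths (100-300, 300-660, 150-450 nt) are deliberately below
genome scale so that the O(n^3) folding step stays affordable, which is a
problem-size choice, not a biological claim.

**Regulatory modes.** `plant_modes()` assigns one of five modes per gene
with the fixed effect map: homodirectional (±e, ±e with the same sign),
opposite (±e, ∓e), transcriptional (±e, 0), translational (0, ±e), stable
(0, 0), with e = 1 log2 unit by default and signs drawn 50/50. The 0 h
mixture is transcription-heavy (0.35/0.17 transcriptional/translational)
and the 2 h mixture mirrors it, reproducing the qualitative buffering
asymmetry between early and late responses without copying any
dataset-dependent numbers.

**Counts.** `simulate_counts()` draws NB(mean = baseline x 2^log2fc x
depth, Var = mu + phi mu^2); phi = 0 degenerates to Poisson. Baselines are
log-normal (sdlog 1) relative abundances. The default dispersion is phi =
0.01 (BCV 0.1), appropriate for a homogeneous immortalized cell line;
calibration checks deliberately use a rougher phi = 0.1 to stress the
test. Library sizes are not renormalized after fold changes are applied,
so asymmetric regulation induces exactly the composition bias TMM exists
to remove.

**RPF reads.** `simulate_rpf_reads()` places each read so its P-site
(5' end + offset, default 12 nt — the conventional mammalian value) falls
in the CDS with probability 1 − leakage (default 0.05, split evenly
between UTRs), on a uniformly chosen codon except codon 0, which carries a
5x initiation-peak weight, and in frame 0 with probability
`frame_fidelity` (default 0.85). The initiation peak matters: with
perfectly uniform codon usage, offsets differing by 3 nt are
indistinguishable in expectation, so the peak — which real metagene
profiles always show — is what makes the planted offset identifiable.

**miRNA sites.** `plant_mirna_targets()` splices the DNA reverse
complement of each small RNA's seed (nucleotides 2-8) into 3'UTRs, then
*recounts*, so recorded site counts include pre-existing chance matches.
In the full experiment the mRNA log2FC at 0 h receives −0.2 log2 units per
site (capped at 3 sites) on top of the mode effect; the truth table keeps
the two components separate.

**tsRNA reads.** Synthetic tRNA references are a precursor leader plus a
72-nt mature body with CCA appended; D-loop (mature 13-22), anticodon loop
(31-40) and the anticodon (34-36) sit at fixed landmarks. Reads are exact
substrings cut at the landmark implied by their origin, with tRFs biased
to 3' ends and tRHs to 5' ends, the biases reported for stimulated
neuronal cells.

# Quality control

Feature mapping rates assign each read to the region containing its
anchor: the P-site for RPFs, the raw 5' end for mRNA reads, which have no
biological P-site (a documented asymmetry). Metagene profiles normalize
each transcript's positional counts by its own window mean before
averaging, making the profile invariant to expression scale;
zero-coverage transcripts are excluded rather than imputed. P-site
calibration scores each candidate offset per read length by the number of
reads whose shifted 5' end lands exactly on a start codon, breaking ties
toward the smaller offset; the consensus is the read-count-weighted mode.
Phasing reports the fraction of in-CDS P-sites per frame, 0-based: the
canonical reading frame is frame 0 here (elsewhere often called "frame
1").

# Differential expression

The DE path is: CPM filter (default: CPM >= 1 in at least the smaller
group's number of samples — explicit configuration, filtering happens
*before* testing so the BH denominator only counts tested genes), TMM
normalization, moment dispersion estimation, NB exact test, BH adjustment,
and the significance rule FDR < 0.05 & |log2FC| > 0.5 (both
configurable).

**TMM.** Factors are 2 to the precision-weighted mean of M-values against
a reference sample (the one whose upper-quartile CPM is closest to the
mean), after trimming 30% of M-values and 5% of A-values on each side,
over genes positive in both libraries. M-values are taken on raw counts,
so the factor absorbs sequencing depth as well as composition: factors are
relative effective library sizes with geometric mean 1, and a column
scaled by c against an otherwise identical one yields exactly
{1/sqrt(c), sqrt(c)}. If fewer than 10 genes survive trimming the
untrimmed weighted mean is used, with a warning.

**Dispersion.** Gene-wise phi is a method-of-moments estimate on
factor-adjusted counts, pooling squared deviations from condition means:
phi_g = (s^2 − mu)/mu^2, floored at 0; the common value is the median of
positive estimates; the working value is w phi_g + (1 − w) phi_common with
w = n_reps/(n_reps + 4). This replaces heavier quasi-likelihood machinery
on purpose — it is transparent and directly testable by parameter
recovery (Poisson data recovers phi ~ 0; phi = 0.1 data recovers 0.08-
0.12). Its cost is noise: with four replicates the moment estimates are
variable, and feeding them to the exact test inflates the type-I error
slightly (~0.06-0.09 at nominal 0.05 in our null simulations). The
calibration acceptance check therefore evaluates the exact test at the
simulation's dispersion, which isolates the test's own behavior; the
residual inflation of the plug-in pipeline is a known limitation shared
by all moment-based NB pipelines.

**Exact test.** Counts are scaled to a common effective library size (the
geometric mean of effective sizes, rounded) and summed within groups.
Writing the group sums as NB variables conditional on their total, the
two-sided p-value is the sum of the probabilities of all splits no more
likely than the observed one (with a 1e-8 relative tolerance guarding
float ties), normalized by the total. phi = 0 uses the Poisson limit,
where the conditional law is exactly binomial. The reported log2FC uses a
pseudo-count (default 0.125 at the common scale) for display stability
only — p-values never see it. Even at the true dispersion the NB
conditional test is only approximately exact (the total is not ancillary
for NB as it is for Poisson); empirically it tracks the field-standard
implementation to within a fraction of a percent of type-I error.

**TE.** Translational efficiency changes are the assay x condition
interaction in a per-gene NB log-linear model with log effective library
size offsets, fitted by IRLS with fixed dispersion; delta log2 TE =
beta_int/ln 2, and the p-value is a 1-df likelihood-ratio test of
beta_int = 0. Non-converging genes are flagged NA and excluded from the
BH denominator. Because the offset absorbs scale, doubling all counts
leaves the interaction unchanged; planted buffering (mRNA shifts, RPF
flat) is recovered with median absolute error ~0.12 log2 units at the
default design point, within the ±0.15 tolerance used in validation.

# Regulatory modes

Classification uses the DE significance rule, not raw p-values: both
assays significant and concordant → homodirectional; discordant →
opposite; mRNA only → transcriptional (the buffering candidate class);
RPF only → translational; neither → stable. A log2FC of exactly 0 on a
significant call is treated as positive and flagged. The partition is
exhaustive and exclusive, and swapping the two input tables swaps the
transcriptional and translational labels — both properties are tested.
The buffering summary reports mode counts and the
transcriptional:translational ratio (NA when the denominator is 0).

# Sequence features

Per region: length, GC fraction, G4 run count, and normalized minimum
free energy; per gene: uAUG count (overlapping ATGs in the 5'UTR; ATG
only, near-cognate starts excluded) and rare-codon frequency. The default
rare set is the bottom decile (6/61) of a bundled human codon-usage
table and is user-replaceable.

**Folding.** The MFE is a Nussinov-style dynamic program minimizing
summed pair energies (GC −3, AU −2, GU −1; hairpin loops enclose >= 3
unpaired bases; no pseudoknots), implemented in C++ and verified
exhaustively against brute-force structure enumeration for short
sequences. It is a deterministic, oracle-testable structure score, not a
thermodynamic model; `compute_features()` accepts externally computed MFE
values for users who want a full thermodynamic treatment.

**G4.** A run-scoring scheme: bases in G runs of length k score
+min(k, 4), C runs score the negative, and windows (25 nt) with mean
score >= 1.2 are G4-positive, merged when overlapping. The count is
monotone under appending disjoint motifs.

**Stratification.** Quartile edges sit at the empirical 25/50/75
percentiles with ties assigned to the lower bin; the across-bin response
comparison is a Kruskal-Wallis test (rank H with tie correction,
chi-squared with 3 df), which is invariant under monotone response
transforms. The generator plants fold changes independent of sequence,
so the full-feature scan in the analysis workflow acts as a genome-wide
negative control, with a synthetic positive control (response coupled to
3'UTR GC) confirming detection power.

# Small RNAs

**Targets.** A small RNA's seed is nucleotides 2-8; target sites are
(possibly overlapping) occurrences of its DNA reverse complement in
3'UTRs. This replaces database-driven context scoring with direct,
auditable seed matching — the analysis logic, not the annotation source,
is what the package reproduces. Target CDF analysis stratifies genes by
site count (default bins 1, 2, >= 3) against the zero-site background,
with a two-sided two-sample KS test and a median-shift summary per bin;
bins below 20 genes are skipped with a notice. Under planted per-site
repression the median shifts are monotone in site count.

**tsRNAs.** Reads map to tRNA references by tiered matching: exact
first, then Hamming distance 1-3 over all gapless offsets (deletions are
approximated by the shifted-offset scan — a documented simplification of
gapped small-RNA mappers). Origin rules, applied in order: start at the
mature 5' end → 5' mature; end at the mature 3' terminus (CCA included)
→ 3' mature; contained in the precursor leader → 5' precursor; overlap
of D- or anticodon-loop without touching a terminus → D/A loop. Length
class: >= 31 nt → tRH; 28-30 nt → tRH iff the read overlaps the
anticodon-loop span; otherwise tRF. The simulator records truth by
applying the same rule to the known cut coordinates, so truth and calls
share one definition — which is exactly why exact cuts must (and do)
classify with 100% agreement, while mismatch-perturbed reads stay above
95%. Species merge over (amino acid, anticodon, origin, class) into ids
like `GluTTC-tRF-3` (suffixes 5/3/DA/1 for the four origins); merging
conserves totals. tsRNA DE filters to robustly expressed species
(CPM > 100 in every sample of at least one condition) before the exact
test.

# Numerical and design notes

* All simulation functions are pure functions of (configuration, seed);
  RNG state is restored after each call.
* Exact-test ties in the double-tail sum use a 1e-8 relative tolerance;
  oracle comparisons agree to < 1e-13.
* The calibration suite uses 2000-gene null simulations and 200-replicate
  uniformity checks; two-sample KS uniformity is checked at sample sizes
  (500 vs 200) where the p-value distribution is effectively continuous,
  because small-sample exact KS p-values are discrete by construction.
* Problem sizes throughout (2000 genes, 1e5 reads, 1e4 tsRNA reads,
  depth 1e6) are the package's validation design point: large enough for
  the stated tolerances, small enough to run on a laptop in minutes.
* Zero-total libraries, empty read sets, missing landmarks, non-ACGT
  symbols and constant features all raise early, named errors; degenerate
  dispersion (phi = 0) takes the Poisson path throughout.

# What the synthetic validation does not show

The generator draws i.i.d. bases, single isoforms, and independent genes.
It does not emulate 3'UTR isoform switching, positional codon-usage
structure, correlated gene programs, GC-dependent library bias, mapping
ambiguity, or tRNA modifications that drive reverse-transcription errors
in real small-RNA data. Passing the suite therefore establishes
correctness of the estimators under the stated model — not that the
model captures every property of a real depolarization experiment.
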