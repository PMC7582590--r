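# ribopost

Integrative post-transcriptional analysis of matched ribosome-profiling
(Ribo-seq), mRNA-seq and small-RNA-seq experiments, for researchers who
want to ask not just *which genes change*, but *at which layer*: mRNA
abundance, ribosome occupancy, or both. The motivating biology is
post-transcriptional buffering after neuronal stimulation — episodes in
which transcripts change in abundance with no matching change in
ribosome-protected fragments (RPFs), or vice versa — and the contribution
of sequence-intrinsic features and small RNAs (miRNAs and tRNA-derived
fragments) to that partition.

Every estimator in the package is validated against a synthetic-data
generator that plants known regulatory structure, so the statistical
machinery can be checked end to end before it ever touches real data.

## What it computes

* **RPF quality control** — feature mapping rates, metagene density
  profiles, per-read-length P-site offset calibration, and sub-codon
  phasing (triplet periodicity).
* **Differential expression** — CPM filtering, TMM normalization,
  moment-estimated NB dispersions, and a double-tail NB exact test with
  Benjamini–Hochberg FDR. Significance: FDR < 0.05 and |log2FC| > 0.5.
* **Translational efficiency** — per gene, the NB log-linear model

  ```
  E[y] = exp(offset + b0 + bA·I(RPF) + bC·I(treated) + bI·I(RPF)I(treated))
  ```

  fitted by IRLS with fixed dispersion; Δlog2TE = bI/ln 2, tested by a
  1-df likelihood-ratio test.
* **Regulatory modes** — each gene is classified as homodirectional,
  opposite, transcriptional (mRNA-only, the buffering class),
  translational (RPF-only) or stable, from the paired DE calls and
  fold-change signs.
* **Sequence features** — per-region length, GC%, normalized minimum
  free energy (Nussinov-style DP, oracle-verified), G-quadruplex run
  scoring, uAUG counts and rare-codon frequency, with quartile
  stratification tested by Kruskal–Wallis.
* **Small RNAs** — seed (nt 2–8) target-site counting in 3'UTRs,
  site-count-stratified CDF comparisons (two-sample KS vs the zero-site
  background), tsRNA mapping to tRNA references with origin (5'/3'
  mature, D/A loop, precursor) and class (tRF 14–30 nt / tRH 28–36 nt)
  assignment, species merging, and tsRNA differential expression with a
  CPM > 100 robustness filter.

## Worked example

The `analysis/` directory is a numbered workflow over the package; run it
from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_riboqc.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_regulatory_modes.R
Rscript analysis/05_sequence_features.R
Rscript analysis/06_small_rna.R
```

`01` simulates the full design — 2000 genes, three conditions (control,
0 h, 2 h post-stimulus), four replicates, matched mRNA/RPF/small-RNA
assays — and writes plain-text inputs plus a JSON truth file under
`results/simulation/`. The later steps consume only those files. Typical
output (master seed fixed in `01`):

```
P-site calibration: consensus offset 12 nt
RPF frame fractions: 0.849 / 0.075 / 0.075 (planted fidelity 0.85)
RPF region rates: 5'UTR 0.026, CDS 0.950, 3'UTR 0.025

[t0h] mRNA: 850 significant (planted non-zero: 1181); cor(est, true) = 0.981
[t0h] RPF:  445 significant (planted non-zero: 447); cor(est, true) = 0.964

[t0h] transcriptional:translational = 2.28; agreement with planted modes (non-stable) = 0.971
[t2h] transcriptional:translational = 0.45; agreement with planted modes (non-stable) = 0.994

tsRNA mapping: 100.0% of 10000 reads assigned; origin/class agreement with truth 1.000
tsRNA DE: 72/72 species pass CPM > 100; 22 significant; sensitivity on planted changes 1.00
```

Reading it: QC recovers the planted P-site offset (12 nt) and frame
fidelity; mRNA finds fewer significant genes than were planted because
miRNA-repressed genes with |log2FC| < 0.5 sit below the effect-size
threshold by design; and the transcriptional:translational ratio flips
from 2.28 at 0 h to 0.45 at 2 h — the planted buffering asymmetry, which
is the analysis' headline readout.

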