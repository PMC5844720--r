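---
title: "Models and methods behind spongeworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spongeworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spongeworks)
```

# The analysis problem

`spongeworks` reconstructs candidate miRNA-sponge (competing endogenous
RNA) interactions from a small matched two-condition RNA-seq design:
long-RNA libraries (mRNA and lncRNA counts) and small-RNA libraries
(miRNA tag counts) for tumour and matched control tissue, typically
three biological replicates per group. The output is a tripartite
network in which a **sponge triplet** (miRNA, lncRNA, mRNA) is
supported by (i) seed-site evidence of the miRNA on both partners and
(ii) differential-expression directions consistent with the sponge
mechanism.

This vignette documents the models, the tunable parameters with their
defaults and rationale, the numerical choices, and what the packaged
synthetic-data generator does and does not emulate.

# Differential expression: the exact count test

Digital expression counts from two libraries are compared with the
Audic–Claverie statistic. Given `x` reads for a feature in a library of
`N1` total clean reads and `y` in a library of `N2`, the conditional
probability of `y` given `x` is

$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!}
  \left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

which is the negative-binomial pmf with `size = x + 1` and success
probability `N1 / (N1 + N2)`; it sums to one over `y` (`ac_pmf()` is
tested against both properties). Evaluation is in log space via
`lchoose()` so that counts in the hundreds of thousands cannot
overflow.

**Tail construction.** `ac_test()` reports the inclusive upper tail
$\sum_{y' \ge y} P(y'\mid x)$ for `alternative = "greater"`; the
`"less"` tail is the same sum in the exchanged orientation
($\sum_{x' \ge x} P(x' \mid y)$ with the library roles swapped), and
the two-sided p-value is `min(1, 2 * min(upper, lower))`. This choice
is deliberate: both one-sided values are literal cumulative tails of
the pmf, and the two-sided value is then *exactly* invariant under
exchanging the two libraries — it coincides with the conditional
binomial exact test for two Poisson rates, since
$\sum_{y' \ge y} P(y'\mid x) = P\!\left(\mathrm{Bin}(x+y,
\tfrac{N_2}{N_1+N_2}) \ge y\right)$. (Constructing the lower tail from
the same conditional distribution instead would break the exchange
symmetry: for `x = 0, y = 1, N1 = N2` it yields 1 in one orientation
and 0.5 in the other.) Doubling the smaller tail makes the test mildly
conservative; under a Poisson null with rate 50 the empirical rejection
rate at α = 0.05 sits near 0.04, which the test suite checks over
10,000 replicates.

**Replicate handling.** The statistic compares two libraries, so
`call_differential()` pools (sums) counts within each condition and
uses the pooled library sizes as `N1`, `N2`. With n = 3 per group this
is the defensible choice; per-sample dispersion modelling
(edgeR/DESeq2-style) is intentionally out of scope because the exact
two-library statistic *is* the package's DE engine, applied uniformly
to long and small RNA counts.

**Calls.** Group means are counts per million of the pooled library.
`log2_fold_change()` adds a pseudocount (default 1) to both means only
when either is zero, so ordinary ratios are unperturbed. Default
thresholds (`de_thresholds()`): |log2FC| ≥ 1 (fold change 2) and
BH-adjusted p ≤ 0.05; both are configurable, and raw-p calling is
available (`use_adjusted = FALSE`) since published small-RNA tables
often report raw p-values. Benjamini–Hochberg is used wherever a
"corrected p" is needed; no π₀-estimating q-value procedure is
involved, which keeps the correction deterministic.

# Quantification conventions

* `compute_tpm()` implements TPM = 10⁶ · C / L with **no length term**.
  This is the small-RNA convention (tags are nearly uniform in length),
  despite the "per kilobase" in the acronym's long form; the function
  documents this explicitly rather than silently "fixing" it.
* `compute_fpkm()` divides counts by exonic kilobases and mapped
  millions; the library-size field of the count matrix stands in for
  "mapped fragments". `gene_fpkm()` sums transcript FPKMs within a
  gene — exactly, not by re-estimation.
* `identify_known_mirnas()` assigns a tag to a miRNA only if the tag is
  an exact substring of the precursor (sense strand — small-RNA
  protocols read the mature strand) *and* its placement overlaps the
  annotated mature interval by ≥ 16 nt. Ties go to the largest mature
  overlap, then lexicographically smallest miRNA id; a tag is assigned
  at most once.

# lncRNA classification cascade

`predict_lncrnas()` runs four ordered, short-circuiting steps; every
transcript receives exactly one label.

1. **Class code** in {j, i, o, u, x} (novel isoform, intronic, exonic
   overlap, intergenic, antisense). Reference-matching codes such as
   `=` are rejected — those are known mRNAs.
2. **Length ≥ 200 nt** (strict below, inclusive at 200), the standard
   lncRNA definition.
3. **Known-lncRNA match**: a deterministic stand-in for a blastn search
   of a lncRNA database. Candidate/reference pairs sharing an 11-mer
   are aligned with a gapless local alignment (Biostrings, prohibitive
   gap penalty); "known" requires identity ≥ 0.95 over ≥ 0.90 of the
   shorter sequence. The thresholds are explicit parameters because the
   field's pipelines rarely state theirs.
4. **Coding potential**: an ORF scan of the three forward frames
   (assembled transcripts are stranded). "Coding" means a longest ORF
   of ≥ 100 codons — the conventional TransDecoder cut-off — or ORF
   coverage ≥ 0.5 of the transcript. ORFs are ATG-to-stop, with
   open-ended ORFs running to the transcript end also counted; the
   codon count includes the stop codon, so a 300-nt transcript that is
   one continuous reading frame counts 100 codons and is called coding
   (the boundary is inclusive).

Known plus novel lncRNAs form the downstream lncRNA set. The cascade
order is load-bearing: a 150-nt fully-coding fragment is labelled
`rejected_length`, never `coding`.

# MRE prediction and target assignment

`find_seed_sites()` reports every canonical seed-site occurrence. With
the miRNA written 5'→3' and the target read 5'→3', the four classes
are: **6mer** — reverse complement of miRNA nucleotides 2–7; **7mer-m8**
— reverse complement of 2–8; **7mer-A1** — the 6mer followed by an A
(facing miRNA position 1); **8mer** — the 7mer-m8 match followed by an
A. Each occurrence is labelled with its most specific class, so classes
are mutually exclusive per occurrence. Matching is in DNA space (U→T
normalised at the boundary). The scanner is validated against an
independent exhaustive windowed scan on random sequences.

**Predictor combination.** Published pipelines intersect the target
sets of two external predictors. Here the two "predictors" are two
site-class regimes of the same scanner — strict ({7mer-m8, 8mer}) and
lenient (all four classes) — combined at the **gene level** by
`combine_predictions()` (default intersection). The combination layer
is predictor-agnostic: any site lists with `mirna_id`/`target_id`
columns can be combined.

**Cis targets** (`assign_cis_targets()`): genes whose span lies within
10 kb (inclusive; gap measured between nearest span ends, overlap =
distance 0) of a lncRNA on the same chromosome, either strand.
Upstream/downstream is oriented by the lncRNA's strand. **Antisense
targets** (`find_antisense_targets()`): transcripts overlapping a
lncRNA by ≥ 1 base on the opposite strand. The reported
complementarity score — the longest contiguous perfectly pairing run
over the overlap — is a deliberately simple stand-in for a duplex
energy model (no free-energy computation); it is reported, not
thresholded.

# Network assembly

`build_global_network()` restricts to differentially expressed
features, draws a miRNA–ceRNA edge for every site-supported pair, and
emits a triplet for every miRNA with edges into both partner classes
(the common-miRNA rule). `filter_coregulated()` then keeps a triplet
only if the lncRNA and mRNA share a direction opposite to the miRNA's.
The anti-correlation requirement is the package's reading of the
sponge mechanism (less miRNA ⇒ more of everything it represses); a
`permissive` mode (any non-ns directions) is available because some
published networks only require joint differential expression. No
expression-correlation filter is applied: with three replicates per
group, sample-level correlations are statistically meaningless, so the
design stops at directions.

Transcripts are kept as distinct nodes (no gene collapsing): published
sponge networks label nodes at the transcript level, and collapsing is
a trivial post-processing step for users who want it.

# Enrichment

`hypergeom_enrich()` computes the inclusive upper hypergeometric tail
`P(X ≥ k)` via `phyper`, the enrichment factor `(k/n)/(K/N)`, and BH
q-values. The default universe is every gene with at least one
annotation — the least assuming choice when the annotation's origin is
unknown — and is configurable. `top_terms()` ranks by enrichment factor
(ties: ascending p, then term id) after requiring ≥ 4 selected genes
per term, returning the top 20 by default.

# The synthetic-data generator

The generator (`sim_config()`, `generate_transcriptome()`,
`simulate_counts()`) emulates the study design the pipeline targets: 3
tumour vs 3 matched control samples; 500 mRNAs, 150 lncRNA candidates
and 200 miRNAs by default; 10% of each class differentially expressed
with |log2FC| = 2 implanted multiplicatively on the tumour mean.

* **Noise model**: negative binomial with variance
  mean + φ·mean², φ = `nb_dispersion` (Poisson at 0). The default
  φ = 0.05 is a typical gene-level dispersion for deep bulk sequencing
  of matched tissue; it is a single global value — no mean-dispersion
  trend — which is the main simplification relative to real data.
  Baseline mean 200 puts pooled per-condition counts around 600, the
  regime in which the exact test has essentially full power at
  four-fold changes, so recovery tests probe correctness of the
  pipeline wiring rather than borderline power.
* **Ground-truth network**: about 30% of DE miRNAs become sponge hubs;
  each receives 1–3 lncRNA and 1–3 mRNA partners drawn from the DE
  features whose implanted direction is opposite to the hub's, and
  `sites_per_true_pair` perfect 8mer sites per pair are implanted at
  recorded positions in the partner's 3' region. The truth triplet set
  is the full lncRNA × mRNA cross product per hub — exactly what the
  common-miRNA rule should recover.
* **Sequence realism**: mRNAs are UTR–ORF–UTR with ORFs of 110–160
  codons; lncRNA candidates are 400–800 nt, class codes drawn from
  {j, i, o, u, x}, verified noncoding under the package's own ORF rule.
  A configurable fraction of lncRNAs is copied into the packaged
  known-lncRNA reference (as `REF_*` entries), so the cascade's "known"
  step has true positives. All transcripts are single-exon; splice
  structure, isoforms and batch effects are not simulated, and long-RNA
  libraries are simulated at the count level only (the small-RNA FASTQ
  from `simulate_small_reads()` exists to exercise the cleaning rules,
  with deterministic doomed reads per removal category).
* **Decoy purity**: every transcript that is not a designated target
  must contain *no* canonical site of any simulated miRNA, or
  site-level precision could not be measured. Whole-sequence rejection
  sampling cannot deliver this at realistic scale (200 six-mers forbid
  ≈ 5% of all hexamer windows; a 1-kb sequence is virtually certain to
  contain one), so sequences are built by constrained sampling: random
  bases with a repair pass that rewrites any window completing a
  forbidden 6mer, codon-aware inside ORFs (rewrites draw from the 61
  non-stop codons; start/stop codons and implanted sites are frozen).
  A per-transcript restart cap (default 1000) turns pathological
  configurations into an explicit error. miRNA seeds are sampled so
  that no miRNA's 8mer site pattern contains another miRNA's core —
  otherwise one implant could be attributed to two miRNAs.
* **Determinism**: one seed drives everything; per-stage sub-seeds are
  derived arithmetically from it, so any stage can be re-run in
  isolation and two runs with the same configuration are
  byte-identical, including all fixture files.

Because decoys are perfectly clean and implanted effects are strong,
passing recovery tests demonstrates that the pipeline's logic is
correct and loses nothing — not that its operating characteristics on
real tissue (where sites are degenerate, dispersion varies and effects
are small) would match. That distinction is intentional: the generator
validates machinery, not biology.

# Validation scales and numerical choices

The test suite and the acceptance script use these problem sizes,
chosen as the smallest scales at which each property is informative:
exact-test calibration over 10,000 Poisson-null replicates; exchange
symmetry over 1,000 random count pairs; scanner-vs-oracle equivalence
on 1,000 random 1-kb targets × 20 miRNAs; DE and network recovery on
the default 500/150/200 design at seeds 42–44; end-to-end determinism
on a 150/60/60 design.

Numerical details worth knowing:

* `ac_pmf` tail sums stop when the running term falls below 10⁻¹⁸ of
  the accumulated mass; normalisation holds to 10⁻⁹ across the tested
  grid (counts up to 200, library ratios 0.5–4).
* p-values are capped at 1; at the symmetric point (x = y, N1 = N2) the
  two-sided p is exactly 1.
* BH adjustment is `stats::p.adjust`; order-preserving and
  permutation-invariant.
* `identify_known_mirnas` and `top_terms` break ties lexicographically
  so that results are independent of input order.
* GTF output is written with a fixed column and attribute layout so
  identical annotations give byte-identical files; reading goes through
  rtracklayer and re-validates spans, strands and id uniqueness.

# Known limitations

* The exact test ignores within-condition biological variability
  (counts are pooled); with overdispersed real data its p-values are
  anti-conservative relative to NB-GLM tests. It is provided as the
  package's uniform DE engine by design, not as a recommendation over
  dispersion-modelling tools for large designs.
* Seed matching has no pairing-stability, context or conservation
  scoring; the intersection of the strict and lenient regimes is a
  structural stand-in for multi-predictor agreement.
* The known-lncRNA matcher is gapless; highly fragmented homology will
  be missed at the default coverage threshold.
* The antisense complementarity score is a pairing-run length, not an
  energy; single-exon geometry only.
* Enrichment assumes a flat term structure (no ontology graph
  propagation).
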