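---
title: "mirwoodnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirwoodnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`mirwoodnet` re-implements, as one tested R pipeline, the analysis chain
used in reaction-wood (tension wood) small-RNA studies: read cleaning,
exact genome mapping, known/novel miRNA discovery by hairpin folding,
reads-per-million (RPM) normalization with two-group differential
abundance calls, plant-style miRNA target prediction by complementarity
scoring, anti-correlation validation of predicted targets, assembly of a
tripartite miRNA–TF–mRNA network, hypergeometric pathway enrichment, and
2^−ΔΔCt qPCR quantification. Because deposited sequencing data are not
desk-scale inputs, the package ships a first-class synthetic-data
generator with planted ground truth; every statistical property claimed
here is demonstrated on that generator by the test suite, not asserted
about any real dataset.

# The synthetic study and what it emulates

`synthetic_config()` encodes the emulated design: three xylem tissues —
normal wood (NW), tension wood (TW), opposite wood (OW) — with three
replicate libraries each (nine samples). Defaults:

* **12 novel + 5 known miRNAs.** Each planted miRNA is an 18–24-nt mature
  (length centered on 21 nt; 70% begin with U, matching the first-base
  bias reported for plant miRNAs) embedded in a hairpin precursor:
  mature arm + loop + reverse-complement star arm. The loop is drawn from
  {A, C} only so it cannot base-pair internally, which keeps the
  base-pair-maximal fold of the precursor a clean stem-loop.
* **Tissue-differential abundance.** Per-miRNA baselines are log-normal;
  each novel miRNA is up-regulated 4-fold (`de_fold`) in one tissue,
  cycling through NW/TW/OW. Replicate abundance multiplies in log-normal
  noise (`noise_sd`, default 0.15). Reads are allocated to matures by
  largest-remainder rounding of the expected proportions, so biological
  variability enters only through the replicate noise term and a
  zero-noise configuration is exactly proportional.
* **39 planted target pairs**, distributed over the 12 novel miRNAs, of
  which 21 target genes are annotated as transcription factors
  (53.85%). A perfect complementary site for the miRNA is inserted in
  the target's transcript, and the target's expression across the nine
  samples is a decreasing affine function of the miRNA's per-sample
  abundance plus Gaussian noise.
* **Planted correlation 0.95.** The noise scale for planted pairs is set
  from the target correlation magnitude `planted_r`:
  σ = s · sqrt(1/r² − 1) with s the signal standard deviation. We chose
  0.95 by Monte-Carlo at design time: with n = 9 samples the sampling
  spread of the empirical correlation is wide (Fisher z s.e. ≈ 0.41), and
  0.95 is the level at which ≥ 90% of planted pairs land at or below the
  r ≤ −0.8 filter line. A planted magnitude of 0.9 would leave only
  ~80% of pairs below the line — the generator is meant to produce a
  recoverable study, not a marginal one.
* **TF co-expression and pathways.** Each TF-annotated target gets two
  downstream co-expressed genes (positive sign, same correlation
  tuning). Pathway labels are uniform over ten pathways except that half
  of the network genes are relabeled to pathway `path01`, the planted
  enriched term.
* **qPCR.** Ct = 35 − log2(expression) (efficiency 2.0), so 2^−ΔΔCt
  inverts the generator exactly: a planted 4-fold miRNA recovers fold 4
  at zero noise. A constant reference gene (`UBQ`) is included.

`zero_noise_config()` switches off replicate noise, pair noise,
background reads and quality degradation; under it the pipeline must
reproduce the truth table exactly (the tests assert this).

**What the generator does not emulate:** sequencing errors and indels,
isomiRs, miRNA* accumulation, count overdispersion beyond log-normal
replicate noise, and any genome complexity (repeats, paralogous
precursors). Passing tests therefore demonstrate correctness of the
algorithms under the stated model, not performance on real libraries.

# Read processing

Cleaning follows the standard small-RNA filters: 3' adapter trimmed at
the first exact occurrence of its ≥ 8-nt prefix; reads discarded when
the N fraction exceeds 10% or any base in the final three positions has
Phred Q < 20 (Q = −10·log10 of the error probability). The published
accounting tables distinguish "clean reads" from "total sRNA"; we define
clean reads as those passing the N and quality rules, and total sRNA as
the clean reads whose trimmed length lies in 18–30 nt — that ordering
reproduces the column monotonicity of such tables, but the original
definition is not stated in the source and ours is a documented choice.

Mapping is exact (no mismatches) on both strands, via
`Biostrings::matchPattern`; the mapping ratio is mapped/total·100 at two
decimals. A multi-locus tag is counted once, not once per placement.
Masking removes a tag only when *every* locus overlaps an annotated
rRNA/tRNA/snRNA/snoRNA/repeat feature; with one unmasked locus the tag
survives. BED input is converted from 0-based half-open to the 1-based
inclusive coordinates used internally.

# miRNA discovery

A tag is a **known** miRNA when it equals a reference mature sequence up
to two nucleotides of terminal trimming (no internal mismatches), the
usual tolerance for mature-end heterogeneity. Known assignment takes
precedence over novel calling.

**Folding.** Novel calling folds candidate precursor windows with a
Nussinov-style base-pair maximization ({AU, GC, GU} pairs, hairpin loops
≥ 3 nt) instead of a thermodynamic model: it is deterministic, has no
parameters to fit, and is checkable against exhaustive structure
enumeration — which the tests do for all sequences ≤ 14 nt. The
traceback is deterministic: the 5'-most position is paired whenever
pairing achieves the optimum, with its 5'-most admissible partner. An
energy-model backend could be substituted behind the same interface.

**Hairpin acceptance.** For each unexplained tag locus two windows are
folded (mature at the window's 5' end with 80 nt downstream, and the
mirror case). The mature must sit on one arm of a single-stemmed
hairpin: (i) at least 14 mature bases form one antiparallel duplex run
(partners strictly decreasing, bulges ≤ 3 nt); (ii) at least 60% of
mature bases are paired; (iii) the run's partners all lie on one side of
the mature; (iv) the unpaired span between the mature arm and its
partner region is at most 50 nt. Rules (iii)/(iv) implement the "no
multiloop on the mature arm's path" idea directly on the pair list
rather than by counting loops in the dot-bracket string: base-pair
maximization has many co-optimal structures, and the traceback can
legally decorate a perfect hairpin's loop with a one-pair hairpin,
which would spuriously fail a literal "single terminal loop" test while
the duplex geometry is unchanged. Tags need ≥ 5 supporting reads to be
considered (read-support evidence in the spirit of miRDeep-style
callers). Accepted windows that overlap on a chromosome are merged
regardless of strand, because a mature read exact-matches both its own
arm and the star arm of the same precursor. Novel IDs are assigned in
genome coordinate order.

# Differential abundance

Normalized abundance = mapped count / total mapped reads × 10⁶, exactly
and with no pseudocount. The source analyses state only the thresholds
(|FC| ≥ 2, P ≤ 0.05), not the test; with n = 3 replicate groups we use a
two-sided Welch t-test on log2(RPM + 1), with a pseudocount of 1 in the
fold-change so zero counts stay finite, and a degenerate-case guard
(p = 0 for distinct constants, p = 1 for identical ones). No multiple
testing correction enters the significance call — matching the raw-P
threshold convention — but BH q-values are reported alongside. The
published per-contrast counts (5/11/2) depend on the deposited data and
are not an implementation target.

# Target prediction and validation

The expectation score sums duplex penalties — mismatch 1.0, G:U wobble
0.5, single-nucleotide bulge 2.0 — doubled at miRNA positions 2–13, with
hits kept at expectation ≤ 3. These are the widely documented defaults
of the plant target server the original analysis used; the source states
only "default parameters", so all constants are exposed in
configuration. Scanning slides the miRNA antiparallel along the
transcript; at most one bulge per site is allowed, never between miRNA
positions 10 and 11; for each site start the better of the gapless and
best bulged variant is reported. The nominal cleavage coordinate is the
transcript base opposite miRNA position 10 (the cut lies between the
bases opposite positions 10 and 11). A predicted pair is **validated**
when Pearson r ≤ −0.8 with two-sided p ≤ 0.05 across the nine pooled
samples — a signed threshold plus a two-sided p, following the "negative
coefficient, P < 0.05" phrasing.

# Network and enrichment

The TF layer reuses |r| ≥ 0.8, p ≤ 0.05 (no separate cutoff is stated in
the source; ours is configurable), keeps the sign on the edge and
forbids self-edges. The assembled network types nodes as miRNA/TF/gene;
every miRNA edge must carry both target-prediction and correlation
evidence. Enrichment is the hypergeometric upper tail P(X ≥ k) over a
(gene, pathway) map with BH correction across pathways.

One property deserves emphasis: with tissue-driven abundance, a TF is
*genuinely* correlated not only with its explicitly planted downstream
genes but with every gene driven by a same-pattern miRNA. These induced
edges are real features of the generated data, not false positives.
`induced_tf_truth()` therefore derives the full true TF edge set from
the deterministic signal components (|cor| ≥ 0.8 of the noiseless
signals), and precision in the recovery tests is measured against that
set; recall is measured against the explicitly planted pairs. Judging
precision against the explicit list alone would be wrong by
construction under pooled-tissue correlation.

# qPCR

2^−ΔΔCt with reference-gene and calibrator-sample double normalization;
amplification efficiency is fixed at 2.0 with an efficiency-corrected
variant exposed. Technical replicates are averaged on the linear scale.
Adding a constant to every Ct of a sample cancels exactly (reference
invariance), which the tests assert.

# Numerical and scale choices

* Test problem sizes: the unit suite runs a 2-chromosome 30-kb genome
  with 6 planted miRNAs at 800 reads/sample; the acceptance-style
  checks use the study-sized configuration (17 miRNAs, 39 pairs) at
  4,000 reads/sample, and the bundled acceptance script at the default
  10,000. These sizes were chosen so the full suite completes on one
  CPU in minutes while leaving every planted structure comfortably
  detectable.
* The default-noise edge-recovery check re-runs the correlation layers
  on 25 freshly generated datasets but fixes the target hits to the
  planted sites; sequence-level site recovery is established separately
  (exactly, at zero noise) so the repeated part measures only the
  statistical filter.
* Determinism: all randomness flows from the single config seed through
  fixed derived seeds per stage; identical configs produce byte-identical
  FASTA/FASTQ/TSV outputs, and reruns of the pipeline produce identical
  file checksums.
* Degenerate inputs: zero-variance expression rows are skipped (and
  logged) by the correlation ops rather than producing NaN; |r| = 1
  maps to p = 0 by convention; empty validated sets still produce valid
  (empty) network exports.

# Known limitations

Exact mapping cannot tolerate sequencing errors; the folding backend
maximizes pairs rather than free energy, so it should not be used to
rank hairpins thermodynamically; no miRNA* evidence, randfold-style
shuffling p-values, or Dicer-offset scoring is implemented; enrichment
uses a plain gene→pathway map and performs no pathway-database access.
Headline counts from any real study (total miRNAs, per-contrast DE
counts, specific network edges) depend on the deposited data and
external tool versions and are deliberately not implementation targets.
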