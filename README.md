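# mirwoodnet

Small-RNA discovery and miRNA–TF–mRNA network analysis for wood
(xylem) transcriptomics.

Reaction-wood studies ask how tension wood (TW) forms on the upper side
of a bent stem, relative to opposite wood (OW) and normal wood (NW), and
what role miRNA-mediated post-transcriptional regulation plays in that
process. `mirwoodnet` implements the full analysis chain such studies
use, as one tested, reproducible R pipeline aimed at analysts who want
every step inspectable rather than delegated to a chain of external
binaries:

1. **Read processing** — adapter trimming, the standard small-RNA
   filters (18–30 nt, N fraction ≤ 10%, 3′-tail Phred Q ≥ 20 with
   Q = −10·log₁₀ *error*), collapsing to unique tags, exact (no
   mismatch) genome mapping on both strands, and masking of annotated
   rRNA/tRNA/snRNA/snoRNA/repeat loci.
2. **miRNA discovery** — known miRNAs by reference matching (≤ 2 nt
   terminal trimming), novel miRNAs by folding candidate precursor
   windows with a deterministic Nussinov base-pair–maximization folder
   and plant-style hairpin acceptance rules (≥ 14-bp mature-arm duplex,
   ≥ 60% of mature bases paired, single-stem geometry).
3. **Differential abundance** — reads-per-million normalization
   (count/total × 10⁶), Welch t-test on log₂(RPM + 1), significance at
   |FC| ≥ 2 and P ≤ 0.05 (BH q-values reported alongside).
4. **Target prediction** — complementarity scanning with the plant
   expectation score (mismatch 1, G:U 0.5, bulge 2, doubled at miRNA
   positions 2–13; hits at expectation ≤ 3) and a cleavage coordinate
   opposite miRNA positions 10/11.
5. **Anti-correlation validation** — a predicted target is kept only if
   its expression has Pearson r ≤ −0.8 (two-sided p ≤ 0.05) with the
   miRNA's abundance across the nine samples.
6. **Network + enrichment** — TF co-expression layer (|r| ≥ 0.8),
   tripartite miRNA→TF→gene assembly with SIF/GraphML export, and
   hypergeometric pathway enrichment with BH correction.
7. **qPCR** — relative expression by 2^−ΔΔCt with reference-gene and
   calibrator double normalization.

Because the deposited read archives of such studies are not desk-scale
inputs, the package ships a first-class synthetic-data generator
(`synthetic_config()`, `simulate_all()`) that plants hairpin precursors,
4-fold tissue effects, anti-correlated targets (21 of 39 target genes
are TFs), TF co-expression and one enriched pathway — with a
machine-readable truth table, so the whole pipeline can be scored
against known ground truth.

## Worked example

```r
library(mirwoodnet)

## simulate a noiseless study (12 novel miRNAs, 39 planted target
## pairs) and run the full pipeline on its FASTQ/FASTA/TSV outputs
cfg <- zero_noise_config(synthetic_config(seed = 1, depth = 4000))
res <- simulate_and_run(1, dir = tempfile(), cfg = cfg)

r <- res$run
nrow(r$known); nrow(r$novel$records)
#> [1] 5
#> [1] 12
r$de_summary
#>   contrast n_significant up-in-NW up-in-OW up-in-TW
#> 1    NW:OW             8        4        4        0
#> 2    NW:TW             8        4        0        4
#> 3    OW:TW             8        0        4        4
sum(r$validated$validated)
#> [1] 39
head(r$enrichment, 2)[, c("pathway_id", "k", "K", "p_value")]
#>   pathway_id  k  K      p_value
#> 1     path01 45 47 1.738338e-08
#> 2     path03 11 17 7.123580e-01
```

Reading the output: all 17 planted miRNAs are recovered (5 known via the
reference, 12 novel via hairpin calling, numbered in genome order); each
of the 12 novel miRNAs was planted 4-fold up in one tissue, so every
pairwise contrast shows its 8 planted differential miRNAs with the
correct directions; all 39 planted miRNA–target pairs survive the
r ≤ −0.8 anti-correlation filter; and the planted pathway `path01` tops
the enrichment table. With default replicate noise
(`synthetic_config()` without the zero-noise wrapper) the same pipeline
recovers ≥ 90% of planted correlation edges at ≥ 95% precision — the
test suite measures this over 25 simulated studies.

`run_all()` also writes every stage table (read accounting, tag catalog,
miRNA table with hairpin report, DE table, target hits, validated pairs,
SIF/GraphML network, enrichment, qPCR summary) plus a JSON run report
with per-stage counts and file checksums to the configured output
directory; identical seeds give byte-identical outputs.

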