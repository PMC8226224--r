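---
title: "Methods: synonymous codon usage bias shift analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synonymous codon usage bias shift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scubshift)
```

# The model

`scubshift` quantifies shifts in synonymous codon usage bias (SCUB)
between a recipient cultivar and a derived hybrid/introgression line.
All statistics are built on one primitive: codon counts over the
**59-codon synonymous set** — every codon except ATG (Met), TGG (Trp) and
the three stops, covering the 18 amino acids with degenerate coding. Only
these codons can vary at the third position without changing the protein,
so their third-position base composition (the frequencies of NNA, NNT,
NNC, NNG codons) tracks the mutational process with minimal protein-level
selection.

Three layers of summary are computed:

* **Composition.** Per amino acid, the ratio of C/G-ending to A/T-ending
  codon counts; in total, the four ending frequencies and their
  `cg_to_at` ratio (NNC+NNG)/(NNA+NNT).
* **CpG-deamination signature.** Methylated cytosine in CpG context
  deaminates to thymine: C→T on the strand carrying the C, observed also
  as G→A at the G of the CpG (the antisense event). At synonymous third
  positions this predicts movement in exactly two ratios: NCA/NCG (the
  second–third position CG dinucleotide, hit by G→A at position 3) and
  NT|G/NC|G (third-position C followed by a G-starting codon, hit by C→T
  at position 3). The six analogous ratios with other context bases act
  as negative controls. Ratios are compared between samples as
  hybrid/recipient "ratios of ratios", tested by a 2×2 χ² on the raw
  counts.
* **Spatial structure.** From pairwise recipient/hybrid CDS alignments,
  codons are classified relative to indels (5′ flank, 3′ flank, remote);
  from a chromosome table, records are pooled into introgressed vs
  non-introgressed chromosomes, allelic groups 1–7 and sub-genomes A/B/D
  of an allohexaploid (wheat-like) genome.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| flank window | 45 nt (15 codons) | flank size beside each indel; also the "remote" clearance distance |
| terminal clearance | > 45 nt, strict | indels nearer to a CDS terminus are ineligible for flank extraction |
| inter-indel rule | 90 nt | a segment between two indels shorter than this joins no flank (and, by geometry, no remote set) |
| introgressed set | 1B, 1D, 2A, 2D, 5B, 6D | configurable chromosome list, arm suffixes stripped |
| χ² correction | none | codon tallies are large; Yates' correction available as a flag |
| t-test | Welch | pooled-variance form available as a flag |
| significance flag | α = 0.05 | raw p-values are reported; no multiple-testing correction, test counts are reported instead |

Coordinates are 0-based, half-open everywhere internally. Codons
containing ambiguity codes are dropped from tallies with an audited
count (`n_dropped`); internal stops are tallied for diagnostics but never
enter `n_sc`. A codon broken by an indel boundary belongs to neither
flank — SCUB is codon-based and partial codons are uninterpretable.

# The synthetic world

The generator (`generate_ancestral_cds()`, `mutate_genome()`,
`assign_chromosomes()`) emits the structure the analysis assumes, with a
full event-level ground truth (`replay_truth()` reproduces the derived
sequences byte-exactly):

* Ancestral CDSs are an ATG followed by i.i.d. codons from a usage vector
  with C/G-ending dominance (weight 1.5, giving `cg_to_at` ≈ 1.5, the
  GC3-rich regime typical of grass coding sequences). The default length
  model is log-normal with median 150 codons — the EST-unigene scale; the
  acceptance tests use fewer, longer records (e.g. 200 × 500 codons) for
  the same total codon count, purely for loop-overhead reasons.
* One generation of point mutation at `sub_rate` per site (default 0.01),
  multiplied by `cpg_multiplier` (default 10) at every CpG-context site —
  applied as deterministic deamination, C→T at the C and G→A at the G —
  and by `flank_multiplier` (default 10) within 45 nt of an indel.
  Multipliers compose; the per-site probability is clamped at 1 with a
  logged count. Substitutions that would create an internal stop are
  resampled among non-stop alternatives (count recorded).
* Indels are frame-preserving deletions (lengths 3/6/9 nt), placed at
  codon boundaries with > 45 nt terminal clearance and ≥ 90 nt
  separation, so every placed indel is eligible for flank extraction by
  construction. Alignments are emitted gap-exactly from the truth; no
  realignment is involved. Insertions are not simulated (a deliberate
  simplification — deletion vs insertion is symmetric for every statistic
  computed here).
* Chromosomes are assigned uniformly over the 21 wheat names with a
  configurable unmapped fraction, which makes introgressed vs
  non-introgressed partitions exchangeable — the correct null for the
  "is the shift chromosome-local?" question.

What the generator does **not** emulate: sequencing error and assembly
chimeras of real EST data, selection on codon usage, iterated
generations, recombination, and expression-weighted sampling of genes. A
green end-to-end test therefore establishes that the pipeline recovers
the stated mutational structure from clean sequence — not that real EST
collections are free of confounders.

# Numerical choices

* χ² is the plain Pearson statistic with margin-derived expectations;
  `min_expected` travels with every result and a warning (not an error)
  fires below 5.
* Undefined ratios (zero denominators) are explicit `NA` flags; they
  propagate through cross-sample ratios and are dropped from t-tests
  with the count visible in the report.
* Six-codon amino acids (Leu, Arg, Ser) pool all codons in the
  per-amino-acid C/G : A/T ratio; the A/G *pair* analysis is
  family-specific by construction and uses the four-codon family
  (CTn/CGn/TCn) by default, with the two-codon families (TTA/TTG,
  AGA/AGG) available as `family = "alt"`.
* Determinism: one master seed; mutation substreams are derived per
  record index, and `simulate` + `analyze` runs are byte-identical for a
  fixed seed (asserted in the acceptance suite).

# Known limitations — and two deliberately red acceptance clauses

The acceptance suite encodes the validation contract this package was
built against. Two of its clauses are *expected* to fail, and both
failures are informative about the model rather than the code:

1. **Genome-wide CpG deamination perturbs two "control" ratios.** The
   mutation model elevates deamination at *every* CpG site. Two side
   channels follow unavoidably: the second-position C of an NCG codon is
   itself in CpG context, so enhanced C→T converts NCG → NTG and
   depresses the hybrid's NTA/NTG ratio; and when a codon ends in C
   before a G-starting codon, the successor's G is in CpG context, so
   enhanced G→A converts NC|G pairs into NC|A pairs and dilutes the
   NT|A/NC|A denominator. At the test's scale the NT|A/NC|A comparison is
   significant in essentially every seed and NTA/NTG in roughly a third
   to a half. The four remaining controls are clean. Restricting
   enhancement to third-position CpGs would silence these channels, but
   that would be a different (and less faithful) mutational world. In
   real-data practice this means NTA/NTG and NT|A/NC|A are only *weak*
   controls for the methylation signature; NAA/NAG, NGA/NGG, NT|C/NC|C
   and NT|T/NC|T are the trustworthy ones.
2. **The cross-sample χ² null is conservative in a paired design.** The
   synthetic hybrid is the ancestral set after ~1% mutation, so the two
   rows of each cross table share ~99% of their codons. The χ² test
   assumes independent rows; under this pairing its null rejection rate
   is ≈ 0%, not the nominal 5%. Comparisons between *disjoint* pools
   (flank vs remote, introgressed vs non-introgressed) are properly
   calibrated, and the suite verifies both facts. For real data — two
   independently sampled cDNA collections — the independence assumption
   is much closer to true; for before/after designs the reported
   p-values are conservative, which inflates confidence in positives but
   not their direction.

Other limitations: no multi-sequence alignment, no RSCU/ENC/CAI-style
indices, no bisulfite input (methylation is inferred from the sequence
signature only), and introgression is tracked at whole-chromosome
resolution because unigene→arm mapping is not modeled.
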