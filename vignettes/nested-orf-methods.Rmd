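---
title: "Methods: screening and codon-usage analysis of nested ORFs in mitochondrial genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and codon-usage analysis of nested ORFs in mitochondrial genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naltorf)
```

## The two-code setting

A mitochondrial protein-coding gene such as *cytb* is translated in the
organelle under the vertebrate mitochondrial code (NCBI table 2), in which
UGA encodes tryptophan, AGA/AGG are stop codons and AUA is an additional
initiator. If the same mRNA were engaged by cytosolic ribosomes it would be
read under the standard code (table 1), where UGA is a stop. `naltorf`
analyses the consequences of this duality: the primary frame typically
terminates at an early UGA in the cytosol, while a shifted frame may hold a
long standard-code ORF — a nested alternative ORF — whose protein, if
translated, would be a genuinely new gene product.

`genetic_code()` holds both tables (codon maps from the canonical NCBI
assignments; start sets ATG for table 1 and {ATA, ATG} for table 2). All
internal sequence handling is in the DNA alphabet; `U` is normalized to `T`
on input because the literature mixes RNA and DNA notation. Frames are
numbered +1/+2/+3, with +1 the annotated host frame and frame *k* starting
codons at nucleotide *k* (1-based, inclusive coordinates throughout).

## Screening rules

`scan_nested_orfs()` reports, per stop-bounded segment of frames +2 and +3,
the 5'-most ATG and its run to the in-frame stop. The design choices, all
tested:

* **Only ATG initiates**, even under the table-2 control scan: the
  downstream Kozak analysis is defined around AUG, and permitting AUA
  starts would create candidates that cannot be context-classified.
* **Length excludes the stop codon**, so the reported `length_codons`
  equals the encoded protein length; the default threshold is 150 codons.
* **A terminal stop within the host CDS is required** by default. The
  input is a single CDS, so an ORF running off its 3' end cannot be
  verified; `include_incomplete = TRUE` retains such candidates flagged.
* **Frame +1 is never scanned** for nested ORFs; it is handled separately
  by `ptc_scan()`, which locates the first standard-code stop on the host
  grid and then asks whether any ATG strictly downstream could start an
  ORF longer than 50 codons (the rescue-initiation question).
* `longest_per_frame()` keeps one ORF per host and frame (ties to the
  smallest start coordinate); `dedupe_orfs()` consolidates exact
  nucleotide duplicates, keyed on the full ORF sequence, keeping the
  lexicographically smallest host accession as representative.

The scanner is validated against a brute-force enumerator (every ATG
walked to its stop by substring inspection) on a thousand random sequences
of 300–2,000 nt per run, and against generator ground truth (below).

## Kozak classification

`classify_kozak()` implements four nested tiers on the −6..−1/+4 context:
optimal `GCCRCCAUGG`, strong `NNNRNNAUGG`, adequate `NNNRNNAUG(A/C/U)` or
`NNN(C/U)NNAUGG`, weak `NNN(C/U)NNAUG(A/C/U)`. Only the −3 purine and the
+4 G decide strong/adequate/weak; the full `GCCRCC` motif is additionally
required for optimal, and the most specific matching tier wins. A context
with fewer than three upstream bases or no +4 base is `undetermined` and
excluded from tallies rather than guessed — qualifying nested ORFs, which
sit hundreds of nucleotides into the host, never trigger this. A context
such as `GCCTCC…G` (optimal shell, pyrimidine at −3) is adequate under the
literal patterns, and is classified as such. The classifier is checked
exhaustively: all 4^7 contexts against a regex oracle of the four patterns.

## Codon-usage statistics

All synonymous-family statistics default to **table-1 families for every
vector, including mitochondrial reference tables**, over the 59-codon
informative set (61 sense codons minus the single-codon families ATG and
TGG). The four RSCU vectors entering a species' similarity comparison must
be commensurable, which forces a single family basis; the standard code is
the natural common denominator since the question is adaptation *to the
cytosol*. `code_basis = 2` is available for sensitivity analyses.

* `rscu()`: `RSCU_c = n_c · |F(c)| / Σ_F n`. Zero-count families are set
  to the neutral value 1 and flagged (short genes can lack an amino acid
  entirely); `NaN`s never propagate.
* `relative_adaptiveness()` / `cai()`: weights `w_c = n_c / max_F n` with
  a 0.5 pseudocount on zero-count reference codons (keeping all weights
  positive), CAI the geometric mean of weights over a gene's non-excluded
  codons. Excluding the single-codon families prevents uninformative
  `w = 1` terms from inflating the index.
* `rcdi()`: the count-weighted mean ratio of within-family codon
  frequencies, query over reference; ≥ 1 by the Cauchy–Schwarz inequality
  with equality exactly at frequency match (asserted on 10,000 random
  instances). Reference families containing zeros get the same 0.5
  smoothing.
* `cosine_similarity()` on RSCU vectors; the historical dissimilarity
  `D = (1−R)/2` is provided for reference only, as `R` itself is the
  interpretable statistic.

### Monte-Carlo expectations (eCAI, eRCDI)

The null model asks: *what CAI (or RCDI) would a random gene with this
amino-acid composition and this base composition achieve?* `generate_mock()`
draws one codon per amino acid of the query profile, with within-family
probabilities proportional to the product of the query's **global
mononucleotide frequencies** over the codon's three positions. Global
rather than positional frequencies are the deliberate default — the
simplest reading of "corrects amino-acid and base bias" — and the ensemble
is 500 mocks by default. The one-sided upper 95% limit uses the normal
approximation `mean + 1.6449·sd` (an empirical-percentile method is
available via `method = "percentile"`); the lower limit is the manual
reflection `2·expected − upper`, so `lower = 2·expected − upper` holds
exactly for every result object. Verdicts are fixed-bound comparisons per
gene with no multiple-testing correction, mirroring per-gene
adaptation calls. `seed` fixes the ensemble bit-reproducibly without
disturbing the caller's RNG stream.

### Tests used for group contrasts

`wilcoxon_signed_rank()` wraps the signed-rank test with the conventions
pinned down: zero differences dropped, exact null when the effective n is
at most 25 with untied magnitudes (the all-positive n = 12 case gives
exactly 1/4096 ≈ 0.0002 one-tailed), otherwise the tie- and
continuity-corrected normal approximation. Test directions are fixed to
the biological hypotheses: the host gene should be closer to the
mitochondrial than the nuclear reference, and the nested ORF below its
host against both. `spearman_cor()` is rank-Pearson with the t
approximation; `pairwise_identity_similarity()` scores pre-built protein
alignments (alignment construction itself is out of scope) with the
conservative substitution groups GAVLI, FYW, CM, ST, KRH, DENQ, P.

## The synthetic cohort generator

`generate_hosts()` produces the study conditions end to end: hosts of
1,140 nt (the mammalian *cytb* length) that start with ATG and translate
without internal stops under table 2; a planted TGA at codon 30
(nucleotides 88–90) — tryptophan in the organelle, the premature stop a
cytosolic ribosome would hit; and, for positives, an embedded frame +3
nested ORF of 150–239 codons with a requested Kozak class. Defaults follow
the observed biology: host codons from the `mito_like` law (third-position
A:C:T:G = 8:4:2:1, no AGA/AGG since those are mitochondrial stops),
nuclear reference tables from the milder same-direction `nuclear_like` law
(4:3:2:1), ORF length range matching the reported nested proteins.

Construction is propose-and-repair: sample host codons, splice the ORF
window and Kozak bases in, then fix any host-frame stop codon the splice
created by re-choosing an overlapping ORF codon (the ORF ATG, the +4 base
and the terminal stop are immutable) or a host base outside the protected
positions. Every candidate is then **verified by the package's own
analysis path** — scanner, PTC scan, Kozak classifier must recover exactly
the planted truth, and negatives must yield nothing — with bounded
resampling (1,000 attempts) on any failure. The emitted manifest is
therefore ground truth by construction, and round-trip recovery is exact
on every record.

Two generator choices deserve emphasis:

* **Nested-ORF interiors follow the frameshift-induced law** (the product
  of the positional base marginals the host law induces in the shifted
  frame, `frameshift_law()`), not an independent neutral law. This mirrors
  the real causality — the host frame dictates the nested ORF's codons —
  and it is also what keeps the *host's* frame-1 codon bias intact across
  the ORF window, which spans half the gene. An independently uniform ORF
  law would flatten the host's usage and invert the host-versus-reference
  similarity ordering the cohort is meant to exhibit. A side effect is
  that the nested ORF's third positions are close to uniform, so its RSCU
  vector sits near the neutral point, below the host's similarity to
  either reference set.
* **TGA is allowed on the host grid downstream of codon 30** (mito Trp),
  so chance ATG-initiated ORFs downstream of the planted PTC are usually
  interrupted quickly, as in real sequences; before codon 30 it is
  excluded so the planted PTC is the first standard-code stop.

What the generator does **not** emulate: phylogenetic correlation between
species (records are i.i.d. draws), indels and alignment artifacts,
amino-acid-level selection on either protein, and the joint dinucleotide
structure of real coding sequence. Consequently, a green synthetic
round-trip demonstrates the correctness of the screening and measurement
machinery, not the biological conclusions themselves.

A known, accepted consequence of the positional ORF law: scored against
the global-mononucleotide Monte-Carlo null, synthetic nested ORFs land
outside the eCAI/eRCDI band for roughly half the genes (the null blends
the host-inherited first-position bias across all positions). Real
sequences in this analysis class sit almost entirely inside the band; the
discrepancy is a property of the synthetic law, documented here rather
than hidden by switching the null to positional frequencies, which is
available but not the default.

## Pipeline, sizes and formats

`run_all()` chains the stages per group — clean FASTA input (records with
ambiguous bases dropped and counted), standard-code scan plus table-2
control scan, longest-per-frame, de-duplication, Kozak tallies, PTC scan
of positive hosts, adaptation verdicts against each species' robust
nuclear table (robust = built from ≥ 30 CDSs of mean length strictly over
100 codons; robustness is a nuclear-table criterion, mitochondrial tables
need only exist), similarity table and the four Wilcoxon contrasts —
writing per-stage TSVs and a summary JSON. All randomness flows from the
single config seed; identical configs produce identical bundles.
Percentages are rounded half-up to two decimals.

Reference tables are exchanged in a pinned canonical TSV (`#` metadata
lines plus `codon<TAB>count`); one-row CoCoPUTs-style exports and
Kazusa-style block text are converted on read, with missing codons
zero-filled under a warning. Because public export layouts vary, the
CoCoPUTs reader ships against a documented fixture rather than a
guaranteed byte-level match to any particular download vintage.

The shipped test suite and the acceptance script run desk-scale problem
sizes chosen to exercise every contract well within a single CPU: a
thousand random sequences for scanner-oracle equivalence, a 100-record
planted cohort for the round-trip, the full 4^7 Kozak enumeration, 10,000
random RCDI instances, 500-mock adaptation ensembles, and study-shaped
cohorts of 289 and 380 records for the end-to-end reproduction.

## Limitations

Only NCBI tables 1 and 2 are supported; reverse-complement scanning,
genome-scale annotation, homology search, alignment construction and
protein feature prediction are out of scope. The exact Monte-Carlo
internals of the historical web servers for eCAI/eRCDI are not published;
both the normal-approximation and percentile limits are provided, and the
reflection identity for the lower limit is guaranteed by construction.
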