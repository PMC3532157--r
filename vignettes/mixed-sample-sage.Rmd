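---
title: "Tag-based expression profiling of mixed host-symbiont samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based expression profiling of mixed host-symbiont samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cool-season grasses such as red fescue (*Festuca rubra*) host intercellular
fungal endophytes (*Epichloë* spp.) that confer insect and disease resistance.
RNA extracted from an infected leaf sheath is a mixture: mostly host
transcripts, with a small fungal component reflecting the low fungal biomass
(a few percent). SOLiD-SAGE / SuperSAGE profiles such samples by counting
short cDNA *tags* rather than whole reads: the anchoring enzyme NlaIII cuts at
CATG, and the tagging enzyme releases a fixed-length fragment, so each
transcript is represented by the 27-base tag starting at its most 3' CATG.
Counting tags gives digital expression ("one tag = one transcript"), and
because a tag retains its strand, tags matching the reverse complement of an
oriented reference reveal antisense transcription.

`sagetag` implements the full computational path from raw tag libraries to
biology: in-silico digest of the reference, tag quality control, strand-aware
mismatch-tolerant mapping against a two-part (host + symbiont) reference,
normalization, replicate t-tests for host differential expression, abundance
ranking of symbiont transcripts, and sense/antisense pairing. A synthetic-data
generator with full ground truth makes every stage testable without raw
sequencing data.

## The model and its conventions

**Canonical tag.** For a transcript the canonical tag is the 27-mer starting
at the most 3' CATG with at least 23 downstream bases. Two edge rules, both
package choices where upstream tools are undocumented: if the most 3' CATG is
closer than 23 bases to the end of a *reference* sequence (a truncated
assembly; on real cDNA the poly(A) tail supplies downstream bases), the next
eligible CATG upstream is used rather than discarding the transcript; and a
candidate window containing an ambiguity code (N) is skipped the same way,
because tags are observed sequences and cannot contain N. Transcripts with no
eligible site are reported tagless — such transcripts are invisible to SAGE.
On uniform random sequence CATG recurs every 4^4 = 256 bp, so tagless
transcripts are rare except for very short references.

**Quality control.** Two filters, applied in order: (1) tags not beginning
with CATG arise from random adaptor ligation and are removed; this is a
strict 5' prefix test. (2) Tags with *more than 10* terminal A's are removed
as poly(A) runoff: when the anchor sits near the transcript end the tag reads
into the tail, and template A's cannot be distinguished from poly(A). The
boundary is inclusive — exactly 10 terminal A's survives. We interpret the A
rule as a *terminal homopolymer run*, not total A content, because the
artifact it targets is terminal. Tags containing N fail the anchor step.
Survivors are the *potential mappable* tags; the QC report satisfies
`total = with_anchor + removed_no_anchor` and
`with_anchor = after_polyA + removed_polyA` by construction.

**Mapping.** Matching is CATG-anchored: candidate positions are exactly the
eligible CATG sites on both strands of every reference transcript, and the
mismatch budget (default 2) applies to the 23 non-anchor bases. Anchoring is
biologically motivated — tags can only arise at NlaIII sites — and bounds the
search space. The index is an exact-window pass followed by a pigeonhole
split of the 23-base suffix into `budget + 1` chunks (any hit within budget
matches at least one chunk exactly); candidates are verified by vectorized
Hamming distance. The test suite proves the index equivalent to an exhaustive
both-strand window scan on randomized instances.

Host/symbiont attribution uses *best-distance partitioning*: a tag belongs to
the partition of its minimal-mismatch hits; tags whose best hits span both
partitions are *ambiguous* and excluded from both, rather than being assigned
by a mapping order. A sequential two-pass scheme (host first, then symbiont)
silently biases attribution toward whichever database is searched first, and
no pass order is documented for the original tooling, so the symmetric rule
is used and ambiguous tags are surfaced explicitly. Quantification stays per
distinct tag sequence: a tag hitting several transcripts within one partition
keeps a single count annotated with all best hits (SNP tags mapping to the
same protein are one expression unit). Antisense calls require oriented
references; hits to non-oriented references are reported strand-unknown.

**Normalization and testing.** Plant tags are scaled to tags per million
plant-mapped tags in their replicate; fungal tags to percent of fungal-mapped
tags. The acronym "TMM" here means this simple per-million scaling, not the
trimmed-mean-of-M-values normalization of count-based DE packages. The two
partitions never share denominators, and ambiguous tags are in neither.
Differential expression uses a two-sided pooled-variance unpaired t-test
(df = 4 at n = 3+3), matching the classic GraphPad-style default; Welch and
one-sided variants were considered and rejected because the original analysis
is described only as "unpaired t tests". Significance is raw p < 0.05 with
*no* multiple-testing correction, reproducing the original procedure; a
`correct` argument exposes `p.adjust` methods for users who want control of
the false discovery rate. Fold changes are signed ratios of group means
(+treated/control when up, -control/treated when down, magnitude always >= 1).
When one group mean is zero the ratio uses half the smallest nonzero
normalized value in the matrix as a floor and the row is flagged
`zero_floored`; both-zero rows are undefined.

**Antisense pairing** is per transcript, not per tag pair: a transcript's
antisense signal is the summed abundance of all tags hitting its reverse
complement, because sense and antisense strands generally anchor at
*different* CATG sites. Ratios are reported as 1:N with
N = round(sense/antisense), half away from zero, computed on mean normalized
abundances across replicates. Transcripts with antisense but no sense signal
are emitted flagged, not dropped.

**Report rounding.** All human-readable percentages round half away from
zero (so 12.5% prints as 13%), integer precision for host-side and category
percentages, one decimal for fungal mapped fractions, two decimals for
fungal abundance percents — matching the precision conventions of the
published tables this report style follows.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the pipeline is meant to operate under, chosen once:

* **References**: 1200 plant and 800 fungal transcripts, lengths
  N(400, 120) truncated at 100 nt, GC 0.5, a 30-base poly(A) tail. Every
  transcript is rejection-sampled to carry a QC-clean, unique canonical tag
  (the poly(A) tail makes the canonical case the common one, as on real
  cDNA). Designated antisense transcripts also carry an eligible site on the
  reverse complement.
* **Abundances**: plant tags log-normal (sdlog 1.0), giving a top plant tag
  near 1% of plant-mapped tags as observed in fescue libraries; fungal tags
  Zipf-distributed with the exponent solved so the top transcript takes 10%
  of fungal tags (the observed extreme skew); fungal tags form 2% of mapped
  tags in the infected sample and are absent from the uninfected one.
* **Design**: 3 + 3 biological replicates of 1e5 tags each; 50 truly DE
  plant tags at 4-fold (half up, half down) with 20% within-group CV.
  Biological CV noise applies to the plant transcriptome (the DE arm). The
  fungal composition is held fixed across replicates so that fungal ranking
  and antisense-ratio recovery are governed by multinomial counting noise
  alone, which is what "recovery within sampling error" quantifies. DE tags
  are drawn only from plant tags with an expected count of at least 20 per
  library: a t-test at n = 3 has no power at near-zero counts, so seeding DE
  into such tags would only dilute a power estimate with foregone cases.
* **Artifacts**: 30% of raw tags are anchorless adaptor artifacts and 0.2%
  poly(A) runoff (both matching the observed attrition between raw and
  potential-mappable tag counts); substitution errors at 0.005 per non-anchor
  base are applied at the read level after tag formation, so ~11% of reads
  carry at least one error and appear as distinct low-count tags that map
  back at 1-2 mismatches. Anchor-breaking errors are not modelled separately
  because anchorless tags are already governed by their own rate.
* **Antisense**: ratios 1:9 and 1:30 attached to the two most abundant
  fungal transcripts, spanning the observed range in order of magnitude
  (observed fungal ratios ran 1:9 to 1:87; a 1:87 transcript at this library
  scale would receive ~2 antisense counts and is deliberately not simulated).

What the generator does *not* emulate: sequencing-platform error profiles
(color space, homopolymer effects), reference incompleteness (simulated
references are complete, so mapped fractions are far higher than the 37-60%
observed with a partial 454 assembly), transcript-length or GC bias in
library preparation, and overdispersion beyond log-normal replicate noise.
Passing recovery tests therefore demonstrate the *computational* correctness
and calibration of the pipeline under its stated model, not robustness to
every artifact of real libraries.

## Numerical and statistical choices

* Degenerate t-tests: two identical zero-variance groups give t = 0, p = 1;
  unequal zero-variance groups give p = 0 flagged `degenerate` rather than an
  error, so a scan never aborts mid-matrix.
* Ties in ranking are broken by tag sequence order after abundance sorting;
  the digest, mapper and report are deterministic functions of their inputs,
  and simulation output is byte-identical under a fixed seed.
* Coordinates are 0-based half-open internally; every written artifact
  (catalogs, hit tables) emits 1-based columns suffixed `_1based`.
* Mapper chunk joins are exact string joins; no heuristics, no seeding — the
  oracle-equivalence property is exact, not approximate.

## Problem sizes and calibration results

The packaged checks run at desk scale, chosen to keep the full suite in a few
minutes of one CPU: the seeded recovery experiment uses 6 libraries of 1e5
tags over 2000 transcripts; spacing is measured on 4 Mb of random sequence;
oracle equivalence on 200 random instances. At this scale the recovery runs
reproduce: DE power > 90% at 4-fold with type-I error within 5% ± 2% on 1000
well-expressed null tags; the mapped fungal fraction within the observed
1.4-2.8% band; and the 1:9 antisense ratio within ±1.

One calibration limit is worth stating plainly. With 2% fungal fraction and
30% artifact attrition, an infected replicate contains ~1400 mapped fungal
tags, so the 5th and 6th most abundant fungal transcripts (Zipf shares 2.3%
and 2.0%) differ by only ~13 counts over three replicates — about one
standard deviation. The *membership* boundary of an observed top-5 list is
therefore unstable at this scale even for a perfect pipeline, while the
*relative order* of the five truly most abundant transcripts is recovered
reliably. The recovery checks accordingly assert relative-order preservation
and report exact-position agreement alongside. At the scale of the real
libraries (40-110 thousand fungal tags per replicate) both formulations
coincide.

## Limitations

* The mapper is ungapped and quality-blind by design; indels and color-space
  error structure are out of scope.
* Attribution trusts the reference partition: a host transcript missing from
  the host database whose tag happens to sit within the mismatch budget of a
  symbiont site will be mis-partitioned; the ambiguous class catches only
  exact ties, not asymmetric database incompleteness.
* Raw p < 0.05 across thousands of tags implies a known false-positive load;
  this is faithful to the procedure the package reproduces, and `correct`
  exists for stricter analyses.
* Percent-of-mapped values are compositional; ratios between them are
  meaningful, absolute differences across samples with different fungal
  loads are not.
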