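---
title: "Methods: evidence classification, figure layout, and curation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence classification, figure layout, and curation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

svcurate turns a set of structural variant (SV) calls and the alignment
files that produced them into reviewable evidence images, and turns a
team's reviews of those images into per-variant curation scores, reports
and annotated VCFs. This vignette records the models, conventions and
numerical choices behind each stage, in the spirit of what the package's
tests actually verify.

## Evidence model

For the window around each candidate SV, three kinds of observation are
extracted per sample from an indexed BAM:

* **Paired-end observations.** One per read pair with at least one primary
  alignment overlapping the window and both mates mapped to the window's
  chromosome. Mates are stored in genomic order. The quantity plotted and
  thresholded is the *outer span*: rightmost mapped end minus leftmost
  mapped start. We deliberately use the outer span rather than the TLEN
  field so that pair and split observations share one y-axis; TLEN
  conventions vary across aligners, while outer span is defined by the
  mapped coordinates alone.
* **Split-read observations.** Discovered through the standard
  supplementary-alignment tag (`SA:Z:rname,pos,strand,CIGAR,mapQ,NM;...`).
  The full segment set of a read is reconstructed from its records and
  their SA entries, ordered by position within the read (recovered from
  the soft/hard-clip structure), and each *adjacent* pair of segments is
  emitted once — a three-segment read yields two observations, and a read
  seen from both its primary and supplementary records is not duplicated.
* **Coverage.** Per-base counts of primary, non-duplicate aligned bases
  (CIGAR `M`/`=`/`X`). Bases soft-clipped off a read and reference bases
  spanned by a read's deletion or skip operations do not count.

Unmapped, secondary, duplicate and QC-fail records are skipped everywhere;
supplementary records participate only in split detection, which avoids
double counting in pair and coverage tracks. Inter-chromosomal mates and
splits are excluded: translocation rendering is out of scope.

### Classification

Each observation is assigned exactly one evidence class. For pairs,
orientation (in genomic order) is considered first, then the span
threshold:

| left, right strand | span | class |
|---|---|---|
| `+`, `-` | ≤ mean + z·sd | `NORMAL` |
| `+`, `-` | > mean + z·sd | `DELETION` |
| `-`, `+` (everted) | any | `DUPLICATION` |
| `+`, `+` | any | `INVERSION_FF` |
| `-`, `-` | any | `INVERSION_RR` |

These are the standard discordant-pair conventions for Illumina
forward/reverse libraries. The insert-size mean and standard deviation are
estimated once per alignment file from up to 10,000 properly paired,
primary, non-duplicate `+/-` pairs taken from the start of the file; the
*population* standard deviation is used (the estimate describes the
sampled spans themselves, and at n = 10,000 the distinction from the
sample sd is negligible anyway). The threshold multiplier z defaults to 4.

Split observations use segment strands and read order. Opposite segment
strands indicate an inversion, sub-typed by the left segment's strand
(`+` gives `INVERSION_FF`, drawn blue; `-` gives `INVERSION_RR`, drawn
green — the blue/green assignment is arbitrary but fixed). Same-strand
segments indicate a deletion when the segment order along the read matches
genomic order, and a tandem duplication when it is inverted. One subtlety
matters here: a reverse-strand read traverses the genome right-to-left, so
its natural segment order is the reverse of genomic order. The
`read_order_flipped` flag is therefore normalized by read orientation
(XOR with minus strand); without this, every reverse-strand deletion split
would be misread as duplication-supporting.

The mate's reference end, needed for outer spans when only one mate falls
in the queried window, is taken from the `MC` (mate CIGAR) tag when
present and otherwise approximated by `mate_pos + read length`. Modern
aligners and the package's own generator always write `MC`; the fallback
only matters for gapped mates in files without it.

### Downsampling

Concordant (`NORMAL`) pairs vastly outnumber informative ones in large
windows, so they are capped at `max_normals` (default 100) per sample per
window: a seeded uniform subset without replacement, preserving relative
order. All discordant pairs are always retained. The cap is applied per
window rather than globally so every image keeps a visible band of
concordant pairs for reference regardless of batch composition.

## Figure layout

Each image stacks, top to bottom: a black locator bar spanning the called
interval; one panel per sample, in exactly the order given (sample of
interest first); and an annotation panel when gene/region annotations are
supplied. All panels share the window's x range. The window pads the call
by `max(min_pad, round(pad_fraction × SV length))` with defaults 1,000 bp
and 0.5.

Within a sample panel, pair glyphs are solid connectors with square ends
and split glyphs dashed connectors with circle ends, positioned by genomic
x and outer span y, colored by class (deletion black, duplication red,
inversions blue/green, concordant grey). The span axis is linear up to the
98th percentile of all plotted spans in the figure; larger spans clamp to
the axis top, so extreme discordant pairs stay visible without crushing
the concordant band. Glyph opacity falls with local glyph density
(1/sqrt of the bin count on a 24×24 grid, floored at 0.15), so dense
stacks read as intensity rather than overplotting — an aesthetic choice.
Coverage is drawn as a grey filled profile against a per-sample secondary
right axis scaled from 0 to that sample's maximum depth.

Output files are named `<id>.png` with characters outside
`[A-Za-z0-9._-]` replaced by `_`. Batch rendering catches per-SV failures,
records them as `render_failed` in the manifest, and continues; results
are independent of the worker count because every SV is rendered from the
same deterministic inputs.

## Curation scoring

A project is a JSON config (question, ordered answers, single-character
key bindings), an image roster taken from the render manifest, and an
append-only response log — a single local JSON file stands in for a hosted
database, with project isolation via the filesystem. A reviewer may
re-score an image; the latest response per (image, reviewer) supersedes
earlier ones, a policy chosen because an explicit correction should win.

A score function maps answers to numbers and aggregates with mean,
median, mode, population sd, min or max. Mode ties break toward the
larger mapped value (toward "more variant" under the usual mappings). The
default trio mapping sends `GOOD` and `DE NOVO` to 1 — both assert a real
variant in the sample of interest — and `BAD` to 0, aggregated by the
mean.

Qualitative classes are defined only for 0/1 mean mappings:
score exactly 1 or 0 is *unanimous*; above 0.8 or below 0.2 is
*unambiguous* (at most one dissenter among nine reviewers); the closed
interval [0.2, 0.8] is *ambiguous*. Other mappings report a score without
a class. In the annotated VCF the score is written as a single
`SVP=<value>` INFO tag rounded to 4 decimals; annotation is performed as
a line-level edit so that every other byte of the input is preserved and
annotate-then-strip is the identity.

Summaries drop excluded images (e.g. failed renders) and unscored images
from all denominators and report them separately. Concordance against
orthogonal callers considers unambiguous deletions only: a low score
agrees with a homozygous-reference genotype or a copy number in the
neutral band (1.4, 2.4]; a high score agrees with a non-reference
genotype or a copy number below 1.4. A copy number above 2.4 under a low
score is treated as disagreement — it may reflect a duplication signal,
but it is not evidence for the called deletion.

## Synthetic data generator

The generator exists so the entire pipeline is testable with no network
access and known ground truth. Each variant lives on its own synthetic
contig (default `chrS`, 100 kb). Fragments are placed uniformly on each of
two haplotypes at depth/2 apiece, with insert sizes drawn from a normal
distribution (defaults: mean 400 bp, sd 50 bp, read length 100 bp,
truncated at the read length). Haplotypes carrying the variant are laid
out in *alternate* coordinates and mapped back to the reference through a
piecewise-linear map, so the SV signatures arise from the geometry rather
than being painted on: deletions inflate spans across the gap,
duplications produce everted pairs across the copy junction, inversions
produce `+/+` and `-/-` pairs across each breakpoint, and coverage dips
or rises according to genotype (het deletion ≈ 0.5×, hom ≈ 0, het
duplication ≈ 1.5×). Reads that cross a junction are emitted as split
primary+supplementary records with correct `SA` and `MC` tags at rate
`split_read_fraction` (default 0.5), and otherwise soft-clipped at the
junction. Records are written as a sorted SAM and converted to an indexed
BAM; everything is deterministic for a fixed spec and seed.

What the generator does **not** emulate: sequencing errors, GC and
mappability bias, chimeric artifacts, repeat-mediated false signals, or
multi-breakpoint events. Passing tests therefore demonstrate that the
extraction, classification, rendering and scoring machinery is correct on
clean signals of known origin — not that curation of real-genome images
is easy; the interesting ambiguity in real data comes precisely from the
artifacts the generator omits.

Simulated reviewers answer with the true label with probability
1 − error_rate and otherwise with a uniformly random wrong label. With a
binary answer set and nine reviewers this gives the closed-form unanimity
rate (1−e)^9 + e^9 that the property tests check.

## Problem sizes and determinism

The test suite and the acceptance script run on deliberately small
conditions chosen to exercise every code path with comfortable margins:
12–20 kb contigs, 2 kb variants, 30× depth, 20 replicate seeds for
recovery checks, and a 30-variant trio (10 deletions, 10 duplications, 10
inversions, mixed genotypes and inheritance patterns) for the end-to-end
run. At 30× a 2 kb event receives on the order of 15–30 supporting pairs,
ample for the modal-class recovery the tests assert. All randomness —
fragment placement, split emission, downsampling, reviewer errors — is
seeded, and every artifact (BAM bytes included) is reproducible from the
spec and seed.

## Known limitations

* Translocations/breakends and insertion evidence are not extracted or
  simulated; insertions are accepted in VCFs and windows but their images
  show only the locus context.
* CRAM is readable only when the caller supplies a reference through the
  usual Rsamtools mechanisms; no reference auto-fetch.
* Score classes presume the 0/1 mean mapping; the unanimity thresholds
  (0.2/0.8) are calibrated to nine reviewers in the sense that "at most
  one dissenter" motivates them, but they are applied as fixed bounds for
  any reviewer count.
* The evidence dump, report and manifest are plain TSVs; very large
  projects would want a real database behind the same interfaces.
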