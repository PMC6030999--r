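# svcurate

Structural variant (SV) callers produce far more candidate deletions,
duplications and inversions than are real, and manual inspection of the
raw alignment evidence remains the most reliable dry-bench validation
step. Doing that at the scale of a full call set needs two things: one
reviewable image per variant, and machinery to collect and aggregate many
reviewers' judgments. svcurate provides both as a self-contained R
package for anyone running SV calling pipelines — no web service, no
cloud account, everything local and scriptable.

For each candidate SV, the package extracts the evidence from indexed BAM
files for the surrounding window and renders a stacked per-sample image:
paired-end alignments (solid connectors, square ends) and split-read
alignments (dashed connectors, circle ends) positioned by genomic
coordinate (x) and the distance between their outermost mapped ends — the
insert size or outer span (left y) — with per-base coverage as a grey
profile (right y) and an optional gene track below. Every observation is
colored by the event it supports, using standard discordant-pair
conventions for FR libraries with insert mean μ and standard deviation σ:

| observation | class |
|---|---|
| `+`/`-` pair, span ≤ μ + zσ (default z = 4) | normal (grey) |
| `+`/`-` pair, span > μ + zσ | deletion (black) |
| `-`/`+` everted pair | duplication (red) |
| `+`/`+`, `-`/`-` pair | inversion (blue/green) |
| split read, same strand, read order preserved / inverted | deletion / duplication |
| split read, opposite strands | inversion |

Normal pairs are downsampled to a per-window cap (default 100) so large
events stay legible.

Reviews are collected under a configurable question/answer scheme (e.g.
"The SV in the top sample is:" GOOD / BAD / DE NOVO). Each variant's
**curation score** is an answer→value map plus an aggregation function;
the default maps GOOD and DE NOVO to 1, BAD to 0, and takes the mean, so
a score of 1.0 means unanimous support. Scores exactly 0 or 1 are
*unanimous*, scores < 0.2 or > 0.8 *unambiguous* (at most one dissenter
among nine reviewers), and scores in [0.2, 0.8] *ambiguous*. Reports are
tab-delimited; scores can also be written back into the VCF as an
`SVP` INFO tag with all other bytes preserved.

A synthetic-alignment generator rounds out the package: it plants
DEL/DUP/INV signatures (discordant pairs, SA-tagged split reads, coverage
dips/gains) in trio samples at configurable depth and insert-size
distribution, with a truth table, so the entire pipeline is testable
offline.

## Worked example

Simulate a trio in which the child carries a de novo heterozygous 2 kb
deletion, render the image, and score it with nine simulated reviewers:

```r
library(svcurate)

sv   <- sv_call("chrS", 40000, 42000, "DEL")
spec <- simulation_spec(sv, depth = 30, seed = 1)
trio <- simulate_trio(spec, "trio_fixture", inheritance = "denovo")

win     <- compute_window(sv)            # chrS:39000-43000 (1 kb pad)
samples <- lapply(names(trio$bams), function(nm)
  gather_sample_evidence(trio$bams[[nm]], win, sample_name = nm))
glance(samples[[1]])
#> # A tibble: 1 × 6
#>   sample n_pairs n_discordant n_splits modal_discordant_class mean_depth
#>   <chr>    <int>        <int>    <int> <chr>                       <dbl>
#> 1 child      124           24        6 DELETION                     24.0

fig <- render_sv_figure(sv, samples, path = "chrS_del.png")
fig$panels
#> # A tibble: 4 × 3
#>   kind    sample n_glyphs
#>   <chr>   <chr>     <int>
#> 1 locator <NA>          0
#> 2 sample  child       130
#> 3 sample  father      100
#> 4 sample  mother      100
```

The child carries 24 discordant pairs and 6 split reads, all
deletion-class, over a coverage dip; the parents show only concordant
evidence (their 100 normal pairs are the downsampling cap). Scoring the
image with nine error-free reviewers gives a unanimous score:

```r
store <- curation_project(trio_config(),
                          data.frame(image_id = sv$id, chrom = sv$chrom,
                                     start = sv$start, end = sv$end,
                                     svtype = sv$svtype))
resp  <- simulate_reviewer_responses(setNames("GOOD", sv$id),
                                     trio_config()$answers,
                                     n_reviewers = 9, error_rate = 0)
store <- import_responses(store, resp)
curation_scores(store)[, c("image_id", "n_responses", "score", "score_class")]
#> # A tibble: 1 × 4
#>   image_id           n_responses score score_class
#>   <chr>                    <int> <dbl> <chr>
#> 1 chrS_40000_42000_DEL         9     1 UNANIMOUS_HIGH
```

`plot_sv_batch()` drives the same loop over a whole VCF and writes a
manifest; `project_init()` / `project_report()` / `project_annotate()`
manage a curation project from the command line via the bundled
`svcurate` script (`exec/svcurate`).

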