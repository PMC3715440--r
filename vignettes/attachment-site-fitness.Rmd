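---
title: "Attachment-site usage, excision, and the fitness cost of being stuck: the iceatt methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attachment-site usage, excision, and the fitness cost of being stuck: the iceatt methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iceatt)
```

# The biological problem

Site-specific integrative and conjugative elements (ICEs) such as ICEBs1
of *Bacillus subtilis* integrate into one primary chromosomal attachment
site, attB, by integrase-mediated site-specific recombination. When the
primary site is absent — or occasionally even when it is present — the
element integrates into secondary sites scattered around the chromosome.
Integration at a secondary site carries two costs. First, excision from
most secondary sites is impaired, and from sites whose crossover sequence
differs from the element's, the excised circle itself is unstable because
it carries a heteroduplex attachment site; both effects limit onward
spread. Second, when element gene expression is induced in a cell whose
element cannot excise, rolling-circle replication initiates from the
element's origin of transfer while it is still embedded in the
chromosome, which is lethal. `iceatt` packages the quantitative side of
this story: the attachment-site sequence model, the catalog and logo
statistics used to describe secondary-site usage, the qPCR chain used to
measure excision, and the population model that turns a per-generation
death fraction into a selective-pressure timescale.

# The attachment-site core model

The core is 17 bp: two 5 bp arms that form an inverted repeat in the
primary site (a stem when the site folds as a stem-loop), flanking a 7 bp
spacer — the crossover region where strand exchange occurs. `att_core()`
applies this fixed 5 + 7 + 5 partition and records whether the arms form
a perfect stem (informational only: secondary sites usually do not).
Similarity between sites is the Hamming distance over the 17 positions
(`mismatch_count()`); characterized secondary sites range from 2 to 12
mismatches from the primary core.

Because recombination happens in the spacer, only spacer differences
matter for heteroduplex formation. When the element integrates into a
target whose spacer differs from its own, replication resolves the
mispairing so that the two junctions, attL and attR, end up with
different crossover sequences; excision then recombines them into a
circle whose attachment site is a heteroduplex
(`predict_heteroduplex()`, `integrate_site()`, `excise_site()`). Which
junction inherits which spacer after resolution is not determined by the
biology we model, only that they differ; the package's default
convention (attL keeps the chromosomal spacer, attR the element's, with
an `attL_spacer` switch) is chosen so that excision reconstitutes the
chromosomal target as the empty site and the element attachment site as
the circle, making the integrate/excise round trip an identity in the
homoduplex case. Every downstream quantity depends only on spacer
*inequality*, so the convention is isolated and inert.

# Catalog statistics and the sequence logo

`tally_sites()` reduces a table of independent transconjugant insertions
to site-usage statistics. Sites are keyed by (locus, orientation): the
same locus entered in opposite orientations presents two different
17 bp target sequences and counts as two sites. Percentages are rounded
to the nearest integer with halves away from zero, the convention that
turns 11 of 27 into 41%. `secondary_site_catalog()` ships the reference
27-insertion/15-site occurrence table (the modal site `yrkM` at 41%,
`mmsA` next at 11%, a locus hit once in each orientation, and 11
singleton sites). The 17 bp core sequences of those sites are
experimental inputs that the user supplies; the catalog carries loci,
orientations, occurrence counts and published mismatch counts.

`build_logo()` summarizes an aligned, ungapped window of site contexts —
26 bases by convention: the 17 bp core plus flanking bases, with the
exact registration of the 9 extra bases left explicit to the user rather
than guessed — as per-position frequencies, Shannon entropy
$H_i = -\sum_b f_{ib}\log_2 f_{ib}$, and information content
$R_i = 2 - H_i$ bits. The small-sample correction
$e(n) = 3/(2\ln(2)\,n)$ is available behind `correction = TRUE` but off
by default: with only ~15 sequences the correction is visually material,
published logos do not always state whether it was applied, and keeping
both modes reproducible is more useful than picking one silently.
Logarithms are base 2 throughout (bits, the natural unit for a 4-letter
alphabet). Gap characters are rejected rather than scored because the
window is fixed-width and ungapped by construction.

# Genome scanning

`scan_genome()` reports every 17-mer on either strand of a genome within
a chosen Hamming distance of a reference core, in 0-based half-open
coordinates (BED convention; strand `-` means the core is read on the
reverse strand). Windows containing non-ACGT characters are skipped
silently because draft genomes contain N runs; skipping, not erroring,
is the behaviour a practitioner wants. The implementation is a
vectorized shift-and-compare over byte codes, which costs the same at
any threshold — important because the full range 0–17 is meaningful
(at 17, every clean window is a hit, which is the correct degenerate
answer, not an error). The suite verifies the scanner against a naive
window-by-window oracle and against an independent pattern-matching
library on random genomes.

# The qPCR quantification chain

Quantification starts at Cq values (no raw fluorescence processing) and
follows the standard-curve model: Cq is linear in log10 input copies,
fitted by ordinary least squares over a dilution series
(`fit_standard_curve()`), with amplification efficiency
$10^{-1/\text{slope}} - 1$. Technical replicates are combined by the
geometric mean of copies — equivalently the arithmetic mean of Cq —
because Cq noise is additive on the log scale; dispersion is reported as
a geometric standard deviation and never silently discarded
(`quantify()`). A switch in `estimate_excision()` lets replicates be
combined after normalization instead, since either ordering is
defensible and published work rarely states which was used; with
unbiased log-scale noise the two agree closely.

Three normalized quantities cover the assays:

* **Excision frequency** (`excision_frequency()`): empty attachment site
  per reference gene, normalized to an element-cured strain that
  represents 100% excision. Scale-invariant per sample; the cured strain
  self-normalizes to 1.
* **Circle:empty ratio** (`circle_to_empty_ratio()`): circle per
  reference over empty-site per reference, normalized to wild type.
  Values well below 1 are the signature of heteroduplex circle loss.
* **Integration ratio** (`integration_ratio()`): site junction per
  reference in a pooled population, normalized to a strain carrying the
  insertion in every cell.

A sample whose mean Cq exceeds the largest dilution-series Cq by more
than 2 cycles (configurable) is flagged below the limit of detection
rather than extrapolated; undetectable excision is reported as that flag
plus the bound, never as a number. A single-plate assay is assumed — no
inter-plate calibration is modeled. The companion diagnostic
`mating_excision_fold()` divides relative excision by relative mating
efficiency: near 1 when the excised circle is stable, large (e.g. 75
for 0.15 excision against 0.002 mating) when circles are lost before
transfer.

# The competition model

Cells carrying the element at a secondary site lose a fraction $D$ of
their number each generation: with spontaneous activation frequency $a$
per generation and viability $v$ of activated cells,
$D = a(1 - v)$ (`effective_death()`; the literal all-die reading,
$v = 0$, hence $D = a$, is the default). Population size follows
$P = P_0 \cdot 2^G (1-D)^G$, so the ratio of an unaffected primary-site
population to the secondary-site population is $R = (1-D)^{-G}$,
independent of $P_0$, and the horizon to a given ratio is
$G = \log(1/R)/\log(1-D)$. With $D = 10^{-4}$, reaching $R = 10$ takes
about 23,000 generations; with $D = 10^{-3}$, about 2,300. Headline
values are conventionally reported to two significant figures
(`signif(g, 2)`); the functions return raw values.

`simulate_competition()` is the individual-based counterpart: per
generation both subpopulations double, each secondary-site cell dies
independently with probability $D$ (binomial draw, applied after
doubling — the closed form is order-independent, the simulator fixes
one order and documents it), and when the total exceeds a cap the
population is down-sampled by a neutral multinomial bottleneck. The cap
exists purely to keep simulations at desk scale; the bottleneck is
unbiased in expectation, and the suite verifies the simulated mean
log-ratio tracks $G \cdot (-\log(1-D))$ within three standard errors.
Replicate $r$ seeds the generator with `seed + r`, so runs are
bit-reproducible and replicates independent.

# Synthetic data: what it emulates, what it does not

All generators are pure functions of (spec, seed).

* `make_genome()` plants mutated cores in an i.i.d. background at a
  chosen GC fraction (default 0.435, typical of the *B. subtilis*
  chromosome). Mutated positions are drawn uniformly without
  replacement, confined to the arms unless the site is flagged
  spacer-divergent (which then forces at least one spacer change), so
  heteroduplex truth labels are exact by construction. Accidental exact
  copies of the reference core are disrupted post hoc, so scan truth
  tables are exact too. The background is i.i.d., not a higher-order
  Markov model: realistic motif false-positive rates in real genomes
  are therefore *not* emulated, and passing scan tests says nothing
  about specificity in genomic sequence.
* `make_qpcr_panel()` draws Cq values through the log-linear curve with
  Gaussian noise (default $\sigma_{Cq} = 0.15$ cycles, ordinary
  technical-replicate scatter; triplicates by default, matching
  standard practice). It emulates technical noise only — no biological
  replicate variance, plate effects or amplification failures.
* `make_transconjugants()` draws a multinomial catalog over sites with
  planted probabilities. A real pooled experiment involves ~1e8
  transconjugants; the generator plants proportions exactly and
  controls sampling noise through `n_isolates`, emulating the ratio
  level, not the colony level.

# Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen to make the
statistical checks decisive while keeping a full run to a couple of
minutes: 100 random genomes of 1–3 kb for scanner/oracle equivalence
(the scanner is size-agnostic; equivalence at 3 kb across all thresholds
implies it at 100 kb), 200 synthetic panels per planted excision level,
and 50 replicate trajectories of 2,301 generations under a 1e6-cell cap
for the simulator-vs-closed-form check. Other conventions: frequencies
and entropies are plain double arithmetic with $0\log 0 = 0$ handled by
dropping zero frequencies; consensus ties break alphabetically;
percentage rounding is half-away-from-zero; scanner output is sorted by
(contig, start, strand); degenerate inputs (contig shorter than 17 bp,
`max_mismatch = 17`, a ratio target of exactly 1) return their correct
degenerate answers rather than errors, while contradictory inputs
($D = 0$ with $R > 1$) signal explicitly.

# Known limitations

The package models sequence identity and a scalar death rate — not
integrase biochemistry, DNA bending, supercoiling, nucleoid proteins or
transcription, all of which plausibly shape real site choice; it does
not predict in vivo site-usage frequencies. The competition model has no
horizontal-transfer benefit term, no population structure and no
SOS-coupled activation dynamics; it is the minimal model its two
parameters can support. The mechanism by which heteroduplex circles are
lost is unresolved biology and deliberately out of scope: the package
predicts *which* sites form heteroduplexes, and quantifies circle loss
from data, but does not model why.
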