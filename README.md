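# iceatt

Quantitative analysis of attachment-site usage by site-specific
integrative and conjugative elements (ICEs).

Site-specific ICEs such as ICEBs1 of *Bacillus subtilis* normally
integrate into a single primary attachment site (attB) in a tRNA gene,
but can integrate into secondary sites elsewhere in the chromosome.
Doing so is costly in two ways: excision from secondary sites is
impaired (and circles excised from sites with a divergent crossover
sequence carry a heteroduplex and are lost), limiting spread, and
induction of element gene expression in a cell whose element cannot
excise kills the cell via stuck rolling-circle replication. `iceatt` is
a toolkit for researchers studying these effects: it models the
attachment-site core, summarizes secondary-site catalogs and sequence
logos, implements the qPCR chain that measures excision, and evaluates
the population-level fitness cost.

## The models at its core

**Attachment-site core.** A 17 bp core partitioned 5 + 7 + 5: two arms
(an inverted repeat in the primary site) flanking the 7 bp spacer where
integrase-mediated strand exchange occurs. Site similarity is Hamming
distance over the 17 positions. Integration into a target whose spacer
differs from the element's yields attL/attR junctions with different
crossover sequences after replication; excision then produces a circle
with a heteroduplex attachment site — predicted by spacer inequality
alone, never by arm differences.

**qPCR chain.** Cq = slope · log10(copies) + intercept per target;
replicates combine as geometric means of copies; excision frequency is
(empty/reference)<sub>sample</sub> ÷ (empty/reference)<sub>cured</sub>,
with analogous wild-type-normalized circle:empty ratios and
control-normalized integration ratios, and a below-limit-of-detection
flag instead of extrapolation.

**Competition model.** A secondary-site population losing a fraction
*D* of cells per generation (activation frequency × (1 − viability))
obeys P = P₀·2^G·(1−D)^G, so the primary:secondary ratio is
R = (1−D)^(−G) and G = log(1/R)/log(1−D). A stochastic individual-based
simulator (binomial deaths, neutral bottleneck at a population cap)
converges to the closed form. Synthetic-data generators produce
genomes with planted sites, Cq panels from known copy numbers, and
multinomial transconjugant catalogs, all with exact recorded truth.

## Worked example

```r
library(iceatt)

# 27 independent insertions over 15 secondary sites
tally_sites(secondary_site_catalog())
#> 15 distinct sites over 27 independent insertions
#> modal site: yrkM (co-directional) 41%
#>
#>        locus    orientation occurrences percent
#> 1       yrkM co-directional          11      41
#> 2       mmsA co-directional           3      11
#> 3      spoVD co-directional           1       4
#> ...

# heteroduplex prediction and integration/excision bookkeeping
element <- att_core("ACCGTTTTCAATACGGT")   # synthetic element att site
target  <- att_core("ACCGTTTTGAATACGGT")   # one spacer mismatch
mismatch_count(target, element)
#> [1] 1
predict_heteroduplex(target, element)
#> [1] TRUE
excise_site(integrate_site(target, element))
#> excision products
#>   circle att: ACCGTTTTCAATACGGT (heteroduplex)
#>   empty site: ACCGTTTTGAATACGGT

# how long until primary-site carriers outnumber secondary-site carriers
# 10-fold, if 1 cell in 10,000 activates (and dies) per generation?
generations_to_ratio(10, 1e-4)
#> [1] 23024.7    # ~23,000 at two significant figures
```

The tally says that in the absence of the primary site, insertions
concentrate in the most attB-like targets (the modal site differs from
attB at only 2 of 17 positions) yet spread over many sites. The
excision example shows a single spacer mismatch sufficing for a
heteroduplex circle, and the closed-form model turns a 10⁻⁴
per-generation death rate into a ~23,000-generation selective horizon.

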