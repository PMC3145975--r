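---
title: "Combinatorial transcription factor co-occupancy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial transcription factor co-occupancy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combind)
```

# The analysis

Hematopoietic lineage decisions are driven by small sets of transcription
factors that bind regulatory DNA in combination rather than singly. Given
ChIP-seq peak calls for K factors (the motivating setting is GATA1, GATA2,
RUNX1, FLI1 and SCL/TAL1 in megakaryocytes), `combind` asks: which exact
combinations of factors co-occupy genomic regions more (or less) often than
independent binding would predict, which genes do those regions control,
and is that combinatorial code reflected in chromatin state, cell-type
specific expression, sequence motifs, and a core-circuit/effector network?

The unit of analysis is the **union region**: a maximal interval covered by
at least one peak from any factor. Each union region gets an **exact
occupancy pattern** — the subset of factors bound there, encoded as a
bitmask over the ordered factor list. With K = 5 there are
$2^5 - 1 = 31$ nonempty patterns, 26 of which involve two or more factors.
Counting is region-level: a region contributes once to its pattern no
matter how many same-factor peaks it contains, and same-factor overlapping
peaks are merged at load because the pattern logic only asks whether a
factor binds, not how often. Exact-pattern counts ("bound by precisely S")
and at-least counts ("bound by S, possibly with others") are both
first-class, because published co-binding totals are usually at-least
counts while pattern tables are exact.

Co-binding is defined as ≥ 1 bp overlap with the union region
(`min_overlap = 1`, configurable). Overlap counting without a bp threshold
is the least-assuming reading of "overlapping peaks", and the threshold is
exposed for sensitivity analysis.

# The independence null

Statistical excess is judged against a fixed universe of $N$ bindable
regions (default 80,000, a published lower-end estimate of the number of
regions available for binding; always a configuration scalar). Factor $i$
binds each universe region independently with $p_i = n_i / N$, where $n_i$
is its marginal region count — by default the region-level marginal taken
from the realized pattern table, for internal consistency with the
observed counts (raw peak counts are available as an option). For pattern
$S$:

$$p_S = \prod_{i \in S} p_i \prod_{j \notin S} (1 - p_j), \qquad
E_S = N p_S, \qquad V_S = N p_S (1 - p_S), \qquad
Z_S = \frac{O_S - E_S}{\sqrt{V_S}}.$$

The binomial variance and normal-approximation Z are a package choice —
published pattern Z-scores rarely state their distributional form — so
every report header flags the model, and `monte_carlo_null()` ships as an
independent auditing oracle: it simulates the $N \times K$ Bernoulli
indicator matrix directly and tabulates exact-pattern counts, making no
use of the closed form.

Two caveats shape how Z should be read. First, the normal approximation is
only meaningful where $E_S$ is not tiny; with sparse marginals the
high-order patterns have $E_S \ll 1$ and a single observed region produces
an enormous Z. That is exactly the regime of the headline all-five result,
where the conclusion ("far more than expected") is robust, but calibration
statements (fractions of |Z| > 1.96) are made only on landscapes whose
marginals give every multi-factor pattern $E_S$ comfortably above ~5
(`null_landscape_config()` defaults). Second, estimating marginals from
the same table that provides the observed counts slightly shrinks the null
variance; the Monte-Carlo oracle lets a user quantify both effects.

# Peak-to-gene annotation

The allocation rule: a region overlapping any promoter window (TSS
−1000/+500 bp, strand-aware; the convention is configurable since
published analyses rarely define "promoter") is a promoter region and is
allocated to the overlapped gene(s); otherwise a region overlapping a gene
body (TSS–TES, exons and introns alike — an exon-only exclusion would
strand exonic peaks) is intragenic and allocated likewise; remaining
(intergenic) regions go to the nearest gene on each side by region-edge to
TSS distance, each side only within 100 kb, ties broken toward the
alphabetically first gene id so output is deterministic. Promoter-category
regions are not additionally assigned to flanking genes. The three
location categories partition the regions, which makes the
promoter/intragenic/intergenic breakdown per factor a well-defined
statistic. Joining assignments to exact patterns yields up to 31 target
gene lists.

# Chromatin states and expression

Promoters are classified from H3K4me3 and H3K27me3 over the promoter
window: K4+/K27− active, K4+/K27+ bivalent, K4− inactive. Marks arrive as
called, scored regions (mirroring how ChIP data are distributed), so the
default presence criterion is any positive-score overlap; a quantile mode
(signal ≥ 75th percentile of positive window signals) is provided for
continuous tracks because the quantification behind published three-way
classifications is typically unstated. H3ac is accepted and reported but
does not enter the three-way rule, which is driven by the K4/K27 pair.
Bound fractions per state use the same promoter windows and ask whether
any union region overlaps them.

# Gene-set enrichment

Genes are ranked by $\log_2\!\big((x_{target} + 1) / (\overline{x}_{others} + 1)\big)$
(pseudocount 1; signal-to-noise is the classic alternative but requires
replicate profiles, and only one profile per cell type is assumed). Ties
break by gene id, so the ranking is invariant to input row order. Each
pattern list is scored with the classic weighted Kolmogorov–Smirnov
running sum (hit weight $|r|^p$, $p = 1$ by default), whose signed
extremum is the enrichment score; the statistic is checked against a
plain-loop oracle and against an independent implementation in the test
suite. Significance uses gene-set permutation — random same-size sets —
because phenotype permutation needs replicated phenotypes. NES divides ES
by the mean same-sign null ES; the FDR q pools normalized null scores
across sets as in the original scheme, then is made monotone in |NES|.
One numerical subtlety: exact ties of |running sum| at different ranks are
resolved as the first rank within $10^{-12}$ of the maximum deviation, so
extended-precision accumulation cannot flip the reported sign of ES.

# Motif scanning

De novo motif discovery is out of scope by design: the aim is testing
enrichment logic with deterministic tools, so scanning uses known IUPAC
consensus strings — GATA `WGATAR`, E-box `CANNTG`, ETS `GGAW`, RUNX
`TGYGGT` — and a composite E-box/(2–10 bp)/GATA element, the docking-site
signature of SCL/GATA complexes. Matches are counted on both strands;
overlapping matches at different offsets count separately, and a
palindromic footprint seen on both strands counts once. Composite parts
must co-occur in order on the same strand with the spacer in range.
Enrichment between a pattern-defined target set and a background set is a
two-sided Fisher exact test on sequences-with-a-match, with
Haldane-corrected fold and odds ratios for degenerate tables.

# The synthetic landscape generator

The generator is first-class, tested code that defines the study
conditions for every end-to-end check. It is a latent-site mixture chosen
as the simplest generative story that can express both excess co-binding
and exact independence:

* a universe of `n_sites` candidate sites on a jittered grid, spaced so
  peaks from neighbouring sites cannot merge (grid spacing ≥ 1 kb versus
  a maximal peak footprint of ~500 bp), each emitting factor $i$'s peak
  independently with a background probability;
* `n_complex` **complex sites** placed in the promoters of designated
  target genes, emitting every factor with probability 0.95 — the planted
  analogue of the all-five-bound regulatory regions;
* `n_pair` GATA1+SCL **pair sites** (emission 0.9 for the pair, 0.05
  otherwise), which both overrepresent GATA1/SCL combinations and give
  the composite-motif stage a target subset;
* a **suppression rule**: a site whose exact pattern would be GATA1+FLI1
  only is deleted with probability 0.8, planting the underrepresented
  pattern;
* **promoter-coupled sites**: each gene's promoter carries a bound site
  with probability 0.05 / 0.35 / 0.7 for inactive / bivalent / active
  states. The wide separation is deliberate: a 1.5 kb promoter window is
  hit by chance by background sites often enough (~0.3 baseline) that
  weakly separated coupling probabilities would not produce a reliably
  monotone observed ordering.

Background emission probabilities are tuned by closed-form accounting
(targets minus expected complex, pair and promoter contributions) so
realized marginals land within binomial error of the configured targets.
Default marginal targets are the study's per-factor peak counts at 1/10
scale (472/248/734/869/308 over a 10,000-site universe on 2 × 5 Mb),
preserving the real relative factor abundances at desk scale; 300
non-overlapping genes with ≥ 2.5 kb clearance (so neighbouring promoter
windows and TSS-centred mark footprints never overlap — a prerequisite
for noise-free state recovery to be exact); histone marks emitted from
latent states with 5% dropout and 2% spurious additions; expression
log-normal around state means (4 / 5.5 / 7 log2 units) with sd 0.8, plus
a +2 log2 bump for planted target genes in the target cell type only; and
300 bp region sequences with motif instances embedded by pattern
(composite with probability 0.8 in exact GATA1+SCL sites). All randomness
derives from one seed; outputs are byte-identical across runs.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: read-level noise and peak-calling artefacts,
GC/mappability structure, chromatin-domain clustering of peaks, distal
enhancer–gene relationships beyond the 100 kb rule, replicate variance in
expression, and motif positional preferences. The generator validates the
pipeline's logic, not the biology of any particular dataset.

# Problem sizes and numerical choices

The shipped checks run the generator at its default scale (10,000 sites,
~2,700 peaks, 300 genes) for 20-seed recovery loops; Monte-Carlo
validation of the null uses 5,000 replicates at universes of a few
hundred regions for 20 random marginal configurations, and 1,000
replicates at the study-scale marginals (N = 80,000); GSEA loops use 200
permutations (NES rankings are stable at that depth; the single-run
pipeline default is 1,000). Degenerate inputs are handled explicitly:
zero-variance patterns report an infinite-Z sentinel with a warning
rather than NaN; gene sets with no overlap with the ranked list are
skipped with a warning; empty state classes report NA fractions, not 0;
degenerate 2×2 motif tables get continuity corrections; an empty BED
yields an empty peak set with a warning.

# Known limitations

Whether published pattern counts were made per union region or per peak
is generally unstated; the region-level choice here is internally
consistent but means exact study counts need not be reproducible from
deposited peak lists. The Z-score's distributional form and the GSEA
metric/permutation mode are likewise package choices where the original
analyses leave them open; both are flagged in report headers and backed
by independent oracles. Chromosome names are matched verbatim with a
mismatch report rather than normalized. The network's core-circuit edges
are configuration, not inference: cross-regulatory connectivity among the
factors is treated as established knowledge, with self-binding detection
from the occupancy data available as an optional consistency check.
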