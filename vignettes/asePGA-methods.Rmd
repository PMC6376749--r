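---
title: "asePGA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{asePGA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`asePGA`, the thresholds they use, what the synthetic-data generator
does and does not emulate, and the design decisions taken where the
published procedure leaves room.

# Setting

An F1 hybrid of two sequenced inbred mouse strains (maternal C57BL/6J ×
paternal DBA/2J and similar crosses) carries one discriminating SNP
roughly every 520 bp.  After SNP-tolerant alignment, reads overlapping
these sites yield per-site maternal and paternal counts — the package's
universal input (`AllelicCounts`; the pipeline deliberately starts
*after* alignment and pile-up assignment, which are not in scope).
Coordinates are uniformly 0-based half-open; BED input is native, VCF
positions are converted on read; chromosome names are matched exactly
(no `"chr"` stripping).  Duplicate sites are an error rather than
last-wins, because a silent overwrite would corrupt allelic sums.

# RNA-seq genotyping

Parthenogenetic (PGA) lines derive from a metaphase-II oocyte that has
already undergone meiotic recombination: retaining the second polar
body yields a diploid genome that is homozygous proximal to the
centromere and heterozygous distal to the crossovers.  Only the
heterozygous part supports allele-specific expression, so the genotype
must be reconstructed from the RNA-seq itself.

**Binning.** Counts are summed in 5 MB (overview) or 1 MB (breakpoint)
bins and expressed as the maternal percentage
$100\,c_\mathrm{mat}/(c_\mathrm{mat}+c_\mathrm{pat})$.  Bins are
half-open, so a site at exactly a boundary belongs to the following
bin; every bin of every declared chromosome is materialized so that
coverage gaps are visible.

**Coverage gates and smoothing.** At 5 MB, bins with ≤ 40 summed
counts are `INSUFFICIENT`; qualifying bins are smoothed with a moving
average over four bins.  At 1 MB, bins are included when they exceed
10 (RNA) or 15 (DNA) counts, and no smoothing is applied — the
published description mentions the moving average only for the 5 MB
overview, and smoothing at 1 MB would blur exactly the breakpoint
sharpness the finer resolution exists for.  The moving-average
*alignment* is unspecified in the source procedure; we use a trailing
window of up to four *qualifying* bins ending at the current bin,
truncated at the chromosome start.  A trailing window is deterministic,
needs no look-ahead and is edge-safe; skipping (rather than resetting
on) non-qualifying bins prevents gene deserts from fragmenting the
series.

**Classification.** Class boundaries on the (smoothed) maternal
percentage are 31 / 78.5 at 5 MB and 15 / 85 at 1 MB, lower-inclusive:
$[0, \mathrm{low})$ paternal-homozygous, $[\mathrm{low},
\mathrm{high})$ heterozygous, $[\mathrm{high}, 100]$
maternal-homozygous.  Lower-inclusiveness is a tie-break convention
(a value exactly at a boundary goes to the higher class); it is the
one numerical choice at these boundaries and is asserted by tests.
The 15/85 pair is symmetric under an allele swap (up to exact boundary
ties), the 31/78.5 pair deliberately is not — the test suite documents
both facts.

**Proximal genotype.** The centromere-proximal genotype of a
chromosome is assigned from the classified (non-`INSUFFICIENT`) bins,
first match wins: (1) ≥ 80 % of the first 5 bins share one homozygous
label; (2) ≥ 60 % of the first 10; (3) more than 5 consecutive
heterozygous bins.  Fewer than 5 classified bins leave the chromosome
`UNASSIGNED`, and everything on it is conservatively excluded
downstream.

**Breakpoints.** Scanning distally, a crossover breakpoint opens where
more than 5 consecutive classified bins lack the current segment label
— or, at the very proximal end only, where at least 4 consecutive bins
share one *other* genotype, which catches crossovers too close to the
centromere for the longer run to form.  The new segment's label is
re-derived by the same proximal rules applied from the breakpoint
onward; if they are indecisive, the ≥ 4-consecutive-bins rule decides,
and if that also fails the candidate breakpoint is dropped
(conservative: no segment without a defensible label).  The breakpoint
coordinate is the start of the first bin of the new segment.  When a
non-matching run begins with `INSUFFICIENT` bins, the breakpoint is
placed at the first *classified* non-matching bin — insufficient bins
carry no evidence of their own.  Finally, breakpoints around segments
of ≤ 15 MB whose two flanks share a label are discarded in a single
left-to-right pass; merged segments are not re-examined iteratively
(the simplest reading, and idempotent in all configurations we
generate).

**Accuracy scoring.** Called and reference breakpoints are paired 1:1
per chromosome by greedy nearest distance; a pair is *exact* when both
positions fall in the same 1 MB bin, and the mean absolute error is
taken over matched pairs.  Unmatched breakpoints are reported via the
true/called totals but do not enter either statistic — the published
accuracy numbers compare breakpoints present in both methods, and a
surrogate against simulation truth should measure the same quantity.
Two structural limits of the published rules are worth knowing: a
crossover closer than ~4 MB to the centromeric end defeats all three
proximal rules (the chromosome comes out `UNASSIGNED`), and one closer
than ~5 MB to the distal end cannot form the required
6-bin run.  Scoring over matched pairs keeps these
undetectable-by-construction cases from masquerading as localization
error.  A second limit concerns exactness: the 15/85 boundaries hand
the crossover-containing mixed bin to the heterozygous class for
mixture fractions up to ~70 %, so transitions *into* homozygosity tend
to be placed one bin distal.  Exact-bin recovery against truth
therefore plateaus near ~55 % at study-like coverage even though the
mean error stays far below 1 MB.

**Aneuploidy screen.** Chromosomes called heterozygous whose pooled
maternal percentage over heterozygous bins leaves the 40–60 % band are
flagged: a 2:1 allelic ratio (~67 %) is the signature of a trisomy
with two copies from one parent, which bin classification alone would
file under "heterozygous".

# Gene-level allelic calls

Counts are summed over the SNPs inside a gene's exon blocks (BED12
models; a SNP at an exon end coordinate is outside by half-openness;
genes without exonic SNPs are kept but flagged uninformative, and
overlapping genes double-count shared sites with a flag rather than
arbitrating between them).  A gene is called when its total exceeds
9 counts and, with at least two qualifying sites, the standard error
of the mean of per-site maternal fractions is at most 0.15
(sample standard deviation over $\sqrt{n}$; bypassed for single-site
genes).  A site qualifies for this consistency statistic when at least
one allele reaches 3 reads — we read "coverage ≥ 3 from either allele"
as `max(mat, pat) >= 3`, the literal "either", with a `sum` variant
behind a config switch; the site gate applies only to the consistency
statistic, not to the gene sums (also switchable).  Allelic bias is a
maternal ratio strictly above 0.80 (maternal-biased) or strictly below
0.20 (paternal-biased); exactly 0.80 falls to the biallelic side.
In PGA samples, calls are restricted to genes whose transcript span
lies entirely inside a heterozygous segment — a gene straddling a
segment boundary mixes informative and uninformative sites and is
conservatively excluded.  Cohort-level analysis additionally requires
every cell-line sample to exceed 40 and every embryonic sample 200
total counts for the gene.  The same summation applies to arbitrary
intervals (`aggregateIntervals`), which covers allelic quantification
of, for example, ChIP enrichment peaks without any peak calling here.

# Expression proxy, fold changes, imprinting, XCI

Expression is proxied as counts-per-kilobase-per-billion over the
SNP-overlapping counts only:
$10^9 \cdot \mathrm{total}_g / (\mathrm{grand\ total} \cdot
\mathrm{exonic\ length})$.  It is monotone in abundance at fixed SNP
density but not comparable in absolute value to alignment-based RPKM;
all conclusions drawn from it here are ratio-based.  Fold changes
between fertilized and PGA groups use a pseudocount of 1 expression
unit (guarding fully silenced genes) and geometric class means.  In a
parthenogenote both alleles carry the maternal epigenotype, so
paternally expressed genes collapse to residual leak expression while
maternally expressed genes double — the generative model and the
analysis agree on this expectation, and the cohort tests verify folds
of ≈ 2 and ≤ 1/4 at depth 200.

Imprinting status per catalogued gene and sample reuses the 80 % rule:
a paternally expressed gene with maternal ratio < 0.20 is a consistent
imprint, > 0.80 is reversed, in between biallelic (loss of
imprinting); maternally expressed genes mirror this.  The raw ratio is
attached so that strong-but-incomplete bias (80–100 %) remains
distinguishable from complete monoallelic expression in downstream
presentation.

XCI skew is called from Xist and X-linked ratios of XX samples.
X-linked genes enter when they pass the gene filters and, if a
balanced reference line is designated, show < 4-fold allelic bias
there (generalizing the published reference-line filter).  A passing
Xist call is required.  `FULLY_SKEWED_*` needs Xist > 0.80 toward one
allele and the median included X-gene ratio > 0.80 toward the other
(Xist marks the inactive X, so the two are reciprocal); `BALANCED`
needs both within 0.35–0.65.  The band is our stated decision — wide
enough to absorb sampling noise at realistic depth, far from the 0.80
bias rule it coexists with.  The report carries median X-linked and
autosomal expression for the dosage-compensation comparison; the test
suite checks dosage as a paired EpiSC-versus-ESC contrast on shared
genes, because within-sample medians are biased by zero-truncation of
low-abundance genes.

# The synthetic generator

The generator emulates the statistical structure the analysis assumes:

* SNP maps with Poisson site counts (default density 1/520 bp,
  routinely scaled down) and uniform positions.
* PGA genotypes: per chromosome 0–3 crossovers (uniform count, uniform
  positions with ≥ 20 MB gaps, strictly inside the chromosome),
  homozygous proximal state with the haplotype of each homozygous run
  drawn at random, states alternating at each crossover.  The
  crossover-count range is a modeling choice exposed in
  `crossoverModel()`; the source material reports no distribution for
  B6D2F1 oocytes.
* Gene universes: non-overlapping multi-exon genes, log-normal
  abundances, imprint classes (10 % maternally expressed, 10 %
  paternally expressed, 5 % biased at 0.85, rest biallelic by
  default), X-linked genes flagged with one Xist-like gene pinned to
  high abundance (as the real transcript is).
* Samples: per-gene Poisson totals at `depth` expected reads for an
  average-abundance gene, beta-binomial maternal counts
  (overdispersion ρ = 0.01 by default, emulating the wider allelic
  spread of amplified low-input libraries), reads spread multinomially
  over exonic sites.  Cell states modulate the expectations: PGA
  scales abundance by twice the maternal share of the class and sets
  the allelic fraction purely by haplotype (0.5 heterozygous, 0/1
  homozygous — no reads ever come from an absent haplotype); ESC loss
  of imprinting is a per-gene Bernoulli collapse to 0.5 (gene-wise
  heterogeneity, not a global switch); NT equals fertilized plus an
  optional force-silenced gene list; XX EpiSC X-linked fractions
  follow the XCI skew with Xist anti-correlated; X0 halves a single-
  haplotype X; trisomy applies parental dose ratios.  A gene
  straddling a simulated crossover takes the genotype state at its
  midpoint.
* Genotyping-grade coverage (`simulateAllelicCoverage`) is generated
  separately, per bin (~Poisson(50) counts per informative 1 MB bin by
  default) with the beta deviate shared within a heterozygous bin, so
  that bin-level overdispersion — the quantity the classifier actually
  sees — is controlled directly.

What it does **not** emulate: read-level errors and mapping bias
(handled upstream by SNP-tolerant alignment in real data), clustered
gene/SNP density (RNA coverage in the simulator is either uniform per
bin or gene-driven, real transcriptomes are burstier, which is exactly
why the published method "lacks resolution in gene deserts"), isoform
structure, and library-specific amplification artifacts beyond the
single overdispersion parameter.  Passing tests therefore demonstrate
the correctness of the rules and estimators under the stated model,
not performance on any particular sequencing run.

# Problem sizes and numerical choices

Tests run on scaled-down genomes (a few chromosomes of 30–100 MB, SNP
density 1/520 to 1/10 kb, 200–300 genes, depth 100–2000) chosen so the
full suite exercises every stage in well under a coffee break; the
breakpoint benchmark uses 200 replicate chromosomes of 100 MB at ~50
counts per 1 MB bin, the cohort benchmark 2 + 2 samples × 300 genes at
depth 200.  Degenerate inputs are defined, not accidental: empty
chromosomes yield all-zero (insufficient) bins; empty SNP maps warn;
chromosomes with fewer than five classified bins are `UNASSIGNED`;
zero-coverage genes are `LOW_COVERAGE`/uninformative; empty intervals
have undefined (`NA`) ratios; breakpoint scoring with no matched pairs
reports `NA` rather than dividing by zero.  All randomness flows from
explicit integer seeds, with one master seed fanned out to per-stage
children (`childSeeds`) so every stage is independently reproducible.

# Known limitations

* The segmentation implements the published rules literally; it is not
  an HMM or changepoint method, and inherits the rules' blind spots
  (very proximal and very distal crossovers, gene deserts).
* Exact-bin breakpoint localization against truth saturates near ~55 %
  under the heterozygous-favoring 15/85 boundaries (see above); the
  mean error remains well under 1 MB at study-like coverage.
* The expression proxy ignores reads not overlapping SNPs; absolute
  values are not RPKM.
* Differential-expression significance testing is intentionally out of
  scope (standard tools exist); the package reports fold changes and
  class summaries.
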