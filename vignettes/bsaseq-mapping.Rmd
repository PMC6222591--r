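---
title: "Pooled-segregant mapping with bsamap: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-segregant mapping with bsamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

## The genetic model

A recessive mutant recovered from an EMS screen is crossed to a
polymorphic mapping background (outcross BSA) or to its own unmutagenized
parent (MutMap), the F1 selfed, and phenotypically mutant F2 individuals
pooled and shotgun-sequenced as one library. Every mutant is homozygous
for the mutagenized haplotype at the causal locus; at a marker at map
distance $d$ Morgans, a gamete that carries the causal allele also carries
the linked marker allele unless an odd number of crossovers fell between
them. Under no interference (crossovers Poisson in genetic distance) that
probability is Haldane's map function

$$r(d) = \tfrac{1}{2}\left(1 - e^{-2d}\right),$$

so the expected pooled frequency of the mutant-parent allele is $1 - r(d)$:
1 at the lesion, decaying to 0.5 for unlinked markers. The mapping signal
is the excess of *homozygous* variant calls — pooled frequency at least
0.99 — around the lesion, counted in fixed 1 Mbp bins.

## Pooled frequencies and filters

The pooled frequency at a pileup position is the number of reads that
differ from the reference divided by the quality-adjusted read total,
where only bases with Phred quality ≥ 20 count. Positions with
quality-adjusted depth below 8 are discarded (sequencing/mapping
artifacts), and for interval mapping positions with coverage above 100 are
discarded too, since heavily enriched pileups sit in repeats and carry no
linkage information. All thresholds live in one place
(`filter_config()`), with these defaults:

| parameter | default | meaning |
|---|---|---|
| `min_base_quality` | 20 | Phred floor for a base to count |
| `min_depth` | 8 | minimum quality-adjusted depth (≥ 8 kept) |
| `max_depth_for_mapping` | 100 | coverage cap, mapping only (> 100 dropped) |
| `hom_threshold` | 0.99 | pooled frequency classed homozygous (≥) |
| `ems_only` | off | restrict candidates to G→A / C→T SNVs |

The EMS test is applied on the reference plus strand only: {G→A, C→T}
jointly cover both strands of a G:C→A:T lesion, so no strand flipping by
gene orientation is performed. Ties for the most frequent non-reference
base are broken in the fixed order A < C < G < T for determinism. In the
pileup tokenizer, deletion placeholders (`*`) and `N` bases consume a
quality character but are excluded from both the numerator and the
denominator of the frequency — they carry no usable base call. Positions
where no passing base differs from the reference are dropped as
non-variant. Heterozygous-but-variant positions are retained in
mapping-purpose output, flagged by their `zygosity` column; only the
binning predicate restricts to homozygous calls.

## Background subtraction

Variant keys are (chrom, pos, ref, alt). Panels — HapMap-style site
lists, an inbred-background panel built by intersecting independent
datasets that share the background, or the homozygous calls of
wild-type-sibling and unmutagenized-parent pools — are subtracted from the
mutant pool's set. The default key mode is allele-wise: an induced lesion
at a position that is polymorphic in a panel for a *different* allele must
not be discarded. Position-wise subtraction is available for conservative
filtering. Subtracting the *homozygous* calls (rather than all calls) of
sibling/parent pools is deliberate: lesions linked to the causal locus
segregate at pooled frequencies near 1/3–1/2 in a wild-type-sibling pool
and would be wrongly removed by an any-call subtraction, whereas fixed
stock-vs-reference differences are homozygous in every pool and are what
the subtraction is meant to remove.

## Interval calling

The published practice is to call the interval limits where the
per-bin homozygous-variant count "returns to background". `call_interval()`
formalizes this: the background level is the genome-wide median bin count;
an interval is a maximal run of contiguous bins all above it; a run is
reported only when its peak count exceeds
`background + k_mad × MAD` (MAD scaled by 1.4826 for consistency with the
median; default `k_mad = 5`). Because counts are small integers and most
bins are empty, the MAD is floored at one count — otherwise an
all-but-empty genome would make the threshold collapse onto the median and
report noise. The run containing the genome-wide maximum is the primary
interval; other qualifying runs are reported with their widths and flagged
secondary rather than suppressed, because peak *shape* is diagnostic:
telomeric artifact peaks from reference-stock differences are narrow with
sharp edges, while a true segregating locus has broad shoulders built from
the staggered recombination breakpoints of the pooled genomes. Bin edges
are fixed multiples of `bin_size` from coordinate 1 (no sliding windows),
and a variant at position $p$ falls in bin $\lfloor (p-1)/\text{bin\_size}
\rfloor$.

## Consequence calling and triage

Candidate SNVs inside the interval are classified against GFF3 gene
models: coding changes are computed by substituting the alternate base
into the spliced CDS (reverse-complemented for minus-strand models) and
translating both codons with the standard genetic code; the first and last
2 intronic bases of each intron are splice donor/acceptor sites. Severity
follows the usual triage — nonsense and splice-site disruption HIGH,
missense MODERATE, synonymous LOW, intergenic/intronic NONE. Start-loss
and stop-loss are also HIGH, an extension beyond the nonsense/splice/
missense tiers the analysis strictly needs. Non-coding exonic (UTR)
positions get a `utr` class with severity NONE. All overlapping
transcripts are annotated; no canonical-transcript policy is imported.
Indels are not consequence-called — they feed marker design instead.

## Indel markers

Fine mapping genotypes individual recombinants at PCR markers whose
product sizes differ between haplotypes. Markers are indels with length
difference ≥ 15 bp (resolvable on 3.5% agarose once products are short),
homozygous in the mutant pool, inside the interval. Primer windows are
placed on each flank with the 3′ end 100–150 bp from the indel footprint.
The flank distance is the biologically given constraint; primer length
18–24 nt, GC fraction 0.40–0.60 and no homopolymer run over 4 are standard
PCR defaults added to make the output usable, and all are configurable.
GC fraction is a deliberate stand-in for a nearest-neighbour melting
temperature model — adequate for gel-resolved length markers. The
expected wild-type/mutant product size difference always equals the indel
length.

## Segregation tests

`segregation_chi_square()` is the plain goodness-of-fit statistic
$\sum_i (O_i - E_i)^2 / E_i$ with $df = k - 1$ and **no continuity
correction**: for 12 mutant among 26 F1 against 1:1, the uncorrected test
gives $P = 0.69$, while Yates' correction would give $P \approx 0.84$; the
uncorrected statistic is the standard choice for multi-class segregation
ratios and matches published practice. On totals of a dozen plants the
chi-squared tail can differ from the exact multinomial tail by up to
about 0.25 — the tests bound that gap as a sanity check, and users with
tiny counts should prefer an exact test.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the synthetic study conditions: two
100 Mbp chromosomes of 1 Morgan each (a deliberately scaled-down
high-recombination genome; the second chromosome is the unlinked control),
causal lesion at 50 Mbp on chr1, 50 pooled mutants, 25× mean coverage,
1,000 EMS SNPs (≈ 5/Mbp, the order implied by the hundreds of induced
SNPs a real mapping interval of tens of Mbp contains), 98% canonical
G:C→A:T changes, 0.5% base error, and 98% of bases at Phred ≥ 20. In
outcross mode 20,000 natural stock-vs-reference SNPs segregate on the
mutant-parent haplotype (≈ 100/Mbp — scaled down from real inbred-pair
densities along with the genome). In mutmap mode the same background is
modelled as *fixed* differences homozygous in every pool, plus 500
residual-heterozygosity SNPs emulating an incompletely inbred parental
stock; wild-type-sibling and parent pools are emitted so the subtraction
path is exercised end to end. The end-to-end runner bins all homozygous
variants in outcross mode (natural background SNPs carry linkage
information there) but restricts to the EMS spectrum in mutmap mode: in a
backcross only induced SNPs segregate, and the handful of fixed background
sites that leak past finite-depth panel subtraction (roughly 1% at 25×)
would otherwise set the noise floor. Even so, mutmap recovery at the
default 5 induced SNPs per Mbp sits near the calling threshold of ~5
homozygous EMS counts per bin, so recovery is partial rather than
near-certain — a faithful reflection of how mutmap power scales with
mutation density and panel depth, not a defect of the caller.

Meiosis draws crossover counts Poisson in genetic length with uniform
breakpoints — no interference. Interference would shorten the tails of
the breakpoint distribution but does not change the form of the tested
invariants (the $1 - r(d)$ frequency law under Haldane's model is exact
for this process). Read sampling is site-independent binomial over the
$2n$ pooled chromosomes with Poisson depth; there is no read-level
simulation, so mapping bias, PCR duplicates, indel realignment artifacts
and repeat mismapping are *not* emulated — the coverage cap and depth
floor exist precisely because real data contain those artifacts, and
passing simulated tests shows the statistical machinery is right, not that
real-data artifact rates are harmless. Identical configuration and seed
give identical output; the read-sampling seed is derived from the
population seed so pools can be resampled reproducibly.

A property worth knowing when interpreting widths: the *expected* pooled
frequency profile $1 - r(d)$ does not depend on pool size, and at 25×
coverage a site samples as homozygous with probability ≈ $f^{25}$, so the
called interval width is driven by read-sampling saturation and is nearly
independent of $n$ — pool size mainly changes the width's variance (small
pools give erratic intervals). Pool-size effects on expected width emerge
only at high coverage, where frequency estimates track the realized pooled
frequency and the exact-homozygosity plateau scales as $1/n$. This is why
deep sequencing matters more than a large pool for interval quality.

## Problem sizes used in the test suite

The shipped tests run the full default conditions for interval recovery
(20 seeded replicates at $n = 50$, plus paired $n = 9$ / $n = 101$
width comparisons), a 200-mutant population for the frequency-law
calibration at $d \in \{0, 0.05, 0.1, 0.25\}$ and an unlinked marker, and
smaller two-chromosome configurations (50 Mbp, a few hundred variants)
for I/O round-trips and determinism checks; the random-pileup oracle
comparison uses 1,000 generated lines. These sizes make the whole suite
run in about a minute and a half on one core while keeping every binomial
tolerance (2–3 SE) meaningful.

## Known limitations

- The consequence caller implements exactly the classes the triage needs;
  UTR subclasses, splice-region (beyond 2 bp), and regulatory effects are
  out of scope.
- Multi-nucleotide substitutions are treated as independent SNVs by the
  caller and as length-difference markers by the indel path.
- The interval caller assumes one causal locus; two linked loci merge into
  one run.
- Varscan-style `FREQ` percentages are honoured only when allele depths
  are absent; when both are present allele depths win.
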