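---
title: "Detecting condition-specific RNA editing in a haploid genome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting condition-specific RNA editing in a haploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editome)
```

## The problem

In a haploid organism, heterozygosity cannot explain a genomic position
where RNA-seq reads carry a mixture of the reference base and one (or
more) alternative bases at intermediate frequency.  After artefacts are
excluded, such positions indicate RNA editing.  `editome` implements the
full analysis chain for this setting: significance calling from per-site
base counts, an artefact-filter cascade, spatial statistics of edits
within genes, per-gene tests of condition-specific differential editing,
variant-effect classification, and sequence-context preparation for
motif discovery — plus a synthetic-data generator so that every stage is
testable without any external download.

## The error model and calling rule

At a site with total coverage $n$, the number of reads miscalled by the
sequencer is modelled as $K \sim \mathrm{Binomial}(n, p)$ with
$p = 0.01$, the error rate of a Phred score of 20.  This is deliberately
the *maximum* plausible error rate rather than the platform average:
using it trades sensitivity for specificity.  The p-value of a site with
$k$ non-reference reads is the upper tail $P(K \ge k)$
(`edit_pvalue()`), computed over all candidate sites (positions with at
least one non-reference read), corrected by Benjamini–Hochberg
(`bh_adjust()`), and called significant at corrected $p < 0.01$.

Design choices the calling model leaves open, and how they are resolved:

* **Multiple-testing family.** Candidates only (the least
  anti-conservative defensible family); configurable to all covered
  positions via `edit_call_config(family = "covered")`.
* **Multi-allelic sites.** The test statistic aggregates *all*
  non-reference reads (the error model concerns any miscall); allele
  assignment happens afterwards.  A site is reported as edited to
  multiple bases when at least two alternative alleles have $\ge 2$
  supporting reads each and the overall non-reference frequency is
  $\ge 20\%$; otherwise only the majority allele is reported and
  minority reads stay in $n$ but not in $k$, keeping the edit frequency
  $f = k/n$ interpretable.
* **Determinism.** Sites are processed in (contig, position) order so
  q-values are bit-reproducible.

## The filter cascade

Five pure predicates, each recorded as an independent flag
(`apply_filters()` reports an audit of survivors after each stage in a
fixed order; because the filters are pure, the surviving set is
independent of that order):

1. **Frequency**: keep $0.05 \le f \le 0.95$, bounds inclusive (the
   removal rule is "below 5%" / "above 95%").  The upper bound guards
   against mis-sequenced reference bases.
2. **Uniqueness**: a 201-bp window centred on the site must not match
   another locus.  The fidelity mode ingests BLASTN `-outfmt 6` hits
   (e-value $\le 10^{-5}$ fails, self-hit excluded).  An internal mode
   exists so tests run without an aligner: exact 16-mer seeds (both
   strands) are extended ungapped with match $+2$ / mismatch $-3$ and
   scored with a Karlin–Altschul e-value, $E = KmN e^{-\lambda S}$, with
   $\lambda$ solved numerically for uniform base composition
   ($\lambda \approx 0.62$) and the conventional ungapped $K = 0.41$.
   For the decisions this filter takes (verbatim repeats vs no shared
   seed), the approximation in $K$ is immaterial.
3. **Strand bias**: fail when strictly more than 85% of the
   edit-supporting reads map to one strand.  The count is over
   edit-supporting reads, not all covering reads — the artefact being
   targeted is spliced reads entering introns unidirectionally — and an
   all-reads mode is available (`bias_scope = "all"`).  Unstranded count
   tables make the filter "not evaluable": the flag is `NA` and the site
   passes through.
4. **Intron edges**: fail within 9 bp (inclusive) of either end of any
   annotated intron, where intron ends resemble the adjacent exon ends
   and spliced reads mis-map.
5. **DNA concordance**: with a DNA-seq count table, keep only sites
   whose DNA reads are 100% reference (coverage $\ge 1$).  In
   `"flagged"` mode, zero-coverage sites pass with a flag.

### A note on strict DNA concordance

Under the package's own error model, strict DNA concordance is
statistically brutal: at DNA coverage $c$ and error rate $e$, a site is
clean with probability $(1-e)^c$ — about 0.5 at $c = 69$, $e = 0.01$.
Any pipeline that applies the strict rule to raw counts therefore caps
sensitivity near that number regardless of the RNA evidence.  The
end-to-end recovery test consequently runs the cascade without the
(optional) DNA table; when you have real DNA-seq data, prefer
base-quality-filtered counts, and treat the strict mode as the
deliberately conservative option it is.

## Spatial statistics

`relative_positions()` places each genic edit at
$(\text{offset})/(\text{length}-1)$ along its gene, exon or intron in
transcript sense and bins at width 0.025; `five_prime_enrichment_test()`
is the one-sided binomial test of the count in the initial 5% of the
gene against a uniform null.

`clustering_test()` asks whether edits sit closer to their neighbours
than chance allows.  Each edit in a gene with $\ge 2$ edits contributes
the mean distance to its flanking neighbours (terminal edits contribute
their single flanking distance).  The null is Monte-Carlo: each gene's
edits are re-placed uniformly without replacement over the gene's
positions (10,000 shuffles by default; per-gene counts conserved by
construction), and the expected histogram is the mean over shuffles.
Observed and expected counts are compared with a $\chi^2$ statistic over
unit-distance bins up to the 99th percentile of the pooled distances
(remainder pooled, adjacent bins merged until every expected count is
$\ge 5$), with $df = \text{bins} - 1$.  Shuffle placements cover the
whole gene, not only exons (an exon-restricted option would be a
straightforward extension); distances are genomic base differences.

**Known limitation (measured, not hidden).**  The $\chi^2$ reference
distribution assumes independent multinomial counts, but neighbour
distances within a gene are positively correlated — a two-edit gene
contributes two *identical* distances, and interior edits share flanking
gaps.  The bin counts are therefore over-dispersed and the test is
anticonservative: on uniform null placements its measured rejection rate
at $\alpha = 0.05$ is roughly 0.11 rather than 0.05.  The corresponding
acceptance test asserts the nominal band and is expected to stay red;
treat the clustering p-value as a descriptive index (extreme clustering
still yields astronomically small values), not a calibrated tail
probability.

## Differential editing

For each stressor-vs-control contrast, genes are testable when they
have $\ge 2$ edited positions covered in *every* replicate of both
conditions.  Per gene, the package fits the binomial GLM

```
cbind(edited, unedited) ~ condition * position    (logit link)
```

on replicate × position cells — replicates enter as individual rows,
never pooled, so each replicate carries equal weight — and tests the
condition main effect and condition × position interaction jointly by
analysis of deviance against the position-only model
($\chi^2$, $df$ = difference in parameter count).  Fitting uses IRLS
with a 25-iteration cap and $10^{-8}$ deviance tolerance
(`glm.control`); non-convergence yields `NA` and the gene leaves the BH
family for that contrast.  P-values are BH-corrected across all genes
tested per contrast; corrected $p < 0.05$ is called differentially
edited.  Dispersion is fixed at 1 (binomial family); editing counts can
be overdispersed in real data, and a quasi-binomial variant would be the
natural extension, but the binomial family is the stated model.
Measured calibration on null simulations (coverage 50, 4+4 replicates,
2 positions): type-I error within Monte-Carlo error of nominal; power
for a 0.2→0.8 shift at coverage 50 is essentially 1.

## Effect annotation

Each genic edit (one annotation per alternative allele) is classified
against its gene model with the standard genetic code: intron; 5'/3'
UTR (exonic positions outside the CDS, sided in transcript sense — also
used when UTRs are not annotated explicitly, matching common annotator
behaviour); synonymous / non-synonymous coding from the mutated codon;
stop-codon gain/loss takes precedence over (non-)synonymous; start
gain/loss refers to the *annotated* start codon only, not upstream
ATGs.  Genes whose CDS length is not a multiple of 3 are excluded from
effect annotation only.  The subset-vs-background contingency analysis
runs a two-sided Fisher's exact test per class (subset = edits in
differentially edited genes; the background includes the subset,
following the printed-table convention) with BH across the nine classes.
Delta shifts (|mean stress − mean control| of per-site edit frequency)
are compared between non-synonymous and synonymous coding edits with a
Welch two-tailed t-test; if both groups are constant the p-value is 1
(equal means) or 0 by convention rather than NaN.

## The synthetic world

`generate_reference()` plants multi-exon genes on both strands with
valid CDS (ATG…stop, length divisible by 3, no internal in-frame
stops), UTRs, introns of 60–200 bp and intergenic gaps; a planted
tandem duplication is available for uniqueness-filter fixtures.
`generate_editome()` places true edits avoiding homopolymer runs and
intron edges (so planted truth survives the artefact filters), with per
condition frequencies: uniform in $[0.1, 0.9]$ by default — inside the
5–95% retained band and bounded away from the detection floor — and a
configurable subset of differential genes at 0.2 (control) vs 0.8
(stress), the effect size used in the power analyses.
`simulate_counts()` draws coverage from a negative binomial with mean
69 (the reported median coverage of called sites; dispersion size 10, a
typical RNA-seq value) and applies the full read-level model: edited
reads Binomial(n, f), uniform miscalls at rate 0.01 on every read,
per-read strand allocation at probability 0.5.  The default design is 4
conditions (control, cold, heat, dark) × 4 replicates.

What the generator does *not* emulate: alignment artefacts (multi-exon
read mis-mapping, soft-clipping), PCR duplicates beyond exact-position
copies, non-uniform error profiles along reads, reference mis-assembly,
and overdispersed editing across replicates.  A green end-to-end test
therefore establishes the statistical machinery (calling, FDR control,
filter logic, GLM behaviour) — not robustness to every artefact the
filters exist for; those are exercised by targeted fixtures instead.
`simulate_sam()` additionally emits reads whose independently tallied
count table serves as the pileup module's round-trip oracle.

All randomness flows from one master seed through per-stage derived
streams (`derive_seed()`), keeping every output byte-reproducible and
all derived seeds within 32-bit integer range.

## Numerical and convention choices

* Coordinates are 1-based inclusive end to end (the GFF3 / R /
  Biostrings convention), so file I/O never shifts coordinates; all
  boundary rules (inclusive frequency bounds, inclusive 9-bp intron
  margins, strict > 85% strand bias) are tested at their exact edges.
* Binomial tails use `pbinom(k-1, n, p, lower.tail = FALSE)`, exact and
  stable; verified against direct pmf summation at 1e-12 relative
  tolerance across n ≤ 500.
* BH is implemented directly (order-preserving step-up, capped at 1)
  and cross-checked against `stats::p.adjust`; the implementation
  additionally supports a family size larger than the p-value vector.
* Ties in majority-allele selection break alphabetically; gene
  assignment of sites inside overlapping genes picks the smallest span,
  then the lexicographically first gene id (the source study does not
  specify either case).
* Genes are reported in transcript sense; re-complementing a
  Crick-strand edit returns the genomic bases (tested as an involution).

## Limitations

Beyond the clustering-test calibration discussed above: no
splice-isoform awareness (one model per gene); no beta-binomial
overdispersion in the differential test; the internal uniqueness search
is ungapped (a gapped repeat diverged by indels may be missed — use the
BLAST mode for real genomes); and headline discovery counts from the
original deep-sequencing study are not reproducible at desk scale, which
is why the acceptance suite targets the recomputable printed statistics
and property-based checks instead.
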