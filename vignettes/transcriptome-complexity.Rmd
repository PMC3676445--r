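---
title: "Transcriptome complexity from two-condition spliced RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome complexity from two-condition spliced RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovtx)
```

# Scope

`bovtx` re-implements, as a tested and reusable pipeline, the
transcriptome-complexity analyses commonly run on a pair of deeply sequenced
bulk RNA-seq libraries — here styled after an embryonic day-135 ("emb135")
versus 30-month adult ("adult30m") bovine longissimus muscle comparison with
one pooled library per condition and no replicates. The pipeline starts at
spliced read alignments (SAM); alignment itself is out of scope, as are
isoform assembly, coding-potential assessment, GO DAG topology, and
quality-score recalibration.

All internal coordinates are 0-based half-open. GTF (1-based closed) and VCF
(1-based) conventions exist only inside the readers and writers, so interval
arithmetic never carries an off-by-one.

# The statistical core

## Audic–Claverie exact count test

For one gene with counts $x$ and $y$ in libraries of sizes $N_1$ and $N_2$,
the model treats counts as Poisson samples and evaluates the conditional
probability of the second count given the first,

$$ p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
   \frac{(x+y)!}{x!\,y!\,\bigl(1+\frac{N_2}{N_1}\bigr)^{x+y+1}} , $$

which is the negative-binomial mass with size $x+1$ and success probability
$N_1/(N_1+N_2)$. `audic_claverie_p()` doubles the smaller of the two tails
and caps at 1. Sums are accumulated in log space; the upper tail is summed
directly past the conditional mode with a relative cut-off of $10^{-18}$, so
the p-value never underflows to zero and agrees with the closed form to
better than $10^{-10}$ relative error (tested on a 50-case grid against the
negative-binomial tails computed independently).

Because the test conditions on $x$, it is *not* exactly symmetric in the two
libraries: swapping them transforms the conditional pmf by a constant but not
its tail sums. Log2 ratios, however, negate exactly and every up/down call
swaps; the test suite asserts exactly that, not p-value equality.

The doubled two-sided exact test is mildly conservative by discreteness: its
attained size under a Poisson(100) null is 0.0460 at $\alpha = 0.05$ and
0.0090 at $\alpha = 0.01$ (computed exactly by weighting the rejection region
with Poisson masses through the package's own p-value function). The
calibration test therefore checks two things separately — that the attained
size lies within three binomial standard deviations of nominal at the
20,000-draw simulation size, and that the 20-seed simulation estimate lies
within three standard deviations of that attained size — rather than letting
the verdict ride on Monte-Carlo luck of a single simulation.

## Differential-expression calls

`call_de()` computes p-values on *raw counts* with the two library sizes (the
model's own normalisation), never on RPKM. Multiple testing is controlled by
Benjamini–Hochberg step-up q-values (`stats::p.adjust`). The reported fold
change is the log2 ratio of library-size-normalised counts (both scaled to
the mean library size) with a pseudocount of 1 added only for the ratio, so
zero counts give finite ratios without perturbing the exact test. Defaults
follow the headline thresholds: q ≤ 0.001 and |log2 ratio| ≥ 1. The source
study states the fold threshold inconsistently (≥ 1 in one place, > 2 in
another); ≥ 1 is the value consistent with its own gene tallies, and it is a
plain argument for users who disagree.

RPKM is the classical reads per kilobase of exon-union model per million
mapped reads; the library size is total mapped reads by default
(`"gene_mapped"` is available — the study does not say which it used).

## Hypergeometric enrichment

`enrich()` tests each term's annotated genes for over-representation in the
DE set against a background universe with the upper hypergeometric tail
(`stats::phyper`; exhaustive enumeration over all draws is the test oracle
for every universe of size ≤ 12). Terms with no DE gene are not tested;
Bonferroni correction multiplies by the number of *tested* terms. The study
names Bonferroni for both its GO and KEGG analyses while calling the KEGG
value a "Qvalue"; Bonferroni is the default here and BH is available by
argument. Flat term→gene maps only: if DAG ancestor propagation is wanted,
propagate before building the map.

## Bayesian consensus genotypes

`call_snps()` implements the Bayes-consensus core of reference-based SNP
discovery. Per site, with per-base error $\varepsilon_i = 10^{-Q_i/10}$:

* homozygote likelihood: $\prod_i [\,1-\varepsilon_i$ if $b_i = a$, else
  $\varepsilon_i/3\,]$;
* heterozygote likelihood: $\prod_i [\tfrac12 P(b_i|a) + \tfrac12 P(b_i|b)]$;
* prior over the 10 unordered diploid genotypes given the reference base:
  heterozygous-site rate $10^{-3}$ shared over reference-containing
  heterozygotes, homozygous-alternative rate $5\times10^{-4}$ over
  alternative homozygotes, both weighted 2:1 transition:transversion and
  renormalised; non-reference heterozygotes get the product of the two rates.

The consensus is the maximum-posterior genotype (ties broken toward
reference-containing genotypes, then lexicographically — implemented in the
bulk path as an additive bonus of $10^{-12}$, far below any posterior
difference of interest); consensus quality is
$-10\log_{10}(1-p_{\text{best}})$ capped at 99. A site is reported when the
consensus is not homozygous reference and passes when quality ≥ 20 *and* at
least 2 distinct unique reads carry a non-reference allele of the called
genotype — the "quality ≥ 20" filter is read as consensus quality, not base
quality, which the source leaves ambiguous. Declared base qualities are used
as-is; no recalibration or rank-sum artifact checks.

# Structural discovery

## TARs, transcript units, novel TUs

Coverage counts uniquely mapped aligned blocks only (multi-mapped and
unmapped reads are excluded everywhere downstream). A transcriptionally
active region (TAR) is a maximal run of bases with depth ≥ 2. TARs touched by
the two mates of one fragment are connected, and connected components of that
link graph are transcript units. A unit is a novel TU when all four filters
hold: no member TAR overlaps an annotated gene span; the unit span lies
inside an intergenic interval (between 200 bp downstream of one gene span and
200 bp upstream of the next; gaps ≤ 400 bp yield nothing; chromosome-end
flanks are included with the buffer on the gene side only — the source is
silent on flanks and inclusion maximises discoverable space); total length
(sum of member TAR lengths, *not* span — coverage gaps are introns) ≥ 150 bp;
and mean coverage ≥ 2 averaged over member-TAR bases (not the span; also an
interpretation the source leaves open). Each filter outcome is recorded per
unit, and the filters are independent predicates, so their order cannot
matter.

## Gene-boundary refinement

A TAR overlapping a gene's terminal exon and protruding beyond the annotated
span yields a 5′ or 3′ extension (strand-aware) of the protrusion length.
Mere overlap of the terminal exon is required, not paired-end connection to
the gene body — the weaker, more inclusive reading of an underspecified rule.

## Splice junctions and AS classification

Junctions are distinct (chromosome, donor, acceptor) triples from gaps in
uniquely mapped spliced alignments, requiring ≥ 8 aligned bases on both
sides of the gap and, for classification, support from ≥ 2 distinct reads —
standard guards against alignment artifacts; the source gives no values.
A junction belongs to every gene whose span contains both boundaries
(ambiguous assignments are flagged); unassigned junctions are dropped.

Four event types are classified, using the field's standard operational
definitions (the source defers its own):

* **alt 5′/3′ splice site** — two junctions sharing one boundary and
  differing at the other. The label names the transcript-side splice site
  that varies, so it is strand-aware: a shared donor on the plus strand is an
  alternative 3′ site, and the same coordinates on the minus strand are an
  alternative 5′ site. Novel (unannotated) boundaries participate.
* **exon skipping** — a junction spanning a complete annotated internal exon
  whose inclusion is independently evidenced (a junction landing at the
  exon's start or leaving its end, or every exon base covered ≥ 2).
* **intron retention** — an annotated intron with every base covered ≥ 2
  *while* a junction also supports its spliced form. Requiring both pieces of
  evidence is a deliberate guard: full coverage alone cannot be told apart
  from unspliced pre-mRNA or an annotation error, and retention is expected
  to be the rarest class.

Alternative first/last exons and mutually exclusive exons are intentionally
not classified.

# The synthetic study

`simulation_config()` fixes the study conditions; `simulate_genome()` and
`simulate_alignments()` realise them deterministically per seed (identical
seed and configuration give byte-identical FASTA/GTF/SAM output).

Defaults, and why:

* **90 bp paired-end reads** — the per-read base count implied by the
  alignment summary's read and base-pair totals (its prose says 100 bp; the
  table's arithmetic wins, and read length is taken from data, never prose).
* **Fragments ~N(300, 50²), clipped to [read length, 700]** — inside the
  200–700 nt library range of the emulated design.
* **Poisson read-pair counts per gene** (default mean 120 pairs, fold changes
  multiplying the emb135 mean) — matching the distributional assumption of
  the exact test so its calibration is testable.
* **Read categories** — unmapped 20%, multi-mapped 5% per read (of the order
  seen in the emulated deep muscle libraries); multi-mapped reads carry
  `NH:i:2`/MAPQ 0 and unmapped reads flag 0x4, and both are excluded by every
  downstream stage.
* **Mismatches** — 25% of mapped reads carry 1–3 planted substitutions, and
  sequencing errors occur at $10^{-Q/10}$ with constant base quality Q30;
  total mismatches per read are capped at 3, emulating an aligner that only
  reports alignments with ≤ 3 mismatches (which is also what keeps the
  perfect/≤3-mismatch partition identity exact).
* **Planted truth** — 2 genes each fold-4 up and down; 8 intergenic novel
  TUs (alternating one- and two-block structures, read pairs tiled so every
  block base reaches the configured depth deterministically); 2 planted AS
  events per classified type, realised as unannotated alternative isoforms
  drawn 50/50 against the canonical isoform, with splice-site shifts
  constructed strand-aware so each planted type matches the classifier's
  label; 30 exonic variant sites alternating heterozygous/homozygous.
  Heterozygous alternate alleles are drawn per read at rate ½; variants are
  placed at least one read length inside the transcript ends so planted
  sites sit at their gene's nominal depth rather than on the coverage ramp.

What the generator does **not** model: empirical error profiles, GC and
fragment bias, positional coverage bias, RNA amplification and pooling
variance, indels, and real splice-site motifs (the genome is i.i.d. random
sequence). Passing recovery tests therefore demonstrate the *logic* of each
stage — coordinate arithmetic, filters, graph connection, statistics — under
the stated model, not robustness to real-library artifacts.

# Numerical and degenerate-input choices

* Percentages round half-up (2 decimals for alignment summaries, 1 for
  category shares) — validated cell-by-cell against the published summary
  table; `round()`'s half-to-even would disagree on several cells.
* An empty alignment set yields zero-count summaries flagged
  `empty_input`, an empty annotation yields a whole-chromosome intergenic
  interval, an empty SNP set yields a valid header-only VCF, and an empty
  p-value vector yields an empty q-value vector.
* `percentage()` with a zero total, RPKM with zero exon length or library
  size, inconsistent hypergeometric parameters, and alignment blocks outside
  chromosome bounds are errors, not silent zeros.
* Genotype posteriors are normalised with log-sum-exp; the posterior over
  the 10 genotypes sums to 1 to 1e-12 at every tested column.

# Problem sizes used in the test suite

The suite runs the full synthetic study at desk scale — two 150 kb
chromosomes, 20 genes, roughly 10–25 thousand reads per library — plus a
noise-free variant of the same study (no unmapped/multi/mismatch reads,
mean 300 pairs per gene) for the planted-recovery checks. Statistical checks
use 1,000-gene count simulations (20 seeds for the null-calibration
estimate, 5 for DE recovery) and exhaustive enumeration oracles up to
universe size 12 (enrichment) and depth 15 (genotypes). These sizes were
chosen so every distributional check has enough draws to be within its
stated tolerance while the suite stays comfortably interactive.

# Known limitations

* One library per condition: the exact test models Poisson sampling only, so
  biological variability between animals is not represented — exactly the
  limitation of the emulated design, inherited deliberately.
* Gene spans (min exon start to max exon end) are the overlap unit for
  novelty filtering and junction assignment; heavily overlapping gene models
  will merge intergenic space conservatively.
* The SNP caller reports substitutions only, and the optional coding-region
  view is a plain exon-overlap filter, with no claim about the source
  study's undocumented procedure.
* The simulator's aligner emulation (mismatch cap, perfect flag/tag
  bookkeeping) makes the mapping-summary partition identities exact; a real
  aligner's records may violate them (e.g. reads with > 3 mismatches), in
  which case the ≤3-mismatch category is simply the subset it names.
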