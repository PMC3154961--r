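---
title: "Detecting allele-specific methylation and its mode of inheritance in simulated family RRBS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-specific methylation and its mode of inheritance in simulated family RRBS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmfam)
```

## The problem

Two homologous chromosomes can carry different DNA methylation. The cause can
be genetic — the local sequence of an allele influences its own methylation in
cis — or epigenetic, as in gametic imprinting, where methylation tracks the
sex of the transmitting parent rather than the allele. Reduced representation
bisulfite sequencing (RRBS) reads that cover both a heterozygous SNP and a CpG
observe the allele and its methylation state on the same molecule, so
allele-specific methylation (ASM) can be detected directly; a pedigree then
lets the two causes be told apart, because an allele's parental origin can
switch between generations while its sequence cannot.

`asmfam` implements this analysis end to end over simulated data with known
ground truth: a cohort generator that plants genotype-dependent, imprinted and
CpG-disrupting methylation effects into a three-generation family, and the
analysis chain — bisulfite-aware alignment, methylation and SNP calling,
Fisher-exact ASM detection with FDR control, pedigree-based classification,
genotype–methylation linear models, clustering, and allele-specific-expression
(ASE) enrichment — that recovers them. Every stage is testable against the
simulator's truth tables and against brute-force statistical oracles.

## The simulated cohort

`build_reference()` draws chromosomes with CpG-island intervals (locally
CpG-enriched, hypomethylated), gene models with exon/intron structure, and
MspI (CCGG) sites whose spacing is a mixture of short gaps (40–120 bp, the
RRBS size selection) and long gaps. The defaults (150 kb, ~4 CCGG per kb,
islands covering ~15% of the sequence) give a few hundred sequencable
fragments — enough co-coverage for every downstream stage while keeping a full
cohort simulation in the tens of seconds on one core.

`default_family_pedigree()` mirrors a three-generation design: two
grandmothers, father, mother and two sons are assayed, plus two assayed
unrelated individuals; the two grandfathers are unassayed placeholder founders
so that every non-founder has two recorded parents. This makes the
middle-generation origin assignment realistic: the mother's variant can often
be shown to come from her *unassayed* father precisely because her assayed
mother lacks it.

`build_pedigree_genotypes()` places one SNP per fragment-end window (the only
territory a 36-bp end read can see), draws founder alleles at a 0.2–0.5
variant frequency, and transmits whole chromosomes without recombination —
at this genomic scale recombination within a fragment is vanishingly rare, and
an optional per-chromosome crossover rate exists for robustness checks.
Planted variants obey bisulfite identifiability: no {C,T} allele pairs (the
forward strand cannot distinguish them after conversion), no variant C in
forward-read territory and no variant G in reverse-read territory (an
unmethylated variant C reads as T and would be miscalled as a different
variant), and no variant that creates a CpG or alters CCGG content (digestion
must be identical across haplotypes).

`assign_methylation_effects()` defines the per-haplotype methylation
propensities:

* **Baseline** (every CpG): island CpGs draw Beta(1, 8) (hypomethylated),
  non-island CpGs a 75/25 mixture of Beta(8, 1) and Beta(1, 8). The bimodal
  shape emulates somatic methylomes; no published distribution was adopted,
  so this is a modelling choice of the generator.
* **Genotype class**: the two alleles at the CpGs co-sequencable with the SNP
  carry propensities differing by Δ percentage points, with the same
  allele-to-propensity mapping in every carrier. Δ is drawn from a normal
  with mean 59.8 and sd 12, truncated symmetrically at ±3 sd, so the planted
  mean equals the 59.8-point default exactly.
* **Imprinted class**: propensity is tied to the haplotype's parental origin
  (maternal vs paternal), independent of allele, so every individual sits
  near 50% methylation at the locus while molecules separate cleanly by
  haplotype.
* **CpG-disrupting class** (chosen at SNP placement): the variant destroys
  the CpG; the intact allele's propensity is drawn from U(0.7, 1) because
  the "trivial mechanism" is only observable when the intact copy is
  methylated — a disrupted unmethylated CpG changes nothing.

`simulate_rrbs_reads()` digests each haplotype, size-selects 40–120 bp
fragments, samples Poisson(depth/2) molecules per haplotype and fragment end,
draws per-molecule CpG states independently from the propensities, applies
bisulfite conversion (efficiency 1.0 by default — configurable to probe
robustness; unconverted unmethylated cytosines inflate apparent methylation)
and uniform substitution errors last. Truth tables (origin, haplotype,
position per read; class, Δ, affected CpGs per locus) are written separately
and never encoded in the FASTQ.

## The analysis chain

**Alignment** is three-letter: read C→T against a C→T forward index, and the
read's reverse complement G→A against a G→A index. Exact 12-mer seeds at
three offsets guarantee (pigeonhole) that every ungapped placement with ≤ 2
mismatches is found; a read is kept only when its best converted-space score
is strictly unique across strands and chromosomes, and ties are discarded.
A mappability mask — each fragment-end window must align uniquely and best to
itself — is on by default and can only remove alignments. Mismatches are
re-annotated against the unconverted reference with conversion masking
(forward T-over-C and reverse A-over-G are methylation signal). Gapped
alignment and quality-aware scoring are out of scope for 36-bp RRBS reads.

**Calling.** Forward reads vote C/T at the CpG cytosine, reverse reads G/A at
the paired guanine, credited to the C coordinate; calls need ≥ 14 combined
votes (a 10x setting exists for descriptive tables). SNP calling requires ≥ 7
variant-assigned reads and a variant fraction ≥ 10% of all covering reads
(both inclusive — the thresholds are "at least" rules); heterozygosity needs
≥ 7 reference reads. Allele assignment is strand-aware: an allele pair
collapsed by conversion on one strand ({C,T} forward, {G,A} reverse) is not
counted from that strand, {C,T} SNP candidates are emitted only as
`bisulfite_obscured` and excluded, and an observed T (A) is not variant
evidence where a C (G) variant explains it as conversion. Genotypes are coded
0/0.5/1 with a 25-read floor; the homozygous rule (minor allele < 7 reads and
major fraction ≥ 0.9) mirrors the heterozygous rule, which leaves a no-call
band between clean classes by design.

**ASM.** Each read covering both positions of a (heterozygous SNP, passing
CpG) pair contributes one count to the 2×2 allele-by-methylation table; for a
pair whose SNP destroys that CpG, variant reads count as unmethylated and the
pair is flagged. The test is two-sided Fisher (sidedness is a package choice;
association has no preferred direction), with Storey q-values (λ grid
0.05–0.9, cubic-spline π₀, falling back to Benjamini–Hochberg below 100
pairs, where π₀ estimation is unstable) and events called at q < 0.05. Pairs
need ≥ 5 reads per allele to be testable — a minimal-evidence guard against
vacuous tables. `compare_event_sets()` computes overlap over events testable
in the second sample, direction consistency, and the allele-switch fraction
(the X-inactivation-style metric).

**Inheritance.** Trio rules resolve the variant's origin wherever one parent
cannot have supplied it (or must have); both parents heterozygous is
ambiguous, and Mendelian inconsistencies are flagged and dropped rather than
repaired, since genotype calls already carry a 25-read floor. Events
significant in ≥ 2 members are classified only when the variant's origin
*switches* between informative members — without a switch, allele and origin
are confounded and the call is `ambiguous`. With a switch: constant
more-methylated allele → `genotype_dependent`; constant more-methylated
*origin* with switching allele → `parental_origin`; CpG-disrupting events are
excluded outright. The operational rule ("same parental sex methylated in all
informative members while the allele identity switches") is this package's
formalisation of the concept; it is symmetric under allele relabelling.

**Genotype model.** Percent methylation is regressed on genotype dosage per
CpG–SNP pair (heterozygotes assumed halfway between homozygotes), restricted
to CpGs with sd ≥ 25 points and SNPs with ≥ 2 distinct codes; ANOVA F
p-values get Storey q-values and models pass at q < 0.05. Held-out
individuals are predicted by pooling all significant pairs into one R².
"Most varying" CpGs for clustering are ranked by variance (sd gives the same
order); clustering is average-linkage on Euclidean distances over the top 237.

**ASE and enrichment.** Per-gene allelic counts are tested two-sided binomial
against 0.5 with BH adjustment and a 25-read cutoff (the smallest total where
an 80% bias reaches p < 0.05); the cutoff is inclusive. The two-sided p sums
outcomes no more likely than the observed one (the `binom.test` convention);
a tail-doubling variant is available behind a flag. ASM–ASE enrichment is
upper-tail hypergeometric over tested genes, counting a gene once however
many events sit within 5 kb of its TSS. Site annotation assigns island
membership and one gene-feature category with priority promoter (2 kb
upstream of the TSS — the definition is a package choice) > first exon >
first intron > other exon > other intron; outside genes, `intergenic` means
at least 2 kb (inclusive, boundary distance) from the nearest gene.
Enrichment per category is two-sided Fisher; score tracks are compared by
two-sided Wilcoxon rank-sum, optionally restricted to intergenic sites.

## What the tests do and do not show

The simulator draws CpG states independently per molecule and per CpG, uses
uniform errors and constant base quality, has no coverage bias, no
recombination by default, and plants effects whose allele-to-propensity map
is exact. Real data violate all of these: co-methylation along molecules,
quality-dependent errors, GC/fragment-length coverage bias, cell-type
mixtures. Passing tests therefore demonstrate that the *pipeline logic* is
correct — counts, thresholds, test statistics, FDR behaviour, origin
bookkeeping — not that the thresholds are optimal for any real library.

Problem sizes were chosen as the smallest that exercise each property with
adequate power, and are stated where used: the shared test fixture is a 60 kb
genome with 60 SNPs at 50x; null-FDR replication uses 20 cohorts of the
six-member family on 100 kb at 50x with SNPs but no methylation effects
(realized false-discovery fraction of the q < 0.05 rule, compared with the
nominal 5% within binomial error); inheritance-mode recovery uses one 250 kb
cohort with 200 SNPs (20% CpG-disrupting, 30% genotype, 30% imprinted) at
60x with error rate 0 — the elevated imprinted fraction exists to yield
enough origin-switching events for the recovery rate to be estimated, since
only roughly a fifth of recurrent events switch origin in a family this
size. Exact-test implementations are checked against full enumeration on
every instance with totals ≤ 40, and Wilcoxon against complete permutation
enumeration up to 10 + 10.

## Numerical and degenerate-input conventions

Thresholds are inclusive throughout ("at least"). Fisher tables with an empty
margin are untestable and reported with p = 1 outside the q-value family.
Equal methylation percentages leave the more-methylated allele undefined (NA).
Storey q-values cap π₀ at 1 and enforce monotonicity; with small families
they reduce exactly to BH. Constant methylation matrices cluster with all
merge heights zero and a warning. Comparisons with an empty testable
intersection report NA fractions with a `defined = FALSE` flag rather than
0/0. All randomness flows through explicit seeds; a fixed configuration
reproduces byte-identical output tables, with the configuration hash stamped
in every file header.

## A small worked run

```{r, eval = FALSE}
cfg <- run_config(seed = 1, chrom_sizes = c(chr1 = 60000L), n_snps = 40,
                  depth = 40)
res <- run_pipeline(cfg)
res$summary$n_asm_significant
table(res$inheritance$mode)
res$predictions$G$r2
```

The `analysis/` directory runs the full-size cohort as a numbered script
sequence (simulate, align/call, ASM, inheritance, model/cluster,
ASE/enrichment), writing its tables under `results/` and printing the audit
of every stage against the planted truth.
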