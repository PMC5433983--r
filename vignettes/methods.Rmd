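---
title: "Models and methods behind riffle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riffle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`riffle` analyses a single diploid MHC class II β exon 2 locus amplified as
a short amplicon (by default 236 bp: a 207-bp exon segment followed by
29 bp of intron) in river fish sampled at upstream/downstream site pairs.
This vignette is the package's own account of the models it implements,
the parameters that matter, and the design choices made where the
methodology was genuinely open.

## The amplicon genotyping model

The caller assumes a *single* locus — at most two alleles per diploid — and
reads that are complete amplicon copies corrupted by two error modes
typical of pyrosequencing-era amplicon data: independent per-base
substitutions and single-base insertions/deletions inside homopolymer
runs. It proceeds in three steps.

**Step 1 — putative alleles within a sample.** Reads are compared
all-against-all with a gap-aware edit distance normalised by mean read
length (a p-distance). Identical reads are collapsed first and enter the
average-linkage (UPGMA) clustering as weighted leaves, which is
mathematically identical to clustering every read separately but far
cheaper. The dendrogram is cut wherever an internal branch — the difference
between a node's merge height and its parent's — reaches `min_branch`
(default 0.1). Each cluster reports a consensus: the column-wise weighted
majority over reads of the cluster's modal length, with ties broken
alphabetically so the output is deterministic. Clusters with fewer than 2
supporting reads are discarded as noise.

Two numerical points deserve emphasis:

* *Units of the branch cutoff.* "Minimum internal branch length 0.1" is
  interpreted on the p-distance merge-height scale. Neither the linkage
  nor the metric is canonical for this procedure; average linkage on
  p-distances is the choice here because it is the standard
  distance-matrix clustering in sequence analysis and makes the cutoff
  directly interpretable as substitutions per site.
* *Under-splitting is expected and harmless.* Alleles of a single MHC
  locus typically differ at a few percent of sites — far below a 0.1
  cutoff — so the two alleles of a heterozygote usually share one cluster.
  The three-step design absorbs this: the cluster consensus is still an
  exact real allele (every polymorphic column's majority is decided by the
  same read majority), the cross-sample pooling step reassembles the full
  catalog, and the final read-level assignment recovers heterozygotes
  regardless of how they clustered. One failure mode remains: an allele
  whose *only* carriers are heterozygotes in which it is the read minority
  would never surface as a consensus. Each cluster therefore also reports
  any exact read sequence that carries at least 10% of the cluster's reads
  and differs from the consensus. A minority allele at typical allele
  balance contributes roughly half of a cluster's reads (about a third of
  them error-free at the default error rates), far above 10%, while a
  *specific* error variant would need an implausible pile-up of identical
  errors to reach it. This is the one deliberate extension of the
  classical "one consensus per cluster" rule, and it is what makes perfect
  truth recovery on error-free data achievable at any allele frequency.

**Step 2 — the catalog.** Putative sequences are pooled over samples and
grouped by exact identity; groups seen in at least `min_support_samples`
(default 2) distinct samples become catalog alleles. A singleton-inclusive
mode (`allow_singletons = TRUE`) repeats the procedure keeping sequences
seen in only one sample, the guard against biasing the catalog against
rare alleles; on clean data the two modes converge, and the tests exercise
both.

**Step 3 — assignment.** Each read is matched to its nearest catalog
allele by edit distance; a read equidistant from several alleles
contributes equal fractional weight to each, keeping fractions normalised
and the rule deterministic. Alleles at ≥ `min_fraction` (default 20%) of
the reads are called; more than two passing alleles flags the sample
`ambiguous`, none flags it `failed`. Samples under 20 reads are flagged
`failed` outright rather than genotyped from data too thin to trust.

**Repeatability.** Independently re-amplified samples are compared as
unordered allele sets; the repeatability rate is
100 × concordant pairs / pairs, and discordant pairs are reported for
exclusion, which is also how the pipeline driver treats them.

## The synthetic-data generator

The generator exists so that every downstream statistic can be tested
against known truth. It emulates: a catalog of `n_alleles` haplotypes
differing at exactly `n_segregating` biallelic positions (defaults 8 and
16), with the exon built from sense codons, no internal stop codons, and
at least one nonsynonymous segregating site; Hardy–Weinberg or
heterozygote-deficit genotypes; read depths drawn log-uniformly from
[101, 14027] (the depth range typical of one-way 454 amplicon runs) or
fixed by the caller; substitution and homopolymer-indel errors (defaults
0.005 each — the homopolymer indel probability scales with run length − 1,
mimicking the dominant pyrosequencing error mode without a full flowgram
model); and a configurable fraction of duplicated samples (default 26/95).
Per-site allele frequencies default to those of the bundled six-site
survey, so the simulated study has the same shape as the system the
package targets: three rivers × (upstream, downstream), 95 fish, one site
with a single fish.

What it deliberately does *not* emulate: flowgram-level signal, PCR
stochasticity and chimera formation (a chimera rate parameter is reserved
but off, as chimera filtering is not part of the genotyping model),
primer/adapter sequence, or quality scores (FASTA output uses uniform
qualities when FASTQ is requested). Passing tests therefore demonstrate
correctness of the algorithms under this error model, not robustness to
every artefact of real amplicon libraries — cross-amplifying paralogs
being the most important real-world threat the single-locus assumption
excludes.

## Diversity and equilibrium statistics

Haplotype diversity and unbiased expected heterozygosity are the same
estimator, H = n/(n−1)·(1 − Σp²), computed on gene-copy counts; the
unbiased correction is used everywhere. `S` counts alignment columns
polymorphic among the alleles actually present; `k` averages nucleotide
differences over all C(n,2) copy pairs; π = k/L with L the full amplicon
length. The number of haplotypes `h` is the count of alleles with non-zero
copies at the site.

The Hardy–Weinberg exact test conditions on allele counts. The conditional
probability of a genotype array is n!·Πm_i!·2^H / ((2n)!·Πn_ij!), which is
exactly the distribution induced by a uniformly random pairing of the 2n
gene copies. The Markov-chain engine exploits this: its state is an
explicit pairing, and each step proposes swapping one member between two
randomly chosen pairs — a symmetric proposal whose stationary distribution
is uniform over pairings, hence exactly the conditional null, with no
acceptance ratio needed. Defaults are 100,000 steps after 1,000
dememorization steps. For small samples a complete-enumeration engine
walks every genotype table with the observed allele counts; the test suite
holds the chain to the enumerated answer within Monte-Carlo error.
Monomorphic samples return p = 1 by convention.

The Ewens–Watterson test compares observed homozygosity F = Σp² to its
neutral null conditional on (n, k). θ is solved from
E[K] = Σ θ/(θ+i) = k by Newton iteration, samples are drawn by the
Chinese-restaurant construction and rejected until they carry exactly k
alleles — the classic conditional construction (k = n short-circuits to
the degenerate all-singleton configuration). The one-sided p-value is
P(F_null ≥ F_obs), so p near 1 signals the excess evenness expected under
balancing selection. Default 1,000 accepted samples.

## Structure: Φ_ST, AMOVA, D_xy

Molecular distance between gene copies is the raw count of nucleotide
differences between the alleles they carry (uncorrected, matching the
"matrix of pairwise differences" convention). All sums of squares reduce
to quadratic forms in allele-count vectors, which makes the permutation
tests cheap. Pairwise Φ_ST is the two-level variance ratio with
significance from reassigning individuals (copy pairs) between the two
populations — 110 permutations by default; that printed default is
unusually small, so the argument is exposed and can simply be raised. The
four-level AMOVA estimates components among rivers, among sites within
rivers, among individuals within sites, and within individuals, using the
standard nested-ANOVA coefficients for unequal sample sizes (the
within-individual nesting always has exactly two copies, which fixes its
coefficient at 2). Negative component estimates are reported as estimated
but truncated to zero for the percent-of-variation column. Permutation
schemes follow the usual AMOVA conventions per level: copies among
individuals within sites (within- and among-individual components; the
within-individual p-value is left-tailed, so small p flags heterozygote
deficit), individuals among sites within rivers, and whole sites among
rivers; 3,024 permutations per scheme by default, with the observed value
always included in the null set so p ≥ 1/(n_perm + 1).

D_xy is Σ x_i y_j d_ij / L over the two populations' allele frequencies.

## Codon-level selection statistics

Nei–Gojobori site counting uses the pathway method: each codon position's
synonymous fraction is the share of its three possible changes that
preserve the amino acid (changes to stops count as nonsynonymous), so
syn + nonsyn = 3 exactly per codon. Differences between codons are
averaged over minimal mutational pathways, dropping pathways that pass
through a stop (re-weighting the rest; if all are blocked the unrestricted
average is used). Pairwise proportions are averaged over weighted copy
pairs — a weight of 2 is exactly equivalent to listing a sequence twice,
which the tests assert — then Jukes–Cantor corrected,
d = −(3/4)·ln(1 − 4p/3), flagged undefined at p ≥ 3/4. The Z-test
bootstraps codon sites (codons resampled whole, 500 replicates by
default) to get the standard error of dN − dS, with a two-sided normal
p-value; degenerate alignments (no variation, zero bootstrap variance)
return p = 1 rather than failing. Only the exon, trimmed to frame, enters
these statistics. The exon's reading frame is taken as offset 0 from its
first base — with a 207-bp segment this yields 69 codons; if the true
frame of a particular primer pair differs, `frame_offset` shifts it and a
partial terminal codon is dropped.

Recombination is summarised by Hudson–Kaplan's R_m: all four gametes at a
pair of biallelic sites imply a crossover between them; nested
incompatible intervals are culled and the maximum set of disjoint
intervals counted. Sites with more than two states are ignored, the usual
convention for the four-gamete test.

The per-window scan is a deliberate simplification of Bayesian
variable-ω/recombination models, which are out of scope here: for each
block of `window_codons` codons (default 10, the block length such models
use) the statistic pN − pS is compared to a null built by shuffling codon
columns genome-wide; a window is flagged only when its exceedance
probability reaches `threshold_prob` (default 0.95) in *both* of two
independently seeded runs — the two-run agreement rule, which squares the
per-window false-positive rate under independence. Outputs are labelled
as scan results, not posterior probabilities; the scan supports the
qualitative question (where along the exon is nonsynonymous variation
concentrated?) and nothing more.

Allele trees are Saitou–Nei neighbor joining (via `ape`) on Jukes–Cantor
distances over the full amplicon, written as unrooted Newick.

## Microsatellite counterpart

GENEPOP files are parsed with 2- or 3-digit allele codes, `Pop` blocks and
zero-coded missing data; populations are labelled by their first
individual's id, and the writer round-trips a parsed dataset. F_ST is the
Weir–Cockerham θ as a ratio of sums of the a, b, c components over alleles
and loci; a haploid mode treats every gene copy as an independent sample,
and the tests verify it coincides (to 1e-6) with the two-level AMOVA under
0/1 distances — the classical equivalence. Rarefied allelic richness uses
the closed hypergeometric form. Mantel and partial Mantel tests (Pearson
correlation on lower triangles; the partial statistic is the correlation
of residuals after removing the control matrix) run on vegan's permutation
engine, one-sided with the observed value included; rank-based variants
were considered and not adopted since the conventional
isolation-by-distance analysis correlates the transformed values
themselves. Before testing, genetic distances are transformed
F_ST/(1−F_ST) — with negative estimates floored at zero so the transform
stays defined — and geographic distances are log-transformed; default
100,000 permutations.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit integer seed; the pipeline driver
expands one master seed into per-stage seeds by a fixed affine-modular
counter, so any stage can be rerun in isolation, and rerunning a config
yields bit-identical outputs (asserted in the tests). Output tables carry
a config-digest header and the run log records all seeds.

The test suite favours problem sizes that keep the full run in a couple of
minutes while leaving the statistics well-resolved: simulated studies of
~95 diploids at read depth 200 for genotyper recovery, 100,000-step HWE
chains compared to enumeration on samples of up to 12 gene copies, 500
neutral alignments for the Z-test's type-I calibration, 100-case sweeps
for neighbor joining, and 40–100 replicates for permutation-calibration
checks. These sizes are the package's choices for routine verification;
all of them scale up through ordinary function arguments.

## Interface

The package's functions, the bundled dataset and this vignette are the
interface: every stage is an exported data-frame-in/tibble-out function,
`run_pipeline()` strings them together from a single configuration list
(or YAML file), and no separate command-line wrapper is shipped.

## Known limitations

* The single-locus, ≤2-alleles assumption is enforced, not inferred;
  cross-amplifying paralogs would surface as `ambiguous` flags but are not
  deconvolved.
* The clustering caller's branch cutoff operates on a scale (p-distance
  merge heights) that the original description of the procedure leaves
  ambiguous; with the default 0.1 it under-splits low-divergence alleles
  by design and relies on the cross-sample catalog plus read-level
  assignment, as discussed above.
* The window scan is a permutation heuristic, not a model-based estimate
  of ω; it cannot separate recombination from selection and should be
  read alongside R_m.
* The Ewens–Watterson rejection sampler can be slow when the observed
  allele number is far from its neutral expectation; it warns and reports
  the achieved number of draws if the try budget is exhausted.
* Published per-population dN/dS values for this system cannot be checked
  without the underlying allele nucleotide sequences, which are not
  public; the selection statistics are therefore validated on synthetic
  alignments with known substitution-class ratios instead, and the bundled
  survey ships as counts only.
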