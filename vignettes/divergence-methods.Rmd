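---
title: "Methods: divergence-with-gene-flow inference on joint spectra and genome scans"
author: "divflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence-with-gene-flow inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divflow)
```

# The inference problem

Two sister species of low-dispersal organisms (the motivating system is a
pair of western-European land snails) may have separated in complete
isolation, or kept exchanging migrants during part or all of their
divergence. Given whole-genome polymorphism data from both species, the
package asks three questions:

1. **Which divergence scenario fits the data?** Five two-deme models share
   a split of an ancestral population of diploid size $N_{anc}$ into
   populations of sizes $N_1$ and $N_2$ at time $T_{split}$ (about 1 Ma at
   one generation per year) and differ only in when gene flow occurred:
   never (M1), from the split until ~200 kya (M2), secondary contact
   100–10 kya (M3), secondary contact 150–100 kya (M4), or continuously
   until ~10 kya (M5).
2. **Which genomic regions diverged first?** Windowed divergence and
   diversity statistics classify 30 kb windows by their absolute
   divergence.
3. **Which genes show protein-level selection?** Per-gene
   McDonald–Kreitman contrasts of synonymous and non-synonymous variation
   within and between species.

All components are exercised end to end on synthetic data whose generating
process is known exactly; nothing in the package depends on any particular
empirical dataset.

# The structured-coalescent engine

`simulate_genealogy()` runs the standard two-deme structured coalescent
backward in time, in units of generations with diploid sizes: a pair of
lineages in deme $i$ coalesces at rate $1/(2N_i)$ per generation; during a
migration epoch each lineage in deme 1 jumps to deme 2 at the backward
rate $m_{12}$ (and vice versa); at $T_{split}$ all lineages merge into the
ancestral deme. Exponential waiting times are re-drawn at every epoch or
split boundary — valid without discretization error because the
exponential distribution is memoryless. Epochs with zero rates are dropped
before simulation, so a zero-rate epoch cannot perturb the random-number
stream (an M3 model with $m = 0$ is bit-identical to M1 under the same
seed).

Preset gene flow is symmetric ($m_{12} = m_{21} = m$), matching the
bidirectional arrows of the scenario definitions; asymmetric rates are
available through `demographic_model()`.

Mutations follow the infinite-sites model: the number of mutations on a
genealogy is Poisson with mean $\mu L \times$ (total branch length), each
mutation lands on a branch proportionally to its length, and each defines
one biallelic site. There is no recombination within a locus and free
recombination between loci; SFS summaries are insensitive to intra-locus
linkage in expectation, which is why the locus is the unit of
independence. The event loop is implemented in C++ (every simulator in
this field compiles its core) but draws all randomness from R's RNG, so
`set.seed()` gives bit-identical output.

Correctness is checked against closed forms (panmictic
$E[T_{MRCA}] = 2N$ for $n = 2$; neutral SFS $E[\xi_i] = \theta/i$;
$E[S] = \theta a_1$; isolation $E[d_{XY}] = 2\mu(T_{split} + 2N_{anc})$)
and against an independent coalescent simulator (msprime/tskit, run
through `python` in the test suite only) on identical parameters.

# ABC scenario selection on the joint SFS

`observed_joint_sfs()` tabulates the two-species joint site-frequency
spectrum at six diploids per species, either by a seeded subsample
(sites with missing calls in the subsample dropped) or by hypergeometric
projection. The default polarization is **folded**: real data from these
organisms have no outgroup-polarized ancestral states, and folding costs
little of the scenario signal. Folding maps each cell onto its
minor-allele configuration; cells exactly at half frequency keep the
average of themselves and their complement, which makes folding
idempotent and mass-preserving.

`abc_model_select()` is plain rejection ABC in the "proportion of
accepted simulations" presentation: the distance is the Euclidean norm
between mass-normalized spectra (the two monomorphic corner cells are
excluded; normalization makes the comparison invariant to dataset size),
the accepted set is the `tolerance` fraction of the pooled reference
table with the smallest distances, and each scenario is scored by its
share of that set. The distance metric and the default tolerance of
0.005 are this package's choices — standard rejection-ABC practice; no
specific metric or tolerance is prescribed by the study design this
mirrors, which is also why the original study's printed acceptance
percentages are not an exact reproduction target. Both are arguments and
can be changed.

Priors are mandatory configuration. The package default
(`prior_spec()`: log-uniform sizes $10^4$–$10^7$, uniform $m$ in
$[0, 10^{-4}]$, $T_{split}$ fixed at $10^6$) is a deliberately wide,
weakly informative choice. The **model-recovery experiment**
(`study_config()`) fixes the generating conditions once:
$N_1 = N_2 = N_{anc} = 10^5$, $T_{split} = 10^6$ generations,
$m = 10^{-5}$ inside the scenario epoch (so $4Nm = 4$, strong but
realistic gene flow), 12+12 sampled haploid genomes, 100 loci of 1 kb at
$\mu = 10^{-8}$, reference priors log-uniform on $[5\times10^4,
2\times10^5]$ for sizes and $[5\times10^{-6}, 5\times10^{-5}]$ for $m$,
2 000 reference simulations per scenario, tolerance 0.005. These values
were chosen a priori as a well-separated but not caricatured parameter
regime: the split is deep ($T_{split}/2N = 5$ coalescent units), and the
migration signal is strong enough that scenario recovery is expected to
succeed when the method is implemented correctly, which is exactly what
the acceptance suite asserts (the generating scenario tops the ranking
in $\ge 18/20$ replicates; gene-flow scenarios jointly dominate M1
whenever the generator includes gene flow).

`abc_posterior()` summarizes accepted parameter draws per scenario
(mean, median, equal-tailed credible interval) — the standard rejection
posterior, with coverage of the generating value checked by experiment
in the test suite.

# Variant filtering, pruning, and fourfold-degenerate sites

`filter_sites()` fixes an explicit order of operations for the classic
hard filters: genotype-quality masking (GQ < 30 to missing) happens
**first**, then per-site rules — missingness > 10%, mean depth over
non-missing calls outside [10, 50], minor allele frequency below 0.1
over non-missing alleles. Applying the filters "simultaneously" is
ambiguous precisely because masking changes missingness, depth and
frequencies; the masking-then-site-filter order matches how
VCFtools-style pipelines compose and is documented and configurable.
Whether mean depth should average over all or only non-missing
individuals is equally unstated in common practice; non-missing is used.
The function is idempotent.

`ld_prune()` mirrors `--indep-pairwise 50 10 0.1`: within each 50-SNP
window, while any pair of retained sites has squared dosage correlation
above 0.1 (pairwise-complete), the lower-MAF member of the worst pair is
dropped (tie: later position), then the window slides by 10 SNPs. PLINK
does not document its tie-breaking, so bit-compatibility with PLINK is
explicitly not promised — the guaranteed invariant, asserted by
exhaustive pair checks in the tests, is that no retained pair within any
window exceeds the threshold. One caveat surfaced by the synthetic
analysis (`analysis/03_sfs_abc.R`): with only six diploids per species,
the expected chance correlation between *unlinked* sites is
$E[r^2] \approx 1/12 = 0.083$, barely below the 0.1 threshold, so
pruning removes most sites and — because the tie-break prefers dropping
rare alleles — biases the surviving SFS toward intermediate
frequencies. The SFS step therefore reports both the pruned and the
unpruned spectrum; at these sample sizes the unpruned one is the honest
input (the simulated loci are unlinked by construction).

`fourfold_degenerate_sites()` extracts the classic neutral proxy sites:
third codon positions whose codon family encodes one amino acid for all
four nucleotides, from a reference FASTA plus GFF3 CDS features, with
strand and phase handled by reverse-complement splicing. Genes with
internal stop codons are skipped with a warning; non-ACGT codons are
skipped; a position covered by several genes is kept only if it is
fourfold in every covering frame. Tests verify every call against a
brute-force oracle that mutates the position to all four bases and
re-translates the gene.

# Windowed genome scan

Windows are half-open 30 kb intervals on a fixed grid (0-based
internally, 1-based inclusive in reports). Per window:

* $\pi$ — sum of per-site unbiased heterozygosity
  $2j(n-j)/(n(n-1))$ divided by the window length (per-bp, the scale on
  which published diversity values are quoted) or by the number of
  variant sites.
* Tajima's $D$ — classical constants at the species' full haploid
  sample size $n$; sites with more than 20% missing calls in the
  species are excluded from $S$ and the diversity sum so that the
  formula's fixed-$n$ assumption is not silently violated, while
  per-site heterozygosity keeps the site's own allele number for
  unbiasedness.
* $D_{XY}$ — per site $p_1(1-p_2) + p_2(1-p_1)$; the **default
  denominator is the number of variant sites**, not window length. This
  matters: per-variant-site divergence is roughly two orders of
  magnitude larger than per-bp diversity, and the early-diverged
  threshold of 0.35 is only meaningful on that scale. The per-bp
  denominator is available as an option.
* $F_{ST}$ — Weir & Cockerham's (1984) two-population estimator as a
  ratio of summed variance components $\sum a / \sum(a+b+c)$; slightly
  negative windows are possible and expected.

`classify_early()` flags windows with $D_{XY} \ge 0.35$
(boundary-inclusive) as early-diverged ($W_{early}$), the set used to
ask which genes began diverging first. `mann_whitney()` provides the
species contrast for $\pi$ and Tajima's $D$ (midranks, tie-corrected
variance, continuity correction; exact enumeration for two samples of
at most 8 without ties); it is a plain rank-sum U, so a published
package-specific "U" statistic of a different magnitude is not a
comparison target. `rare_shared_fraction()` computes the gene-flow
indicator: among sites whose global minor-allele count is 2–5, the
fraction in which the minor allele is seen in both species.

$\pi$, Tajima's $D$ and $D_{XY}$ are validated to $10^{-6}$ relative
against tskit's site-mode statistics on a shared simulated locus, and
$F_{ST}$ against an independent scalar transcription of the 1984
estimator, since no installed package provides Weir–Cockerham $F_{ST}$.

# McDonald–Kreitman selection scan

`count_mkt()` walks every variable codon of a two-species CDS haplotype
alignment. A variant is a **fixed difference** when the species share no
allele at the position, otherwise a **polymorphism** (segregating in at
least one species — polymorphism is pooled across species rather than
taken from a designated ingroup, which is the interpretation consistent
with running the test "on all samples"; a focal-species analysis can be
had by subsetting the alignment). Synonymy is judged against the codon
context of the within-gene consensus. Codons with more than one variable
position (or more than two alleles) are skipped and counted, keeping the
classification unambiguous without enumerating mutational paths; genes
with a premature consensus stop are skipped with a warning.

`fisher_2x2()` is the exact conditional test (two-sided by summing
hypergeometric probabilities of tables as or less probable, the same
rule as `stats::fisher.test`, against which it is cross-checked along
with a `choose()`-based enumeration oracle). `neutrality_index()` gives
$NI = (P_n/P_s)/(D_n/D_s)$ and $\alpha = 1 - NI$, undefined when a
required margin is zero unless Haldane pseudo-counts are requested.
`classify_selection()` calls a gene positive when $p < 0.05$ and
$NI < 1$, negative when $p < 0.05$ and $NI > 1$; no multiple-testing
correction is applied by default (matching the practice of reporting raw
MKT significance; a BH-FDR column is available via `fdr = TRUE`).
`genes_in_early_windows()` intersects positively selected genes with
$W_{early}$ using 1 bp-of-CDS overlap as the inclusion rule.

Unphased genotypes cannot be phased into true haplotypes;
`gene_alignments_from_vcf()` builds pseudo-haplotypes with the ref allele
on one copy and the alt on the other. Because multi-hit codons are
skipped anyway, MKT counts are invariant to this arbitrary phase choice.

# The synthetic-data generator

`genotypes_from_model()` turns simulated genealogies into diploid
genotype calls: consecutive haploid lineages pair into individuals, loci
tile two 5 Mb chromosomes with 1 kb spacing, the reference allele is the
ancestral state (an option mis-polarizes a configurable fraction to
exercise folding), and clean calls carry depth 10–50 and GQ 30–99.
`inject_noise()` degrades configured fractions of calls (missingness,
out-of-range depth, low GQ) and rewrites a configured number of sites to
a single heterozygote (forcing MAF < 0.1), recording per site which
filter rules fail; the truth sidecar is computed by direct bookkeeping of
each rule on the degraded table, so `filter_sites()` can be checked for
exact agreement.

`make_coding_fixture()` builds protein-coding genes with exactly planted
$(D_n, D_s, P_n, P_s)$: synonymous events use a fourfold-family third
position (GGA/GGT), non-synonymous ones a Lys/Glu first position
(AAA/GAA), polymorphic codons segregate at frequency 1/2 within one
species (alternating which species is polymorphic), and every planted
event sits in its own codon so the classification is unambiguous by
construction. Genes alternate strands; the reference carries the
species-1 consensus. Fixtures are written as plain-text FASTA, GFF3 and
a JSON truth sidecar.

What the generator deliberately does **not** emulate: read-level errors
and mapping artefacts, indels and multiallelic sites, recombination
within loci, population structure within species, linked selection, and
GC-biased processes. Green tests therefore demonstrate that the
*methods* are implemented correctly and behave as theory predicts on
clean coalescent data — not that any particular empirical dataset would
yield a particular scenario.

# Numerical and design notes

* All stochastic entry points thread R's RNG; a single integer seed
  reproduces every stage bit-for-bit, including the C++ core.
* The SFS excludes the monomorphic corner cells everywhere (simulation,
  observation, distances).
* Window statistics return `NA` (never 0) when undefined: no usable
  sites, $S = 0$, $n < 4$ for Tajima's $D$, zero $F_{ST}$ denominator;
  `rare_shared_fraction()` reports `NA` when no site is rare.
* Fisher p-values use the conventional $(1 + 10^{-7})$ slack when
  comparing table probabilities, avoiding floating-point misclassation
  of ties.
* Problem sizes in tests and the acceptance script (5 000 loci for the
  neutral-theory checks, 2 000 reference simulations per scenario,
  2 000 oracle loci, 500 neutral MKT genes) were chosen as the smallest
  sizes at which the Monte-Carlo error bars make the checks sharp; all
  complete in a few minutes on one CPU.

# Known limitations

* Rejection ABC only; no regression adjustment, SMC, or
  composite-likelihood machinery. For five models and a 13×13 folded
  spectrum at these locus counts, rejection is sufficient for scenario
  ranking, which is all the pipeline claims.
* LD pruning at $r^2 = 0.1$ is frequency-biased at small sample sizes
  (see above); the workflow makes that visible rather than hiding it.
* The upstream read-processing world — trimming, mapping, duplicate
  marking, genotype calling — is out of scope; the pipeline starts at a
  genotyped, biallelic-SNP VCF.
* PSMC-style size-history inference, clustering (PCA/ADMIXTURE), GO
  enrichment and functional annotation are out of scope; where such
  results motivate model parameters (the 1 Ma split, the size scale)
  they enter as explicit configuration.
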