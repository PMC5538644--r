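---
title: "Dissecting admixed genomes by heterozygosity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting admixed genomes by heterozygosity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`cohet` analyses dense SNP genotypes from populations descended from two
divergent ancestral gene pools — the motivating system is cattle, where
*Bos indicus* (indicine) and *Bos taurus* (taurine) subspecies and their
composites coexist — and asks three questions:

1. How much does each SNP, gene and chromosome contribute to the
   indicine–taurine axis of variation?
2. Where does heterozygosity, and departure from Hardy–Weinberg
   equilibrium (HWE), mark ancestry-informative or selected regions?
3. Which genes co-vary in their per-breed heterozygosity strongly enough
   to form a "co-heterozygosity" network, and how do genes of *a priori*
   interest (e.g. fertility-related) sit inside it?

The pipeline has six stages: preprocessing, genotype PCA, mixture-based
ancestry assignment, heterozygosity/HWE screening with breed clustering,
gene-set testing, and PCIT network inference.  Every stage is driven by
plain-text standard formats (PLINK PED/MAP or TPED/TFAM, BED annotation,
TSV tables) and is reproducible from a configuration and a seed.

Because panels of hundreds of thousands of genotyped animals are not
redistributable, the package ships a synthetic-data generator that
reproduces the statistical structure the analyses rely on; all tests and
the acceptance script run on generated panels.

# The synthetic panel generator

## Divergence model

Subspecies allele frequencies follow the Balding–Nichols model: for each
SNP an ancestral frequency $p$ is drawn uniformly from the configured
minor-allele range (default $[0.05, 0.5]$, mimicking the common-variant
ascertainment of commercial SNP arrays) or its mirror image, and each
subspecies' frequency is an independent draw from

$$\mathrm{Beta}\!\left(p\frac{1-F}{F},\ (1-p)\frac{1-F}{F}\right),$$

which has mean $p$ and variance $p(1-p)F$.  The parameter $F$ is the
fixation index $F_{ST}$ between each descendant pool and the ancestor;
for two pools simulated this way the Weir–Cockerham estimator recovers
$F$ directly (the package's tests verify $\pm 0.03$ at $F = 0.2$ with
10,000 SNP).  The default $F = 0.2$ is of the order of the indicine
versus taurine divergence.

## Breeds and individual ancestry

A breed is a labelled group of animals with a lineage (`BI`, `BT`,
`BTI`) and an indicine ancestry proportion $\alpha$ (1 for BI, 0 for BT,
intermediate for composites).  Each admixed animal receives an
*individual* proportion

$$\alpha_i \sim \mathrm{Beta}(\alpha\nu,\ (1-\alpha)\nu),$$

and every allele copy at every SNP is independently of indicine origin
with probability $\alpha_i$, then drawn Bernoulli from the matching
subspecies frequency.  SNP are unlinked; no LD, recombination map or sex
chromosome is simulated.

The dispersion $\nu$ (default 4, i.e. $\mathrm{sd}(\alpha_i) \approx
0.22$ at $\alpha = 0.5$) is the one genuinely open design choice in the
generator and deserves explanation.  If every animal of a breed had
exactly the breed proportion and allele copies were sampled
independently (`ancestry_dispersion = Inf`), admixed breeds would sit in
exact Hardy–Weinberg equilibrium at every SNP — genotypes would be
Binomial(2, mixture frequency) — and the HWE screening stage would have
nothing to find.  Real composite populations are not like that:
individual admixture varies (crossbred pedigrees span F1s, backcrosses
and stabilised composites), and pooling animals of unequal ancestry
produces the classic Wahlund homozygote deficit at SNP with divergent
subspecies frequencies,

$$F_{IS} \approx \frac{\mathrm{Var}(\alpha_i)\,(p_I - p_T)^2}
{\bar q (1 - \bar q)},$$

which is exactly the signal the HWE stage uses to flag
ancestry-informative genes.  $\nu = 4$ makes composite animals span the
middle of PC1 (as genuinely admixed panels do) and yields strong but not
universal HWE rejections at strongly differentiated SNP.  Setting
$\nu = \infty$ is useful for testing: the package asserts in that regime
that a fixed difference at $\alpha = 0.5$ gives exactly 50% expected
heterozygosity.

## Gene blocks and designed gene sets

SNP are laid out in contiguous blocks of at least six SNP per gene, 200
bp apart, with 4 kb between genes so that the 1 kb assignment windows
never overlap, plus decoy SNP placed more than 1 kb from any gene.  The
layout is deterministic given the configuration.

Optional *skewed sets* rewrite the subspecies frequencies of chosen
genes so that the set is strongly informative for one component: a
taurine-targeted gene receives SNP with $p_T \sim U(0.35, 0.5)$ and
$p_I \sim U(0.005, 0.05)$ (and symmetrically for indicine targets).
Such SNP have large $|p_I - p_T|$ with the common allele in the matching
pure lineage, so their PC1 loadings fall in the matching mixture mode.
These sets exist to exercise the gene-set permutation machinery with a
known answer; their default sizes in the acceptance script (125
taurine-skewed, 86 indicine-skewed) match the milk- and fertility-gene
list sizes of the motivating study design.

## What the generator does not emulate

Linkage disequilibrium (and hence haplotype statistics), selective
sweeps, genotyping error, ascertainment bias beyond the MAF range,
pedigree structure within breeds, and sex chromosomes.  Passing tests on
synthetic panels therefore demonstrate that the *algorithms* behave as
specified under the stated population model, not that any biological
conclusion transfers to a particular real panel.

# Ancestry from PC1 loadings

Genotypes are standardized per SNP as $(g - 2\hat p)/\sqrt{2\hat
p(1-\hat p)}$ with $\hat p$ estimated over non-missing calls; missing
entries are mean-imputed (zero after centring) and monomorphic SNP
dropped.  PCA is computed by exact eigendecomposition of the
animal-by-animal covariance — the cheap side when animals number in the
hundreds or thousands and SNP in the hundreds of thousands — and SNP
loadings are recovered by back-projection and unit-normalised.  PC1 is
oriented so the pure indicine lineage scores negative, making component
labels reproducible; other components get a canonical sign (largest
loading positive).

The empirical distribution of PC1 SNP loadings in an admixed panel is
bimodal: SNP whose minor allele is common on the taurine side load
positively, indicine-common SNP negatively.  A two-component Normal
mixture is fitted by maximum-likelihood EM:

- deterministic initialisation (median split; half-sample moments; equal
  mixing), no random restarts, so a fit is a pure function of the data;
- convergence when the relative log-likelihood change falls below
  $10^{-8}$, capped at 1,000 iterations; variances floored at
  $10^{-12}$ against component collapse; E-step on the log scale;
- the smaller-mean component is labelled indicine, matching the PC1
  orientation.

Per-SNP posteriors $m_1$ (indicine) and $m_2 = 1 - m_1$ are averaged
unweighted over a gene's SNP to give gene memberships
(`pr_indicine`, `pr_taurine`); the unweighted mean is the
minimal-assumption way to collapse SNP to genes, and chromosome-level
content is in turn the unweighted mean over genes.  Genome-wide profile
plots use $-\log_{10}$ of the *opposing* component's posterior (a gene
with tiny taurine membership scores high on the indicine profile),
floored at $10^{-300}$, with a significance flag above 4; base 10 and
the threshold are configurable.

# Heterozygosity and HWE

Percentage heterozygosity (HET) of a SNP in a breed is $100\times$ the
proportion of non-missing animals with a heterozygous genotype; gene HET
is the unweighted mean over the gene's SNP, lineage HET the unweighted
mean over a lineage's breeds (equal breed weights), chromosome HET the
unweighted mean over genes.  Expected HET is maximal for balanced
admixture, which is why admixed breeds sit at the top of the
"inverted-V" of HET against PC1.

HWE is tested per (SNP, breed) with the classic 1-df Pearson chi-square
against $\hat p^2, 2\hat p\hat q, \hat q^2$, no continuity correction
and no multiple-testing adjustment (the nominal 1% threshold is part of
the method: the gene lists are deliberately permissive candidate pools).
Monomorphic SNP are defined as non-deviating.  A gene is flagged for a
breed when any of its SNP deviates; a stricter fraction-based rule is
available (`min_frac`).

Breeds are clustered on their gene-HET columns by Euclidean distance
and average (UPGMA) linkage — a standard, deterministic stand-in for
seriation-based heatmap software; columns are processed in breed-id
order so tie-breaks and the Newick export are reproducible.

# Gene-set tests

The ancestry-skew permutation test counts the set's genes with
`pr_taurine >=` 0.5 and compares the count with that of `n_perm` random
same-size draws (without replacement) from the background.  The
percentile uses a *strict-less* convention — trials tying the observed
count are not counted — which is documented because with a tie-heavy
null the choice matters: in a degenerate background where every gene
clears the threshold, every trial ties and the percentile is 0.  The
Monte-Carlo percentile converges to the exhaustive hypergeometric
percentile (verified by full enumeration on small backgrounds), and its
standard error is bounded by $100\sqrt{0.25/n_{\mathrm{perm}}}$.

Over-representation of attribute terms uses the exact one-sided
upper-tail hypergeometric test, the standard replacement for
ranked-list web tools when the term map is user-supplied; term genes
outside the background are ignored.

# The co-heterozygosity network

Gene co-heterozygosity is the Pearson correlation between two genes'
per-breed HET profiles — breeds are the only axis along which gene HET
varies, so they are the observations; at least three breeds are
required and zero-variance profiles are excluded.  Correlations are
clipped to $\pm(1 - 10^{-12})$ so first-order partial correlations stay
finite.

PCIT (partial correlation and information theory) decides edge
significance: for every unordered trio $(x, y, z)$ the three first-order
partials

$$r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
{\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}$$

are computed and the trio tolerance $\varepsilon$ is the mean of the
signed ratios $r_{xy\cdot z}/r_{xy}$ (ratios with a zero denominator are
skipped; a trio with all three raw correlations zero discards nothing).
The edge $(x,y)$ is discarded by the trio when $|r_{xy}| \le
|\varepsilon r_{xz}|$ **and** $|r_{xy}| \le |\varepsilon r_{yz}|$, with
non-strict comparisons; an edge is significant iff no trio discards it.
The $O(n^3)$ loop is implemented in C++; a deliberately naive R triple
loop in the test suite is the normative reference, and the two are
asserted identical on random correlation matrices.  The final network
keeps edges that are significant *and* have $|r|$ at or above the
threshold (default 0.95; the absolute value is used because strong
negative co-heterozygosity is as informative as positive), and nodes
left without edges are dropped.

Degree diagnostics regress $\log_{10}$ frequency on $\log_{10}$ degree
over observed degrees $\ge 1$ (zero-frequency degrees are undefined on
the log scale and excluded); an approximately linear, negative-slope fit
is reported as the scale-free diagnostic along with maximum-degree hub
genes.

The trio-span search scores a trio of fertility genes by the fraction of
network nodes inside its closed neighbourhood ("majority of the
topology" is read as node coverage).  With at most $10^5$ candidate
trios the search is exhaustive with a lexicographic tie-break; beyond
that, a greedy build-up restarted from every seed gene with pairwise
swap refinement is used — on random graphs it matches the exhaustive
optimum in the package's tests, but it is a heuristic and carries no
optimality guarantee.

# Numerical and determinism choices

- All randomness flows from a single integer seed; component seeds are
  small fixed offsets of it.  Seeded operations restore the caller's RNG
  state.
- Median gene filtering uses the lower central value for even counts, so
  the threshold is always an attained integer.  Re-applying the filter
  with its recorded threshold is the identity; re-resolving `"median"`
  on already-filtered data may tighten it further, which is why the
  resolved threshold is stored in the result.
- TSV outputs print doubles at 4 decimals in fixed order, making
  re-runs byte-identical; the manifest records versions, seed,
  parameters and input checksums and contains no timestamps.
- The window mapper treats both window boundaries as inclusive; a SNP in
  two overlapping windows counts for both genes.
- Missing genotypes are R's native `NA` and are excluded from every
  statistic by contract.

# Problem sizes used in the test-suite study conditions

Structure-recovery checks use six breeds (2 BI, 2 BT, 2 half-indicine
composites) of 200 animals with 3,600 SNP in 500 genes at $F_{ST} =
0.2$, over 10 seeds.  Permutation-direction checks use 1,000 genes /
6,500 SNP with 125-gene designed sets over 20 seeds, 2,000 trials each.
HWE calibration uses a single pure breed of 500 animals and ~6,000
polymorphic SNP; the Wahlund check a single $\alpha = 0.5$ composite at
$F_{ST} = 0.3$.  The acceptance script runs the full nine-breed default
design (1,350 animals, 6,000 SNP, 750 genes) with 10,000 permutation
trials.  These sizes were chosen so each property is measured with
comfortable statistical margin while a full run of suite plus script
stays in the minutes range on a single core.

# Known limitations

- Ancestry is a single axis; panels admixed from three or more sources
  need a different model (the mixture is strictly two-component).
- Gene HET profiles over a handful of breeds make correlations coarse;
  with few breeds the 0.95 threshold retains many edges and the network
  is denser than one inferred across many populations.
- The chi-square HWE test is asymptotic; very rare alleles in small
  breeds would warrant an exact test, which is out of scope.
- PCIT significance is topological, not inferential: it carries no
  p-value and depends on the set of genes supplied.
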