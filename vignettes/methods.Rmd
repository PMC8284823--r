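---
title: "Models and methods in admixpaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in admixpaint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

admixpaint decomposes the ancestry of recently admixed individuals into
contributions from closely related source populations and times that
admixture from diploid local-ancestry summaries. This vignette describes
the models, the choices behind their defaults, and what the synthetic
cohorts used in the test suite do and do not establish about real data.

## The analysis in one paragraph

Each admixed individual's phased genome is *painted* against a reference
panel with a Li & Stephens haplotype-copying HMM, producing for every
donor the expected centimorgans copied from them ("chunk lengths") and
the expected number of copied segments ("chunk counts"). Chunk lengths,
condensed to reference-population proportions, give each individual a
*copying vector*; each reference population's mean vector over its own
members serves as its *surrogate*. A Bayesian mixture model then explains
a target's copying vector as a sparse convex combination of surrogates,
sampled by MCMC — posterior means, exceedance probabilities and credible
intervals summarize the contribution of each candidate source, per
individual and for the "mathematically average" member of the cohort.
Orthogonally, a three-state HMM on unphased genotypes assigns each
genomic window 0, 1 or 2 European alleles; the cM-weighted genome
fractions with 0/1/2 European alleles (*ternary fractions*) are compared
with closed-form pedigree expectations to classify how recently each
individual's European ancestry arrived.

## Haplotype-copying model

A target haplotype is modelled as a mosaic copied from the \(K\) donor
haplotypes. The hidden state is the donor being copied; across a map gap
of \(d\) Morgans the donor is re-drawn uniformly with probability
\(1 - e^{-N_e d}\), and each emitted allele mismatches the donor with
probability \(\mu\). The defaults \(N_e = 103.35\) and
\(\mu = 2.04\times10^{-5}\) are the values this model family estimates by
EM on dense SNP-array cohorts of this kind; both can be re-estimated with
`em_estimate_params()`, which accumulates expected switch and mismatch
counts by forward–backward and combines per-chromosome M-step estimates
by a map-length-weighted mean. Because the combination step is not the
exact pooled M-step, the monotone-likelihood assertion carries a 1e-6
relative tolerance.

Two accounting conventions matter downstream and are fixed here: every
site owns half the map gap to each neighbour (so chunk lengths sum
exactly to the painted map length), and a chromosome start counts as one
segment entry while a switch event that re-selects the same donor does
not create a new segment. Reference individuals are painted with both of
their own haplotypes excluded; admixed targets are painted against the
full panel. Copying vectors are normalized genome-wide, not per
chromosome.

The forward–backward recursions are scaled (stable beyond \(10^5\) sites)
and implemented in C++; an exhaustive path-enumeration oracle in the test
suite verifies expected chunk lengths and counts to \(10^{-10}\) on all
small instances.

## Source decomposition

The mixture model is a reimplementation in the spirit of the
SOURCEFIND approach, not a bit-compatible clone: proportions live on a
grid of `n_slots = 100` slots; the likelihood treats the concentration-
scaled target vector \(c\,x\) as multinomial counts under
\(p = \sum_s \beta_s m_s\) (surrogates \(m_s\)); the prior draws the
number of contributing sources from a Poisson with mean
`t_expected = 4` (sparse alternative 2) truncated to
\([1, \texttt{t\_eligible} = 8]\), uniformly over source subsets and slot
compositions. A Metropolis–Hastings sampler moves single slots between
sources and relabels whole sources; on small state spaces its stationary
distribution matches exhaustive enumeration to within 0.02 total
variation. Convergence is monitored with the classic split-chain
Gelman–Rubin statistic (not the rank-normalized variant); degenerate
all-constant chains are defined to have Rhat 1 and flagged.

The concentration \(c\) calibrates how literally the copying vector is
treated as counts. Per target it defaults to the painted map length in
cM. For the group analysis the target is the mean vector of \(n\)
individuals, whose painted support is \(n\) genomes; `summarize_group()`
therefore scales \(c\) by the group size. Larger \(c\) tightens the
posterior around the best-fitting mixture; the test suite checks this
monotonicity at \(c \in \{300, 3000, 30000\}\).

Individual-level results are summarized the way cohort tables of this
kind are reported: for thresholds 1%, 5% and 20%, an individual counts
toward a source only when the posterior probability of at least that
contribution exceeds 0.99 (strictly).

## Admixture timing from ternary fractions

Tract-length dating is fragile when phasing switch errors are common
relative to the recombination since admixture, so timing rests on a
phase-free summary. A three-state HMM on the *unphased* genotype sequence
tracks \(z\), the number of European alleles at a site: each haplotype
independently switches ancestry at intensity \(g\) per Morgan (run at
both \(g = 3\) and \(g = 8\) to check robustness to the assumed
admixture date) with stationary European probability \(q\) taken from the
individual's supervised global-ancestry estimate; the diploid transition
matrix is the two-chain binomial combination, and emissions convolve
allele draws from the European and Inuit reference frequencies. Site
posteriors are cM-averaged within 0.2 cM windows; a window's call is the
argmax state. Cohort-level window filtering removes windows whose
cohort-mean Inuit allele fraction falls outside an accepted band — the
absolute band 62.5%–72.5% matches a cohort that is about two-thirds
Inuit; for synthetic cohorts with other means the band can be centred on
the cohort mean (the pipeline default, ±0.05).

For an individual whose maternally and paternally transmitted gametes
carry expected European ancestry \(a_m\) and \(a_f\), the expected
ternary fractions are
\[(f_{II}, f_{IE}, f_{EE}) = \big((1-a_m)(1-a_f),\;
a_m(1-a_f) + (1-a_m)a_f,\; a_m a_f\big).\]
Classification applies, in order: *two European parents* if
\(f_{EE} \ge 1 - \mathrm{tol}\); *one European parent* if
\(f_{II} \le \mathrm{tol}\) (a fully European parent leaves no genomic
region with two Inuit alleles); else *other*. No published numeric rule
exists for this boundary; tol defaults to 0.02 and the pipeline reports
sensitivity at 0.01/0.02/0.05. The parent-accounting identity
\(n_\text{parents} = n_\text{one} + 2 n_\text{two}\), the ancestor
fraction \(n_\text{parents}/(2 n_\text{admixed})\), and those parents'
share of the cohort's European ancestry
\(0.5\,n_\text{parents}/(n_\text{admixed}\,\bar q)\) are exposed as
`parent_accounting()`.

## QC and cohort construction

Variant filters apply in a fixed order (region mask, multi-allelic,
missingness, singletons, MAF), each reported against the survivors of the
previous one. Global ancestry is a supervised two-way binomial EM against
reference frequencies (the likelihood is monotone by construction; a flat
likelihood, \(f_E = f_I\) everywhere, is flagged rather than resolved).
The unadmixed/admixed split uses strict inequalities: unadmixed means
Inuit ancestry above 99%, admixed means European ancestry above a 1%
floor (the floor is configurable; individuals exactly at a threshold fall
into neither set). Pairwise relatedness uses individual-specific allele
frequencies \(h_i = q_i f_E + (1-q_i) f_I\) and a variance-weighted
method-of-moments fit of the nine genotype-combination counts to their
expectations under IBD 0/1/2 (negative coefficients truncated,
renormalized); relatives are pruned greedily above \(r > 0.2\) with
call-rate then lexicographic tie-breaks. An exact Hardy–Weinberg test is
included as an optional, off-by-default stand-in; it assumes a
homogeneous population and is *not* an admixture-aware test, which is why
it is off.

## The synthetic cohort generator

The generator reproduces the statistical structure the analysis assumes,
not the demography of any real population. Source allele frequencies
follow the Balding–Nichols model around shared ancestral frequencies
(drawn uniform on 0.05–0.95): one strongly diverged Inuit-like source
(F = 0.15) and five weakly diverged European-like sources. Founder
haplotypes are site-independent draws — there is no background linkage
disequilibrium, a deliberate simplification: the painting and
decomposition machinery is exercised for contract correctness, not LD
realism. Admixed genomes descend from explicit pedigrees: meioses draw a
Poisson number of crossovers per chromosome (no interference, matching
the cM-scale expectations used throughout), crossover positions uniform
in cM, and the true ancestry of every site on both haplotypes is
recorded. Phasing errors are injected at heterozygous sites by swapping
the haplotypes from the site onward, which never changes a genotype.

Default design, chosen once and documented here:

* 4 chromosomes × 1.5 Morgans, 30 sites/cM (dense SNP arrays of the kind
  this analysis targets carry roughly 39 sites/cM);
* European-like drift F = 0.02, 0.04, …, 0.10 (steps of 0.02). Because
  founders carry no LD, source separability must come from frequency
  drift alone; at the weak end of plausible differentiation the
  decomposition is genuinely unidentifiable at this scale, so the
  defaults sit at the separable end while keeping pairwise European
  differentiation weak relative to the Inuit–European split;
* 40 reference individuals per source (surrogate noise is the limiting
  factor for separating adjacent sources), 80 admixed targets drawn from
  one-European-parent and one-European-grandparent histories (sources
  EUR_A and EUR_B), 2% switch-error rate.

What passing tests on these cohorts show: the inference machinery
recovers truths generated under its own assumptions, at realistic marker
density and panel sizes, and the phase-robustness and conservation
invariants hold exactly. What they do not show: robustness to background
LD, array ascertainment, genotyping error, or real reference-panel
misspecification — on real data the copying signal rides largely on
shared haplotypes, which these founders do not carry.

## Numerical choices and degenerate inputs

* Scaled forward–backward throughout; log-likelihoods finite at
  \(10^5\) sites.
* Frequency clipping at \(\varepsilon = 10^{-6}\) avoids log(0) at
  boundary sites; \(\mu\) floors at \(10^{-9}\) when EM sees no
  mismatches; \(N_e\) is bounded in \([10^{-3}, 10^6]\).
* Slot-MCMC proposals that would exceed `t_eligible` active sources are
  rejected; the add/remove move draws the incoming source uniformly among
  inactive candidates.
* Windows containing no site get an `NA` call and drop out of ternary
  aggregation; single-site chromosomes carry zero cM weight.
* Ties in window argmax resolve to the lower state index; individuals
  exactly at a cohort-split threshold are assigned to neither set.
* The simulation, painting and ternary stages are bit-reproducible under
  a fixed seed; MCMC summaries are reproducible given per-chain seeds
  (chain \(i\) uses seed + i − 1).

## Problem sizes in the shipped tests

The test suite exercises enumeration oracles at up to 6 sites / 3 donors
(copying HMM) and \(3^6\) paths (diploid HMM); pedigree-recovery cohorts
use 30 one-Morgan chromosomes at 30 sites/cM with 50 replicates per
history; the end-to-end check runs the full default design above. These
sizes keep the whole suite in the tens of minutes on a single CPU while
leaving the statistical tolerances meaningful; all are configurable
upward for heavier validation runs.
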