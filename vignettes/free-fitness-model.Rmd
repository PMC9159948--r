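---
title: "The free-fitness model of driver-gene missense mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The free-fitness model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic-data generator does and does not emulate,
the numerical choices, and the design decisions taken where the design was
genuinely open.

## 1. The model

The observed frequency distribution of missense mutations in a driver gene
is modelled as a softmax over a per-mutation *free fitness*

$$F_m = \log p_m + \sigma_T\, P^{\mathrm{onc}}_m - \sigma_I\, \langle P^{\mathrm{pres}}_m \rangle,
\qquad q_m = \frac{e^{F_m}}{\sum_{m'} e^{F_{m'}}},$$

with three ingredients.

**Background probability $p_m$.** Every single-nucleotide substitution of
the coding sequence whose codon translates to a different, non-stop residue
is a candidate; each carries the trinucleotide context of its mutated base
(flanking bases are required at the sequence ends — an ambiguous flank is
refused rather than guessed, because a silently wrong context corrupts the
background). A context rate table (192 keys, or 96 pyrimidine-strand keys
expanded by reverse complement, the COSMIC signature convention) assigns
each candidate a rate, normalised over the candidate set to give $p_m$.
The model's support is missense-only: synonymous and nonsense changes are
excluded, as are indels and splice variants. No signature deconvolution is
performed — the rate table is an input, since which mutational process mix
applies is a property of the dataset, not of this model.

**Pro-oncogenic probability $P^{\mathrm{onc}}_m$.** Transactivation assay
data (percent of wild-type activity across the eight canonical p53 target
promoters WAF1, MDM2, BAX, h1433s, AIP1, GADD45, NOXA, P53R2) are
converted to relative association constants by inverting the two-state
binding isotherm $\theta = cK/(1+cK)$: wild type is anchored at occupancy
$\theta_{wt} = 0.5$ at reference concentration $c_{ref} = 1$, a mutant at
activity $T$% has $\theta_m = \theta_{wt} T/100$, clipped to
$[0.005, 0.995]$ because the yeast assay reports exact zeros and
above-wild-type values that would otherwise map to $K \in \{0, \infty\}$.
The per-mutation summary is the median $K$ over available targets (missing
targets are dropped, not imputed), and

$$P^{\mathrm{onc}}_m = \frac{1}{1 + c_m K_m}$$

is the probability that the mutant fails to occupy its target sites at its
per-allele concentration $c_m$ — loss of tumour-suppressor binding read as
oncogenic benefit. $c_m$ is the median over carrier samples of abundance
divided by mutant copy number (median, not mean: mutant p53 accumulation
has a heavy upper tail), with a default of 1 for mutations never observed
with abundance data. For genes without functional assays, the per-position
conservation score $1 - H/\ln 20$ (Shannon entropy of an alignment column,
gaps excluded) substitutes for $P^{\mathrm{onc}}$.

**Presentation probability $\langle P^{\mathrm{pres}}_m \rangle$.** All
nonamers containing the mutated residue (lengths configurable) are scored
against the six HLA alleles of a haplotype through a peptide–allele
dissociation-constant table; unknown pairs score the non-binder cap
(default 50,000 nM) rather than erroring, because predictor exports are
sparse. Channels aggregate harmonically,
$K_{\mathrm{eff}} = (\sum_i 1/K_{d,i})^{-1}$ — binding strengths of
independent parallel channels add, so adding a channel can only improve
presentation — and convert to a probability through the saturation form
$P^{\mathrm{pres}} = 1/(1 + K_{\mathrm{eff}}/(c_m \kappa))$ with
$\kappa = 500$ nM, the conventional MHC-I binder threshold: a mutation
whose pooled affinity sits at the threshold at reference concentration is
presented with probability one half. Haplotypes are sampled with
replacement under Hardy–Weinberg independence within and across the A, B
and C loci (homozygous slots count twice in the channel pool), and
$P^{\mathrm{pres}}$ is averaged over draws with a Monte Carlo standard
error. Both probabilities are *concentration-coupled*: raising $c_m$
simultaneously lowers the oncogenic probability (more residual binding)
and raises the immune cost (more antigen) — the mechanistic heart of the
trade-off.

**Assumptions worth stating.** Mutation occurrences are treated as
independent multinomial draws (no per-patient clustering, no tumour-type
stratification beyond what the user supplies); the two probabilities enter
linearly in the exponent with non-negative weights; presentation is
averaged over a population haplotype distribution rather than matched to
each tumour's HLA type; wild-type (self) presentation is not subtracted.

## 2. Fitting, comparison and scans

The weights maximise the multinomial kernel
$\sum_m n_m \log q_m(\sigma_T, \sigma_I)$. This is a log-linear
(exponential-family) model, so the log-likelihood is concave in the
weights; we nevertheless run box-constrained L-BFGS-B on
$[0, \sigma_{\max}]^2$ ($\sigma_{\max} = 50$) from five deterministic
starts $(0,0), (1,1), (5,5), (10,1), (1,10)$ with relative
function-tolerance $10^{-8}$, as a safeguard against plateaus at extreme
weights. Nested models (background, function-only, immune-only) fix the
excluded weight at zero and reuse the same code path, which guarantees the
nesting inequalities numerically.

Model fit is reported as $D_{KL}(\text{observed} \,\|\, \text{predicted})$
in nats — this direction asks how well the model explains the data; the
per-position variant pools both distributions over all amino-acid changes
at a residue before the divergence. Model comparison reports AIC
($2k - 2\log L$, $k$ = number of free weights) and likelihood ratios
against the background null.

The *relative immune weight* scan reparametrises
$\sigma_T = s(1-\lambda)$, $\sigma_I = s\lambda$ and fits the overall
selection strength $s \ge 0$ per grid point (default grid
$0, 0.05, \ldots, 1$); $\lambda = 0$ and $\lambda = 1$ reproduce the
function-only and immune-only fits exactly because they share the
optimiser. The survival variant rescores the cohort at each $\lambda$'s
fitted weights, median-splits and reports the log-rank statistic — the
statistic itself, not a transform, with 3.841 as the $\alpha = 0.05$
reference line.

## 3. Pareto front

The trade-off is analysed in the plane of intrinsic fitness
($\log p_m + \sigma_T P^{\mathrm{onc}}_m$) versus extrinsic immune fitness
($-\sigma_I \langle P^{\mathrm{pres}}_m \rangle \le 0$), both maximised.
The front is the non-dominated set; coincident points collapse to one
vertex that lists all members. "Distance to the front" is the Euclidean
distance to the piecewise-linear polyline through the front vertices —
chosen over a dominance-gap definition because it is symmetric in the two
axes and has an unambiguous value for points beyond the front's ends
(distance to the nearest vertex). The constrained free-fitness optimum
maximises $x + y$ along the polyline; the objective is linear, so the
optimum is a vertex, and on a slope $-1$ segment (exact ties) the vertex
with the larger intrinsic coordinate is returned, preferring the
functionally stronger representative.

## 4. Cohort analyses

Patients are scored with their mutation's chosen fitness component; a
patient recorded with several scored mutations keeps the highest-free-
fitness one (a clonally dominant driver assumption — documented as this
package's rule, not asserted as the only defensible one). Median splits
send ties to the high group; a split in which either group would be empty
(all scores identical) is an error, and the survival scan records such
grid points as degenerate rather than failing. Kaplan–Meier estimation
delegates to the survival package's product-limit implementation; the
log-rank test is implemented directly from the observed-minus-expected
table with hypergeometric variance, because the weight scans call it
thousands of times and the package needs a fixed, unit-testable convention
(it agrees with `survival::survdiff` to floating-point precision in the
test suite). The two-sided binomial enrichment test uses the
minimum-likelihood convention — stated explicitly because two-sided
binomial conventions differ and the p-values change; distribution
comparisons between catalogs use frequencies renormalised within the
shared mutation support.

## 5. The synthetic-data generator

The generator produces every input the pipeline consumes, with ground
truth attached, under a single recorded seed. Its defaults are the
simulated study conditions used throughout the tests:

| parameter | default | what it emulates |
|---|---|---|
| `n_codons` | 60 | a small driver-gene-like ORF (ATG start, no stops) |
| `hotspot_fraction` | 0.1 | the minority of recurrently selected changes |
| `sigma_t`, `sigma_i` | 4, 2 | function-dominated selection with a real immune term |
| `n_mutation_draws` | 50,000 | a large pooled mutation catalog |
| `aff_meanlog`, `aff_sdlog` | ln 5000, 2 | log-normal Kd spanning strong binders (<500 nM) to non-binders |
| `hotspot_shift` | +2 ln-units | poorer MHC-I binding of hotspot-derived peptides |
| `alleles_per_locus` | 8 | a compact HLA panel with Dirichlet frequencies |
| `conc_meanlog`, `conc_sdlog` | 0, 0.5 | mutation-to-mutation spread in per-allele concentration |
| `cohort_n`, `baseline_hazard` | 500, 0.02/yr | a mid-sized cohort on a years scale |
| `beta` | 1 | log-linear hazard link to the chosen fitness component |
| `censor_rate` | 0.2 | uniform independent censoring |

Transactivation activities are Normal(5, 5) for hotspots and Normal(70,
30) for the rest, clipped at zero, with a 15% low-activity tail
(Normal(15, 10)) among non-hotspots so that loss of function does not
perfectly label hotspots — the overlap seen in real assay data. When the
full study chain is generated, the hotspot affinity shift scales with the
mutation's retained activity, `min(shift · retention/0.05, 2·shift)`:
functionally wild-type-like hotspots bind MHC-I worst while complete-loss
hotspots stay presentable. This single coupling is what lets the
intrinsic-versus-extrinsic scatter reproduce the anti-correlated,
front-hugging hotspot structure the model is designed to detect; with a
constant shift the within-hotspot correlation would be zero by
construction.

Survival times are exponential with hazard
$h_0 \exp(\beta \cdot (\text{component} - \overline{\text{component}}))$ —
the simplest generator for which log-rank behaviour is analytically
predictable; centring the component absorbs its scale into the baseline
hazard without changing group contrasts. Each synthetic patient carries
exactly one mutation.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: real mutational-signature structure
(rates are i.i.d. log-normal per context), linkage between HLA loci and
population substructure, predictor-specific biases in Kd tables, shared
peptides between overlapping mutations beyond sequence identity,
per-patient mutation multiplicity, tumour-type heterogeneity, and any
gain-of-function phenotype. Recovery of $(\sigma_T, \sigma_I)$ on this
generator validates the inference machinery, not the biological claim.

## 6. Numerical choices and degenerate inputs

Softmax uses log-sum-exp stabilisation; predicted frequencies sum to one
within $10^{-12}$ and are invariant under additive shifts of $F$.
Candidates with $p_m = 0$ are excluded from the support with a warning;
observed counts on zero-probability categories report $-\infty$
log-likelihood and infinite KL, flagged rather than masked. Catalog counts
attached at protein level are apportioned to nucleotide routes
proportionally to background probability. The log-rank variance term skips
risk sets of size one; a pooled dataset with no events is an error, not a
zero. Monte Carlo presentation averages report their standard error so
downstream users can see haplotype-sampling noise; a fixed seed gives
bit-identical output.

## 7. Open design points, resolved

Where the concrete functional forms were open, the package commits to the
simplest member of the plausible family and exposes the choice as a
parameter: the occupancy inversion uses a single global wild-type
calibration ($\theta_{wt} = 0.5$ at $c_{ref} = 1$) rather than per-target
calibration (per-target wild-type activity is already the assay's own
normalisation); effective affinity is the harmonic channel sum rather than
the minimum Kd (the minimum is the limiting case when one channel
dominates); peptides are pooled within a haplotype *before* the
probability is taken, and wild-type (self) presentation is not subtracted
— differential-to-self scoring is a plausible alternative left
deliberately out of the default path. Weights multiply the probabilities
directly rather than their log-odds. These are this package's committed
defaults; all are single-point switches in the code should a user want the
alternatives.

## 8. Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to make every stochastic check stable under its
stated threshold while completing in about a minute each: weight-recovery
and model-comparison experiments use 600–1,000 candidate mutations and
30,000–50,000 occurrences over 20 seeds; Pareto geometry is checked on
1,000 points across 100 seeds against a quadratic oracle; null log-rank
calibration uses 2,000 cohorts of 100 patients and the power check 50
cohorts of 500; the end-to-end chain uses a 60-codon gene (roughly 350
protein changes) with 300 haplotype draws per mutation. These sizes are
the package's validation conditions, not limits of the implementation.

## 9. Known limitations

The model is missense-only and single-gene at a time; weights are fitted
per catalog, so cross-dataset weight comparisons inherit any differences
in the background tables used; concentration estimates require
pre-normalised abundance input (no cross-cohort normalisation is
attempted); the immune term uses population-averaged haplotypes rather
than patient-matched typing; and MHC-I binding prediction itself is out of
scope — the package consumes affinity tables, it does not produce them.
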