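# freefit

Why are missense mutations in cancer driver genes concentrated in a handful
of hotspots? Three forces plausibly shape the observed frequency of each
candidate mutation: how easily it arises (the innate, trinucleotide-context
mutation rate), how much oncogenic benefit it confers (loss of
tumour-suppressor function, for p53 the loss of transcription-factor
activity at its target promoters), and how much it costs the clone
immunologically (the mutant neopeptides it exposes to MHC class I
presentation). `freefit` implements a quantitative "free fitness" model
that weighs these forces against each other and fits the weights to
observed mutation-count distributions, for computational cancer biologists
who want to ask which forces a given mutation catalog actually requires.

## The model

For each candidate missense mutation *m* of a driver gene:

- **p_m** — background probability from trinucleotide-context substitution
  rates (96-context COSMIC-style or full 192-context tables), normalised
  over all enumerated missense candidates of the coding sequence;
- **P_onc(m)** = 1 / (1 + c_m K_m) — the probability that the mutant fails
  to occupy its target promoters, with K_m the median association constant
  inferred from transactivation assays (eight canonical p53 targets) by
  inverting a two-state binding isotherm, and c_m the per-allele mutant
  protein concentration (median abundance per mutant gene copy);
- **⟨P_pres(m)⟩** — the MHC-I presentation probability
  1 / (1 + K_eff / (c_m κ)), with K_eff the harmonic aggregate of
  peptide–allele dissociation constants over all mutation-spanning
  nonamers and the six alleles of a haplotype, averaged over haplotypes
  sampled from HLA allele frequencies.

These combine into the per-mutation free fitness

    F_m = log p_m + σ_T · P_onc(m) − σ_I · ⟨P_pres(m)⟩

analogous to a free energy with the background rate as the multiplicity
term. Predicted frequencies are the softmax q_m ∝ exp(F_m); the weights
(σ_T, σ_I) are fitted by multinomial maximum likelihood against observed
counts. On top of the fit the package provides Kullback–Leibler divergence
(per mutation and per protein position), AIC/likelihood-ratio comparison of
the nested models (background, function-only, immune-only, combined), scans
over the relative immune weight λ with σ_T = s(1−λ), σ_I = sλ, the Pareto
front of the intrinsic (log p_m + functional) versus extrinsic (immune)
trade-off with distances and the constrained free-fitness optimum, and
Kaplan–Meier / log-rank cohort analyses in which patients are scored by
their mutation's fitness components. A synthetic-data module generates
fully ground-truth-labelled inputs (gene, rate table, transactivation
assay, immunopeptidome, haplotype frequencies, mutation counts, survival
cohorts) so the entire pipeline is testable without any external download.

## Worked example

A complete synthetic study — generate a gene, enumerate its missense
candidates, build phenotypes and an immunopeptidome at true weights
(σ_T, σ_I) = (4, 2), draw 50,000 mutation occurrences, refit:

```r
library(freefit)

cfg   <- synth_config(seed = 11, n_codons = 40, n_hap_draws = 200, cohort_n = 300)
study <- synthesize_study(cfg)          # 231 candidate protein changes

fit <- fit_weights(study$catalog$count, study$catalog$p_background,
                   study$ground_truth$p_onc, study$ground_truth$p_pres,
                   "combined", positions = study$catalog$protein_pos)
fit
#> <freefit_fit: combined> sigma_t = 3.9949, sigma_i = 2.0018, logLik = -226669.089, KL = 0.0023
```

Both true weights are recovered to well under 1% here, and the KL
divergence of predicted to observed frequencies drops from 0.42 (background
only) through 0.068 (function only) to 0.0023 (combined) — the synthetic
data, like the real phenomenon it emulates, *requires* both components:

```r
bg <- fit_weights(study$catalog$count, study$catalog$p_background,
                  study$ground_truth$p_onc, study$ground_truth$p_pres, "background")
fn <- fit_weights(study$catalog$count, study$catalog$p_background,
                  study$ground_truth$p_onc, study$ground_truth$p_pres, "function_only")
model_comparison(list(bg, fn, fit))
#>           model k log_lik delta_ll    aic delta_aic lr_vs_background       kl
#> 3      combined 2 -226669        0 453342         0            42057 0.002333
#> 2 function_only 1 -229964     3294 459929      6587            35468 0.068223
#> 1    background 0 -247698    21029 495395     42053                0 0.422905
```

Trade-off and cohort analyses on the same study:

```r
pf  <- pareto_front(study$landscape)
opt <- optimal_front_point(pf)          # optimum at (-0.12, -0.71)

hot <- study$ground_truth$hotspot
welch_compare(study$landscape$free[hot], study$landscape$free[!hot])
#> hotspot vs non-hotspot free fitness: t = 7.48, p = 5.18e-08

scored <- score_patients(study$cohort, study$landscape)
sp     <- median_split(scored$score)
logrank_test(scored$time[sp$low],  scored$event[sp$low],
             scored$time[sp$high], scored$event[sp$high])
#> median-split log-rank: chi2 = 125.05, p = 4.96e-29
```

Hotspots carry significantly higher free fitness than the remaining
mutations, and a median split on the combined fitness separates the
synthetic cohort's survival — the two behaviours the model is built to
capture.

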