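#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the ground-truth generators. Defaults describe the
#' standard simulated study: a 60-codon gene, 10% of protein changes
#' designated hotspots, true weights `(sigma_t, sigma_i) = (4, 2)`, 50,000
#' mutation occurrences, log-normal peptide-allele affinities centred on
#' non-binding (`meanlog = log(5000)`, `sdlog = 2`) with a +2 ln-unit shift
#' for hotspot-derived peptides (poorer binding), eight alleles per HLA
#' locus, and a 500-patient cohort with exponential survival whose hazard
#' is log-linear in the chosen fitness component.
#'
#' @param seed Base RNG seed.
#' @param n_codons Gene length in codons (>= 2).
#' @param hotspot_fraction Fraction of protein changes labelled hotspot.
#' @param sigma_t,sigma_i True free-fitness weights.
#' @param n_mutation_draws Total mutation occurrences N.
#' @param aff_meanlog,aff_sdlog Log-normal affinity parameters (ln nM).
#' @param hotspot_shift Additive shift of `meanlog` for hotspot peptides.
#' @param alleles_per_locus Panel size per HLA locus.
#' @param n_hap_draws Haplotype draws per presentation average.
#' @param kd_cap Non-binder cap (nM).
#' @param kappa Presentation affinity scale (nM).
#' @param conc_meanlog,conc_sdlog Log-normal per-mutation concentration.
#' @param cohort_n Patients per synthetic cohort.
#' @param baseline_hazard Baseline exponential hazard (events/year).
#' @param beta Log-hazard slope on the (centred) fitness component.
#' @param hazard_component Component driving survival (`"free"`,
#'   `"functional"`, `"immune"`, `"intrinsic"`, or `"none"` for the null).
#' @param censor_rate Probability a patient is censored uniformly before
#'   the event.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_codons = 60L, hotspot_fraction = 0.1,
                         sigma_t = 4, sigma_i = 2,
                         n_mutation_draws = 50000L,
                         aff_meanlog = log(5000), aff_sdlog = 2,
                         hotspot_shift = 2, alleles_per_locus = 8L,
                         n_hap_draws = 300L, kd_cap = 50000, kappa = 500,
                         conc_meanlog = 0, conc_sdlog = 0.5,
                         cohort_n = 500L, baseline_hazard = 0.02, beta = 1,
                         hazard_component = "free", censor_rate = 0.2) {
  cfg <- list(seed = as.integer(seed), n_codons = as.integer(n_codons),
              hotspot_fraction = hotspot_fraction, sigma_t = sigma_t,
              sigma_i = sigma_i, n_mutation_draws = as.integer(n_mutation_draws),
              aff_meanlog = aff_meanlog, aff_sdlog = aff_sdlog,
              hotspot_shift = hotspot_shift,
              alleles_per_locus = as.integer(alleles_per_locus),
              n_hap_draws = as.integer(n_hap_draws), kd_cap = kd_cap,
              kappa = kappa, conc_meanlog = conc_meanlog,
              conc_sdlog = conc_sdlog, cohort_n = as.integer(cohort_n),
              baseline_hazard = baseline_hazard, beta = beta,
              hazard_component = hazard_component, censor_rate = censor_rate)
  stopifnot(cfg$n_codons >= 2L, cfg$hotspot_fraction >= 0,
            cfg$hotspot_fraction <= 1, cfg$sigma_t >= 0, cfg$sigma_i >= 0,
            cfg$n_mutation_draws >= 1L, cfg$cohort_n >= 1L,
            cfg$censor_rate >= 0, cfg$censor_rate <= 1)
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a random valid coding sequence
#'
#' ATG start, random non-stop codons thereafter, random ACGT flanks.
#'
#' @param n_codons Number of codons (>= 2).
#' @param seed Optional RNG seed.
#' @param gene_id Identifier for the synthetic gene.
#' @return A [coding_sequence()].
#' @export
generate_gene <- function(n_codons, seed = NULL, gene_id = "SYNGENE") {
  if (n_codons < 2L) stop_input("n_codons must be >= 2")
  with_seed(seed, {
    code <- Biostrings::GENETIC_CODE
    pool <- names(code)[code != "*"]
    codons <- c("ATG", sample(pool, n_codons - 1L, replace = TRUE))
    coding_sequence(gene_id, paste(codons, collapse = ""),
                    flank5 = sample(c("A", "C", "G", "T"), 1L),
                    flank3 = sample(c("A", "C", "G", "T"), 1L))
  })
}

#' Generate random trinucleotide context rates
#'
#' Log-normal rates over all 192 substitution contexts, giving a
#' non-uniform but strictly positive background.
#'
#' @param seed Optional RNG seed.
#' @param sdlog Spread of the log-normal rates (default 1).
#' @return A [context_rate_table()].
#' @export
generate_context_rates <- function(seed = NULL, sdlog = 1) {
  with_seed(seed, {
    keys <- all_context_keys()
    context_rate_table(setNames(rlnorm(length(keys), 0, sdlog), keys),
                       dialect = "192")
  })
}

#' Generate synthetic transactivation phenotypes with a hotspot structure
#'
#' A random fraction of protein changes is designated hotspot and loses
#' transactivation across all eight targets (activities ~ Normal(5, 5),
#' clipped at 0). Non-hotspots centre on near-wild-type activity
#' (Normal(70, 30)) but include a low-activity tail (15% drawn from
#' Normal(15, 10)), so some non-hotspots also lose function — matching the
#' overlap seen in real assay data.
#'
#' @param mutations Protein-change identifiers.
#' @param hotspot_fraction Fraction designated hotspot.
#' @param seed Optional RNG seed.
#' @return List `activities` (data.frame `mutation` + the eight
#'   [TA_TARGETS] columns) and `hotspot` (logical vector).
#' @export
generate_phenotypes <- function(mutations, hotspot_fraction = 0.1,
                                seed = NULL) {
  m <- length(mutations)
  if (!m) stop_input("empty mutation set")
  with_seed(seed, {
    n_hot <- round(hotspot_fraction * m)
    hot <- rep(FALSE, m)
    if (n_hot > 0) hot[sample.int(m, n_hot)] <- TRUE
    draw_row <- function(is_hot) {
      if (is_hot) {
        pmax(rnorm(8L, 5, 5), 0)
      } else if (runif(1) < 0.15) {
        pmax(rnorm(8L, 15, 10), 0)
      } else {
        pmax(rnorm(8L, 70, 30), 0)
      }
    }
    act <- t(vapply(hot, draw_row, numeric(8L)))
    colnames(act) <- TA_TARGETS
    list(activities = data.frame(mutation = mutations, act,
                                 stringsAsFactors = FALSE,
                                 check.names = FALSE),
         hotspot = hot)
  })
}

#' Generate a synthetic immunopeptidome
#'
#' Draws log-normal peptide-allele dissociation constants for every
#' mutation-spanning nonamer against a synthetic HLA panel, with
#' hotspot-derived peptides shifted upward in ln Kd (poorer binding), and a
#' haplotype model with symmetric-Dirichlet locus allele frequencies.
#'
#' When `retention` (per-mutation retained transactivation as a fraction of
#' wild type) is supplied, the hotspot shift scales with it:
#' `shift_m = min(hotspot_shift * retention_m / 0.05, 2 * hotspot_shift)`.
#' Functionally wild-type-like hotspots then bind MHC-I worst while
#' complete-loss hotspots remain presentable, reproducing the
#' oncogenicity-immunogenicity trade-off structure within the hotspot set;
#' without `retention` all hotspot peptides get the constant shift.
#'
#' @param catalog Protein-level catalog (columns `mutation`, `protein_pos`,
#'   `alt_aa`).
#' @param protein Reference protein sequence.
#' @param hotspot Logical vector along the catalog.
#' @param config A [synth_config()].
#' @param seed Optional RNG seed (defaults to `config$seed`).
#' @param retention Optional per-mutation retained activity in `[0, 1]`.
#' @return List `affinities` ([affinity_table()]), `hap`
#'   ([haplotype_model()]).
#' @export
generate_immunopeptidome <- function(catalog, protein, hotspot, config,
                                     seed = NULL, retention = NULL) {
  with_seed(seed %||% config$seed, {
    alleles <- lapply(c("A", "B", "C"), function(loc) {
      sprintf("HLA-%s*SYN:%02d", loc, seq_len(config$alleles_per_locus))
    })
    freqs <- do.call(rbind, lapply(seq_along(alleles), function(i) {
      w <- rgamma(length(alleles[[i]]), 1)
      data.frame(locus = c("A", "B", "C")[i], allele = alleles[[i]],
                 freq = w / sum(w), stringsAsFactors = FALSE)
    }))
    all_alleles <- unlist(alleles)
    shifts <- if (is.null(retention)) {
      ifelse(hotspot, config$hotspot_shift, 0)
    } else {
      ifelse(hotspot,
             pmin(config$hotspot_shift * retention / 0.05,
                  2 * config$hotspot_shift),
             0)
    }
    rows <- lapply(seq_len(nrow(catalog)), function(i) {
      peps <- enumerate_neopeptides(protein, catalog$protein_pos[i],
                                    catalog$alt_aa[i], 9L)$peptide
      peps <- unique(peps)
      grid <- expand.grid(peptide = peps, allele = all_alleles,
                          stringsAsFactors = FALSE)
      shift <- shifts[i]
      grid$kd_nm <- pmin(rlnorm(nrow(grid), config$aff_meanlog + shift,
                                config$aff_sdlog), config$kd_cap)
      grid
    })
    aff <- do.call(rbind, rows)
    # the same nonamer can arise from two mutations; keep the first draw
    aff <- aff[!duplicated(paste(aff$peptide, aff$allele)), ]
    list(affinities = affinity_table(aff, kd_cap = config$kd_cap),
         hap = haplotype_model(freqs = freqs))
  })
}

#' Draw multinomial mutation counts from true frequencies
#'
#' @param q True frequency distribution (sums to 1).
#' @param n Total occurrences N.
#' @param seed Optional RNG seed.
#' @return Integer counts summing to `n`.
#' @export
generate_mutation_counts <- function(q, n, seed = NULL) {
  if (abs(sum(q) - 1) > 1e-8 || any(q < 0)) {
    stop_input("q must be a probability distribution")
  }
  if (n < 1) stop_input("n must be >= 1")
  with_seed(seed, as.integer(rmultinom(1L, n, q)))
}

#' Generate a synthetic survival cohort from a fitness landscape
#'
#' Each patient carries one mutation sampled proportionally to the
#' predicted frequencies `q_m`; the event time is exponential with hazard
#' `h0 * exp(beta * (component - mean(component)))` (the component is
#' centred so the baseline hazard keeps its scale), and with probability
#' `censor_rate` the patient is instead censored at a uniform time before
#' the event. `hazard_component = "none"` gives the null cohort: survival
#' independent of fitness.
#'
#' @param landscape A `freefit_landscape`.
#' @param config A [synth_config()].
#' @param seed Optional RNG seed (defaults to `config$seed`).
#' @return data.frame `patient_id`, `mutation`, `time`, `event`.
#' @export
generate_cohort <- function(landscape, config, seed = NULL) {
  if (!nrow(landscape)) stop_input("empty landscape")
  with_seed(seed %||% config$seed, {
    n <- config$cohort_n
    i <- sample.int(nrow(landscape), n, replace = TRUE, prob = landscape$q)
    comp <- switch(config$hazard_component,
                   none = rep(0, n),
                   free = landscape$free[i],
                   functional = landscape$f_t[i],
                   immune = landscape$f_i[i],
                   intrinsic = landscape$intrinsic[i],
                   stop_input("unknown hazard_component"))
    lin <- if (sd(comp) > 0) comp - mean(comp) else rep(0, n)
    t_event <- rexp(n, rate = config$baseline_hazard *
                      exp(config$beta * lin))
    censored <- runif(n) < config$censor_rate
    time <- ifelse(censored, runif(n) * t_event, t_event)
    # uniform censoring can hit 0 exactly only with probability 0; guard anyway
    time <- pmax(time, .Machine$double.eps)
    data.frame(patient_id = sprintf("P%05d", seq_len(n)),
               mutation = landscape$mutation[i],
               time = time, event = as.integer(!censored),
               stringsAsFactors = FALSE)
  })
}

#' Generate model-level inputs directly (no sequence plumbing)
#'
#' Light-weight generator for fitting experiments at a chosen support size:
#' background probabilities from normalised log-normal rates, independent
#' Beta-distributed pro-oncogenic and presentation probabilities, true
#' frequencies under `(sigma_t, sigma_i)` and a multinomial count draw.
#' Mutations are assigned synthetic protein positions (three changes per
#' position) so per-position analyses work.
#'
#' @param m Number of candidate mutations.
#' @param n Total occurrences.
#' @param sigma_t,sigma_i True weights.
#' @param seed Optional RNG seed.
#' @return List `mutation`, `protein_pos`, `p`, `p_onc`, `p_pres`, `q`,
#'   `counts`, `sigma_t`, `sigma_i`.
#' @export
generate_landscape_inputs <- function(m, n, sigma_t = 4, sigma_i = 2,
                                      seed = NULL) {
  if (m < 2L) stop_input("need m >= 2")
  with_seed(seed, {
    r <- rlnorm(m, 0, 1)
    p <- r / sum(r)
    p_onc <- rbeta(m, 1.2, 1.2)
    p_pres <- rbeta(m, 1.2, 1.2)
    f <- log(p) + sigma_t * p_onc - sigma_i * p_pres
    q <- predicted_frequencies(f)
    counts <- generate_mutation_counts(q, n)
    list(mutation = paste0("m", seq_len(m)),
         protein_pos = (seq_len(m) - 1L) %/% 3L + 1L,
         p = p, p_onc = p_onc, p_pres = p_pres, q = q, counts = counts,
         sigma_t = sigma_t, sigma_i = sigma_i)
  })
}

#' Synthesize a complete ground-truth study
#'
#' Runs the full generative chain: random gene, context-rate background,
#' missense enumeration, hotspot-structured transactivation phenotypes,
#' log-normal immunopeptidome with haplotype-averaged presentation,
#' per-mutation concentrations, true free-fitness frequencies, a
#' multinomial count draw, and a survival cohort. All stages are
#' deterministic under `config$seed`, and the true weights, component
#' probabilities, frequencies and hotspot labels are returned as ground
#' truth.
#'
#' @param config A [synth_config()].
#' @return List with `gene`, `rates`, `catalog` (protein-level, with counts
#'   and background), `phenotypes`, `immune`, `affinities`, `hap`,
#'   `concentration`, `landscape` (at the true weights), `cohort` and
#'   `ground_truth` (`sigma_t`, `sigma_i`, `q`, `p_onc`, `p_pres`,
#'   `hotspot`, `seed`).
#' @export
synthesize_study <- function(config = synth_config()) {
  seed <- config$seed
  gene <- generate_gene(config$n_codons, seed = seed)
  rates <- generate_context_rates(seed = seed + 1L)
  nt_catalog <- background_probability(enumerate_missense(gene), rates)
  catalog <- aggregate_protein(nt_catalog)

  phen <- generate_phenotypes(catalog$mutation, config$hotspot_fraction,
                              seed = seed + 2L)
  conc <- with_seed(seed + 3L, {
    data.frame(mutation = catalog$mutation,
               c_m = rlnorm(nrow(catalog), config$conc_meanlog,
                            config$conc_sdlog),
               stringsAsFactors = FALSE)
  })
  ponc <- transactivation_to_ponc(phen$activities,
                                  c_m = setNames(conc$c_m, conc$mutation))

  retention <- pmin(rowMeans(phen$activities[, TA_TARGETS]) / 100, 1)
  immuno <- generate_immunopeptidome(catalog, gene$protein, phen$hotspot,
                                     config, seed = seed + 4L,
                                     retention = retention)
  imm <- immune_profile(catalog, gene$protein, immuno$affinities,
                        immuno$hap, c_m = conc$c_m, kappa = config$kappa,
                        n_draws = config$n_hap_draws, seed = seed + 5L)

  landscape <- free_fitness(catalog$p_background, ponc$p_onc, imm$p_pres,
                            config$sigma_t, config$sigma_i,
                            mutation = catalog$mutation,
                            protein_pos = catalog$protein_pos)
  counts <- generate_mutation_counts(landscape$q, config$n_mutation_draws,
                                     seed = seed + 6L)
  catalog$count <- counts
  cohort <- generate_cohort(landscape, config, seed = seed + 7L)

  list(gene = gene, rates = rates, nt_catalog = nt_catalog,
       catalog = catalog, phenotypes = phen, concentration = conc,
       p_onc = ponc, affinities = immuno$affinities, hap = immuno$hap,
       immune = imm, landscape = landscape, cohort = cohort,
       ground_truth = list(sigma_t = config$sigma_t,
                           sigma_i = config$sigma_i,
                           q = landscape$q, p_onc = ponc$p_onc,
                           p_pres = imm$p_pres, hotspot = phen$hotspot,
                           seed = seed))
}
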