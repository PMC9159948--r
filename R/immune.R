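#' Enumerate mutation-spanning neopeptides
#'
#' All peptides of the requested lengths that contain the mutated residue
#' and lie within the protein. For length `L` and mutation position `pos`
#' the window starts run from `max(1, pos - L + 1)` to
#' `min(pos, len - L + 1)`.
#'
#' @param protein Protein sequence (single string).
#' @param pos 1-based mutated position.
#' @param alt_aa Alternate residue (must differ from the reference).
#' @param lengths Peptide lengths (default 9, the MHC-I nonamer).
#' @return data.frame `peptide`, `start`, `length` (mutant residue
#'   substituted in every peptide).
#' @export
#' @examples
#' enumerate_neopeptides(strrep("A", 20), 10, "V")  # 9 nonamers
enumerate_neopeptides <- function(protein, pos, alt_aa, lengths = 9L) {
  len <- nchar(protein)
  if (pos < 1L || pos > len) stop_input("position out of protein range")
  ref <- substr(protein, pos, pos)
  if (identical(ref, alt_aa)) stop_input("alt_aa equals the reference residue")
  mutated <- protein
  substr(mutated, pos, pos) <- alt_aa
  out <- lapply(lengths, function(L) {
    starts <- seq.int(max(1L, pos - L + 1L), min(pos, len - L + 1L))
    starts <- starts[starts >= 1L & starts + L - 1L <= len]
    if (!length(starts)) return(NULL)
    data.frame(peptide = substring(mutated, starts, starts + L - 1L),
               start = starts, length = L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Peptide-allele dissociation constant table
#'
#' Sparse map from (peptide, HLA allele) to a predicted dissociation
#' constant in nM. Pairs absent from the table are treated as non-binders
#' at the cap `kd_cap` rather than erroring, since predictor exports are
#' sparse.
#'
#' @param df data.frame with columns `peptide`, `allele`, `kd_nm`.
#' @param kd_cap Non-binder cap in nM (default 50000).
#' @return An `affinity_table` object.
#' @export
affinity_table <- function(df, kd_cap = 50000) {
  need <- c("peptide", "allele", "kd_nm")
  if (!all(need %in% names(df))) {
    stop_input("affinity table needs columns ", paste(need, collapse = ", "))
  }
  kd <- pmin(as.numeric(df$kd_nm), kd_cap)
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop_input("dissociation constants must be positive and finite")
  }
  key <- paste(df$peptide, df$allele, sep = "|")
  if (anyDuplicated(key)) stop_input("duplicate peptide-allele pairs")
  structure(list(kd = setNames(kd, key), kd_cap = kd_cap),
            class = "affinity_table")
}

# Kd lookup, total: unknown pairs score the non-binder cap.
lookup_kd <- function(affinities, peptides, alleles) {
  kd <- affinities$kd[paste(peptides, alleles, sep = "|")]
  kd[is.na(kd)] <- affinities$kd_cap
  unname(kd)
}

#' Effective affinity of a set of binding channels
#'
#' Aggregates peptide-allele dissociation constants as independent parallel
#' binding channels: binding strengths (1/Kd) add, so
#' \deqn{K_{eff} = \left(\sum_i 1/K_{d,i}\right)^{-1}.}
#' Adding a channel can only decrease `K_eff` (improve presentation).
#'
#' @param kd_values Positive dissociation constants (nM).
#' @return Effective dissociation constant (nM).
#' @export
#' @examples
#' effective_affinity(c(500, 500))  # 250
effective_affinity <- function(kd_values) {
  if (!length(kd_values)) stop_input("no dissociation constants supplied")
  if (any(kd_values <= 0)) stop_input("dissociation constants must be positive")
  1 / sum(1 / kd_values)
}

#' Presentation probability from effective affinity
#'
#' Concentration-coupled saturation form:
#' \deqn{P_{pres} = \frac{1}{1 + K_{eff} / (c_m \kappa)}}
#' increasing in concentration, decreasing in `K_eff`. The scale
#' `kappa = 500` nM is the conventional MHC-I binder threshold, so a
#' mutation whose effective affinity sits at the threshold at reference
#' concentration is presented with probability one half.
#'
#' @param k_eff Effective dissociation constant (nM, > 0).
#' @param c_m Mutant concentration (> 0, relative units).
#' @param kappa Affinity scale in nM (default 500).
#' @return Probability in (0, 1). Vectorised.
#' @export
presentation_probability <- function(k_eff, c_m = 1, kappa = 500) {
  if (any(k_eff <= 0) || any(c_m <= 0) || any(kappa <= 0)) {
    stop_input("k_eff, c_m and kappa must be positive")
  }
  1 / (1 + k_eff / (c_m * kappa))
}

#' MHC-I haplotype model
#'
#' Either locus-wise allele frequencies (columns `locus` in A/B/C, `allele`,
#' `freq`; normalised per locus) from which 6-allele haplotypes are drawn
#' under Hardy-Weinberg independence, or an explicit list of haplotypes
#' (data.frame with 6 allele columns and a `weight` column).
#'
#' @param freqs Optional allele-frequency data.frame.
#' @param haplotypes Optional explicit haplotype data.frame.
#' @return A `haplotype_model` object.
#' @export
haplotype_model <- function(freqs = NULL, haplotypes = NULL) {
  if (is.null(freqs) == is.null(haplotypes)) {
    stop_input("supply exactly one of freqs or haplotypes")
  }
  if (!is.null(freqs)) {
    need <- c("locus", "allele", "freq")
    if (!all(need %in% names(freqs))) {
      stop_input("freqs needs columns ", paste(need, collapse = ", "))
    }
    if (any(freqs$freq < 0)) stop_input("negative allele frequency")
    loci <- split(freqs, freqs$locus)
    if (!setequal(names(loci), c("A", "B", "C"))) {
      stop_input("freqs must cover loci A, B and C")
    }
    loci <- lapply(loci, function(d) {
      tot <- sum(d$freq)
      if (tot <= 0) stop_input("locus with zero total frequency")
      d$freq <- d$freq / tot
      d
    })
    structure(list(type = "freqs", loci = loci[c("A", "B", "C")]),
              class = "haplotype_model")
  } else {
    acol <- grep("^allele", names(haplotypes), value = TRUE)
    if (length(acol) != 6L || !"weight" %in% names(haplotypes)) {
      stop_input("haplotypes needs 6 allele columns (allele1..allele6) and weight")
    }
    if (!nrow(haplotypes) || any(haplotypes$weight < 0) ||
        sum(haplotypes$weight) <= 0) {
      stop_input("haplotype weights must be non-negative with positive total")
    }
    structure(list(type = "explicit",
                   alleles = as.matrix(haplotypes[, acol]),
                   weight = haplotypes$weight / sum(haplotypes$weight)),
              class = "haplotype_model")
  }
}

#' Sample MHC-I haplotypes
#'
#' Draws `n` haplotypes of 6 alleles (2 per locus, sampled independently
#' with replacement from the locus frequencies) or weighted rows from an
#' explicit haplotype list.
#'
#' @param hap A [haplotype_model()].
#' @param n Number of draws.
#' @param seed Optional RNG seed for reproducibility.
#' @return Character matrix `n x 6`.
#' @export
sample_haplotypes <- function(hap, n, seed = NULL) {
  if (!inherits(hap, "haplotype_model")) stop_input("not a haplotype_model")
  if (n < 1L) stop_input("n must be >= 1")
  with_seed(seed, {
    if (hap$type == "freqs") {
      cols <- lapply(hap$loci, function(d) {
        matrix(sample(d$allele, 2L * n, replace = TRUE, prob = d$freq),
               ncol = 2L)
      })
      do.call(cbind, cols)
    } else {
      hap$alleles[sample.int(nrow(hap$alleles), n, replace = TRUE,
                             prob = hap$weight), , drop = FALSE]
    }
  })
}

#' Haplotype-averaged presentation probability of one mutation
#'
#' Monte Carlo average of the presentation probability over sampled MHC-I
#' haplotypes. For each haplotype, all peptide-allele channels over the six
#' allele slots (homozygous slots counted twice) are pooled by
#' [effective_affinity()] and converted with [presentation_probability()].
#'
#' @param peptides Neopeptide set from [enumerate_neopeptides()] (or a
#'   character vector of peptides).
#' @param affinities An [affinity_table()].
#' @param hap A [haplotype_model()].
#' @param c_m Mutant concentration (default 1).
#' @param kappa Affinity scale, nM (default 500).
#' @param n_draws Number of haplotype draws (default 1000).
#' @param seed Optional seed; the same seed and inputs give identical output.
#' @return List `p_pres_mean`, `p_pres_se` (Monte Carlo standard error),
#'   `k_eff` and `p_pres` per sampled haplotype, `n_draws`.
#' @export
haplotype_average <- function(peptides, affinities, hap, c_m = 1,
                              kappa = 500, n_draws = 1000L, seed = NULL) {
  peps <- if (is.data.frame(peptides)) peptides$peptide else peptides
  if (!length(peps)) stop_input("no peptides supplied")
  draws <- sample_haplotypes(hap, n_draws, seed = seed)
  alleles <- sort(unique(as.vector(draws)))
  # per-allele summed binding strength over the peptide set
  strength <- vapply(alleles, function(a) {
    sum(1 / lookup_kd(affinities, peps, rep(a, length(peps))))
  }, 0)
  inv_keff <- matrix(strength[match(draws, alleles)], nrow = nrow(draws))
  k_eff <- 1 / rowSums(inv_keff)
  p <- presentation_probability(k_eff, c_m = c_m, kappa = kappa)
  se <- if (length(p) > 1L) sd(p) / sqrt(length(p)) else 0
  list(p_pres_mean = mean(p), p_pres_se = se, k_eff = k_eff, p_pres = p,
       n_draws = n_draws)
}

#' Immune presentation profile over a protein-level catalog
#'
#' Computes the haplotype-averaged presentation probability for every
#' protein change in a catalog, sharing one set of haplotype draws across
#' mutations so that all mutations are scored against the same sampled
#' population.
#'
#' @param catalog Protein-level catalog (columns `mutation`, `protein_pos`,
#'   `alt_aa`), e.g. from [aggregate_protein()].
#' @param protein Reference protein sequence.
#' @param affinities An [affinity_table()].
#' @param hap A [haplotype_model()].
#' @param c_m Concentrations: single value or vector along the catalog.
#' @param kappa Affinity scale (nM).
#' @param lengths Peptide lengths (default 9).
#' @param n_draws Haplotype draws (default 1000).
#' @param seed Optional seed.
#' @return data.frame `mutation`, `p_pres`, `p_pres_se`, `k_eff_median`.
#' @export
immune_profile <- function(catalog, protein, affinities, hap, c_m = 1,
                           kappa = 500, lengths = 9L, n_draws = 1000L,
                           seed = NULL) {
  n <- nrow(catalog)
  conc <- rep_len(c_m, n)
  draws <- sample_haplotypes(hap, n_draws, seed = seed)
  alleles <- sort(unique(as.vector(draws)))
  idx <- matrix(match(draws, alleles), nrow = nrow(draws))
  out <- data.frame(mutation = catalog$mutation, p_pres = NA_real_,
                    p_pres_se = NA_real_, k_eff_median = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    peps <- enumerate_neopeptides(protein, catalog$protein_pos[i],
                                  catalog$alt_aa[i], lengths)$peptide
    strength <- vapply(alleles, function(a) {
      sum(1 / lookup_kd(affinities, peps, rep(a, length(peps))))
    }, 0)
    k_eff <- 1 / rowSums(matrix(strength[idx], nrow = nrow(idx)))
    p <- presentation_probability(k_eff, c_m = conc[i], kappa = kappa)
    out$p_pres[i] <- mean(p)
    out$p_pres_se[i] <- sd(p) / sqrt(length(p))
    out$k_eff_median[i] <- median(k_eff)
  }
  out
}

#' Read a peptide-allele affinity table from TSV
#' @param path TSV with columns `peptide`, `allele`, `kd_nm`.
#' @param kd_cap Non-binder cap (nM).
#' @return An [affinity_table()].
#' @export
read_affinity_tsv <- function(path, kd_cap = 50000) {
  affinity_table(read.delim(path, stringsAsFactors = FALSE), kd_cap = kd_cap)
}

#' Read locus-wise HLA allele frequencies from TSV
#' @param path TSV with columns `locus`, `allele`, `freq`.
#' @return A [haplotype_model()].
#' @export
read_allele_freq_tsv <- function(path) {
  haplotype_model(freqs = read.delim(path, stringsAsFactors = FALSE))
}
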