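#' Per-allele protein concentration of one sample
#'
#' Sample-level normalized abundance divided by the number of mutant gene
#' copies, giving the concentration contributed per mutant allele.
#'
#' @param abundance Normalized protein abundance (> 0, cohort-median wild
#'   type = 1). Vectorised.
#' @param copies Mutant allele copy number (integer >= 1). Vectorised.
#' @return Per-allele concentration(s).
#' @export
per_allele_concentration <- function(abundance, copies) {
  if (any(abundance <= 0)) stop_input("abundance must be positive")
  if (any(copies < 1) || any(copies != round(copies))) {
    stop_input("mutant copy number must be a positive integer")
  }
  abundance / copies
}

#' Typical per-allele concentration per mutation
#'
#' Median of per-allele concentrations over the samples carrying each
#' mutation; the median resists the heavy upper tail of mutant protein
#' accumulation. Mutations with no samples fall back to a default.
#'
#' @param samples data.frame with columns `mutation`, `abundance`,
#'   `mutant_copies` (and optionally `sample_id`).
#' @param mutations Mutations to report (default: those present).
#' @param default Concentration for mutations without samples (default 1).
#' @return data.frame `mutation`, `c_m`, `n_samples`, `default_flag`.
#' @export
mutant_concentration <- function(samples, mutations = NULL, default = 1) {
  need <- c("mutation", "abundance", "mutant_copies")
  if (!all(need %in% names(samples))) {
    stop_input("samples needs columns ", paste(need, collapse = ", "))
  }
  per <- per_allele_concentration(samples$abundance, samples$mutant_copies)
  mutations <- mutations %||% unique(samples$mutation)
  grp <- split(per, factor(samples$mutation, levels = mutations))
  n <- lengths(grp)
  c_m <- vapply(grp, function(v) if (length(v)) median(v) else default, 0)
  data.frame(mutation = mutations, c_m = unname(c_m), n_samples = unname(n),
             default_flag = unname(n) == 0L, stringsAsFactors = FALSE)
}

#' Concentration vs MDM2-promoter-affinity relationship
#'
#' Correlates log2 per-allele concentration with the effective MDM2-promoter
#' association constant across mutations; the biological expectation is an
#' inverse relationship (weaker MDM2 binding, less degradation, higher
#' mutant protein concentration).
#'
#' @param c_m Per-mutation concentrations (> 0).
#' @param k_mdm2 Per-mutation effective MDM2-promoter association constants.
#' @return List with `pearson_r`, `pearson_p`, `spearman_r`, `spearman_p`,
#'   `n`.
#' @export
concentration_affinity_trend <- function(c_m, k_mdm2) {
  ok <- is.finite(c_m) & is.finite(k_mdm2)
  x <- log2(c_m[ok]); y <- k_mdm2[ok]
  if (length(x) < 3L) stop_input("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_input("zero variance: correlation undefined")
  }
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x))
}

#' Read a sample abundance table
#' @param path TSV with columns `sample_id`, `mutation`, `abundance`,
#'   `mutant_copies`.
#' @return data.frame.
#' @export
read_sample_abundance_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
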