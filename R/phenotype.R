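#' The eight canonical p53 transactivation target promoters
#'
#' Order used throughout for transactivation tables.
#' @export
TA_TARGETS <- c("WAF1", "MDM2", "BAX", "h1433s", "AIP1", "GADD45",
                "NOXA", "P53R2")

#' Infer a relative association constant from transactivation activity
#'
#' Inverts a two-state binding isotherm. Wild-type activity (100%) is
#' assigned promoter occupancy `theta_wt` at reference concentration
#' `c_ref`; a mutant with activity `T` (% of wild type) has occupancy
#' `theta = theta_wt * T / 100`, clipped to `(theta_min, theta_max)` to keep
#' saturated assay readings (0% or >100%) finite, and its association
#' constant follows from `theta = c K / (1 + c K)`:
#' \deqn{K = \theta / (c_{ref} (1 - \theta))}
#' With the defaults, wild type maps to `K = 1`, the reference unit.
#'
#' @param t_percent Activity as percent of wild type (vectorised, >= 0).
#' @param theta_wt Wild-type occupancy at `c_ref` (default 0.5).
#' @param c_ref Reference concentration (default 1).
#' @param theta_min,theta_max Occupancy clipping bounds (0.005, 0.995).
#' @return Association constant(s), relative units (wild type = 1).
#' @export
#' @examples
#' infer_association_constant(c(100, 50, 0))
infer_association_constant <- function(t_percent, theta_wt = 0.5, c_ref = 1,
                                       theta_min = 0.005, theta_max = 0.995) {
  if (any(!is.na(t_percent) & t_percent < 0)) {
    stop_input("activities must be non-negative")
  }
  stopifnot(theta_wt > 0, theta_wt < 1, c_ref > 0)
  theta <- pmin(pmax(theta_wt * t_percent / 100, theta_min), theta_max)
  theta / (c_ref * (1 - theta))
}

#' Median association constant across transcriptional targets
#'
#' Summarises a mutation's inferred per-target association constants by
#' their median; missing targets are dropped, not imputed.
#'
#' @param k_values Numeric vector (or one-row slice) of per-target K values;
#'   may contain `NA` for missing targets.
#' @return The median K over available targets.
#' @export
median_activity <- function(k_values) {
  k <- k_values[is.finite(k_values)]
  if (!length(k)) stop_input("no finite association constants available")
  median(k)
}

#' Pro-oncogenic probability from binding occupancy
#'
#' The probability that the mutant protein fails to occupy its target sites
#' at concentration `c_m`: one minus the binding isotherm,
#' \deqn{P_{onc} = 1 - \frac{c K}{1 + c K} = \frac{1}{1 + c K}.}
#' Strictly decreasing in both `k_med` and `c_m`.
#'
#' @param k_med Median association constant (> 0), from [median_activity()].
#' @param c_m Per-allele mutant concentration (> 0), relative units.
#' @return Probability in (0, 1). Vectorised.
#' @export
#' @examples
#' oncogenic_probability(1, 1)   # 0.5
#' oncogenic_probability(1, 4)   # 0.2
oncogenic_probability <- function(k_med, c_m = 1) {
  if (any(k_med <= 0) || any(c_m <= 0)) {
    stop_input("k_med and c_m must be positive")
  }
  1 / (1 + c_m * k_med)
}

#' Transactivation table to pro-oncogenic probabilities
#'
#' Convenience pipeline: per-target association constants via
#' [infer_association_constant()], per-mutation median, then
#' [oncogenic_probability()] at the given concentrations.
#'
#' @param activities data.frame with a `mutation` column and one activity
#'   column (% of wild type) per target.
#' @param c_m Concentration per mutation: single value or named vector
#'   keyed by mutation id (unmatched mutations get 1).
#' @param targets Which columns are assay channels (default: all but
#'   `mutation`).
#' @param ... Passed to [infer_association_constant()].
#' @return data.frame `mutation`, `k_med`, `c_m`, `p_onc`.
#' @export
transactivation_to_ponc <- function(activities, c_m = 1, targets = NULL, ...) {
  if (!"mutation" %in% names(activities)) {
    stop_input("activities needs a 'mutation' column")
  }
  targets <- targets %||% setdiff(names(activities), "mutation")
  act <- as.matrix(activities[, targets, drop = FALSE])
  k <- infer_association_constant(act, ...)
  k_med <- apply(k, 1L, median_activity)
  conc <- if (length(c_m) == 1L && is.null(names(c_m))) {
    rep(c_m, nrow(activities))
  } else {
    ifelse(is.na(c_m[activities$mutation]), 1, c_m[activities$mutation])
  }
  data.frame(mutation = activities$mutation, k_med = k_med,
             c_m = as.numeric(conc),
             p_onc = oncogenic_probability(k_med, conc),
             stringsAsFactors = FALSE)
}

#' Column conservation score from a homologue alignment
#'
#' For genes without functional assay data, conservation stands in for the
#' functional phenotype. Gaps are excluded; the score is one minus the
#' Shannon entropy of residue frequencies normalised by `ln 20`:
#' a fully conserved column scores 1, a uniform column 0.
#'
#' @param column Character vector of residues in one alignment column
#'   (gap characters `-`, `.` and `X` ignored).
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' conservation_score(rep("R", 10))          # 1
#' conservation_score(c(rep("R", 8), "K", "K"))
conservation_score <- function(column) {
  res <- toupper(column[!column %in% c("-", ".", "X", NA)])
  if (!length(res)) stop_input("all-gap alignment column")
  p <- table(res) / length(res)
  h <- -sum(p * log(p))
  max(0, min(1, 1 - h / log(20)))
}

#' Per-position conservation profile of an alignment
#'
#' @param alignment Character matrix (rows = sequences, columns = positions)
#'   or a character vector of equal-length aligned sequences.
#' @return Numeric vector of [conservation_score()] per column.
#' @export
conservation_profile <- function(alignment) {
  if (!is.matrix(alignment)) {
    if (length(unique(nchar(alignment))) != 1L) {
      stop_input("aligned sequences must have equal length")
    }
    alignment <- do.call(rbind, strsplit(alignment, ""))
  }
  apply(alignment, 2L, conservation_score)
}

#' Read a transactivation assay table
#'
#' TSV with a mutation-id column (e.g. `"R175H"`) followed by one
#' percent-of-wild-type activity column per target promoter, matching the
#' usual yeast-assay export layout.
#' @param path TSV path.
#' @return data.frame with column `mutation` first.
#' @export
read_transactivation_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[1] <- "mutation"
  out
}
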