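# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: translation goes through seqinr, enumeration is
# a literal triple loop, the Pareto oracle is quadratic dominance checking,
# and distances are found by dense sampling along the front polyline.

oracle_translate <- function(cds) {
  paste(seqinr::translate(seqinr::s2c(cds)), collapse = "")
}

# Brute force over all 9L single-nucleotide substitutions, keeping changes
# that translate to a different non-stop residue.
oracle_enumerate <- function(cds, flank5, flank3) {
  bases <- strsplit(cds, "")[[1]]
  padded <- c(flank5, bases, flank3)
  out <- list()
  for (j in seq_along(bases)) {
    for (alt in setdiff(c("A", "C", "G", "T"), bases[j])) {
      mut <- bases
      mut[j] <- alt
      prot_ref <- oracle_translate(cds)
      prot_alt <- oracle_translate(paste(mut, collapse = ""))
      codon <- (j - 1) %/% 3 + 1
      ref_aa <- substr(prot_ref, codon, codon)
      alt_aa <- substr(prot_alt, codon, codon)
      if (alt_aa != ref_aa && alt_aa != "*") {
        out[[length(out) + 1L]] <- data.frame(
          nt_pos = j, alt = alt, protein_pos = codon,
          ref_aa = ref_aa, alt_aa = alt_aa,
          context = sprintf("%s[%s>%s]%s", padded[j], bases[j], alt,
                            padded[j + 2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# Random coding sequence without stop codons, built independently of the
# package generator.
oracle_random_cds <- function(n_codons) {
  repeat {
    cds <- paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
                 collapse = "")
    if (!grepl("\\*", oracle_translate(cds))) return(cds)
  }
}

# Quadratic dominance filter: maximal points when both axes are maximised.
oracle_pareto <- function(x, y) {
  n <- length(x)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (x[j] >= x[i] && y[j] >= y[i] && (x[j] > x[i] || y[j] > y[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# Minimum distance from (px, py) to the polyline through (vx, vy), found by
# exhaustive dense sampling along every segment.
oracle_polyline_dist <- function(px, py, vx, vy, n_samples = 2001L) {
  if (length(vx) == 1L) return(sqrt((px - vx)^2 + (py - vy)^2))
  best <- Inf
  for (s in seq_len(length(vx) - 1L)) {
    t <- seq(0, 1, length.out = n_samples)
    sx <- vx[s] + t * (vx[s + 1] - vx[s])
    sy <- vy[s] + t * (vy[s + 1] - vy[s])
    best <- min(best, sqrt((px - sx)^2 + (py - sy)^2))
  }
  best
}

# Two-sided binomial p-value by full enumeration under the
# minimum-likelihood convention.
oracle_binom_minlike <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}
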