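#' Enumerate all candidate missense mutations of a coding sequence
#'
#' Every single-nucleotide substitution of the CDS whose translated codon
#' changes the amino acid to a different non-stop residue becomes one
#' catalog entry. Synonymous and nonsense changes are excluded: the model's
#' support is missense mutations only. Entries from distinct nucleotide
#' changes that yield the same protein change (e.g. two routes to R175H)
#' are kept distinct at nucleotide level; use [aggregate_protein()] to sum
#' them per protein change.
#'
#' @param seq A [coding_sequence()].
#' @return A `mutation_catalog`: a data.frame with one row per candidate and
#'   columns `gene`, `mutation` (e.g. `"R175H"`), `protein_pos` (1-based),
#'   `ref_aa`, `alt_aa`, `codon_change` (e.g. `"CGT>CAT"`), `nt_pos`,
#'   `context` (trinucleotide context key), `count` (initialised to 0) and
#'   `p_background` (`NA` until [background_probability()] is applied).
#' @export
#' @examples
#' gene <- coding_sequence("demo", "ATGCGT", "A", "G")
#' nrow(enumerate_missense(gene))  # 15 candidates
enumerate_missense <- function(seq) {
  if (!inherits(seq, "coding_sequence")) {
    stop_input("seq must be a coding_sequence")
  }
  bases <- strsplit(seq$cds, "")[[1]]
  aas <- strsplit(seq$protein, "")[[1]]
  n <- length(bases)
  code <- Biostrings::GENETIC_CODE
  padded <- c(seq$flank5, bases, seq$flank3)

  # all 3n substitutions, filtered through the codon table
  nt_pos <- rep(seq_len(n), each = 3L)
  ref <- bases[nt_pos]
  alts <- unlist(lapply(ref[seq(1L, length(nt_pos), 3L)], function(b) {
    setdiff(c("A", "C", "G", "T"), b)
  }), use.names = FALSE)
  codon_idx <- (nt_pos - 1L) %/% 3L + 1L
  offset <- (nt_pos - 1L) %% 3L + 1L
  codon_start <- (codon_idx - 1L) * 3L + 1L
  ref_codon <- paste0(bases[codon_start], bases[codon_start + 1L],
                      bases[codon_start + 2L])
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- alts
  alt_aa <- unname(code[alt_codon])
  ref_aa <- aas[codon_idx]
  keep <- alt_aa != ref_aa & alt_aa != "*"

  context <- sprintf("%s[%s>%s]%s", padded[nt_pos], ref, alts,
                     padded[nt_pos + 2L])
  out <- data.frame(
    gene = seq$gene_id,
    mutation = paste0(ref_aa, codon_idx, alt_aa),
    protein_pos = codon_idx,
    ref_aa = ref_aa,
    alt_aa = alt_aa,
    codon_change = paste0(ref_codon, ">", alt_codon),
    nt_pos = nt_pos,
    context = context,
    count = 0L,
    p_background = NA_real_,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mutation_catalog", "data.frame")
  out
}

#' Assign normalized background probabilities from a context rate table
#'
#' Each candidate receives `p_m = rate(context_m) / sum(rate(context_m'))`
#' over all catalog entries, so that the background probabilities form a
#' distribution over the enumerated candidate set.
#'
#' @param catalog A catalog from [enumerate_missense()].
#' @param rates A [context_rate_table()].
#' @return The catalog with `p_background` filled in (sums to 1).
#' @export
background_probability <- function(catalog, rates) {
  if (!inherits(rates, "context_rate_table")) {
    stop_input("rates must be a context_rate_table")
  }
  r <- unclass(rates)[catalog$context]
  if (any(is.na(r))) stop_input("unresolvable context key in catalog")
  total <- sum(r)
  if (total <= 0) {
    stop_input("all applicable context rates are zero: degenerate background")
  }
  catalog$p_background <- as.numeric(r) / total
  catalog
}

#' Aggregate a catalog to protein-level mutations
#'
#' Sums counts and background probabilities over all nucleotide routes to
#' the same protein change (same position, same alternate residue), the
#' level at which phenotype and immune scores are defined.
#'
#' @param catalog A `mutation_catalog`.
#' @return A data.frame with one row per protein change: `gene`, `mutation`,
#'   `protein_pos`, `ref_aa`, `alt_aa`, `count`, `p_background`,
#'   `n_nt_routes`.
#' @export
aggregate_protein <- function(catalog) {
  key <- catalog$mutation
  idx <- split(seq_len(nrow(catalog)), factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(
      gene = catalog$gene[i[1]],
      mutation = catalog$mutation[i[1]],
      protein_pos = catalog$protein_pos[i[1]],
      ref_aa = catalog$ref_aa[i[1]],
      alt_aa = catalog$alt_aa[i[1]],
      count = sum(catalog$count[i]),
      p_background = sum(catalog$p_background[i]),
      n_nt_routes = length(i),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Attach observed mutation counts to a catalog
#'
#' Matches a table of observed occurrences (protein-change identifiers such
#' as `"R175H"` with counts) against the catalog. Observed counts for one
#' protein change reached by several nucleotide routes are apportioned to
#' routes proportionally to their background probability (equal split if
#' the background is not yet assigned); counts therefore stay integers only
#' at protein level.
#'
#' @param catalog A `mutation_catalog`.
#' @param observed data.frame with columns `mutation` and `count`.
#' @param unmatched `"warn"` (default) or `"error"` for observed mutations
#'   absent from the catalog.
#' @return The catalog with `count` updated.
#' @export
assign_counts <- function(catalog, observed, unmatched = c("warn", "error")) {
  unmatched <- match.arg(unmatched)
  if (!all(c("mutation", "count") %in% names(observed))) {
    stop_input("observed needs columns 'mutation' and 'count'")
  }
  if (any(observed$count < 0)) stop_input("counts must be non-negative")
  miss <- setdiff(observed$mutation, catalog$mutation)
  if (length(miss)) {
    msg <- sprintf("%d observed mutation(s) not in catalog (e.g. %s)",
                   length(miss), miss[1])
    if (unmatched == "error") stop_input(msg) else warning(msg, call. = FALSE)
  }
  catalog$count <- 0
  for (j in seq_len(nrow(observed))) {
    i <- which(catalog$mutation == observed$mutation[j])
    if (!length(i)) next
    w <- catalog$p_background[i]
    w <- if (all(is.na(w)) || sum(w) == 0) rep(1 / length(i), length(i)) else w / sum(w)
    catalog$count[i] <- catalog$count[i] + observed$count[j] * w
  }
  catalog
}

#' Write a mutation catalog to TSV
#' @param catalog A `mutation_catalog` or protein-level aggregate.
#' @param path Output path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutation catalog from TSV
#' @param path Path written by [write_catalog_tsv()].
#' @return A data.frame (classed `mutation_catalog` when nucleotide-level
#'   columns are present).
#' @export
read_catalog_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  if (all(c("nt_pos", "context") %in% names(out))) {
    class(out) <- c("mutation_catalog", "data.frame")
  }
  out
}
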