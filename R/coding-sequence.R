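#' Construct a coding sequence for mutation enumeration
#'
#' A `coding_sequence` holds the coding DNA of one gene together with the
#' single upstream and downstream nucleotides needed to resolve the
#' trinucleotide context of substitutions at the first and last coding
#' positions. The sequence must be a clean open reading frame: length
#' divisible by three, bases in ACGT only, and no stop codons (the terminal
#' stop is not part of the coding sequence here).
#'
#' @param gene_id Character scalar, gene identifier.
#' @param cds Coding DNA string (ACGT, length a positive multiple of 3,
#'   no stop codons).
#' @param flank5,flank3 Single nucleotides immediately 5' and 3' of the CDS.
#'   `N` or missing flanks are refused rather than guessed, since a wrong
#'   context silently corrupts background probabilities.
#' @return An object of class `coding_sequence` with fields `gene_id`,
#'   `cds`, `flank5`, `flank3` and `protein` (the translation).
#' @export
#' @examples
#' gene <- coding_sequence("demo", "ATGCGT", flank5 = "A", flank3 = "G")
#' gene$protein
coding_sequence <- function(gene_id, cds, flank5, flank3) {
  cds <- toupper(as.character(cds))
  if (!nzchar(cds)) stop_input("empty coding sequence")
  bases <- strsplit(cds, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop_input("coding sequence contains non-ACGT characters")
  }
  if (length(bases) %% 3L != 0L) {
    stop_input("coding sequence length must be divisible by 3")
  }
  for (fl in c(flank5, flank3)) {
    if (length(fl) != 1L || !toupper(fl) %in% c("A", "C", "G", "T")) {
      stop_input("flank5/flank3 must each be a single A, C, G or T ",
                 "(ambiguous flanks are refused)")
    }
  }
  protein <- translate_cds(cds)
  if (any(strsplit(protein, "")[[1]] == "*")) {
    stop_input("coding sequence contains a stop codon")
  }
  structure(
    list(gene_id = as.character(gene_id), cds = cds,
         flank5 = toupper(flank5), flank3 = toupper(flank3),
         protein = protein),
    class = "coding_sequence"
  )
}

# Translate an in-frame DNA string using the standard genetic code.
translate_cds <- function(cds) {
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt / %d aa (flanks %s..%s)\n",
              x$gene_id, nchar(x$cds), nchar(x$protein), x$flank5, x$flank3))
  invisible(x)
}

#' Read a coding sequence from a FASTA file
#'
#' Reads a single-record FASTA. Flanking bases are taken from `flank5=` /
#' `flank3=` tags in the header (e.g. `>TP53 flank5=G flank3=A`) unless
#' supplied explicitly, in which case the arguments win.
#'
#' @param path Path to a FASTA file with exactly one DNA record.
#' @param flank5,flank3 Optional flank overrides.
#' @return A [coding_sequence()].
#' @export
read_cds_fasta <- function(path, flank5 = NULL, flank3 = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) stop_input("expected exactly one FASTA record")
  header <- names(set)[1]
  tag <- function(name) {
    m <- regmatches(header, regexpr(paste0(name, "=[ACGTacgt]"), header))
    if (length(m)) sub(paste0(name, "="), "", m) else NULL
  }
  flank5 <- flank5 %||% tag("flank5")
  flank3 <- flank3 %||% tag("flank3")
  if (is.null(flank5) || is.null(flank3)) {
    stop_input("flank5/flank3 must be given in the header or as arguments")
  }
  gene_id <- sub("\\s.*$", "", header)
  coding_sequence(gene_id, as.character(set[[1]]), flank5, flank3)
}
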