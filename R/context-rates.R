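#' Trinucleotide-context substitution rate table
#'
#' Holds one non-negative rate per single-nucleotide substitution type in
#' its trinucleotide context, keyed as `"X[R>A]Y"` (5' base, ref > alt,
#' 3' base). Two dialects are accepted: the full 192-key table, and the
#' 96-key pyrimidine-strand convention used by COSMIC mutational signatures
#' (reference base C or T only), which is expanded to 192 keys by
#' reverse-complement so that lookup is total.
#'
#' @param rates Either a named numeric vector (names are context keys) or a
#'   data.frame with columns `context` and `rate`.
#' @param dialect `"auto"` (default), `"96"` or `"192"`.
#' @return An object of class `context_rate_table`: a named numeric vector
#'   of length 192 with attribute `dialect`.
#' @export
#' @examples
#' tbl <- uniform_context_rates()
#' tbl["A[C>T]G"]
context_rate_table <- function(rates, dialect = c("auto", "96", "192")) {
  dialect <- match.arg(dialect)
  if (is.data.frame(rates)) {
    if (!all(c("context", "rate") %in% names(rates))) {
      stop_input("rate table needs columns 'context' and 'rate'")
    }
    rates <- setNames(as.numeric(rates$rate), as.character(rates$context))
  }
  keys <- names(rates)
  if (is.null(keys) || anyDuplicated(keys)) {
    stop_input("rates must be uniquely named by context key")
  }
  if (!all(grepl("^[ACGT]\\[[ACGT]>[ACGT]\\][ACGT]$", keys))) {
    stop_input("malformed context key(s); expected e.g. \"A[C>T]G\"")
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop_input("all rates must be finite and non-negative")
  }
  refs <- substr(keys, 3L, 3L)
  if (dialect == "auto") {
    dialect <- if (all(refs %in% c("C", "T"))) "96" else "192"
  }
  if (dialect == "96") {
    if (!all(refs %in% c("C", "T"))) {
      stop_input("96-context dialect requires pyrimidine reference bases")
    }
    if (length(rates) != 96L) stop_input("96-context table must have 96 entries")
    full <- c(rates, setNames(rates, vapply(keys, revcomp_context, "")))
  } else {
    if (length(rates) != 192L) stop_input("192-context table must have 192 entries")
    full <- rates
  }
  if (length(full) != 192L || anyDuplicated(names(full))) {
    stop_input("rate table does not cover the 192 context keys exactly once")
  }
  if (all(full == 0)) stop_input("at least one rate must be positive")
  structure(full[order(names(full))], dialect = dialect,
            class = "context_rate_table")
}

# Reverse complement of a context key: "A[G>A]T" -> "A[C>T]T".
revcomp_context <- function(key) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sprintf("%s[%s>%s]%s",
          comp[substr(key, 7L, 7L)], comp[substr(key, 3L, 3L)],
          comp[substr(key, 5L, 5L)], comp[substr(key, 1L, 1L)])
}

all_context_keys <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(l = b, ref = b, alt = b, r = b, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  sort(sprintf("%s[%s>%s]%s", g$l, g$ref, g$alt, g$r))
}

#' Uniform context rate table
#'
#' All 192 substitution contexts at equal rate; background probabilities
#' computed from it are uniform over the candidate set.
#' @param rate Common rate value (default 1).
#' @return A [context_rate_table()].
#' @export
uniform_context_rates <- function(rate = 1) {
  context_rate_table(setNames(rep(rate, 192L), all_context_keys()),
                     dialect = "192")
}

#' Read a context rate table from TSV
#'
#' Expects columns `context` (e.g. `"A[C>T]G"`) and `rate`; 96- and
#' 192-entry dialects are auto-detected.
#' @param path TSV path.
#' @return A [context_rate_table()].
#' @export
read_rate_table_tsv <- function(path) {
  context_rate_table(read.delim(path, stringsAsFactors = FALSE))
}
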