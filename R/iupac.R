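# IUPAC nucleotide ambiguity codes: each code names a non-empty subset of
# {A, C, G, T}. The lookup is the canonical 15-code table; gaps and U are
# handled upstream (U -> T on input, '-' only in alignments).

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_KEY <- vapply(.IUPAC_SETS, function(b) paste(sort(b), collapse = ""),
                     character(1))

#' IUPAC code for a set of bases
#'
#' Returns the unique IUPAC nucleotide symbol whose expansion equals the
#' given base set. The mapping is a bijection over the 15 non-empty subsets
#' of `{A, C, G, T}`.
#'
#' @param bases Character vector, a non-empty subset of `c("A","C","G","T")`
#'   (duplicates allowed and ignored).
#' @return Single character, the IUPAC symbol.
#' @examples
#' iupac_for(c("A", "G"))      # "R"
#' iupac_for(c("C", "G", "T")) # "B"
#' @export
iupac_for <- function(bases) {
  if (length(bases) == 0L) {
    stop("iupac_for() requires a non-empty set of bases", call. = FALSE)
  }
  bases <- unique(toupper(bases))
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be a subset of {A, C, G, T}, got: ",
         paste(setdiff(bases, c("A", "C", "G", "T")), collapse = ","),
         call. = FALSE)
  }
  key <- paste(sort(bases), collapse = "")
  names(.IUPAC_KEY)[match(key, .IUPAC_KEY)]
}

#' Expand an IUPAC symbol to its base set
#'
#' @param symbol Single IUPAC nucleotide character.
#' @return Character vector of concrete bases (subset of A/C/G/T).
#' @export
iupac_expand <- function(symbol) {
  symbol <- toupper(symbol)
  if (symbol == "U") symbol <- "T"
  bases <- .IUPAC_SETS[[symbol]]
  if (is.null(bases)) {
    stop("not an IUPAC nucleotide code: '", symbol, "'", call. = FALSE)
  }
  bases
}

.IUPAC_CARD <- vapply(.IUPAC_SETS, length, integer(1))

# symmetric 15x15 lookup: do two IUPAC symbols share a base?
.IUPAC_COMPAT <- outer(names(.IUPAC_SETS), names(.IUPAC_SETS),
                       Vectorize(function(a, b) {
                         length(intersect(.IUPAC_SETS[[a]],
                                          .IUPAC_SETS[[b]])) > 0L
                       }))
dimnames(.IUPAC_COMPAT) <- list(names(.IUPAC_SETS), names(.IUPAC_SETS))

#' Number of degenerate positions in an IUPAC string
#'
#' Counts positions whose symbol expands to more than one base.
#'
#' @param seq IUPAC nucleotide string.
#' @return Integer count.
#' @export
count_degenerate <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  card <- .IUPAC_CARD[chars]
  if (anyNA(card)) {
    stop("not an IUPAC nucleotide string: '", seq, "'", call. = FALSE)
  }
  sum(card > 1L)
}

#' Degeneracy (number of concrete expansions) of an IUPAC string
#'
#' @param seq IUPAC nucleotide string.
#' @return Numeric product of per-position cardinalities.
#' @export
degeneracy <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  card <- .IUPAC_CARD[chars]
  if (anyNA(card)) {
    stop("not an IUPAC nucleotide string: '", seq, "'", call. = FALSE)
  }
  prod(as.numeric(card))
}

#' Enumerate all concrete expansions of a degenerate sequence
#'
#' Expands every IUPAC ambiguity position to each of its bases and returns
#' the full Cartesian product. Refuses to expand past `cap` to guard against
#' combinatorial blow-up on long degenerate stretches.
#'
#' @param seq IUPAC nucleotide string.
#' @param cap Maximum number of expansions allowed (default 256).
#' @return Character vector of concrete A/C/G/T sequences.
#' @export
expand_degenerate <- function(seq, cap = 256L) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sets <- lapply(chars, iupac_expand)
  n <- prod(vapply(sets, length, numeric(1)))
  if (n > cap) {
    stop("degenerate expansion of '", seq, "' has ", n,
         " realizations, above the cap of ", cap, call. = FALSE)
  }
  out <- ""
  for (s in sets) {
    out <- as.vector(outer(out, s, paste0))
  }
  out
}

#' Reverse complement of an IUPAC string
#'
#' @param seq IUPAC nucleotide string.
#' @return Reverse-complemented string (IUPAC-aware).
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# TRUE when the IUPAC base sets of two symbols intersect; used for
# probe/template matching where degenerate positions match by intersection.
.iupac_compatible <- function(a, b) {
  .IUPAC_COMPAT[a, b]
}
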