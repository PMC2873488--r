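# Aligned 16S target groups and IUPAC consensus extraction.
#
# An aligned group is a set of equal-length gapped sequences for one
# taxonomic target (positive set) or for its discrimination background
# (negative set). Consensus extraction follows a majority cutoff: a column
# is called as its dominant base when that base reaches the cutoff
# frequency; otherwise the column is coded with the IUPAC symbol covering
# every base above a minor-frequency floor.

.align_alphabet <- function() c(names(.IUPAC_SETS), "U", "-", ".")

#' Construct an aligned sequence group
#'
#' @param group_name Group label.
#' @param sequences Character vector of equal-length aligned sequences
#'   (IUPAC codes plus `-`/`.` gaps; `U` is normalized to `T`, case is
#'   normalized to upper).
#' @param member_ids Sequence identifiers (defaults to names of
#'   `sequences` or seq_1..seq_n).
#' @param role `"positive"` or `"negative"`.
#' @return An `aligned_group` object.
#' @export
aligned_group <- function(group_name, sequences, member_ids = NULL,
                          role = c("positive", "negative")) {
  role <- match.arg(role)
  if (length(sequences) == 0L) {
    stop("aligned group '", group_name, "' is empty", call. = FALSE)
  }
  sequences <- chartr("u", "U", toupper(sequences))
  sequences <- chartr("U", "T", sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop("alignment error: sequences in group '", group_name,
         "' have unequal lengths (", paste(unique(widths), collapse = ", "),
         ")", call. = FALSE)
  }
  if (widths[1] == 0L) {
    stop("alignment error: zero-length alignment in group '", group_name,
         "'", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(paste(sequences, collapse = ""), "",
                                 fixed = TRUE)[[1]]), .align_alphabet())
  if (length(bad) > 0L) {
    stop("alphabet error: illegal characters in group '", group_name,
         "': ", paste(bad, collapse = " "), call. = FALSE)
  }
  if (is.null(member_ids)) {
    member_ids <- names(sequences)
    if (is.null(member_ids)) {
      member_ids <- paste0("seq_", seq_along(sequences))
    }
  }
  structure(
    list(group_name = group_name,
         sequences = unname(sequences),
         member_ids = member_ids,
         role = role),
    class = "aligned_group"
  )
}

#' @export
print.aligned_group <- function(x, ...) {
  cat("Aligned group '", x$group_name, "' (", x$role, "): ",
      length(x$sequences), " sequences x ", nchar(x$sequences[1]),
      " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned multi-FASTA file as a group
#'
#' Reads a gapped multi-FASTA alignment and validates it (equal lengths,
#' IUPAC alphabet). Lowercase is accepted and uppercased; `U` becomes `T`.
#'
#' @param path FASTA file path.
#' @param group_name Group label (defaults to the file stem).
#' @param role `"positive"` or `"negative"`.
#' @return An `aligned_group`.
#' @export
read_alignment <- function(path, group_name = NULL,
                           role = c("positive", "negative")) {
  role <- match.arg(role)
  if (!file.exists(path)) {
    stop("input error: no such file: ", path, call. = FALSE)
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    stop("input error: no FASTA records in ", path, call. = FALSE)
  }
  if (is.null(group_name)) {
    group_name <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  }
  ids <- sub("\\s.*$", "", names(ss))
  aligned_group(group_name, as.character(ss), member_ids = ids, role = role)
}

#' Read a group manifest
#'
#' The manifest is a TSV with columns `group_name`, `role`
#' (positive/negative) and `fasta_path` (relative paths resolved against
#' the manifest's directory). Optional column `level`
#' (`"family"`/`"genus"`) feeds the hierarchical negative-set rule in
#' [design_probe_set()].
#'
#' @param path Manifest TSV path.
#' @return List of `aligned_group` objects; `level` attribute set when the
#'   column is present.
#' @export
read_group_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group_name", "role", "fasta_path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    fp <- man$fasta_path[i]
    if (!file.exists(fp)) fp <- file.path(base, man$fasta_path[i])
    g <- read_alignment(fp, group_name = man$group_name[i],
                        role = man$role[i])
    if ("level" %in% names(man)) attr(g, "level") <- man$level[i]
    g
  })
}

#' Extract a group consensus with IUPAC ambiguity coding
#'
#' Per alignment column: when the most frequent base reaches `cutoff`
#' (default 0.75), that base is emitted; otherwise the IUPAC code covering
#' every base with frequency at least `minor_floor` is emitted. Gap
#' handling: columns whose gap frequency reaches `cutoff` are dropped;
#' in all other columns gaps are ignored and base frequencies renormalized
#' over real characters. Ties at the cutoff resolve to the ambiguity code
#' of all tied bases, independent of input order. IUPAC symbols in the
#' input contribute fractionally to each of their bases.
#'
#' @param group An `aligned_group`.
#' @param cutoff Base-calling majority cutoff in (0.5, 1] (default 0.75).
#' @param minor_floor Minimum frequency for a base to enter the ambiguity
#'   code (default 0.05); must be < `cutoff`.
#' @return A `consensus_sequence`: list with `group_name`, `consensus`
#'   (ungapped IUPAC string), `column_frequencies` (4 x L matrix over kept
#'   columns), `kept_columns` (original alignment indices), `cutoff`,
#'   `minor_floor`.
#' @export
extract_consensus <- function(group, cutoff = 0.75, minor_floor = 0.05) {
  stopifnot(inherits(group, "aligned_group"))
  if (!(cutoff > 0.5 && cutoff <= 1)) {
    stop("cutoff must lie in (0.5, 1]", call. = FALSE)
  }
  if (!(minor_floor >= 0 && minor_floor < cutoff)) {
    stop("minor_floor must lie in [0, cutoff)", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(group$sequences, "", fixed = TRUE))
  n <- nrow(mat)
  L <- ncol(mat)
  bases <- c("A", "C", "G", "T")
  freq <- matrix(0, nrow = 4L, ncol = L, dimnames = list(bases, NULL))
  gapf <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    isgap <- col %in% c("-", ".")
    gapf[j] <- mean(isgap)
    real <- col[!isgap]
    if (length(real) > 0L) {
      for (ch in real) {
        ex <- iupac_expand(ch)
        freq[ex, j] <- freq[ex, j] + 1 / length(ex)
      }
      freq[, j] <- freq[, j] / length(real)
    }
  }
  keep <- gapf < cutoff
  if (!any(keep)) {
    stop("degenerate alignment: every column is gap-dominated", call. = FALSE)
  }
  cons <- character(sum(keep))
  kidx <- which(keep)
  for (k in seq_along(kidx)) {
    f <- freq[, kidx[k]]
    if (sum(f) == 0) {
      stop("degenerate column ", kidx[k], ": no countable characters",
           call. = FALSE)
    }
    top <- max(f)
    winners <- bases[f >= top - 1e-12]
    if (top >= cutoff - 1e-12 && length(winners) == 1L) {
      cons[k] <- winners
    } else {
      above <- bases[f >= minor_floor - 1e-12]
      if (length(above) == 0L) above <- winners
      cons[k] <- iupac_for(above)
    }
  }
  structure(
    list(group_name = group$group_name,
         consensus = paste(cons, collapse = ""),
         column_frequencies = freq[, keep, drop = FALSE],
         kept_columns = kidx,
         cutoff = cutoff,
         minor_floor = minor_floor),
    class = "consensus_sequence"
  )
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat("Consensus for '", x$group_name, "': ", nchar(x$consensus),
      " nt, cutoff ", x$cutoff, ", ", count_degenerate(x$consensus),
      " degenerate positions\n", sep = "")
  invisible(x)
}

#' Write a consensus to FASTA plus a frequency sidecar TSV
#'
#' @param cons A `consensus_sequence`.
#' @param fasta_path Output FASTA path.
#' @param freq_path Optional sidecar TSV path for the per-column base
#'   frequency table.
#' @return Invisibly, `fasta_path`.
#' @export
write_consensus <- function(cons, fasta_path, freq_path = NULL) {
  stopifnot(inherits(cons, "consensus_sequence"))
  writeLines(c(paste0(">", cons$group_name), cons$consensus), fasta_path)
  if (!is.null(freq_path)) {
    df <- data.frame(column = cons$kept_columns,
                     t(cons$column_frequencies))
    names(df) <- c("column", "A", "C", "G", "T")
    utils::write.table(df, freq_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Remove gap characters from a sequence
#'
#' @param seq Gapped sequence string.
#' @return Ungapped string.
#' @export
degap <- function(seq) {
  gsub("[-.]", "", seq)
}
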