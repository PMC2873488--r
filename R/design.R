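# Discriminating Probe / Common Probe pair design.
#
# On an ungapped group consensus, a probe pair is a pair of adjacent
# windows: the Discriminating Probe (DS, 5'-labelled) whose 3'-terminal
# base sits on the discriminating position, and the Common Probe (CP,
# 5'-phosphate, cZipCode tail) starting at the next template base. The
# ligase seals the DS/CP junction only on a perfectly matching template,
# so specificity is enforced at the DS 3' end: every positive-set sequence
# must match the full DS+CP footprint, and every negative-set sequence
# must carry at least one mismatch inside the discrimination window at the
# DS 3' end wherever the rest of the footprint matches.

#' Probe design constraints
#'
#' @param min_len Minimum probe length in nt (default 25).
#' @param max_len Maximum probe length in nt (default 60).
#' @param tm_target Target melting temperature in C (default 68).
#' @param tm_tol Allowed deviation from `tm_target` in C (default 1).
#' @param max_degenerate Maximum degenerate bases per probe (default 4).
#' @param discrimination_window Number of bases at the DS 3' end that must
#'   mismatch the negative set (default 1, the 3'-terminal base).
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(min_len = 25L, max_len = 60L,
                               tm_target = 68, tm_tol = 1,
                               max_degenerate = 4L,
                               discrimination_window = 1L) {
  stopifnot(min_len <= max_len, tm_tol > 0, max_degenerate >= 0,
            discrimination_window >= 1L)
  structure(list(min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 tm_target = tm_target, tm_tol = tm_tol,
                 max_degenerate = as.integer(max_degenerate),
                 discrimination_window = as.integer(discrimination_window)),
            class = "design_constraints")
}

.probe_pair_row <- function(probe_id, target_group, level, ds_seq, cp_seq,
                            template_position, zipcode_id = NA_character_) {
  data.frame(probe_id = probe_id, target_group = target_group,
             level = level, ds_seq = ds_seq, cp_seq = cp_seq,
             ds_tm = melting_temperature(ds_seq),
             cp_tm = melting_temperature(cp_seq),
             ds_degenerate = count_degenerate(ds_seq),
             cp_degenerate = count_degenerate(cp_seq),
             zipcode_id = zipcode_id,
             template_position = as.integer(template_position),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate probe pairs on a consensus
#'
#' Scans every (position, DS length, CP length) triple on the ungapped
#' consensus and keeps the pairs where both probes satisfy the length,
#' melting-temperature and degeneracy constraints, with the CP annealing
#' immediately 3'-adjacent to the DS (junction gap 0). Candidates are
#' ordered by distance of the pair's mean Tm from the target, then by
#' total degenerate bases, then by leftmost template position: a total,
#' deterministic order.
#'
#' @param consensus A `consensus_sequence` or an IUPAC string.
#' @param constraints A [design_constraints()] list.
#' @return A `probe_set` data frame of candidates (possibly empty), one
#'   row per pair.
#' @export
enumerate_candidates <- function(consensus, constraints = design_constraints()) {
  seq <- if (inherits(consensus, "consensus_sequence")) {
    consensus$consensus
  } else {
    toupper(as.character(consensus))
  }
  gname <- if (inherits(consensus, "consensus_sequence")) {
    consensus$group_name
  } else {
    "consensus"
  }
  L <- nchar(seq)
  cn <- constraints
  ds_v <- character(0); cp_v <- character(0); pos_v <- integer(0)
  ds_tm_v <- numeric(0); cp_tm_v <- numeric(0)
  ds_dg_v <- integer(0); cp_dg_v <- integer(0)
  if (L >= 2L * cn$min_len) {
    # a window is admissible when its degeneracy is within constraints
    # and its Tm is inside the target band; window scores come from the
    # cumulative-sum scorer in O(1) for concrete windows
    scorer <- .tm_window_scorer(seq)
    score <- function(i, j) {
      sc <- scorer(i, j)
      sc$ok <- sc$deg <= cn$max_degenerate && !is.na(sc$tm) &&
        abs(sc$tm - cn$tm_target) <= cn$tm_tol
      sc
    }
    for (start in seq_len(L - 2L * cn$min_len + 1L)) {
      for (ds_len in cn$min_len:cn$max_len) {
        junction <- start + ds_len - 1L
        if (junction + cn$min_len > L) break
        ds_sc <- score(start, junction)
        if (!ds_sc$ok) next
        for (cp_len in cn$min_len:cn$max_len) {
          cp_end <- junction + cp_len
          if (cp_end > L) break
          cp_sc <- score(junction + 1L, cp_end)
          if (!cp_sc$ok) next
          k <- length(ds_v) + 1L
          ds_v[k] <- substr(seq, start, junction)
          cp_v[k] <- substr(seq, junction + 1L, cp_end)
          pos_v[k] <- start
          ds_tm_v[k] <- ds_sc$tm; cp_tm_v[k] <- cp_sc$tm
          ds_dg_v[k] <- ds_sc$deg; cp_dg_v[k] <- cp_sc$deg
        }
      }
    }
  }
  out <- data.frame(
    probe_id = character(length(ds_v)),
    target_group = rep(gname, length(ds_v)),
    level = rep("probe", length(ds_v)),
    ds_seq = ds_v, cp_seq = cp_v,
    ds_tm = ds_tm_v, cp_tm = cp_tm_v,
    ds_degenerate = ds_dg_v, cp_degenerate = cp_dg_v,
    zipcode_id = rep(NA_character_, length(ds_v)),
    template_position = pos_v, stringsAsFactors = FALSE
  )
  if (nrow(out) > 0L) {
    key1 <- abs((out$ds_tm + out$cp_tm) / 2 - cn$tm_target)
    key2 <- out$ds_degenerate + out$cp_degenerate
    out <- out[order(key1, key2, out$template_position,
                     nchar(out$ds_seq), nchar(out$cp_seq)), , drop = FALSE]
    out$probe_id <- sprintf("%s_c%04d", out$target_group, seq_len(nrow(out)))
    rownames(out) <- NULL
  }
  class(out) <- c("probe_set", "data.frame")
  out
}

# All template offsets (1-based) where the probe footprint (DS followed
# by CP) anneals. Degenerate positions match by IUPAC intersection. The
# junction window (last `window` bases of DS) must match exactly; at most
# `body_tol` mismatches are tolerated elsewhere. The zero-tolerance case
# (a full-footprint match) is delegated to Biostrings ambiguity matching.
.probe_match_positions <- function(template, ds, cp, window = 1L,
                                   body_tol = 0L) {
  template <- toupper(template)
  probe <- toupper(paste0(ds, cp))
  n <- nchar(probe)
  if (nchar(template) < n) return(integer(0))
  if (body_tol == 0L) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(probe),
                                     Biostrings::DNAString(template),
                                     fixed = FALSE)
    return(Biostrings::start(hits))
  }
  tchars <- strsplit(template, "", fixed = TRUE)[[1]]
  pchars <- strsplit(probe, "", fixed = TRUE)[[1]]
  win_idx <- (nchar(ds) - window + 1L):nchar(ds)
  span <- length(tchars) - n + 1L
  # per-offset mismatch profile via the compatibility lookup matrix
  ok <- vapply(seq_len(span), function(p) {
    comp <- .IUPAC_COMPAT[cbind(pchars, tchars[p:(p + n - 1L)])]
    all(comp[win_idx]) && sum(!comp) <= body_tol
  }, logical(1))
  which(ok)
}

#' Check a probe pair's specificity against positive and negative sets
#'
#' A positive hit requires the DS+CP footprint to match the sequence
#' exactly (IUPAC intersection at degenerate positions) somewhere along
#' its length. A negative violation is a negative-set sequence on which
#' the footprint anneals with the discrimination window at the DS 3' end
#' fully matched, i.e. the ligase would seal the junction. Positive-set
#' sequences whose footprint region contains gaps are skipped and
#' reported.
#'
#' @param pair One-row `probe_set` data frame (or list with `ds_seq`,
#'   `cp_seq`, `probe_id`).
#' @param positives Named character vector of positive-set sequences
#'   (gapped sequences are degapped).
#' @param negatives Named character vector of negative-set sequences.
#' @param constraints A [design_constraints()] list (supplies the
#'   discrimination window).
#' @param body_mismatch_tolerance Mismatches tolerated outside the
#'   junction window when scanning negatives (default 0: a violation is a
#'   full-footprint match).
#' @return A `match_report` list: `probe_id`, `positive_hits`,
#'   `positive_misses`, `skipped_gapped`, `negative_violations`, `pass`.
#' @export
check_specificity <- function(pair, positives, negatives = character(0),
                              constraints = design_constraints(),
                              body_mismatch_tolerance = 0L) {
  if (length(positives) == 0L) {
    stop("positive set is empty", call. = FALSE)
  }
  ds <- pair$ds_seq
  cp <- pair$cp_seq
  window <- constraints$discrimination_window
  ids_pos <- names(positives)
  if (is.null(ids_pos)) ids_pos <- paste0("pos_", seq_along(positives))
  hits <- character(0); misses <- character(0); skipped <- character(0)
  for (i in seq_along(positives)) {
    raw <- positives[[i]]
    s <- degap(raw)
    if (length(.probe_match_positions(s, ds, cp, window, 0L)) > 0L) {
      hits <- c(hits, ids_pos[i])
    } else if (nchar(s) < nchar(raw)) {
      # gapped member with no footprint match: alignment artifact, not a
      # design failure -- reported separately
      skipped <- c(skipped, ids_pos[i])
    } else {
      misses <- c(misses, ids_pos[i])
    }
  }
  ids_neg <- names(negatives)
  if (is.null(ids_neg) && length(negatives) > 0L) {
    ids_neg <- paste0("neg_", seq_along(negatives))
  }
  viol <- character(0)
  for (i in seq_along(negatives)) {
    s <- degap(negatives[[i]])
    if (length(.probe_match_positions(s, ds, cp, window,
                                      body_mismatch_tolerance)) > 0L) {
      viol <- c(viol, ids_neg[i])
    }
  }
  structure(list(probe_id = pair$probe_id,
                 positive_hits = hits,
                 positive_misses = misses,
                 skipped_gapped = skipped,
                 negative_violations = viol,
                 pass = length(misses) == 0L && length(viol) == 0L),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("Probe ", x$probe_id, ": ", length(x$positive_hits), " positive hits, ",
      length(x$positive_misses), " misses, ",
      length(x$negative_violations), " negative violations -> ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' Design one probe pair per target group
#'
#' For each group the group consensus is extracted (unless supplied),
#' candidates are enumerated under the constraints, and the best-ranked
#' candidate passing [check_specificity()] against the group's positive
#' members and its negative set is retained. Groups with no passing
#' candidate are reported as failures. The negative set respects the
#' design hierarchy: for family/phylum-level groups the negatives are the
#' consensus sequences of the other family/phylum groups; for
#' genus/species-level groups they are the member sequences of groups from
#' other families.
#'
#' @param groups List of group specifications; each element is a list with
#'   `positive` (an `aligned_group`), optional `negatives` (named
#'   character vector of sequences; when omitted it is built from the
#'   other groups per the hierarchy rule), optional `level` (`"family"` or
#'   `"genus"`, default `"family"`), optional `family` (label used to
#'   exclude same-family groups from genus-level negatives), and optional
#'   `consensus`.
#' @param constraints A [design_constraints()] list.
#' @param cutoff,minor_floor Consensus extraction parameters.
#' @param max_candidates_checked Cap on specificity checks per group
#'   (candidates are ranked, so the cap truncates the tail; default 200).
#' @return List with `probes` (a `probe_set` data frame of passing pairs)
#'   and `failures` (character vector of group names without a passing
#'   candidate).
#' @export
design_probe_set <- function(groups, constraints = design_constraints(),
                             cutoff = 0.75, minor_floor = 0.05,
                             max_candidates_checked = 200L) {
  if (length(groups) == 0L) stop("no groups supplied", call. = FALSE)
  specs <- lapply(groups, function(g) {
    if (inherits(g, "aligned_group")) g <- list(positive = g)
    stopifnot(inherits(g$positive, "aligned_group"))
    if (is.null(g$level)) g$level <- "family"
    if (is.null(g$family)) g$family <- g$positive$group_name
    if (is.null(g$consensus)) {
      g$consensus <- extract_consensus(g$positive, cutoff, minor_floor)
    }
    g
  })
  names(specs) <- vapply(specs, function(g) g$positive$group_name,
                         character(1))
  rows <- list()
  failures <- character(0)
  for (g in specs) {
    negatives <- g$negatives
    if (is.null(negatives)) {
      others <- specs[setdiff(names(specs), g$positive$group_name)]
      if (identical(g$level, "genus")) {
        others <- others[vapply(others, function(o) o$family != g$family,
                                logical(1))]
        negatives <- unlist(lapply(others, function(o) {
          s <- vapply(o$positive$sequences, degap, character(1))
          names(s) <- o$positive$member_ids
          s
        }))
      } else {
        negatives <- vapply(others, function(o) degap(o$consensus$consensus),
                            character(1))
      }
      if (is.null(negatives)) negatives <- character(0)
    }
    positives <- vapply(g$positive$sequences, degap, character(1))
    names(positives) <- g$positive$member_ids
    cands <- enumerate_candidates(g$consensus, constraints)
    found <- FALSE
    if (nrow(cands) > 0L) {
      n_check <- min(nrow(cands), max_candidates_checked)
      for (i in seq_len(n_check)) {
        rep <- check_specificity(cands[i, ], positives, negatives,
                                 constraints)
        if (rep$pass) {
          row <- cands[i, ]
          row$probe_id <- g$positive$group_name
          row$level <- if (identical(g$level, "genus")) "sub-probe" else "probe"
          rows[[length(rows) + 1L]] <- row
          found <- TRUE
          break
        }
      }
    }
    if (!found) failures <- c(failures, g$positive$group_name)
  }
  probes <- if (length(rows) == 0L) {
    enumerate_candidates("A", design_constraints())  # empty probe_set
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("probe_set", "data.frame")
    out
  }
  list(probes = probes, failures = failures)
}

#' Summary statistics of a probe set
#'
#' Mean and standard deviation of melting temperature and length over all
#' DS and CP oligonucleotides (each pair contributes two oligos), and the
#' count of pairs with no degenerate base.
#'
#' @param probes A `probe_set` data frame.
#' @return List: `n_pairs`, `n_oligos`, `tm_mean`, `tm_sd`, `length_mean`,
#'   `length_sd`, `n_nondegenerate_pairs`.
#' @export
probe_set_summary <- function(probes) {
  if (nrow(probes) == 0L) stop("empty probe set", call. = FALSE)
  tms <- c(probes$ds_tm, probes$cp_tm)
  lens <- c(nchar(probes$ds_seq), nchar(probes$cp_seq))
  list(n_pairs = nrow(probes),
       n_oligos = length(tms),
       tm_mean = mean(tms),
       tm_sd = stats::sd(tms),
       length_mean = mean(lens),
       length_sd = stats::sd(lens),
       n_nondegenerate_pairs =
         sum(probes$ds_degenerate + probes$cp_degenerate == 0L))
}

#' Write / read a probe-set TSV
#'
#' Columns: probe_id, target_group, level, ds_seq, cp_seq, ds_tm, cp_tm,
#' ds_degenerate, cp_degenerate, zipcode_id, template_position.
#'
#' @param probes A `probe_set` data frame.
#' @param path Output TSV path.
#' @return Invisibly, `path` (write) / a `probe_set` (read).
#' @export
write_probe_set <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_set
#' @export
read_probe_set <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(zipcode_id = "character"))
  class(out) <- c("probe_set", "data.frame")
  out
}
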