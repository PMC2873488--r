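# Sample fingerprints: presence/absence profiles over the probe set,
# relative fluorescence contributions, Ward clustering and replicate
# reproducibility.

#' Binary presence/absence fingerprint of a sample
#'
#' @param calls A `call_table` for one sample (one row per probe).
#' @param probe_order Optional character vector fixing the probe order
#'   shared across samples (default: order of appearance).
#' @return Named integer vector of 0/1 over probes.
#' @export
binary_fingerprint <- function(calls, probe_order = NULL) {
  if (is.null(probe_order)) probe_order <- unique(calls$probe_id)
  idx <- match(probe_order, calls$probe_id)
  if (anyNA(idx)) {
    stop("schema error: calls missing probes: ",
         paste(probe_order[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.integer(calls$present[idx]), probe_order)
}

#' Relative fluorescence contributions of a sample
#'
#' Averages each probe's mean intensity over one or two replicate
#' experiments, drops sub-probes (finer-resolution probes nested inside a
#' broader group probe, which would double-count their parent's signal),
#' and scales to percent of the total.
#'
#' @param call_tables A `call_table` or list of 1-2 of them (technical
#'   replicates of the same sample).
#' @param sub_probes Character vector of probe_ids to exclude (default
#'   none).
#' @return Named numeric vector of percentages over included probes,
#'   summing to 100.
#' @export
relative_contributions <- function(call_tables, sub_probes = character(0)) {
  if (inherits(call_tables, "data.frame")) call_tables <- list(call_tables)
  stopifnot(length(call_tables) >= 1L, length(call_tables) <= 2L)
  order1 <- unique(call_tables[[1]]$probe_id)
  ifs <- sapply(call_tables, function(ct) {
    ct$mean_if[match(order1, ct$probe_id)]
  })
  mean_if <- rowMeans(as.matrix(ifs))
  names(mean_if) <- order1
  keep <- setdiff(order1, sub_probes)
  v <- mean_if[keep]
  total <- sum(v)
  if (!is.finite(total) || total <= 0) {
    stop("degenerate-sample error: total intensity is zero", call. = FALSE)
  }
  100 * v / total
}

#' Hierarchical clustering of sample fingerprints
#'
#' Euclidean distance between sample profiles, Ward agglomeration
#' (squared-Euclidean Ward criterion, i.e. `hclust` method `ward.D2` on
#' the Euclidean distance). Deterministic for a fixed input order; leaf
#' order and a newick export are returned.
#'
#' @param profiles Matrix (samples x probes) or list of equal-length
#'   named fingerprint vectors.
#' @return List: `hclust` (the tree), `leaf_order` (sample labels in
#'   dendrogram order), `newick` (tree serialization), `method`
#'   (`"ward.D2 / euclidean"`).
#' @export
cluster_fingerprints <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      !is.matrix(profiles)) {
    lens <- vapply(profiles, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("schema error: profiles have unequal lengths", call. = FALSE)
    }
    profiles <- do.call(rbind, profiles)
  }
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) {
    stop("need at least 2 profiles to cluster", call. = FALSE)
  }
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("sample_", seq_len(nrow(profiles)))
  }
  d <- stats::dist(profiles, method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  list(hclust = hc,
       leaf_order = hc$labels[hc$order],
       newick = ape::write.tree(ape::as.phylo(hc)),
       method = "ward.D2 / euclidean")
}

#' Reproducibility of two replicate fingerprints
#'
#' Percentage of probes giving the same presence/absence response in both
#' technical replicates.
#'
#' @param a,b Equal-length 0/1 fingerprint vectors.
#' @return Percent agreement in `[0, 100]`.
#' @export
replicate_reproducibility <- function(a, b) {
  if (length(a) != length(b)) {
    stop("schema error: fingerprints have different lengths", call. = FALSE)
  }
  100 * mean(a == b)
}

#' Read the probe ecology annotation
#'
#' The package ships an annotation of the default 30-probe intestinal
#' panel: for each probe its ecological class (M mutualist, O
#' opportunist, P pathogen), its contribution grouping (major / minor /
#' opportunistic) and whether it is a sub-probe nested under a broader
#' probe (sub-probes are excluded from contribution totals).
#'
#' @param path Annotation TSV (default: the panel shipped in
#'   `extdata/probe_ecology.tsv`).
#' @return Data frame: `probe_id`, `eco_class`, `grouping`, `sub_probe`
#'   (logical), `parent_probe`.
#' @export
read_probe_ecology <- function(path = system.file("extdata",
                                                  "probe_ecology.tsv",
                                                  package = "ldrua")) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$sub_probe <- as.logical(out$sub_probe)
  out
}

#' Contribution totals per ecological grouping
#'
#' Sums a sample's relative contributions over the major-mutualist,
#' minor-mutualist and opportunistic groupings; the three totals sum to
#' 100.
#'
#' @param contributions Named percent vector from
#'   [relative_contributions()].
#' @param ecology Annotation data frame from [read_probe_ecology()].
#' @return Named numeric vector with elements `major`, `minor`,
#'   `opportunistic`.
#' @export
group_contribution_summary <- function(contributions, ecology) {
  ids <- names(contributions)
  idx <- match(ids, ecology$probe_id)
  if (anyNA(idx)) {
    stop("schema error: unmapped probes: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  grouping <- factor(ecology$grouping[idx],
                     levels = c("major", "minor", "opportunistic"))
  out <- tapply(contributions, grouping, sum, default = 0)
  stats::setNames(as.numeric(out), levels(grouping))
}

#' Assemble a fingerprint matrix from call tables
#'
#' @param call_tables Named list of `call_table`s, one per sample.
#' @param probe_order Probe order shared across samples (default: order
#'   in the first table).
#' @return Integer matrix samples x probes.
#' @export
fingerprint_matrix <- function(call_tables, probe_order = NULL) {
  if (is.null(probe_order)) {
    probe_order <- unique(call_tables[[1]]$probe_id)
  }
  m <- t(vapply(call_tables, binary_fingerprint,
                integer(length(probe_order)), probe_order = probe_order))
  colnames(m) <- probe_order
  m
}
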