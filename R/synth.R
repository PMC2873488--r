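# Synthetic assay panels.
#
# Generates self-contained toy assay panels: random amplicon templates
# (one per target group), probe pairs designed on each template with the
# other templates as the negative set, and an array layout with ZipCodes
# assigned. These panels emulate the structure of a 16S amplicon panel --
# one discriminating site per target, a shared multi-subarray ZipCode
# layout -- without the phylogenetic correlation structure of real 16S
# alignments.

#' Generate random amplicon templates
#'
#' @param n Number of templates.
#' @param length_nt Template length in nt (default 300).
#' @param seed Integer seed (default 7).
#' @param gc Per-base probability of G or C (default 0.5).
#' @return Named character vector of concrete sequences
#'   (`target_01`, ...).
#' @export
synth_templates <- function(n, length_nt = 300L, seed = 7L, gc = 0.5) {
  stopifnot(n >= 1L, length_nt >= 60L)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(names(p), length_nt, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  stats::setNames(seqs, sprintf("target_%02d", seq_len(n)))
}

#' Build a complete synthetic assay panel
#'
#' Designs one probe pair per synthetic template (positives: the template
#' itself; negatives: all other templates), builds a layout sized to the
#' panel and assigns ZipCodes. Raises if any template yields no passing
#' probe -- enlarge `length_nt` or change `seed` in that case.
#'
#' @param n_targets Number of target templates (default 6).
#' @param length_nt Template length (default 300).
#' @param seed Integer seed (default 7).
#' @param n_subarrays Subarrays in the layout (default 8).
#' @param constraints A [design_constraints()] list.
#' @return List: `templates` (named character vector), `probes`
#'   (`probe_set` with ZipCodes), `layout` (`array_layout`), `map`
#'   (probe_id -> zip_id).
#' @export
synth_panel <- function(n_targets = 6L, length_nt = 300L, seed = 7L,
                        n_subarrays = 8L,
                        constraints = design_constraints()) {
  templates <- synth_templates(n_targets, length_nt, seed)
  groups <- lapply(names(templates), function(id) {
    list(positive = aligned_group(id, stats::setNames(templates[id], id)),
         negatives = templates[setdiff(names(templates), id)])
  })
  design <- design_probe_set(groups, constraints)
  if (length(design$failures) > 0L) {
    stop("no passing probe pair for: ",
         paste(design$failures, collapse = ", "),
         "; increase length_nt or change seed", call. = FALSE)
  }
  layout <- build_layout(n_subarrays = n_subarrays,
                         probe_zip_count = max(n_targets, 4L))
  asg <- assign_zipcodes(design$probes, layout)
  list(templates = templates, probes = asg$probes, layout = asg$layout,
       map = asg$map)
}
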