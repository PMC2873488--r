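# In-silico LDR-Universal Array experiments.
#
# A template mixture (amplicon sequences with amounts in fmol, plus an
# inert genomic-DNA diluent mass) is reacted against a probe set: a probe
# pair yields ligation product proportional to the amount of any template
# carrying a perfectly matching DS+CP site (the junction window must match
# exactly -- the ligase rule). Products are rendered onto an array layout
# as spot intensities with additive background and multiplicative
# lognormal noise; per-spot pixel SD is emitted so the downstream
# conservative-null calling rule is exercisable.

#' Template mixture
#'
#' @param templates Named character vector of concrete (non-degenerate)
#'   template sequences.
#' @param amounts_fmol Numeric vector of amounts in fmol, one per
#'   template (recycled if length 1).
#' @param background_gdna_ug Non-hybridizing genomic DNA mass in
#'   micrograms (default 0); inert except for fractional-abundance
#'   bookkeeping.
#' @param label Sample name (default "sample").
#' @return A `template_mix` object.
#' @export
template_mix <- function(templates, amounts_fmol,
                         background_gdna_ug = 0, label = "sample") {
  stopifnot(length(templates) >= 1L)
  amounts_fmol <- rep_len(amounts_fmol, length(templates))
  if (any(amounts_fmol < 0)) stop("amounts must be >= 0", call. = FALSE)
  if (is.null(names(templates))) {
    names(templates) <- paste0("template_", seq_along(templates))
  }
  structure(list(templates = toupper(templates),
                 amounts_fmol = stats::setNames(amounts_fmol,
                                                names(templates)),
                 background_gdna_ug = background_gdna_ug,
                 label = label),
            class = "template_mix")
}

#' Ligation and noise parameters
#'
#' @param junction_stringency Exact-match window at the DS 3' end in nt
#'   (default 1).
#' @param body_mismatch_tolerance Mismatches tolerated outside the
#'   junction window (default 0).
#' @param yield_per_fmol Signal units of ligation product per fmol of
#'   matching template (calibration constant, default 400).
#' @return A `ligation_params` list.
#' @export
ligation_params <- function(junction_stringency = 1L,
                            body_mismatch_tolerance = 0L,
                            yield_per_fmol = 400) {
  stopifnot(junction_stringency >= 1L, body_mismatch_tolerance >= 0L,
            yield_per_fmol >= 0)
  structure(list(junction_stringency = as.integer(junction_stringency),
                 body_mismatch_tolerance = as.integer(body_mismatch_tolerance),
                 yield_per_fmol = yield_per_fmol),
            class = "ligation_params")
}

#' Spot noise parameters
#'
#' @param background_mean Additive background intensity in arbitrary
#'   units (default 100).
#' @param spot_cv Coefficient of variation of the multiplicative
#'   lognormal spot noise (default 0.15).
#' @param pixel_sd_fraction Per-spot pixel SD emitted as this fraction of
#'   the spot intensity (default 0.10).
#' @param hyb_control_level Intensity level of hybridization-control
#'   spots (default 20000).
#' @param lig_control_level Intensity level of ligation-control spots
#'   (default 10000).
#' @return A `noise_params` list.
#' @export
noise_params <- function(background_mean = 100, spot_cv = 0.15,
                         pixel_sd_fraction = 0.10,
                         hyb_control_level = 20000,
                         lig_control_level = 10000) {
  stopifnot(background_mean >= 0, spot_cv >= 0, pixel_sd_fraction >= 0)
  structure(list(background_mean = background_mean, spot_cv = spot_cv,
                 pixel_sd_fraction = pixel_sd_fraction,
                 hyb_control_level = hyb_control_level,
                 lig_control_level = lig_control_level),
            class = "noise_params")
}

#' Ligation product yield for one probe pair on one template
#'
#' Yield is linear in template amount when the template carries a DS+CP
#' site matching under the junction stringency rule (IUPAC-aware), and
#' zero otherwise.
#'
#' @param pair One-row `probe_set` data frame (or list with `ds_seq`,
#'   `cp_seq`).
#' @param template Concrete template sequence.
#' @param amount_fmol Template amount in fmol.
#' @param ligation A [ligation_params()] list.
#' @return Product amount in signal units.
#' @export
ligation_yield <- function(pair, template, amount_fmol,
                           ligation = ligation_params()) {
  stopifnot(amount_fmol >= 0)
  if (amount_fmol == 0) return(0)
  hit <- length(.probe_match_positions(
    template, pair$ds_seq, pair$cp_seq,
    window = ligation$junction_stringency,
    body_tol = ligation$body_mismatch_tolerance)) > 0L
  if (hit) amount_fmol * ligation$yield_per_fmol else 0
}

# Expected (noiseless) signal of each probe against a mix.
.expected_yields <- function(probes, mix, ligation) {
  vapply(seq_len(nrow(probes)), function(i) {
    sum(vapply(seq_along(mix$templates), function(j) {
      ligation_yield(probes[i, ], mix$templates[[j]],
                     mix$amounts_fmol[[j]], ligation)
    }, numeric(1)))
  }, numeric(1))
}

# Lognormal draw with given mean and CV (mean parameterization).
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an LDR-Universal Array experiment
#'
#' Renders one sample per subarray. Each mix in `mixes` is hybridized to
#' the corresponding subarray of the layout. Probe spots draw from a
#' lognormal with expectation background + ligation yield; blank and
#' unused-ZipCode spots draw around the background; hybridization and
#' ligation controls draw at their fixed control levels. Output is
#' bit-identical for identical inputs and seed.
#'
#' @param probes A `probe_set` with `zipcode_id` assigned (see
#'   [assign_zipcodes()]).
#' @param layout An `array_layout`.
#' @param mixes A single [template_mix()] or a list of them, one per
#'   subarray used (at most `n_subarrays`).
#' @param noise A [noise_params()] list.
#' @param ligation A [ligation_params()] list.
#' @param seed Integer RNG seed (default 1).
#' @return A `spot_table` data frame: `sample_id`, `subarray`, `zip_id`,
#'   `replicate`, `IF`, `pixel_sd`, `type_flag`.
#' @export
simulate_experiment <- function(probes, layout, mixes,
                                noise = noise_params(),
                                ligation = ligation_params(),
                                seed = 1L) {
  if (inherits(mixes, "template_mix")) mixes <- list(mixes)
  n_sub <- max(layout$subarray)
  if (length(mixes) > n_sub) {
    stop("more mixes than subarrays in the layout", call. = FALSE)
  }
  if (any(is.na(probes$zipcode_id)) ||
      !all(probes$zipcode_id %in% layout$zip_id)) {
    stop("configuration error: every probe needs a ZipCode present in ",
         "the layout (run assign_zipcodes first)", call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng$restore())
  out <- list()
  for (k in seq_along(mixes)) {
    mix <- mixes[[k]]
    yields <- .expected_yields(probes, mix, ligation)
    names(yields) <- probes$zipcode_id
    sub <- layout[layout$subarray == k, , drop = FALSE]
    expected <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      expected[i] <- switch(
        as.character(sub$type_flag[i]),
        "1" = noise$hyb_control_level,
        "2" = noise$lig_control_level,
        "3" = noise$background_mean +
          if (sub$zip_id[i] %in% names(yields)) yields[[sub$zip_id[i]]] else 0,
        "4" = noise$background_mean,
        "5" = noise$background_mean
      )
    }
    IF <- .rlnorm_mean_cv(nrow(sub), 1, noise$spot_cv) * expected
    repl <- stats::ave(seq_len(nrow(sub)), sub$zip_id,
                       FUN = seq_along)
    out[[k]] <- data.frame(
      sample_id = mix$label, subarray = k, zip_id = sub$zip_id,
      replicate = as.integer(repl), IF = IF,
      pixel_sd = noise$pixel_sd_fraction * IF,
      type_flag = sub$type_flag, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("spot_table", "data.frame")
  out
}

#' Mass of an amplicon amount
#'
#' Converts an amount of double-stranded amplicon to nanograms using a
#' configurable average mass per base pair.
#'
#' @param length_bp Amplicon length in base pairs.
#' @param amount_fmol Amount in fmol.
#' @param mass_per_bp Average molar mass per base pair in g/mol (default
#'   650).
#' @return Mass in ng.
#' @examples
#' amplicon_mass(1700, 1)  # ~1.105 ng
#' @export
amplicon_mass <- function(length_bp, amount_fmol, mass_per_bp = 650) {
  stopifnot(length_bp > 0, amount_fmol >= 0)
  amount_fmol * 1e-15 * length_bp * mass_per_bp * 1e9
}

#' Fractional abundance of a target mass in a DNA background
#'
#' @param target_mass_ng Target amplicon mass in ng.
#' @param background_mass_ug Background DNA mass in micrograms (> 0).
#' @param digits Decimal places of percent for the presented value
#'   (default 2).
#' @return List with `percent` (exact) and `presented` (rounded percent).
#' @examples
#' fractional_abundance(amplicon_mass(1700, 1), 6.3)$presented  # 0.02
#' @export
fractional_abundance <- function(target_mass_ng, background_mass_ug,
                                 digits = 2L) {
  if (background_mass_ug <= 0) {
    stop("division error: background mass must be > 0", call. = FALSE)
  }
  pct <- 100 * target_mass_ng / (background_mass_ug * 1000)
  list(percent = pct, presented = round(pct, digits))
}

#' Write / read a spot-intensity TSV
#'
#' Columns: sample_id, subarray, zip_id, replicate, IF, pixel_sd,
#' type_flag.
#'
#' @param spots A `spot_table`.
#' @param path TSV path.
#' @return Invisibly `path` (write) / a `spot_table` (read).
#' @export
write_spot_table <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("spot_table", "data.frame")
  out
}
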