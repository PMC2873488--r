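# Presence calling against a blank-spot null distribution.
#
# For each subarray the null is the population of blank spots, each
# shifted up by twice its pixel SD (a conservative estimate of local
# background). Replicate probe intensities are screened with the
# low-outlier rule, then tested against the adjusted null with a
# one-sided two-sample t-test (H0: mu_test = mu_null, H1: mu_test >
# mu_null). The signal-to-noise ratio of a probe is its mean intensity
# over the raw (unadjusted) blank mean.

#' Calling parameters
#'
#' @param alpha Significance level of the one-sided presence test
#'   (default 0.01; use 0.05 in sensitivity mode for very low template
#'   amounts).
#' @param outlier_factor Replicates below `outlier_factor` times the
#'   adjusted null mean are discarded as low outliers when at least one
#'   replicate is above the threshold (default 2.5).
#' @param min_replicates Minimum retained replicates for a test (default
#'   2).
#' @param var_equal Pool variances in the t-test (default FALSE: Welch).
#' @param bonferroni Divide alpha by the number of probes tested per
#'   sample (default FALSE).
#' @return A `call_params` list.
#' @export
call_params <- function(alpha = 0.01, outlier_factor = 2.5,
                        min_replicates = 2L, var_equal = FALSE,
                        bonferroni = FALSE) {
  stopifnot(alpha > 0, alpha < 1, outlier_factor > 0, min_replicates >= 2L)
  structure(list(alpha = alpha, outlier_factor = outlier_factor,
                 min_replicates = as.integer(min_replicates),
                 var_equal = var_equal, bonferroni = bonferroni),
            class = "call_params")
}

#' Build the blank-spot null distribution
#'
#' Each blank contributes its intensity plus twice its pixel SD (the
#' conservative adjustment); the raw and adjusted means are both kept
#' since presence testing uses the adjusted values while SNR uses the raw
#' blank mean.
#'
#' @param spots A `spot_table` scoped to one sample/subarray (rows with
#'   `type_flag == 5` are used).
#' @return A `null_distribution` list: `adjusted_values`, `raw_values`,
#'   `raw_mean`, `adjusted_mean`, `n`.
#' @export
build_null <- function(spots) {
  blanks <- spots[spots$type_flag == 5L, , drop = FALSE]
  if (nrow(blanks) < 2L) {
    stop("insufficient-null error: need >= 2 blank spots, found ",
         nrow(blanks), call. = FALSE)
  }
  adj <- blanks$IF + 2 * blanks$pixel_sd
  structure(list(adjusted_values = adj, raw_values = blanks$IF,
                 raw_mean = mean(blanks$IF), adjusted_mean = mean(adj),
                 n = nrow(blanks)),
            class = "null_distribution")
}

#' Exclude low-outlier replicates
#'
#' Replicates with intensity below `outlier_factor` times the adjusted
#' null mean are discarded, provided at least one replicate clears the
#' threshold and at least `min_replicates` would remain. When every
#' replicate is below the threshold none is excluded: the probe is tested
#' as-is (and will fail the presence test).
#'
#' @param replicates Numeric vector of replicate intensities.
#' @param null A `null_distribution` from [build_null()].
#' @param params A [call_params()] list.
#' @return List with `retained` and `n_excluded`.
#' @export
exclude_outliers <- function(replicates, null, params = call_params()) {
  stopifnot(length(replicates) >= 1L)
  threshold <- params$outlier_factor * null$adjusted_mean
  above <- replicates >= threshold
  if (!any(above) || all(above)) {
    return(list(retained = replicates, n_excluded = 0L))
  }
  keep <- replicates[above]
  if (length(keep) < params$min_replicates) {
    # cannot drop below the testable minimum; keep the largest ones
    ord <- order(replicates, decreasing = TRUE)
    keep <- replicates[sort(ord[seq_len(params$min_replicates)])]
  }
  list(retained = keep, n_excluded = length(replicates) - length(keep))
}

#' One-sided presence test for a probe
#'
#' Two-sample one-sided t-test (Welch by default) of retained replicate
#' intensities against the adjusted null values.
#'
#' @param replicates Retained replicate intensities.
#' @param null A `null_distribution`.
#' @param params A [call_params()] list.
#' @param probe_id Probe label carried into the record.
#' @param n_excluded Count of replicates excluded upstream.
#' @return A one-row data frame (`call_record`): `probe_id`,
#'   `n_replicates_used`, `n_excluded`, `mean_if`, `p_value`, `present`.
#' @export
test_presence <- function(replicates, null, params = call_params(),
                          probe_id = "probe", n_excluded = 0L) {
  n <- length(replicates)
  if (n < params$min_replicates) {
    return(data.frame(probe_id = probe_id, n_replicates_used = n,
                      n_excluded = n_excluded,
                      mean_if = mean(replicates), p_value = NA_real_,
                      present = FALSE, reason = "too_few_replicates",
                      stringsAsFactors = FALSE))
  }
  p <- if (stats::sd(replicates) == 0 && stats::sd(null$adjusted_values) == 0) {
    # degenerate: no variance on either side; fall back to a sign rule
    if (mean(replicates) > null$adjusted_mean) 0 else 1
  } else {
    stats::t.test(replicates, null$adjusted_values,
                  alternative = "greater",
                  var.equal = params$var_equal)$p.value
  }
  data.frame(probe_id = probe_id, n_replicates_used = n,
             n_excluded = n_excluded, mean_if = mean(replicates),
             p_value = p, present = p < params$alpha, reason = "",
             stringsAsFactors = FALSE)
}

#' Call probe presence for every sample in a spot table
#'
#' Applies, per sample and subarray: null construction from the blanks,
#' low-outlier exclusion, the one-sided presence test, and SNR
#' computation (probe mean over raw blank mean).
#'
#' @param spots A `spot_table`.
#' @param probes A `probe_set` with `zipcode_id` assigned; gives the
#'   probe <-> ZipCode map.
#' @param params A [call_params()] list.
#' @return A `call_table` data frame: `sample_id`, `probe_id`,
#'   `zipcode_id`, `n_replicates_used`, `n_excluded`, `mean_if`, `snr`,
#'   `p_value`, `present`.
#' @export
call_spots <- function(spots, probes, params = call_params()) {
  out <- list()
  for (sid in unique(spots$sample_id)) {
    ss <- spots[spots$sample_id == sid, , drop = FALSE]
    for (sub in unique(ss$subarray)) {
      scope <- ss[ss$subarray == sub, , drop = FALSE]
      null <- build_null(scope)
      alpha <- if (params$bonferroni) {
        params$alpha / nrow(probes)
      } else {
        params$alpha
      }
      eff <- params
      eff$alpha <- alpha
      for (i in seq_len(nrow(probes))) {
        reps <- scope$IF[scope$zip_id == probes$zipcode_id[i] &
                           scope$type_flag == 3L]
        if (length(reps) == 0L) next
        ex <- exclude_outliers(reps, null, eff)
        rec <- test_presence(ex$retained, null, eff,
                             probe_id = probes$probe_id[i],
                             n_excluded = ex$n_excluded)
        rec$sample_id <- sid
        rec$zipcode_id <- probes$zipcode_id[i]
        rec$snr <- mean(reps) / null$raw_mean
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  if (length(out) == 0L) {
    stop("no probe spots found for the supplied probe set", call. = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[, c("sample_id", "probe_id", "zipcode_id",
                 "n_replicates_used", "n_excluded", "mean_if", "snr",
                 "p_value", "present", "reason")]
  rownames(out) <- NULL
  class(out) <- c("call_table", "data.frame")
  out
}

#' Signal-to-noise ratios of probe spots
#'
#' Per-probe SNR is the mean probe-spot intensity divided by the raw
#' blank mean of the same scope. The summary splits probes into the
#' expected-specific set and all others, mirroring the specificity
#' figures of a single-template hybridization: `snr_s` (mean over
#' expected-specific probes) and `snr_ns` (mean over the rest).
#'
#' @param spots A `spot_table` for one sample/subarray, or a data frame
#'   with per-probe SNR columns `snr` and logical `specific` (see
#'   `snr_summary`).
#' @param probes A `probe_set` with ZipCodes.
#' @param expected_specific Character vector of probe_ids expected to
#'   respond.
#' @return List: `per_probe` (data frame probe_id, snr, specific),
#'   `snr_s`, `snr_s_sd`, `snr_ns`, `snr_ns_sd`.
#' @export
compute_snr <- function(spots, probes, expected_specific) {
  null <- build_null(spots)
  if (null$raw_mean <= 0) {
    stop("division error: blank mean is zero", call. = FALSE)
  }
  per <- do.call(rbind, lapply(seq_len(nrow(probes)), function(i) {
    reps <- spots$IF[spots$zip_id == probes$zipcode_id[i] &
                       spots$type_flag == 3L]
    data.frame(probe_id = probes$probe_id[i],
               snr = mean(reps) / null$raw_mean,
               specific = probes$probe_id[i] %in% expected_specific,
               stringsAsFactors = FALSE)
  }))
  snr_summary(per)
}

#' Summarize specific vs non-specific SNR values
#'
#' Operates on a per-probe (or per-measurement) SNR table with columns
#' `snr` and logical `specific`; paired rows (same measurement index
#' within each class) also yield the mean specific/non-specific ratio.
#'
#' @param per Data frame with columns `snr`, `specific` (and anything
#'   else, carried through).
#' @return List: `per_probe`, `snr_s`, `snr_s_sd`, `snr_ns`, `snr_ns_sd`,
#'   and `mean_ratio` when specific and non-specific rows pair 1:1.
#' @export
snr_summary <- function(per) {
  s <- per$snr[per$specific]
  ns <- per$snr[!per$specific]
  out <- list(per_probe = per,
              snr_s = mean(s), snr_s_sd = stats::sd(s),
              snr_ns = mean(ns), snr_ns_sd = stats::sd(ns))
  if (length(s) == length(ns) && length(s) > 0L) {
    out$mean_ratio <- mean(s / ns)
  }
  out
}

#' Write / read a call-table TSV
#'
#' @param calls A `call_table`.
#' @param path TSV path.
#' @return Invisibly `path` (write) / a `call_table` (read).
#' @export
write_call_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_call_table
#' @export
read_call_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("call_table", "data.frame")
  out
}
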