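# Published reference measurements shipped with the package.

#' Reference specificity SNR measurements
#'
#' Signal-to-noise ratios from the specificity validation of the assay
#' panel: 28 pure-culture 16S rRNA amplicons, each hybridized in two
#' independent experiments (56 measurements). Per measurement the table
#' holds the SNR of the group-specific probe (`snr_s`), the mean SNR of
#' all other probes (`snr_ns`), and the presence-test p-value of the
#' specific probe.
#'
#' @return Data frame: `target`, `experiment`, `snr_ns`, `snr_s`,
#'   `p_value`.
#' @export
specificity_snr_reference <- function() {
  path <- system.file("extdata", "specificity_snr.tsv", package = "ldrua")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
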