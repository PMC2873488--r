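# Universal Array layout: a slide of identical, independently addressable
# subarrays. Each subarray spots a pool of ZipCode oligos in replicate
# plus hybridization controls, ligation controls and blanks. Spot type
# flags: 1 = hybridization control, 2 = ligation control, 3 = probe,
# 4 = unused ZipCode, 5 = blank.

.TYPE_FLAGS <- c(hybridization_control = 1L, ligation_control = 2L,
                 probe = 3L, unused = 4L, blank = 5L)

#' Generate a ZipCode pool
#'
#' Deterministically generates `n` distinct ZipCode address sequences of
#' the given length from a seeded RNG stream (local to the call; the
#' global RNG state is untouched).
#'
#' @param n Number of ZipCodes.
#' @param length_nt ZipCode length in nt (default 25).
#' @param seed Integer seed (default 42).
#' @return Data frame: `zip_id`, `sequence`.
#' @export
zipcode_pool <- function(n, length_nt = 25L, seed = 42L) {
  stopifnot(n >= 1L)
  rng <- local_rng(seed)
  seqs <- character(0)
  while (length(seqs) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), length_nt, replace = TRUE),
                  collapse = "")
    if (!cand %in% seqs) seqs <- c(seqs, cand)
  }
  rng$restore()
  data.frame(zip_id = sprintf("zip%02d", seq_len(n)), sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Build a multi-subarray Universal Array layout
#'
#' Lays out each subarray as a deterministic grid holding
#' `probe_zip_count` probe-addressable ZipCodes in `replicates` copies,
#' plus the control spots. Spots are placed row-major: hybridization
#' controls first (so they frame the subarray for localization), then
#' ligation controls, then the ZipCode replicates, then blanks.
#'
#' @param n_subarrays Number of subarrays per slide (default 8).
#' @param probe_zip_count Number of probe-addressable ZipCodes (default
#'   47).
#' @param replicates Replicate spots per ZipCode per subarray (default 4).
#' @param control_replicates Named integer vector with elements
#'   `hybridization`, `ligation`, `blank` (default 8, 6, 6).
#' @param grid_ncol Grid columns per subarray (default 13).
#' @return An `array_layout` data frame: `subarray`, `row`, `col`,
#'   `zip_id`, `type_flag`, with attributes `replicates_per_zip` and
#'   `control_replicates`.
#' @export
build_layout <- function(n_subarrays = 8L, probe_zip_count = 47L,
                         replicates = 4L,
                         control_replicates = c(hybridization = 8L,
                                                ligation = 6L, blank = 6L),
                         grid_ncol = 13L) {
  stopifnot(n_subarrays >= 1L, probe_zip_count >= 1L, replicates >= 1L,
            all(control_replicates >= 0L))
  need <- c("hybridization", "ligation", "blank")
  if (!all(need %in% names(control_replicates))) {
    stop("control_replicates needs elements: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  per_sub <- probe_zip_count * replicates + sum(control_replicates)
  n_rows <- ceiling(per_sub / grid_ncol)
  if (n_rows * grid_ncol < per_sub) {
    stop("layout error: grid capacity exceeded", call. = FALSE)
  }
  zips <- c(
    rep("hyb_ctrl", control_replicates[["hybridization"]]),
    rep("lig_ctrl", control_replicates[["ligation"]]),
    rep(sprintf("zip%02d", seq_len(probe_zip_count)), each = replicates),
    rep("blank", control_replicates[["blank"]])
  )
  flags <- c(
    rep(.TYPE_FLAGS[["hybridization_control"]],
        control_replicates[["hybridization"]]),
    rep(.TYPE_FLAGS[["ligation_control"]], control_replicates[["ligation"]]),
    rep(.TYPE_FLAGS[["unused"]], probe_zip_count * replicates),
    rep(.TYPE_FLAGS[["blank"]], control_replicates[["blank"]])
  )
  idx <- seq_len(per_sub)
  one <- data.frame(
    row = ((idx - 1L) %/% grid_ncol) + 1L,
    col = ((idx - 1L) %% grid_ncol) + 1L,
    zip_id = zips,
    type_flag = as.integer(flags),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(seq_len(n_subarrays), function(s) {
    cbind(subarray = s, one)
  }))
  rownames(out) <- NULL
  attr(out, "replicates_per_zip") <- as.integer(replicates)
  attr(out, "control_replicates") <- control_replicates
  class(out) <- c("array_layout", "data.frame")
  out
}

#' Assign ZipCodes to probes
#'
#' Injectively maps probe identifiers to probe-addressable ZipCodes of a
#' layout (or pool), in order: assignment is stable under re-runs. Spots
#' carrying an assigned ZipCode are reflagged from unused (4) to probe
#' (3).
#'
#' @param probes A `probe_set` data frame.
#' @param layout An `array_layout` from [build_layout()].
#' @return List with `probes` (zipcode_id filled), `layout` (type flags
#'   updated) and `map` (named character vector probe_id -> zip_id).
#' @export
assign_zipcodes <- function(probes, layout) {
  pool <- unique(layout$zip_id[layout$type_flag %in%
                                 c(.TYPE_FLAGS[["probe"]],
                                   .TYPE_FLAGS[["unused"]])])
  if (nrow(probes) > length(pool)) {
    stop("capacity error: ", nrow(probes), " probes but only ",
         length(pool), " ZipCodes available", call. = FALSE)
  }
  map <- pool[seq_len(nrow(probes))]
  names(map) <- probes$probe_id
  probes$zipcode_id <- unname(map)
  layout$type_flag[layout$zip_id %in% map] <- .TYPE_FLAGS[["probe"]]
  layout$type_flag[layout$type_flag == .TYPE_FLAGS[["probe"]] &
                     !(layout$zip_id %in% map)] <- .TYPE_FLAGS[["unused"]]
  list(probes = probes, layout = layout, map = map)
}

#' Write / read a layout TSV
#'
#' Columns: subarray, row, col, zip_id, type_flag.
#'
#' @param layout An `array_layout`.
#' @param path TSV path.
#' @return Invisibly `path` (write) / an `array_layout` (read; replicate
#'   attributes are reconstructed from the spot table).
#' @export
write_layout <- function(layout, path) {
  utils::write.table(layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  probe_zips <- out$zip_id[out$type_flag %in% c(3L, 4L) & out$subarray == 1L]
  if (length(probe_zips) > 0L) {
    attr(out, "replicates_per_zip") <- as.integer(max(table(probe_zips)))
  }
  class(out) <- c("array_layout", "data.frame")
  out
}
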