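# Nearest-neighbor duplex melting temperature.
#
# Unified NN parameters of Allawi & SantaLucia (1997): per-dimer enthalpy
# (kcal/mol) and entropy (cal/mol/K), terminal A.T / G.C initiation terms,
# a -1.4 cal/mol/K entropy penalty for self-complementary duplexes, and
# the entropic monovalent-salt correction 0.368 * (L - 1) * ln[Na+].

.NN_DH <- c("AA" = -7.9, "TT" = -7.9, "AT" = -7.2, "TA" = -7.2,
            "CA" = -8.5, "TG" = -8.5, "GT" = -8.4, "AC" = -8.4,
            "CT" = -7.8, "AG" = -7.8, "GA" = -8.2, "TC" = -8.2,
            "CG" = -10.6, "GC" = -9.8, "GG" = -8.0, "CC" = -8.0)
.NN_DS <- c("AA" = -22.2, "TT" = -22.2, "AT" = -20.4, "TA" = -21.3,
            "CA" = -22.7, "TG" = -22.7, "GT" = -22.4, "AC" = -22.4,
            "CT" = -21.0, "AG" = -21.0, "GA" = -22.2, "TC" = -22.2,
            "CG" = -27.2, "GC" = -24.4, "GG" = -19.9, "CC" = -19.9)
.INIT_AT <- c(dh = 2.3, ds = 4.1)
.INIT_GC <- c(dh = 0.1, ds = -2.8)
.GAS_R <- 1.987  # cal / (mol K)

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.tm_from_chars <- function(chars, na_mM, strand_conc) {
  L <- length(chars)
  dimers <- paste0(chars[-L], chars[-1])
  dh <- sum(.NN_DH[dimers])
  ds <- sum(.NN_DS[dimers])
  for (end in chars[c(1L, L)]) {
    init <- if (end %in% c("A", "T")) .INIT_AT else .INIT_GC
    dh <- dh + init[["dh"]]
    ds <- ds + init[["ds"]]
  }
  # self-complementary duplexes: symmetry entropy and CT (not CT/4)
  if (all(chars == rev(unname(.COMPLEMENT[chars])))) {
    ds <- ds - 1.4
    k <- strand_conc
  } else {
    k <- strand_conc / 4
  }
  ds <- ds + 0.368 * (L - 1) * log(na_mM / 1000)
  dh * 1000 / (ds + .GAS_R * log(k)) - 273.15
}

.tm_concrete <- function(seq, na_mM, strand_conc) {
  .tm_from_chars(strsplit(seq, "", fixed = TRUE)[[1]], na_mM, strand_conc)
}

# Closure scoring arbitrary windows of one sequence in O(1) amortized
# time: dimer enthalpy/entropy cumulative sums for concrete stretches,
# with a fallback to full (expansion-averaged) evaluation for windows
# containing degenerate symbols. Used by candidate enumeration, where the
# same consensus is scanned tens of thousands of times.
.tm_window_scorer <- function(seq, na_mM = 50, strand_conc = 2.5e-7) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(chars)
  card <- .IUPAC_CARD[chars]
  deg_cum <- c(0, cumsum(card > 1L))
  log_card_cum <- c(0, cumsum(log(card)))
  dimers <- paste0(chars[-L], chars[-1])
  dh_vals <- unname(.NN_DH[dimers])
  ds_vals <- unname(.NN_DS[dimers])
  dh_vals[is.na(dh_vals)] <- 0  # dimers touching a degenerate symbol;
  ds_vals[is.na(ds_vals)] <- 0  # only read for all-concrete windows
  dh_cum <- c(0, cumsum(dh_vals))
  ds_cum <- c(0, cumsum(ds_vals))
  comp <- unname(.COMPLEMENT[chars])
  salt <- log(na_mM / 1000)
  function(i, j) {
    n_deg <- deg_cum[j + 1L] - deg_cum[i]
    n_exp <- exp(log_card_cum[j + 1L] - log_card_cum[i])
    if (n_deg == 0L) {
      dh <- dh_cum[j] - dh_cum[i]
      ds <- ds_cum[j] - ds_cum[i]
      for (end in chars[c(i, j)]) {
        init <- if (end %in% c("A", "T")) .INIT_AT else .INIT_GC
        dh <- dh + init[["dh"]]
        ds <- ds + init[["ds"]]
      }
      win <- chars[i:j]
      if (all(win == rev(comp[i:j]))) {
        ds <- ds - 1.4
        k <- strand_conc
      } else {
        k <- strand_conc / 4
      }
      ds <- ds + 0.368 * (j - i) * salt
      tm <- dh * 1000 / (ds + .GAS_R * log(k)) - 273.15
    } else if (n_deg <= 8L && n_exp <= 256) {
      tm <- melting_temperature(paste(chars[i:j], collapse = ""),
                                na_mM = na_mM, strand_conc = strand_conc)
    } else {
      tm <- NA_real_
    }
    list(tm = tm, deg = n_deg)
  }
}

#' Nearest-neighbor melting temperature of a probe
#'
#' Duplex Tm under the unified nearest-neighbor model with an entropic
#' monovalent-salt correction. Defaults: 50 mM Na+ and a total strand
#' concentration of 0.25 uM (the CT/4 approximation is used for
#' non-self-complementary duplexes; self-complementary duplexes use CT and
#' the symmetry entropy term). Degenerate sequences return the arithmetic
#' mean Tm over all concrete expansions, capped at `expansion_cap`
#' realizations.
#'
#' @param seq IUPAC nucleotide string, length >= 8.
#' @param na_mM Monovalent sodium concentration in mM (default 50).
#' @param strand_conc Total oligonucleotide strand concentration in M
#'   (default 2.5e-7).
#' @param expansion_cap Maximum degenerate expansions averaged (default
#'   256).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("ACGTTGCAACGTGGATCCGATCGATTACA")
#' @export
melting_temperature <- function(seq, na_mM = 50, strand_conc = 2.5e-7,
                                expansion_cap = 256L) {
  seq <- toupper(seq)
  if (nchar(seq) < 8L) {
    stop("input error: sequence shorter than 8 nt", call. = FALSE)
  }
  if (count_degenerate(seq) == 0L) {
    return(.tm_concrete(seq, na_mM, strand_conc))
  }
  mean(vapply(expand_degenerate(seq, cap = expansion_cap),
              .tm_concrete, numeric(1),
              na_mM = na_mM, strand_conc = strand_conc))
}
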