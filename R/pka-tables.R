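#' Residue mass tables
#'
#' Monoisotopic and average residue (i.e. dehydrated amino-acid) masses in Da
#' for the 20 standard amino acids, plus the mass of one water molecule added
#' for the free termini. Values follow the standard proteomics reference
#' tables.
#'
#' @param kind `"monoisotopic"` or `"average"`.
#' @return A named numeric vector over one-letter residue codes, with an
#'   attribute `water` holding the corresponding water mass.
#' @export
#' @examples
#' residue_masses()[["W"]]
residue_masses <- function(kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  mono <- c(
    A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694,
    C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
    H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
    M = 131.04049, F = 147.06841, P = 97.05276,  S = 87.03203,
    T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
  )
  avg <- c(
    A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886,
    C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
    H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
    M = 131.1926, F = 147.1766, P = 97.1167,  S = 87.0782,
    T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
  )
  if (kind == "monoisotopic") {
    structure(mono, water = 18.010565)
  } else {
    structure(avg, water = 18.01524)
  }
}

#' Default pKa table for peptide ionizable groups
#'
#' A standard textbook-style set of intrinsic pKa values for the free termini
#' and ionizable side chains. Measured pKa values for a particular peptide
#' (e.g. from its titration curve) can be supplied instead wherever a
#' `pka_set` argument is accepted, and tables can be read from CSV with
#' [read_pka_csv()].
#'
#' `charge_when_protonated` is +1 for basic groups (the protonated form is
#' cationic) and 0 for acidic groups (the deprotonated form is anionic).
#'
#' @return A tibble with columns `group`, `pka`, `charge_when_protonated`.
#'   Rows `N-term` and `C-term` apply to the termini; one-letter rows to the
#'   matching side chains.
#' @export
#' @examples
#' default_pka_table()
default_pka_table <- function() {
  tibble::tribble(
    ~group,   ~pka, ~charge_when_protonated,
    "N-term",  9.0, 1L,
    "C-term",  3.1, 0L,
    "D",       3.65, 0L,
    "E",       4.25, 0L,
    "C",       8.3,  0L,
    "Y",      10.1,  0L,
    "H",       6.0,  1L,
    "K",      10.5,  1L,
    "R",      12.5,  1L
  )
}

#' Read a pKa table from CSV
#'
#' Expects columns `group`, `pka` (or `pKa`), `charge_when_protonated`.
#'
#' @param path Path to a CSV file.
#' @return A tibble in the same shape as [default_pka_table()].
#' @export
read_pka_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("group", "pka", "charge_when_protonated")
  if (!all(need %in% names(tab))) {
    stop("pKa CSV must have columns group, pKa, charge_when_protonated",
         call. = FALSE)
  }
  tab <- tibble::as_tibble(tab[need])
  tab$charge_when_protonated <- as.integer(tab$charge_when_protonated)
  validate_pka_table(tab)
  tab
}

validate_pka_table <- function(tab) {
  if (any(tab$pka <= 0 | tab$pka >= 14)) {
    stop("pKa values must lie strictly between 0 and 14", call. = FALSE)
  }
  if (!all(tab$charge_when_protonated %in% c(0L, 1L))) {
    stop("charge_when_protonated must be 0 (acid) or +1 (base)", call. = FALSE)
  }
  invisible(tab)
}
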