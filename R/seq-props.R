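#' Parse a peptide sequence into its ionizable-group description
#'
#' Builds a peptide specification from a one-letter sequence: the N-terminal
#' amine, the C-terminal carboxylate, and one entry per ionizable side chain,
#' each with a pKa drawn from `pka_set`. The specification is the input to
#' every downstream charge calculation ([net_charge()], [speciation()],
#' [isoelectric_point()]).
#'
#' The sequence may be a plain string or the text of a single-record FASTA
#' (the header line is ignored); whitespace is stripped.
#'
#' @param sequence One-letter peptide sequence, e.g. `"WWRR"`.
#' @param pka_set pKa table as returned by [default_pka_table()] or
#'   [read_pka_csv()].
#' @return An object of class `peptide_spec`: a list with `sequence` and
#'   `groups`, a tibble with columns `label`, `pka`, `charge_when_protonated`.
#' @export
#' @examples
#' parse_peptide("WR")$groups
parse_peptide <- function(sequence, pka_set = default_pka_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  lines <- strsplit(sequence, "\n", fixed = TRUE)[[1]]
  lines <- lines[!startsWith(trimws(lines), ">")]
  seq <- gsub("\\s", "", paste0(lines, collapse = ""))
  if (!nzchar(seq)) stop("empty peptide sequence", call. = FALSE)
  seq <- toupper(seq)
  residues <- strsplit(seq, "")[[1]]
  standard <- names(residue_masses())
  bad <- which(!(residues %in% standard))
  if (length(bad) > 0) {
    stop(sprintf("invalid residue '%s' at position %d", residues[bad[1]], bad[1]),
         call. = FALSE)
  }
  validate_pka_table(pka_set)
  lookup <- function(g) {
    row <- pka_set[pka_set$group == g, ]
    if (nrow(row) == 0) NULL else row
  }
  nt <- lookup("N-term")
  ct <- lookup("C-term")
  if (is.null(nt) || is.null(ct)) {
    stop("pka_set must contain N-term and C-term entries", call. = FALSE)
  }
  groups <- tibble::tibble(
    label = c("N-term", "C-term"),
    pka = c(nt$pka, ct$pka),
    charge_when_protonated = c(nt$charge_when_protonated, ct$charge_when_protonated)
  )
  for (i in seq_along(residues)) {
    row <- lookup(residues[i])
    if (!is.null(row)) {
      groups <- dplyr::bind_rows(groups, tibble::tibble(
        label = paste0(aa_three_letter(residues[i]), "-", i),
        pka = row$pka,
        charge_when_protonated = row$charge_when_protonated
      ))
    }
  }
  structure(list(sequence = seq, groups = groups), class = "peptide_spec")
}

aa_three_letter <- function(aa) {
  c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", E = "Glu",
    Q = "Gln", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
    M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
    Y = "Tyr", V = "Val")[[aa]]
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat("<peptide_spec> ", x$sequence, " (", nrow(x$groups),
      " ionizable groups)\n", sep = "")
  print(x$groups)
  invisible(x)
}

as_peptide <- function(p, pka_set = default_pka_table()) {
  if (inherits(p, "peptide_spec")) p else parse_peptide(p, pka_set)
}

peptide_mass <- function(p, kind) {
  p <- as_peptide(p)
  tab <- residue_masses(kind)
  residues <- strsplit(p$sequence, "")[[1]]
  m <- sum(tab[residues]) + attr(tab, "water")
  round_half_up(m, 2)
}

#' Peptide molecular masses
#'
#' Sum of residue masses plus one water, reported to two decimal places
#' (round-half-up, the convention of mass-spec materials sections).
#'
#' @param p A `peptide_spec` from [parse_peptide()] or a plain sequence
#'   string.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("WR")   # 360.19
#' average_mass("WR")        # 360.42
monoisotopic_mass <- function(p) peptide_mass(p, "monoisotopic")

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(p) peptide_mass(p, "average")

# per-group protonation probability at given pH (Henderson-Hasselbalch,
# independent sites)
protonation_prob <- function(groups, pH) {
  1 / (1 + 10^(pH - groups$pka))
}

# expected charge contribution of each group at given pH
group_charge <- function(groups, pH) {
  p <- protonation_prob(groups, pH)
  ifelse(groups$charge_when_protonated == 1L, p, -(1 - p))
}

#' Net (fractional) peptide charge at a given pH
#'
#' Multi-site Henderson-Hasselbalch expectation: each basic group contributes
#' \eqn{+1/(1+10^{pH-pKa})}, each acidic group \eqn{-1/(1+10^{pKa-pH})}.
#' Sites are treated as independent (no interaction terms). The result is
#' strictly decreasing in pH.
#'
#' @inheritParams monoisotopic_mass
#' @param pH pH value(s) in 0..14; vectorized.
#' @param pka_set pKa table used when `p` is a plain sequence.
#' @return Net charge (same length as `pH`).
#' @export
#' @examples
#' net_charge("WR", pH = 5.5)
net_charge <- function(p, pH, pka_set = default_pka_table()) {
  p <- as_peptide(p, pka_set)
  stopifnot(all(pH >= 0 & pH <= 14))
  vapply(pH, function(h) sum(group_charge(p$groups, h)), numeric(1))
}

#' Integer charge-state speciation at a given pH
#'
#' Distribution over integer net charges obtained by convolving the
#' independent per-site Bernoulli charge states (each site is protonated with
#' its Henderson-Hasselbalch probability). Equivalent to, and tested against,
#' Boltzmann enumeration of all \eqn{2^N} protonation microstates.
#'
#' @inheritParams net_charge
#' @return A tibble with columns `pH`, `charge` (integer), `fraction`;
#'   fractions sum to 1 at each pH. Multiple `pH` values give a long table.
#' @export
#' @examples
#' speciation("WWRR", pH = 12)
speciation <- function(p, pH, pka_set = default_pka_table()) {
  p <- as_peptide(p, pka_set)
  stopifnot(all(pH >= 0 & pH <= 14))
  purrr::map_dfr(pH, function(h) {
    pr <- protonation_prob(p$groups, h)
    base <- p$groups$charge_when_protonated == 1L
    # each site's charge distribution over offset {0, +1} (base) or {-1, 0}
    # (acid); convolve
    n <- nrow(p$groups)
    lo <- -sum(!base)
    hi <- sum(base)
    dist <- 1   # over support starting at current lo index
    cur_lo <- 0
    for (i in seq_len(n)) {
      if (base[i]) {
        site <- c(1 - pr[i], pr[i])       # charges 0, +1
        s_lo <- 0
      } else {
        site <- c(1 - pr[i], pr[i])       # charges -1, 0
        s_lo <- -1
      }
      dist <- convolve_full(dist, site)
      cur_lo <- cur_lo + s_lo
    }
    tibble::tibble(pH = h,
                   charge = seq.int(cur_lo, cur_lo + length(dist) - 1L),
                   fraction = dist)
  })
}

convolve_full <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (j in seq_along(b)) {
    idx <- seq_along(a) + j - 1L
    out[idx] <- out[idx] + a * b[j]
  }
  out
}

#' Isoelectric point
#'
#' pH at which the expected net charge is zero, found by bisection to
#' \eqn{|charge| < 10^{-6}}. Unique because [net_charge()] is strictly
#' decreasing in pH.
#'
#' @inheritParams net_charge
#' @return The isoelectric pH.
#' @export
#' @examples
#' isoelectric_point("WR")
isoelectric_point <- function(p, pka_set = default_pka_table()) {
  p <- as_peptide(p, pka_set)
  f <- function(h) net_charge(p, h)
  if (f(0) * f(14) > 0) {
    stop("net charge does not change sign on pH 0..14; no isoelectric point",
         call. = FALSE)
  }
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) < 1e-6 || (hi - lo) < 1e-12) return(mid)
    if (v > 0) lo <- mid else hi <- mid
  }
}

#' Strong-base concentration needed to reach a target pH
#'
#' Solves the solution charge balance for the NaOH concentration that brings
#' a peptide solution to `target_pH`. The peptide is assumed supplied as a
#' TFA salt: `tfa_per_molecule` trifluoroacetate counterions per molecule
#' (default: one per basic group, i.e. the fully protonated supply form) are
#' carried as fully dissociated spectator anions. Charge balance:
#' \deqn{[Na^+] + [H^+] + C_p Z(pH) = [OH^-] + C_p n_{TFA}}
#'
#' @inheritParams net_charge
#' @param peptide_conc Peptide concentration, mol/L.
#' @param target_pH pH to reach.
#' @param tfa_per_molecule TFA counterions per peptide molecule; `NULL`
#'   (default) uses the number of basic groups.
#' @return NaOH concentration in mol/L.
#' @export
#' @examples
#' base_to_reach_pH("WWRR", peptide_conc = 0.04, target_pH = 12)
base_to_reach_pH <- function(p, peptide_conc, target_pH,
                             pka_set = default_pka_table(),
                             tfa_per_molecule = NULL) {
  p <- as_peptide(p, pka_set)
  stopifnot(peptide_conc >= 0, target_pH >= 0, target_pH <= 14)
  if (is.null(tfa_per_molecule)) {
    tfa_per_molecule <- sum(p$groups$charge_when_protonated == 1L)
  }
  cb <- base_required(p, peptide_conc, target_pH, tfa_per_molecule)
  if (cb < 0) {
    stop("target pH is below the solution's base-free pH; not reachable by adding base",
         call. = FALSE)
  }
  cb
}

base_required <- function(p, cp, pH, n_tfa) {
  k <- physical_constants()
  h <- 10^(-pH)
  oh <- k$Kw / h
  oh - h - cp * net_charge(p, pH) + cp * n_tfa
}

#' Simulated titration: pH as a function of added strong base
#'
#' Forward solve of the same charge balance used by [base_to_reach_pH()]:
#' for each NaOH concentration, finds the pH at which the balance closes.
#'
#' @inheritParams base_to_reach_pH
#' @param base_conc Vector of NaOH concentrations, mol/L.
#' @return A tibble with columns `base_conc`, `pH`.
#' @export
titration_curve <- function(p, peptide_conc, base_conc,
                            pka_set = default_pka_table(),
                            tfa_per_molecule = NULL) {
  p <- as_peptide(p, pka_set)
  if (is.null(tfa_per_molecule)) {
    tfa_per_molecule <- sum(p$groups$charge_when_protonated == 1L)
  }
  pH <- vapply(base_conc, function(cb) {
    f <- function(h) base_required(p, peptide_conc, h, tfa_per_molecule) - cb
    stats::uniroot(f, c(1e-6, 14 - 1e-6), tol = 1e-10)$root
  }, numeric(1))
  tibble::tibble(base_conc = base_conc, pH = pH)
}

#' Write a speciation table to CSV
#'
#' Long format `(pH, charge, fraction)`.
#'
#' @param spec A tibble from [speciation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_speciation_csv <- function(spec, path) {
  readr::write_csv(spec, path)
  invisible(path)
}
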