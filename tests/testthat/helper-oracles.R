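# Independent oracles used across the suite.

# Brute-force enumeration of all 2^N protonation microstates for a group
# table (label, pka, charge_when_protonated). Independent of the package's
# convolution: each microstate's probability is the product of per-site
# Henderson-Hasselbalch protonation probabilities.
enumerate_microstates <- function(groups, pH) {
  n <- nrow(groups)
  p <- 1 / (1 + 10^(pH - groups$pka))
  states <- expand.grid(rep(list(0:1), n))
  prob <- apply(states, 1, function(s) prod(ifelse(s == 1, p, 1 - p)))
  charge <- apply(states, 1, function(s) {
    sum(ifelse(groups$charge_when_protonated == 1, s, s - 1))
  })
  agg <- tapply(prob, charge, sum)
  tibble::tibble(charge = as.integer(names(agg)), fraction = as.numeric(agg))
}

# Closed-form Debye function for an ideal Gaussian chain, x = (q Rg)^2
debye_function <- function(x) 2 * (exp(-x) - 1 + x) / x^2

# Build a bare peptide_spec from an explicit group table (bypasses sequence
# parsing so degenerate site sets can be exercised)
make_spec <- function(groups, sequence = "X") {
  structure(list(sequence = sequence, groups = groups),
            class = "peptide_spec")
}

random_group_table <- function(n_sites) {
  tibble::tibble(
    label = paste0("g", seq_len(n_sites)),
    pka = stats::runif(n_sites, 2, 12.5),
    charge_when_protonated = sample(c(0L, 1L), n_sites, replace = TRUE)
  )
}
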