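test_that("parse_peptide builds the ionizable-group set", {
  p <- parse_peptide("WR")
  expect_setequal(p$groups$label, c("N-term", "C-term", "Arg-2"))

  p4 <- parse_peptide("WWRR")
  expect_equal(sum(grepl("^Arg", p4$groups$label)), 2)

  expect_error(parse_peptide("WX1"), "position 2")
  expect_error(parse_peptide(""), "empty")

  # FASTA text with header is accepted, header ignored
  pf <- parse_peptide(">pep1 test\nWWRR\n")
  expect_equal(pf$sequence, "WWRR")
})

test_that("monoisotopic and average masses match reference values", {
  expect_equal(monoisotopic_mass("WR"), 360.19)
  expect_equal(monoisotopic_mass("WWRR"), 702.37)
  expect_equal(monoisotopic_mass("WWWRRR"), 1044.55)
  expect_equal(monoisotopic_mass("G"), 75.03)

  expect_equal(round(average_mass("WR"), 1), 360.4)
  expect_equal(round(average_mass("WWRR"), 1), 702.8)
  expect_equal(average_mass("G"), 75.07)
})

test_that("masses are additive under peptide-bond condensation", {
  water_mono <- 18.010565
  expect_equal(monoisotopic_mass("WRWR"),
               2 * monoisotopic_mass("WR") - water_mono,
               tolerance = 1e-4)
})

test_that("net charge follows Henderson-Hasselbalch expectations", {
  # fully protonated Arg + N-term vs deprotonated C-term near pH 5.5
  expect_lt(abs(net_charge("WR", 5.5) - 1), 0.05)

  # single basic site at its pKa is half protonated
  single_base <- make_spec(tibble::tibble(
    label = "b", pka = 8, charge_when_protonated = 1L))
  expect_equal(net_charge(single_base, 8), 0.5)

  # strictly decreasing in pH
  ph <- seq(0, 14, by = 0.25)
  z <- net_charge("WWRR", ph)
  expect_true(all(diff(z) < 0))
})

test_that("net charge equals the microstate-enumeration expectation", {
  set.seed(42)
  for (n in c(2, 5, 8)) {
    g <- random_group_table(n)
    spec <- make_spec(g)
    for (ph in c(3, 7.2, 11)) {
      oracle <- enumerate_microstates(g, ph)
      expect_equal(net_charge(spec, ph),
                   sum(oracle$charge * oracle$fraction), tolerance = 1e-9)
    }
  }
})

test_that("speciation equals 2^N microstate enumeration and sums to 1", {
  set.seed(7)
  for (n in c(2, 6, 12)) {
    g <- random_group_table(n)
    spec <- make_spec(g)
    for (ph in c(4, 9.5)) {
      sp <- speciation(spec, ph)
      expect_equal(sum(sp$fraction), 1, tolerance = 1e-9)
      oracle <- enumerate_microstates(g, ph)
      merged <- merge(sp, oracle, by = "charge", all = TRUE)
      merged[is.na(merged)] <- 0
      expect_equal(merged$fraction.x, merged$fraction.y, tolerance = 1e-9)
      # expectation of the speciation equals the fractional net charge
      expect_equal(sum(sp$charge * sp$fraction), net_charge(spec, ph),
                   tolerance = 1e-9)
    }
  }
})

test_that("single base at its pKa splits 50:50 between charges 0 and +1", {
  single_base <- make_spec(tibble::tibble(
    label = "b", pka = 9, charge_when_protonated = 1L))
  sp <- speciation(single_base, 9)
  expect_equal(sp$fraction[sp$charge == 0], 0.5)
  expect_equal(sp$fraction[sp$charge == 1], 0.5)
})

test_that("hexapeptide speciation at high pH carries -1..+2 populations", {
  sp <- speciation("WWWRRR", 12)
  for (z in c(-1, 0, 1, 2)) {
    expect_gt(sp$fraction[sp$charge == z], 0.01)
  }
})

test_that("isoelectric point is the unique zero of the net charge", {
  sym <- make_spec(tibble::tibble(
    label = c("a", "b"), pka = c(4, 10),
    charge_when_protonated = c(0L, 1L)))
  expect_equal(isoelectric_point(sym), 7, tolerance = 1e-5)

  # bisection agrees with a dense grid scan
  for (seqn in c("WR", "WWRR", "DKE")) {
    pi_hat <- isoelectric_point(seqn)
    grid <- seq(0, 14, by = 1e-4)
    z <- net_charge(seqn, grid)
    cross <- grid[which(diff(sign(z)) < 0)[1]]
    expect_lt(abs(pi_hat - cross), 1e-3)
  }

  # WR's pI sits between the N-terminal and arginine pKas
  pka <- default_pka_table()
  pi_wr <- isoelectric_point("WR")
  expect_gt(pi_wr, pka$pka[pka$group == "N-term"])
  expect_lt(pi_wr, pka$pka[pka$group == "R"])

  # all-basic group set never crosses zero
  basic_only <- make_spec(tibble::tibble(
    label = c("a", "b"), pka = c(9, 12),
    charge_when_protonated = c(1L, 1L)))
  expect_error(isoelectric_point(basic_only), "sign")
})

test_that("base_to_reach_pH solves the charge balance", {
  # pure water + strong base
  p <- parse_peptide("WR")
  expect_equal(base_to_reach_pH(p, 0, 12), 0.01, tolerance = 1e-6)

  # inverse check: the forward titration re-crosses the target pH
  target <- 11.5
  cb <- base_to_reach_pH(p, 0.02, target)
  fwd <- titration_curve(p, 0.02, cb)
  expect_equal(fwd$pH, target, tolerance = 1e-6)

  # base cannot lower the pH below the TFA-salt solution's own acidic pH
  expect_error(base_to_reach_pH(p, 0.02, 2), "not reachable")

  # monotone in target pH
  cbs <- vapply(c(9, 10, 11, 12), function(t) base_to_reach_pH(p, 0.02, t),
                numeric(1))
  expect_true(all(diff(cbs) > 0))
})

test_that("pKa tables round-trip through CSV and are validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(default_pka_table(), path)
  tab <- read_pka_csv(path)
  expect_equal(tab$pka, default_pka_table()$pka)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("group,pKa,charge_when_protonated\nN-term,15,1", bad)
  expect_error(read_pka_csv(bad), "between 0 and 14")
})

test_that("speciation table writes to long CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  sp <- speciation("WR", c(7, 12))
  write_speciation_csv(sp, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("pH", "charge", "fraction"))
  expect_equal(nrow(back), nrow(sp))
})
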