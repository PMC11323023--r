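test_that("SAXS ASCII reader handles comments, sorting and bad rows", {
  path <- withr::local_tempfile(fileext = ".dat")
  q <- seq(0.01, 0.2, length.out = 100)
  writeLines(c("# q I err",
               paste(rev(q), rev(q)^-2, 0.01 * rev(q)^-2)), path)
  crv <- read_saxs_ascii(path)
  expect_equal(nrow(crv), 100)
  expect_false(is.unsorted(crv$q))
  expect_true("sigma" %in% names(crv))

  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 1.0", "-0.02 2.0"), bad)
  expect_error(read_saxs_ascii(bad), "line 2")

  onecol <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01", "0.02"), onecol)
  expect_error(read_saxs_ascii(onecol), "columns")
})

test_that("SAXS curves round-trip through ASCII", {
  synth <- gen_saxs(seed = 3)
  path <- withr::local_tempfile(fileext = ".dat")
  write_saxs_ascii(synth$curve, path)
  back <- read_saxs_ascii(path)
  expect_equal(back$q, synth$curve$q, tolerance = 1e-9)
  expect_equal(back$intensity, synth$curve$intensity, tolerance = 1e-9)
})

test_that("generalized Gaussian coil has the right limits", {
  # forward scattering normalization
  expect_equal(gg_coil_intensity(1e-8, rg = 10, nu = 0.4, scale = 3,
                                 background = 0.5), 3.5, tolerance = 1e-6)

  # nu = 1/2 reduces to the Debye function
  rg <- 7
  qrg <- 10^seq(log10(0.01), log10(10), length.out = 60)
  p <- gg_coil_intensity(qrg / rg, rg = rg, nu = 0.5)
  expect_equal(p, debye_function(qrg^2), tolerance = 1e-6)

  # Guinier regime
  q <- seq(0.01, 0.29, by = 0.02) / rg
  guinier <- 1 - q^2 * rg^2 / 3
  expect_equal(gg_coil_intensity(q, rg, 0.5), guinier, tolerance = 0.01)

  # positive and monotone non-increasing for nu in [0.3, 1]
  qs <- 10^seq(-3, 0.5, length.out = 80)
  for (nu in c(0.3, 0.5, 0.75, 1)) {
    v <- gg_coil_intensity(qs, rg = 12, nu = nu)
    expect_true(all(v > 0))
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("Porod term and peak structure factor behave as stated", {
  q <- c(0.01, 0.02, 0.04)
  expect_equal(diff(log(porod_term(q, 2, 4))) / diff(log(q)), c(-4, -4))
  expect_equal(porod_term(q, 0, 4), rep(0, 3))
  expect_equal(porod_term(0.02, 1, 4) / porod_term(0.01, 1, 4), 1 / 16)

  expect_equal(peak_structure_factor(seq(0, 1, 0.1), 0, 0.1, 30), rep(1, 11))
  expect_equal(peak_structure_factor(0.1, 0.7, 0.1, 30), 1.7)
  expect_equal(peak_structure_factor(50, 0.7, 0.1, 30), 1, tolerance = 1e-4)
})

test_that("composite model assembles its terms additively", {
  q <- 10^seq(log10(0.004), log10(0.4), length.out = 50)
  flat <- saxs_params(rg = 10, nu = 0.5, coil_scale = 0, porod_amplitude = 0,
                      background = 0.3)
  expect_equal(composite_intensity(q, flat, "coacervate"), rep(0.3, 50))
  expect_equal(composite_intensity(q, flat, "monomer"), rep(0.3, 50))

  p <- saxs_params(rg = 10, nu = 0.5, coil_scale = 1, porod_amplitude = 1e-8,
                   background = 0.01)
  expect_equal(composite_intensity(q, p, "coacervate"),
               porod_term(q, 1e-8, 4) + gg_coil_intensity(q, 10, 0.5) + 0.01)

  # low-q log-log slope approaches -n
  lowq <- c(0.004, 0.005)
  slope <- diff(log(composite_intensity(lowq, p, "coacervate"))) /
    diff(log(lowq))
  expect_equal(as.numeric(slope), -4, tolerance = 0.05)
})

test_that("noise-free fit from the truth is a fixed point", {
  truth <- saxs_params(rg = 9.23, nu = 0.4, coil_scale = 1,
                       porod_amplitude = 1e-8, background = 0.01)
  q <- 10^seq(log10(0.004), log10(0.4), length.out = 200)
  crv <- saxs_curve(q, composite_intensity(q, truth, "coacervate"))
  fit <- fit_saxs(crv, "coacervate", truth)
  expect_true(fit$converged)
  expect_equal(fit$params$rg, truth$rg, tolerance = 1e-8)
  expect_equal(fit$params$nu, truth$nu, tolerance = 1e-8)
  expect_lt(fit$reduced_chisq, 1e-16)
})

test_that("fit recovers the radius of gyration from noisy data", {
  synth <- gen_saxs(seed = 11)
  init <- saxs_params(rg = synth$truth$rg * 1.5, nu = synth$truth$nu * 1.5,
                      coil_scale = synth$truth$coil_scale * 1.5,
                      porod_amplitude = synth$truth$porod_amplitude * 1.5,
                      background = synth$truth$background * 1.5)
  fit <- fit_saxs(synth$curve, "coacervate", init)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$rg - synth$truth$rg) / synth$truth$rg, 0.05)
  # Porod exponent stays fixed at 4 by default
  expect_equal(fit$params$porod_exponent, 4)
  # descent: final misfit no worse than at the initial values
  resid0 <- (composite_intensity(synth$curve$q, init, "coacervate") -
               synth$curve$intensity) / synth$curve$sigma
  expect_lte(fit$reduced_chisq,
             sum(resid0^2) / (nrow(synth$curve) - 5))
})

test_that("fit is covariant under intensity rescaling", {
  synth <- gen_saxs(seed = 5)
  init <- saxs_params(rg = 12, nu = 0.5, coil_scale = 1.2,
                      porod_amplitude = 2e-8, background = 0.02)
  f1 <- fit_saxs(synth$curve, "coacervate", init)
  k <- 40
  scaled <- saxs_curve(synth$curve$q, k * synth$curve$intensity,
                       k * synth$curve$sigma)
  init_k <- saxs_params(rg = 12, nu = 0.5, coil_scale = k * 1.2,
                        porod_amplitude = k * 2e-8, background = k * 0.02)
  f2 <- fit_saxs(scaled, "coacervate", init_k)
  expect_equal(f2$params$rg, f1$params$rg, tolerance = 1e-6)
  expect_equal(f2$params$nu, f1$params$nu, tolerance = 1e-6)
  expect_equal(f2$params$coil_scale, k * f1$params$coil_scale,
               tolerance = 1e-6)
})

test_that("monomer variant fits a correlation peak", {
  synth <- gen_saxs(seed = 9, variant = "monomer")
  init <- synth$truth
  init$rg <- init$rg * 1.3
  init$peak_amplitude <- init$peak_amplitude * 1.4
  fit <- fit_saxs(synth$curve, "monomer", init)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$rg - synth$truth$rg) / synth$truth$rg, 0.1)
  expect_lt(abs(fit$params$peak_q0 - 0.1), 0.01)
})

test_that("tidy and glance summarize fits in broom style", {
  synth <- gen_saxs(seed = 2)
  fit <- fit_saxs(synth$curve, "coacervate", synth$truth)
  td <- tidy(fit)
  expect_setequal(td$term, c("porod_amplitude", "porod_exponent",
                             "coil_scale", "rg", "nu", "background"))
  expect_true(td$fixed[td$term == "porod_exponent"])
  expect_true(all(is.na(td$std.error[td$fixed])))
  gl <- glance(fit)
  expect_equal(gl$nobs, 200)
  expect_s3_class(autoplot(fit), "ggplot")
})
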