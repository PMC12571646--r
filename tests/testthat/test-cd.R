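# single-peak spectrum whose negative far-UV band vanishes above 207 nm,
# so the sampled maximum in the 210-230 nm band is exactly `peak_mre`
make_spectrum <- function(peak_mre, peak_nm = 212, wl = 190:260, temperature = 0) {
  lobe <- pmax(0, exp(-(wl - 197)^2 / (2 * 5^2)) - exp(-(207 - 197)^2 / (2 * 5^2)))
  tibble::tibble(
    wavelength_nm = wl,
    mre = peak_mre * exp(-(wl - peak_nm)^2 / (2 * 6^2)) - 3000 * lobe,
    temperature_C = temperature,
    label = paste0("T", temperature)
  )
}

test_that("theta_max reads the sampled maximum with lower-wavelength tie-break", {
  sp <- make_spectrum(1000)
  tm <- theta_max(sp)
  expect_equal(tm$lambda_max_nm, 212)
  expect_equal(tm$theta_max, 1000)

  flat <- tibble::tibble(wavelength_nm = 190:260, mre = 0)
  tm0 <- theta_max(flat)
  expect_equal(tm0$lambda_max_nm, 210)
  expect_equal(tm0$theta_max, 0)

  truncated <- dplyr::filter(sp, wavelength_nm >= 220)
  expect_error(theta_max(truncated), "does not span")

  # several spectra in one table: one row each
  two <- dplyr::bind_rows(make_spectrum(1000, temperature = 0), make_spectrum(500, temperature = 65))
  tm2 <- theta_max(two)
  expect_equal(nrow(tm2), 2)
  expect_equal(sort(tm2$theta_max), c(500, 1000))
})

test_that("the empirical CD relation gives the printed populations and is affine", {
  expect_equal(round(ppii_population(1000)), 43)
  expect_equal(round(ppii_population(1600)), 47)
  expect_identical(ppii_population(-5560), 0)
  expect_identical(ppii_population(9580), 100)
  # affine and strictly increasing, unclamped with a warning outside [0, 100]
  th <- seq(-8000, 12000, by = 500)
  pop <- suppressWarnings(ppii_population(th))
  expect_true(all(diff(pop) > 0))
  expect_lt(max(abs(diff(diff(pop)))), 1e-9)
  expect_warning(ppii_population(-6000), "outside")
  expect_warning(ppii_population(12000), "outside")
  expect_error(ppii_population(NA_real_), "finite")
})

test_that("melt fitting recovers the printed linear melts exactly", {
  t_grid <- seq(0, 65, by = 5)
  for (ab in list(c(835, -10.8), c(13200, -15.8))) {
    tr <- tibble::tibble(
      temperature_C = t_grid,
      mre = ab[1] + ab[2] * t_grid,
      wavelength_nm = 217
    )
    fit <- fit_melt(tr)
    expect_equal(fit$intercept, ab[1], tolerance = 1e-9)
    expect_equal(fit$slope, ab[2], tolerance = 1e-9)
    expect_lt(abs(abs(fit$r) - 1), 1e-9)
    expect_false(fit$degenerate)
    td <- tidy(fit)
    expect_equal(td$estimate, c(ab[1], ab[2]), tolerance = 1e-9)
    expect_equal(glance(fit)$wavelength_nm, 217)
  }
})

test_that("melt fitting is scale-equivariant and handles degenerate traces", {
  set.seed(4)
  tr <- tibble::tibble(temperature_C = seq(0, 60, 5), mre = 900 - 9 * seq(0, 60, 5) + rnorm(13, 0, 20))
  f1 <- fit_melt(tr)
  tr2 <- dplyr::mutate(tr, mre = 3.5 * mre)
  f2 <- fit_melt(tr2)
  expect_equal(f2$intercept, 3.5 * f1$intercept, tolerance = 1e-9)
  expect_equal(f2$slope, 3.5 * f1$slope, tolerance = 1e-9)
  expect_equal(f2$r, f1$r, tolerance = 1e-12)

  flat <- tibble::tibble(temperature_C = seq(0, 60, 5), mre = 500)
  ff <- fit_melt(flat)
  expect_true(ff$degenerate)
  expect_equal(ff$slope, 0)
  expect_equal(ff$r, 0)

  expect_error(fit_melt(flat[1:2, ]), "At least 3")
  expect_error(
    fit_melt(tibble::tibble(temperature_C = rep(5, 4), mre = 1:4)),
    "identical"
  )
})

test_that("difference spectra subtract pointwise and are antisymmetric", {
  a <- make_spectrum(1000, temperature = 5)
  b <- make_spectrum(400, temperature = 65)
  self <- difference_spectrum(a, a)
  expect_true(all(self$mre == 0))
  d_ab <- difference_spectrum(a, b)
  d_ba <- difference_spectrum(b, a)
  expect_equal(d_ab$mre, -d_ba$mre)
  expect_equal(unique(d_ab$label), "5C - 65C")

  shifted <- dplyr::mutate(b, wavelength_nm = wavelength_nm + 0.5)
  expect_error(difference_spectrum(a, shifted), "grids differ")
  expect_error(difference_spectrum(a, shifted, restrict = TRUE), "no wavelengths")
  # common-grid restriction when grids merely overlap
  partial <- dplyr::filter(b, wavelength_nm >= 200)
  d_r <- difference_spectrum(a, partial, restrict = TRUE)
  expect_equal(range(d_r$wavelength_nm), c(200, 260))
})

test_that("linearity diagnostics separate linear from sigmoidal melts", {
  t_grid <- seq(0, 65, by = 5)
  lin <- tibble::tibble(temperature_C = t_grid, mre = 835 - 10.8 * t_grid)
  out <- linearity_check(lin)
  expect_true(out$linear)
  expect_equal(out$longest_sign_run, 0L)

  # steep two-state melt, midpoint 30 C
  sig <- tibble::tibble(
    temperature_C = t_grid,
    mre = 100 + 800 / (1 + exp((t_grid - 30) / 3))
  )
  out_sig <- linearity_check(sig)
  expect_false(out_sig$linear)

  set.seed(8)
  span <- 835 - 10.8 * t_grid
  noisy <- tibble::tibble(
    temperature_C = t_grid,
    mre = span + rnorm(length(t_grid), 0, 0.05 * diff(range(span)) / 2)
  )
  expect_true(linearity_check(noisy)$linear)

  # flat control passes as (degenerately) linear
  flat <- tibble::tibble(temperature_C = t_grid, mre = 0)
  expect_true(linearity_check(flat)$linear)
})

test_that("populations derived from a linear melt are linear in temperature", {
  sim <- simulate_cd_series(pop0 = 43.3, slope_pop = -0.0713)
  pop <- suppressWarnings(ppii_population(sim$melt$mre))
  fit <- lm(pop ~ sim$melt$temperature_C)
  expect_lt(max(abs(resid(fit))) / max(abs(pop)), 1e-9)
})

test_that("raw millidegree conversion applies the mean residue weight per bond", {
  # 14-residue peptide of mass 1000 Da: MRW = 1000/13
  expect_equal(
    mre_from_millideg(50, 1000, 14, 0.1, 0.5),
    50 * (1000 / 13) / (10 * 0.1 * 0.5)
  )
  expect_error(mre_from_millideg(50, 1000, 1, 0.1, 0.5), "n_residues")
  expect_error(mre_from_millideg(50, 1000, 14, 0, 0.5), "positive")
})
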