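test_that("backbone builder validates its inputs", {
  expect_error(build_backbone("AGG", phi = c(NA, -75), psi = c(150, 150, NA)), "match the sequence length")
  expect_error(build_backbone("AGG", phi = numeric(0), psi = numeric(0)), "match the sequence length")
  expect_error(build_backbone("AXG", phi = c(NA, 0, 0), psi = c(0, 0, NA)), "Nonstandard")
  expect_error(build_backbone("AGG", phi = c(NA, NA, 0), psi = c(0, 0, NA)), "finite")
  expect_error(peptide_geometry(b_n_ca = -1), "positive")
  expect_error(peptide_geometry(ang_n_ca_c = 180), "0, 180")
})

test_that("the fully extended conformation maximizes end-to-end distance", {
  n <- 10
  end_to_end <- function(phi, psi) {
    bb <- build_backbone(strrep("G", n), rep(phi, n), rep(psi, n))
    p1 <- as.numeric(bb[1, c("x", "y", "z")])
    p2 <- as.numeric(bb[nrow(bb), c("x", "y", "z")])
    sqrt(sum((p2 - p1)^2))
  }
  ext <- end_to_end(180, 180)
  grid <- tidyr::expand_grid(phi = seq(-120, 180, 60), psi = seq(-120, 180, 60))
  others <- grid[!(grid$phi == 180 & grid$psi == 180), ]
  d <- mapply(end_to_end, others$phi, others$psi)
  expect_true(all(d < ext))
})

test_that("simulated ensembles are bit-identical for identical specs", {
  spec <- simulation_spec(n_frames = 100, occupancy = 0.3, persistence = 3, seed = 99)
  e1 <- simulate_ensemble(spec)
  e2 <- simulate_ensemble(simulation_spec(n_frames = 100, occupancy = 0.3, persistence = 3, seed = 99))
  expect_identical(e1, e2)
  e3 <- simulate_ensemble(simulation_spec(n_frames = 100, occupancy = 0.3, persistence = 3, seed = 100))
  expect_false(identical(e1$phi_deg, e3$phi_deg))
})

test_that("spec validation enforces the occupancy/persistence constraint", {
  expect_error(simulation_spec(occupancy = 1.2), "\\[0, 1\\]")
  expect_error(simulation_spec(persistence = 0.5), "persistence")
  expect_error(simulation_spec(occupancy = 0.7, persistence = 1), "increase `persistence`")
  # attainable with more persistent states
  expect_s3_class(simulation_spec(occupancy = 0.7, persistence = 5), "simulation_spec")
  # degenerate occupancies are always allowed
  expect_s3_class(simulation_spec(occupancy = 1, persistence = 1), "simulation_spec")
})

test_that("degenerate occupancies saturate the classifier", {
  all_in <- simulate_ensemble(simulation_spec(n_chains = 2, n_frames = 50, occupancy = 1, seed = 3))
  defined <- !is.na(all_in$phi_deg) & !is.na(all_in$psi_deg)
  expect_true(all(is_ppii(all_in$phi_deg, all_in$psi_deg)[defined]))
  none <- simulate_ensemble(simulation_spec(n_chains = 2, n_frames = 50, occupancy = 0, seed = 3))
  expect_false(any(is_ppii(none$phi_deg, none$psi_deg)))
})

test_that("empirical occupancy is stationary at the nominal value", {
  spec <- simulation_spec(n_frames = 2000, occupancy = 0.30, seed = 41)
  ens <- simulate_ensemble(spec)
  defined <- !is.na(ens$phi_deg) & !is.na(ens$psi_deg)
  p_hat <- sum(is_ppii(ens$phi_deg, ens$psi_deg)) / sum(defined)
  se <- sqrt(0.3 * 0.7 / sum(defined))
  expect_lt(abs(p_hat - 0.30), 3 * se)
  # first and second halves agree (no transient)
  halves <- split(seq_len(2000), rep(1:2, each = 1000))
  for (h in halves) {
    sub <- ens[ens$frame %in% h & defined, ]
    expect_lt(abs(mean(is_ppii(sub$phi_deg, sub$psi_deg)) - 0.30), 4 * sqrt(0.3 * 0.7 / nrow(sub)))
  }
})

test_that("mean PPII dwell times match the persistence parameter", {
  mean_dwell <- function(persistence) {
    spec <- simulation_spec(
      n_chains = 1, sequence = strrep("A", 12), n_frames = 5000,
      occupancy = 0.3, persistence = persistence, seed = 7 + persistence
    )
    ens <- simulate_ensemble(spec)
    runs <- ens |>
      dplyr::filter(residue_index %in% 2:11) |>
      dplyr::group_by(residue_index) |>
      dplyr::arrange(frame, .by_group = TRUE) |>
      dplyr::summarise(dwell = list({
        r <- rle(is_ppii(phi_deg, psi_deg))
        # drop runs touching either end (censored dwells)
        keep <- r$values
        if (length(keep) > 0) keep[1] <- FALSE
        if (length(keep) > 1) keep[length(keep)] <- FALSE
        r$lengths[keep & r$values]
      }))
    mean(unlist(runs$dwell))
  }
  for (p in c(1, 5, 20)) {
    expect_lt(abs(mean_dwell(p) - p) / p, 0.10)
  }
})

test_that("simulated ensembles feed the trajectory analysis without coercion", {
  ens <- simulate_ensemble(simulation_spec(n_frames = 100, occupancy = 0.25, seed = 12))
  rep <- ppii_report(ens)
  expect_s3_class(rep, "ppii_report")
  expect_equal(nrow(rep$per_residue), 7 * 14)
  expect_true(all(rep$per_segment_windowed$fraction >= 0 & rep$per_segment_windowed$fraction <= 1))
})

test_that("CD series invert the population equation exactly and melt linearly", {
  sim <- simulate_cd_series(pop0 = 43.3, slope_pop = -0.0713)
  pops <- cd_populations(sim$spectra)
  expect_equal(pops$ppii_percent, 43.3 - 0.0713 * pops$temperature_C, tolerance = 1e-12)
  expect_true(all(pops$lambda_max_nm == 212))

  fit <- fit_melt(sim$melt)
  expect_lt(abs(abs(fit$r) - 1), 1e-9)

  # no population change: difference spectra vanish identically
  flat <- simulate_cd_series(pop0 = 30, slope_pop = 0, temps = c(5, 65))
  d <- difference_spectrum(
    dplyr::filter(flat$spectra, temperature_C == 5),
    dplyr::filter(flat$spectra, temperature_C == 65)
  )
  expect_true(all(d$mre == 0))

  expect_error(simulate_cd_series(pop0 = 99, slope_pop = 1), "\\[0, 100\\]")
  expect_error(simulate_cd_series(melt_wavelength = 216.5), "not on the basis grid")
})

test_that("difference spectra recover the PPII basis shape up to a positive scalar", {
  sim <- simulate_cd_series()
  d <- difference_spectrum(
    dplyr::filter(sim$spectra, temperature_C == 0),
    dplyr::filter(sim$spectra, temperature_C == 65)
  )
  basis <- cd_basis_spectra()
  cosine <- sum(d$mre * basis$ppii) / sqrt(sum(d$mre^2) * sum(basis$ppii^2))
  expect_gt(cosine, 0.999)
  expect_gt(max(d$mre), 0)
})

test_that("simulated shift tables span the intended secondary-shift regimes", {
  zero <- simulate_shift_table("AGGMGGMGGMGGMM", dca_scale = 0, seed = 5)
  expect_true(all(conformational_shift(zero$ca_obs_ppm, zero$ca_ref_ppm) == 0))
  expect_true(segment_verdict(zero)$no_alpha_beta)

  small <- simulate_shift_table("AMGGMGGGMGGGMF", dca_scale = 0.2, seed = 6)
  expect_true(segment_verdict(small)$no_alpha_beta)

  big <- simulate_shift_table("EPEPVPVGNPMDNSGYGY", dca_scale = 5, seed = 7)
  v <- segment_verdict(big)
  expect_false(v$no_alpha_beta)
  expect_gt(v$frac_alpha + v$frac_beta + v$frac_ambiguous, 0.1)

  expect_error(simulate_shift_table("AG", dca_scale = -1), "dca_scale")
})
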