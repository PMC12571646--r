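test_that("saturated and empty ensembles give fractions 1 and 0 everywhere", {
  segs <- groel_segments("CtS")
  full <- constant_ensemble(100, 2, 14, phi = -75, psi = 150)
  wc <- ppii_windowed_content(full, segs, window_ns = 50, stride_ns = 50)
  expect_true(all(wc$fraction == 1))
  expect_equal(nrow(wc), 2 * 2) # 2 chains x 2 windows

  none <- constant_ensemble(100, 2, 14, phi = 60, psi = -60)
  wc0 <- ppii_windowed_content(none, segs, window_ns = 50, stride_ns = 50)
  expect_true(all(wc0$fraction == 0))

  pr <- ppii_per_residue(full)
  expect_true(all(pr$mean_fraction == 1))
  expect_equal(ppii_run_summary(wc, "CtS")$fraction, 1)
})

test_that("windowed content recovers a known stationary occupancy", {
  spec <- simulation_spec(n_frames = 1000, occupancy = 0.30, seed = 11)
  ens <- simulate_ensemble(spec)
  # one window covering the whole run
  wc <- ppii_windowed_content(ens, groel_segments("CtS"),
    segment = "CtS",
    window_ns = 1000, stride_ns = 1000
  )
  est <- ppii_run_summary(wc, "CtS")$fraction
  n_obs <- sum(wc$n_obs)
  se <- sqrt(0.30 * 0.70 / n_obs)
  expect_lt(abs(est - 0.30), 3 * se)
})

test_that("per-residue populations: pinned, alternating and terminal residues", {
  segs <- groel_segments("CtS")
  # residue 5 alternates in/out each frame, residue 8 always in, rest out
  ens <- rule_ensemble(200, 1, 14, function(frame, chain, res) {
    (res == 5 & frame %% 2 == 0) | res == 8
  })
  pr <- ppii_per_residue(ens)
  expect_equal(pr$mean_fraction[pr$residue_index == 5], 0.5)
  expect_equal(pr$mean_fraction[pr$residue_index == 8], 1.0)
  expect_equal(pr$mean_fraction[pr$residue_index == 1], 0.0)

  # simulated ensembles mark termini as NA with zero denominators
  ens2 <- simulate_ensemble(simulation_spec(n_frames = 50, occupancy = 0.3, seed = 2))
  pr2 <- ppii_per_residue(ens2)
  term <- pr2[pr2$residue_index %in% c(1, 14), ]
  expect_true(all(is.na(term$mean_fraction)))
  expect_true(all(term$n_obs == 0))
  expect_true(all(pr2$n_obs[!pr2$residue_index %in% c(1, 14)] > 0))
})

test_that("per-residue estimator recovers an occupancy profile within 3 SE", {
  p_profile <- c(0.4, seq(0.1, 0.7, by = 0.1), 0.4)
  spec <- simulation_spec(
    n_chains = 7, sequence = strrep("A", 9), n_frames = 2000,
    occupancy = p_profile, persistence = 5, seed = 31
  )
  ens <- simulate_ensemble(spec)
  pr <- ppii_per_residue(ens) |>
    dplyr::group_by(residue_index) |>
    dplyr::summarise(
      est = sum(mean_fraction * n_obs) / sum(n_obs),
      n = sum(n_obs)
    )
  for (i in 2:8) {
    p <- p_profile[i]
    row <- pr[pr$residue_index == i, ]
    # Markov-chain variance inflation for the mean of a correlated indicator
    lam <- 1 - 1 / 5 - p / (5 * (1 - p))
    se <- sqrt(p * (1 - p) / row$n * (1 + lam) / (1 - lam))
    expect_lt(abs(row$est - p), 3 * se)
  }
})

test_that("repeat content segregates and is exchangeable under uniform occupancy", {
  segs <- groel_segments("CtS")
  # only GGM1 (residues 2-4) ever occupies the window
  ens <- rule_ensemble(100, 3, 14, function(frame, chain, res) res %in% 2:4)
  rep_tbl <- ppii_per_repeat(ens, segs, window_ns = 100, stride_ns = 100)
  expect_equal(rep_tbl$fraction[rep_tbl$segment == "GGM1"], 1)
  expect_true(all(rep_tbl$fraction[rep_tbl$segment != "GGM1"] == 0))

  # uniform occupancy: no repeat differs from another beyond sampling noise
  ens2 <- simulate_ensemble(simulation_spec(n_frames = 2000, occupancy = 0.25, seed = 17))
  rep2 <- ppii_per_repeat(ens2, segs, window_ns = 2000, stride_ns = 2000)
  p <- 0.25
  se_diff <- sqrt(2 * p * (1 - p) / min(rep2$n_obs))
  diffs <- abs(outer(rep2$fraction, rep2$fraction, "-"))
  expect_lt(max(diffs), 3 * se_diff)

  expect_error(
    ppii_per_repeat(ens, segment_map(CtS = 1:14), window_ns = 50),
    "No GGM repeats"
  )
})

test_that("denominators are conserved and windows aggregate to the run mean", {
  spec <- simulation_spec(n_frames = 400, occupancy = 0.3, seed = 5)
  ens <- simulate_ensemble(spec)
  segs <- groel_segments("CtS")
  wc <- ppii_windowed_content(ens, segs, segment = "CtS", window_ns = 50, stride_ns = 50)

  # per window: denominator equals the defined-dihedral observation count
  defined <- !is.na(ens$phi_deg) & !is.na(ens$psi_deg)
  expect_equal(sum(wc$n_obs), sum(defined))

  # windows tile the run exactly: observation-weighted window mean equals
  # the pooled whole-run mean
  pooled <- sum(is_ppii(ens$phi_deg, ens$psi_deg)) / sum(defined)
  expect_equal(ppii_run_summary(wc, "CtS")$fraction, pooled, tolerance = 1e-12)
})

test_that("segment content nests: CtC is the weighted average of CtS and its complement", {
  segs <- dplyr::bind_rows(
    groel_segments("CtC"),
    segment_map(head24 = 1:10)
  )
  spec <- simulation_spec(
    sequence = "PKNDAADLGAAGGMGGMGGMGGMM",
    n_frames = 300, occupancy = 0.25, seed = 23
  )
  ens <- simulate_ensemble(spec)
  wc <- ppii_windowed_content(ens, segs,
    segment = c("CtC", "CtS", "head24"),
    window_ns = 50, stride_ns = 50
  )
  wide <- tidyr::pivot_wider(wc,
    id_cols = c("chain", "time_ns"),
    names_from = "segment", values_from = c("fraction", "n_obs")
  )
  lhs <- wide$fraction_CtC * wide$n_obs_CtC
  rhs <- wide$fraction_CtS * wide$n_obs_CtS + wide$fraction_head24 * wide$n_obs_head24
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_equal(wide$n_obs_CtC, wide$n_obs_CtS + wide$n_obs_head24)
})

test_that("run-summary estimator bias is below 0.01 across occupancies", {
  for (p in c(0.05, 0.15, 0.25, 0.35)) {
    spec <- simulation_spec(n_frames = 1000, occupancy = p, seed = 100 + round(100 * p))
    ens <- simulate_ensemble(spec)
    wc <- ppii_windowed_content(ens, groel_segments("CtS"),
      segment = "CtS",
      window_ns = 50, stride_ns = 50
    )
    est <- ppii_run_summary(wc, "CtS")$fraction
    expect_lt(abs(est - p), 0.01)
  }
})

test_that("chain weighting and observation weighting agree on balanced designs", {
  ens <- simulate_ensemble(simulation_spec(n_frames = 200, occupancy = 0.3, seed = 9))
  wc <- ppii_windowed_content(ens, groel_segments("CtS"), segment = "CtS")
  obs <- ppii_run_summary(wc, "CtS", weights = "observation")
  chn <- ppii_run_summary(wc, "CtS", weights = "chain")
  expect_equal(obs$fraction, chn$fraction, tolerance = 1e-12)
  expect_equal(obs$weighting, "observation")
  expect_equal(chn$weighting, "chain")
})

test_that("windowing preconditions are enforced", {
  ens <- constant_ensemble(20, 1, 14, -75, 150)
  segs <- groel_segments("CtS")
  expect_error(ppii_windowed_content(ens, segs, segment = "nope"), "Unknown segment")
  expect_error(
    ppii_windowed_content(ens, segs, window_ns = 50, stride_ns = 50),
    "shorter than one"
  )
  expect_error(
    ppii_windowed_content(ens, segment_map(far = 50:60), segment = "far"),
    "no residues present"
  )
  # a segment holding only a terminal residue has no defined dihedrals
  expect_error(
    ppii_windowed_content(
      simulate_ensemble(simulation_spec(n_frames = 20, seed = 1)),
      segment_map(tail_end = 14L), segment = "tail_end", window_ns = 10, stride_ns = 10
    ),
    "no residues with defined"
  )
  expect_error(segment_map(GGM1 = 1:4), "exactly 3")
  expect_error(segment_map(GGM1 = 1:3, GGM2 = 3:5), "disjoint")
  expect_error(segment_map(1:3), "named")
})
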