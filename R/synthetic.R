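# Synthetic-data generators: ideal-geometry backbones, two-state dihedral
# ensembles with known PPII occupancy, CD melt series and coil-like shift
# tables. These stand in for microsecond MD trajectories and spectrometer
# output so that every analysis stage can be validated against known
# ground truth.

.AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
  Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", V = "VAL",
  W = "TRP", Y = "TYR"
)

.split_sequence <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1L]]
  }
  toupper(sequence)
}

#' Ideal peptide backbone geometry
#'
#' Standard bond lengths (angstroms) and angles (degrees) used by the
#' internal-coordinate backbone builder; the peptide bond is held trans
#' (omega = 180).
#'
#' @param b_n_ca,b_ca_c,b_c_n Bond lengths N-CA, CA-C and C-N (angstroms).
#' @param ang_n_ca_c,ang_ca_c_n,ang_c_n_ca Backbone bond angles (degrees).
#' @param omega Peptide bond torsion (degrees).
#' @return A list of class `peptide_geometry`.
#' @export
peptide_geometry <- function(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                             ang_n_ca_c = 111.0, ang_ca_c_n = 116.6,
                             ang_c_n_ca = 121.7, omega = 180) {
  g <- list(
    b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n,
    ang_n_ca_c = ang_n_ca_c, ang_ca_c_n = ang_ca_c_n,
    ang_c_n_ca = ang_c_n_ca, omega = omega
  )
  if (any(unlist(g[1:3]) <= 0)) abort("Bond lengths must be positive.")
  angs <- unlist(g[4:6])
  if (any(angs <= 0 | angs >= 180)) abort("Bond angles must lie in (0, 180) degrees.")
  structure(g, class = "peptide_geometry")
}

# Natural-extension-reference-frame placement: position atom D given the
# three preceding atoms A, B, C, the C-D bond length, the B-C-D angle and
# the A-B-C-D torsion. Angles in degrees.
.place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  theta <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  d2 <- c(
    -bond * cos(theta),
    bond * sin(theta) * cos(chi),
    -bond * sin(theta) * sin(chi)
  )
  bc <- c - b
  bc_hat <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(
    ab[2] * bc_hat[3] - ab[3] * bc_hat[2],
    ab[3] * bc_hat[1] - ab[1] * bc_hat[3],
    ab[1] * bc_hat[2] - ab[2] * bc_hat[1]
  )
  n_hat <- n / sqrt(sum(n^2))
  m_hat <- c(
    n_hat[2] * bc_hat[3] - n_hat[3] * bc_hat[2],
    n_hat[3] * bc_hat[1] - n_hat[1] * bc_hat[3],
    n_hat[1] * bc_hat[2] - n_hat[2] * bc_hat[1]
  )
  M <- cbind(bc_hat, m_hat, n_hat)
  as.numeric(M %*% d2 + c)
}

#' Build an ideal-geometry peptide backbone from dihedrals
#'
#' Grows an N/CA/C backbone by internal-coordinate placement (bond length,
#' bond angle, torsion) with a trans peptide bond. The phi of the first
#' residue and the psi of the last are not realizable without flanking
#' atoms and are ignored (they may be `NA`). Recomputing dihedrals from
#' the built chain with [chain_dihedrals()] recovers the inputs to
#' numerical precision, which makes the builder the round-trip oracle for
#' the torsion code.
#'
#' @param sequence Peptide sequence: a 1-letter string or character vector.
#' @param phi,psi Dihedral vectors in degrees, one entry per residue.
#' @param geometry A [peptide_geometry()].
#' @param chain,model Labels stored in the output table.
#' @return A backbone coordinate tibble (one row per atom) as consumed by
#'   [chain_dihedrals()] and [write_backbone_pdb()].
#' @examples
#' bb <- build_backbone("AGG", phi = c(NA, -75, -75), psi = c(150, 150, NA))
#' chain_dihedrals(bb)
#' @export
build_backbone <- function(sequence, phi, psi, geometry = peptide_geometry(),
                           chain = "A", model = 1L) {
  seq1 <- .split_sequence(sequence)
  n <- length(seq1)
  if (n < 1L) abort("`sequence` must contain at least one residue.")
  if (length(phi) != n || length(psi) != n) {
    abort(sprintf(
      "Dihedral vectors must match the sequence length (%d residues; got %d phi, %d psi).",
      n, length(phi), length(psi)
    ))
  }
  unknown <- !(seq1 %in% names(.AA3))
  if (any(unknown)) {
    abort(sprintf(
      "Nonstandard residue code(s) at position(s) %s: %s",
      paste(which(unknown), collapse = ", "), paste(seq1[unknown], collapse = ", ")
    ))
  }
  if (n >= 2L) {
    need_phi <- phi[2:n]
    need_psi <- psi[1:(n - 1L)]
    if (any(!is.finite(need_phi)) || any(!is.finite(need_psi))) {
      abort("Interior dihedrals (phi of residues 2..n, psi of residues 1..n-1) must be finite.")
    }
  }
  g <- geometry
  stopifnot(inherits(g, "peptide_geometry"))

  # canonical frame for residue 1
  pos <- matrix(NA_real_, nrow = 3L * n, ncol = 3L) # rows: N1, CA1, C1, N2, ...
  pos[1L, ] <- c(0, 0, 0)
  pos[2L, ] <- c(g$b_n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  pos[3L, ] <- pos[2L, ] + g$b_ca_c * c(-cos(th), sin(th), 0)

  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      iN <- 3L * (i - 1L) + 1L
      # N(i+1) from N(i), CA(i), C(i) via psi_i
      pos[iN + 3L, ] <- .place_atom(
        pos[iN, ], pos[iN + 1L, ], pos[iN + 2L, ],
        g$b_c_n, g$ang_ca_c_n, psi[i]
      )
      # CA(i+1) from CA(i), C(i), N(i+1) via omega
      pos[iN + 4L, ] <- .place_atom(
        pos[iN + 1L, ], pos[iN + 2L, ], pos[iN + 3L, ],
        g$b_n_ca, g$ang_c_n_ca, g$omega
      )
      # C(i+1) from C(i), N(i+1), CA(i+1) via phi_{i+1}
      pos[iN + 5L, ] <- .place_atom(
        pos[iN + 2L, ], pos[iN + 3L, ], pos[iN + 4L, ],
        g$b_ca_c, g$ang_n_ca_c, phi[i + 1L]
      )
    }
  }

  tibble(
    model = as.integer(model),
    chain = chain,
    residue_index = rep(seq_len(n), each = 3L),
    residue_name = rep(unname(.AA3[seq1]), each = 3L),
    atom = rep(c("N", "CA", "C"), times = n),
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L]
  )
}

#' Specification of a synthetic two-state dihedral ensemble
#'
#' Describes the simulated system: a number of independent chains sharing
#' one sequence, a frame grid, a per-residue stationary PPII occupancy and
#' a dwell-time (persistence) parameter controlling temporal
#' autocorrelation. Defaults mirror the chaperonin tail system: seven
#' chains of the GroEL Gly/Met-rich short tail (CtS, AGGMGGMGGMGGMM).
#'
#' Each residue follows an independent two-state Markov chain. The PPII
#' state is left with probability `1 / persistence` per frame, so the mean
#' dwell in the PPII state is exactly `persistence` frames; the entry
#' probability is set so that the stationary occupancy equals `occupancy`.
#' `persistence = 1` therefore gives single-frame PPII visits. The
#' construction requires `occupancy <= persistence / (1 + persistence)`
#' (with the degenerate occupancies 0 and 1 always allowed).
#'
#' @param n_chains Number of independent chains.
#' @param sequence 1-letter sequence shared by all chains.
#' @param n_frames Number of frames.
#' @param dt_ns Frame spacing in nanoseconds.
#' @param occupancy Per-residue stationary PPII probability in `[0, 1]`;
#'   a scalar is recycled across residues.
#' @param persistence Expected PPII dwell time in frames (>= 1).
#' @param seed Integer seed; identical specs reproduce bit-identical
#'   ensembles.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_chains = 7, sequence = "AGGMGGMGGMGGMM",
                            n_frames = 1000, dt_ns = 1, occupancy = 0.25,
                            persistence = 1, seed = 1) {
  seq1 <- .split_sequence(sequence)
  n_res <- length(seq1)
  if (n_res < 2L) abort("`sequence` must have at least 2 residues.")
  occupancy <- rep_len(as.numeric(occupancy), n_res)
  if (any(!is.finite(occupancy)) || any(occupancy < 0 | occupancy > 1)) {
    abort("`occupancy` values must lie in [0, 1].")
  }
  if (persistence < 1) abort("`persistence` must be >= 1 frame.")
  interior <- occupancy > 0 & occupancy < 1
  p_max <- persistence / (1 + persistence)
  if (any(occupancy[interior] > p_max + 1e-12)) {
    abort(sprintf(
      "occupancy must be <= persistence / (1 + persistence) = %.4f for persistence = %g; increase `persistence` for higher occupancies.",
      p_max, persistence
    ))
  }
  if (n_chains < 1 || n_frames < 1 || dt_ns <= 0) {
    abort("`n_chains` and `n_frames` must be >= 1 and `dt_ns` > 0.")
  }
  structure(
    list(
      n_chains = as.integer(n_chains), sequence = seq1,
      n_frames = as.integer(n_frames), dt_ns = dt_ns,
      occupancy = occupancy, persistence = persistence,
      seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

# uniform draw from the torus excluding the PPII window, by rejection
.draw_coil <- function(m, window) {
  phi <- runif(m, -180, 180)
  psi <- runif(m, -180, 180)
  repeat {
    inside <- is_ppii(phi, psi, window)
    if (!any(inside)) break
    k <- sum(inside)
    phi[inside] <- runif(k, -180, 180)
    psi[inside] <- runif(k, -180, 180)
  }
  list(phi = phi, psi = psi)
}

#' Simulate a two-state dihedral ensemble with known PPII occupancy
#'
#' Generates per-frame (phi, psi) angles for every residue of every chain
#' of a [simulation_spec()]. In the PPII state angles are drawn uniformly
#' inside `window` (so nominal occupancy equals classifiable occupancy
#' exactly); in the coil state they are drawn uniformly from the rest of
#' the torus by rejection, making the two states classification-disjoint.
#' Initial states are drawn from the stationary distribution, so the
#' process is stationary from frame 1. As in a real chain, the first
#' residue has an undefined phi and the last an undefined psi (`NA`).
#'
#' Randomness comes from a single seeded R stream consumed in a fixed
#' order (states for all chains, then PPII angles, then coil angles), so
#' identical specs give bit-identical ensembles.
#'
#' @param spec A [simulation_spec()].
#' @param window The PPII window defining the two states.
#' @return A dihedral ensemble tibble with columns `frame`, `time_ns`,
#'   `chain`, `residue_index`, `residue_name`, `phi_deg`, `psi_deg` and a
#'   `sim_spec` attribute recording the generator inputs.
#' @export
simulate_ensemble <- function(spec, window = ppii_window()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n_res <- length(spec$sequence)
  n_cells <- spec$n_chains * n_res
  p <- rep(spec$occupancy, times = spec$n_chains) # residue-major within chain blocks
  q_exit <- ifelse(p >= 1, 0, 1 / spec$persistence)
  q_enter <- ifelse(p >= 1, 1, pmin(1, p * (1 / spec$persistence) / (1 - p)))

  states <- matrix(0L, nrow = spec$n_frames, ncol = n_cells)
  s <- rbinom(n_cells, 1L, p)
  states[1L, ] <- s
  if (spec$n_frames > 1L) {
    for (t in 2:spec$n_frames) {
      stay <- rbinom(n_cells, 1L, 1 - q_exit)
      enter <- rbinom(n_cells, 1L, q_enter)
      s <- ifelse(s == 1L, stay, enter)
      states[t, ] <- s
    }
  }

  ppii_idx <- states == 1L
  n_ppii <- sum(ppii_idx)
  phi <- matrix(NA_real_, spec$n_frames, n_cells)
  psi <- matrix(NA_real_, spec$n_frames, n_cells)
  wrap <- function(a) {
    a <- ((a + 180) %% 360) - 180
    a[a <= -180] <- 180
    a
  }
  phi[ppii_idx] <- wrap(runif(n_ppii, window$phi_center - window$half_width, window$phi_center + window$half_width))
  psi[ppii_idx] <- wrap(runif(n_ppii, window$psi_center - window$half_width, window$psi_center + window$half_width))
  coil <- .draw_coil(sum(!ppii_idx), window)
  phi[!ppii_idx] <- coil$phi
  psi[!ppii_idx] <- coil$psi

  chain_lab <- sprintf("chain_%d", seq_len(spec$n_chains))
  grid <- expand_grid(
    chain = chain_lab,
    residue_index = seq_len(n_res)
  )
  # column k of the matrices corresponds to grid row k
  ens <- expand_grid(frame = seq_len(spec$n_frames), grid)
  ord <- (match(ens$chain, chain_lab) - 1L) * n_res + ens$residue_index
  idx <- cbind(ens$frame, ord)
  ens$phi_deg <- phi[idx]
  ens$psi_deg <- psi[idx]
  ens$time_ns <- ens$frame * spec$dt_ns
  ens$residue_name <- spec$sequence[ens$residue_index]
  # chain termini carry undefined dihedrals, as in a real backbone
  ens$phi_deg[ens$residue_index == 1L] <- NA_real_
  ens$psi_deg[ens$residue_index == n_res] <- NA_real_
  out <- ens[, c("frame", "time_ns", "chain", "residue_index", "residue_name", "phi_deg", "psi_deg")]
  attr(out, "sim_spec") <- spec
  out
}

#' Synthetic CD basis spectra
#'
#' Basis mean-residue-ellipticity spectra for the fully formed PPII state
#' and the disordered (coil) state, on a 1 nm grid. The PPII basis has the
#' canonical weak positive band (+9580 deg cm2/dmol at 212 nm) and a
#' strong negative band near 196 nm (truncated to vanish at and above
#' 210 nm so the 210-230 nm analysis band is a pure 212 nm peak). The coil
#' basis is the scaled inversion `-(5560/9580)` of the PPII basis: with
#' these anchors a population-weighted mixture inverts the empirical CD
#' population equation exactly, and temperature difference spectra are
#' exactly proportional to the PPII basis. Real coil spectra differ; see
#' the package vignette.
#'
#' @param wavelengths Wavelength grid in nm (must contain 210-230 nm).
#' @return Tibble with columns `wavelength_nm`, `ppii`, `coil`.
#' @export
cd_basis_spectra <- function(wavelengths = 190:260) {
  wl <- sort(as.numeric(wavelengths))
  peak <- 9580 * exp(-(wl - 212)^2 / (2 * 7^2))
  g <- exp(-(wl - 196)^2 / (2 * 5^2))
  cutoff <- exp(-(210 - 196)^2 / (2 * 5^2))
  lobe <- -16000 * pmax(0, (g - cutoff) / (1 - cutoff))
  lobe[wl >= 210] <- 0
  ppii <- peak + lobe
  tibble(wavelength_nm = wl, ppii = ppii, coil = -(5560 / 9580) * ppii)
}

#' Simulate a CD spectrum series and thermal melt with linear PPII loss
#'
#' Builds spectra as population mixtures of the PPII and coil basis,
#' `theta(lambda, T) = p(T) * ppii + (1 - p(T)) * coil`, with the PPII
#' population linear in temperature: `p(T) = pop0 + slope_pop * T`
#' (percent). The default parameters emulate the behaviour of the GroEL
#' short-tail peptide: a ~43% population at 0 C decaying by ~0.07% per
#' degree C. A melt trace is extracted at `melt_wavelength`.
#'
#' @param pop0 PPII population at 0 C, percent.
#' @param slope_pop Population change per degree C, percent (negative for
#'   PPII loss on heating).
#' @param temps Temperatures (C) at which full spectra are generated.
#' @param melt_temps Temperature grid (C) for the melt trace.
#' @param basis Basis spectra from [cd_basis_spectra()].
#' @param melt_wavelength Wavelength (nm) monitored in the melt.
#' @return A list with elements `spectra` (CD spectrum tibble, all
#'   temperatures) and `melt` (melt trace tibble).
#' @export
simulate_cd_series <- function(pop0 = 43.3, slope_pop = -0.0713,
                               temps = c(0, 5, 10, 17, 25, 37, 50, 65),
                               melt_temps = 0:65,
                               basis = cd_basis_spectra(),
                               melt_wavelength = 217) {
  all_t <- c(temps, melt_temps)
  pops <- pop0 + slope_pop * all_t
  if (any(pops < 0 | pops > 100)) {
    abort("PPII populations leave [0, 100]% over the requested temperatures.")
  }
  if (!melt_wavelength %in% basis$wavelength_nm) {
    abort(sprintf("`melt_wavelength` (%g nm) is not on the basis grid.", melt_wavelength))
  }
  mix <- function(t_c) {
    p <- (pop0 + slope_pop * t_c) / 100
    p * basis$ppii + (1 - p) * basis$coil
  }
  spectra <- purrr::map_dfr(temps, function(t_c) {
    tibble(
      wavelength_nm = basis$wavelength_nm,
      mre = mix(t_c),
      temperature_C = t_c,
      label = sprintf("sim_%gC", t_c)
    )
  })
  k <- which(basis$wavelength_nm == melt_wavelength)
  melt <- tibble(
    temperature_C = as.numeric(melt_temps),
    mre = purrr::map_dbl(melt_temps, function(t_c) mix(t_c)[k]),
    wavelength_nm = melt_wavelength
  )
  list(spectra = spectra, melt = melt)
}

#' Simulate a near-coil chemical-shift table
#'
#' Produces a per-residue shift table whose observed 13Ca shifts scatter
#' uniformly within `dca_scale` ppm of the random-coil reference and whose
#' 3J(HN-Ha) couplings are uniform in `j_range` (the statistical-coil /
#' PPII band). Couplings are left missing for glycine, mirroring the
#' practical limit that glycine couplings are rarely measurable in
#' crowded spectra.
#'
#' @param sequence 1-letter peptide sequence.
#' @param dca_scale Half-width of the uniform 13Ca deviation, ppm (>= 0).
#' @param seed Integer seed.
#' @param temperature Temperature (C) passed to [coil_reference()].
#' @param j_range Range of simulated couplings, Hz.
#' @return A shift table tibble with columns `residue_index`, `aa`,
#'   `ca_obs_ppm`, `ca_ref_ppm`, `ha_obs_ppm`, `ha_ref_ppm`, `j_hnha_hz`.
#' @export
simulate_shift_table <- function(sequence, dca_scale = 0.2, seed = 1,
                                 temperature = 25, j_range = c(5.5, 8.0)) {
  if (dca_scale < 0) abort("`dca_scale` must be >= 0.")
  set.seed(seed)
  ref <- coil_reference(sequence, temperature = temperature)
  n <- nrow(ref)
  out <- tibble(
    residue_index = ref$residue_index,
    aa = ref$aa,
    ca_obs_ppm = ref$ca_ref_ppm + runif(n, -dca_scale, dca_scale),
    ca_ref_ppm = ref$ca_ref_ppm,
    ha_obs_ppm = ref$ha_ref_ppm + runif(n, -dca_scale / 10, dca_scale / 10),
    ha_ref_ppm = ref$ha_ref_ppm,
    j_hnha_hz = runif(n, j_range[1], j_range[2])
  )
  out$j_hnha_hz[out$aa == "G"] <- NA_real_
  out
}
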