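# Conformational (secondary) chemical shifts and residue-level
# conformational classification.
#
# Near-zero 13Ca secondary shifts together with 3J(HN-Ha) couplings in the
# 5.5-8.0 Hz band rule out alpha-helix and beta-strand but cannot separate
# PPII from statistical coil; that distinction is carried by CD. The
# classifier therefore reports a merged "coil_or_ppii" class and never
# overclaims a PPII call from NMR alone.

# Static random-coil reference shifts (ppm), Wishart-type consensus values
# for 13Ca and 1Ha at neutral pH. No neighbor or pH corrections.
.COIL_SHIFTS <- tibble(
  aa = c(
    "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y"
  ),
  ca_ppm = c(
    52.5, 56.0, 53.1, 54.2, 58.2, 56.6, 55.7, 45.1, 55.0, 61.1,
    55.1, 56.2, 55.4, 57.7, 63.3, 58.3, 61.8, 62.2, 57.5, 57.9
  ),
  ha_ppm = c(
    4.32, 4.34, 4.74, 4.64, 4.55, 4.35, 4.34, 3.96, 4.73, 4.17,
    4.34, 4.32, 4.48, 4.62, 4.42, 4.47, 4.35, 4.12, 4.66, 4.55
  )
)

#' Random-coil chemical-shift references for a sequence
#'
#' Per-residue 13Ca and 1Ha random-coil reference shifts from a packaged
#' static lookup table (Wishart-type consensus values, no neighbor
#' corrections), with an optional linear temperature correction applied
#' about a 25 C reference. With the default zero coefficients the 25 C
#' values are returned verbatim.
#'
#' @param sequence 1-letter sequence (string or character vector).
#' @param temperature Sample temperature in C.
#' @param ca_temp_coeff,ha_temp_coeff Linear temperature coefficients in
#'   ppm per C applied as `ref + coeff * (temperature - 25)`.
#' @return Tibble with columns `residue_index`, `aa`, `ca_ref_ppm`,
#'   `ha_ref_ppm`; the `reference` attribute records provenance.
#' @export
coil_reference <- function(sequence, temperature = 25,
                           ca_temp_coeff = 0, ha_temp_coeff = 0) {
  seq1 <- .split_sequence(sequence)
  if (!length(seq1)) abort("`sequence` is empty.")
  unknown <- !(seq1 %in% .COIL_SHIFTS$aa)
  if (any(unknown)) {
    abort(sprintf(
      "Nonstandard residue code(s) at position(s) %s: %s",
      paste(which(unknown), collapse = ", "),
      paste(seq1[unknown], collapse = ", ")
    ))
  }
  i <- match(seq1, .COIL_SHIFTS$aa)
  out <- tibble(
    residue_index = seq_along(seq1),
    aa = seq1,
    ca_ref_ppm = .COIL_SHIFTS$ca_ppm[i] + ca_temp_coeff * (temperature - 25),
    ha_ref_ppm = .COIL_SHIFTS$ha_ppm[i] + ha_temp_coeff * (temperature - 25)
  )
  attr(out, "reference") <- list(
    source = "packaged static random-coil table (Wishart-type consensus, 25 C, no neighbor corrections)",
    temperature = temperature,
    ca_temp_coeff = ca_temp_coeff,
    ha_temp_coeff = ha_temp_coeff
  )
  out
}

#' Residue classification criteria
#'
#' Thresholds used to classify residue conformational tendency from the
#' 13Ca secondary shift and the 3J(HN-Ha) coupling. The coupling band
#' 5.5-8.0 Hz is the range consistent with statistical coil or PPII;
#' the secondary-shift cutoffs are configurable conventions (large
#' positive 13Ca shifts indicate alpha-helix, clearly negative ones
#' beta-strand, and a narrow band about zero coil/PPII).
#'
#' @param dca_alpha_min Minimum 13Ca secondary shift (ppm) calling alpha.
#' @param dca_beta_max Maximum (most positive) 13Ca secondary shift (ppm)
#'   calling beta; must be negative.
#' @param dca_coil_band Half-width (ppm) of the near-zero band calling
#'   coil/PPII.
#' @param j_coil_lo,j_coil_hi Coupling band (Hz) consistent with coil or
#'   PPII.
#' @return A list of class `class_criteria`.
#' @export
class_criteria <- function(dca_alpha_min = 1.0, dca_beta_max = -0.7,
                           dca_coil_band = 0.4,
                           j_coil_lo = 5.5, j_coil_hi = 8.0) {
  if (!(dca_beta_max < 0 && 0 < dca_alpha_min)) {
    abort("Need dca_beta_max < 0 < dca_alpha_min.")
  }
  if (dca_coil_band <= 0) abort("`dca_coil_band` must be > 0.")
  if (!(j_coil_lo < j_coil_hi)) abort("Need j_coil_lo < j_coil_hi.")
  structure(
    list(
      dca_alpha_min = dca_alpha_min, dca_beta_max = dca_beta_max,
      dca_coil_band = dca_coil_band,
      j_coil_lo = j_coil_lo, j_coil_hi = j_coil_hi
    ),
    class = "class_criteria"
  )
}

#' Conformational (secondary) chemical shift
#'
#' The observed shift minus the random-coil reference for the same
#' residue, `delta_delta = obs - ref` (ppm). Missing members propagate as
#' `NA` (not-applicable), never as zero.
#'
#' @param obs,ref Numeric vectors of observed and reference shifts (ppm).
#' @return Numeric vector of secondary shifts (ppm) with `NA` where
#'   either member is missing.
#' @export
conformational_shift <- function(obs, ref) {
  if (is.logical(obs) && all(is.na(obs))) obs <- as.numeric(obs)
  if (is.logical(ref) && all(is.na(ref))) ref <- as.numeric(ref)
  if (!is.numeric(obs) || !is.numeric(ref)) abort("`obs` and `ref` must be numeric.")
  obs - ref
}

.classify_vec <- function(dca, j, c) {
  n <- max(length(dca), length(j))
  dca <- rep_len(dca, n)
  j <- rep_len(j, n)
  both_missing <- is.na(dca) & is.na(j)
  if (any(both_missing)) {
    abort(sprintf(
      "Residue row(s) %s have neither a secondary shift nor a coupling; nothing to classify.",
      paste(which(both_missing), collapse = ", ")
    ))
  }
  j_coil <- !is.na(j) & j >= c$j_coil_lo & j <= c$j_coil_hi
  alpha <- !is.na(dca) & dca >= c$dca_alpha_min & (is.na(j) | j < c$j_coil_lo)
  beta <- !is.na(dca) & dca <= c$dca_beta_max & (is.na(j) | j > c$j_coil_hi)
  coil <- (!is.na(dca) & abs(dca) <= c$dca_coil_band & (is.na(j) | j_coil)) |
    (is.na(dca) & j_coil)
  out <- rep("ambiguous", n)
  out[coil] <- "coil_or_ppii"
  out[beta] <- "beta"
  out[alpha] <- "alpha"
  factor(out, levels = c("alpha", "beta", "coil_or_ppii", "ambiguous"))
}

#' Classify residue conformational tendency from shifts and couplings
#'
#' Adds the 13Ca secondary shift and a per-residue class to a shift
#' table. Classes: `alpha` (secondary shift at or above
#' `dca_alpha_min` with no coil-band coupling contradicting it), `beta`
#' (at or below `dca_beta_max`, likewise), `coil_or_ppii` (near-zero
#' secondary shift and, when measured, a coupling inside the coil band;
#' or coupling-only evidence inside the band), else `ambiguous`. PPII and
#' statistical coil are deliberately merged: NMR alone cannot separate
#' them at residue level.
#'
#' @param shifts Shift table tibble with columns `residue_index`, `aa`,
#'   `ca_obs_ppm`, `ca_ref_ppm`, optionally `ha_obs_ppm`, `ha_ref_ppm`,
#'   `j_hnha_hz` (`NA` allowed).
#' @param criteria A [class_criteria()].
#' @return The input with added columns `dca_ppm`, `dha_ppm` (when 1Ha
#'   data are present) and `class`.
#' @export
classify_residues <- function(shifts, criteria = class_criteria()) {
  shifts <- as_tibble(shifts)
  need <- c("residue_index", "aa", "ca_obs_ppm", "ca_ref_ppm")
  missing_cols <- setdiff(need, names(shifts))
  if (length(missing_cols)) {
    abort(paste0("`shifts` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!nrow(shifts)) abort("`shifts` is empty.")
  stopifnot(inherits(criteria, "class_criteria"))
  if (!"j_hnha_hz" %in% names(shifts)) shifts$j_hnha_hz <- NA_real_
  shifts$dca_ppm <- conformational_shift(shifts$ca_obs_ppm, shifts$ca_ref_ppm)
  if (all(c("ha_obs_ppm", "ha_ref_ppm") %in% names(shifts))) {
    shifts$dha_ppm <- conformational_shift(shifts$ha_obs_ppm, shifts$ha_ref_ppm)
  }
  shifts$class <- .classify_vec(shifts$dca_ppm, shifts$j_hnha_hz, criteria)
  shifts
}

#' Segment-level conformational verdict
#'
#' Summarizes per-residue classes into class fractions and a verdict.
#' The verdict "no alpha/beta; coil or PPII" requires the alpha and beta
#' fractions each to stay below `max_structured` and the affirmative
#' coil-or-PPII fraction to reach `min_coil`; anything else is reported
#' as rejected. Demanding affirmative coil evidence (not merely the
#' absence of alpha/beta calls) prevents a verdict from resting on
#' residues the criteria cannot interpret.
#'
#' @param shifts A shift table (classified or not; see
#'   [classify_residues()]).
#' @param criteria A [class_criteria()].
#' @param max_structured Maximum tolerated alpha (and beta) fraction.
#' @param min_coil Minimum coil-or-PPII fraction.
#' @return One-row tibble: `n_classified`, the four class fractions,
#'   `no_alpha_beta` and `verdict`.
#' @export
segment_verdict <- function(shifts, criteria = class_criteria(),
                            max_structured = 0.1, min_coil = 0.8) {
  if (!"class" %in% names(as_tibble(shifts))) {
    shifts <- classify_residues(shifts, criteria)
  }
  shifts <- as_tibble(shifts)
  if (!nrow(shifts)) abort("`shifts` is empty.")
  n <- nrow(shifts)
  frac <- function(lv) sum(shifts$class == lv) / n
  f_alpha <- frac("alpha")
  f_beta <- frac("beta")
  f_coil <- frac("coil_or_ppii")
  f_amb <- frac("ambiguous")
  ok <- f_alpha <= max_structured && f_beta <= max_structured && f_coil >= min_coil
  tibble(
    n_classified = n,
    frac_alpha = f_alpha, frac_beta = f_beta,
    frac_coil_or_ppii = f_coil, frac_ambiguous = f_amb,
    no_alpha_beta = ok,
    verdict = if (ok) "no alpha/beta; coil or PPII" else "rejected: structured or uninterpretable content"
  )
}
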