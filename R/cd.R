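# Circular dichroism analysis: PPII population from the empirical
# mean-residue-ellipticity relation, spectral maximum search, linear
# thermal-melt fitting and temperature difference spectra.
#
# Mean residue ellipticity ([theta]) is in deg cm2 dmol-1 throughout.

.spectrum_groups <- function(spectra) {
  intersect(c("temperature_C", "label"), names(spectra))
}

#' Maximum mean residue ellipticity in a wavelength band
#'
#' Finds the maximum sampled MRE between `lo` and `hi` nm (default
#' 210-230 nm, the band in which the PPII positive band falls). No
#' interpolation is performed: values are read directly from the sampled
#' spectrum, and ties break toward the lower wavelength. When the table
#' holds several spectra (distinct `temperature_C` / `label`), one row is
#' returned per spectrum.
#'
#' @param spectra CD spectrum tibble with columns `wavelength_nm`, `mre`
#'   and optionally `temperature_C`, `label`.
#' @param lo,hi Search band in nm; each spectrum must cover `[lo, hi]`.
#' @return Tibble with the spectrum grouping columns plus
#'   `lambda_max_nm` and `theta_max`.
#' @export
theta_max <- function(spectra, lo = 210, hi = 230) {
  spectra <- as_tibble(spectra)
  if (!all(c("wavelength_nm", "mre") %in% names(spectra))) {
    abort("`spectra` needs columns wavelength_nm and mre.")
  }
  if (lo >= hi) abort("`lo` must be < `hi`.")
  grp <- .spectrum_groups(spectra)
  one <- function(df, key) {
    wl <- df$wavelength_nm
    if (min(wl) > lo || max(wl) < hi) {
      abort(sprintf(
        "Spectrum covers %g-%g nm and does not span the search band [%g, %g] nm.",
        min(wl), max(wl), lo, hi
      ))
    }
    in_band <- df[wl >= lo & wl <= hi, ]
    if (!nrow(in_band)) abort("No samples inside the search band.")
    in_band <- dplyr::arrange(in_band, .data$wavelength_nm)
    i <- which.max(in_band$mre) # first maximum = lower-wavelength tie-break
    tibble(lambda_max_nm = in_band$wavelength_nm[i], theta_max = in_band$mre[i])
  }
  if (length(grp)) {
    spectra |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::group_modify(one) |>
      dplyr::ungroup()
  } else {
    one(spectra, NULL)
  }
}

#' PPII population from maximum mean residue ellipticity
#'
#' The empirical relation of Park, Shalongo and Stellwagen calibrated on
#' alanine-based peptides:
#' \deqn{\%PPII = 100 \cdot ([\Theta]_{max} + 5560) / 15140}
#' with \eqn{[\Theta]_{max}} the maximum MRE between 210 and 230 nm in
#' deg cm2 dmol-1. The result is not clamped: values outside 0-100%
#' signal unit or baseline problems and trigger a warning rather than
#' silent truncation.
#'
#' @param theta Numeric vector of maximum MRE values (deg cm2 dmol-1).
#' @return Numeric vector of PPII helix populations in percent.
#' @examples
#' ppii_population(1000) # ~43% (GroEL short tail at 0 C)
#' ppii_population(1600) # ~47% (mHsp60 short tail at 0 C)
#' @export
ppii_population <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    abort("`theta` must be finite numeric.")
  }
  pct <- 100 * (theta + 5560) / 15140
  out_of_range <- pct < 0 | pct > 100
  if (any(out_of_range)) {
    warn(sprintf(
      "%d PPII population value(s) fall outside [0, 100]%%; check units and baseline.",
      sum(out_of_range)
    ))
  }
  pct
}

#' PPII populations for a table of CD spectra
#'
#' Applies [theta_max()] then [ppii_population()] to every spectrum in
#' the table, recording the estimation route and flagging out-of-range
#' populations.
#'
#' @inheritParams theta_max
#' @return Tibble with grouping columns, `lambda_max_nm`, `theta_max`,
#'   `ppii_percent`, `out_of_range`.
#' @export
cd_populations <- function(spectra, lo = 210, hi = 230) {
  tm <- theta_max(spectra, lo = lo, hi = hi)
  tm$ppii_percent <- suppressWarnings(ppii_population(tm$theta_max))
  tm$out_of_range <- tm$ppii_percent < 0 | tm$ppii_percent > 100
  if (any(tm$out_of_range)) {
    warn("Some PPII populations fall outside [0, 100]%; check units and baseline.")
  }
  tm
}

#' Fit a linear thermal melt
#'
#' Ordinary least squares of MRE on temperature for a single-wavelength
#' melt trace, the model appropriate to the non-cooperative PPII-to-coil
#' transition (which shows a linear, not sigmoidal, loss of signal on
#' heating). A zero-variance (flat) trace is not an error: it returns
#' slope 0 with `r` reported as 0 and a degeneracy flag, so batch
#' processing survives flat controls.
#'
#' @param trace Melt trace tibble with columns `temperature_C`, `mre`
#'   and optionally `wavelength_nm`.
#' @return An object of class `melt_fit` with intercept (MRE at 0 C),
#'   slope (MRE per C), Pearson `r`, and the residuals. Supports
#'   [tidy()], [glance()], `autoplot()` and `print()`.
#' @examples
#' tr <- tibble::tibble(temperature_C = seq(0, 65, 5), mre = 835 - 10.8 * seq(0, 65, 5))
#' fit_melt(tr)
#' @export
fit_melt <- function(trace) {
  trace <- as_tibble(trace)
  if (!all(c("temperature_C", "mre") %in% names(trace))) {
    abort("`trace` needs columns temperature_C and mre.")
  }
  trace <- dplyr::filter(trace, is.finite(.data$temperature_C), is.finite(.data$mre))
  if (nrow(trace) < 3L) abort("At least 3 melt points are required.")
  if (dplyr::n_distinct(trace$temperature_C) < 2L) {
    abort("All temperatures are identical; the melt slope is undefined.")
  }
  degenerate <- stats::var(trace$mre) == 0
  if (degenerate) {
    intercept <- trace$mre[1]
    slope <- 0
    r <- 0
    res <- rep(0, nrow(trace))
  } else {
    fit <- lm(mre ~ temperature_C, data = trace)
    intercept <- unname(coef(fit)[1])
    slope <- unname(coef(fit)[2])
    r <- cor(trace$temperature_C, trace$mre)
    res <- unname(resid(fit))
  }
  structure(
    list(
      intercept = intercept, slope = slope, r = r,
      degenerate = degenerate, n = nrow(trace),
      wavelength_nm = if ("wavelength_nm" %in% names(trace)) trace$wavelength_nm[1] else NA_real_,
      data = dplyr::mutate(trace, fitted = intercept + slope * .data$temperature_C, residual = res)
    ),
    class = "melt_fit"
  )
}

#' @export
print.melt_fit <- function(x, ...) {
  wl <- if (is.na(x$wavelength_nm)) "" else sprintf("_%gnm", x$wavelength_nm)
  cat(sprintf(
    "<melt_fit> [theta]%s = %.4g %+.4g (T C), R = %.3f (n = %d)%s\n",
    wl, x$intercept, x$slope, x$r, x$n,
    if (x$degenerate) " [degenerate: zero response variance]" else ""
  ))
  invisible(x)
}

#' @rdname fit_melt
#' @param x A `melt_fit`.
#' @param ... Unused.
#' @export
tidy.melt_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    unit = c("deg cm2 dmol-1", "deg cm2 dmol-1 per C")
  )
}

#' @rdname fit_melt
#' @export
glance.melt_fit <- function(x, ...) {
  tibble(
    intercept = x$intercept, slope = x$slope, r = x$r,
    r.squared = x$r^2, n = x$n, degenerate = x$degenerate,
    wavelength_nm = x$wavelength_nm
  )
}

#' Temperature difference spectrum
#'
#' Pointwise subtraction `a - b` of two CD spectra on identical
#' wavelength grids. Because the disordered-ensemble contribution largely
#' cancels, the difference between a cold and a hot spectrum isolates the
#' spectral signature of the conformation lost on heating; for PPII
#' formers it reproduces the canonical PPII spectrum shape.
#'
#' @param a,b CD spectrum tibbles (single spectrum each) with columns
#'   `wavelength_nm`, `mre` and optionally `temperature_C`.
#' @param restrict If `TRUE`, first restrict both spectra to their common
#'   wavelength grid; an empty intersection is an error.
#' @return A CD spectrum tibble; `label` records "Ta - Tb" when
#'   temperatures are available.
#' @export
difference_spectrum <- function(a, b, restrict = FALSE) {
  a <- as_tibble(a)
  b <- as_tibble(b)
  for (s in list(a, b)) {
    if (!all(c("wavelength_nm", "mre") %in% names(s))) {
      abort("Spectra need columns wavelength_nm and mre.")
    }
  }
  a <- dplyr::arrange(a, .data$wavelength_nm)
  b <- dplyr::arrange(b, .data$wavelength_nm)
  if (restrict) {
    common <- intersect(a$wavelength_nm, b$wavelength_nm)
    if (!length(common)) abort("The two spectra share no wavelengths.")
    a <- dplyr::filter(a, .data$wavelength_nm %in% common)
    b <- dplyr::filter(b, .data$wavelength_nm %in% common)
  }
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a$wavelength_nm, b$wavelength_nm))) {
    abort("Wavelength grids differ; use `restrict = TRUE` to subtract on the common grid.")
  }
  t_a <- if ("temperature_C" %in% names(a)) a$temperature_C[1] else NA_real_
  t_b <- if ("temperature_C" %in% names(b)) b$temperature_C[1] else NA_real_
  tibble(
    wavelength_nm = a$wavelength_nm,
    mre = a$mre - b$mre,
    temperature_C = NA_real_,
    label = if (!is.na(t_a) && !is.na(t_b)) sprintf("%gC - %gC", t_a, t_b) else "a - b"
  )
}

#' Diagnose linearity of a thermal melt
#'
#' Tests whether a melt trace is consistent with the linear,
#' non-cooperative PPII-to-coil transition: the Pearson correlation must
#' exceed `r_threshold` in magnitude and the residuals must not contain a
#' same-sign run longer than `max_sign_run` (long runs betray the
#' systematic curvature of a sigmoidal two-state melt). Residuals within
#' numerical noise of zero do not contribute to runs, so an exactly
#' linear (or flat) trace passes.
#'
#' @param trace Melt trace tibble (`temperature_C`, `mre`).
#' @param r_threshold Minimum `|r|` accepted as linear.
#' @param max_sign_run Longest tolerated run of same-sign residuals.
#' @return One-row tibble with `linear`, `r`, `longest_sign_run`,
#'   `degenerate`, and the residual table in the list-column `residuals`.
#' @export
linearity_check <- function(trace, r_threshold = 0.95, max_sign_run = 6L) {
  fit <- fit_melt(trace)
  res <- fit$data$residual
  tol <- 1e-8 * max(abs(fit$data$mre), 1)
  s <- sign(res)
  s[abs(res) < tol] <- 0
  longest <- 0L
  run <- 0L
  prev <- 0
  for (v in s) {
    if (v != 0 && v == prev) {
      run <- run + 1L
    } else {
      run <- if (v != 0) 1L else 0L
    }
    prev <- v
    longest <- max(longest, run)
  }
  linear <- (fit$degenerate || abs(fit$r) >= r_threshold) && longest <= max_sign_run
  tibble(
    linear = linear, r = fit$r, longest_sign_run = longest,
    degenerate = fit$degenerate,
    residuals = list(fit$data)
  )
}

#' Mean residue ellipticity from raw ellipticity
#'
#' Converts a raw CD signal in millidegrees to mean residue ellipticity,
#' `MRE = theta_mdeg * MRW / (10 * pathlength_cm * conc_mg_ml)`, with the
#' mean residue weight `MRW = peptide_mass_da / (n_residues - 1)` (per
#' peptide bond).
#'
#' @param theta_mdeg Raw ellipticity, millidegrees.
#' @param peptide_mass_da Peptide mass in daltons.
#' @param n_residues Number of residues (>= 2).
#' @param pathlength_cm Cuvette path length, cm.
#' @param conc_mg_ml Peptide concentration, mg/mL.
#' @return MRE in deg cm2 dmol-1.
#' @export
mre_from_millideg <- function(theta_mdeg, peptide_mass_da, n_residues,
                              pathlength_cm, conc_mg_ml) {
  if (n_residues < 2) abort("`n_residues` must be >= 2.")
  if (pathlength_cm <= 0 || conc_mg_ml <= 0) {
    abort("Path length and concentration must be positive.")
  }
  mrw <- peptide_mass_da / (n_residues - 1)
  theta_mdeg * mrw / (10 * pathlength_cm * conc_mg_ml)
}
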