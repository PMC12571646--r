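# Plain-text readers and writers for the formats the pipeline exchanges:
# dihedral TSV, CD spectrum CSV, melt CSV, shift TSV, report TSVs and
# multi-model backbone PDB. Output tables carry a '#' header comment block
# with units; readers skip such comments.

.write_commented <- function(df, path, comments, delim) {
  writeLines(paste0("# ", comments), path)
  readr::write_delim(df, path, delim = delim, na = "NA", append = TRUE, col_names = TRUE)
  invisible(path)
}

.read_table <- function(path, delim, required, col_types) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_delim(
    path,
    delim = delim, comment = "#", na = "NA",
    show_col_types = FALSE, col_types = col_types, trim_ws = TRUE
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  df
}

#' Read and write per-frame dihedral tables
#'
#' The dihedral TSV dialect has columns `frame`, `time_ns`, `chain`,
#' `residue_index` (1-based), `residue_name`, `phi_deg`, `psi_deg`, with
#' the literal string "NA" for undefined terminal angles. Angles outside
#' (-180, 180] are rejected on read.
#'
#' @param path File path.
#' @return `read_dihedrals_tsv()` returns a dihedral ensemble tibble.
#' @export
read_dihedrals_tsv <- function(path) {
  df <- .read_table(
    path, "\t",
    c("frame", "time_ns", "chain", "residue_index", "residue_name", "phi_deg", "psi_deg"),
    readr::cols(
      frame = readr::col_integer(), time_ns = readr::col_double(),
      chain = readr::col_character(), residue_index = readr::col_integer(),
      residue_name = readr::col_character(),
      phi_deg = readr::col_double(), psi_deg = readr::col_double()
    )
  )
  .check_ensemble(df)
}

#' @rdname read_dihedrals_tsv
#' @param ens Dihedral ensemble tibble.
#' @export
write_dihedrals_tsv <- function(ens, path) {
  ens <- .check_ensemble(ens)
  .write_commented(
    ens[, c("frame", "time_ns", "chain", "residue_index", "residue_name", "phi_deg", "psi_deg")],
    path,
    c(
      "per-frame backbone dihedrals",
      "time_ns: ns; phi_deg/psi_deg: degrees in (-180, 180], NA = undefined (terminus)"
    ),
    "\t"
  )
}

#' Read and write CD spectrum tables
#'
#' CD CSV dialect: `wavelength_nm`, `mre` (mean residue ellipticity,
#' deg cm2 dmol-1), `temperature_C`, `label`; one file may hold several
#' temperatures.
#'
#' @param path File path.
#' @return A CD spectrum tibble.
#' @export
read_cd_csv <- function(path) {
  df <- .read_table(
    path, ",", c("wavelength_nm", "mre"),
    readr::cols(
      wavelength_nm = readr::col_double(), mre = readr::col_double(),
      .default = readr::col_guess()
    )
  )
  if (any(df$wavelength_nm < 180 | df$wavelength_nm > 300)) {
    abort("Wavelengths must lie within 180-300 nm.")
  }
  df
}

#' @rdname read_cd_csv
#' @param spectra CD spectrum tibble.
#' @export
write_cd_csv <- function(spectra, path) {
  .write_commented(
    spectra, path,
    c("far-UV CD spectra", "mre: mean residue ellipticity, deg cm2 dmol-1; temperature_C: C"),
    ","
  )
}

#' Read and write melt traces
#'
#' Melt CSV dialect: `temperature_C`, `mre`, `wavelength_nm`.
#'
#' @param path File path.
#' @return A melt trace tibble.
#' @export
read_melt_csv <- function(path) {
  .read_table(
    path, ",", c("temperature_C", "mre"),
    readr::cols(
      temperature_C = readr::col_double(), mre = readr::col_double(),
      .default = readr::col_guess()
    )
  )
}

#' @rdname read_melt_csv
#' @param trace Melt trace tibble.
#' @export
write_melt_csv <- function(trace, path) {
  .write_commented(
    trace, path,
    c("thermal melt monitored at fixed wavelength", "mre: deg cm2 dmol-1; temperature_C: C"),
    ","
  )
}

#' Read and write chemical-shift tables
#'
#' Shift TSV dialect: `residue_index`, `aa`, `ca_obs_ppm`, `ca_ref_ppm`,
#' `ha_obs_ppm`, `ha_ref_ppm`, `j_hnha_hz` ("NA" allowed). Plausibility
#' ranges are enforced on read: 40-70 ppm for 13Ca, 3-6 ppm for 1Ha,
#' 0-12 Hz for couplings.
#'
#' @param path File path.
#' @return A shift table tibble.
#' @export
read_shifts_tsv <- function(path) {
  df <- .read_table(
    path, "\t", c("residue_index", "aa", "ca_obs_ppm"),
    readr::cols(
      residue_index = readr::col_integer(), aa = readr::col_character(),
      .default = readr::col_double()
    )
  )
  if (anyDuplicated(df$residue_index) || is.unsorted(df$residue_index)) {
    abort("residue_index must be unique and increasing.")
  }
  in_range <- function(x, lo, hi) all(is.na(x) | (x >= lo & x <= hi))
  for (col in intersect(c("ca_obs_ppm", "ca_ref_ppm"), names(df))) {
    if (!in_range(df[[col]], 40, 70)) abort(sprintf("%s outside 40-70 ppm.", col))
  }
  for (col in intersect(c("ha_obs_ppm", "ha_ref_ppm"), names(df))) {
    if (!in_range(df[[col]], 3, 6)) abort(sprintf("%s outside 3-6 ppm.", col))
  }
  if ("j_hnha_hz" %in% names(df) && !in_range(df$j_hnha_hz, 0, 12)) {
    abort("j_hnha_hz outside 0-12 Hz.")
  }
  df
}

#' @rdname read_shifts_tsv
#' @param shifts Shift table tibble.
#' @export
write_shifts_tsv <- function(shifts, path) {
  .write_commented(
    shifts, path,
    c("per-residue chemical shifts and couplings", "shifts: ppm; j_hnha_hz: Hz; NA = not measured"),
    "\t"
  )
}

#' Write PPII report tables
#'
#' Emits the long-format windowed-content table (`chain`, `segment`,
#' `time_ns`, `fraction`, `n_obs`), the pooled per-repeat table and the
#' per-residue table of a [ppii_report()] as commented TSV files in
#' `dir`.
#'
#' @param report A `ppii_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ppii_report <- function(report, dir) {
  stopifnot(inherits(report, "ppii_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "ppii_windowed.tsv")
  .write_commented(
    report$per_segment_windowed, p,
    c(
      "windowed PPII content per chain and segment",
      sprintf(
        "window %g ns, stride %g ns; fraction in [0,1]; n_obs = defined-dihedral observations",
        report$params$window_ns, report$params$stride_ns
      )
    ),
    "\t"
  )
  paths <- c(paths, p)
  if (!is.null(report$per_repeat_windowed)) {
    p <- file.path(dir, "ppii_repeats.tsv")
    .write_commented(
      report$per_repeat_windowed, p,
      "windowed PPII content per GGM repeat, pooled over chains", "\t"
    )
    paths <- c(paths, p)
  }
  p <- file.path(dir, "ppii_per_residue.tsv")
  .write_commented(
    report$per_residue, p,
    "whole-run mean per-residue PPII population; NA = terminal residue (undefined dihedral)",
    "\t"
  )
  paths <- c(paths, p)
  invisible(paths)
}

#' Write backbone coordinates as a multi-model PDB
#'
#' Minimal writer for N/CA/C backbone tables: one MODEL/ENDMDL block per
#' model, fixed-width ATOM records readable by standard tools.
#'
#' @param coords Backbone coordinate tibble (see [build_backbone()]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_backbone_pdb <- function(coords, path) {
  coords <- as_tibble(coords)
  need <- c("chain", "residue_index", "residue_name", "atom", "x", "y", "z")
  missing_cols <- setdiff(need, names(coords))
  if (length(missing_cols)) {
    abort(paste0("`coords` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"model" %in% names(coords)) coords$model <- 1L
  element <- function(a) substr(a, 1, 1)
  lines <- character()
  for (m in sort(unique(coords$model))) {
    sub <- coords[coords$model == m, ]
    lines <- c(lines, sprintf("MODEL     %4d", as.integer(m)))
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s%4s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(sub)), sub$atom, sub$residue_name, sub$chain,
      as.integer(sub$residue_index), sub$x, sub$y, sub$z, 1, 0,
      element(sub$atom)
    ))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
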