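# Configuration, validation and the one-call runner tying the analysis
# stages and the simulator together. All results are written as plain
# TSV/CSV with unit header comments plus a JSON manifest sufficient to
# reproduce deterministic stages byte-identically; logging goes to
# standard error, results only to files.

#' Build a run configuration
#'
#' Collects the inputs and parameters of one analysis run. Residue ranges
#' are 1-based inclusive everywhere. Unset parameters are filled with
#' package defaults by [validate_run_config()].
#'
#' @param stage One of `"traj"`, `"cd"`, `"nmr"`, `"sim"`.
#' @param input Input path for traj (dihedral TSV or multi-model PDB) or
#'   nmr (shift TSV).
#' @param spectra,melt Input CSV paths for the cd stage.
#' @param out_dir Output directory.
#' @param segments Segment map tibble (traj); default the canonical CtS
#'   map.
#' @param window_ns,stride_ns Trajectory windowing parameters (ns).
#' @param theta_lo,theta_hi CD maximum search band (nm).
#' @param criteria [class_criteria()] overrides (nmr).
#' @param sequence Optional sequence used to fill missing coil references
#'   (nmr) or for simulation.
#' @param temperature_C Sample temperature for coil references.
#' @param sim_what For the sim stage: `"traj"`, `"cd"` or `"nmr"`.
#' @param sim_spec A [simulation_spec()] (sim traj).
#' @param dt_ns Frame spacing when reading a multi-model PDB as a
#'   trajectory.
#' @param seed Integer seed (mandatory for the sim stage).
#' @return A list of class `ppii_run_config`.
#' @export
run_config <- function(stage, input = NULL, spectra = NULL, melt = NULL,
                       out_dir = NULL, segments = NULL,
                       window_ns = NULL, stride_ns = NULL,
                       theta_lo = NULL, theta_hi = NULL,
                       criteria = NULL, sequence = NULL,
                       temperature_C = NULL, sim_what = NULL,
                       sim_spec = NULL, dt_ns = NULL, seed = NULL) {
  structure(
    list(
      stage = stage, input = input, spectra = spectra, melt = melt,
      out_dir = out_dir, segments = segments,
      window_ns = window_ns, stride_ns = stride_ns,
      theta_lo = theta_lo, theta_hi = theta_hi,
      criteria = criteria, sequence = sequence,
      temperature_C = temperature_C, sim_what = sim_what,
      sim_spec = sim_spec, dt_ns = dt_ns, seed = seed,
      validated = FALSE
    ),
    class = "ppii_run_config"
  )
}

.log_msg <- function(...) message(sprintf(...))

#' Validate and normalize a run configuration
#'
#' Checks paths, stage-specific requirements and parameter domains, and
#' injects package defaults (50 ns window and stride, 210-230 nm search
#' band, default classification criteria, 25 C). Every injected default
#' is echoed to standard error. Validation is idempotent: a validated
#' configuration passes through unchanged.
#'
#' @param cfg A [run_config()].
#' @return The normalized configuration.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "ppii_run_config"))
  if (isTRUE(cfg$validated)) return(cfg)
  if (!cfg$stage %in% c("traj", "cd", "nmr", "sim")) {
    abort(sprintf("Unknown stage '%s'; expected traj, cd, nmr or sim.", cfg$stage))
  }
  default <- function(field, value) {
    if (is.null(cfg[[field]])) {
      .log_msg("config: %s defaulted to %s", field, paste(format(value), collapse = " "))
      cfg[[field]] <<- value
    }
  }
  need_file <- function(field) {
    p <- cfg[[field]]
    if (is.null(p)) abort(sprintf("Stage '%s' requires `%s`.", cfg$stage, field))
    if (!file.exists(p)) abort(sprintf("Input path does not exist: %s", p))
  }
  default("out_dir", file.path(tempdir(), "ppii_run"))
  if (cfg$stage == "traj") {
    need_file("input")
    default("segments", groel_segments("CtS"))
    default("window_ns", 50)
    default("stride_ns", 50)
    default("dt_ns", 1)
    if (cfg$window_ns <= 0 || cfg$stride_ns <= 0) abort("window_ns and stride_ns must be > 0.")
    if (!all(c("segment", "residue_index") %in% names(cfg$segments))) {
      abort("`segments` must be a segment map (columns segment, residue_index).")
    }
    if (any(cfg$segments$residue_index < 1)) abort("Residue ranges are 1-based; positions must be >= 1.")
  } else if (cfg$stage == "cd") {
    need_file("spectra")
    if (!is.null(cfg$melt)) need_file("melt")
    default("theta_lo", 210)
    default("theta_hi", 230)
    if (cfg$theta_lo >= cfg$theta_hi) abort("theta_lo must be < theta_hi.")
  } else if (cfg$stage == "nmr") {
    need_file("input")
    default("criteria", class_criteria())
    default("temperature_C", 25)
  } else if (cfg$stage == "sim") {
    if (is.null(cfg$seed)) abort("The sim stage requires an explicit `seed`.")
    default("sim_what", "traj")
    if (!cfg$sim_what %in% c("traj", "cd", "nmr")) {
      abort("`sim_what` must be traj, cd or nmr.")
    }
    if (cfg$sim_what == "traj") {
      default("sim_spec", simulation_spec(n_frames = 1000, seed = cfg$seed))
    }
    if (cfg$sim_what == "nmr") default("sequence", "AGGMGGMGGMGGMM")
  }
  cfg$validated <- TRUE
  cfg
}

.write_manifest <- function(cfg, out_dir, outputs, extra = list()) {
  manifest <- c(
    list(
      package = "ppiihelix",
      version = as.character(packageVersion("ppiihelix")),
      stage = cfg$stage,
      parameters = Filter(
        Negate(is.null),
        list(
          input = cfg$input, spectra = cfg$spectra, melt = cfg$melt,
          window_ns = cfg$window_ns, stride_ns = cfg$stride_ns,
          theta_lo = cfg$theta_lo, theta_hi = cfg$theta_hi,
          criteria = if (!is.null(cfg$criteria)) unclass(cfg$criteria),
          segments = if (!is.null(cfg$segments)) {
            lapply(split(cfg$segments$residue_index, cfg$segments$segment), as.integer)
          },
          temperature_C = cfg$temperature_C, dt_ns = cfg$dt_ns,
          sim_what = cfg$sim_what, seed = cfg$seed,
          sim_spec = if (!is.null(cfg$sim_spec)) {
            s <- unclass(cfg$sim_spec)
            s$sequence <- paste(s$sequence, collapse = "")
            s
          }
        )
      ),
      outputs = outputs
    ),
    extra
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

#' Execute a configured analysis stage
#'
#' Validates the configuration, runs the requested stage and writes its
#' result tables plus a `manifest.json` recording inputs, effective
#' parameter values, package version and seed. Identical configurations
#' and inputs produce identical outputs for the deterministic stages.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `status` (0 on success), the output
#'   `dir`, the `manifest` path and stage-specific result tables.
#' @export
run_ppii <- function(cfg) {
  cfg <- validate_run_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character()
  extra <- list()

  if (cfg$stage == "traj") {
    ens <- if (grepl("\\.pdb$", cfg$input, ignore.case = TRUE)) {
      coords <- read_backbone_pdb(cfg$input)
      d <- chain_dihedrals(coords)
      d$frame <- d$model
      d$time_ns <- d$model * cfg$dt_ns
      d
    } else {
      read_dihedrals_tsv(cfg$input)
    }
    report <- ppii_report(
      ens, cfg$segments,
      window_ns = cfg$window_ns, stride_ns = cfg$stride_ns
    )
    outputs <- write_ppii_report(report, out_dir)
    results$report <- report
    segs <- unique(report$per_segment_windowed$segment)
    extra$run_summaries <- lapply(
      stats::setNames(segs, segs),
      function(s) ppii_run_summary(report, s)$fraction
    )
  } else if (cfg$stage == "cd") {
    spectra <- read_cd_csv(cfg$spectra)
    pops <- cd_populations(spectra, lo = cfg$theta_lo, hi = cfg$theta_hi)
    p <- file.path(out_dir, "cd_populations.csv")
    .write_commented(pops, p, "PPII populations from theta_max via the empirical CD relation (route: theta_max of each spectrum)", ",")
    outputs <- c(outputs, p)
    results$populations <- pops
    if ("temperature_C" %in% names(spectra)) {
      temps <- sort(unique(spectra$temperature_C))
      if (length(temps) >= 2L) {
        pairs <- utils::combn(temps, 2, simplify = FALSE)
        diffs <- purrr::map_dfr(pairs, function(pr) {
          difference_spectrum(
            dplyr::filter(spectra, .data$temperature_C == pr[1]),
            dplyr::filter(spectra, .data$temperature_C == pr[2])
          )
        })
        p <- file.path(out_dir, "cd_difference_spectra.csv")
        .write_commented(diffs, p, "temperature difference spectra (cold minus hot), deg cm2 dmol-1", ",")
        outputs <- c(outputs, p)
        results$difference_spectra <- diffs
      }
    }
    if (!is.null(cfg$melt)) {
      trace <- read_melt_csv(cfg$melt)
      fit <- fit_melt(trace)
      lin <- linearity_check(trace)
      fit_tbl <- dplyr::bind_cols(
        glance(fit),
        lin[, c("linear", "longest_sign_run")]
      )
      p <- file.path(out_dir, "melt_fit.csv")
      .write_commented(fit_tbl, p, "linear melt fit: mre = intercept + slope * T(C); r = Pearson", ",")
      outputs <- c(outputs, p)
      results$melt_fit <- fit
    }
  } else if (cfg$stage == "nmr") {
    shifts <- read_shifts_tsv(cfg$input)
    if (!"ca_ref_ppm" %in% names(shifts)) {
      if (is.null(cfg$sequence)) {
        abort("Shift table lacks ca_ref_ppm; provide `sequence` to fill coil references.")
      }
      ref <- coil_reference(cfg$sequence, temperature = cfg$temperature_C)
      if (nrow(ref) != nrow(shifts)) abort("`sequence` length does not match the shift table.")
      shifts$ca_ref_ppm <- ref$ca_ref_ppm
      shifts$ha_ref_ppm <- ref$ha_ref_ppm
    }
    classed <- classify_residues(shifts, cfg$criteria)
    verdict <- segment_verdict(classed, cfg$criteria)
    p <- file.path(out_dir, "nmr_classes.tsv")
    .write_commented(classed, p, "secondary shifts (dca_ppm = obs - coil ref) and residue classes", "\t")
    outputs <- c(outputs, p)
    p <- file.path(out_dir, "nmr_verdict.tsv")
    .write_commented(verdict, p, "segment-level conformational verdict", "\t")
    outputs <- c(outputs, p)
    results$classes <- classed
    results$verdict <- verdict
    extra$verdict <- verdict$verdict
  } else if (cfg$stage == "sim") {
    if (cfg$sim_what == "traj") {
      ens <- simulate_ensemble(cfg$sim_spec)
      p <- file.path(out_dir, "sim_dihedrals.tsv")
      write_dihedrals_tsv(ens, p)
      outputs <- c(outputs, p)
      results$ensemble <- ens
      extra$nominal_occupancy <- cfg$sim_spec$occupancy
    } else if (cfg$sim_what == "cd") {
      series <- simulate_cd_series()
      p1 <- file.path(out_dir, "sim_cd_spectra.csv")
      p2 <- file.path(out_dir, "sim_melt.csv")
      write_cd_csv(series$spectra, p1)
      write_melt_csv(series$melt, p2)
      outputs <- c(outputs, p1, p2)
      results$cd <- series
    } else {
      shifts <- simulate_shift_table(cfg$sequence, seed = cfg$seed)
      p <- file.path(out_dir, "sim_shifts.tsv")
      write_shifts_tsv(shifts, p)
      outputs <- c(outputs, p)
      results$shifts <- shifts
    }
  }

  manifest <- .write_manifest(cfg, out_dir, outputs, extra)
  .log_msg("stage %s complete; %d output file(s) in %s", cfg$stage, length(outputs), out_dir)
  invisible(c(list(status = 0L, dir = out_dir, manifest = manifest), results))
}
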