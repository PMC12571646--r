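# Aggregation of per-frame PPII classifications into windowed, per-residue
# and per-repeat populations.
#
# The estimator is everywhere the same: (# PPII-classified observations) /
# (# observations with both dihedrals defined). Chain termini, whose phi or
# psi is undefined, are excluded from denominators rather than counted as
# non-PPII, so short segments are not biased downward.

.check_ensemble <- function(ens) {
  ens <- as_tibble(ens)
  need <- c("frame", "time_ns", "chain", "residue_index", "phi_deg", "psi_deg")
  missing_cols <- setdiff(need, names(ens))
  if (length(missing_cols)) {
    abort(paste0("Ensemble is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"residue_name" %in% names(ens)) ens$residue_name <- NA_character_
  ang <- c(ens$phi_deg, ens$psi_deg)
  ang <- ang[!is.na(ang)]
  if (length(ang) && (any(ang <= -180) || any(ang > 180))) {
    abort("Dihedral angles must lie in (-180, 180] degrees.")
  }
  tm <- dplyr::distinct(ens, .data$frame, .data$time_ns)
  if (anyDuplicated(tm$frame)) {
    abort("Each frame must have a single time_ns value shared by all chains.")
  }
  tm <- dplyr::arrange(tm, .data$frame)
  if (is.unsorted(tm$time_ns, strictly = TRUE)) {
    abort("Frame times must be strictly increasing.")
  }
  ens
}

#' Define named residue segments
#'
#' Builds a segment map from named 1-based residue position vectors, e.g.
#' `segment_map(CtS = 1:14, GGM1 = 2:4)`. Segments whose names start with
#' "GGM" are treated as the tripeptide Gly-Gly-Met repeats and must each
#' contain exactly 3 positions and be mutually disjoint.
#'
#' @param ... Named integer vectors of residue positions.
#' @return A tibble with columns `segment` and `residue_index`.
#' @seealso [groel_segments()] for the canonical chaperonin tail map.
#' @export
segment_map <- function(...) {
  segs <- list(...)
  if (!length(segs) || is.null(names(segs)) || any(names(segs) == "")) {
    abort("All segments must be named.")
  }
  for (nm in names(segs)) {
    v <- segs[[nm]]
    if (!length(v) || any(v != as.integer(v)) || any(v < 1)) {
      abort(sprintf("Segment '%s' must be a non-empty vector of positive integer positions.", nm))
    }
  }
  repeats <- segs[grepl("^GGM", names(segs))]
  if (length(repeats)) {
    if (any(lengths(repeats) != 3L)) {
      abort("GGM repeats must each contain exactly 3 residues.")
    }
    all_pos <- unlist(repeats)
    if (anyDuplicated(all_pos)) abort("GGM repeats must be disjoint.")
  }
  purrr::map_dfr(names(segs), function(nm) {
    tibble(segment = nm, residue_index = as.integer(sort(unique(segs[[nm]]))))
  })
}

#' Canonical GroEL C-terminal tail segments
#'
#' Segment maps for the two peptide constructs used throughout the
#' package. `"CtS"` is the 14-residue Gly/Met-rich short tail
#' AGGMGGMGGMGGMM with the four GGM repeats at positions 2-4, 5-7, 8-10
#' and 11-13 (the final MM belongs to no repeat). `"CtC"` is the complete
#' 24-residue tail PKNDAADLGAAGGMGGMGGMGGMM, which contains CtS at
#' positions 11-24; repeat positions shift accordingly. Solubility tags
#' present in the synthesized peptides (C-terminal Lys/His) are not part
#' of the analyzed segments because they are absent in the protein.
#'
#' @param tail `"CtS"` or `"CtC"`.
#' @return A segment map tibble as from [segment_map()].
#' @export
groel_segments <- function(tail = c("CtS", "CtC")) {
  tail <- match.arg(tail)
  if (tail == "CtS") {
    segment_map(
      CtS = 1:14,
      GGM1 = 2:4, GGM2 = 5:7, GGM3 = 8:10, GGM4 = 11:13
    )
  } else {
    segment_map(
      CtC = 1:24, CtS = 11:24,
      GGM1 = 12:14, GGM2 = 15:17, GGM3 = 18:20, GGM4 = 21:23
    )
  }
}

# per-(frame, chain, segment) PPII and defined-observation counts
.frame_counts <- function(ens, segments, segment_names, window) {
  seg <- dplyr::filter(segments, .data$segment %in% segment_names)
  df <- dplyr::inner_join(ens, seg, by = "residue_index", relationship = "many-to-many")
  for (nm in segment_names) {
    sub <- dplyr::filter(df, .data$segment == nm)
    if (!nrow(sub)) {
      abort(sprintf("Segment '%s' has no residues present in the ensemble.", nm))
    }
    if (!any(!is.na(sub$phi_deg) & !is.na(sub$psi_deg))) {
      abort(sprintf("Segment '%s' has no residues with defined dihedrals.", nm))
    }
  }
  df$defined <- !is.na(df$phi_deg) & !is.na(df$psi_deg)
  df$hit <- is_ppii(df$phi_deg, df$psi_deg, window)
  df |>
    dplyr::group_by(.data$chain, .data$segment, .data$frame, .data$time_ns) |>
    dplyr::summarise(
      n_def = sum(.data$defined),
      n_ppii = sum(.data$hit),
      .groups = "drop"
    )
}

# half-open trailing windows (t - window_ns, t] at report times that are
# multiples of the stride; a trailing partial window is dropped
.window_series <- function(counts, window_ns, stride_ns, pool_chains) {
  t_max <- max(counts$time_ns)
  t_report <- if (t_max >= stride_ns) seq(stride_ns, t_max, by = stride_ns) else numeric(0)
  t_report <- t_report[t_report >= window_ns - 1e-9]
  if (!length(t_report)) {
    abort(sprintf(
      "Trajectory (%g ns) is shorter than one %g ns window.", t_max, window_ns
    ))
  }
  grp <- if (pool_chains) "segment" else c("chain", "segment")
  purrr::map_dfr(t_report, function(t_k) {
    inside <- counts$time_ns > t_k - window_ns & counts$time_ns <= t_k + 1e-9
    if (!any(inside)) {
      abort(sprintf("Window ending at %g ns contains no frames.", t_k))
    }
    counts[inside, ] |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(
        time_ns = t_k,
        fraction = sum(.data$n_ppii) / sum(.data$n_def),
        n_obs = sum(.data$n_def),
        .groups = "drop"
      )
  })
}

#' Windowed PPII content of named segments
#'
#' PPII helical content averaged over the `window_ns` preceding each
#' report time, per chain: the value reported at time t is the fraction
#' of PPII-classified observations among defined-dihedral observations in
#' frames with time in (t - window_ns, t] and residues in the segment.
#' Report times are multiples of `stride_ns`; a trailing partial window
#' is dropped. With the 50/50 defaults, the value at 50 ns averages
#' 0-50 ns, the value at 100 ns averages 50-100 ns, and so on.
#'
#' @param ens Dihedral ensemble tibble (columns `frame`, `time_ns`,
#'   `chain`, `residue_index`, `phi_deg`, `psi_deg`).
#' @param segments Segment map from [segment_map()].
#' @param segment Segment name(s) to report; default: every non-GGM
#'   segment in the map.
#' @param window_ns,stride_ns Averaging window and report stride in ns.
#' @param window PPII classification window ([ppii_window()]).
#' @return Tibble with columns `chain`, `segment`, `time_ns`, `fraction`,
#'   `n_obs` (the denominator: defined-dihedral observations).
#' @export
ppii_windowed_content <- function(ens, segments, segment = NULL,
                                  window_ns = 50, stride_ns = 50,
                                  window = ppii_window()) {
  ens <- .check_ensemble(ens)
  if (window_ns <= 0 || stride_ns <= 0) abort("`window_ns` and `stride_ns` must be > 0.")
  seg_names <- segment %||% setdiff(unique(segments$segment), grep("^GGM", unique(segments$segment), value = TRUE))
  unknown <- setdiff(seg_names, unique(segments$segment))
  if (length(unknown)) {
    abort(paste0("Unknown segment(s): ", paste(unknown, collapse = ", ")))
  }
  counts <- .frame_counts(ens, segments, seg_names, window)
  out <- .window_series(counts, window_ns, stride_ns, pool_chains = FALSE)
  out[, c("chain", "segment", "time_ns", "fraction", "n_obs")]
}

#' Windowed PPII content of the GGM repeats, pooled over chains
#'
#' Same windowed estimator as [ppii_windowed_content()], restricted to
#' each 3-residue GGM repeat and pooled over all chains (a single trace
#' per repeat).
#'
#' @inheritParams ppii_windowed_content
#' @return Tibble with columns `segment`, `time_ns`, `fraction`, `n_obs`.
#' @export
ppii_per_repeat <- function(ens, segments, window_ns = 50, stride_ns = 50,
                            window = ppii_window()) {
  ens <- .check_ensemble(ens)
  if (window_ns <= 0 || stride_ns <= 0) abort("`window_ns` and `stride_ns` must be > 0.")
  rep_names <- grep("^GGM", unique(segments$segment), value = TRUE)
  if (!length(rep_names)) abort("No GGM repeats defined in `segments`.")
  counts <- .frame_counts(ens, segments, rep_names, window)
  out <- .window_series(counts, window_ns, stride_ns, pool_chains = TRUE)
  out[, c("segment", "time_ns", "fraction", "n_obs")]
}

#' Mean per-residue PPII population over a whole run
#'
#' For each (chain, residue), the mean of the PPII classification
#' indicator over all frames in which both dihedrals are defined.
#' Terminal residues, which never have both dihedrals, are reported with
#' `n_obs = 0` and an `NA` fraction (not-applicable, never 0).
#'
#' @inheritParams ppii_windowed_content
#' @return Tibble with columns `chain`, `residue_index`, `residue_name`,
#'   `mean_fraction`, `n_obs`.
#' @export
ppii_per_residue <- function(ens, window = ppii_window()) {
  ens <- .check_ensemble(ens)
  ens$defined <- !is.na(ens$phi_deg) & !is.na(ens$psi_deg)
  ens$hit <- is_ppii(ens$phi_deg, ens$psi_deg, window)
  ens |>
    dplyr::group_by(.data$chain, .data$residue_index, .data$residue_name) |>
    dplyr::summarise(
      n_obs = sum(.data$defined),
      mean_fraction = ifelse(sum(.data$defined) > 0, sum(.data$hit) / sum(.data$defined), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::select("chain", "residue_index", "residue_name", "mean_fraction", "n_obs") |>
    dplyr::arrange(.data$chain, .data$residue_index)
}

#' Full PPII population report for an ensemble
#'
#' Convenience wrapper computing the three standard summaries in one
#' pass: whole-run per-residue populations, windowed content per chain
#' for each named (non-GGM) segment, and windowed content per GGM repeat
#' pooled over chains (when the map defines repeats).
#'
#' @inheritParams ppii_windowed_content
#' @return An object of class `ppii_report`: a list with tibbles
#'   `per_residue`, `per_segment_windowed`, `per_repeat_windowed` (or
#'   `NULL`), and `params`.
#' @export
ppii_report <- function(ens, segments = groel_segments("CtS"),
                        window_ns = 50, stride_ns = 50,
                        window = ppii_window()) {
  ens <- .check_ensemble(ens)
  rep_names <- grep("^GGM", unique(segments$segment), value = TRUE)
  out <- list(
    per_residue = ppii_per_residue(ens, window),
    per_segment_windowed = ppii_windowed_content(
      ens, segments,
      window_ns = window_ns, stride_ns = stride_ns, window = window
    ),
    per_repeat_windowed = if (length(rep_names)) {
      ppii_per_repeat(ens, segments, window_ns = window_ns, stride_ns = stride_ns, window = window)
    },
    params = list(
      window_ns = window_ns, stride_ns = stride_ns,
      window = unclass(window),
      n_frames = dplyr::n_distinct(ens$frame),
      chains = sort(unique(ens$chain))
    )
  )
  structure(out, class = "ppii_report")
}

#' @export
print.ppii_report <- function(x, ...) {
  cat(sprintf(
    "<ppii_report> %d frames, %d chain(s); window %g ns / stride %g ns\n",
    x$params$n_frames, length(x$params$chains),
    x$params$window_ns, x$params$stride_ns
  ))
  segs <- unique(x$per_segment_windowed$segment)
  for (s in segs) {
    cat(sprintf(
      "  %s: run-average PPII fraction %.3f\n", s,
      ppii_run_summary(x, s)$fraction
    ))
  }
  invisible(x)
}

#' Time-averaged PPII fraction of a segment
#'
#' Collapses windowed content into the single scalar quoted per
#' condition. `weights = "observation"` (default) weights every
#' defined-dihedral observation equally, i.e. the mean over all windows
#' and chains weighted by their denominators; `weights = "chain"` first
#' averages within each chain (observation-weighted) and then averages
#' the chains with equal weight.
#'
#' @param x A `ppii_report` or a windowed-content tibble with columns
#'   `segment`, `fraction`, `n_obs` (and `chain` for chain weighting).
#' @param segment Segment name to summarize.
#' @param weights `"observation"` or `"chain"`.
#' @return One-row tibble with `segment`, `weighting`, `fraction`,
#'   `n_obs`, `n_windows`.
#' @export
ppii_run_summary <- function(x, segment, weights = c("observation", "chain")) {
  weights <- match.arg(weights)
  tbl <- if (inherits(x, "ppii_report")) x$per_segment_windowed else as_tibble(x)
  need <- c("segment", "fraction", "n_obs")
  if (!all(need %in% names(tbl))) {
    abort("`x` must be a ppii_report or a windowed-content table with segment, fraction, n_obs.")
  }
  tbl <- dplyr::filter(tbl, .data$segment == !!segment)
  if (!nrow(tbl)) abort(sprintf("Segment '%s' not present in the report.", segment))
  if (weights == "observation") {
    frac <- weighted.mean(tbl$fraction, tbl$n_obs)
  } else {
    if (!"chain" %in% names(tbl)) abort("Chain weighting requires a `chain` column.")
    per_chain <- tbl |>
      dplyr::group_by(.data$chain) |>
      dplyr::summarise(f = weighted.mean(.data$fraction, .data$n_obs), .groups = "drop")
    frac <- mean(per_chain$f)
  }
  tibble(
    segment = segment, weighting = weights, fraction = frac,
    n_obs = sum(tbl$n_obs), n_windows = dplyr::n_distinct(tbl$time_ns)
  )
}
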