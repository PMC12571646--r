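# Backbone torsion geometry and the PPII dihedral window.
#
# Angles are reported in degrees throughout, in (-180, 180], following the
# IUPAC convention (cis = 0, trans = 180). Radians are never exposed.

.as_point_matrix <- function(p, arg) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) {
      abort(sprintf("`%s` must be a 3-vector or an n x 3 matrix.", arg))
    }
    p <- matrix(as.numeric(p), ncol = 3L)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 3L) abort(sprintf("`%s` must have 3 columns.", arg))
    storage.mode(p) <- "double"
  }
  if (!all(is.finite(p))) abort(sprintf("`%s` contains non-finite coordinates.", arg))
  p
}

.rowcross <- function(a, b) {
  cbind(
    a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
    a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
    a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  )
}

.rownorm <- function(a) sqrt(rowSums(a * a))

#' Signed torsion angle defined by four points
#'
#' Computes the dihedral angle about the p2--p3 axis using the IUPAC sign
#' convention: 0 degrees for a cis (eclipsed) arrangement, 180 degrees for
#' trans. All four arguments may be single 3-vectors or n x 3 matrices of
#' row-wise point sets, in which case a vector of n angles is returned.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors or n x 3 matrices (angstroms, or any
#'   consistent length unit).
#' @return Numeric vector of angles in degrees, in (-180, 180].
#' @examples
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # trans: 180
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)) # cis: 0
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- .as_point_matrix(p1, "p1")
  p2 <- .as_point_matrix(p2, "p2")
  p3 <- .as_point_matrix(p3, "p3")
  p4 <- .as_point_matrix(p4, "p4")
  n <- max(nrow(p1), nrow(p2), nrow(p3), nrow(p4))
  rep_rows <- function(m) if (nrow(m) == n) m else m[rep(seq_len(nrow(m)), length.out = n), , drop = FALSE]
  p1 <- rep_rows(p1); p2 <- rep_rows(p2); p3 <- rep_rows(p3); p4 <- rep_rows(p4)

  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .rowcross(b1, b2)
  n2 <- .rowcross(b2, b3)

  scale1 <- .rownorm(b1) * .rownorm(b2)
  scale2 <- .rownorm(b2) * .rownorm(b3)
  bad1 <- .rownorm(n1) <= 1e-9 * pmax(scale1, .Machine$double.eps)
  bad2 <- .rownorm(n2) <= 1e-9 * pmax(scale2, .Machine$double.eps)
  if (any(bad1) || any(bad2)) {
    i <- which(bad1 | bad2)[1L]
    which_triple <- if (isTRUE(bad1[i])) "p1, p2, p3" else "p2, p3, p4"
    abort(sprintf(
      "Degenerate geometry at row %d: points %s are collinear; the torsion is undefined.",
      i, which_triple
    ))
  }

  b2u <- b2 / .rownorm(b2)
  m1 <- .rowcross(n1, b2u)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  # contract is (-180, 180]
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' PPII dihedral window
#'
#' The rectangular Ramachandran window used to call a residue conformation
#' polyproline II: phi within `half_width` of `phi_center` and psi within
#' `half_width` of `psi_center`, distances measured on the circle and
#' boundaries inclusive. Defaults are phi = -75 +/- 20 and psi = +150 +/- 20
#' degrees.
#'
#' @param phi_center,psi_center Window centers in degrees, in (-180, 180].
#' @param half_width Half-width in degrees, > 0.
#' @return An object of class `ppii_window`.
#' @export
ppii_window <- function(phi_center = -75, psi_center = 150, half_width = 20) {
  for (v in c(phi_center, psi_center, half_width)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort("`ppii_window()` arguments must be finite scalars.")
    }
  }
  if (half_width <= 0) abort("`half_width` must be > 0.")
  if (phi_center <= -180 || phi_center > 180 || psi_center <= -180 || psi_center > 180) {
    abort("Window centers must lie in (-180, 180].")
  }
  structure(
    list(phi_center = phi_center, psi_center = psi_center, half_width = half_width),
    class = "ppii_window"
  )
}

#' @export
print.ppii_window <- function(x, ...) {
  cat(sprintf(
    "<ppii_window> phi = %g +/- %g deg, psi = %g +/- %g deg (inclusive)\n",
    x$phi_center, x$half_width, x$psi_center, x$half_width
  ))
  invisible(x)
}

# circular difference a - b mapped into [-180, 180)
.circ_delta <- function(a, b) ((a - b + 180) %% 360) - 180

#' Classify dihedral pairs against the PPII window
#'
#' A pair is PPII when both angles are defined (non-`NA`) and each lies
#' within the window half-width of its center, measured as circular
#' distance with inclusive boundaries. Undefined angles (chain termini)
#' are never PPII.
#'
#' @param phi,psi Numeric vectors of backbone dihedrals in degrees; `NA`
#'   marks an undefined angle.
#' @param window A [ppii_window()].
#' @return Logical vector, never `NA`.
#' @examples
#' is_ppii(-75, 150)
#' is_ppii(c(-55, -120, NA), c(170, 130, 150))
#' @export
is_ppii <- function(phi, psi, window = ppii_window()) {
  stopifnot(inherits(window, "ppii_window"))
  inside <- abs(.circ_delta(phi, window$phi_center)) <= window$half_width &
    abs(.circ_delta(psi, window$psi_center)) <= window$half_width
  inside & !is.na(inside)
}

#' Backbone dihedrals of a chain
#'
#' Computes phi/psi for every residue of each (model, chain) group in a
#' backbone coordinate table: phi_i from C(i-1), N(i), CA(i), C(i) and
#' psi_i from N(i), CA(i), C(i), N(i+1). The first residue carries an
#' undefined phi and the last an undefined psi (`NA`).
#'
#' @param coords Data frame with one row per backbone atom and columns
#'   `chain`, `residue_index`, `residue_name`, `atom` (one of "N", "CA",
#'   "C"), `x`, `y`, `z`, and optionally `model`.
#' @return A tibble with columns `model`, `chain`, `residue_index`,
#'   `residue_name`, `phi_deg`, `psi_deg`.
#' @seealso [build_backbone()] for the inverse construction.
#' @export
chain_dihedrals <- function(coords) {
  coords <- as_tibble(coords)
  need <- c("chain", "residue_index", "atom", "x", "y", "z")
  missing_cols <- setdiff(need, names(coords))
  if (length(missing_cols)) {
    abort(paste0("`coords` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"model" %in% names(coords)) coords$model <- 1L
  if (!"residue_name" %in% names(coords)) coords$residue_name <- "UNK"
  coords <- dplyr::filter(coords, .data$atom %in% c("N", "CA", "C"))
  if (!all(is.finite(coords$x) & is.finite(coords$y) & is.finite(coords$z))) {
    abort("`coords` contains non-finite coordinates.")
  }

  one_group <- function(df, key) {
    df <- dplyr::arrange(df, .data$residue_index, .data$atom)
    wide <- tidyr::pivot_wider(
      df,
      id_cols = c("residue_index", "residue_name"),
      names_from = "atom", values_from = c("x", "y", "z")
    )
    for (col in c("x_N", "y_N", "z_N", "x_CA", "y_CA", "z_CA", "x_C", "y_C", "z_C")) {
      if (!col %in% names(wide)) wide[[col]] <- NA_real_
    }
    bad <- !stats::complete.cases(wide[, c("x_N", "x_CA", "x_C", "y_N", "y_CA", "y_C", "z_N", "z_CA", "z_C")])
    if (any(bad)) {
      abort(sprintf(
        "Residue %s of chain %s (model %s) is missing one or more backbone atoms (N, CA, C).",
        paste(wide$residue_index[bad], collapse = ", "), key$chain[1], key$model[1]
      ))
    }
    wide <- dplyr::arrange(wide, .data$residue_index)
    n <- nrow(wide)
    if (n < 2L) {
      abort(sprintf(
        "Chain %s (model %s) has %d residue(s); at least 2 are required to define any dihedral.",
        key$chain[1], key$model[1], n
      ))
    }
    N <- as.matrix(wide[, c("x_N", "y_N", "z_N")])
    CA <- as.matrix(wide[, c("x_CA", "y_CA", "z_CA")])
    C <- as.matrix(wide[, c("x_C", "y_C", "z_C")])
    i <- 2:n
    phi <- c(NA_real_, dihedral_angle(
      C[i - 1L, , drop = FALSE], N[i, , drop = FALSE],
      CA[i, , drop = FALSE], C[i, , drop = FALSE]
    ))
    j <- 1:(n - 1L)
    psi <- c(dihedral_angle(
      N[j, , drop = FALSE], CA[j, , drop = FALSE],
      C[j, , drop = FALSE], N[j + 1L, , drop = FALSE]
    ), NA_real_)
    tibble(
      residue_index = wide$residue_index,
      residue_name = wide$residue_name,
      phi_deg = phi,
      psi_deg = psi
    )
  }

  out <- coords |>
    dplyr::group_by(.data$model, .data$chain) |>
    dplyr::group_modify(one_group) |>
    dplyr::ungroup()
  out[, c("model", "chain", "residue_index", "residue_name", "phi_deg", "psi_deg")]
}

#' Read backbone coordinates from a (multi-model) PDB file
#'
#' Reads N/CA/C ATOM records via \pkg{bio3d}, one coordinate set per MODEL
#' record. Alternate locations are resolved by keeping the highest
#' occupancy conformer.
#'
#' @param path Path to a PDB file.
#' @param chains Optional character vector restricting the chains kept.
#' @return A backbone coordinate tibble with columns `model`, `chain`,
#'   `residue_index`, `residue_name`, `atom`, `x`, `y`, `z`.
#' @export
read_backbone_pdb <- function(path, chains = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atoms <- as_tibble(pdb$atom)
  atoms$row <- seq_len(nrow(atoms))
  atoms <- dplyr::filter(atoms, .data$type == "ATOM", .data$elety %in% c("N", "CA", "C"))
  if (!nrow(atoms)) abort(sprintf("No backbone ATOM records (N, CA, C) found in %s", path))
  atoms$chain[is.na(atoms$chain) | atoms$chain == ""] <- "A"
  if (!is.null(chains)) atoms <- dplyr::filter(atoms, .data$chain %in% chains)
  atoms$o[is.na(atoms$o)] <- 1
  # altloc: keep the highest-occupancy record per (chain, residue, atom)
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$row, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$row)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  sel <- atoms$row
  purrr::map_dfr(seq_len(n_models), function(m) {
    tibble(
      model = m,
      chain = atoms$chain,
      residue_index = atoms$resno,
      residue_name = atoms$resid,
      atom = atoms$elety,
      x = xyz[m, 3L * (sel - 1L) + 1L],
      y = xyz[m, 3L * (sel - 1L) + 2L],
      z = xyz[m, 3L * (sel - 1L) + 3L]
    )
  })
}
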