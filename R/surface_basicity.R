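# Solvent-accessible surface area by the Shrake-Rupley method with a
# deterministic golden-section spiral point lattice, and exposed
# basic-residue profiling (pepsin-like vs cathepsin-D-like surfaces).

# Bondi van der Waals radii (Angstrom); unknown elements fall back to carbon.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
               I = 1.98)
VDW_DEFAULT <- 1.70

# Theoretical maximum accessible surface areas per residue (Angstrom^2),
# Tien et al. 2013 "theoretical" column; used for relative exposure.
MAX_ASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

element_radius <- function(element) {
  element <- toupper(element)
  r <- unname(VDW_RADII[element])
  if (anyNA(r)) {
    warn(paste0("unknown element(s) ",
                paste(unique(element[is.na(r)]), collapse = ", "),
                ": using default radius ", VDW_DEFAULT, " A"))
    r[is.na(r)] <- VDW_DEFAULT
  }
  r
}

#' Read atoms from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records, assigns Bondi van der Waals
#' radii from the element, and drops waters and heteroatoms by default.
#'
#' @param path PDB file path.
#' @param keep_waters keep HOH/WAT residues (default `FALSE`).
#' @param keep_hetero keep HETATM records (default `FALSE`).
#' @return tibble with one row per atom: `element`, `x`, `y`, `z`,
#'   `vdw_radius`, `atom_name`, `residue_name`, `residue_number`, `chain`,
#'   `is_sidechain`.
#' @export
read_structure <- function(path, keep_waters = FALSE, keep_hetero = FALSE) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  keep <- at$type == "ATOM" | (keep_hetero & at$type == "HETATM")
  if (!keep_waters) keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) abort(paste0("no usable ATOM records in ", path))
  elem <- toupper(trimws(at$elesy))
  blank <- is.na(elem) | !nzchar(elem)
  # fall back on the first letter of the atom name when the element column
  # is absent (common in minimal / generated PDB files)
  elem[blank] <- substr(gsub("[0-9 ]", "", toupper(at$elety[blank])), 1, 1)
  tibble(
    element = elem,
    x = at$x, y = at$y, z = at$z,
    vdw_radius = element_radius(elem),
    atom_name = trimws(at$elety),
    residue_name = trimws(at$resid),
    residue_number = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    is_sidechain = !(trimws(at$elety) %in% BACKBONE_ATOMS) &
      !startsWith(elem, "H")
  )
}

# Deterministic near-uniform unit-sphere lattice (golden-section spiral).
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the atom set: each atom's accessible area is the
#' fraction of `n_points` lattice points on its probe-expanded sphere that
#' fall outside every neighbor's probe-expanded sphere, times the sphere
#' area. The point lattice is a fixed golden-section spiral, so results are
#' bit-stable across runs.
#'
#' @param atoms atom tibble from [read_structure()] (needs `x`, `y`, `z`,
#'   `vdw_radius`; residue columns enable the per-residue summary).
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points lattice points per atom (default 960).
#' @return object of class `pep_sasa`: list with `atoms` (input plus `area`),
#'   `residues` (per-residue `area`, `sidechain_area`, `rel_exposure` =
#'   area / theoretical maximum for that residue type), `total`, `probe`,
#'   `n_points`.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0) {
    abort("atoms must be a non-empty data frame")
  }
  if (!is.numeric(probe) || probe < 0) abort("probe radius must be >= 0")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) abort("atom coordinates must be finite")
  re <- atoms$vdw_radius + probe
  n <- nrow(xyz)
  lattice <- sphere_lattice(n_points)
  area <- numeric(n)
  max_re <- max(re)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (re[i] + max_re)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < re[i] + re[nb]]
    if (length(nb) == 0) {
      area[i] <- 4 * pi * re[i]^2
      next
    }
    pts <- sweep(lattice * re[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
        (pts[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 > re[j]^2
    }
    area[i] <- 4 * pi * re[i]^2 * sum(free) / n_points
  }
  atoms$area <- area
  if (is.null(atoms$is_sidechain)) atoms$is_sidechain <- TRUE
  residues <- NULL
  if (all(c("residue_name", "residue_number", "chain") %in% names(atoms))) {
    residues <- atoms |>
      group_by(.data$chain, .data$residue_number, .data$residue_name) |>
      summarise(
        area = sum(.data$area),
        sidechain_area = sum(.data$area[.data$is_sidechain]),
        .groups = "drop"
      ) |>
      mutate(rel_exposure = .data$area /
               unname(MAX_ASA[.data$residue_name]))
    if (anyNA(residues$rel_exposure)) {
      warn(paste0("no reference area for residue(s): ",
                  paste(unique(residues$residue_name[
                    is.na(residues$rel_exposure)]), collapse = ", ")))
    }
  }
  structure(
    list(atoms = as_tibble(atoms), residues = residues,
         total = sum(area), probe = probe, n_points = n_points),
    class = "pep_sasa"
  )
}

#' @export
print.pep_sasa <- function(x, ...) {
  cat("Shrake-Rupley SASA: ", nrow(x$atoms), " atoms, total ",
      round(x$total, 1), " A^2 (probe ", x$probe, " A, ", x$n_points,
      " points)\n", sep = "")
  invisible(x)
}

#' @method tidy pep_sasa
#' @export
tidy.pep_sasa <- function(x, ...) {
  if (is.null(x$residues)) x$atoms else x$residues
}

#' Classify a basic-residue surface profile
#'
#' Cutoffs derive from the two archetype surfaces: cathepsin D exposes 20
#' lysines and 8 arginines, pepsin A only 3 arginines and no lysines. A
#' surface is `cathepsinD_like` with at least `cathepsin_min` exposed basics
#' and a lysine majority, `pepsin_like` with at most `pepsin_max` exposed
#' basics, `indeterminate` otherwise.
#'
#' @param exposed_lys,exposed_arg exposed residue counts.
#' @param cathepsin_min,pepsin_max classification cutoffs (defaults 10, 5).
#' @return character scalar.
#' @export
classify_basicity <- function(exposed_lys, exposed_arg,
                              cathepsin_min = 10, pepsin_max = 5) {
  total <- exposed_lys + exposed_arg
  if (total >= cathepsin_min && exposed_lys > exposed_arg) "cathepsinD_like"
  else if (total <= pepsin_max) "pepsin_like"
  else "indeterminate"
}

#' Count exposed basic residues on a SASA result
#'
#' Lys/Arg residues whose relative exposure (residue area over the
#' theoretical maximum for that residue type) is at least `rel_threshold`
#' are counted as surface-exposed; the profile is then classified with
#' [classify_basicity()]. Residues without a reference area are skipped with
#' a warning.
#'
#' @param sasa a `pep_sasa` result with a per-residue summary.
#' @param rel_threshold relative exposure cut, default 0.25.
#' @param ... cutoffs passed to [classify_basicity()].
#' @return one-row tibble: `exposed_lys`, `exposed_arg`, `exposed_basics`,
#'   `classification`.
#' @export
count_exposed_basics <- function(sasa, rel_threshold = 0.25, ...) {
  if (!inherits(sasa, "pep_sasa") || is.null(sasa$residues)) {
    abort("count_exposed_basics needs a pep_sasa result with residue info")
  }
  res <- sasa$residues
  if (anyNA(res$rel_exposure)) {
    warn(paste0("skipping residue(s) without reference area: ",
                paste(unique(res$residue_name[is.na(res$rel_exposure)]),
                      collapse = ", ")))
    res <- res[!is.na(res$rel_exposure), ]
  }
  exposed <- res[res$rel_exposure >= rel_threshold, ]
  lys <- sum(exposed$residue_name == "LYS")
  arg <- sum(exposed$residue_name == "ARG")
  tibble(
    exposed_lys = lys, exposed_arg = arg, exposed_basics = lys + arg,
    classification = classify_basicity(lys, arg, ...)
  )
}
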