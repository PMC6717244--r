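# Solvent accessible and buried surface area.

atom_radii <- function(s, radii, probe, strict) {
  el <- toupper(s$atoms$element)
  r <- radii[el]
  if (anyNA(r)) {
    if (strict) stop("no vdW radius for element(s): ",
                     paste(unique(el[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- 1.8
  }
  unname(r) + probe
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Test-point SASA with deterministic golden-spiral directions, probe
#' radius 1.4 A and 3000 points per atom by default.
#'
#' @param s structure.
#' @param probe probe (rolling ball) radius in Angstrom.
#' @param n_points test points per atom.
#' @param radii named vdW radii vector, default [vdw_radii()].
#' @param strict error on elements missing from the radii table instead
#'   of falling back to 1.8 A.
#' @return object of class `sasa_result`: `per_atom_sasa` (A^2, one
#'   value per atom row), `per_residue_sasa` (named by residue key),
#'   `probe_radius`, `n_points`.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 3000, radii = NULL,
                         strict = FALSE) {
  stopifnot(probe > 0, n_points >= 1)
  if (is.null(radii)) radii <- vdw_radii()
  r <- atom_radii(s, radii, probe, strict)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  per_atom <- sasa_kernel(xyz, r, pts)
  key <- residue_key(s$atoms$chain, s$atoms$resno, s$atoms$ins)
  per_res <- tapply(per_atom, key, sum)
  structure(list(per_atom_sasa = per_atom,
                 per_residue_sasa = per_res[unique(key)],
                 probe_radius = probe, n_points = n_points),
            class = "sasa_result")
}

#' Buried surface area upon complex formation
#'
#' BSA of each query atom/residue = SASA computed on the query alone
#' minus SASA computed in the presence of the partner, clipped at zero.
#'
#' @param query,partner structures.
#' @inheritParams compute_sasa
#' @return object of class `bsa_result`: `per_atom_bsa`,
#'   `per_residue_bsa`, plus the two underlying per-atom SASA vectors
#'   (`sasa_alone`, `sasa_complex`).
#' @export
compute_bsa <- function(query, partner, probe = 1.4, n_points = 3000,
                        radii = NULL, strict = FALSE) {
  if (nrow(query$atoms) == 0L || nrow(partner$atoms) == 0L)
    stop("empty structure")
  alone <- compute_sasa(query, probe, n_points, radii, strict)
  both <- query
  both$atoms <- rbind(query$atoms, partner$atoms)
  cplx <- compute_sasa(both, probe, n_points, radii, strict)
  nq <- nrow(query$atoms)
  sasa_complex <- cplx$per_atom_sasa[seq_len(nq)]
  per_atom <- pmax(alone$per_atom_sasa - sasa_complex, 0)
  key <- residue_key(query$atoms$chain, query$atoms$resno, query$atoms$ins)
  per_res <- tapply(per_atom, key, sum)
  structure(list(per_atom_bsa = per_atom,
                 per_residue_bsa = per_res[unique(key)],
                 sasa_alone = alone$per_atom_sasa,
                 sasa_complex = sasa_complex,
                 probe_radius = probe, n_points = n_points),
            class = "bsa_result")
}
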