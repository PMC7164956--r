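#' @title Geometry metrics
#' @description Torsion angles (IUPAC sign convention), Kabsch least-squares
#'   superposition, and radial displacement of residue stretches relative to a
#'   reference atom — the metrics used to quantify chromophore and backbone
#'   rearrangements (e.g. the D-ring twist and the helix shift away from the
#'   pyrrole water).
#' @name geometry
NULL

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion (dihedral) angle of four points
#'
#' Signed IUPAC torsion in degrees in (-180, 180]: looking along p2 -> p3,
#' clockwise rotation of the far bond is positive. Invariant under rigid
#' motion of all four points.
#'
#' @param p1,p2,p3,p4 Cartesian 3-vectors (angstrom).
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 || sqrt(sum(b3^2)) < 1e-9) {
    stop("degenerate dihedral: coincident consecutive points")
  }
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    stop("degenerate dihedral: collinear points")
  }
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(vcross(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Torsion angle from a model and four atom identifiers
#'
#' @param model An `xtal_model`.
#' @param atoms List of four specs, each `list(chain=, resno=, name=)`
#'   (missing fields match anything, but each spec must resolve to exactly
#'   one atom).
#' @return Angle in degrees.
#' @export
model_dihedral <- function(model, atoms) {
  stopifnot(length(atoms) == 4)
  pts <- lapply(atoms, function(sp) {
    a <- model$atoms
    keep <- rep(TRUE, nrow(a))
    if (!is.null(sp$chain)) keep <- keep & a$chain == sp$chain
    if (!is.null(sp$resno)) keep <- keep & a$resno == sp$resno
    if (!is.null(sp$name)) keep <- keep & a$name == sp$name
    i <- which(keep)
    if (length(i) != 1) {
      stop("atom spec resolves to ", length(i), " atoms: ",
           paste(unlist(sp), collapse = " "))
    }
    as.numeric(a[i, c("x", "y", "z")])
  })
  dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation minimising the rmsd between two
#' paired coordinate lists (correspondence by row order).
#'
#' @param coords_a,coords_b Matrices (n x 3), n >= 3, in angstrom.
#' @return List with `rmsd` (angstrom), `rotation` (3 x 3, applied to
#'   centred `coords_a`), and `translation` such that
#'   `coords_a %*% t(rotation) + translation` superposes onto `coords_b`.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- rbind_coords(coords_a); b <- rbind_coords(coords_b)
  if (nrow(a) != nrow(b)) stop("coordinate lists differ in length")
  if (nrow(a) < 3) stop("need at least 3 paired points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  sv <- svd(crossprod(a0, b0))          # H = t(a0) b0 = U D t(V)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  list(rmsd = rmsd, rotation = rot,
       translation = as.numeric(cb - ca %*% t(rot)))
}

#' Mean radial displacement of a residue stretch
#'
#' For each selected atom i, Dd_i = dist(b_i, ref) - dist(a_i, ref), where
#' ref is the position of the reference atom in `model_a` (conventionally the
#' dark model; the reference is the stable anchor when the corresponding atom
#' moves in the excited state). Positive values mean the atom moved away from
#' the reference.
#'
#' @param model_a,model_b `xtal_model`s containing the same selection.
#' @param chain,residues,atom_names Selection passed to [select_atoms()];
#'   defaults keep all non-hydrogen atoms of the chosen residues.
#' @param reference `list(chain=, resno=, name=)` identifying the reference
#'   atom, resolved in `model_a`.
#' @return List with `mean` (angstrom) and `per_atom` (data.frame of signed
#'   per-atom displacements).
#' @export
mean_displacement <- function(model_a, model_b, chain = NULL, residues = NULL,
                              atom_names = NULL, reference) {
  sel_a <- select_atoms(model_a, chain, residues, atom_names)
  sel_b <- select_atoms(model_b, chain, residues, atom_names)
  sel_a$atoms <- sel_a$atoms[sel_a$atoms$element != "H", , drop = FALSE]
  sel_b$atoms <- sel_b$atoms[sel_b$atoms$element != "H", , drop = FALSE]
  key <- function(a) paste(a$chain, a$resno, a$name)
  ka <- key(sel_a$atoms); kb <- key(sel_b$atoms)
  if (!identical(sort(ka), sort(kb))) {
    stop("selections differ between models; missing: ",
         paste(union(setdiff(ka, kb), setdiff(kb, ka)), collapse = ", "))
  }
  ord <- match(ka, kb)
  ref_model <- select_atoms(model_a, reference$chain,
                            rep(reference$resno, 2), reference$name)
  if (n_atoms(ref_model) != 1) stop("reference atom spec does not resolve uniquely")
  ref <- as.numeric(coords(ref_model))
  da <- sqrt(rowSums(sweep(coords(sel_a), 2, ref)^2))
  db <- sqrt(rowSums(sweep(coords(sel_b)[ord, , drop = FALSE], 2, ref)^2))
  per <- data.frame(atom = ka, d_dark = da, d_other = db, delta = db - da)
  list(mean = mean(per$delta), per_atom = per)
}
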