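#' Rigid transforms and Kabsch superposition
#'
#' `kabsch()` computes the proper rotation and translation minimizing the RMSD
#' of `mobile` onto `reference` (matched row-by-row) by singular value
#' decomposition of the covariance matrix. If the optimal orthogonal matrix
#' has determinant -1 the sign of the smallest singular vector is flipped, so
#' the result is always a proper rotation (no reflection).
#'
#' @param mobile,reference n x 3 coordinate matrices, equal n >= 3
#' @return object of class `rigid_transform`: list with `rotation` (3x3,
#'   orthonormal, det +1), `translation` (length-3), and `rmsd` (Angstrom, the
#'   minimized value)
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3)
    pf_stop("input", "coordinate matrices must have 3 columns")
  if (nrow(mobile) != nrow(reference))
    pf_stop("input", "mobile and reference have different lengths (",
            nrow(mobile), " vs ", nrow(reference), ")")
  if (nrow(mobile) < 3)
    pf_stop("input", "need at least 3 paired points, got ", nrow(mobile))
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  for (M in list(P, Q)) {
    sv <- svd(M)$d
    if (sv[2] <= 1e-8 * max(sv[1], 1e-12))
      pf_stop("geometry", "points are collinear; rotation is rank-deficient")
  }
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.vector(cr - R %*% cm)
  moved <- P %*% t(R)  # centered mobile, rotated
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 4), collapse = " "), "\n")
  if (!is.null(x$rmsd)) cat("rmsd:", format(x$rmsd), "A\n")
  invisible(x)
}

#' Identity and inverse transforms
#' @return a `rigid_transform`
#' @export
identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0), rmsd = NULL),
            class = "rigid_transform")
}

#' @param tf a `rigid_transform`
#' @rdname identity_transform
#' @export
invert_transform <- function(tf) {
  R <- t(tf$rotation)
  structure(list(rotation = R, translation = as.vector(-R %*% tf$translation),
                 rmsd = tf$rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform
#'
#' Every position p becomes `rotation %*% p + translation`; non-coordinate
#' fields are untouched.
#'
#' @param x a `pf_structure` or an n x 3 coordinate matrix
#' @param tf a `rigid_transform`
#' @return same type as `x`, transformed
#' @export
apply_transform <- function(x, tf) {
  if (!inherits(tf, "rigid_transform"))
    pf_stop("input", "tf must be a rigid_transform")
  if (inherits(x, "pf_structure")) {
    xyz <- apply_transform(coords(x), tf)
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  xyz <- as.matrix(x)
  sweep(xyz %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Place a receptor in the membrane frame
#'
#' Superposes `mobile` onto a membrane-aligned `reference` (z = membrane
#' normal, extracellular at larger z, as in the OPM convention) and returns
#' the transformed structure. Atom pairing uses Calpha atoms sharing
#' `(chain, resno, insert)`; with `pairing = "tm"` (default when a TM
#' annotation is supplied) pairing is restricted to TM-annotated residues,
#' since loops differ between receptor states.
#'
#' @param mobile,reference `pf_structure`s
#' @param tm optional [tm_annotation()] applied to both structures
#' @param pairing `"tm"` or `"all"`
#' @return list with `structure` (transformed mobile), `transform`,
#'   `rmsd` (Angstrom) and `n_pairs`
#' @export
membrane_align <- function(mobile, reference, tm = NULL,
                           pairing = c("tm", "all")) {
  pairing <- match.arg(pairing)
  ma <- ca_atoms(mobile)$atoms
  ra <- ca_atoms(reference)$atoms
  if (pairing == "tm" && !is.null(tm)) {
    ma <- ma[tm_residue_mask(list(atoms = ma), tm), , drop = FALSE]
    ra <- ra[tm_residue_mask(list(atoms = ra), tm), , drop = FALSE]
  }
  key_m <- paste(ma$chain, ma$resno, ma$insert)
  key_r <- paste(ra$chain, ra$resno, ra$insert)
  common <- intersect(key_m, key_r)
  if (length(common) < 3)
    pf_stop("pairing", "only ", length(common),
            " common Calpha atoms between mobile and reference")
  mi <- match(common, key_m); ri <- match(common, key_r)
  tf <- kabsch(as.matrix(ma[mi, c("x", "y", "z")]),
               as.matrix(ra[ri, c("x", "y", "z")]))
  list(structure = apply_transform(mobile, tf), transform = tf,
       rmsd = tf$rmsd, n_pairs = length(common))
}
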