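#' van der Waals radii
#'
#' Bondi radii for the elements found in protein models. Element `"X"`
#' (grid-point pseudo-atoms) has radius 0. Unknown elements fall back to the
#' carbon radius of the set.
#'
#' @param elements character vector of element symbols
#' @param set radius table name; only `"bondi"` is shipped
#' @return numeric vector of radii in Angstrom
#' @export
vdw_radius <- function(elements, set = "bondi") {
  if (!identical(set, "bondi"))
    pf_stop("input", "unknown radius set: ", set)
  tab <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
           P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
           X = 0.00)
  r <- unname(tab[toupper(elements)])
  r[is.na(r)] <- 1.70
  r
}

#' Grid configuration for cavity-volume calculation
#'
#' @param spacing grid spacing in Angstrom; 0.5 by default (a grid-convergence
#'   test against 0.25 justifies the default)
#' @param probe_radius probe radius in Angstrom added to each atomic van der
#'   Waals radius for the clash test; 0 by default, 1.4 approximates a water
#'   probe
#' @param radius_set name of the van der Waals radius table
#' @param window z half-window (Angstrom) for helix-center estimation
#' @param helix_order bundle ordering, `"index"` or `"angular"`
#' @return object of class `grid_config`
#' @export
grid_config <- function(spacing = 0.5, probe_radius = 0.0,
                        radius_set = "bondi", window = 2.0,
                        helix_order = c("index", "angular")) {
  helix_order <- match.arg(helix_order)
  if (!is.numeric(spacing) || spacing <= 0)
    pf_stop("input", "spacing must be > 0")
  if (!is.numeric(probe_radius) || probe_radius < 0)
    pf_stop("input", "probe_radius must be >= 0")
  structure(list(spacing = spacing, probe_radius = probe_radius,
                 radius_set = radius_set, window = window,
                 helix_order = helix_order),
            class = "grid_config")
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Vectorized even-odd ray-casting test handling non-convex rings. Points
#' lying exactly on an edge count as inside.
#'
#' @param points n x 2 matrix (or length-2 vector) of query points
#' @param ring m x 2 matrix of polygon vertices (open ring, m >= 3 distinct)
#' @param eps tolerance for the on-edge test
#' @return logical vector of length n
#' @export
point_in_polygon <- function(points, ring, eps = 1e-9) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  ring <- as.matrix(ring)
  if (nrow(unique(round(ring, 12))) < 3)
    pf_stop("geometry", "degenerate ring: fewer than 3 distinct vertices")
  px <- points[, 1]; py <- points[, 2]
  n <- length(px); m <- nrow(ring)
  inside <- logical(n); on_edge <- logical(n)
  j <- m
  for (i in seq_len(m)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      tt <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
      on_edge <- on_edge |
        ((px - (xi + tt * dx))^2 + (py - (yi + tt * dy))^2 <= eps * eps)
      crosses <- ((yi > py) != (yj > py)) &
        (px < dx * (py - yi) / dy + xi)
      crosses[is.na(crosses)] <- FALSE
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside | on_edge
}

#' @keywords internal
#' Remove points clashing with atoms. points: n x 3 (must be sorted by z for
#' the interval prefilter to be valid); atoms: m x 3; radii: length m
#' (vdW + probe). Returns logical keep-mask over points.
clash_free_mask <- function(points, atoms, radii) {
  n <- nrow(points)
  keep <- rep(TRUE, n)
  if (n == 0 || nrow(atoms) == 0) return(keep)
  pz <- points[, 3]
  for (k in seq_len(nrow(atoms))) {
    r <- radii[k]
    if (r <= 0) next
    lo <- findInterval(atoms[k, 3] - r, pz) + 1L
    hi <- findInterval(atoms[k, 3] + r, pz)
    if (hi < lo) next
    idx <- lo:hi
    idx <- idx[keep[idx]]
    if (!length(idx)) next
    d2 <- (points[idx, 1] - atoms[k, 1])^2 +
      (points[idx, 2] - atoms[k, 2])^2 +
      (points[idx, 3] - atoms[k, 3])^2
    keep[idx[d2 < r * r]] <- FALSE
  }
  keep
}

#' @keywords internal
receptor_selection <- function(x, exclude) {
  rec <- if (is.null(exclude)) x else select_atoms(x, exclude, invert = TRUE)
  rec <- heavy_atoms(rec)
  if (n_atoms(rec) == 0)
    pf_stop("input", "receptor selection is empty after exclusions")
  rec
}

#' Solvent-accessible ligand-binding cavity volume
#'
#' Implements the TM-bundle-bounded grid algorithm. The structure must already
#' be membrane-aligned (see [membrane_align()]). A regular 3D grid with the
#' configured spacing covers the receptor's bounding box, anchored at
#' multiples of the spacing so results are deterministic for a given input. A
#' grid point is retained iff
#' \enumerate{
#'   \item its z lies in the closed interval from the toggle-switch (6.48)
#'     Calpha z to the most extracellular TM Calpha z;
#'   \item it falls inside the lateral boundary polygon of its z level --
#'     the ring through the TM helix centers;
#'   \item no heavy atom of the receptor selection lies within
#'     (van der Waals radius + probe radius) of it.
#' }
#' The volume is the retained count times spacing cubed. Non-receptor atoms
#' (bound ligand, peptide agonist, G protein, antibody fragments, waters,
#' ions) must be excluded via `exclude`, otherwise they self-occlude the
#' pocket; the receptor conformation alone defines the cavity.
#'
#' @param x a membrane-aligned `pf_structure`
#' @param tm a [tm_annotation()]
#' @param bw a [bw_map()] resolving `"6.48"`
#' @param grid a [grid_config()]
#' @param exclude optional [atom_select()] matching the NON-receptor atoms
#' @return object of class `cavity_result`: `volume` (Angstrom^3, identically
#'   `n_points_retained * spacing^3`), `n_points_retained`, `points` (retained
#'   grid points, n x 3), `grid`, `bounds`, `polygons`, `provenance`
#' @export
compute_cavity_volume <- function(x, tm, bw, grid = grid_config(),
                                  exclude = NULL) {
  rec <- receptor_selection(x, exclude)
  bounds <- pocket_z_bounds(rec, tm, bw)
  s <- grid$spacing
  xyz <- coords(rec)
  lo <- floor(apply(xyz, 2, min) / s) * s
  hi <- apply(xyz, 2, max)
  zg <- seq(lo[3], hi[3] + s, by = s)
  zg <- zg[zg >= bounds$z_lower - 1e-9 & zg <= bounds$z_upper + 1e-9]
  if (length(zg) == 0) {
    return(empty_cavity_result(grid, bounds, x$label))
  }
  polys <- lateral_polygons(rec, tm, zg, window = grid$window,
                            order = grid$helix_order)
  gx <- seq(lo[1], hi[1] + s, by = s)
  gy <- seq(lo[2], hi[2] + s, by = s)
  xy <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  kept <- vector("list", length(zg))
  for (i in seq_along(zg)) {
    m <- point_in_polygon(xy, polys$vertices[[i]])
    if (any(m)) kept[[i]] <- cbind(xy[m, 1], xy[m, 2], zg[i])
  }
  pts <- do.call(rbind, kept)
  if (is.null(pts)) return(empty_cavity_result(grid, bounds, x$label, polys))
  # points are z-sorted by construction (levels ascending)
  radii <- vdw_radius(rec$atoms$elesy, grid$radius_set) + grid$probe_radius
  keep <- clash_free_mask(pts, xyz, radii)
  pts <- pts[keep, , drop = FALSE]
  colnames(pts) <- c("x", "y", "z")
  structure(list(volume = nrow(pts) * s^3,
                 n_points_retained = nrow(pts),
                 points = pts, grid = grid, bounds = bounds,
                 polygons = polys,
                 provenance = list(label = x$label,
                                   n_receptor_atoms = n_atoms(rec),
                                   excluded = !is.null(exclude))),
            class = "cavity_result")
}

#' @keywords internal
empty_cavity_result <- function(grid, bounds, label, polys = NULL) {
  structure(list(volume = 0, n_points_retained = 0L,
                 points = matrix(numeric(0), ncol = 3,
                                 dimnames = list(NULL, c("x", "y", "z"))),
                 grid = grid, bounds = bounds, polygons = polys,
                 provenance = list(label = label)),
            class = "cavity_result")
}

#' @export
print.cavity_result <- function(x, ...) {
  cat(sprintf(paste0("<cavity_result> %.1f A^3 (%d grid points at %.2f A",
                     " spacing, probe %.2f A)\n"),
              x$volume, x$n_points_retained, x$grid$spacing,
              x$grid$probe_radius))
  print(x$bounds)
  invisible(x)
}

#' Monte-Carlo cavity-volume oracle
#'
#' Independent check of the grid method: uniform rejection sampling in the
#' bounding box of the boundary region, applying the identical three retention
#' predicates (z bounds, lateral polygon of the nearest z level, atomic
#' clash). The volume estimate is the box volume times the acceptance
#' fraction; the standard error comes from the binomial variance.
#'
#' @inheritParams compute_cavity_volume
#' @param n_samples number of uniform samples (>= 1000)
#' @param seed integer seed; the sampler restores the caller's RNG state
#' @return list with `volume` (Angstrom^3), `se` (standard error, Angstrom^3),
#'   `n_samples`, `n_accepted`
#' @export
mc_cavity_volume <- function(x, tm, bw, grid = grid_config(), exclude = NULL,
                             n_samples = 200000L, seed = 1L) {
  if (n_samples < 1000) pf_stop("input", "n_samples must be >= 1000")
  rec <- receptor_selection(x, exclude)
  bounds <- pocket_z_bounds(rec, tm, bw)
  s <- grid$spacing
  xyz <- coords(rec)
  lo <- floor(apply(xyz, 2, min) / s) * s
  hi <- apply(xyz, 2, max)
  zg <- seq(lo[3], hi[3] + s, by = s)
  zg <- zg[zg >= bounds$z_lower - 1e-9 & zg <= bounds$z_upper + 1e-9]
  height <- bounds$z_upper - bounds$z_lower
  if (length(zg) == 0 || height <= 0)
    return(list(volume = 0, se = 0, n_samples = as.integer(n_samples),
                n_accepted = 0L))
  polys <- lateral_polygons(rec, tm, zg, window = grid$window,
                            order = grid$helix_order)
  vx <- do.call(rbind, polys$vertices)
  box_lo <- c(min(vx[, 1]), min(vx[, 2]), bounds$z_lower)
  box_hi <- c(max(vx[, 1]), max(vx[, 2]), bounds$z_upper)
  box_vol <- prod(box_hi - box_lo)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  p <- cbind(stats::runif(n_samples, box_lo[1], box_hi[1]),
             stats::runif(n_samples, box_lo[2], box_hi[2]),
             stats::runif(n_samples, box_lo[3], box_hi[3]))
  lev <- pmin(pmax(round((p[, 3] - zg[1]) / s) + 1L, 1L), length(zg))
  ok <- logical(n_samples)
  for (i in unique(lev)) {
    idx <- which(lev == i)
    ok[idx] <- point_in_polygon(p[idx, 1:2, drop = FALSE],
                                polys$vertices[[i]])
  }
  cand <- which(ok)
  if (length(cand)) {
    ord <- cand[order(p[cand, 3])]
    radii <- vdw_radius(rec$atoms$elesy, grid$radius_set) + grid$probe_radius
    keep <- clash_free_mask(p[ord, , drop = FALSE], xyz, radii)
    n_acc <- sum(keep)
  } else n_acc <- 0L
  frac <- n_acc / n_samples
  list(volume = box_vol * frac,
       se = box_vol * sqrt(frac * (1 - frac) / n_samples),
       n_samples = as.integer(n_samples), n_accepted = as.integer(n_acc))
}

#' Export retained grid points as PDB pseudo-atoms
#'
#' Writes the retained cavity grid as HETATM records (residue GRD, element
#' `"X"`, occupancy 1.00) for visual inspection alongside the receptor.
#'
#' @param result a `cavity_result`
#' @param file output PDB path
#' @return `file`, invisibly
#' @export
write_cavity_pdb <- function(result, file) {
  pts <- result$points
  if (nrow(pts) == 0) pf_stop("input", "no retained grid points to write")
  n <- nrow(pts)
  bio3d::write.pdb(pdb = NULL, file = file,
                   xyz = as.vector(t(pts)),
                   type = rep("HETATM", n),
                   resno = rep(1L, n), resid = rep("GRD", n),
                   eleno = seq_len(n), elety = rep("X", n),
                   chain = rep("G", n), o = rep(1, n), b = rep(0, n),
                   elesy = rep("X", n))
  invisible(file)
}
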