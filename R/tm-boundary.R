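#' Helix center at a z level
#'
#' The center of a TM helix at a discrete membrane-normal level z is the mean
#' (x, y) of the helix Calpha atoms whose z lies within `window` of the level.
#' If no Calpha falls inside the window (the level is beyond the helix end),
#' the (x, y) of the helix Calpha nearest in z is used instead -- the
#' nearest-point fallback. A z-tie in the fallback is broken toward the lower
#' residue number, deterministically.
#'
#' @param x a membrane-aligned `pf_structure`
#' @param tm a [tm_annotation()]
#' @param helix_id which helix
#' @param z level in Angstrom
#' @param window half-width of the z window in Angstrom (default 2.0)
#' @return numeric length-2 vector (x, y)
#' @export
helix_center_at_z <- function(x, tm, helix_id, z, window = 2.0) {
  h <- tm[tm$helix_id == helix_id, , drop = FALSE]
  if (nrow(h) != 1)
    pf_stop("annotation", "helix ", helix_id, " not in TM annotation")
  at <- ca_atoms(x)$atoms
  at <- at[at$chain == h$chain & at$resno >= h$start & at$resno <= h$end, ,
           drop = FALSE]
  if (nrow(at) == 0)
    pf_stop("annotation", "helix ", helix_id, " has no Calpha atoms")
  dz <- abs(at$z - z)
  inwin <- dz <= window + 1e-9
  if (any(inwin)) {
    c(mean(at$x[inwin]), mean(at$y[inwin]))
  } else {
    at <- at[order(dz, at$resno), , drop = FALSE]
    c(at$x[1], at$y[1])
  }
}

#' Lateral boundary polygons
#'
#' For each discrete z level, the helix centers are connected in bundle order
#' (TM1 -> TM2 -> ... -> TM7 -> TM1) into a closed ring: the cavity's lateral
#' boundary at that level. GPCR helices run sequentially around the bundle, so
#' index order is the default; `order = "angular"` instead sorts helices by
#' the polar angle of their mean (x, y). Rings may be non-convex; no hull or
#' smoothing is applied.
#'
#' @param x a membrane-aligned `pf_structure`
#' @param tm a [tm_annotation()] with >= 3 helices
#' @param z_levels numeric vector of z levels (Angstrom)
#' @param window passed to [helix_center_at_z()]
#' @param order `"index"` or `"angular"`
#' @return object of class `slab_polygons`: list with `z_levels`, `helix_ids`
#'   (bundle order), and `vertices` (list of n_helix x 2 matrices, one ring
#'   per level, rows in bundle order)
#' @export
lateral_polygons <- function(x, tm, z_levels, window = 2.0,
                             order = c("index", "angular")) {
  order <- match.arg(order)
  if (nrow(tm) < 3)
    pf_stop("geometry", "need >= 3 annotated helices to form a lateral boundary")
  ids <- sort(tm$helix_id)
  if (order == "angular") {
    ang <- vapply(ids, function(h) {
      hrow <- tm[tm$helix_id == h, ]
      at <- ca_atoms(x)$atoms
      at <- at[at$chain == hrow$chain & at$resno >= hrow$start &
                 at$resno <= hrow$end, , drop = FALSE]
      atan2(mean(at$y), mean(at$x))
    }, numeric(1))
    ids <- ids[base::order(ang)]
  }
  z_levels <- sort(as.numeric(z_levels))
  verts <- lapply(z_levels, function(z) {
    m <- t(vapply(ids, function(h) helix_center_at_z(x, tm, h, z, window),
                  numeric(2)))
    colnames(m) <- c("x", "y")
    m
  })
  structure(list(z_levels = z_levels, helix_ids = ids, vertices = verts),
            class = "slab_polygons")
}

#' @export
print.slab_polygons <- function(x, ...) {
  cat(sprintf("<slab_polygons> %d levels (z %.2f..%.2f), %d-gon rings\n",
              length(x$z_levels), min(x$z_levels), max(x$z_levels),
              length(x$helix_ids)))
  invisible(x)
}

#' Export slab polygons as a table
#' @param x a `slab_polygons`
#' @return data frame with columns z, helix_id, x, y
#' @export
polygons_table <- function(x) {
  do.call(rbind, lapply(seq_along(x$z_levels), function(i) {
    data.frame(z = x$z_levels[i], helix_id = x$helix_ids,
               x = x$vertices[[i]][, 1], y = x$vertices[[i]][, 2])
  }))
}

#' Signed polygon area (shoelace)
#' @param ring m x 2 matrix of vertices (open ring)
#' @return signed area; positive for counterclockwise orientation
#' @export
polygon_area <- function(ring) {
  xr <- ring[, 1]; yr <- ring[, 2]
  j <- c(nrow(ring), seq_len(nrow(ring) - 1))
  sum(xr[j] * yr - xr * yr[j]) / 2
}

#' Canonicalize ring orientation to counterclockwise
#' @param ring m x 2 matrix
#' @return the ring, reversed if it was clockwise
#' @export
canonicalize_ring <- function(ring) {
  if (polygon_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  else ring
}

#' Vertical bounds of the ligand-binding pocket
#'
#' The lower boundary is the z coordinate of the Calpha of the toggle-switch
#' residue (generic position 6.48); the upper boundary is the largest Calpha z
#' over all TM-annotated residues, i.e. the TM residues closest to the
#' extracellular region. Calpha atoms are used for both bounds.
#'
#' @param x a membrane-aligned `pf_structure`
#' @param tm a [tm_annotation()]
#' @param bw a [bw_map()] resolving code `"6.48"`
#' @return object of class `pocket_bounds`: list with `z_lower`, `z_upper`
#' @export
pocket_z_bounds <- function(x, tm, bw) {
  if (nrow(tm) == 0) pf_stop("annotation", "empty TM annotation")
  tog <- bw_residue(bw, "6.48")
  at <- ca_atoms(x)$atoms
  tca <- at[at$chain == tog$chain & at$resno == tog$resno, , drop = FALSE]
  if (nrow(tca) == 0)
    pf_stop("annotation", "toggle residue ", tog$chain, " ", tog$resno,
            " has no Calpha atom in the structure")
  z_lower <- tca$z[1]
  m <- tm_residue_mask(list(atoms = at), tm)
  if (!any(m)) pf_stop("annotation", "no Calpha atoms in TM-annotated ranges")
  z_upper <- max(at$z[m])
  if (z_upper <= z_lower)
    pf_stop("geometry", "toggle Calpha (z = ", round(z_lower, 2),
            ") is at or above the TM helix tops (z = ", round(z_upper, 2), ")")
  structure(list(z_lower = z_lower, z_upper = z_upper),
            class = "pocket_bounds")
}

#' @export
print.pocket_bounds <- function(x, ...) {
  cat(sprintf("<pocket_bounds> z in [%.2f, %.2f] A (height %.2f A)\n",
              x$z_lower, x$z_upper, x$z_upper - x$z_lower))
  invisible(x)
}
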