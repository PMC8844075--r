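# Independent oracles used to cross-check package computations. These are
# deliberately written without reference to the implementations they test.

# Winding-number point-in-polygon (vs the even-odd ray caster)
winding_inside <- function(point, ring) {
  n <- nrow(ring)
  total <- 0
  for (i in seq_len(n)) {
    a <- ring[i, ] - point
    b <- ring[if (i == n) 1 else i + 1, ] - point
    total <- total + atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
  }
  abs(total) > pi  # ~2*pi inside, ~0 outside
}

# Brute-force rigid superposition: minimize RMSD over ZYZ Euler angles after
# centering, by numerical optimization from several starts.
brute_force_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rotmat <- function(ang) {
    cz1 <- cos(ang[1]); sz1 <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz2 <- cos(ang[3]); sz2 <- sin(ang[3])
    Rz1 <- matrix(c(cz1, sz1, 0, -sz1, cz1, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz2 <- matrix(c(cz2, sz2, 0, -sz2, cz2, 0, 0, 0, 1), 3, 3)
    Rz2 %*% Ry %*% Rz1
  }
  obj <- function(ang) sqrt(mean(rowSums((P %*% t(rotmat(ang)) - Q)^2)))
  best <- Inf
  for (start in list(c(0, 0, 0), c(1, 1, 1), c(-2, 0.5, 2), c(3, 2, -1))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Brute-force minimum pairwise distance (double loop)
brute_min_distance <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

shoelace_area <- function(ring) {
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1))
  abs(sum(ring[j, 1] * ring[, 2] - ring[, 1] * ring[j, 2]) / 2)
}

# Voxel-surface discretization bound for grid-volume comparisons:
# spacing * (lateral boundary area + 2 * polygon area), from ground truth.
discretization_bound <- function(truth, spacing) {
  ring <- truth$axis_xy
  n <- nrow(ring)
  per <- sum(sqrt(rowSums((ring - ring[c(2:n, 1), , drop = FALSE])^2)))
  h <- truth$z_upper - truth$z_lower
  spacing * (per * h + 2 * truth$polygon_area)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Minimal hand-written PDB fixture writer (fixed-column format)
write_mini_pdb <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

pdb_atom_line <- function(serial, name, resn, chain, resi, x, y, z,
                          element, altloc = " ", type = "ATOM  ") {
  sprintf("%-6s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, altloc, resn, chain, resi, x, y, z, 1, 0,
          element)
}
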