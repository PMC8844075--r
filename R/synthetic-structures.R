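#' Rotation matrix about an axis
#' @param axis 3-vector (normalized internally)
#' @param angle_deg rotation angle, degrees, right-handed
#' @return 3x3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n == 0) pf_stop("input", "zero rotation axis")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Place an atom by internal coordinates (NeRF)
#'
#' Position `d` with bond length |c-d|, bond angle b-c-d, and dihedral
#' a-b-c-d (IUPAC sign convention, matching [dihedral_angle()]).
#'
#' @param a,b,c length-3 positions of the three reference atoms
#' @param length bond length in Angstrom
#' @param angle bond angle in degrees
#' @param dihedral dihedral in degrees
#' @return length-3 position
#' @export
place_dihedral_atom <- function(a, b, c, length, angle, dihedral) {
  ar <- angle * pi / 180; dr <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) pf_stop("geometry", "collinear reference atoms in NeRF placement")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-length * cos(ar),
          length * sin(ar) * cos(dr),
          length * sin(ar) * sin(dr))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Ideal alpha-helix with minimal pseudo-residues
#'
#' Calpha k sits at angle `phase + k * twist` and height `k * rise` around the
#' axis, at radius `ca_radius`. Each residue carries N, CA, C, CB and a CG
#' pseudo-atom -- enough for chi1 dihedrals and contact tests without a
#' rotamer library. Defaults are textbook alpha-helix constants (1.5 A rise,
#' 100 deg twist, 2.3 A Calpha radius).
#'
#' @param n_res number of residues (>= 4)
#' @param origin axis point of residue 0 (length-3)
#' @param direction axis direction (normalized internally)
#' @param rise rise per residue, Angstrom
#' @param twist twist per residue, degrees
#' @param ca_radius Calpha helix radius, Angstrom; 0 gives a line of Calpha
#'   atoms on the axis (and suppresses sidechain pseudo-atoms)
#' @param phase initial phase angle, degrees
#' @param chain,start_resno,resid atom bookkeeping
#' @param atoms `"full"` (N, CA, C, CB, CG) or `"ca"` (Calpha trace only)
#' @return a [pf_structure()]
#' @export
make_ideal_helix <- function(n_res, origin = c(0, 0, 0),
                             direction = c(0, 0, 1), rise = 1.5, twist = 100,
                             ca_radius = 2.3, phase = 0, chain = "A",
                             start_resno = 1L, resid = "LEU",
                             atoms = c("full", "ca")) {
  atoms <- match.arg(atoms)
  if (n_res < 4) pf_stop("input", "need n_res >= 4, got ", n_res)
  if (rise <= 0 || ca_radius < 0)
    pf_stop("input", "rise must be > 0 and ca_radius >= 0")
  dir <- direction / sqrt(sum(direction^2))
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * dir) * dir; u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  if (ca_radius == 0) atoms <- "ca"
  rows <- vector("list", n_res)
  for (k in seq_len(n_res) - 1L) {
    ang <- (phase + k * twist) * pi / 180
    radial <- cos(ang) * u + sin(ang) * v
    axis_pt <- origin + k * rise * dir
    ca <- axis_pt + ca_radius * radial
    resno <- start_resno + k
    rec <- list(c("CA", "C", ca))
    if (atoms == "full") {
      ang_n <- ang - 27 * pi / 180
      ang_c <- ang + 27 * pi / 180
      nn <- origin + (k * rise - 0.6) * dir +
        max(ca_radius - 0.7, 0.5) * (cos(ang_n) * u + sin(ang_n) * v)
      cc <- origin + (k * rise + 0.6) * dir +
        max(ca_radius - 0.7, 0.5) * (cos(ang_c) * u + sin(ang_c) * v)
      cb <- ca + 1.53 * radial
      cg <- cb + 1.52 * (0.5 * radial + sqrt(0.75) * dir)
      rec <- list(c("N", "N", nn), c("CA", "C", ca), c("C", "C", cc),
                  c("CB", "C", cb), c("CG", "C", cg))
    }
    rows[[k + 1L]] <- do.call(rbind, lapply(rec, function(r) {
      data.frame(chain = chain, resno = resno, insert = "", resid = resid,
                 elety = r[1], elesy = r[2], alt = "", het = FALSE,
                 x = as.numeric(r[3]), y = as.numeric(r[4]),
                 z = as.numeric(r[5]), stringsAsFactors = FALSE)
    }))
  }
  pf_structure(do.call(rbind, rows), label = "ideal-helix")
}

#' Synthetic TM-bundle specification
#'
#' Defines the study conditions for the synthetic generator: an idealized
#' 7-helix transmembrane bundle with helices at equal angles on a circle,
#' alternating N-to-C direction as in a real TM bundle, a designated
#' toggle-switch residue on helix 6 labeled with generic code 6.48, and
#' optionally a short peptide probe inserted from the extracellular side.
#'
#' @param n_helices number of helices (default 7)
#' @param bundle_radius circle radius for the helix axes, Angstrom
#' @param helix_length residues per helix
#' @param rise,twist,ca_radius ideal-helix constants (see
#'   [make_ideal_helix()])
#' @param tilt per-helix tilt in degrees (scalar recycled), applied in the
#'   radial plane about the helix midpoint
#' @param toggle_helix helix carrying the toggle residue (default 6)
#' @param toggle_z target z for the toggle Calpha; the residue with the
#'   nearest Calpha z is designated (default -2, mimicking a mid-membrane
#'   toggle below an extracellular pocket)
#' @param peptide_depth if non-NULL, add a peptide chain "P" whose lowest
#'   heavy atom sits exactly this many Angstrom below the helix tops
#' @param seed integer recorded in the spec (generation is deterministic)
#' @return object of class `bundle_spec`
#' @export
bundle_spec <- function(n_helices = 7L, bundle_radius = 12, helix_length = 22L,
                        rise = 1.5, twist = 100, ca_radius = 2.3, tilt = 0,
                        toggle_helix = NULL, toggle_z = -2.0,
                        peptide_depth = NULL, seed = 1L) {
  if (n_helices < 3) pf_stop("spec", "need >= 3 helices")
  if (is.null(toggle_helix)) toggle_helix <- min(6L, n_helices)
  if (bundle_radius <= 0 || helix_length < 4 || rise <= 0 || ca_radius < 0)
    pf_stop("spec", "all bundle dimensions must be positive (helix_length >= 4)")
  if (toggle_helix < 1 || toggle_helix > n_helices)
    pf_stop("spec", "toggle_helix outside 1..n_helices")
  min_sep <- 2 * bundle_radius * sin(pi / n_helices)
  if (min_sep < 2 * ca_radius + 1)
    pf_stop("spec", "helices overlap: bundle_radius too small for ca_radius")
  tilt <- rep_len(tilt, n_helices)
  structure(list(n_helices = as.integer(n_helices),
                 bundle_radius = bundle_radius,
                 helix_length = as.integer(helix_length), rise = rise,
                 twist = twist, ca_radius = ca_radius, tilt = tilt,
                 toggle_helix = as.integer(toggle_helix), toggle_z = toggle_z,
                 peptide_depth = peptide_depth, seed = as.integer(seed)),
            class = "bundle_spec")
}

#' Generate a synthetic TM bundle with ground truth
#'
#' Builds the bundle described by a [bundle_spec()], together with its TM
#' annotation, generic-numbering map (toggle residue labeled `"6.48"`, other
#' positions numbered relative to it / to the helix midpoint), and a
#' `GroundTruth` record holding quantities recomputed analytically and
#' independently of the analysis pipeline: the polygon through the true helix
#' axes, its shoelace area, the vertical pocket bounds, and the resulting
#' empty-interior prism volume.
#'
#' @param spec a [bundle_spec()]
#' @return list of class `pf_bundle` with elements `structure`, `tm`, `bw`,
#'   `truth`
#' @export
make_bundle <- function(spec) {
  if (!inherits(spec, "bundle_spec")) spec <- do.call(bundle_spec, spec)
  n <- spec$n_helices
  len <- spec$helix_length
  span <- (len - 1L) * spec$rise
  helices <- vector("list", n)
  tmrows <- vector("list", n)
  axis_xy <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  for (h in seq_len(n)) {
    th <- 2 * pi * (h - 1) / n
    center <- c(spec$bundle_radius * cos(th), spec$bundle_radius * sin(th), 0)
    axis_xy[h, ] <- center[1:2]
    up <- (h %% 2L) == 1L
    dir <- if (up) c(0, 0, 1) else c(0, 0, -1)
    origin <- center + c(0, 0, if (up) -span / 2 else span / 2)
    hx <- make_ideal_helix(len, origin = origin, direction = dir,
                           rise = spec$rise, twist = spec$twist,
                           ca_radius = spec$ca_radius,
                           phase = 137 * h, chain = "R",
                           start_resno = 100L * h + 1L,
                           atoms = if (spec$ca_radius == 0) "ca" else "full")
    if (spec$tilt[h] != 0) {
      tangent <- c(-sin(th), cos(th), 0)
      R <- rotation_about_axis(tangent, spec$tilt[h])
      xyz <- sweep(coords(hx), 2, center)
      xyz <- sweep(xyz %*% t(R), 2, center, "+")
      hx$atoms$x <- xyz[, 1]; hx$atoms$y <- xyz[, 2]; hx$atoms$z <- xyz[, 3]
    }
    helices[[h]] <- hx$atoms
    tmrows[[h]] <- data.frame(helix_id = h, chain = "R",
                              start = 100L * h + 1L, end = 100L * h + len)
  }
  atoms <- do.call(rbind, helices)
  # toggle residue: Calpha nearest the target z on the toggle helix
  tg <- spec$toggle_helix
  ca <- atoms[atoms$elety == "CA" &
                atoms$resno > 100L * tg & atoms$resno <= 100L * tg + len, ]
  dz <- abs(ca$z - spec$toggle_z)
  toggle_resno <- ca$resno[order(dz, ca$resno)][1]
  toggle_ca_z <- ca$z[ca$resno == toggle_resno]
  # generic numbering anchored so the toggle is x.48, midpoints .50 elsewhere
  # the toggle helix is numbered with generic prefix 6 so its toggle residue
  # always carries the canonical code 6.48 (bundles with < 6 helices keep
  # injectivity because no other helix uses prefix 6)
  if (tg != 6L && n >= 6L)
    pf_stop("spec", "toggle_helix must be 6 in bundles with >= 6 helices")
  bwrows <- lapply(seq_len(n), function(h) {
    resnos <- 100L * h + seq_len(len)
    anchor_idx <- if (h == tg) (toggle_resno - 100L * h) else ceiling(len / 2)
    anchor_pos <- if (h == tg) 48L else 50L
    prefix <- if (h == tg) 6L else h
    data.frame(chain = "R", resno = resnos,
               bw = sprintf("%d.%d", prefix,
                            anchor_pos + seq_len(len) - anchor_idx),
               stringsAsFactors = FALSE)
  })
  peptide_truth <- NULL
  ca_all <- atoms[atoms$elety == "CA", ]
  z_top <- max(ca_all$z)
  if (!is.null(spec$peptide_depth)) {
    depth <- spec$peptide_depth
    m <- max(2L, ceiling(depth / 3) + 1L)
    zp <- z_top - depth + 3 * (seq_len(m) - 1)
    pep <- data.frame(chain = "P", resno = seq_len(m), insert = "",
                      resid = "GLY", elety = "CA", elesy = "C", alt = "",
                      het = FALSE, x = 0, y = 0, z = zp,
                      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, pep)
    peptide_truth <- list(depth = depth, n_res = m)
  }
  tm <- tm_annotation(do.call(rbind, tmrows))
  bw <- bw_map(do.call(rbind, bwrows))
  area <- abs(polygon_area(axis_xy))
  truth <- list(
    spec = spec,
    axis_xy = axis_xy,
    polygon_area = area,
    z_lower = toggle_ca_z, z_upper = z_top,
    prism_volume = area * (z_top - toggle_ca_z),
    toggle = list(chain = "R", resno = toggle_resno, z = toggle_ca_z),
    n_residues = n * len + if (is.null(peptide_truth)) 0L else peptide_truth$n_res,
    n_bundle_atoms = sum(atoms$chain == "R"),
    peptide = peptide_truth,
    perturbations = list()
  )
  structure(list(structure = pf_structure(atoms, label = "synthetic-bundle"),
                 tm = tm, bw = bw, truth = truth),
            class = "pf_bundle")
}

#' @export
print.pf_bundle <- function(x, ...) {
  cat(sprintf(paste0("<pf_bundle> %d helices, radius %.1f A, %d atoms; ",
                     "analytic prism volume %.0f A^3\n"),
              x$truth$spec$n_helices, x$truth$spec$bundle_radius,
              n_atoms(x$structure), x$truth$prism_volume))
  invisible(x)
}

#' Perturb a synthetic bundle into a paired state
#'
#' Applies stated rigid displacements and/or tilts to whole helices and chi1
#' reassignments to individual residues, recording every applied perturbation
#' in the ground truth for parameter-recovery tests. An empty perturbation
#' returns an identical structure.
#'
#' @param bundle a `pf_bundle` from [make_bundle()]
#' @param displace data frame with columns `helix_id, dx, dy, dz` and
#'   optionally `mode` (`"rigid"` moves the whole helix; `"tip"` ramps the
#'   displacement linearly from 0 at the intracellular end to the full vector
#'   at the extracellular tip residue)
#' @param tilt data frame with columns `helix_id, angle_deg`; rotates the
#'   helix about the tangential axis through its Calpha centroid
#' @param chi1 data frame with columns `chain, resno, chi1_deg`; repositions
#'   the CG pseudo-atom to the requested chi1 dihedral
#' @return a `pf_bundle` with perturbed structure and updated truth
#' @export
perturb_bundle <- function(bundle, displace = NULL, tilt = NULL, chi1 = NULL) {
  at <- bundle$structure$atoms
  tm <- bundle$tm
  helix_rows <- function(h) {
    hr <- tm[tm$helix_id == h, , drop = FALSE]
    if (nrow(hr) != 1) pf_stop("input", "unknown helix id: ", h)
    which(at$chain == hr$chain & at$resno >= hr$start & at$resno <= hr$end)
  }
  if (!is.null(displace)) {
    for (i in seq_len(nrow(displace))) {
      rows <- helix_rows(displace$helix_id[i])
      v <- c(displace$dx[i], displace$dy[i], displace$dz[i])
      mode <- if ("mode" %in% names(displace)) displace$mode[i] else "rigid"
      if (mode == "rigid") {
        at$x[rows] <- at$x[rows] + v[1]
        at$y[rows] <- at$y[rows] + v[2]
        at$z[rows] <- at$z[rows] + v[3]
      } else if (mode == "tip") {
        sub <- at[rows, ]
        caz <- tapply(sub$z[sub$elety == "CA"], sub$resno[sub$elety == "CA"],
                      identity)
        resnos <- as.integer(names(caz))
        w <- rank(unlist(caz)) - 1
        w <- w / max(w)
        wmap <- stats::setNames(w, resnos)
        wt <- wmap[as.character(at$resno[rows])]
        at$x[rows] <- at$x[rows] + wt * v[1]
        at$y[rows] <- at$y[rows] + wt * v[2]
        at$z[rows] <- at$z[rows] + wt * v[3]
      } else pf_stop("input", "unknown displacement mode: ", mode)
    }
  }
  if (!is.null(tilt)) {
    for (i in seq_len(nrow(tilt))) {
      h <- tilt$helix_id[i]
      rows <- helix_rows(h)
      th <- 2 * pi * (h - 1) / bundle$truth$spec$n_helices
      tangent <- c(-sin(th), cos(th), 0)
      R <- rotation_about_axis(tangent, tilt$angle_deg[i])
      carows <- rows[at$elety[rows] == "CA"]
      ctr <- c(mean(at$x[carows]), mean(at$y[carows]), mean(at$z[carows]))
      xyz <- cbind(at$x[rows], at$y[rows], at$z[rows])
      xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
      at$x[rows] <- xyz[, 1]; at$y[rows] <- xyz[, 2]; at$z[rows] <- xyz[, 3]
    }
  }
  if (!is.null(chi1)) {
    for (i in seq_len(nrow(chi1))) {
      rr <- which(at$chain == chi1$chain[i] & at$resno == chi1$resno[i])
      if (!length(rr)) pf_stop("input", "unknown residue in chi1 table: ",
                               chi1$chain[i], " ", chi1$resno[i])
      gname <- gamma_atom_name(at$resid[rr[1]])
      gi <- rr[at$elety[rr] == gname]
      ni <- rr[at$elety[rr] == "N"]
      cai <- rr[at$elety[rr] == "CA"]
      cbi <- rr[at$elety[rr] == "CB"]
      if (!length(gi) || !length(ni) || !length(cai) || !length(cbi))
        pf_stop("input", "residue lacks chi1 atoms: ", chi1$chain[i], " ",
                chi1$resno[i])
      p <- function(j) c(at$x[j], at$y[j], at$z[j])
      blen <- sqrt(sum((p(gi) - p(cbi))^2))
      v1 <- p(cai) - p(cbi); v2 <- p(gi) - p(cbi)
      bang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      newg <- place_dihedral_atom(p(ni), p(cai), p(cbi), blen, bang,
                                  chi1$chi1_deg[i])
      at$x[gi] <- newg[1]; at$y[gi] <- newg[2]; at$z[gi] <- newg[3]
    }
  }
  out <- bundle
  out$structure$atoms <- at
  out$structure$label <- paste0(bundle$structure$label, "-perturbed")
  out$truth$perturbations <- list(displace = displace, tilt = tilt,
                                  chi1 = chi1)
  out
}

#' Randomized bundle specification for validation sweeps
#'
#' Samples realistic bundle conditions (radius 10.5-14 A, 18-26 residues per
#' helix, per-helix tilts up to 8 degrees) deterministically from a seed, for
#' grid-vs-Monte-Carlo agreement checks over varied geometries.
#'
#' @param seed integer seed
#' @return a [bundle_spec()]
#' @export
random_bundle_spec <- function(seed) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  bundle_spec(n_helices = 7L,
              bundle_radius = stats::runif(1, 10.5, 14),
              helix_length = sample(18:26, 1),
              tilt = stats::runif(7, 0, 8),
              toggle_z = stats::runif(1, -4, 0),
              seed = seed)
}

#' The analytic-prism preset
#'
#' A fixture for analytic validation of the grid volume: line helices
#' (ca_radius 0, atoms exactly on the lateral polygon's vertex columns) on a
#' wide 24 A circle, so the interior is an exact heptagonal prism between the
#' toggle Calpha z and the helix tops, with only a ~1% vertex-column clash
#' sliver. Ground truth is the shoelace area times the height.
#'
#' @param bundle_radius circle radius (default 24)
#' @param helix_length residues per helix (default 22)
#' @return a `pf_bundle`
#' @export
prism_bundle <- function(bundle_radius = 24, helix_length = 22L) {
  make_bundle(bundle_spec(bundle_radius = bundle_radius,
                          helix_length = helix_length, ca_radius = 0))
}
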