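test_that("self-comparison gives all-zero displacements", {
  b <- make_bundle(bundle_spec())
  d <- ca_displacements(b$structure, b$structure, align = b$tm)
  expect_true(all(d$displacement < 1e-9))
  expect_equal(nrow(d), b$truth$n_residues)
})

test_that("an applied 2.2 A tip displacement is recovered", {
  b0 <- make_bundle(bundle_spec())
  dir <- c(cos(2 * pi * 5 / 7), sin(2 * pi * 5 / 7), 0)  # outward, helix 6
  b1 <- perturb_bundle(b0, displace = data.frame(
    helix_id = 6, dx = 2.2 * dir[1], dy = 2.2 * dir[2], dz = 0,
    mode = "tip"))
  d <- ca_displacements(b0$structure, b1$structure,
                        align = b0$tm[b0$tm$helix_id != 6, ])
  h6 <- b0$tm[b0$tm$helix_id == 6, ]
  tip <- d[d$resno >= h6$start & d$resno <= h6$end, ]
  expect_equal(max(tip$displacement), 2.2, tolerance = 0.05 / 2.2)
  # residues on unperturbed helices stay put
  others <- d[d$resno < h6$start | d$resno > h6$end, ]
  expect_lt(max(others$displacement), 1e-6)
  # swapped arguments give identical unsigned metrics
  d_rev <- ca_displacements(b1$structure, b0$structure,
                            align = b0$tm[b0$tm$helix_id != 6, ])
  expect_equal(d_rev$displacement, d$displacement, tolerance = 1e-9)
})

test_that("disjoint structures raise a pairing error", {
  b <- make_bundle(bundle_spec())
  other <- b$structure
  other$atoms$chain <- "Z"
  expect_error(ca_displacements(b$structure, other),
               class = "pf_pairing_error")
})

test_that("helix axes are recovered for ideal, rotated and collinear cases", {
  h <- make_ideal_helix(20, origin = c(0, 0, 0))
  ca <- coords(select_atoms(h, atom_select(elety = "CA")))
  ax <- helix_axis(ca)
  expect_lt(tilt_angle(ax$axis, c(0, 0, 1)), 1)
  R8 <- rotation_about_axis(c(1, 0, 0), 8)
  ax8 <- helix_axis(ca %*% t(R8))
  expect_equal(tilt_angle(ax$axis, ax8$axis), 8, tolerance = 0.2 / 8)
  line <- cbind(1:5 * 1.0, 0, 0)
  expect_equal(helix_axis(line)$axis, c(1, 0, 0))
  expect_error(helix_axis(line[1:4, ]), class = "pf_input_error")
})

test_that("tilt angles follow the unsigned acute convention", {
  expect_equal(tilt_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(tilt_angle(c(0, 0, 1), c(0, 0, -1)), 0)
  a8 <- c(sin(8 * pi / 180), 0, cos(8 * pi / 180))
  expect_equal(tilt_angle(c(0, 0, 1), a8), 8, tolerance = 1e-6)
  expect_equal(tilt_angle(a8, c(0, 0, 1)), tilt_angle(c(0, 0, 1), a8))
  expect_error(tilt_angle(c(0, 0, 0), c(0, 0, 1)), class = "pf_input_error")
  # bounded by [0, 90] on random pairs
  set.seed(2)
  for (i in 1:25) {
    t <- tilt_angle(rnorm(3), rnorm(3))
    expect_gte(t, 0); expect_lte(t, 90)
  }
})

test_that("chi1 dihedrals and classes follow the canonical wells", {
  build_res <- function(chi1) {
    n <- c(0, 1.4, 0); caa <- c(0, 0, 0); cb <- c(1.5, 0, 0)
    cg <- place_dihedral_atom(n, caa, cb, 1.52, 114, chi1)
    pf_structure(data.frame(
      chain = "A", resno = 1, insert = "", resid = "LEU",
      elety = c("N", "CA", "CB", "CG"), elesy = c("N", "C", "C", "C"),
      alt = "", het = FALSE,
      x = c(n[1], caa[1], cb[1], cg[1]), y = c(n[2], caa[2], cb[2], cg[2]),
      z = c(n[3], caa[3], cb[3], cg[3])))
  }
  r <- chi1_rotamer(build_res(180), "A", 1)
  expect_equal(r$chi1, 180, tolerance = 1e-6)
  expect_equal(r$class, "trans")
  r <- chi1_rotamer(build_res(-65), "A", 1)
  expect_equal(r$chi1, -65, tolerance = 1e-6)
  expect_equal(r$class, "gauche+")
  r <- chi1_rotamer(build_res(65), "A", 1)
  expect_equal(r$class, "gauche-")
  # cross-check the dihedral against bio3d
  s <- build_res(-135)
  expect_equal(chi1_rotamer(s, "A", 1)$chi1,
               bio3d::torsion.xyz(as.vector(t(coords(s))), atm.inc = 4),
               tolerance = 1e-6, ignore_attr = TRUE)
  # glycine and missing atoms are undefined, not errors
  g <- build_res(180); g$atoms$resid <- "GLY"
  expect_equal(chi1_rotamer(g, "A", 1)$class, "undefined")
  m <- build_res(180); m$atoms <- m$atoms[m$atoms$elety != "CG", ]
  expect_warning(r <- chi1_rotamer(m, "A", 1), "undefined")
  expect_equal(r$class, "undefined")
})

test_that("chi1 reassignment in the generator is recovered exactly", {
  b0 <- make_bundle(bundle_spec())
  targets <- data.frame(chain = "R", resno = c(305, 412, 620),
                        chi1_deg = c(-65, 180, 60))
  b1 <- perturb_bundle(b0, chi1 = targets)
  for (i in seq_len(nrow(targets))) {
    r <- chi1_rotamer(b1$structure, "R", targets$resno[i])
    expect_equal(r$chi1, targets$chi1_deg[i], tolerance = 1e-6)
  }
})

test_that("contact detection applies the per-kind distance cutoffs", {
  mk <- function(df) {
    df$insert <- ""; df$alt <- ""; df$het <- FALSE
    pf_structure(df)
  }
  # isolated pair far apart: nothing
  a <- mk(data.frame(chain = "A", resno = 1, resid = "SER", elety = "OG",
                     elesy = "O", x = 0, y = 0, z = 0))
  b <- mk(data.frame(chain = "B", resno = 1, resid = "SER", elety = "OG",
                     elesy = "O", x = 10, y = 0, z = 0))
  expect_equal(nrow(detect_contacts(a, b)), 0)
  # N...O at 3.0 A: polar (and vdw)
  b2 <- mk(data.frame(chain = "B", resno = 1, resid = "GLN", elety = "NE2",
                      elesy = "N", x = 3, y = 0, z = 0))
  ct <- detect_contacts(a, b2)
  expect_setequal(ct$kind, c("polar", "vdw"))
  expect_equal(ct$distance[ct$kind == "polar"], 3.0, tolerance = 1e-9)
  # Arg guanidinium vs Asp carboxylate at 3.8 A: salt bridge
  arg <- mk(data.frame(chain = "A", resno = 5, resid = "ARG",
                       elety = c("NE", "NH1", "CZ"), elesy = c("N", "N", "C"),
                       x = c(0, 0.8, 0.4), y = c(0, 0, 1), z = 0))
  asp <- mk(data.frame(chain = "B", resno = 9, resid = "ASP",
                       elety = c("OD1", "OD2"), elesy = c("O", "O"),
                       x = c(3.8, 4.6), y = 0, z = 0))
  ct <- detect_contacts(arg, asp)
  sb <- ct[ct$kind == "salt_bridge", ]
  expect_gt(nrow(sb), 0)
  expect_true(any(abs(sb$distance - 3.8) < 1e-9))  # NE...OD1 pair
  expect_true(all(sb$distance <= 4.0))
  # Lys NZ 5 A from a Phe ring centroid: pi-cation
  phe <- mk(data.frame(chain = "B", resno = 3, resid = "PHE",
                       elety = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                       elesy = "C",
                       x = 1.4 * cos(seq(0, 5) * pi / 3),
                       y = 1.4 * sin(seq(0, 5) * pi / 3), z = 0))
  lys <- mk(data.frame(chain = "A", resno = 7, resid = "LYS", elety = "NZ",
                       elesy = "N", x = 0, y = 0, z = 5))
  ct <- detect_contacts(lys, phe)
  pc <- ct[ct$kind == "pi_cation", ]
  expect_equal(nrow(pc), 1)
  expect_equal(pc$distance, 5.0, tolerance = 1e-9)
  # permutation invariance
  perm <- phe; set.seed(4)
  perm$atoms <- perm$atoms[sample(nrow(perm$atoms)), ]
  ct2 <- detect_contacts(lys, perm)
  expect_equal(ct2, ct[ct$kind %in% ct2$kind, ], ignore_attr = TRUE)
})

test_that("minimum distances match a brute-force double loop", {
  expect_equal(min_distance(
    pf_structure(data.frame(chain = "A", resno = 1, insert = "",
                            resid = "GLY", elety = "CA", elesy = "C",
                            alt = "", het = FALSE, x = 0, y = 0, z = 0)),
    pf_structure(data.frame(chain = "B", resno = 1, insert = "",
                            resid = "GLY", elety = "CA", elesy = "C",
                            alt = "", het = FALSE, x = 3, y = 4, z = 0))), 5)
  set.seed(8)
  mk_rand <- function(n, chain) {
    pf_structure(data.frame(chain = chain, resno = seq_len(n), insert = "",
                            resid = "GLY", elety = "CA", elesy = "C",
                            alt = "", het = FALSE,
                            x = runif(n, 0, 30), y = runif(n, 0, 30),
                            z = runif(n, 0, 30)))
  }
  A <- mk_rand(120, "A"); B <- mk_rand(150, "B")
  expect_equal(min_distance(A, B), brute_min_distance(coords(A), coords(B)),
               tolerance = 1e-12)
  expect_equal(min_distance(A, B), min_distance(B, A))
  # invariant under a common rigid transform
  set.seed(12)
  tf <- structure(list(rotation = random_rotation(), translation = rnorm(3),
                       rmsd = NULL), class = "rigid_transform")
  expect_equal(min_distance(apply_transform(A, tf), apply_transform(B, tf)),
               min_distance(A, B), tolerance = 1e-9)
})

test_that("insertion depth measures down from the upper pocket boundary", {
  b <- make_bundle(bundle_spec(peptide_depth = 11))
  bounds <- pocket_z_bounds(
    select_atoms(b$structure, atom_select(chain = "P"), invert = TRUE),
    b$tm, b$bw)
  pep <- select_atoms(b$structure, atom_select(chain = "P"))
  expect_equal(insertion_depth(pep, bounds), 11, tolerance = 1e-9)
  # an atom exactly at z_upper has depth 0; above it is clamped to 0
  at_top <- pep
  at_top$atoms <- at_top$atoms[1, ]
  at_top$atoms$z <- bounds$z_upper
  expect_equal(insertion_depth(at_top, bounds), 0)
  at_top$atoms$z <- bounds$z_upper + 4
  expect_equal(insertion_depth(at_top, bounds), 0)
  expect_error(insertion_depth(select_atoms(pep, atom_select(chain = "Q")),
                               bounds),
               class = "pf_input_error")
})

test_that("compare_states aggregates displacement, tilt and rotamer changes", {
  b0 <- make_bundle(bundle_spec())
  r0 <- chi1_rotamer(b0$structure, "R", 210)
  new_chi1 <- if (r0$class == "trans") -65 else 175  # force a class change
  b1 <- perturb_bundle(
    b0,
    displace = data.frame(helix_id = 3, dx = 1.0, dy = 0, dz = 0,
                          mode = "rigid"),
    tilt = data.frame(helix_id = 5, angle_deg = 6),
    chi1 = data.frame(chain = "R", resno = 210, chi1_deg = new_chi1))
  cmp <- compare_states(b0$structure, b1$structure, b0$tm,
                        align = b0$tm[!b0$tm$helix_id %in% c(3, 5), ])
  expect_equal(cmp$tilts$tilt_deg[cmp$tilts$helix_id == 5], 6,
               tolerance = 0.05)
  expect_lt(max(cmp$tilts$tilt_deg[!cmp$tilts$helix_id %in% c(3, 5)]), 0.1)
  h3 <- cmp$displacements$resno %in% 301:322
  expect_equal(mean(cmp$displacements$displacement[h3]), 1.0,
               tolerance = 1e-6)
  rc <- cmp$rotamer_changes
  expect_true(210 %in% rc$resno[rc$changed])
})
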