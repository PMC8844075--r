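#' Dihedral angle of four points
#'
#' IUPAC convention: cis = 0 degrees, right-handed rotation positive, result
#' in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors
#' @return angle in degrees
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Per-residue Calpha displacements between two states
#'
#' Structure `b` is superposed onto `a` using the Calpha atoms matched by
#' `align` (Kabsch, proper rotation); the reported displacement is then the
#' Calpha distance for every residue matched by `measure` and present in
#' both structures. Residues pair on `(chain, resno, insert)`.
#'
#' @param a,b `pf_structure`s (e.g. inactive and active states)
#' @param align [atom_select()] or [tm_annotation()] choosing alignment
#'   residues; `NULL` uses all common Calpha
#' @param measure [atom_select()] choosing measured residues; `NULL` measures
#'   all common residues
#' @return data frame with columns chain, resno, insert, displacement (A),
#'   ordered by (chain, resno)
#' @export
ca_displacements <- function(a, b, align = NULL, measure = NULL) {
  ca_a <- ca_atoms(a)$atoms
  ca_b <- ca_atoms(b)$atoms
  restrict <- function(at, sel) {
    if (is.null(sel)) return(at)
    if (inherits(sel, "tm_annotation"))
      return(at[tm_residue_mask(list(atoms = at), sel), , drop = FALSE])
    at[selector_mask(list(atoms = at), sel), , drop = FALSE]
  }
  al_a <- restrict(ca_a, align); al_b <- restrict(ca_b, align)
  key <- function(d) paste(d$chain, d$resno, d$insert)
  common_al <- intersect(key(al_a), key(al_b))
  if (length(common_al) < 3)
    pf_stop("pairing", "only ", length(common_al),
            " common alignment Calpha atoms")
  ia <- match(common_al, key(al_a)); ib <- match(common_al, key(al_b))
  tf <- kabsch(as.matrix(al_b[ib, c("x", "y", "z")]),
               as.matrix(al_a[ia, c("x", "y", "z")]))
  ca_b[, c("x", "y", "z")] <- apply_transform(
    as.matrix(ca_b[, c("x", "y", "z")]), tf)
  me_a <- restrict(ca_a, measure); me_b <- restrict(ca_b, measure)
  common <- intersect(key(me_a), key(me_b))
  if (length(common) == 0)
    pf_stop("pairing", "no common residues to measure")
  ia <- match(common, key(me_a)); ib <- match(common, key(me_b))
  d <- sqrt(rowSums((as.matrix(me_a[ia, c("x", "y", "z")]) -
                       as.matrix(me_b[ib, c("x", "y", "z")]))^2))
  out <- data.frame(chain = me_a$chain[ia], resno = me_a$resno[ia],
                    insert = me_a$insert[ia], displacement = d,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno, out$insert), ]
  rownames(out) <- NULL
  out
}

#' Principal axis of a helix
#'
#' Largest-variance direction of the centered Calpha coordinates; the sign is
#' chosen to point toward increasing residue order (first to last point).
#'
#' @param xyz ordered n x 3 Calpha coordinate matrix, n >= 5
#' @return list with `axis` (unit 3-vector) and `centroid`
#' @export
helix_axis <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 5)
    pf_stop("input", "helix_axis needs >= 5 Calpha atoms, got ", nrow(xyz))
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  ax <- sv$v[, 1]
  if (sum(ax * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) ax <- -ax
  list(axis = ax / sqrt(sum(ax^2)), centroid = ctr)
}

#' Unsigned tilt angle between two axes
#'
#' `acos(|a . b|)` in degrees: the acute angle between undirected axes,
#' symmetric in its arguments and bounded by [0, 90].
#'
#' @param a,b 3-vectors (need not be exactly unit length)
#' @return angle in degrees
#' @export
tilt_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) pf_stop("input", "zero-length axis vector")
  acos(min(1, abs(sum(a * b)) / (na * nb))) * 180 / pi
}

#' @keywords internal
gamma_atom_name <- function(resid) {
  switch(resid,
         SER = "OG", THR = "OG1", CYS = "SG", VAL = "CG1", ILE = "CG1",
         "CG")
}

#' chi1 sidechain rotamer
#'
#' chi1 is the N-CA-CB-gamma dihedral (IUPAC sign convention). Classes by
#' nearest canonical well: trans (180 +/- 60), gauche+ (-60 +/- 60), gauche-
#' (+60 +/- 60). Gly and Ala have no chi1 and return class `"undefined"`;
#' missing atoms give `NA`/`"undefined"` with a warning rather than an error.
#'
#' @param x a `pf_structure`
#' @param chain,resno,insert residue identity
#' @return list with `chi1` (degrees or NA) and `class`
#' @export
chi1_rotamer <- function(x, chain, resno, insert = "") {
  at <- x$atoms
  at <- at[at$chain == chain & at$resno == resno & at$insert == insert, ,
           drop = FALSE]
  if (nrow(at) == 0) {
    warning("residue ", chain, " ", resno, " not found; chi1 undefined")
    return(list(chi1 = NA_real_, class = "undefined"))
  }
  resid <- at$resid[1]
  if (resid %in% c("GLY", "ALA"))
    return(list(chi1 = NA_real_, class = "undefined"))
  need <- c("N", "CA", "CB", gamma_atom_name(resid))
  idx <- match(need, at$elety)
  if (anyNA(idx)) {
    warning("residue ", chain, " ", resno, " (", resid, ") lacks atom(s) ",
            paste(need[is.na(idx)], collapse = ","), "; chi1 undefined")
    return(list(chi1 = NA_real_, class = "undefined"))
  }
  p <- as.matrix(at[idx, c("x", "y", "z")])
  chi1 <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  list(chi1 = chi1, class = chi1_class(chi1))
}

#' @rdname chi1_rotamer
#' @param chi1 angle in degrees
#' @export
chi1_class <- function(chi1) {
  if (is.na(chi1)) return("undefined")
  wrap <- function(a) ((a + 180) %% 360) - 180
  wells <- c(trans = 180, `gauche+` = -60, `gauche-` = 60)
  names(wells)[which.min(abs(wrap(chi1 - wells)))]
}

#' Minimum heavy-atom distance between two atom groups
#'
#' @param a,b `pf_structure`s (hydrogens ignored)
#' @return minimum pairwise Euclidean distance in Angstrom
#' @export
min_distance <- function(a, b) {
  pa <- coords(heavy_atoms(a)); pb <- coords(heavy_atoms(b))
  if (nrow(pa) == 0 || nrow(pb) == 0)
    pf_stop("input", "empty atom group in min_distance")
  # chunk over the larger group to bound memory
  best <- Inf
  step <- max(1L, floor(2e6 / max(1, nrow(pb))))
  for (i in seq(1, nrow(pa), by = step)) {
    j <- min(i + step - 1L, nrow(pa))
    d2 <- outer(rowSums(pa[i:j, , drop = FALSE]^2), rowSums(pb^2), "+") -
      2 * (pa[i:j, , drop = FALSE] %*% t(pb))
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Contact detection criteria
#'
#' Distance-only criteria (deposited models lack hydrogens, so no angle
#' terms): `polar` N/O/S vs N/O/S heavy atoms within 3.5 A; `vdw` any heavy
#' atom pair within 4.0 A; `salt_bridge` sidechain charged-group N/O of
#' Arg/Lys/His vs Asp/Glu or a C-terminal carboxylate within 4.0 A;
#' `pi_cation` Arg/Lys cation atom within 6.0 A of a Phe/Tyr/Trp ring
#' centroid.
#'
#' @param polar,vdw,salt_bridge,pi_cation cutoffs in Angstrom
#' @param kinds which contact kinds to report
#' @return object of class `contact_criteria`
#' @export
contact_criteria <- function(polar = 3.5, vdw = 4.0, salt_bridge = 4.0,
                             pi_cation = 6.0,
                             kinds = c("polar", "vdw", "salt_bridge",
                                       "pi_cation")) {
  structure(list(polar = polar, vdw = vdw, salt_bridge = salt_bridge,
                 pi_cation = pi_cation, kinds = kinds),
            class = "contact_criteria")
}

#' @keywords internal
atom_id_string <- function(at) {
  paste0(at$chain, "/", at$resid, at$resno, at$insert, "/", at$elety)
}

#' @keywords internal
pair_table <- function(pa, pb, cutoff) {
  # index pairs (i in pa rows, j in pb rows) within cutoff
  if (nrow(pa) == 0 || nrow(pb) == 0)
    return(cbind(i = integer(0), j = integer(0), d = numeric(0)))
  A <- as.matrix(pa[, c("x", "y", "z")]); B <- as.matrix(pb[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  cbind(i = hit[, 1], j = hit[, 2],
        d = sqrt(pmax(d2[hit], 0)))
}

#' Detect inter-group atomic contacts
#'
#' Each qualifying atom pair is reported once per contact kind. Symmetric in
#' its arguments up to the a/b column labels; invariant under atom-order
#' permutation.
#'
#' @param a,b `pf_structure`s for the two groups (e.g. receptor and peptide)
#' @param criteria a [contact_criteria()]
#' @return data frame with columns kind, atom_a, atom_b, distance plus the
#'   identity fields of both atoms, sorted by (kind, atom_a, atom_b)
#' @export
detect_contacts <- function(a, b, criteria = contact_criteria()) {
  ha <- heavy_atoms(a)$atoms; hb <- heavy_atoms(b)$atoms
  if (nrow(ha) == 0 || nrow(hb) == 0)
    pf_stop("input", "empty atom group in detect_contacts")
  out <- list()
  add <- function(kind, pa, pb, pairs) {
    if (nrow(pairs) == 0) return()
    out[[length(out) + 1]] <<- data.frame(
      kind = kind,
      atom_a = atom_id_string(pa[pairs[, "i"], ]),
      atom_b = atom_id_string(pb[pairs[, "j"], ]),
      chain_a = pa$chain[pairs[, "i"]], resno_a = pa$resno[pairs[, "i"]],
      elety_a = pa$elety[pairs[, "i"]],
      chain_b = pb$chain[pairs[, "j"]], resno_b = pb$resno[pairs[, "j"]],
      elety_b = pb$elety[pairs[, "j"]],
      distance = pairs[, "d"], stringsAsFactors = FALSE)
  }
  kinds <- criteria$kinds
  if ("vdw" %in% kinds)
    add("vdw", ha, hb, pair_table(ha, hb, criteria$vdw))
  if ("polar" %in% kinds) {
    pa <- ha[ha$elesy %in% c("N", "O", "S"), , drop = FALSE]
    pb <- hb[hb$elesy %in% c("N", "O", "S"), , drop = FALSE]
    add("polar", pa, pb, pair_table(pa, pb, criteria$polar))
  }
  if ("salt_bridge" %in% kinds) {
    basic <- function(d) d[(d$resid == "ARG" & d$elety %in% c("NE", "NH1", "NH2")) |
                             (d$resid == "LYS" & d$elety == "NZ") |
                             (d$resid == "HIS" & d$elety %in% c("ND1", "NE2")), ,
                           drop = FALSE]
    cterm_ox <- function(d) {
      has_oxt <- unique(d[d$elety == "OXT", c("chain", "resno", "insert")])
      if (nrow(has_oxt) == 0) return(d[0, , drop = FALSE])
      k <- paste(d$chain, d$resno, d$insert)
      d[k %in% paste(has_oxt$chain, has_oxt$resno, has_oxt$insert) &
          d$elety %in% c("O", "OXT"), , drop = FALSE]
    }
    acidic <- function(d) rbind(
      d[(d$resid == "ASP" & d$elety %in% c("OD1", "OD2")) |
          (d$resid == "GLU" & d$elety %in% c("OE1", "OE2")), , drop = FALSE],
      cterm_ox(d))
    add("salt_bridge", basic(ha), acidic(hb),
        pair_table(basic(ha), acidic(hb), criteria$salt_bridge))
    add("salt_bridge", acidic(ha), basic(hb),
        pair_table(acidic(ha), basic(hb), criteria$salt_bridge))
  }
  if ("pi_cation" %in% kinds) {
    cation <- function(d) d[(d$resid == "ARG" & d$elety == "CZ") |
                              (d$resid == "LYS" & d$elety == "NZ"), ,
                            drop = FALSE]
    rings <- function(d) {
      ringdef <- list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                      TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                      TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
      res <- unique(d[d$resid %in% names(ringdef),
                      c("chain", "resno", "insert", "resid")])
      if (nrow(res) == 0) return(res[0, , drop = FALSE])
      cen <- lapply(seq_len(nrow(res)), function(i) {
        sub <- d[d$chain == res$chain[i] & d$resno == res$resno[i] &
                   d$insert == res$insert[i] &
                   d$elety %in% ringdef[[res$resid[i]]], , drop = FALSE]
        if (nrow(sub) < 5) return(NULL)
        data.frame(chain = res$chain[i], resno = res$resno[i],
                   insert = res$insert[i], resid = res$resid[i],
                   elety = "ring", elesy = "C",
                   x = mean(sub$x), y = mean(sub$y), z = mean(sub$z),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, cen)
    }
    ra <- rings(ha); rb <- rings(hb)
    ca_ <- cation(ha); cb_ <- cation(hb)
    if (!is.null(rb) && nrow(ca_) > 0 && NROW(rb) > 0)
      add("pi_cation", ca_, rb, pair_table(ca_, rb, criteria$pi_cation))
    if (!is.null(ra) && nrow(cb_) > 0 && NROW(ra) > 0)
      add("pi_cation", ra, cb_, pair_table(ra, cb_, criteria$pi_cation))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(0), atom_a = character(0),
               atom_b = character(0), chain_a = character(0),
               resno_a = integer(0), elety_a = character(0),
               chain_b = character(0), resno_b = integer(0),
               elety_b = character(0), distance = numeric(0))
  res <- unique(res)
  res <- res[order(res$kind, res$atom_a, res$atom_b), ]
  rownames(res) <- NULL
  res
}

#' Peptide insertion depth
#'
#' Distance along the membrane normal from the pocket's upper boundary (the
#' top surface of the membrane, z_upper) down to the deepest heavy atom of the
#' peptide selection. Reported as `z_upper - min(z)`, clamped at 0 when the
#' peptide sits entirely above the boundary.
#'
#' @param peptide a `pf_structure` holding the peptide atoms
#' @param bounds a `pocket_bounds`
#' @return depth in Angstrom (>= 0)
#' @export
insertion_depth <- function(peptide, bounds) {
  hp <- heavy_atoms(peptide)
  if (n_atoms(hp) == 0) pf_stop("input", "empty peptide selection")
  max(0, bounds$z_upper - min(hp$atoms$z))
}

#' Compare two receptor states
#'
#' Aggregates the per-residue and per-helix activation metrics for a paired
#' (e.g. inactive/active) structure set: Calpha displacements after
#' superposition on the common TM core, per-helix axis tilt angles, and chi1
#' rotamer changes.
#'
#' @param a,b `pf_structure`s (reference state first)
#' @param tm a [tm_annotation()] shared by both states
#' @param align alignment selector passed to [ca_displacements()]; defaults
#'   to the TM annotation
#' @return object of class `state_comparison`: list with `displacements`
#'   (data frame), `tilts` (data frame helix_id, tilt_deg), `rotamer_changes`
#'   (data frame with chi1/class before and after, changed flag)
#' @export
compare_states <- function(a, b, tm, align = tm) {
  disp <- ca_displacements(a, b, align = align)
  tilts <- do.call(rbind, lapply(tm$helix_id, function(h) {
    hr <- tm[tm$helix_id == h, ]
    get_ca <- function(s) {
      at <- ca_atoms(s)$atoms
      at <- at[at$chain == hr$chain & at$resno >= hr$start &
                 at$resno <= hr$end, , drop = FALSE]
      at[order(at$resno), , drop = FALSE]
    }
    ca_a <- get_ca(a); ca_b <- get_ca(b)
    common <- intersect(ca_a$resno, ca_b$resno)
    if (length(common) < 5) return(NULL)
    ax_a <- helix_axis(as.matrix(ca_a[match(common, ca_a$resno),
                                      c("x", "y", "z")]))
    ax_b <- helix_axis(as.matrix(ca_b[match(common, ca_b$resno),
                                      c("x", "y", "z")]))
    data.frame(helix_id = h, tilt_deg = tilt_angle(ax_a$axis, ax_b$axis))
  }))
  key <- function(d) unique(d[, c("chain", "resno", "insert")])
  res_a <- key(a$atoms); res_b <- key(b$atoms)
  common <- merge(res_a, res_b)
  rot <- do.call(rbind, lapply(seq_len(nrow(common)), function(i) {
    ra <- suppressWarnings(chi1_rotamer(a, common$chain[i], common$resno[i],
                                        common$insert[i]))
    rb <- suppressWarnings(chi1_rotamer(b, common$chain[i], common$resno[i],
                                        common$insert[i]))
    if (ra$class == "undefined" && rb$class == "undefined") return(NULL)
    data.frame(chain = common$chain[i], resno = common$resno[i],
               insert = common$insert[i],
               chi1_before = ra$chi1, chi1_after = rb$chi1,
               class_before = ra$class, class_after = rb$class,
               changed = !identical(ra$class, rb$class),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(rot)) {
    rot <- rot[order(rot$chain, rot$resno, rot$insert), ]
    rownames(rot) <- NULL
  }
  structure(list(displacements = disp, tilts = tilts, rotamer_changes = rot),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat(sprintf("<state_comparison> %d residues, max displacement %.2f A\n",
              nrow(x$displacements), max(x$displacements$displacement)))
  if (!is.null(x$tilts)) {
    cat("helix tilts (deg):",
        paste(sprintf("TM%d %.1f", x$tilts$helix_id, x$tilts$tilt_deg),
              collapse = ", "), "\n")
  }
  nch <- if (is.null(x$rotamer_changes)) 0 else sum(x$rotamer_changes$changed)
  cat(nch, "chi1 class change(s)\n")
  invisible(x)
}
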