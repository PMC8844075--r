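#' Atomic structures as ordered atom tables
#'
#' A `pf_structure` is a thin S3 wrapper around an ordered data frame of atom
#' records -- the universal substrate of every computation in the package.
#' Columns:
#' \describe{
#'   \item{chain}{chain identifier (character)}
#'   \item{resno}{residue number as deposited (integer, 1-based, no renumbering)}
#'   \item{insert}{insertion code, `""` when absent; participates in residue
#'     identity}
#'   \item{resid}{3-letter residue name}
#'   \item{elety}{atom name (e.g. `"CA"`, `"OG1"`)}
#'   \item{elesy}{element symbol; never empty}
#'   \item{alt}{alternate-location indicator, `""` or `"A"` after parsing}
#'   \item{het}{logical, `TRUE` for HETATM records}
#'   \item{x, y, z}{coordinates in Angstrom; `z` is the membrane normal once
#'     the structure is membrane-aligned, extracellular side at larger z}
#' }
#'
#' @param atoms data frame with the columns above
#' @param label free-text label carried through reports
#' @return object of class `pf_structure`
#' @export
pf_structure <- function(atoms, label = "") {
  req <- c("chain", "resno", "insert", "resid", "elety", "elesy", "alt",
           "het", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    pf_stop("input", "atom table lacks columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, req]
  atoms$chain  <- as.character(atoms$chain)
  atoms$resno  <- as.integer(atoms$resno)
  atoms$insert <- ifelse(is.na(atoms$insert), "", as.character(atoms$insert))
  atoms$alt    <- ifelse(is.na(atoms$alt), "", as.character(atoms$alt))
  atoms$het    <- as.logical(atoms$het)
  if (nrow(atoms) > 0) {
    if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
      pf_stop("input", "non-finite coordinates in atom table")
    if (any(is.na(atoms$elesy) | !nzchar(atoms$elesy)))
      pf_stop("input", "empty element symbol in atom table")
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
                 atoms$alt, sep = "|")
    if (anyDuplicated(key))
      pf_stop("input", "duplicate atom identity (chain/resno/insert/elety/alt): ",
              key[duplicated(key)][1])
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = as.character(label)[1]),
            class = "pf_structure")
}

#' @export
print.pf_structure <- function(x, ...) {
  cat(sprintf("<pf_structure> %s: %d atoms, %d residues, %d chain(s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$atoms), n_residues(x), length(unique(x$atoms$chain))))
  invisible(x)
}

#' Number of atoms / residues in a structure
#' @param x a `pf_structure`
#' @return integer count
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @rdname n_atoms
#' @export
n_residues <- function(x) {
  length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert)))
}

#' Coordinate matrix of a structure
#' @param x a `pf_structure`
#' @return numeric n x 3 matrix (columns x, y, z)
#' @export
coords <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' @keywords internal
infer_element <- function(elety) {
  # strip leading digits/primes then take leading letters; two-letter symbols
  # only for common hetero elements to avoid eating e.g. "CA" (calpha)
  s <- toupper(gsub("^[0-9']+", "", elety))
  two <- c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN", "CU", "NI", "CO")
  out <- substr(s, 1, 1)
  s2 <- substr(s, 1, 2)
  out[s2 %in% two & nchar(s) > 2] <- s2[s2 %in% two & nchar(s) > 2]
  out
}

#' Read a structure from PDB or mmCIF
#'
#' One atom record is produced per ATOM/HETATM row. Alternate locations other
#' than blank or `"A"` are dropped, giving a deterministic single-conformer
#' model. Hydrogens are retained at parse time but flagged by element; all
#' downstream geometry ignores them.
#'
#' @param file path to a PDB or mmCIF file
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`
#' @param label label stored on the structure; defaults to the file name
#' @return a [pf_structure()]
#' @export
read_structure <- function(file, format = c("auto", "pdb", "cif"),
                           label = NULL) {
  format <- match.arg(format)
  if (!file.exists(file))
    pf_stop("input", "cannot read structure file: ", file)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", file, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(file, verbose = FALSE)
    else bio3d::read.pdb(file, verbose = FALSE, rm.alt = FALSE),
    error = function(e) pf_stop("input", "failed to parse ", file, ": ",
                                conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    pf_stop("input", "no atoms parsed from ", file)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  keep <- alt %in% c("", "A", ".")
  at <- at[keep, , drop = FALSE]
  alt <- ifelse(alt[keep] == ".", "", alt[keep])
  if (nrow(at) == 0)
    pf_stop("input", "no atoms left after altloc filtering in ", file)
  ele <- if ("elesy" %in% names(at)) toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy))) else ""
  need <- !nzchar(ele)
  ele[need] <- infer_element(at$elety[need])
  pf_structure(
    data.frame(chain = ifelse(is.na(at$chain), "", at$chain),
               resno = at$resno,
               insert = ifelse(is.na(at$insert), "", at$insert),
               resid = at$resid, elety = at$elety, elesy = ele, alt = alt,
               het = at$type == "HETATM",
               x = at$x, y = at$y, z = at$z,
               stringsAsFactors = FALSE),
    label = if (is.null(label)) basename(file) else label
  )
}

#' Write a structure to a PDB file
#'
#' @param x a `pf_structure`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_structure <- function(x, file) {
  at <- x$atoms
  if (nrow(at) == 0) pf_stop("input", "refusing to write empty structure")
  n <- nrow(at)
  bio3d::write.pdb(
    pdb = NULL, file = file,
    xyz = as.vector(t(coords(x))),
    type = ifelse(at$het, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resid,
    eleno = seq_len(n), elety = at$elety,
    chain = ifelse(nzchar(at$chain), at$chain, " "),
    insert = ifelse(nzchar(at$insert), at$insert, ""),
    alt = ifelse(nzchar(at$alt), at$alt, ""),
    o = rep(1, n), b = rep(0, n), elesy = at$elesy
  )
  invisible(file)
}

#' Atom selection criteria
#'
#' Builds a selector: criteria combine with AND; each criterion matches when
#' the field is in the supplied set. `NULL` criteria are ignored. Selection
#' never fabricates atoms and preserves input order; an empty result is valid.
#'
#' @param chain,resid,elety,element character vectors of admissible values
#' @param resno integer vector of admissible residue numbers
#' @param het `TRUE`/`FALSE` to require/exclude HETATM records
#' @return object of class `pf_selector`
#' @export
atom_select <- function(chain = NULL, resno = NULL, resid = NULL,
                        elety = NULL, element = NULL, het = NULL) {
  structure(list(chain = chain, resno = resno, resid = resid,
                 elety = elety, element = element, het = het),
            class = "pf_selector")
}

#' @keywords internal
selector_mask <- function(x, sel) {
  if (!inherits(sel, "pf_selector")) pf_stop("input", "selector must be built with atom_select()")
  at <- x$atoms
  m <- rep(TRUE, nrow(at))
  if (!is.null(sel$chain))   m <- m & at$chain %in% as.character(sel$chain)
  if (!is.null(sel$resno))   m <- m & at$resno %in% as.integer(sel$resno)
  if (!is.null(sel$resid))   m <- m & at$resid %in% as.character(sel$resid)
  if (!is.null(sel$elety))   m <- m & at$elety %in% as.character(sel$elety)
  if (!is.null(sel$element)) m <- m & at$elesy %in% toupper(as.character(sel$element))
  if (!is.null(sel$het))     m <- m & at$het == isTRUE(sel$het)
  m
}

#' Select a subset of atoms
#'
#' @param x a `pf_structure`
#' @param sel a selector from [atom_select()]
#' @param invert keep atoms NOT matching the selector
#' @return a `pf_structure` with exactly the matching atoms, original order
#' @export
select_atoms <- function(x, sel, invert = FALSE) {
  m <- selector_mask(x, sel)
  if (invert) m <- !m
  out <- x
  out$atoms <- x$atoms[m, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' @keywords internal
heavy_atoms <- function(x) {
  out <- x
  out$atoms <- x$atoms[!(x$atoms$elesy %in% c("H", "D")), , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' @keywords internal
ca_atoms <- function(x) {
  out <- x
  out$atoms <- x$atoms[x$atoms$elety == "CA" & !(x$atoms$elesy %in% c("H", "D")), ,
                       drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}
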