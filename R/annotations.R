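#' Transmembrane helix annotation
#'
#' A `tm_annotation` maps each TM helix (1..7, plus optional extra segments)
#' to an inclusive residue range on a chain. Ranges must not overlap within a
#' chain and each helix needs at least 4 residues. These ranges anchor the
#' lateral cavity boundaries and the extracellular upper bound.
#'
#' @param df data frame with columns `helix_id` (integer), `chain`, `start`,
#'   `end` (inclusive residue numbers)
#' @return object of class `tm_annotation` (a validated data frame)
#' @export
tm_annotation <- function(df) {
  req <- c("helix_id", "chain", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss))
    pf_stop("annotation", "TM table lacks columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req]
  df$helix_id <- as.integer(df$helix_id)
  df$chain <- as.character(df$chain)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$helix_id)) || any(is.na(df$start)) || any(is.na(df$end)))
    pf_stop("annotation", "non-integer helix_id/start/end in TM table")
  if (any(df$end - df$start + 1L < 4L))
    pf_stop("annotation", "each TM helix needs >= 4 residues")
  if (anyDuplicated(df$helix_id))
    pf_stop("annotation", "duplicate helix_id in TM table")
  for (ch in unique(df$chain)) {
    d <- df[df$chain == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      pf_stop("annotation", "overlapping helix ranges on chain ", ch)
  }
  df <- df[order(df$helix_id), ]
  rownames(df) <- NULL
  class(df) <- c("tm_annotation", "data.frame")
  df
}

#' Generic (Ballesteros-Weinstein) numbering map
#'
#' Maps `(chain, resno)` to a generic code `"t.pp"` (helix t, position pp).
#' The map must be injective in both directions over the residues it covers;
#' in particular the toggle-switch code `"6.48"` must resolve to exactly one
#' residue when helix 6 is covered.
#'
#' @param df data frame with columns `chain`, `resno`, `bw`
#' @return object of class `bw_map` (a validated data frame)
#' @export
bw_map <- function(df) {
  req <- c("chain", "resno", "bw")
  miss <- setdiff(req, names(df))
  if (length(miss))
    pf_stop("annotation", "BW table lacks columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req]
  df$chain <- as.character(df$chain)
  df$resno <- as.integer(df$resno)
  df$bw <- as.character(df$bw)
  if (!all(grepl("^[0-9]+\\.[0-9]+$", df$bw)))
    pf_stop("annotation", "BW codes must look like 't.pp'")
  if (anyDuplicated(df$bw))
    pf_stop("annotation", "duplicate BW code: ",
            df$bw[duplicated(df$bw)][1])
  key <- paste(df$chain, df$resno)
  if (anyDuplicated(key))
    pf_stop("annotation", "residue mapped to two BW codes: ",
            key[duplicated(key)][1])
  rownames(df) <- NULL
  class(df) <- c("bw_map", "data.frame")
  df
}

#' Resolve a generic-numbering code to a residue
#'
#' @param bw a [bw_map()]
#' @param code generic code, e.g. `"6.48"`
#' @return one-row data frame with `chain` and `resno`
#' @export
bw_residue <- function(bw, code) {
  hit <- which(bw$bw == code)
  if (length(hit) != 1)
    pf_stop("annotation", "code ", code, " resolves to ", length(hit),
            " residues (need exactly 1)")
  bw[hit, c("chain", "resno")]
}

#' Load TM and generic-numbering annotation tables
#'
#' Both files are tab-separated with a one-line header (lines starting with
#' `#` are comments). The TM table has columns `helix_id, chain, start, end`;
#' the BW table has `chain, resno, bw`. After validation the two are
#' cross-checked: if the map covers helix 6, the residue carrying code 6.48
#' must lie inside the annotated helix-6 range.
#'
#' @param tm_file,bw_file paths to the two tables
#' @return list with elements `tm` ([tm_annotation()]) and `bw` ([bw_map()])
#' @export
load_annotations <- function(tm_file, bw_file) {
  for (f in c(tm_file, bw_file))
    if (!file.exists(f)) pf_stop("input", "cannot read annotation table: ", f)
  tm <- tm_annotation(utils::read.delim(tm_file, comment.char = "#",
                                        stringsAsFactors = FALSE))
  bw <- bw_map(utils::read.delim(bw_file, comment.char = "#",
                                 colClasses = c("character", "integer", "character"),
                                 stringsAsFactors = FALSE))
  if (any(bw$bw == "6.48")) {
    tog <- bw_residue(bw, "6.48")
    h6 <- tm[tm$helix_id == 6L, , drop = FALSE]
    if (nrow(h6) == 1) {
      inside <- tog$chain == h6$chain && tog$resno >= h6$start &&
        tog$resno <= h6$end
      if (!inside)
        pf_stop("annotation", "residue mapped to 6.48 (", tog$chain, " ",
                tog$resno, ") lies outside the annotated helix-6 range")
    }
  }
  list(tm = tm, bw = bw)
}

#' Write annotation tables
#' @param tm a [tm_annotation()]
#' @param bw a [bw_map()]
#' @param file output path (tab-separated, one-line header)
#' @return `file`, invisibly
#' @export
write_tm_annotation <- function(tm, file) {
  utils::write.table(as.data.frame(tm), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_tm_annotation
#' @export
write_bw_map <- function(bw, file) {
  utils::write.table(as.data.frame(bw), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @keywords internal
tm_residue_mask <- function(x, tm) {
  at <- x$atoms
  m <- rep(FALSE, nrow(at))
  for (i in seq_len(nrow(tm))) {
    m <- m | (at$chain == tm$chain[i] & at$resno >= tm$start[i] &
                at$resno <= tm$end[i])
  }
  m
}
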