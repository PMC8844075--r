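#' Classed error helper
#'
#' All user-facing failures in pocketframe carry a category so that scripted
#' callers can dispatch on the condition class. Categories: `input`
#' (unreadable/ill-formed arguments or files), `annotation` (TM table / generic
#' numbering problems), `geometry` (degenerate geometry), `pairing` (no common
#' residues between two structures), `spec` (inconsistent synthetic-bundle
#' parameters).
#'
#' @param category one of "input", "annotation", "geometry", "pairing", "spec"
#' @param ... message parts, pasted with `paste0`
#' @keywords internal
pf_stop <- function(category, ...) {
  category <- match.arg(category, c("input", "annotation", "geometry",
                                    "pairing", "spec"))
  msg <- paste0(...)
  cond <- structure(
    class = c(paste0("pf_", category, "_error"), "pf_error",
              "error", "condition"),
    list(message = paste0(category, " error: ", msg), call = sys.call(-1))
  )
  stop(cond)
}

#' @keywords internal
pf_error_category <- function(cond) {
  cl <- class(cond)
  m <- regmatches(cl, regexpr("^pf_[a-z]+_error$", cl))
  m <- m[nzchar(m)]
  if (length(m)) sub("_error$", "", sub("^pf_", "", m[[1]])) else "unknown"
}
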