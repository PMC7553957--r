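#' Parse an HGVS-style protein-change string
#'
#' Understands the common MAF dialects for TP53 protein changes: missense
#' (\code{"p.R273H"}, \code{"R273H"}, \code{"p.Arg273His"}), nonsense
#' (\code{"p.R306*"}, \code{"p.R306X"}, \code{"p.Arg306Ter"}), frameshift
#' (\code{"p.E62fs"}, \code{"p.E62Gfs*4"}), in-frame indels
#' (\code{"p.I255del"}, \code{"p.K120_A123del"}, \code{"p.P58dup"},
#' \code{"p.A39_Q40insV"}) and splice markers (\code{"p.X187_splice"},
#' \code{"_splice"}). Unparseable input raises a classed condition
#' (\code{p53_parse_error}) carrying the raw string; it is never silently
#' dropped or coerced.
#'
#' @param raw a single non-empty protein-change string.
#' @param keep_splice_codon keep the codon number of \code{X123_splice}-style
#'   markers (\code{TRUE}, default) or drop it.
#' @return an object of class \code{p53_protein_change}: a list with fields
#'   \code{kind} (one of \code{missense}, \code{nonsense_stop},
#'   \code{frameshift}, \code{inframe_indel}, \code{splice}, \code{other}),
#'   \code{ref_aa}, \code{codon}, \code{alt_aa} (each possibly \code{NA})
#'   and \code{raw}.
#' @examples
#' parse_protein_change("p.R273H")
#' parse_protein_change("p.R306*")
#' @export
parse_protein_change <- function(raw, keep_splice_codon = TRUE) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop_parse_error(raw, "protein change must be a single non-empty string")

  s <- sub("^p\\.", "", trimws(raw))

  pc <- function(kind, ref = NA_character_, codon = NA_integer_,
                 alt = NA_character_) {
    structure(list(kind = kind, ref_aa = ref, codon = as.integer(codon),
                   alt_aa = alt, raw = raw),
              class = "p53_protein_change")
  }

  # splice markers: "X187_splice", "187_splice", "_splice"
  m <- regmatches(s, regexec("^[A-Za-z]?([0-9]*)_splice$", s))[[1]]
  if (length(m) > 0L) {
    codon <- if (keep_splice_codon && nzchar(m[2L])) as.integer(m[2L])
             else NA_integer_
    return(pc("splice", codon = codon))
  }

  aa1 <- "[A-Z]"
  aa3 <- "(?:[A-Z][a-z]{2})"
  one <- function(tok) {
    if (is.na(tok) || !nzchar(tok)) return(NA_character_)
    out <- if (nchar(tok) == 3L) unname(AA_THREE[tok]) else tok
    if (is.na(out) || !(out %in% c(AA_ONE, "*", "X")))
      stop_parse_error(raw, paste0("unknown amino-acid code '", tok, "'"))
    out
  }

  # frameshift: E62fs, E62Gfs, E62Gfs*4, Glu62GlyfsTer4
  pat <- paste0("^(", aa1, "|", aa3, ")([0-9]+)(", aa1, "|", aa3,
                ")?fs(?:\\*?[0-9]*|Ter[0-9]*)?$")
  m <- regmatches(s, regexec(pat, s))[[1]]
  if (length(m) > 0L)
    return(pc("frameshift", ref = one(m[2L]), codon = m[3L]))

  # substitution: missense or nonsense
  pat <- paste0("^(", aa1, "|", aa3, ")([0-9]+)(\\*|", aa1, "|", aa3, ")$")
  m <- regmatches(s, regexec(pat, s))[[1]]
  if (length(m) > 0L) {
    ref <- one(m[2L]); alt <- if (m[4L] == "*") "*" else one(m[4L])
    codon <- as.integer(m[3L])
    if (alt %in% c("*", "X"))
      return(pc("nonsense_stop", ref = ref, codon = codon, alt = "*"))
    if (identical(ref, alt))
      return(pc("other", ref = ref, codon = codon, alt = alt))
    return(pc("missense", ref = ref, codon = codon, alt = alt))
  }

  # in-frame indel: I255del, K120_A123del, P58dup, A39_Q40insV, H178delinsPR
  pat <- paste0("^(", aa1, "|", aa3, ")([0-9]+)",
                "(?:_(?:", aa1, "|", aa3, ")?([0-9]+))?",
                "(delins|del|ins|dup)(?:", aa1, "|", aa3, ")*$")
  m <- regmatches(s, regexec(pat, s))[[1]]
  if (length(m) > 0L)
    return(pc("inframe_indel", ref = one(m[2L]), codon = m[3L]))

  stop_parse_error(raw, "unrecognised protein-change syntax")
}

stop_parse_error <- function(raw, message) {
  cond <- structure(
    class = c("p53_parse_error", "error", "condition"),
    list(message = paste0("cannot parse protein change ",
                          deparse(as.character(raw)[1L]), ": ", message),
         call = NULL, raw = raw))
  stop(cond)
}

# Vectorised parse over a character vector; unparseable non-empty strings
# raise, empty/NA yield an all-NA row of kind "other" (the caller decides the
# kind from the variant classification).
parse_protein_changes <- function(raw, keep_splice_codon = TRUE) {
  n <- length(raw)
  out <- data.frame(kind = rep("other", n), ref_aa = NA_character_,
                    codon = NA_integer_, alt_aa = NA_character_,
                    protein_change_raw = as.character(raw),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(raw[i]) || !nzchar(trimws(raw[i]))) next
    p <- parse_protein_change(raw[i], keep_splice_codon = keep_splice_codon)
    out$kind[i] <- p$kind
    out$ref_aa[i] <- p$ref_aa
    out$codon[i] <- p$codon
    out$alt_aa[i] <- p$alt_aa
  }
  out
}

#' @export
print.p53_protein_change <- function(x, ...) {
  cat(x$raw, "->", x$kind)
  if (!is.na(x$codon)) cat(" at codon", x$codon)
  if (!is.na(x$ref_aa) && !is.na(x$alt_aa))
    cat(" (", x$ref_aa, ">", x$alt_aa, ")", sep = "")
  cat("\n")
  invisible(x)
}
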