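#' IUPAC nucleotide ambiguity-code set algebra
#'
#' Direct Sanger sequencing of a hybrid superposes both parental ribotypes in
#' one chromatogram, so a site where the parents carry different bases reads
#' as the IUPAC code for the *union* of the parental bases ("additive
#' polymorphism"). These helpers implement the underlying set algebra over
#' the 15 IUPAC codes. The gap character `"-"` is deliberately *not* part of
#' this algebra: an indel is a length difference between ribotypes, not a
#' base-call ambiguity, and is handled by the indel-superposition logic in
#' [shifted_superposition()].
#'
#' @section Encoding:
#' Internally each code maps to a bitmask over \{A, C, G, T\} (A = 1, C = 2,
#' G = 4, T = 8); union is bitwise OR and containment is a mask test, so all
#' operations are vectorised.
#'
#' @param a,b character vectors of single IUPAC codes (recycled to a common
#'   length). Lowercase and `"U"` are accepted and normalised.
#' @return `iupac_union()` returns a character vector of IUPAC codes whose
#'   base sets are the element-wise unions; `iupac_subsumes()` returns a
#'   logical vector, `TRUE` where every base of `b` is contained in `a`;
#'   `iupac_bases()` returns a list of character vectors (the base sets).
#' @examples
#' iupac_union("A", "G")        # "R"
#' iupac_union("C", "T")        # "Y"
#' iupac_union("R", "C")        # "V" ({A,G} + {C})
#' iupac_subsumes("R", "A")     # TRUE
#' iupac_subsumes("A", "R")     # FALSE
#' @name iupac
NULL

# bitmask per code: A=1, C=2, G=4, T=8
.iupac_mask <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)
.iupac_code <- character(15L)
.iupac_code[.iupac_mask] <- names(.iupac_mask)

.iupac_alphabet <- c(names(.iupac_mask), "-")

.normalize_symbol <- function(x) {
  chartr("U", "T", toupper(x))
}

.to_mask <- function(x, what = "symbol") {
  x <- .normalize_symbol(x)
  if (any(x == "-")) {
    stop("gap character '-' has no IUPAC base set; gaps are a separate state",
         call. = FALSE)
  }
  m <- .iupac_mask[x]
  if (anyNA(m)) {
    bad <- unique(x[is.na(m)])
    stop(sprintf("invalid IUPAC %s: %s", what,
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  unname(m)
}

#' @rdname iupac
#' @export
iupac_union <- function(a, b) {
  .iupac_code[bitwOr(.to_mask(a), .to_mask(b))]
}

#' @rdname iupac
#' @export
iupac_subsumes <- function(a, b) {
  mb <- .to_mask(b)
  bitwAnd(.to_mask(a), mb) == mb
}

#' @rdname iupac
#' @export
iupac_bases <- function(a) {
  lapply(.to_mask(a), function(m) c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L])
}

#' All 15 IUPAC ambiguity codes
#'
#' @return character vector of the one-letter codes, in mask order.
#' @export
iupac_codes <- function() names(.iupac_mask)
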