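# IUPAC nucleotide ambiguity codes. In a direct-sequenced diploid consensus,
# an ambiguity letter marks a heterozygous site (e.g. W = A/T).

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# reverse lookup: sorted base set -> code
.IUPAC_REV <- setNames(names(.IUPAC),
                       vapply(.IUPAC, function(b)
                         paste0(sort(b), collapse = ""), ""))

#' Expand an IUPAC nucleotide symbol to its base set
#'
#' @param symbol single IUPAC nucleotide letter (one of
#'   A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @return Character vector of the nucleotides the symbol denotes, in
#'   alphabetical order.
#' @examples
#' expandIUPAC("W")  # A T
#' @export
expandIUPAC <- function(symbol) {
  .assertScalarString(symbol, "symbol")
  symbol <- toupper(symbol)
  out <- .IUPAC[[symbol]]
  if (is.null(out))
    stop("unknown IUPAC symbol: '", symbol, "'", call. = FALSE)
  sort(out)
}

#' Encode a set of nucleotides as an IUPAC symbol
#'
#' Inverse of \code{\link{expandIUPAC}}: the unique single letter denoting
#' exactly the given base set.
#'
#' @param bases character vector drawn from A, C, G, T.
#' @return Single IUPAC letter.
#' @examples
#' iupacCode(c("T", "A"))  # "W"
#' @export
iupacCode <- function(bases) {
  key <- .collapse(sort(unique(toupper(bases))))
  out <- .IUPAC_REV[[key]]
  if (is.null(out))
    stop("not a nucleotide set: ", key, call. = FALSE)
  out
}

# expand every character of a string (codon or longer) into the set of
# plain-base strings consistent with it; ambiguity positions combine freely
.expandString <- function(x) {
  sets <- lapply(.chars(x), expandIUPAC)
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  sort(unique(apply(grid, 1L, .collapse)))
}
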