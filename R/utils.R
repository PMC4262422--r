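# small shared helpers

# run code under a temporary RNG state; seed = NULL leaves the RNG alone
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# round half away from zero (R's round() is banker's)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
.assertScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
  invisible(x)
}

# character vector of single residues/bases from a sequence-like object
.chars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1L]]

# upper-case character vector preserving names (base as.character drops
# names on plain character input; XStringSet keeps them)
.upperNamed <- function(x) {
  nm <- names(x)
  s <- toupper(as.character(x))
  names(s) <- nm
  s
}

.collapse <- function(x) paste0(x, collapse = "")

# sample bases i.i.d. at a given GC fraction
.sampleBases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")
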