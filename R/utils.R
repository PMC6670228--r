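#' @importFrom stats runif rbinom setNames
NULL

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (display convention for percentage tables;
# base round() is round-half-even).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# IUPAC nucleotide code -> set of plain bases it matches.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Thin character-in/character-out wrapper around
#' \code{\link[Biostrings]{reverseComplement}}.
#'
#' @param x a single DNA string (IUPAC codes allowed).
#' @return the reverse complement as a character scalar.
#' @examples
#' revComp("GATTTTGTGGCTGCAATTG")
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Check a DNA string for non-ACGT characters; error names the first offender.
assertACGT <- function(dna, what = "dna") {
  bad <- regexpr("[^ACGT]", dna)
  if (bad > 0)
    stop(sprintf("%s contains non-ACGT character '%s' at position %d",
                 what, substr(dna, bad, bad), bad))
  invisible(TRUE)
}

assertProbability <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("%s must be a single probability in [0,1]", name))
  invisible(TRUE)
}

assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    stop(sprintf("%s must be a single integer >= %d", name, min))
  invisible(TRUE)
}
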