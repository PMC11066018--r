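#' @import methods
#' @importFrom stats coef lm rbinom rgeom rnorm runif setNames dist dpois sd
#' @importFrom utils head read.table write.table
NULL

# Standard 20-residue alphabet, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic operations in the package take an explicit integer seed and
#' evaluate under it without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a per-stage substream seed from a master seed. Keeps results
# independent across stages while staying below .Machine$integer.max.
deriveSeed <- function(seed, stage) {
  (as.integer(seed) * 131L + as.integer(stage) * 7919L) %% 2147483587L
}

# Split a character string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Tile a unit string until it reaches at least `len` characters.
tileString <- function(unit, len) {
  reps <- ceiling(len / nchar(unit))
  substr(strrep(unit, reps), 1L, len)
}

# Cyclic left rotation of a string by k characters.
rotateString <- function(x, k) {
  n <- nchar(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  paste0(substr(x, k + 1L, n), substr(x, 1L, k))
}

# Reverse complement of a plain character DNA string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a plain character DNA string (length divisible by 3 is enforced
# by truncation) to an amino-acid string; stops appear as "*".
translateDNA <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

gcdPair <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# Greatest common divisor of a vector of non-negative integers.
gcdAll <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0) return(0)
  Reduce(gcdPair, x)
}
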