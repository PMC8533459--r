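## Low-level nucleotide helpers shared by the fixture generator and the
## comparison stages. All randomness flows through R's RNG so that callers
## control determinism with a single seed.

DNA_BASES4 <- c("A", "C", "G", "T")

## n random bases as one character string
randomDnaString <- function(n) {
    paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

#' Mutate a nucleotide sequence by random substitutions
#'
#' Each position is substituted independently with probability \code{rate};
#' a substituted base is drawn uniformly from the three alternatives, so the
#' realised divergence of a mutated copy is binomial around \code{rate}.
#' Substitution-only mutation keeps homolog identity arithmetic exact: a
#' pair generated at rate \eqn{d} aligns without gaps at identity
#' \eqn{\approx 1 - d}.
#'
#' @param x a single character string of \code{A/C/G/T} bases.
#' @param rate per-position substitution probability in \[0, 1).
#' @return the mutated character string.
#' @examples
#' set.seed(1)
#' mutateSequence("ACGTACGTAC", 0.2)
#' @export
mutateSequence <- function(x, rate) {
    stopifnot(is.character(x), length(x) == 1L, rate >= 0, rate < 1)
    if (rate == 0) return(x)
    bases <- strsplit(x, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(bases)) < rate)
    if (length(hit)) {
        repl <- vapply(bases[hit], function(b) {
            sample(setdiff(DNA_BASES4, b), 1L)
        }, character(1L))
        bases[hit] <- repl
    }
    paste(bases, collapse = "")
}

## set of k-mers of a character sequence (any alphabet, case-sensitive)
kmerSet <- function(x, k) {
    n <- nchar(x)
    if (n < k) return(character(0))
    unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

## reverse-complement of a character string
revcompChar <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
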