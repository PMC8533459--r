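## Structured error conditions. Every user-facing failure mode raises a
## condition with a distinct class so callers (and tests) can discriminate
## without matching message text.

lbgcError <- function(class, message, ...) {
    stop(errorCondition(message,
                        ...,
                        class = c(class, "lichenBGC_error", "error")))
}

#' @name lichenBGC-errors
#' @title Error conditions raised by lichenBGC
#'
#' @description
#' All errors raised by the package carry the condition class
#' \code{"lichenBGC_error"} plus one of the specific classes below, so that
#' \code{tryCatch()} handlers can target a precise failure mode:
#' \describe{
#'   \item{\code{missingFileError}}{an input file does not exist.}
#'   \item{\code{coordinateError}}{a gene violates the 1-based inclusive
#'     coordinate convention (\code{end < start}, \code{start < 1}, or the
#'     gene extends beyond its contig).}
#'   \item{\code{duplicateGeneError}}{a gene identifier occurs more than
#'     once in one annotation.}
#'   \item{\code{unknownGeneError}}{a cluster table references a gene
#'     absent from the annotation.}
#'   \item{\code{unknownTokenError}}{a PKS domain string contains a token
#'     outside the recognised vocabulary.}
#'   \item{\code{emptySequenceError}}{an alignment was requested for an
#'     empty sequence.}
#'   \item{\code{ambiguityError}}{a uniqueness requirement failed (e.g.
#'     more than one atranorin-type cluster).}
#'   \item{\code{configError}}{a configuration value is outside its
#'     documented range.}
#'   \item{\code{calibrationError}}{library-size calibration was attempted
#'     with no usable (nonzero) observation.}
#'   \item{\code{readLengthError}}{simulated reads would be longer than the
#'     shortest gene.}
#'   \item{\code{schemeError}}{an invalid step in the depside/depsidone
#'     assembly model (e.g. depsidonizing a depsidone).}
#'   \item{\code{stageError}}{a pipeline stage failed; the condition holds
#'     a \code{stage} field naming it.}
#' }
NULL
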