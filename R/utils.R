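#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that simulator operations are
#' deterministic without clobbering the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' @keywords internal
is_fraction <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

#' @keywords internal
stopifnot_fraction <- function(x, what) {
  if (!is_fraction(x)) stop(sprintf("%s must be a fraction in [0, 1]", what), call. = FALSE)
  invisible(x)
}

#' @keywords internal
stopifnot_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be positive", what), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param x character scalar of DNA.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a CDS to protein
#'
#' Drops a trailing stop codon if present.  Sequences whose length is not a
#' multiple of 3 are truncated to the longest in-frame prefix with a warning.
#'
#' @param cds character scalar of DNA.
#' @return character scalar of amino acids.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    warning("CDS length not divisible by 3; using longest in-frame prefix")
    cds <- substr(cds, 1L, n - n %% 3L)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}
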