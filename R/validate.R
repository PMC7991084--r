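# CDR3 sequence validation and integer encoding shared by all metrics.

#' Validate CDR3 amino-acid sequences
#'
#' Upper-cases and strips surrounding whitespace, then checks that every
#' residue is one of the 20 standard one-letter codes.  Ambiguity and
#' non-standard codes (B, J, O, U, X, Z, `*`) are rejected, not skipped.
#'
#' @param x character vector of raw sequences.
#' @return the cleaned character vector (invisibly identical order).
#' @export
validateCDR3 <- function(x) {
  if (!is.character(x)) stop("sequences must be character")
  x <- toupper(trimws(x))
  if (any(is.na(x) | !nzchar(x))) stop("empty sequence")
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x)
  if (any(bad))
    stop("invalid residue in sequence(s): ",
         paste(utils::head(x[bad], 5), collapse = ", "))
  x
}

# 0-based integer codes for the C++ kernels; validates on the way
.encodeSeqs <- function(x) {
  x <- validateCDR3(x)
  lapply(strsplit(x, "", fixed = TRUE),
         function(ch) match(ch, AA_ALPHABET) - 1L)
}

.decodeSeq <- function(codes, gap = "-") {
  out <- AA_ALPHABET[pmax(codes, 0L) + 1L]
  out[codes < 0L] <- gap
  paste(out, collapse = "")
}
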