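# The TCRMatch k-mer kernel.
#
# K(s, t) sums, over every k from 1 to the shorter sequence length and every
# pair of contiguous k-mers (one from each sequence), the product of the
# kernel-matrix values of the position-wise residue pairs.  The normalized
# score divides by the self-kernels so identical sequences score exactly 1.

#' Raw (unnormalized) k-mer kernel value
#'
#' @param seq1,seq2 CDR3 amino-acid strings (single sequences).
#' @param matrix a [KernelMatrix-class]; defaults to the BLOSUM62
#'   frequency matrix raised to 0.11387.
#' @return a single non-negative number, symmetric in its arguments.
#' @examples
#' km <- buildKernelMatrix()
#' kernelRaw("A", "A", km) == km@values["A", "A"]
#' @export
kernelRaw <- function(seq1, seq2, matrix = .defaultKernel()) {
  stopifnot(is(matrix, "KernelMatrix"))
  e <- .encodeSeqs(c(seq1, seq2))
  cpp_kernel_raw(e[[1]], e[[2]], matrix@values)
}

#' Normalized TCRMatch similarity score
#'
#' `kernelRaw(s1, s2) / sqrt(kernelRaw(s1, s1) * kernelRaw(s2, s2))` under
#' the default geometric normalization, which guarantees a self-score of
#' exactly 1; the plain-product normalization of the two self-kernels is
#' available via `norm = "product"` for comparison.
#'
#' @inheritParams kernelRaw
#' @param norm `"geometric"` (default) or `"product"`.
#' @return list with elements `raw` (unnormalized kernel) and `normalized`
#'   (in (0, 1] for the geometric normalization).
#' @examples
#' tcrmatchScore("CASSLG", "CASSLG")$normalized  # exactly 1
#' @export
tcrmatchScore <- function(seq1, seq2, matrix = .defaultKernel(),
                          norm = c("geometric", "product")) {
  norm <- match.arg(norm)
  stopifnot(is(matrix, "KernelMatrix"))
  e <- .encodeSeqs(c(seq1, seq2))
  raw <- cpp_kernel_raw(e[[1]], e[[2]], matrix@values)
  k11 <- cpp_kernel_raw(e[[1]], e[[1]], matrix@values)
  k22 <- cpp_kernel_raw(e[[2]], e[[2]], matrix@values)
  denom <- if (norm == "geometric") sqrt(k11 * k22) else k11 * k22
  list(raw = raw, normalized = raw / denom)
}

#' Normalized score matrix between two sequence sets
#'
#' Entry (i, j) is `tcrmatchScore(queries[i], references[j])$normalized`;
#' row and column order follow the inputs.
#'
#' @param queries,references character vectors of CDR3 sequences.
#' @inheritParams tcrmatchScore
#' @return numeric matrix `length(queries)` x `length(references)`, with
#'   the input sequences as dimnames.
#' @export
scoreMatrix <- function(queries, references, matrix = .defaultKernel(),
                        norm = c("geometric", "product")) {
  norm <- match.arg(norm)
  stopifnot(is(matrix, "KernelMatrix"))
  if (length(queries) == 0L || length(references) == 0L)
    stop("'queries' and 'references' must be non-empty")
  eq <- tryCatch(.encodeSeqs(queries),
                 error = function(e) stop("in 'queries': ", conditionMessage(e)))
  er <- tryCatch(.encodeSeqs(references),
                 error = function(e) stop("in 'references': ",
                                          conditionMessage(e)))
  out <- cpp_kernel_score_matrix(eq, er, matrix@values, norm == "geometric",
                                 identical(queries, references))
  dimnames(out) <- list(queries, references)
  out
}
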