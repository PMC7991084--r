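# Pinned scoring matrices.  Two distinct BLOSUM62 objects are shipped:
# the observed joint-frequency matrix (basis of the k-mer kernel) and the
# standard integer log-odds matrix (alignments, TCRdist).

.matrixCache <- new.env(parent = emptyenv())

.readSquareMatrix <- function(file) {
  m <- as.matrix(utils::read.table(file, header = TRUE, check.names = FALSE))
  stopifnot(identical(rownames(m), AA_ALPHABET),
            identical(colnames(m), AA_ALPHABET))
  m
}

#' BLOSUM62 observed joint-frequency matrix
#'
#' The 20x20 symmetric matrix of observed amino-acid pair frequencies
#' underlying BLOSUM62 (entries sum to ~1 over ordered pairs).  This is the
#' base matrix of the k-mer kernel; it is shipped as a whitespace-delimited
#' data file with rows/columns in alphabetical one-letter order.
#'
#' @return numeric 20x20 matrix.
#' @seealso [buildKernelMatrix()], [blosum62LogOdds()]
#' @export
blosum62Frequencies <- function() {
  if (is.null(.matrixCache$qij))
    .matrixCache$qij <- .readSquareMatrix(
      system.file("extdata", "blosum62_qij.txt", package = "TCRMatchR",
                  mustWork = TRUE))
  .matrixCache$qij
}

#' BLOSUM62 integer log-odds matrix
#'
#' The standard half-bit BLOSUM62 substitution matrix used for
#' Needleman-Wunsch alignment and the TCRdist mismatch cost; distinct from
#' the frequency matrix used by the kernel.
#'
#' @return integer 20x20 matrix.
#' @export
blosum62LogOdds <- function() {
  if (is.null(.matrixCache$lod)) {
    m <- .readSquareMatrix(
      system.file("extdata", "blosum62_logodds.txt", package = "TCRMatchR",
                  mustWork = TRUE))
    storage.mode(m) <- "integer"
    .matrixCache$lod <- m
  }
  .matrixCache$lod
}

#' Build the k-mer kernel matrix
#'
#' Raises the BLOSUM62 observed joint-frequency matrix element-wise to
#' `exponent`.  The default exponent 0.11387 is the published default of the
#' k-mer kernel method the TCRMatch score adopts; exponent 1 returns the raw
#' frequencies.
#'
#' @param exponent positive real, element-wise power.
#' @return a [KernelMatrix-class] object.
#' @examples
#' km <- buildKernelMatrix()
#' km@values["L", "L"] > km@values["L", "D"]
#' @export
buildKernelMatrix <- function(exponent = 0.11387) {
  if (!is.numeric(exponent) || length(exponent) != 1L || is.na(exponent) ||
      exponent <= 0)
    stop("'exponent' must be a single positive number")
  base <- blosum62Frequencies()
  new("KernelMatrix", values = base^exponent, exponent = exponent,
      provenance = sprintf("BLOSUM62 joint frequencies ^ %g", exponent))
}

.defaultKernel <- function() {
  if (is.null(.matrixCache$kernel))
    .matrixCache$kernel <- buildKernelMatrix()
  .matrixCache$kernel
}
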