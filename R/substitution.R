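#' The 20 standard amino acids, in the fixed alphabet order used throughout
#'
#' All positional encodings index their 20-score blocks by this order
#' (the conventional substitution-matrix row order A, R, N, D, ...).
#' The order is frozen: serialized models are only exchangeable between
#' package versions because every encoder uses it.
#'
#' @format Character vector of length 20, one-letter codes.
#' @export
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' BLOSUM62 substitution matrix over the 20 standard amino acids
#'
#' Returns the raw integer BLOSUM62 log-odds scores (no rescaling), subset
#' to the standard alphabet and ordered by [AA_ALPHABET20]. The matrix is
#' the positional residue embedding used by the encoders: column `j` of an
#' encoded sequence is the 20 scores of residue `j` against the alphabet.
#'
#' @return Symmetric 20 x 20 integer matrix with dimnames `AA_ALPHABET20`.
#' @seealso [read_substitution_matrix()] to swap in another matrix.
#' @examples
#' b <- blosum62()
#' b["A", "A"]  # 4
#' @export
blosum62 <- function() {
  env <- new.env(parent = emptyenv())
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET20, AA_ALPHABET20]
  storage.mode(m) <- "integer"
  m
}

#' Read an NCBI-style substitution matrix file
#'
#' Parses the standard whitespace-delimited scoring-matrix format (comment
#' lines starting with `#`, a header row of residue letters, one labelled
#' score row per residue). Rows/columns are subset and reordered to
#' [AA_ALPHABET20]; any extra ambiguity codes (B, Z, X, *) are dropped.
#'
#' @param path Path to the matrix file.
#' @return Symmetric 20 x 20 integer matrix ordered by [AA_ALPHABET20].
#' @export
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) stop("substitution matrix file not found: ", path)
  m <- as.matrix(utils::read.table(path, comment.char = "#", check.names = FALSE))
  if (is.null(rownames(m)) || !all(AA_ALPHABET20 %in% rownames(m)) ||
      !all(AA_ALPHABET20 %in% colnames(m)))
    stop("matrix file must contain labelled rows/columns for all 20 standard amino acids")
  m <- m[AA_ALPHABET20, AA_ALPHABET20]
  if (!isSymmetric(unname(m))) stop("substitution matrix is not symmetric")
  storage.mode(m) <- "integer"
  m
}

check_substitution_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !identical(dim(matrix), c(20L, 20L)) ||
      !identical(rownames(matrix), AA_ALPHABET20))
    stop("`matrix` must be a 20x20 substitution matrix ordered by AA_ALPHABET20")
  invisible(matrix)
}
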