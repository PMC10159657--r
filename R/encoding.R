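# Fixed maximum lengths of the two sequence blocks; together with the
# 34-residue HLA pseudo-sequence they give the frozen feature dimensions
# 20*19 + 20*11 = 600 (pair mode) and 600 + 20*34 = 1280 (pmhc mode).
CDR3B_MAX <- 19L
PEPTIDE_MAX <- 11L
PSEUDO_LEN <- 34L

#' Encode one amino-acid sequence as a flat positional BLOSUM62 vector
#'
#' Position `j` of the sequence contributes a block of 20 values: the
#' substitution-matrix scores of residue `j` against the alphabet in
#' [AA_ALPHABET20] order. Sequences shorter than `max_len` are
#' right-padded with all-zero blocks (zeros, never gap scores). Flattening
#' is position-major: entries `(j-1)*20 + 1 ... j*20` belong to position `j`.
#'
#' @param seq Single amino-acid string, `1 <= nchar(seq) <= max_len`.
#' @param max_len Padded length in residues.
#' @param matrix Substitution matrix from [blosum62()] or
#'   [read_substitution_matrix()].
#' @return Numeric vector of length `20 * max_len`.
#' @examples
#' v <- encode_sequence("GILGFVFTL", 11)
#' length(v)          # 220
#' all(v[181:220] == 0)  # padding block
#' @export
encode_sequence <- function(seq, max_len, matrix = blosum62()) {
  check_substitution_matrix(matrix)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  n <- nchar(seq)
  if (n < 1L || n > max_len)
    stop("sequence length ", n, " outside [1, ", max_len, "]")
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], AA_ALPHABET20)
  if (anyNA(idx)) stop("sequence contains a non-standard residue: ", seq)
  out <- numeric(20L * max_len)
  out[seq_len(20L * n)] <- as.numeric(matrix[, idx])
  out
}

#' Encode a CDR3beta-peptide pair (600 features)
#'
#' Concatenates the positional encodings of the CDR3beta (padded to 19
#' residues, 380 values) and the peptide (padded to 11 residues, 220
#' values). Any HLA information is ignored in this mode.
#'
#' @param cdr3b,peptide Valid amino-acid strings (8-19 and 8-11 residues).
#' @param matrix Substitution matrix.
#' @return Numeric vector of length 600 with attribute `mode = "pair"`.
#' @export
encode_pair <- function(cdr3b, peptide, matrix = blosum62()) {
  v <- c(encode_sequence(cdr3b, CDR3B_MAX, matrix),
         encode_sequence(peptide, PEPTIDE_MAX, matrix))
  stopifnot(length(v) == 600L)
  structure(v, mode_tag = "pair")
}

#' Encode a CDR3beta-peptide-HLA complex (1280 features)
#'
#' Appends the positional encoding of the 34-residue HLA pseudo-sequence
#' (680 values) to the 600-feature pair encoding.
#'
#' @param cdr3b,peptide Valid amino-acid strings.
#' @param pseudo 34-residue HLA pseudo-sequence
#'   (see [hla_pseudo_sequence()]).
#' @param matrix Substitution matrix.
#' @return Numeric vector of length 1280 with attribute `mode = "pmhc"`.
#' @export
encode_pmhc <- function(cdr3b, peptide, pseudo, matrix = blosum62()) {
  if (!is.character(pseudo) || length(pseudo) != 1L ||
      nchar(pseudo) != PSEUDO_LEN)
    stop("pseudo must be a single ", PSEUDO_LEN, "-residue string")
  v <- c(encode_pair(cdr3b, peptide, matrix),
         encode_sequence(pseudo, PSEUDO_LEN, matrix))
  stopifnot(length(v) == 1280L)
  structure(as.numeric(v), mode_tag = "pmhc")
}

#' Encode a batch of records into a feature matrix
#'
#' Row `i` of the result equals the single-record encoding of record `i`.
#' In `"pmhc"` mode each record must carry a resolvable HLA allele: its
#' pseudo-sequence is taken from `pseudo_map` after name normalisation
#' with [parse_hla_name()].
#'
#' @param records Validated pair table.
#' @param mode `"pair"` (600 features) or `"pmhc"` (1280 features).
#' @param matrix Substitution matrix.
#' @param pseudo_map Named character vector or two-column data frame
#'   mapping canonical allele names to 34-residue pseudo-sequences
#'   (required in pmhc mode); see [read_pseudo_map()].
#' @return Numeric matrix, one row per record.
#' @export
encode_batch <- function(records, mode = c("pair", "pmhc"),
                         matrix = blosum62(), pseudo_map = NULL) {
  mode <- match.arg(mode)
  assert_validated(records)
  check_substitution_matrix(matrix)
  n <- nrow(records)
  p <- if (mode == "pair") 600L else 1280L
  pseudo <- NULL
  if (mode == "pmhc") {
    if (any(is.na(records$hla)))
      stop("pmhc mode requires an HLA allele for every record (missing at row ",
           which(is.na(records$hla))[1], ")")
    pseudo <- resolve_pseudo(records$hla, pseudo_map)
  }
  out <- base::matrix(0, nrow = n, ncol = p)
  for (i in seq_len(n)) {
    out[i, ] <- tryCatch(
      if (mode == "pair")
        encode_pair(records$cdr3b[i], records$peptide[i], matrix)
      else
        encode_pmhc(records$cdr3b[i], records$peptide[i], pseudo[i], matrix),
      error = function(e) stop("record ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  rownames(out) <- rownames(records)
  out
}

#' Contact positions of the class-I pseudo-sequence
#'
#' The 34 positions (1-based, on the mature heavy chain) whose residues lie
#' within contact distance of the bound peptide, as defined for the
#' NetMHCpan pseudo-sequence. Shipped as a plain-text file so the position
#' definition is inspectable and swappable.
#'
#' @param path Optional path to an alternative position-list file (one
#'   integer per line, `#` comments allowed).
#' @return Sorted integer vector of length 34.
#' @export
pseudo_positions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pseudo_positions.txt", package = "tcrbind")
  pos <- scan(path, what = integer(), comment.char = "#", quiet = TRUE)
  if (length(pos) != PSEUDO_LEN) stop("position list must contain exactly 34 entries")
  sort(pos)
}

#' Extract the 34-residue pseudo-sequence of a class-I heavy chain
#'
#' Given the mature heavy-chain protein sequence, returns the residues at
#' the 34 peptide-contact positions, concatenated in position order. When
#' only an allele name is given, the sequence is looked up in `pseudo_map`
#' (defaulting to the bundled synthetic demonstration panel; supply a real
#' panel via [read_pseudo_map()] or full sequences via [read_hla_fasta()]).
#'
#' @param allele Optional allele name (any dialect accepted by
#'   [parse_hla_name()]).
#' @param full_sequence Optional mature heavy-chain protein string; must
#'   cover the largest contact position.
#' @param pseudo_map Allele-to-pseudo-sequence lookup used when only a name
#'   is given.
#' @param positions Contact positions, default [pseudo_positions()].
#' @return Single 34-character string.
#' @export
hla_pseudo_sequence <- function(allele = NULL, full_sequence = NULL,
                                pseudo_map = NULL,
                                positions = pseudo_positions()) {
  if (!is.null(full_sequence)) {
    full_sequence <- toupper(full_sequence)
    if (nchar(full_sequence) < max(positions))
      stop("heavy-chain sequence (", nchar(full_sequence),
           " aa) shorter than the largest contact position (", max(positions), ")")
    chars <- strsplit(full_sequence, "", fixed = TRUE)[[1]]
    ps <- paste(chars[positions], collapse = "")
    if (!grepl(sprintf("^[%s]+$", paste(AA_ALPHABET20, collapse = "")), ps))
      stop("non-standard residue at a contact position")
    return(ps)
  }
  if (is.null(allele)) stop("provide an allele name or a full_sequence")
  resolve_pseudo(allele, pseudo_map)
}

resolve_pseudo <- function(alleles, pseudo_map = NULL) {
  map <- normalize_pseudo_map(pseudo_map)
  canon <- parse_hla_name(alleles)
  ps <- unname(map[canon])
  if (anyNA(ps))
    stop("allele not present in the pseudo-sequence lookup: ",
         canon[is.na(ps)][1])
  if (any(nchar(ps) != PSEUDO_LEN))
    stop("pseudo-sequence of wrong length in lookup")
  ps
}

normalize_pseudo_map <- function(pseudo_map) {
  if (is.null(pseudo_map)) {
    path <- system.file("extdata", "hla_pseudo_synthetic.tsv",
                        package = "tcrbind")
    return(read_pseudo_map(path))
  }
  if (is.data.frame(pseudo_map))
    return(setNames(toupper(pseudo_map[[2]]), parse_hla_name(pseudo_map[[1]])))
  setNames(toupper(unname(pseudo_map)), parse_hla_name(names(pseudo_map)))
}

#' Read an allele-to-pseudo-sequence map
#'
#' Two-column whitespace- or tab-delimited text: allele name, 34-residue
#' pseudo-sequence. Lines starting with `#` are ignored. Names are
#' normalised with [parse_hla_name()].
#'
#' @param path File path.
#' @return Named character vector keyed by canonical allele name.
#' @export
read_pseudo_map <- function(path) {
  if (!file.exists(path)) stop("pseudo-map file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("pseudo-map must have two columns: allele, sequence")
  if (any(nchar(tab[[2]]) != PSEUDO_LEN))
    stop("all pseudo-sequences must have length ", PSEUDO_LEN)
  setNames(toupper(tab[[2]]), parse_hla_name(tab[[1]]))
}

#' Read HLA heavy-chain sequences from FASTA
#'
#' Record IDs must be allele names (any dialect accepted by
#' [parse_hla_name()]); sequences are taken as mature heavy chains. The
#' result is an allele-to-pseudo-sequence map ready for
#' [encode_batch()]'s pmhc mode.
#'
#' @param path FASTA file of protein sequences.
#' @param positions Contact positions, default [pseudo_positions()].
#' @return Named character vector keyed by canonical allele name.
#' @export
read_hla_fasta <- function(path, positions = pseudo_positions()) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  full <- as.character(seqs)
  names(full) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  ps <- vapply(full, function(s)
    hla_pseudo_sequence(full_sequence = s, positions = positions), "")
  setNames(unname(ps), parse_hla_name(names(full)))
}
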