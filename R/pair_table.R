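#' Construct a pair table of TCR-peptide observations
#'
#' A pair table is a plain `data.frame` with columns `cdr3b`, `peptide`,
#' `hla`, `label` and `source`; it is the package's standard container for
#' CDR3beta-peptide(-HLA) observations. `hla`, `label` and `source` may be
#' `NA`. Labels are binary: 1 = binding, 0 = non-binding.
#'
#' @param cdr3b Character vector of CDR3beta amino-acid sequences.
#' @param peptide Character vector of peptide amino-acid sequences.
#' @param hla Optional character vector of HLA allele names.
#' @param label Optional integer vector of 0/1 binding labels.
#' @param source Optional character vector of free-text source tags.
#' @return A `data.frame` with the five canonical columns.
#' @export
pair_records <- function(cdr3b, peptide, hla = NA_character_,
                         label = NA_integer_, source = NA_character_) {
  n <- length(cdr3b)
  if (length(peptide) != n) stop("cdr3b and peptide must have equal length")
  data.frame(cdr3b = toupper(as.character(cdr3b)),
             peptide = toupper(as.character(peptide)),
             hla = rep_len(as.character(hla), n),
             label = rep_len(suppressWarnings(as.integer(label)), n),
             source = rep_len(as.character(source), n),
             stringsAsFactors = FALSE)
}

# Length bounds for valid observations.
CDR3B_LEN <- c(8L, 19L)
PEPTIDE_LEN <- c(8L, 11L)

seq_ok <- function(x, bounds) {
  !is.na(x) & nchar(x) >= bounds[1] & nchar(x) <= bounds[2] &
    grepl(sprintf("^[%s]+$", paste(AA_ALPHABET20, collapse = "")), x)
}

#' Validate a single TCR-peptide observation
#'
#' A record is accepted iff the CDR3beta is 8-19 residues, the peptide is
#' 8-11 residues, both use only the 20 standard amino-acid letters
#' (uppercase), and the label, when present, is exactly 0 or 1.
#' Rejection is a value, not an error; the reason codes are
#' `"cdr3b_length"`, `"cdr3b_alphabet"`, `"peptide_length"`,
#' `"peptide_alphabet"` and `"bad_label"`.
#'
#' @param cdr3b,peptide Single amino-acid strings.
#' @param label Optional label (`NA`, 0 or 1).
#' @return List with `ok` (logical) and `reason` (character, `NA` if accepted).
#' @examples
#' validate_record("CASSLGTDTQYF", "GILGFVFTL", 1)$ok  # TRUE
#' validate_record("CASSLGT", "GILGFVFTL")$reason      # "cdr3b_length"
#' @export
validate_record <- function(cdr3b, peptide, label = NA) {
  r <- pair_records(cdr3b, peptide, label = label)
  reasons <- reject_reasons(r)
  list(ok = is.na(reasons[1]), reason = reasons[1])
}

# Vectorized reason codes; NA means the row is valid.  First failing check
# wins, in the documented order.
reject_reasons <- function(records) {
  alpha <- sprintf("^[%s]+$", paste(AA_ALPHABET20, collapse = ""))
  len_c <- !is.na(records$cdr3b) & nchar(records$cdr3b) >= CDR3B_LEN[1] &
    nchar(records$cdr3b) <= CDR3B_LEN[2]
  len_p <- !is.na(records$peptide) & nchar(records$peptide) >= PEPTIDE_LEN[1] &
    nchar(records$peptide) <= PEPTIDE_LEN[2]
  alp_c <- !is.na(records$cdr3b) & grepl(alpha, records$cdr3b)
  alp_p <- !is.na(records$peptide) & grepl(alpha, records$peptide)
  lab <- is.na(records$label) | records$label %in% c(0L, 1L)
  reason <- rep(NA_character_, nrow(records))
  reason[!lab] <- "bad_label"
  reason[!alp_p] <- "peptide_alphabet"
  reason[!len_p] <- "peptide_length"
  reason[!alp_c] <- "cdr3b_alphabet"
  reason[!len_c] <- "cdr3b_length"
  reason
}

#' Validate a pair table
#'
#' Applies [validate_record()]'s rules to every row and splits the table
#' into valid records (row order preserved) and a rejection report.
#'
#' @param records Pair table (see [pair_records()]).
#' @return List with `records` (the valid rows) and `report`, itself a list
#'   with counts `n_input`, `n_valid` and a `rejects` data frame of
#'   `(row, reason)`; `n_valid + nrow(rejects) == n_input` always holds.
#' @export
validate_pairs <- function(records) {
  records <- pair_records(records$cdr3b, records$peptide,
                          records$hla %||% NA_character_,
                          records$label %||% NA_integer_,
                          records$source %||% NA_character_)
  reason <- reject_reasons(records)
  bad <- !is.na(reason)
  valid <- records[!bad, , drop = FALSE]
  rownames(valid) <- NULL
  list(records = valid,
       report = list(n_input = nrow(records),
                     n_valid = nrow(valid),
                     rejects = data.frame(row = which(bad),
                                          reason = reason[bad],
                                          stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Contract guard used by every downstream operation: feeding unvalidated or
# invalid rows is a programming error, not a data condition.
assert_validated <- function(records, require_label = FALSE) {
  if (!is.data.frame(records) ||
      !all(c("cdr3b", "peptide") %in% names(records)))
    stop("expected a pair table with at least cdr3b and peptide columns")
  reason <- reject_reasons(pair_records(records$cdr3b, records$peptide,
                                        records$hla %||% NA,
                                        records$label %||% NA,
                                        records$source %||% NA))
  if (any(!is.na(reason)))
    stop("pair table contains invalid records (first: row ",
         which(!is.na(reason))[1], ", ", reason[!is.na(reason)][1],
         "); run validate_pairs() first")
  if (require_label && any(is.na(records$label %||% NA)))
    stop("operation requires labelled records")
  invisible(records)
}

# Canonical column names in written files.
PAIR_FILE_COLS <- c(cdr3b = "CDR3b", peptide = "epitope", hla = "HLA",
                    label = "binder", source = "source",
                    probability = "prediction_proba")

#' Read a delimited pair table
#'
#' Reads a comma- or tab-delimited text file (delimiter auto-detected from
#' the header line) with one TCR-peptide observation per row, maps columns
#' via `schema`, validates every row, and returns valid records plus the
#' rejection report. Sequences are uppercased on read. Textual label
#' dialects are not guessed: `label_map` must translate them.
#'
#' @param path File path.
#' @param schema Named character vector mapping internal fields
#'   (`cdr3b`, `peptide`, and optionally `hla`, `label`, `source`) to column
#'   names in the file. Defaults to the canonical names
#'   `CDR3b`, `epitope`, `HLA`, `binder`, `source`.
#' @param label_map Optional named numeric vector translating textual label
#'   values, e.g. `c(binder = 1, "non-binder" = 0)`.
#' @return As [validate_pairs()]: list of `records` and `report`.
#' @export
read_pair_table <- function(path, schema = NULL, label_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  raw[] <- lapply(raw, function(x) replace(x, !is.na(x) & x == "", NA))
  defaults <- c(cdr3b = "CDR3b", peptide = "epitope", hla = "HLA",
                label = "binder", source = "source")
  schema <- if (is.null(schema)) defaults else
    utils::modifyList(as.list(defaults), as.list(schema))
  schema <- unlist(schema)
  for (field in c("cdr3b", "peptide"))
    if (!schema[[field]] %in% names(raw))
      stop("missing mapped column '", schema[[field]], "' for field ", field)
  pick <- function(field) {
    col <- schema[[field]]
    if (col %in% names(raw)) raw[[col]] else NA_character_
  }
  lab <- pick("label")
  if (!all(is.na(lab))) {
    if (!is.null(label_map)) {
      known <- lab %in% names(label_map) | is.na(lab)
      if (!all(known)) stop("unparseable label value: ", lab[!known][1])
      lab <- unname(label_map[lab])
    } else {
      num <- suppressWarnings(as.numeric(lab))
      if (any(!is.na(lab) & is.na(num)))
        stop("unparseable label value: ", lab[!is.na(lab) & is.na(num)][1])
      lab <- num
    }
  } else lab <- NA_integer_
  validate_pairs(pair_records(pick("cdr3b"), pick("peptide"), pick("hla"),
                              lab, pick("source")))
}

#' Write a pair table to delimited text
#'
#' Writes the canonical column layout (`CDR3b`, `epitope`, `HLA`, `binder`,
#' `source`, optionally `prediction_proba`). Reading the file back with
#' [read_pair_table()] reproduces the records field for field.
#'
#' @param records Validated pair table.
#' @param path Output path.
#' @param probability Optional numeric vector of predicted probabilities to
#'   include as a `prediction_proba` column.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(records, path, probability = NULL, sep = ",") {
  assert_validated(records)
  out <- data.frame(records$cdr3b, records$peptide,
                    records$hla %||% NA, records$label %||% NA,
                    records$source %||% NA, stringsAsFactors = FALSE)
  names(out) <- PAIR_FILE_COLS[c("cdr3b", "peptide", "hla", "label", "source")]
  if (!is.null(probability)) {
    if (length(probability) != nrow(records))
      stop("probability length must match record count")
    out[[PAIR_FILE_COLS[["probability"]]]] <- probability
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                       na = "")
    TRUE
  }, error = function(e) stop("cannot write pair table: ", conditionMessage(e)))
  invisible(path)
}

#' Normalize an HLA allele name to 2-field (protein-level) nomenclature
#'
#' Accepts the common dialects `HLA-A*02:01`, `A*02:01`, `A*0201` and the
#' colon-free 4-digit form `A0201`, and returns the canonical
#' `HLA-<gene>*<group>:<protein>` form. Higher-resolution fields
#' (synonymous/noncoding suffixes, e.g. `:01:02N`) are truncated: the
#' pseudo-sequence is identical at protein level. Class-I genes A, B and C
#' are recognised.
#'
#' @param x Character vector of allele names.
#' @return Character vector of canonical names; errors on unparseable input.
#' @examples
#' parse_hla_name(c("A0201", "HLA-B*07:02"))  # "HLA-A*02:01" "HLA-B*07:02"
#' @export
parse_hla_name <- function(x) {
  if (length(x) == 0) return(character(0))
  x0 <- toupper(trimws(as.character(x)))
  x1 <- sub("^HLA-", "", x0)
  # colon form: A*02:01[:...], allowing 1-3 digit fields
  m_colon <- regmatches(x1, regexec("^([ABC])\\*?([0-9]{1,3}):([0-9]{1,3})(:.*)?$", x1))
  # compact form: A0201 / A*0201 (exactly 4 digits, 2+2)
  m_flat <- regmatches(x1, regexec("^([ABC])\\*?([0-9]{2})([0-9]{2})$", x1))
  out <- character(length(x1))
  for (i in seq_along(x1)) {
    mc <- m_colon[[i]]; mf <- m_flat[[i]]
    if (length(mc)) {
      out[i] <- sprintf("HLA-%s*%02d:%02d", mc[2],
                        as.integer(mc[3]), as.integer(mc[4]))
    } else if (length(mf)) {
      out[i] <- sprintf("HLA-%s*%s:%s", mf[2], mf[3], mf[4])
    } else if (is.na(x[i])) {
      out[i] <- NA_character_
    } else {
      stop("unparseable HLA allele name: '", x[i], "'")
    }
  }
  out
}
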