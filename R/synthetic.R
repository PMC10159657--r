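#' Configuration for the synthetic repertoire generator
#'
#' The generator emulates the structure of curated TCR-peptide collections:
#' a heavily imbalanced set of CDR3beta-peptide pairs (binding fraction
#' defaulting to 3.27%, the composition of the large multi-database
#' collections this pipeline targets), drawn from finite pools of distinct
#' TCRs and peptides, with binding decided by a planted, exactly checkable
#' compatibility rule: a pair binds iff the peptide carries motif k-mer
#' `i` at a fixed anchor window and the CDR3beta carries the partner k-mer
#' of rule row `i` at its own anchor window. The rule is exported with the
#' data so every downstream stage can be scored against perfect labels.
#'
#' @param n_pairs Number of pairs to generate.
#' @param binding_fraction Target fraction of binding pairs; default 0.0327.
#' @param n_distinct_peptides,n_distinct_tcrs Pool sizes.
#' @param n_motifs Number of rule rows (peptide k-mer, CDR3beta k-mer).
#' @param k Motif length; default 3.
#' @param peptide_anchor,cdr3b_anchor 1-based start of the motif window in
#'   each sequence (must fit the shortest valid sequence).
#' @param label_noise Probability of flipping each label after rule
#'   evaluation; default 0.
#' @param dominant Optional data frame (`peptide`, `n_pairs`,
#'   `binding_rate`) forwarded to [inject_dominant_peptides()].
#' @param seed Integer seed.
#' @return Object of class `"synthetic_config"` (a list).
#' @export
synthetic_config <- function(n_pairs = 10000L, binding_fraction = 0.0327,
                             n_distinct_peptides = 60L,
                             n_distinct_tcrs = 2000L, n_motifs = 4L, k = 3L,
                             peptide_anchor = 3L, cdr3b_anchor = 5L,
                             label_noise = 0, dominant = NULL, seed = 1L) {
  stopifnot(binding_fraction >= 0, binding_fraction <= 1,
            label_noise >= 0, label_noise <= 1,
            peptide_anchor + k - 1L <= PEPTIDE_LEN[1],
            cdr3b_anchor + k - 1L <= CDR3B_LEN[1])
  structure(list(n_pairs = as.integer(n_pairs),
                 binding_fraction = binding_fraction,
                 n_distinct_peptides = as.integer(n_distinct_peptides),
                 n_distinct_tcrs = as.integer(n_distinct_tcrs),
                 n_motifs = as.integer(n_motifs), k = as.integer(k),
                 peptide_anchor = as.integer(peptide_anchor),
                 cdr3b_anchor = as.integer(cdr3b_anchor),
                 label_noise = label_noise, dominant = dominant,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

random_seqs <- function(n, len_range) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(l)
    paste(sample(AA_ALPHABET20, l, replace = TRUE), collapse = ""), "")
}

implant <- function(seqs, kmers, anchor) {
  k <- nchar(kmers)
  paste0(substr(seqs, 1, anchor - 1), kmers,
         substr(seqs, anchor + k, nchar(seqs)))
}

#' Does the planted rule fire for these pairs?
#'
#' The exported ground-truth oracle: a pair fires iff for some rule row the
#' peptide's anchor window equals that row's peptide k-mer and the
#' CDR3beta's anchor window equals the row's CDR3beta k-mer. Vectorised.
#'
#' @param rule Rule table as produced by [generate_repertoire()] (columns
#'   `peptide_kmer`, `cdr3b_kmer`, plus attributes for anchors and k).
#' @param cdr3b,peptide Character vectors (recycled to equal length).
#' @return Logical vector.
#' @export
rule_fires <- function(rule, cdr3b, peptide) {
  k <- attr(rule, "k"); pa <- attr(rule, "peptide_anchor")
  ca <- attr(rule, "cdr3b_anchor")
  n <- max(length(cdr3b), length(peptide))
  cdr3b <- rep_len(cdr3b, n); peptide <- rep_len(peptide, n)
  pw <- substr(peptide, pa, pa + k - 1L)
  cw <- substr(cdr3b, ca, ca + k - 1L)
  out <- rep(FALSE, n)
  for (i in seq_len(nrow(rule)))
    out <- out | (pw == rule$peptide_kmer[i] & cw == rule$cdr3b_kmer[i])
  out
}

#' Generate a synthetic labelled repertoire with a planted binding rule
#'
#' Sequences are drawn uniformly over the 20-letter alphabet with lengths
#' uniform on the valid ranges (8-19 for CDR3beta, 8-11 for peptides).
#' The number of binding pairs is drawn Binomial(n, binding_fraction), so
#' the achieved fraction is within sampling error of the target. Binding
#' pairs are constructed by combining a motif-carrying peptide with a
#' compatible motif-carrying TCR; non-binding pairs are random pool
#' combinations on which the rule is verified not to fire. With
#' `label_noise = 0` the labels equal the rule evaluation exactly; noise
#' then flips each label independently. Every emitted record passes
#' [validate_record()].
#'
#' @param config A [synthetic_config()].
#' @return List of class `"tcr_repertoire"`: `records` (labelled pair
#'   table; noisy/injected rows flagged in `source`), `rule` (the
#'   compatibility table with anchor attributes) and `rule_fired` (logical
#'   ground truth per record, unaffected by label noise).
#' @export
generate_repertoire <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  with_seed(cf$seed, {
    rule <- data.frame(
      peptide_kmer = replicate(cf$n_motifs,
        paste(sample(AA_ALPHABET20, cf$k, replace = TRUE), collapse = "")),
      cdr3b_kmer = replicate(cf$n_motifs,
        paste(sample(AA_ALPHABET20, cf$k, replace = TRUE), collapse = "")),
      stringsAsFactors = FALSE)
    rule <- rule[!duplicated(rule$peptide_kmer), , drop = FALSE]
    attr(rule, "k") <- cf$k
    attr(rule, "peptide_anchor") <- cf$peptide_anchor
    attr(rule, "cdr3b_anchor") <- cf$cdr3b_anchor

    # Pools: half of each pool carries a motif (rule rows cycled).
    n_motif_pep <- max(nrow(rule), ceiling(cf$n_distinct_peptides / 2))
    peptides <- random_seqs(cf$n_distinct_peptides, PEPTIDE_LEN)
    pep_rule <- rep(NA_integer_, cf$n_distinct_peptides)
    motif_pep_idx <- seq_len(min(n_motif_pep, cf$n_distinct_peptides))
    pep_rule[motif_pep_idx] <- rep_len(seq_len(nrow(rule)),
                                       length(motif_pep_idx))
    peptides[motif_pep_idx] <- implant(peptides[motif_pep_idx],
      rule$peptide_kmer[pep_rule[motif_pep_idx]], cf$peptide_anchor)

    n_motif_tcr <- max(nrow(rule), ceiling(cf$n_distinct_tcrs / 2))
    tcrs <- random_seqs(cf$n_distinct_tcrs, CDR3B_LEN)
    tcr_rule <- rep(NA_integer_, cf$n_distinct_tcrs)
    motif_tcr_idx <- seq_len(min(n_motif_tcr, cf$n_distinct_tcrs))
    tcr_rule[motif_tcr_idx] <- rep_len(seq_len(nrow(rule)),
                                       length(motif_tcr_idx))
    tcrs[motif_tcr_idx] <- implant(tcrs[motif_tcr_idx],
      rule$cdr3b_kmer[tcr_rule[motif_tcr_idx]], cf$cdr3b_anchor)
    # Re-derive which pool members actually satisfy each rule row (an
    # implant can be overwritten only by itself, but random sequences may
    # also hit a motif by chance).
    pep_match <- lapply(seq_len(nrow(rule)), function(i)
      which(substr(peptides, cf$peptide_anchor,
                   cf$peptide_anchor + cf$k - 1L) == rule$peptide_kmer[i]))
    tcr_match <- lapply(seq_len(nrow(rule)), function(i)
      which(substr(tcrs, cf$cdr3b_anchor,
                   cf$cdr3b_anchor + cf$k - 1L) == rule$cdr3b_kmer[i]))
    feasible <- vapply(seq_len(nrow(rule)), function(i)
      length(pep_match[[i]]) > 0 && length(tcr_match[[i]]) > 0, NA)
    if (cf$binding_fraction > 0 && !any(feasible))
      stop("infeasible config: no pool member satisfies the planted rule")

    n_pos <- stats::rbinom(1L, cf$n_pairs, cf$binding_fraction)
    n_neg <- cf$n_pairs - n_pos
    pos_rows <- if (n_pos > 0) {
      ri <- sample(which(feasible), n_pos, replace = TRUE)
      data.frame(
        cdr3b = tcrs[vapply(ri, function(i)
          pick1(tcr_match[[i]]), 0L)],
        peptide = peptides[vapply(ri, function(i)
          pick1(pep_match[[i]]), 0L)],
        stringsAsFactors = FALSE)
    } else data.frame(cdr3b = character(0), peptide = character(0))

    neg_rows <- data.frame(cdr3b = character(0), peptide = character(0))
    while (nrow(neg_rows) < n_neg) {
      need <- n_neg - nrow(neg_rows)
      cand <- data.frame(
        cdr3b = tcrs[sample.int(length(tcrs), ceiling(need * 1.2) + 5L,
                                replace = TRUE)],
        peptide = peptides[sample.int(length(peptides),
                                      ceiling(need * 1.2) + 5L,
                                      replace = TRUE)],
        stringsAsFactors = FALSE)
      cand <- cand[!rule_fires(rule, cand$cdr3b, cand$peptide), , drop = FALSE]
      neg_rows <- rbind(neg_rows, utils::head(cand, need))
    }

    records <- pair_records(c(pos_rows$cdr3b, neg_rows$cdr3b),
                            c(pos_rows$peptide, neg_rows$peptide),
                            label = c(rep(1L, n_pos), rep(0L, n_neg)),
                            source = "synthetic")
    perm <- sample.int(nrow(records))
    records <- records[perm, , drop = FALSE]
    rownames(records) <- NULL
    fired <- rule_fires(rule, records$cdr3b, records$peptide)
    stopifnot(identical(as.integer(fired), records$label))
    if (cf$label_noise > 0) {
      flip <- stats::runif(nrow(records)) < cf$label_noise
      records$label[flip] <- 1L - records$label[flip]
      records$source[flip] <- "synthetic-noisy"
    }
    out <- structure(list(records = records, rule = rule,
                          rule_fired = fired, config = cf),
                     class = "tcr_repertoire")
    if (!is.null(cf$dominant))
      out <- inject_dominant_peptides(out, cf$dominant, seed = cf$seed + 1L)
    out
  })
}

pick1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

#' @export
print.tcr_repertoire <- function(x, ...) {
  n <- nrow(x$records)
  np <- sum(x$records$label == 1L)
  cat("Synthetic TCR-peptide repertoire: ", n, " pairs, ", np, " binding (",
      sprintf("%.2f%%", 100 * np / n), ")\n", sep = "")
  cat("Planted rule rows:", nrow(x$rule), " (k =", attr(x$rule, "k"), ")\n")
  invisible(x)
}

#' Inject high-frequency, noisy-label peptides
#'
#' Adds, for each row of `spec`, `n_pairs` new observations pairing that
#' peptide with TCRs drawn from the repertoire's pool and labelling each
#' binding with probability `binding_rate` independent of any sequence
#' signal. Such peptides emulate the dominant epitopes of curated data:
#' frequent, label-ambiguous, and a known positive control for
#' [fp_attribution()] and [ratio_titration()].
#'
#' @param x A `"tcr_repertoire"` (or a plain pair table).
#' @param spec Data frame with columns `peptide`, `n_pairs`,
#'   `binding_rate`; an empty spec returns the input unchanged.
#' @param seed Integer seed.
#' @return Same class as `x`, with injected records appended
#'   (`source = "dominant-injected"`; `rule_fired` extended with the true
#'   rule evaluation for the new rows when `x` is a repertoire).
#' @export
inject_dominant_peptides <- function(x, spec, seed = 1L) {
  records <- if (inherits(x, "tcr_repertoire")) x$records else x
  assert_validated(records)
  if (is.null(spec) || nrow(spec) == 0) return(x)
  stopifnot(all(c("peptide", "n_pairs", "binding_rate") %in% names(spec)))
  bad <- reject_reasons(pair_records(rep("CASSLGTDTQYF", nrow(spec)),
                                     spec$peptide))
  if (any(!is.na(bad))) stop("invalid peptide in dominant spec")
  pool <- unique(records$cdr3b)
  new <- with_seed(seed, do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    n <- spec$n_pairs[i]
    pair_records(pool[sample.int(length(pool), n, replace = TRUE)],
                 rep(spec$peptide[i], n),
                 label = stats::rbinom(n, 1L, spec$binding_rate[i]),
                 source = "dominant-injected")
  })))
  combined <- rbind(records, new)
  rownames(combined) <- NULL
  if (inherits(x, "tcr_repertoire")) {
    x$records <- combined
    x$rule_fired <- c(x$rule_fired, rule_fires(x$rule, new$cdr3b, new$peptide))
    x
  } else combined
}

#' Generate a synthetic panel of class-I HLA alleles
#'
#' Emits `n_alleles` alleles with fictitious names (experimental-range
#' `HLA-A*90:xx` nomenclature, so they cannot be mistaken for real typing
#' results) and random heavy-chain sequences long enough to cover all 34
#' contact positions. Panels are pairwise distinct at one or more contact
#' positions, so their pseudo-sequences are distinct.
#'
#' @param n_alleles Number of alleles (>= 1).
#' @param seed Integer seed.
#' @param chain_length Heavy-chain length; default 275 (covers the largest
#'   contact position with margin).
#' @return Data frame with columns `allele`, `full_sequence`,
#'   `pseudo_sequence` (34 residues each).
#' @export
generate_hla_panel <- function(n_alleles, seed = 1L, chain_length = 275L) {
  stopifnot(n_alleles >= 1)
  pos <- pseudo_positions()
  stopifnot(chain_length >= max(pos))
  with_seed(seed, {
    repeat {
      seqs <- vapply(seq_len(n_alleles), function(i)
        paste(sample(AA_ALPHABET20, chain_length, replace = TRUE),
              collapse = ""), "")
      ps <- vapply(seqs, function(s)
        hla_pseudo_sequence(full_sequence = s, positions = pos), "",
        USE.NAMES = FALSE)
      if (!anyDuplicated(ps)) break
    }
    data.frame(allele = sprintf("HLA-A*90:%02d", seq_len(n_alleles)),
               full_sequence = seqs, pseudo_sequence = ps,
               stringsAsFactors = FALSE)
  })
}
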