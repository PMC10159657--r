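test_that("positional encoding places scores and zero padding correctly", {
  b <- blosum62()
  # single residue at max_len 1: the BLOSUM62 column of A; (A,A) = 4
  v <- encode_sequence("A", 1, b)
  expect_equal(v, unname(as.numeric(b[, "A"])))
  expect_equal(v[1], 4)

  # 9-mer padded to 11: 220 values, final 40 exactly zero
  v9 <- encode_sequence("GILGFVFTL", 11, b)
  expect_length(v9, 220)
  expect_true(all(v9[181:220] == 0))
  expect_false(all(v9[161:180] == 0))  # position 9 carries scores

  # full-length 19-mer: no padding block
  v19 <- encode_sequence(strrep("C", 19), 19, b)
  expect_length(v19, 380)
  # every position block carries scores (no padding)
  expect_true(all(vapply(1:19, function(j)
    any(v19[((j - 1) * 20 + 1):(j * 20)] != 0), NA)))
  # position-major flattening: block j is the matrix column of residue j
  seq <- "ARNDY"
  v5 <- encode_sequence(seq, 6, b)
  for (j in 1:5) {
    res <- substr(seq, j, j)
    expect_equal(v5[((j - 1) * 20 + 1):(j * 20)], unname(as.numeric(b[, res])))
  }
  expect_error(encode_sequence(strrep("A", 12), 11), "outside")
  expect_error(encode_sequence("GILGFVFTX", 11), "non-standard")
})

test_that("pair and pmhc encodings have the frozen dimensions", {
  set.seed(21)
  for (i in 1:10) {
    cd <- random_cdr3b(); pep <- random_peptide()
    v <- encode_pair(cd, pep)
    expect_length(v, 600)
    # deterministic
    expect_identical(v, encode_pair(cd, pep))
  }
  # 8-aa CDR3b: positions 9..19 of the TCR block (entries 161..380) are zero
  v8 <- encode_pair(strrep("A", 8), "GILGFVFTL")
  expect_true(all(v8[161:380] == 0))
  expect_false(all(v8[141:160] == 0))

  ps <- strrep("ARNDYWKCQV", 4) |> substr(1, 34)
  vp <- encode_pmhc("CASSLGTDTQYF", "GILGFVFTL", ps)
  expect_length(vp, 1280)
  expect_length(encode_sequence(ps, 34), 680)
  expect_identical(as.numeric(vp[1:600]),
                   as.numeric(encode_pair("CASSLGTDTQYF", "GILGFVFTL")))
  expect_error(encode_pmhc("CASSLGTDTQYF", "GILGFVFTL", "SHORT"), "34")
})

test_that("encoding is injective on equal-length sequence pairs", {
  set.seed(33)
  pairs <- unique(data.frame(cdr3b = random_cdr3b(40, len = 12),
                             peptide = random_peptide(40, len = 9)))
  vecs <- apply(pairs, 1, function(r) encode_pair(r[["cdr3b"]], r[["peptide"]]))
  expect_false(any(duplicated(t(vecs))))
})

test_that("batch encoding equals per-record encoding row by row", {
  rec <- toy_records(5)
  m <- encode_batch(rec, "pair")
  expect_equal(dim(m), c(5, 600))
  for (i in 1:5)
    expect_equal(m[i, ], as.numeric(encode_pair(rec$cdr3b[i], rec$peptide[i])))
  # a bad record aborts naming its row
  bad <- rec; bad$peptide[3] <- "GILGFVF"  # too short
  expect_error(encode_batch(bad), "row 3|record 3|invalid")
})

test_that("pmhc batch encoding resolves alleles through the lookup", {
  panel <- generate_hla_panel(3, seed = 14)
  map <- setNames(panel$pseudo_sequence, panel$allele)
  rec <- toy_records(4)
  rec$hla <- c(panel$allele[c(1, 2, 3)], "A9001")  # dialect of allele 1
  m <- encode_batch(rec, "pmhc", pseudo_map = map)
  expect_equal(dim(m), c(4, 1280))
  expect_equal(m[4, 601:1280], m[1, 601:1280])  # same allele, same HLA block
  rec$hla[2] <- NA
  expect_error(encode_batch(rec, "pmhc", pseudo_map = map), "requires an HLA")
})

test_that("pseudo-sequences extract the 34 contact residues", {
  pos <- pseudo_positions()
  expect_length(pos, 34)
  panel <- generate_hla_panel(5, seed = 2)
  expect_equal(nrow(panel), 5)
  expect_true(all(nchar(panel$pseudo_sequence) == 34))
  expect_false(any(duplicated(panel$pseudo_sequence)))
  # the pseudo-sequence is a pure function of the contact residues
  chars <- strsplit(panel$full_sequence[1], "")[[1]]
  expect_equal(panel$pseudo_sequence[1], paste(chars[pos], collapse = ""))
  other <- panel$full_sequence[2]
  spliced <- strsplit(other, "")[[1]]
  spliced[pos] <- chars[pos]
  expect_equal(hla_pseudo_sequence(full_sequence = paste(spliced, collapse = "")),
               panel$pseudo_sequence[1])
  # truncated chain errors
  expect_error(hla_pseudo_sequence(full_sequence = strrep("A", 50)),
               "shorter than")
  # determinism of the panel
  expect_identical(panel, generate_hla_panel(5, seed = 2))
})

test_that("bundled synthetic lookup and FASTA reader agree on pseudo-sequences", {
  map_file <- system.file("extdata", "hla_pseudo_synthetic.tsv",
                          package = "tcrbind")
  map <- read_pseudo_map(map_file)
  expect_true(all(nchar(map) == 34))
  expect_equal(unname(hla_pseudo_sequence("HLA-A*90:01")),
               unname(map[["HLA-A*90:01"]]))
  # FASTA round trip through full sequences
  panel <- generate_hla_panel(3, seed = 8)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(paste0(">", panel$allele, "\n", panel$full_sequence), fa)
  from_fasta <- read_hla_fasta(fa)
  expect_equal(unname(from_fasta[panel$allele]), panel$pseudo_sequence)
})

test_that("substitution matrices are swappable via the NCBI file format", {
  b <- blosum62()
  expect_true(isSymmetric(unname(b)))
  expect_equal(b["A", "A"], 4L)
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# test matrix",
               paste(c(" ", colnames(b)), collapse = " "),
               vapply(rownames(b), function(r)
                 paste(c(r, b[r, ]), collapse = " "), "")), path)
  expect_equal(read_substitution_matrix(path), b)
  # a swapped matrix changes the encoding
  m2 <- b; m2["A", "A"] <- 9L
  expect_false(identical(encode_sequence("ARN", 3, m2),
                         encode_sequence("ARN", 3, b)))
})
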