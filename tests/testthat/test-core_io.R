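test_that("variant tokens parse over the documented grammar", {
  v <- parse_variant("A45C")
  expect_equal(v$wt, "A")
  expect_equal(v$pos, 45L)
  expect_equal(v$mut, "C")
  expect_false(v$identity)

  low <- parse_variant("g1g")
  expect_equal(low$wt, "G")
  expect_equal(low$mut, "G")
  expect_true(low$identity)

  expect_error(parse_variant("A0C"), "position")
  expect_error(parse_variant("45C"), "malformed")
  expect_error(parse_variant("A45"), "malformed")
  expect_error(parse_variant("A45CC"), "malformed")
  for (bad in c("B", "J", "O", "U", "X", "Z")) {
    expect_error(parse_variant(paste0(bad, "10A")), "non-standard")
    expect_error(parse_variant(paste0("A10", bad)), "non-standard")
  }
})

test_that("variant parsing is total over the grammar and rejects junk", {
  set.seed(11)
  for (i in 1:50) {
    wt <- sample(AA_ALPHABET, 1)
    mut <- sample(AA_ALPHABET, 1)
    pos <- sample.int(5000, 1)
    tok <- paste0(wt, pos, mut)
    v <- parse_variant(tok)
    expect_equal(format(v), tok)
  }
  for (junk in c("", "A-3C", "A3.5C", "AA45C", "45", "A 45C", "#45C")) {
    expect_error(parse_variant(junk))
  }
})

test_that("aligned FASTA round-trips and validates", {
  aln <- new_alignment(ids = c("query", "h1", "h2"),
                       rows = c("AC-GT-KLMN", "ACWGTPKLMN", "AC-GT-KL-N"))
  expect_equal(aln$width, 10L)
  expect_equal(aln$query_seq, "ACGTKLMN")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  back <- read_alignment(path)
  expect_equal(back$ids, aln$ids)
  expect_equal(back$rows, aln$rows)
  expect_equal(back$query_seq, aln$query_seq)

  by_id <- read_alignment(path, query_id = "h1")
  expect_equal(by_id$query_index, 2L)
  expect_error(read_alignment(path, query_id = "nope"), "not found")

  expect_error(new_alignment(c("a", "b"), c("ACDEFGHIKL", "ACDEFGHIK")),
               "ragged")
})

test_that("PDB structures parse with altloc and backbone rules", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CA ASER A   2       4.000   2.000   0.000  0.60  0.00           C",
    "ATOM      6  CA BSER A   2       9.000   9.000   9.000  0.40  0.00           C",
    "ATOM      7  N   GLY A   3       6.000   3.000   0.000  1.00  0.00           N",
    "HETATM    8 ZN    ZN A  90      20.000  20.000  20.000  1.00  0.00          ZN",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  s <- read_structure(path)
  expect_s3_class(s, "varmod_structure")
  expect_equal(nrow(s$residues), 3L)
  # altloc A (occupancy 0.6) retained
  ca2 <- s$atoms[s$atoms$seq_pos == 2 & s$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca2), 1L)
  expect_equal(ca2$x, 4.0)
  # HETATM dropped unless requested
  expect_false(any(s$atoms$het))
  s_zn <- read_structure(path, keep_hetatm_names = "ZN")
  expect_true(any(s_zn$atoms$het))
  # residue 3 lacks CA: retained but flagged
  expect_true(s$residues$has_ca[s$residues$seq_pos == 1])
  expect_false(s$residues$has_ca[s$residues$seq_pos == 3])
  expect_true(s$residues$has_backbone[s$residues$seq_pos == 1])
  expect_false(s$residues$has_backbone[s$residues$seq_pos == 2])

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty), "no ATOM records")
})

test_that("structures round-trip through PDB text", {
  h <- make_helix(8, sequence = "ACDEFGHI")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h, path)
  back <- read_structure(path)
  expect_equal(back$residues$res_name, h$residues$res_name)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(h$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("variant validation reports mismatches and continues", {
  vs <- list(new_variant("A", 1, "C"), new_variant("K", 1, "C"),
             new_variant("A", 9, "C"))
  res <- validate_variants(vs, "AKL")
  expect_equal(res$valid, c(TRUE, FALSE, FALSE))
  expect_match(res$reason[2], "variant says K, query has A")
  expect_match(res$reason[3], "beyond query length")
})

test_that("site annotations and labelled variants round-trip", {
  sites <- list(new_site("ligand", c(4, 5, 6), 12, 0.8),
                new_site("interface", c(10, 12), 3, 0.1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sites(sites, path)
  back <- read_sites(path)
  expect_equal(back, sites)

  lab <- data.frame(protein_id = c("p1", "p1", "p2"),
                    wt = c("A", "K", "G"), pos = c(1L, 5L, 3L),
                    mut = c("C", "R", "W"), label = c(1L, 0L, 1L),
                    stringsAsFactors = FALSE)
  lpath <- withr::local_tempfile(fileext = ".tsv")
  write_labelled_variants(lab, lpath)
  expect_equal(read_labelled_variants(lpath), lab)

  expect_error(new_site("ligand", integer()), "length")
})
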