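test_that("FASTA reading takes the first header token as id and validates the alphabet", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MARKST", "RKPLE",
               ">p2", "STY"), f)
  recs <- read_fasta(f)
  expect_named(recs, c("p1", "p2"))
  expect_equal(recs$p1$sequence, "MARKSTRKPLE")
  expect_equal(nchar(recs$p1$sequence), 11)

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_length(read_fasta(empty), 0)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MAB"), bad)
  expect_error(read_fasta(bad), "illegal residue")
  expect_warning(recs2 <- read_fasta(bad, on_illegal = "drop"), "dropping")
  expect_length(recs2, 0)
})

test_that("site tables are validated against the protein sequences", {
  prot <- list(p1 = protein_record("p1", "MARKSTRKPLE"))
  ok <- phospho_sites("p1", 6, "T", "PKA", "positive", proteins = prot)
  expect_equal(nrow(ok), 1)
  expect_error(phospho_sites("p1", 5, "T", "PKA", "positive",
                             proteins = prot), "does not match")
  expect_error(phospho_sites("p1", 99, "S", "PKA", "positive",
                             proteins = prot), "outside protein")

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tresidue\tkinase_group\tlabel",
               "p1\t6\tT\tPKA\tpositive",
               "p1\t5\tS\tPKA\tnegative"), f)
  tab <- read_site_table(f, prot)
  expect_equal(tab$position, c(6L, 5L))
  round <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(tab, round)
  expect_equal(read_site_table(round, prot), tab)
})

test_that("window extraction pads with the terminal symbol and round-trips", {
  p <- protein_record("p1", "MARKSTRKPLE")
  expect_equal(extract_window(p, 6), "-MARKSTRKPLE-")
  p13 <- protein_record("p2", "AAAAAASAAAAAA")
  expect_equal(extract_window(p13, 7), p13$sequence)
  expect_error(extract_window(p, 2), "not S/T/Y")

  # stripping terminal symbols recovers the exact subsequence, any position
  set.seed(42)
  seqs <- paste(sample(AA20, 80, replace = TRUE), collapse = "")
  prot <- protein_record("r", seqs)
  for (pos in which(seq_chars(seqs) %in% c("S", "T", "Y"))) {
    win <- extract_window(prot, pos)
    core <- gsub("-", "", win, fixed = TRUE)
    lo <- max(1, pos - 6); hi <- min(80, pos + 6)
    expect_equal(core, substr(seqs, lo, hi))
  }
})

test_that("negative sites are exactly the unannotated acceptor residues", {
  p <- protein_record("p1", "MARKSTRKPLE")
  neg <- build_negative_set(p, 6)
  expect_equal(neg$position, 5L)
  expect_equal(neg$residue, "S")
  expect_equal(nrow(build_negative_set(protein_record("x", "MARK"), integer())), 0)
  expect_equal(nrow(build_negative_set(p, c(5, 6))), 0)

  set.seed(7)
  seqs <- paste(sample(AA20, 60, replace = TRUE), collapse = "")
  prot <- protein_record("r", seqs)
  sty <- which(seq_chars(seqs) %in% c("S", "T", "Y"))
  pos <- sample(sty, min(3, length(sty)))
  neg <- build_negative_set(prot, pos)
  expect_setequal(c(neg$position, pos), sty)
  expect_length(intersect(neg$position, pos), 0)
})

test_that("PDB structures round-trip through write/read within 1e-3 Angstrom", {
  skip_if_not_installed("bio3d")
  s <- random_structure(15, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_structure(s, f)
  s2 <- read_pdb_structure(f)
  expect_equal(s2$atoms$aa, s$atoms$aa)
  expect_equal(s2$atoms$resno, s$atoms$resno)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("PDB parsing keeps the first altloc and rejects HETATM-only files", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0, alt = "A"),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 9.9, 9.9, 9.9, alt = "B"),
    pdb_atom_line(4, "CA", "HOH", "A", 3, 1, 1, 1, record = "HETATM"),
    "END"), f)
  s <- read_pdb_structure(f)
  expect_equal(nrow(s$atoms), 2)          # water dropped, one altloc kept
  expect_equal(s$atoms$x[s$atoms$resno == 2], 3.8)

  het <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0,
                             record = "HETATM"), "END"), het)
  expect_error(read_pdb_structure(het))
})

test_that("DSSP parsing normalises ASA and collapses secondary structure", {
  f <- withr::local_tempfile(fileext = ".dssp")
  dssp_file(c(dssp_line(1, 1, "A", "A", "H", 0),
              dssp_line(2, 2, "A", "G", "G", 999),
              dssp_line(3, 3, "A", "S", "E", 78),
              dssp_line(4, 4, "A", "L", " ", 50)), f)
  ann <- read_dssp(f)
  expect_equal(ann$asa_rel[1], 0)
  expect_equal(ann$asa_rel[2], 1)                   # clamped at maxASA
  expect_equal(ann$ss3, c("H", "H", "E", "C"))      # G -> H, blank -> C
  expect_equal(ann$asa_rel[3], 78 / MAX_ASA[["S"]])
  expect_true(all(ann$asa_rel >= 0 & ann$asa_rel <= 1))

  nohdr <- withr::local_tempfile(fileext = ".dssp")
  writeLines("not a dssp file", nohdr)
  expect_error(read_dssp(nohdr), "header")
})

test_that("sites map onto identical chains with identity 1 and miss absent windows", {
  set.seed(9)
  seqs <- paste(sample(AA20, 40, replace = TRUE), collapse = "")
  seqs <- paste0(substr(seqs, 1, 19), "S", substr(seqs, 21, 40))
  prot <- protein_record("p", seqs)
  s <- random_structure(40, seed = 10)
  s$atoms$aa <- seq_chars(seqs)
  site <- list(position = 20L, residue = "S")
  m <- map_site_to_structure(prot, site, s)
  expect_equal(m$identity, 1)
  expect_equal(m$residue_number, 20)

  other <- random_structure(40, seed = 11)  # unrelated sequence
  expect_null(map_site_to_structure(prot, site, other))

  # two identical chains: tie broken by first chain id
  twoc <- s
  b <- s$atoms; b$chain <- "B"
  twoc$atoms <- rbind(s$atoms, b)
  m2 <- map_site_to_structure(prot, site, twoc)
  expect_equal(m2$chain_id, "A")
})
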