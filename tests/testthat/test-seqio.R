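test_that("FASTA parsing handles single records, wrapped lines and headers", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDE"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, "p1")
  expect_equal(rec$sequence, "ACDE")
  expect_equal(rec$length, 4L)

  writeLines(c(">p1 some description", "AC", "DE", ">p2", "KKKK"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("p1", "p2"))
  expect_equal(rec$sequence, c("ACDE", "KKKK"))
})

test_that("FASTA write/read round-trips 50 synthetic records", {
  set.seed(42)
  prots <- tibble::tibble(
    id = sprintf("prot%02d", 1:50),
    sequence = vapply(sample(15:80, 50, replace = TRUE), random_protein, character(1))
  )
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(prots, f, width = 60)
  back <- read_fasta(f)
  expect_equal(back$id, prots$id)
  expect_equal(back$sequence, prots$sequence)
})

test_that("FASTA errors: empty file, duplicate ids, bad residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "no records")

  writeLines(c(">a", "ACDE", ">a", "KKKK"), f)
  expect_error(read_fasta(f), "duplicate.*a")

  writeLines(c(">p1", "ACBDE"), f)
  expect_error(read_fasta(f, lenient = FALSE), "position 3.*p1")
  expect_warning(rec <- read_fasta(f, lenient = TRUE), "non-standard")
  expect_equal(rec$sequence, "ACXDE")
})

test_that("pair tables parse, coerce labels and reject bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\tp2\t1", f)
  tab <- read_pair_table(f)
  expect_equal(tab$label, 1L)

  writeLines(c("a,b,0", "b,c,1"), f)
  tab <- read_pair_table(f, delimiter = ",")
  expect_equal(tab$label, c(0L, 1L))
  expect_equal(tab$id_a, c("a", "b"))

  writeLines(c("id_a\tid_b\tlabel", "x\ty\t+1", "y\tz\t-1"), f)
  tab <- read_pair_table(f)
  expect_equal(tab$label, c(1L, 0L))

  writeLines("p1\tp2\t2", f)
  expect_error(read_pair_table(f), "row 1")
  writeLines(c("a\tb\t1", "c\td"), f)
  expect_error(read_pair_table(f), "row 2")
})

test_that("pair table writer/reader is identity on valid tables", {
  pairs <- tibble::tibble(id_a = c("a", "b"), id_b = c("b", "c"), label = c(1L, 0L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(pairs, f)
  expect_equal(read_pair_table(f), pairs)
})

test_that("PSSM ASCII writer/parser round-trips and reconstructs the query", {
  set.seed(7)
  seq <- random_protein(5)
  p <- structure(list(
    protein_id = "p5",
    residues = strsplit(seq, "")[[1]],
    scores = matrix(sample(-10:10, 100, replace = TRUE), 5, 20,
                    dimnames = list(NULL, c("A","R","N","D","C","Q","E","G","H","I",
                                            "L","K","M","F","P","S","T","W","Y","V")))
  ), class = "pssm")
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(p, f)
  back <- read_pssm(f, protein_id = "p5")
  expect_equal(unname(back$scores), unname(p$scores))
  expect_true(all(back$scores == round(back$scores)))
  expect_equal(pssm_sequence(back), seq)
})

test_that("PSSM parser tolerates ragged whitespace and missing trailer", {
  lines <- c(
    "Banner line",
    paste(c(rep("A", 40)), collapse = "  "),
    "  1 M   1 2 3 4 5 6 7 8 9 10 11 12 13 14 15 16 17 18 19 20  0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0.1 0.2",
    "    2  K    1  1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1   0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0.1 0.2"
  )
  f <- withr::local_tempfile(fileext = ".pssm")
  writeLines(lines, f)
  p <- read_pssm(f)
  expect_equal(dim(p$scores), c(2L, 20L))
  expect_equal(p$scores[1, ], setNames(as.numeric(1:20), colnames(p$scores)))
  expect_equal(p$residues, c("M", "K"))
})

test_that("PSSM parser errors on truncated rows and empty files", {
  f <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c("banner", "  1 M  1 2 3 4 5"), f)
  expect_error(read_pssm(f), "row 1.*fewer than 20")
  writeLines(c("banner only"), f)
  expect_error(read_pssm(f), "no PSSM data rows")
})

test_that("feature matrix CSV round-trips with names and id columns", {
  ft <- tibble::tibble(protein_id = c("a", "b"),
                       pseaac_comp_A = c(0.25, 0.5),
                       ad_mba_polarity_1 = c(-1.5, 2.25))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(ft, f)
  expect_equal(read_feature_matrix(f), ft)
})

test_that("model serialization embeds and checks a schema version", {
  f <- withr::local_tempfile(fileext = ".model")
  save_model(list(a = 1), f)
  expect_equal(load_model(f), list(a = 1))
  saveRDS(list(no_schema = TRUE), f)
  expect_error(load_model(f), "schema")
})
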