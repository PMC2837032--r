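test_that("count tables read with validated column sums as totals", {
  path <- write_tsv_lines(c("contig_id\thits_d\thits_l",
                            "c1\t40\t1", "c2\t68\t2", "c3\t3\t171"))
  ct <- read_count_table(path)
  expect_equal(unname(ct$totals), c(111, 174))
  expect_false(ct$totals_overridden)
  expect_identical(ct$counts$contig_id, c("c1", "c2", "c3"))  # order kept

  empty <- read_count_table(write_tsv_lines("contig_id\thits_d\thits_l"))
  expect_equal(nrow(empty$counts), 0)
  expect_equal(unname(empty$totals), c(0, 0))
})

test_that("count-table totals can be overridden for subset analyses", {
  path <- write_tsv_lines(c("contig_id\thits_d\thits_l", "c1\t40\t1"))
  ct <- read_count_table(path, totals = c(125456, 99632))
  expect_equal(unname(ct$totals), c(125456, 99632))
  expect_true(ct$totals_overridden)
  expect_error(read_count_table(path, totals = c(10, 99632)),
               "smaller than the column sums")
})

test_that("malformed count tables are rejected with the offending entry named", {
  dup <- write_tsv_lines(c("contig_id\thits_d\thits_l",
                           "c1\t1\t0", "c2\t2\t2", "c1\t3\t1"))
  expect_error(read_count_table(dup), "c1")
  neg <- write_tsv_lines(c("contig_id\thits_d\thits_l", "c1\t-1\t0"))
  expect_error(read_count_table(neg), "hits_d")
  frac <- write_tsv_lines(c("contig_id\thits_d\thits_l", "c1\t1.5\t0"))
  expect_error(read_count_table(frac), "hits_d")
  miss <- write_tsv_lines(c("contig_id\thits_d", "c1\t1"))
  expect_error(read_count_table(miss), "hits_l")
})

test_that("count tables round-trip through write/read exactly", {
  ct <- tiny_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, path)
  back <- read_count_table(path)
  expect_identical(back$counts, ct$counts)
  expect_identical(back$totals, ct$totals)
})

test_that("annotation tables parse pipe-separated GO terms and flag bad ids", {
  path <- write_tsv_lines(c(
    "contig_id\taccession\tdescription\tgo_terms\tko_id",
    "c1\tP36618\tCDC16\tGO:0008219|GO:0048468\tK00001",
    "c2\t\t\t\t"))
  ann <- read_annotation_table(path)
  expect_identical(ann$go_terms[[1]], c("GO:0008219", "GO:0048468"))
  expect_identical(ann$accession[2], "")
  expect_length(ann$go_terms[[2]], 0)

  bad <- write_tsv_lines(c("contig_id\taccession\tdescription\tgo_terms",
                           "c1\tP1\tx\tGO:12"))
  expect_error(read_annotation_table(bad), "GO")
  dup <- write_tsv_lines(c("contig_id\taccession\tdescription\tgo_terms",
                           "c1\tP1\tx\t", "c1\tP2\ty\t"))
  expect_error(read_annotation_table(dup), "duplicate")
})

test_that("annotation round-trips through write_annotation_table", {
  ann <- make_annotations(c("c1", "c2"),
                          list(c("GO:0008219", "GO:0016265"), character(0)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ann, path)
  back <- read_annotation_table(path)
  expect_identical(back$go_terms, ann$go_terms)
  expect_identical(back$accession, ann$accession)
})

test_that("prior edges deduplicate undirected pairs keeping max probability", {
  path <- write_tsv_lines(c(
    "accession_a\taccession_b\tprobability\tprovenance",
    "P36618\tP20072\t0.95\tfixture",
    "P20072\tP36618\t0.40\tfixture",   # same pair, other orientation
    "P18281\tP34121\t0.50\tfixture"))
  pe <- read_prior_edges(path)
  expect_equal(nrow(pe), 2)
  row <- pe[pe$accession_a == "P20072", ]
  expect_equal(row$probability, 0.95)

  self <- write_tsv_lines(c("accession_a\taccession_b\tprobability",
                            "P36618\tP36618\t0.5"))
  expect_error(read_prior_edges(self), "self-edge")
  oob <- write_tsv_lines(c("accession_a\taccession_b\tprobability",
                           "A\tB\t1.5"))
  expect_error(read_prior_edges(oob), "probability")
})

test_that("FASTA reading maps first header token to sequence", {
  path <- write_tsv_lines(c(">c1 some description", "ACGT", ">c2", "AA"))
  fa <- read_fasta(path)
  expect_identical(fa, c(c1 = "ACGT", c2 = "AA"))
  empty <- write_tsv_lines(c(">c1", "", ">c2", "A"))
  expect_error(read_fasta(empty))
})
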