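test_that("FASTA parsing preserves order, uppercases and validates ids", {
  path <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">X first protein", "mkvl", ">Y", "ACDE"), path)
  recs <- read_fasta(path, "protein")
  expect_equal(recs$id, c("X", "Y"))
  expect_equal(recs$seq, c("MKVL", "ACDE"))
  expect_equal(recs$desc[1], "first protein")

  dup <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">HSP70", "ACDE", ">HSP70", "ACDF"), dup)
  expect_error(read_fasta(dup), "HSP70")

  empty <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(), empty)
  expect_equal(nrow(read_fasta(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".faa")
  writeLines(c("not a header", "ACDE"), bad)
  expect_error(read_fasta(bad), "line 1")
})

test_that("FASTA write-then-read is the identity", {
  withr::with_seed(7, {
    for (case in 1:5) {
      n <- sample(1:8, 1)
      x <- seq_tbl(paste0("s", seq_len(n)),
                   vapply(seq_len(n), function(i) rand_prot(sample(5:200, 1)),
                          character(1)),
                   "protein",
                   desc = sample(c("", "some desc"), n, replace = TRUE))
      path <- withr::local_tempfile(fileext = ".faa")
      write_fasta(x, path)
      expect_equal(read_fasta(path, "protein"), x)
    }
  })
})

test_that("GFF3 gene models: exon counts, isoform choice, error semantics", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "2\tsrc\tgene\t100\t1000\t.\t+\t.\tID=g1",
    "2\tsrc\tmRNA\t100\t1000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "2\tsrc\texon\t100\t200\t.\t+\t.\tID=e1;Parent=g1.t1",
    "2\tsrc\texon\t300\t400\t.\t+\t.\tID=e2;Parent=g1.t1",
    "2\tsrc\texon\t500\t600\t.\t+\t.\tID=e3;Parent=g1.t1",
    "2\tsrc\texon\t700\t1000\t.\t+\t.\tID=e4;Parent=g1.t1",
    "2\tsrc\tCDS\t100\t200\t.\t+\t0\tID=c1;Parent=g1.t1"
  ), gff)
  models <- read_gff3(gff)
  expect_equal(models$chromosome, "2")
  expect_equal(exon_count(models)$exon_count, 4L)

  # two isoforms: summed CDS 300 vs 450; the 450 isoform's exons win
  iso <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\tsrc\tgene\t1\t2000\t.\t+\t.\tID=g2",
    "1\tsrc\tmRNA\t1\t2000\t.\t+\t.\tID=g2.t1;Parent=g2",
    "1\tsrc\texon\t1\t300\t.\t+\t.\tID=x1;Parent=g2.t1",
    "1\tsrc\tCDS\t1\t300\t.\t+\t0\tID=y1;Parent=g2.t1",
    "1\tsrc\tmRNA\t1\t2000\t.\t+\t.\tID=g2.t2;Parent=g2",
    "1\tsrc\texon\t1\t250\t.\t+\t.\tID=x2;Parent=g2.t2",
    "1\tsrc\texon\t500\t699\t.\t+\t.\tID=x3;Parent=g2.t2",
    "1\tsrc\tCDS\t1\t250\t.\t+\t0\tID=y2;Parent=g2.t2",
    "1\tsrc\tCDS\t500\t699\t.\t+\t0\tID=y3;Parent=g2.t2"
  ), iso)
  m2 <- read_gff3(iso)
  expect_equal(m2$mrna_id, "g2.t2")
  expect_equal(m2$exon_count, 2L)

  badc <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g3",
    "1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=g3.t1;Parent=g3",
    "1\tsrc\texon\t10\t5\t.\t+\t.\tID=e9;Parent=g3.t1"
  ), badc)
  expect_error(read_gff3(badc), "coordinate")

  orphan <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g4",
    "1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=g4.t1;Parent=nosuch"
  ), orphan)
  expect_error(read_gff3(orphan), "nosuch")

  noprag <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g5",
    "1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=g5.t1;Parent=g5",
    "1\tsrc\texon\t1\t100\t.\t+\t.\tID=e5;Parent=g5.t1"
  ), noprag)
  expect_warning(read_gff3(noprag), "gff-version")
})

test_that("simulated gene models round-trip through GFF3 with sorted exons", {
  for (seed in 1:3) {
    fam <- simulate_protein_family(n_members = 4, length_aa = 60,
                                   exon_count_range = c(1, 12), seed = seed)
    path <- withr::local_tempfile(fileext = ".gff3")
    write_gff3(fam$models, path)
    models <- read_gff3(path)
    expect_equal(exon_count(models)$exon_count,
                 exon_count(fam$models)$exon_count)
    for (iv in models$exons) {
      expect_true(all(diff(iv$start) > 0))
      expect_true(all(iv$start <= iv$end))
      if (nrow(iv) > 1) expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
    }
  }
  # a 59-exon gene model reads back with 59 exons
  fam59 <- simulate_protein_family(n_members = 2, length_aa = 200,
                                   exon_count_range = c(59, 59), seed = 1)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(fam59$models, path)
  expect_equal(exon_count(read_gff3(path))$exon_count, c(59L, 59L))
})

test_that("CDS translation uses the standard code and flags bad frames", {
  expect_equal(translate_cds(seq_tbl("a", "ATGGAA", "dna"))$seq, "ME")
  expect_equal(translate_cds(seq_tbl("a", "ATGTAA", "dna"))$seq, "M")
  expect_error(translate_cds(seq_tbl("a", "ATGTAAGAA", "dna")), "codon 2")
  expect_error(translate_cds(seq_tbl("a", "ATGGA", "dna")), "frame")

  # length contract: len/3, minus 1 iff terminal stop
  withr::with_seed(3, {
    for (case in 1:10) {
      n_codons <- sample(2:50, 1)
      sim <- simulate_divergent_cds_pair(n_codons, seed = case)
      prot <- translate_cds(sim$ref)
      expect_equal(nchar(prot$seq), n_codons)
      with_stop <- seq_tbl("s", paste0(sim$ref$seq, "TGA"), "dna")
      expect_equal(nchar(translate_cds(with_stop)$seq), n_codons)
    }
  })
})
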