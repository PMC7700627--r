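test_that("codon alignment preserves frame and places constructed deletions", {
  sim <- simulate_divergent_cds_pair(300, n_syn = 3, n_nonsyn = 2, seed = 71)
  ca <- codon_align(sim$ref, sim$alt)
  expect_true(all(nchar(ca$codons$ref_codon) == 3))
  expect_equal(sum(ca$codons$ref_codon == "---") +
                 sum(ca$codons$alt_codon == "---"), 0)

  del <- simulate_divergent_cds_pair(
    300, indels = tibble::tibble(codon_index = 260, codon_count = 5,
                                 kind = "deletion"), seed = 72
  )
  ca2 <- codon_align(del$ref, del$alt)
  runs <- rle(ca2$codons$alt_codon == "---")
  expect_equal(sum(runs$values), 1)
  expect_equal(runs$lengths[runs$values], 5)
  # every nucleotide gap run is a multiple of 3 by construction
  gap_nt <- nchar(paste(rep("---", runs$lengths[runs$values]), collapse = ""))
  expect_equal(gap_nt %% 3, 0)
})

test_that("substitution classification matches translate-and-compare everywhere", {
  code <- Biostrings::GENETIC_CODE
  expect_equal(classify_substitution("GAA", 3, "G"), "synonymous")
  expect_equal(classify_substitution("GAA", 2, "T"), "non-synonymous")
  expect_error(classify_substitution("GAA", 1, "G"), "equals")
  expect_error(classify_substitution("GZA", 1, "A"), "invalid codon")

  n_checked <- 0
  for (codon in names(code)) {
    for (off in 1:3) {
      ref_base <- substr(codon, off, off)
      for (nb in setdiff(c("A", "C", "G", "T"), ref_base)) {
        mut <- codon
        substr(mut, off, off) <- nb
        oracle <- if (code[[codon]] != "*" && code[[mut]] != "*" &&
                        code[[codon]] == code[[mut]]) {
          "synonymous"
        } else "non-synonymous"
        expect_equal(classify_substitution(codon, off, nb), oracle)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, 576)
})

test_that("substitution calling emits one record per differing base", {
  ref <- paste(c("ATG", "GAA", "CTT", "GGG"), collapse = "")
  alt <- paste(c("ATG", "GTC", "CTT", "GGG"), collapse = "")
  ca <- codon_align(seq_tbl("g", ref, "dna"), seq_tbl("g", alt, "dna"))
  subs <- call_substitutions(ca)
  expect_equal(nrow(subs), 2)               # GAA -> GTC differs at 2 and 3
  expect_equal(subs$codon_index, c(2L, 2L))
  expect_equal(subs$cds_position, c(5L, 6L))
  expect_equal((subs$cds_position - 1) %/% 3 + 1, subs$codon_index)
  # identical pair yields nothing
  ca0 <- codon_align(seq_tbl("g", ref, "dna"), seq_tbl("g", ref, "dna"))
  expect_equal(nrow(call_substitutions(ca0)), 0)
})

test_that("indel records use left-aligned 1-based inclusive reference spans", {
  # deletion of codons 260-264 whose flanks allow one left shift: the
  # reported span is 777-791, 15 nt
  ref <- rep("AAA", 300)
  ref[259] <- "TCA"
  ref[264] <- "GGA"
  alt <- ref
  alt[260:264] <- "---"
  rec <- call_indels(make_codon_alignment(ref, alt))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$start, 777L)
  expect_equal(rec$end, 791L)
  expect_equal(rec$length_nt, 15L)
  expect_equal(rec$kind, "deletion")

  # single-codon deletion shifting left twice: reported at 1703-1705, 3 nt
  ref2 <- rep("AAA", 600)
  ref2[568] <- "ACG"
  ref2[569] <- "TCG"
  alt2 <- ref2
  alt2[569] <- "---"
  rec2 <- call_indels(make_codon_alignment(ref2, alt2))
  expect_equal(rec2$start, 1703L)
  expect_equal(rec2$end, 1705L)
  expect_equal(rec2$length_nt, 3L)

  # gap-free alignment: no records; invariant length = end - start + 1
  expect_equal(nrow(call_indels(make_codon_alignment(ref, ref))), 0)
  expect_equal(rec$length_nt, rec$end - rec$start + 1)
  expect_equal(rec2$length_nt, rec2$end - rec2$start + 1)
})

test_that("summary rows apply count-ratio arithmetic with half-away rounding", {
  expect_equal(kaks_summary("HSP70", 39, 23),
               tibble::tibble(gene_id = "HSP70", syn_count = 39L,
                              nonsyn_count = 23L, total = 62L, ratio = 0.59))
  expect_equal(kaks_summary("HSP90B1", 19, 0)$ratio, 0)
  # 9/24 = 0.375 must round half away from zero to 0.38
  expect_equal(kaks_summary("HSPA13", 24, 9)$ratio, 0.38)
  expect_true(is.na(kaks_summary("odd", 0, 3)$ratio))
  row <- kaks_summary("x", 7, 2)
  expect_equal(row$total, row$syn_count + row$nonsyn_count)
})

test_that("family totals re-derive the ratio from summed counts", {
  rows <- dplyr::bind_rows(purrr::pmap(
    list(hsp70_rows$gene_id, hsp70_rows$syn, hsp70_rows$nonsyn), kaks_summary
  ))
  tot <- kaks_total(rows)
  expect_equal(tot$syn_count, 232L)
  expect_equal(tot$nonsyn_count, 59L)
  expect_equal(tot$total, 291L)
  expect_equal(tot$ratio, 0.25)
  one <- kaks_summary("solo", 5, 1)
  expect_equal(kaks_total(one)[, -1], one[, -1])
})

test_that("planted substitution counts round-trip through the full pipeline", {
  for (seed in 1:10) {
    sim <- simulate_divergent_cds_pair(300, n_syn = 10, n_nonsyn = 5,
                                       seed = seed)
    res <- kaks_pipeline(sim$ref, sim$alt)
    row <- res$summary[res$summary$gene_id == "gene1", ]
    expect_equal(c(row$syn_count, row$nonsyn_count, row$total),
                 c(10L, 5L, 15L))
  }
  # with an indel as well, counts and the indel record match the truth
  sim <- simulate_divergent_cds_pair(
    300, n_syn = 6, n_nonsyn = 2,
    indels = tibble::tibble(codon_index = 120, codon_count = 2,
                            kind = "deletion"),
    seed = 99
  )
  res <- kaks_pipeline(sim$ref, sim$alt)
  expect_equal(res$summary$syn_count[1], 6L)
  expect_equal(res$summary$nonsyn_count[1], 2L)
  expect_equal(res$indels$start, sim$truth$indels$start)
  expect_equal(res$indels$length_nt, sim$truth$indels$length_nt)
})
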