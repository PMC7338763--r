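test_that("motif scanning matches the naive scanner and edge cases", {
  expect_equal(nrow(scan_motif("ACGTACGT", "AAAACAAACAAAAAC")), 0L)
  expect_error(scan_motif("ACGT", "AXC"), "non-IUPAC")

  set.seed(41)
  for (rep in 1:15) {
    prom <- paste(sample(c("A", "C", "G", "T"), sample(50:300, 1), TRUE),
                  collapse = "")
    motif <- paste(sample(c("A", "C", "G", "T", "R", "N", "W"),
                          sample(4:8, 1), TRUE), collapse = "")
    mm <- sample(0:2, 1)
    hits <- scan_motif(prom, motif, max_mismatch = mm)
    expect_equal(hits$offset, naive_scan(prom, motif, mm))
  }
})

test_that("offsets are anchored at the start codon and survive padding", {
  prom <- paste0(strrep("G", 100), "AAAACAAACAAAAAC", strrep("T", 50))
  hits <- scan_motif(prom, "AAAACAAACAAAAAC")
  expect_equal(hits$offset, -(50 + 15))
  # prepending upstream padding leaves offsets unchanged
  hits2 <- scan_motif(paste0(strrep("C", 500), prom), "AAAACAAACAAAAAC")
  expect_equal(hits2$offset, hits$offset)
})

test_that("a planted mismatched copy is found at its planted offset", {
  fx <- mem1b_promoter_fixture(length = 3000, seed = 2)
  core <- builtin_motifs()$seq[1]
  # mutate one base of the distal copy, then scan with 1 mismatch allowed
  s <- fx$seq
  idx <- offset_to_index(-2783L, nchar(s)) + 1L
  substr(s, idx, idx) <- "G"
  expect_false(-2783 %in% scan_motif(s, core)$offset)
  hits <- scan_motif(s, core, max_mismatch = 1)
  expect_true(-2783 %in% hits$offset)
  expect_equal(hits$mismatches[hits$offset == -2783], 1L)
})

test_that("offset/index converters are exact inverses", {
  L <- 3000L
  offs <- c(-1L, -15L, -2783L, -L)
  expect_equal(index_to_offset(offset_to_index(offs, L), L), offs)
  idx <- c(0L, 217L, L - 1L)
  expect_equal(offset_to_index(index_to_offset(idx, L), L), idx)
  expect_error(offset_to_index(0L, L))
  expect_error(offset_to_index(-(L + 1L), L))
})

test_that("promoter identity delegates to global identity with logging", {
  p <- mem1b_promoter_fixture(length = 500 + 2783, seed = 3)$seq
  v <- promoter_identity(p, p)
  expect_equal(as.numeric(v), 100)
  expect_equal(attr(v, "params")[["gap"]], -1)
})

test_that("conserved blocks split at insertions and span identical input", {
  set.seed(47)
  a <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  same <- find_conserved_blocks(a, a)
  expect_equal(nrow(same), 1L)
  expect_equal(same$a_start, -600L)
  expect_equal(same$a_end, -1L)
  expect_equal(same$identity, 100)

  ins <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  b <- paste0(substr(a, 1, 300), ins, substr(a, 301, 600))
  blocks <- find_conserved_blocks(a, b)
  expect_equal(nrow(blocks), 2L)
  expect_true(all(blocks$identity >= 70))
  # the two blocks flank the insertion point in a
  expect_lt(blocks$a_end[1], blocks$a_start[2])
})

test_that("unrelated promoters yield no conserved blocks", {
  set.seed(53)
  n_blocks <- 0L
  for (rep in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    n_blocks <- n_blocks + nrow(find_conserved_blocks(a, b))
  }
  expect_equal(n_blocks, 0L)
})

test_that("the motif library ships the MEM1 B core and loads user motifs", {
  lib <- builtin_motifs()
  expect_true("MEM1_B_core" %in% lib$motif_id)
  expect_equal(get_motif("MEM1_B_core")$length, 15L)
  expect_equal(get_motif("MEM1_B_core")$seq, "AAAACAAACAAAAAC")
  expect_error(get_motif("nope"), "unknown motif")

  f <- tempfile(fileext = ".tsv")
  writeLines(c("motif_id\tseq", "user1\tacgtn"), f)
  um <- read_motifs(f)
  expect_equal(um$seq, "ACGTN")
  expect_equal(um$length, 5L)
  unlink(f)
})

test_that("submodule presence requires two copies in a tight window", {
  region <- mem1b_region_fixture()
  res <- submodule_present(region)
  expect_true(res$present)
  expect_equal(res$n_hits, 2L)
  # same two copies too far apart: no submodule call
  core <- builtin_motifs()$seq[1]
  far <- paste0(core, strrep("G", 200), core)
  res2 <- submodule_present(far)
  expect_false(res2$present)
  expect_equal(res2$n_hits, 2L)
})

test_that("hit tables export as promoter-local BED with signed offsets", {
  fx <- mem1b_promoter_fixture(length = 3000, seed = 4)
  hits <- scan_motif(fx$seq, builtin_motifs()$seq[1],
                     promoter_id = "p1", motif_id = "MEM1_B_core")
  f <- tempfile(fileext = ".bed")
  write_hits_bed(hits, 3000L, 15L, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(nrow(bed), 2L)
  expect_equal(bed$V3 - bed$V2, c(15L, 15L))
  expect_equal(bed$V7, hits$offset)
  # slice coordinates recover the motif
  expect_equal(substr(fx$seq, bed$V2[1] + 1, bed$V3[1]),
               builtin_motifs()$seq[1])
  unlink(f)
})
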