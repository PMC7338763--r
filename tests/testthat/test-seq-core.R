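test_that("FASTA headers carry species and photosynthetic-type labels", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a|Frob|C3", "MKV"), f)
  rec <- read_fasta(f, "protein")
  expect_equal(rec$id, "a")
  expect_equal(rec$species, "Frob")
  expect_equal(rec$ptype, "C3")
  expect_equal(rec$seq, "MKV")

  writeLines(c(">b", "mkv"), f)
  expect_equal(read_fasta(f, "protein")$seq, "MKV")  # uppercased
  writeLines(c(">c", "MKV*"), f)
  expect_warning(rec <- read_fasta(f, "protein"), "stop")
  expect_equal(rec$seq, "MKV")
})

test_that("FASTA format violations are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ATG", ">x", "ATG"), f)
  expect_error(read_fasta(f, "dna"), "duplicate")
  writeLines(c(">y", "MKJV"), f)
  expect_error(read_fasta(f, "protein"), "'J' at position 3")
  writeLines(c(">z", "MK.V"), f)
  expect_error(read_fasta(f, "protein"), "use '-'")
  writeLines(character(), f)
  expect_error(read_fasta(f, "dna"), "no records")
})

test_that("FASTA write/read round-trips random records", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    recs <- data.frame(
      id = paste0("g", seq_len(n)),
      species = paste0("sp", seq_len(n)),
      ptype = sample(c("C3", "C4", NA), n, replace = TRUE),
      molecule = "protein",
      seq = vapply(seq_len(n), function(i)
        paste(sample(c4recruit:::AA_LETTERS, sample(10:200, 1),
                     replace = TRUE), collapse = ""), ""),
      stringsAsFactors = FALSE)
    f <- tempfile(fileext = ".fa")
    write_fasta(recs, f, width = sample(c(10, 60, 80), 1))
    back <- read_fasta(f, "protein")
    expect_equal(back$seq, recs$seq)
    expect_equal(back$id, recs$id)
    expect_equal(back$ptype, recs$ptype)
    unlink(f)
  }
})

test_that("sidecar metadata overrides header labels", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a|WrongSp|C4", "MKV"), f)
  md <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tspecies\tptype", "a\tFtri\tC4"), md)
  rec <- apply_seq_metadata(read_fasta(f, "protein"), md)
  expect_equal(rec$species, "Ftri")
})

test_that("translation follows the standard code and handles stops", {
  expect_equal(translate_cds("ATGGCGGCG"), "MAA")
  expect_equal(translate_cds("ATGTAA"), "M")       # terminal stop stripped
  expect_error(translate_cds("ATGTAAGCG"), "internal stop")
  expect_error(translate_cds("ATGG"), "multiple of 3")
  expect_error(translate_cds("ATGNNN"), "illegal")
})

test_that("back-translation then translation is the identity", {
  set.seed(7)
  for (rep in 1:10) {
    prot <- paste(sample(c4recruit:::AA_LETTERS, 50, replace = TRUE),
                  collapse = "")
    expect_equal(translate_cds(backtranslate(prot)), prot)
    expect_equal(translate_cds(backtranslate(prot, c(A = "GCG"))), prot)
  }
})

test_that("global identity matches definition on limiting cases", {
  expect_equal(global_identity("MKVLW", "MKVLW"), 100)
  expect_equal(global_identity("AAAA", "TTTT"), 0)
  expect_equal(global_identity("ACGT", "ACGT"), 100)
  # symmetry
  set.seed(3)
  for (rep in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = "")
    expect_equal(global_identity(a, b), global_identity(b, a))
  }
  expect_error(global_identity("ACGT", "MKWF"), "mixed molecules")
})

test_that("alignment score equals exhaustive enumeration on 8-mers", {
  set.seed(11)
  for (rep in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(4:8, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(4:8, 1), TRUE),
               collapse = "")
    al <- global_align(a, b)
    expect_equal(al$score, bf_global_score(a, b), info = paste(a, b))
  }
})

test_that("Newick round-trips preserve topology, labels and lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1)N1:1,C:2);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_true("N1" %in% tr$node.label)

  set.seed(5)
  for (rep in 1:10) {
    tr <- ape::rtree(sample(4:12, 1))
    tr$node.label <- paste0("N", seq_len(tr$Nnode))
    write_newick(tr, f)
    back <- read_newick(f)
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))
    expect_true("N1" %in% back$node.label)
  }

  writeLines("((A:1,B:1,C:2);", f)
  expect_error(read_newick(f))
  writeLines("((A:1,A:1):1,C:2);", f)
  expect_error(read_newick(f), "duplicate")
})

test_that("ortholog_set validates species pairing and CDS consistency", {
  tr <- ape::read.tree(text = "((A:1,C:1):1,D:1);")
  prot <- data.frame(id = c("A", "B"), species = c("A", "B"),
                     ptype = NA, molecule = "protein",
                     seq = c("MKV", "MKV"))
  expect_error(ortholog_set(prot, tree = tr), "absent from tree")

  tr2 <- ape::read.tree(text = "((A:1,B:1):1,D:1);")
  cds <- data.frame(id = c("A", "B"), species = c("A", "B"),
                    molecule = "dna",
                    seq = c("ATGAAAGTA", "ATGAAAGTA"))
  os <- ortholog_set(prot, cds, tr2)
  expect_s3_class(os, "ortholog_set")
  cds$seq[2] <- "ATGAAAGCA"   # MKA, not MKV
  expect_error(ortholog_set(prot, cds, tr2), "does not translate")
})
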