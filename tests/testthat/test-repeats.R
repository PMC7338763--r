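test_that("planted tandem units are recovered exactly (vs brute force)", {
  set.seed(17)
  aas <- c4recruit:::AA_LETTERS
  for (rep in 1:20) {
    u_len <- sample(3:20, 1)
    k <- sample(2:6, 1)
    unit <- paste(sample(aas, u_len, replace = TRUE), collapse = "")
    ins <- strrep(unit, k)
    ctx1 <- paste(sample(aas, 12, TRUE), collapse = "")
    ctx2 <- paste(sample(aas, 12, TRUE), collapse = "")
    aln <- data.frame(
      id = c("carrier", "other1", "other2"),
      species = c("carrier", "other1", "other2"),
      ptype = NA, molecule = "protein",
      seq = c(paste0(ctx1, ins, ctx2),
              paste0(ctx1, strrep("-", nchar(ins)), ctx2),
              paste0(ctx1, strrep("-", nchar(ins)), ctx2)),
      stringsAsFactors = FALSE)
    det <- detect_tandem_insertion(aln)
    expect_length(det, 1)
    oracle <- bf_tandem(ins)
    expect_equal(det[[1]]$unit_length_aa, oracle$unit,
                 info = paste("unit", unit, "k", k))
    expect_equal(unname(det[[1]]$copies["carrier"]), oracle$copies)
    expect_equal(unname(det[[1]]$total_span_aa["carrier"]),
                 oracle$unit * oracle$copies)
  }
})

test_that("a short lineage-specific insertion is reported as non-repetitive", {
  aln <- data.frame(id = c("a", "b"), species = c("a", "b"), ptype = NA,
                    molecule = "protein",
                    seq = c("MKVWLRP", "MKV--RP"))
  det <- detect_tandem_insertion(aln, min_unit = 3)
  expect_length(det, 1)
  expect_false(det[[1]]$repetitive)
  expect_true(is.na(det[[1]]$unit_length_aa))
})

test_that("deleting the insertion reproduces the non-carrier sequence", {
  fx <- ppt1_insertion_fixture()
  det <- detect_tandem_insertion(fx$set)[[1]]
  m <- alignment_matrix(fx$set$protein)
  span <- det$insertion_column_span[1]:det$insertion_column_span[2]
  carrier <- paste(m["Ftri", -span], collapse = "")
  noncarrier <- gsub("-", "", paste(m["Frob", ], collapse = ""))
  expect_equal(gsub("-", "", carrier), noncarrier)
  expect_equal(unname(det$total_span_aa), unname(det$copies) *
                 det$unit_length_aa)
})

test_that("ancestral element inference respects conservation and the unit", {
  fx <- ppt1_insertion_fixture()
  det <- detect_tandem_insertion(fx$set)[[1]]
  anc <- infer_ancestral_unit(fx$set, det)
  expect_equal(anc$length, 12L)
  expect_equal(anc$ancestral_unit, fx$element12)
  expect_equal(anc$missing_prefix, "A")

  # planted element of length m is recovered
  set.seed(23)
  for (m_len in c(5L, 9L, 12L)) {
    unit <- paste(sample(c4recruit:::AA_LETTERS, 13, TRUE), collapse = "")
    elem <- substr(unit, 13 - m_len + 1, 13)
    ctx <- "MKWC"   # does not extend the element match
    ins <- strrep(unit, 3)
    aln <- data.frame(
      id = c("c1", "n1", "n2"), species = c("c1", "n1", "n2"),
      ptype = NA, molecule = "protein",
      seq = c(paste0(ctx, elem, ins, "WK"),
              paste0(ctx, elem, strrep("-", nchar(ins)), "WK"),
              paste0(ctx, elem, strrep("-", nchar(ins)), "WK")),
      stringsAsFactors = FALSE)
    det2 <- detect_tandem_insertion(aln)[[1]]
    anc2 <- infer_ancestral_unit(aln, det2)
    expect_gte(anc2$length, m_len)
  }

  # element carried only by carriers yields nothing
  aln3 <- data.frame(
    id = c("c1", "n1", "n2"), species = c("c1", "n1", "n2"),
    ptype = NA, molecule = "protein",
    seq = c("MKWCFFFFFF WK", "MKWCYYY--- WK", "MKWCYYY--- WK"),
    stringsAsFactors = FALSE)
  aln3$seq <- gsub(" ", "", aln3$seq)
  det3 <- detect_tandem_insertion(aln3)
  if (length(det3)) {
    anc3 <- infer_ancestral_unit(aln3, det3[[1]])
    expect_equal(anc3$ancestral_unit, "")
  }
})

test_that("flanking direct repeats match a naive quadratic scan", {
  expect_equal(find_flanking_direct_repeats("AAAATTTT")$len, 0L)
  set.seed(29)
  for (rep in 1:20) {
    L <- sample(3:10, 1)
    flank <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    mid <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    region <- paste0(flank, mid, flank)
    got <- find_flanking_direct_repeats(region)
    expect_equal(got$len, bf_flank(region))
    expect_gte(got$len, L)   # at least the planted length
  }
})

test_that("Nussinov pairing equals exhaustive structure enumeration", {
  expect_equal(nussinov_hairpin("GGGAAACCC")$pairs, 3L)
  expect_equal(nussinov_hairpin("AAAAAA")$pairs, 0L)
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    expect_equal(nussinov_hairpin(s)$pairs, bf_nussinov(s), info = s)
    expect_equal(nussinov_hairpin(s, allow_gu = FALSE)$pairs,
                 bf_nussinov(s, allow_gu = FALSE), info = s)
  }
})

test_that("reported Nussinov structures are valid and score-consistent", {
  set.seed(37)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1), TRUE),
               collapse = "")
    res <- nussinov_hairpin(s, min_loop = 3)
    db <- strsplit(res$structure, "")[[1]]
    expect_equal(sum(db == "("), res$pairs)
    expect_equal(sum(db == ")"), res$pairs)
    # pairs nest and honor the minimum loop
    stack <- integer()
    ok <- TRUE
    for (i in seq_along(db)) {
      if (db[i] == "(") stack <- c(stack, i)
      if (db[i] == ")") {
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (i - j <= 3) ok <- FALSE
      }
    }
    expect_true(ok)
    expect_length(stack, 0)
  }
})

test_that("slippage reports serialize and round-trip as JSON", {
  fx <- ppt1_insertion_fixture()
  det <- detect_tandem_insertion(fx$set)[[1]]
  anc <- infer_ancestral_unit(fx$set, det)
  flank <- find_flanking_direct_repeats(fx$segment15_cds)
  hp <- nussinov_hairpin(fx$element12_cds)
  f <- tempfile(fileext = ".json")
  rec <- slippage_report(det, anc, flank, hp, origin_node = "N7", path = f)
  back <- jsonlite::read_json(f)
  expect_equal(back$unit_length_aa, 13L)
  expect_equal(back$flank_repeat_seq, "GCGGCG")
  expect_equal(back$origin_node, "N7")
  expect_true(back$hairpin_capable)
  unlink(f)

  empty <- slippage_report()
  expect_null(empty$unit_length_aa)
  expect_null(empty$origin_node)
})
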