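test_that("zero substitution rate and no plants reproduce the root", {
  sim <- simulate_ortholog_set(sim_config(seed = 2, subst_rate = 0))
  expect_true(all(sim$set$protein$seq == sim$truth$root_protein))
})

test_that("a fixed seed makes the generators byte-identical", {
  a <- simulate_ortholog_set(sim_config(seed = 9))
  b <- simulate_ortholog_set(sim_config(seed = 9))
  fa <- tempfile(); fb <- tempfile()
  write_fasta(a$set$protein, fa)
  write_fasta(b$set$protein, fb)
  expect_identical(readLines(fa), readLines(fb))
  unlink(c(fa, fb))
  expect_identical(a$set$cds$seq, b$set$cds$seq)

  p1 <- simulate_promoters(sim_config(seed = 4))
  p2 <- simulate_promoters(sim_config(seed = 4))
  expect_identical(p1$seqs$seq, p2$seqs$seq)
  e1 <- simulate_expression(sim_config(seed = 4))
  e2 <- simulate_expression(sim_config(seed = 4))
  expect_identical(e1$values, e2$values)
})

test_that("planted modifications are recovered exactly at rate zero", {
  set.seed(31)
  mods <- random_planted_mods(5, origin = "N7")
  sim <- simulate_ortholog_set(sim_config(seed = 31, subst_rate = 0,
                                          planted_mods = mods))
  found <- classify_columns(sim$set$protein, c("Fcro", "Frob"),
                            c("Fkoc", "Faus", "Fbid", "Ftri"),
                            tree = sim$set$tree)
  expect_equal(found$column, mods$column)
  expect_equal(found$c3_state, mods$anc)
  expect_equal(found$c4_state, mods$derived)
  expect_true(all(found$origin_node == "N7"))
})

test_that("a planted insertion is recovered with its truth table", {
  ins <- list(column = 100L, unit_aa = "AAASVPDSADGGY",
              copies = c(Ftri = 4L, Fbid = 4L, Fkoc = 5L))
  sim <- simulate_ortholog_set(sim_config(seed = 6, subst_rate = 0,
                                          insertion = ins))
  det <- detect_tandem_insertion(sim$set)
  expect_length(det, 1)
  expect_equal(det[[1]]$unit_length_aa, 13L)
  expect_equal(sort(det[[1]]$carrier_species), sort(names(ins$copies)))
  expect_equal(det[[1]]$copies[names(ins$copies)], ins$copies)
  expect_equal(unname(det[[1]]$insertion_column_span),
               unname(sim$truth$insertion$span))
})

test_that("insertion conflicts and bad origins are caught", {
  mods <- data.frame(column = 100L, anc = "A", derived = "S", origin = "N7")
  ins <- list(column = 100L, unit_aa = "AAASVPDSADGGY",
              copies = c(Ftri = 4L))
  expect_error(simulate_ortholog_set(
    sim_config(seed = 1, planted_mods = mods, insertion = ins)),
    "conflicts")
  mods$origin <- "NOPE"
  expect_error(simulate_ortholog_set(
    sim_config(seed = 1, planted_mods = mods)), "unknown origin")
})

test_that("planted promoter motifs are found where planted", {
  motifs <- data.frame(promoter_id = "promoter1",
                       seq = "AAAACAAACAAAAAC", offset = -2783L)
  sim <- simulate_promoters(sim_config(seed = 8, promoter_motifs = motifs,
                                       promoter_gc = 0.5))
  hits <- scan_motif(sim$seqs$seq[1], "AAAACAAACAAAAAC")
  expect_true(-2783L %in% hits$offset)
})

test_that("a zero-GC background is pure A/T", {
  sim <- simulate_promoters(sim_config(seed = 3, promoter_gc = 0,
                                       promoter_length = 500L))
  expect_false(grepl("[GC]", sim$seqs$seq[1]))
})

test_that("zero expression noise reproduces configured means exactly", {
  sim <- simulate_expression(sim_config(seed = 5, expression_sdlog = 0))
  spec <- sim$truth
  for (k in seq_len(nrow(spec))) {
    sel <- sim$metadata$ptype == spec$ptype[k] &
      sim$metadata$tissue == spec$tissue[k] &
      sim$metadata$cell == spec$cell[k]
    expect_equal(unname(sim$values[spec$gene[k], sel]),
                 rep(spec$mean[k], sum(sel)))
  }
})

test_that("expression values are strictly positive at any noise level", {
  sim <- simulate_expression(sim_config(seed = 10, expression_sdlog = 1.5))
  expect_true(all(sim$values > 0))
})

test_that("the light course uses the configured time grid", {
  sim <- simulate_light_course(sim_config(seed = 2))
  expect_equal(sort(unique(sim$series$time)), c(0, 0.5, 2, 4))
  expect_equal(sim$truth$time, c(0, 0.5, 2, 4))
  sim2 <- simulate_light_course(sim_config(seed = 2, light_sdlog = 0))
  agg <- tapply(sim2$series$abundance, sim2$series$time, unique)
  expect_equal(as.numeric(unlist(agg)), sim2$truth$mean)
})

test_that("flat light courses rarely trigger the stepwise test", {
  rejections <- 0L
  n_tests <- 0L
  for (s in 1:60) {
    sim <- simulate_light_course(sim_config(seed = s,
                                            light_folds = c(1, 1, 1)))
    res <- stepwise_light_test(sim$series)
    rejections <- rejections + sum(res$intervals$p < 0.05)
    n_tests <- n_tests + nrow(res$intervals)
  }
  expect_lt(rejections / n_tests, 0.12)   # nominal 5%
})

test_that("noise-free qPCR tables recover abundances exactly", {
  ct <- simulate_qpcr_ct(c(s1 = 2, s2 = 0.5),
                         sim_config(seed = 1, ct_noise_sd = 0))
  ra <- relative_abundance(ct)
  expect_equal(unname(ra[ct$sample == "s1"]), rep(2, 3))
  expect_equal(unname(ra[ct$sample == "s2"]), rep(0.5, 3))
  # 2x the reference means delta-Ct of exactly -1
  expect_equal(unique(ct$ct_target[ct$sample == "s1"] - ct$ct_reference[1]),
               -1)
})
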