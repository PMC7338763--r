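test_that("the codon rate matrix is a proper symmetric generator", {
  Q <- codon_rate_matrix(2, 0.5)
  expect_equal(dim(Q), c(61L, 61L))
  expect_equal(unname(rowSums(Q)), rep(0, 61), tolerance = 1e-12)
  expect_equal(Q, t(Q), tolerance = 1e-12)     # uniform frequencies
  expect_equal(-mean(diag(Q)), 1, tolerance = 1e-12)  # mean rate 1
  # multi-nucleotide changes are forbidden
  expect_equal(Q["AAA", "ACC"], 0)
  expect_equal(Q["AAA", "TTT"], 0)
  # kappa scales transitions relative to transversions (both synonymous)
  Q2 <- codon_rate_matrix(3, 1)
  expect_equal(Q2["GGA", "GGG"] / Q2["GGA", "GGC"], 3, tolerance = 1e-12)
})

test_that("transition matrices are stochastic and match the series expansion", {
  Q <- codon_rate_matrix(2, 0.3)
  e <- eigen(Q, symmetric = TRUE)
  for (t in c(0.01, 0.1, 1, 5)) {
    P <- e$vectors %*% (exp(e$values * t) * t(e$vectors))
    expect_equal(unname(rowSums(P)), rep(1, 61), tolerance = 1e-9)
    expect_true(all(P > -1e-12))
  }
  t <- 1e-4
  P <- e$vectors %*% (exp(e$values * t) * t(e$vectors))
  series <- diag(61) + Q * t + Q %*% Q * t^2 / 2
  expect_equal(unname(P), unname(series), tolerance = 1e-10)
  # uniform stationary distribution
  pi_t <- rep(1 / 61, 61) %*% (e$vectors %*% (exp(e$values * 10) *
                                                t(e$vectors)))
  expect_equal(as.numeric(pi_t), rep(1 / 61, 61), tolerance = 1e-9)
})

test_that("site likelihood approaches 1/61 for identical tips at tiny t", {
  tr <- ape::read.tree(text = "(a:1e-9,b:1e-9)R;")
  mat <- matrix(c(5L, 5L), nrow = 2,
                dimnames = list(c("a", "b"), NULL))
  ca <- c4recruit:::new_codon_alignment(mat, tr, foreground = "a")
  lnl <- branch_site_lnl(ca, 2, 0.5, 1.5, 0.5, 0.3)
  expect_equal(lnl, log(1 / 61), tolerance = 1e-6)
})

test_that("pruning equals brute-force ancestral-state summation", {
  tr <- ape::read.tree(text = "((a:0.2,b:0.3)F1:0.25,c:0.4)R;")
  for (seed in c(3, 8)) {
    ca <- simulate_codon_alignment(tr, "F1", n_codons = 5, seed = seed,
                                   w2 = 3)
    states <- ca$codon_matrix
    rownames(states) <- tr$tip.label
    for (pars in list(c(1.7, 0.3, 2.5, 0.5, 0.3),
                      c(3.0, 0.8, 1.0, 0.2, 0.6))) {
      lnl <- branch_site_lnl(ca, pars[1], pars[2], pars[3], pars[4],
                             pars[5])
      bf <- bf_bs_lnl_3taxa(states, 0.2, 0.3, 0.25, 0.4,
                            pars[1], pars[2], pars[3], pars[4], pars[5])
      expect_equal(lnl, bf, tolerance = 1e-8)
    }
  }
})

test_that("likelihood is invariant to tip order and site order", {
  ts <- selection_sim_tree()
  ca <- simulate_codon_alignment(ts$tree, ts$foreground, n_codons = 40,
                                 seed = 5, w2 = 2)
  base <- branch_site_lnl(ca, 2, 0.2, 2, 0.6, 0.2)
  # site order
  perm <- sample(ncol(ca$codon_matrix))
  ca2 <- c4recruit:::new_codon_alignment(ca$codon_matrix[, perm],
                                         ts$tree, ts$foreground)
  expect_equal(branch_site_lnl(ca2, 2, 0.2, 2, 0.6, 0.2), base,
               tolerance = 1e-10)
  # tip order in the input table
  codons <- sense_codons()
  seqs <- apply(ca$codon_matrix, 1, function(r)
    paste(codons[r], collapse = ""))
  names(seqs) <- ts$tree$tip.label
  ca3 <- codon_alignment(seqs[rev(names(seqs))], ts$tree, ts$foreground)
  expect_equal(branch_site_lnl(ca3, 2, 0.2, 2, 0.6, 0.2), base,
               tolerance = 1e-10)
})

test_that("codon alignments drop gap/stop columns and validate input", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.1)R;")
  seqs <- c(a = "ATGTAAGGG---", b = "ATGAAAGGGAAA")
  ca <- codon_alignment(seqs, tr, foreground = "a")
  expect_equal(ca$n_codons, 2L)   # TAA column and gap column removed
  expect_error(codon_alignment(c(a = "ATG", b = "ATGAAA"), tr, "a"),
               "equal length")
  expect_error(codon_alignment(c(a = "ATGA", b = "ATGA"), tr, "a"),
               "multiple of 3")
  expect_error(codon_alignment(seqs, tr, foreground = "zz"),
               "no foreground")
})

test_that("foreground #1 tags parse from Newick labels", {
  fg <- read_foreground_newick(
    text = "((a:1,b:1)N1#1:1,(c:1,d:1)N2:1)R;")
  expect_equal(fg$foreground, "N1")
  expect_true("N1" %in% fg$tree$node.label)
  fg2 <- read_foreground_newick(text = "((a#1:1,b:1):1,c:1);")
  expect_equal(fg2$foreground, "a")
  expect_error(read_foreground_newick(text = "((a:1,b:1):1,c:1);"),
               "no '#1'")
})

test_that("the alternative never falls below the null (nesting)", {
  ts <- selection_sim_tree()
  for (seed in c(2, 12)) {
    ca <- simulate_codon_alignment(ts$tree, ts$foreground, n_codons = 100,
                                   seed = seed, w2 = if (seed == 2) 1 else 4)
    f0 <- fit_null(ca, n_starts = 1, maxit = 300)
    f1 <- fit_alt(ca, null_fit = f0, n_starts = 1, maxit = 300)
    expect_gte(f1$lnL, f0$lnL - 1e-6)
    expect_gte(lrt(f0, f1)$statistic, 0)
  }
})

test_that("the chi-square LRT and BH adjustment are exact", {
  res <- lrt(-1000, -1000 + 3.841459 / 2)
  expect_equal(res$p, 0.05, tolerance = 1e-4)
  expect_equal(res$statistic, 3.841459, tolerance = 1e-9)
  expect_equal(lrt(-10, -20)$statistic, 0)   # clamped at the boundary

  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # hand-computed step-up on an uneven set
  p <- c(0.001, 0.02, 0.03, 0.8)
  expect_equal(bh_adjust(p), c(0.004, 0.04, 0.04, 0.8))
})

test_that("simulation is seed-deterministic and parameters are recoverable", {
  ts <- selection_sim_tree()
  a <- simulate_codon_alignment(ts$tree, ts$foreground, n_codons = 50,
                                seed = 33)
  b <- simulate_codon_alignment(ts$tree, ts$foreground, n_codons = 50,
                                seed = 33)
  expect_identical(a$codon_matrix, b$codon_matrix)

  ca <- simulate_codon_alignment(ts$tree, ts$foreground, n_codons = 1000,
                                 kappa = 2.5, seed = 77)
  f0 <- fit_null(ca, n_starts = 1)
  expect_lt(abs(f0$params[["kappa"]] - 2.5) / 2.5, 0.2)
  expect_equal(f0$convergence, 0)
})

test_that("selection_scan reports BH-adjusted per-gene calls", {
  ts <- selection_sim_tree()
  cas <- list(
    neutral = simulate_codon_alignment(ts$tree, ts$foreground,
                                       n_codons = 120, w2 = 1, seed = 91),
    selected = simulate_codon_alignment(ts$tree, ts$foreground,
                                        n_codons = 120, w2 = 8, seed = 92))
  out <- selection_scan(cas, n_starts = 1)
  expect_equal(out$gene, c("neutral", "selected"))
  expect_true(all(out$p_bh >= out$p - 1e-12))
  expect_true(all(out$lnL_alt >= out$lnL_null - 1e-6))
})
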