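# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (enumeration / quadratic scans) and share no code
# with the implementations they check.

# exhaustive global-alignment score: enumerate all alignments recursively
bf_global_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# one-pass naive re-check of the consistent-modification definition
naive_consistent_columns <- function(m, c3, c4) {
  hits <- integer()
  for (j in seq_len(ncol(m))) {
    s3 <- unique(m[c3, j]); s4 <- unique(m[c4, j])
    if (length(s3) == 1L && length(s4) == 1L && s3 != s4 &&
        s3 != "-" && s4 != "-") {
      hits <- c(hits, j)
    }
  }
  hits
}

# minimum number of changes over all internal labelings (exhaustive)
bf_parsimony <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  states <- sort(unique(unname(tip_states)))
  nint <- tree$Nnode
  edges <- tree$edge
  grid <- do.call(expand.grid, rep(list(states), nint))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- c(unname(tip_states[tree$tip.label]),
             as.character(unlist(grid[g, ])))
    changes <- sum(lab[edges[, 1]] != lab[edges[, 2]])
    best <- min(best, changes)
  }
  best
}

# naive O(n*m) IUPAC motif scan returning signed offsets
naive_scan <- function(promoter, motif, max_mismatch = 0) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  pc <- strsplit(promoter, "")[[1]]
  mc <- strsplit(motif, "")[[1]]
  n <- length(pc); m <- length(mc)
  if (m > n) return(integer())
  offs <- integer()
  for (s in seq_len(n - m + 1)) {
    mm <- 0
    for (i in seq_len(m)) if (!(pc[s + i - 1] %in% sets[[mc[i]]])) mm <- mm + 1
    if (mm <= max_mismatch) offs <- c(offs, -(n - s + 1))
  }
  offs
}

# exhaustive maximum nested base pairing (no memoization; pure recursion
# over "last base unpaired or paired with k")
bf_nussinov <- function(dna, min_loop = 3, allow_gu = TRUE) {
  x <- strsplit(dna, "")[[1]]
  ok <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AT", "TA", "GC", "CG") || (allow_gu && p %in% c("GT", "TG"))
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i, j - 1)
    for (k in i:(j - min_loop - 1)) {
      if (ok(x[k], x[j])) {
        left <- if (k > i) rec(i, k - 1) else 0
        inner <- if (k + 1 <= j - 1) rec(k + 1, j - 1) else 0
        best <- max(best, left + inner + 1)
      }
    }
    best
  }
  if (length(x) < 2) return(0)
  rec(1, length(x))
}

# exhaustive tandem-repeat decomposition: best (unit, offset, copies) by
# covered length, ties to the smallest unit then earliest offset
bf_tandem <- function(seq, min_unit = 3, max_unit = 50, max_mismatch = 2) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  best <- list(covered = 0, unit = NA, copies = 0)
  for (u in min_unit:min(max_unit, n %/% 2)) {
    for (s in seq_len(n - 2 * u + 1)) {
      for (k in 2:((n - s + 1) %/% u)) {
        cm <- matrix(chars[s:(s + k * u - 1)], nrow = k, byrow = TRUE)
        cons <- apply(cm, 2, function(col) names(sort(table(col),
                                                      decreasing = TRUE))[1])
        if (all(apply(cm, 1, function(r) sum(r != cons)) <= max_mismatch)) {
          if (k * u > best$covered) best <- list(covered = k * u, unit = u,
                                                 copies = k)
        }
      }
    }
  }
  best
}

# direct-repeat finder by quadratic substring comparison
bf_flank <- function(region, max_len = 30) {
  n <- nchar(region)
  best <- 0
  for (L in seq_len(min(max_len, n %/% 2))) {
    if (substr(region, 1, L) == substr(region, n - L + 1, n)) best <- L
  }
  best
}

# Welch t-test p-value from first principles
bf_welch_p <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(y) - mean(x)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# branch-site lnL by summation over all internal codon assignments for a
# 3-taxon tree ((a,b)F1,c) with branch lengths ta, tb, tf, tc and the
# foreground on the F1 stem; uses the same class-matrix convention as the
# package (via the internal helper) but an independent summation path.
bf_bs_lnl_3taxa <- function(states, ta, tb, tf, tc, kappa, w0, w2, p0, p1) {
  Qs <- c4recruit:::bs_class_matrices(kappa, w0, w2, p0, p1)
  pm <- function(Q, t) {
    e <- eigen(Q, symmetric = TRUE)
    e$vectors %*% (exp(e$values * t) * t(e$vectors))
  }
  p2 <- 1 - p0 - p1
  props <- c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
  bgw <- list(Qs$Q0, Qs$Q1, Qs$Q0, Qs$Q1)
  fgw <- list(Qs$Q0, Qs$Q1, Qs$Q2, Qs$Q2)
  lnl <- 0
  for (s in seq_len(ncol(states))) {
    tot <- 0
    for (cl in 1:4) {
      Pa <- pm(bgw[[cl]], ta); Pb <- pm(bgw[[cl]], tb)
      Pf <- pm(fgw[[cl]], tf); Pc <- pm(bgw[[cl]], tc)
      acc <- 0
      for (r in 1:61) for (x in 1:61) {
        acc <- acc + (1 / 61) * Pf[r, x] * Pa[x, states["a", s]] *
          Pb[x, states["b", s]] * Pc[r, states["c", s]]
      }
      tot <- tot + props[cl] * acc
    }
    lnl <- lnl + log(tot)
  }
  lnl
}
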