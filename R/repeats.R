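#' Detect lineage-specific tandem-repeat insertions in a protein alignment
#'
#' Insertion spans are alignment-anchored: maximal runs of columns in which
#' at least one species is gapped and at least one carries residues, with a
#' non-empty set of species gapped across the whole run (the non-carriers).
#' Within each span, the repeat unit is chosen by exhaustive enumeration of
#' (unit length, start offset): the decomposition covering the most
#' residues wins, with ties broken toward the smallest unit. Each copy may
#' differ from the positionwise-majority consensus of its carrier's copies
#' by at most `max_mismatch_per_copy` residues.
#'
#' @param x an [ortholog_set()] or a protein alignment table.
#' @param min_unit,max_unit unit-length search range (amino acids).
#' @param max_mismatch_per_copy maximum residue mismatches between a copy
#'   and the copy consensus.
#' @return list of `repeat_insertion` objects. Each has: `carrier_species`,
#'   `insertion_column_span` (1-based inclusive), `repetitive` flag,
#'   `unit_length_aa`, `copies` (named per carrier), `total_span_aa` (named
#'   per carrier, `copies * unit_length_aa`), `consensus_unit`,
#'   `variant_sites` (`data.frame` of unit positions with >1 observed
#'   state). Spans shorter than `2 * min_unit` are reported with
#'   `repetitive = FALSE`, not as errors.
#' @export
detect_tandem_insertion <- function(x, min_unit = 3L, max_unit = 50L,
                                    max_mismatch_per_copy = 2L) {
  aln <- if (inherits(x, "ortholog_set")) x$protein else x
  m <- alignment_matrix(aln)
  gap <- m == GAP_CHAR
  cand <- apply(gap, 2L, any) & !apply(gap, 2L, all)
  if (!any(cand)) return(list())
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- cbind(starts[r$values], ends[r$values])
  out <- list()
  for (s in seq_len(nrow(spans))) {
    cols <- spans[s, 1L]:spans[s, 2L]
    sub <- m[, cols, drop = FALSE]
    non_carriers <- rownames(m)[apply(sub == GAP_CHAR, 1L, all)]
    carriers <- setdiff(rownames(m), non_carriers)
    if (!length(non_carriers) || !length(carriers)) next
    ins_seqs <- vapply(carriers, function(sp) {
      paste(sub[sp, sub[sp, ] != GAP_CHAR], collapse = "")
    }, "")
    ins <- characterize_insertion(ins_seqs, min_unit, max_unit,
                                  max_mismatch_per_copy)
    ins$carrier_species <- carriers
    ins$insertion_column_span <- c(spans[s, 1L], spans[s, 2L])
    class(ins) <- "repeat_insertion"
    out[[length(out) + 1L]] <- ins
  }
  out
}

# Shared-unit characterization across carriers.
characterize_insertion <- function(ins_seqs, min_unit, max_unit,
                                   max_mismatch) {
  lens <- nchar(ins_seqs)
  if (max(lens) < 2L * min_unit) {
    return(list(repetitive = FALSE, unit_length_aa = NA_integer_,
                copies = setNames(rep(NA_integer_, length(ins_seqs)),
                                  names(ins_seqs)),
                total_span_aa = lens,
                consensus_unit = NA_character_,
                variant_sites = data.frame(unit_pos = integer(),
                                           states = character())))
  }
  units <- min_unit:min(max_unit, floor(max(lens) / 2))
  # per carrier, best coverage achievable at each candidate unit length
  cover <- matrix(0L, nrow = length(ins_seqs), ncol = length(units))
  best_at <- vector("list", length(ins_seqs))
  for (i in seq_along(ins_seqs)) {
    best_at[[i]] <- lapply(units, function(u)
      best_run(ins_seqs[i], u, max_mismatch))
    cover[i, ] <- vapply(best_at[[i]], function(z) z$covered, 1L)
  }
  tot <- colSums(cover)
  if (max(tot) == 0L) {
    return(list(repetitive = FALSE, unit_length_aa = NA_integer_,
                copies = setNames(rep(NA_integer_, length(ins_seqs)),
                                  names(ins_seqs)),
                total_span_aa = lens,
                consensus_unit = NA_character_,
                variant_sites = data.frame(unit_pos = integer(),
                                           states = character())))
  }
  u_idx <- which(tot == max(tot))[1L]  # units ascending: smallest unit wins ties
  u <- units[u_idx]
  copies <- vapply(seq_along(ins_seqs), function(i)
    best_at[[i]][[u_idx]]$copies, 1L)
  names(copies) <- names(ins_seqs)
  copy_mat <- do.call(rbind, lapply(seq_along(ins_seqs), function(i) {
    z <- best_at[[i]][[u_idx]]
    if (z$copies < 2L) return(NULL)
    t(vapply(seq_len(z$copies), function(k) {
      strsplit(substr(ins_seqs[i], z$start + (k - 1L) * u,
                      z$start + k * u - 1L), "")[[1L]]
    }, character(u)))
  }))
  consensus <- apply(copy_mat, 2L, majority_char)
  var_pos <- which(apply(copy_mat, 2L, function(x) length(unique(x)) > 1L))
  variant_sites <- data.frame(
    unit_pos = var_pos,
    states = vapply(var_pos, function(j)
      paste(sort(unique(copy_mat[, j])), collapse = "/"), ""),
    stringsAsFactors = FALSE)
  list(repetitive = TRUE, unit_length_aa = u, copies = copies,
       total_span_aa = ifelse(is.na(copies), lens, copies * u),
       consensus_unit = paste(consensus, collapse = ""),
       variant_sites = variant_sites)
}

majority_char <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  names(tb)[1L]
}

# Best tandem decomposition of one sequence at fixed unit length u:
# exhaustive over start offsets and run lengths (compiled); returns the
# run covering the most residues (ties: earliest start).
best_run <- function(seq, u, max_mismatch) {
  codes <- utf8ToInt(seq) - utf8ToInt("A")
  res <- .best_run_cpp(codes, u, max_mismatch)
  if (res$copies == 0L) res$start <- NA_integer_
  res
}

#' Infer the ancestral element at the N-terminal boundary of an insertion
#'
#' Looks for the longest block of alignment columns immediately upstream of
#' the insertion span that (i) is present with identical residues in every
#' species and (ii) matches a suffix of the insertion's consensus repeat
#' unit exactly. This is the element from which a slipped-strand
#' duplication would have been seeded; its edit relation to the unit (e.g.
#' a missing N-terminal residue) is reported.
#'
#' @param x an [ortholog_set()] or protein alignment table.
#' @param insertion a `repeat_insertion` from [detect_tandem_insertion()].
#' @return list with `ancestral_unit` (possibly `""`), `length`, and
#'   `missing_prefix` (residues of the consensus unit absent from the
#'   element's N-terminal end).
#' @export
infer_ancestral_unit <- function(x, insertion) {
  aln <- if (inherits(x, "ortholog_set")) x$protein else x
  m <- alignment_matrix(aln)
  start <- insertion$insertion_column_span[1L]
  unit <- insertion$consensus_unit
  empty <- list(ancestral_unit = "", length = 0L, missing_prefix = NA_character_)
  if (is.na(unit) || start <= 1L) return(empty)
  ulen <- nchar(unit)
  for (L in seq(min(ulen, start - 1L), 1L)) {
    cols <- (start - L):(start - 1L)
    block <- m[, cols, drop = FALSE]
    if (any(block == GAP_CHAR)) next
    if (!all(apply(block, 2L, function(x) length(unique(x)) == 1L))) next
    elem <- paste(block[1L, ], collapse = "")
    if (identical(elem, substr(unit, ulen - L + 1L, ulen))) {
      return(list(ancestral_unit = elem, length = L,
                  missing_prefix = substr(unit, 1L, ulen - L)))
    }
  }
  empty
}

#' Longest direct repeat shared by the head and tail of a DNA region
#'
#' Returns the longest DNA word that is both a prefix and a suffix of the
#' region (capped at `max_len` and at half the region length), the
#' signature left by slipped-strand mispairing between flanking direct
#' repeats.
#'
#' @param cds_region DNA string.
#' @param max_len maximum repeat length considered (bp).
#' @return list with `seq` (`""` if none) and `len` (bp).
#' @export
find_flanking_direct_repeats <- function(cds_region, max_len = 30L) {
  s <- extract_seq(cds_region)
  n <- nchar(s)
  cap <- min(max_len, n %/% 2L)
  for (L in seq(cap, 1L)) {
    head_w <- substr(s, 1L, L)
    tail_w <- substr(s, n - L + 1L, n)
    if (identical(head_w, tail_w)) return(list(seq = head_w, len = L))
  }
  list(seq = "", len = 0L)
}

#' Maximum base pairing of a DNA word (Nussinov dynamic program)
#'
#' Computes the Nussinov maximum number of nested base pairs (Watson-Crick
#' plus, by default, G-T wobble - the DNA is a transcript proxy) with a
#' minimum hairpin loop length, and one optimal structure in dot-bracket
#' notation. The sequence is called hairpin-capable when the maximum
#' pairing reaches `threshold` (default `ceiling(n/6)`, an artifact
#' convention: no thermodynamic model is implied).
#'
#' @param dna DNA string (A/C/G/T).
#' @param min_loop minimum number of unpaired bases enclosed by a pair.
#' @param allow_gu allow G-T (G-U) wobble pairs.
#' @param threshold pair count at which `hairpin_capable` becomes `TRUE`.
#' @return list with `pairs`, `structure` (dot-bracket), `hairpin_capable`,
#'   `threshold`.
#' @export
nussinov_hairpin <- function(dna, min_loop = 3L, allow_gu = TRUE,
                             threshold = NULL) {
  s <- extract_seq(dna)
  check_alphabet(s, "dna", "<region>", allow_gap = FALSE)
  x <- strsplit(s, "")[[1L]]
  n <- length(x)
  if (is.null(threshold)) threshold <- ceiling(n / 6)
  can_pair <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AT", "TA", "GC", "CG") || (allow_gu && p %in% c("GT", "TG"))
  }
  D <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- D[i, j - 1L]            # j unpaired
        for (k in i:(j - min_loop - 1L)) {  # j pairs with k
          if (can_pair(x[k], x[j])) {
            left <- if (k > i) D[i, k - 1L] else 0L
            inner <- if (k + 1L <= j - 1L) D[k + 1L, j - 1L] else 0L
            best <- max(best, left + inner + 1L)
          }
        }
        D[i, j] <- best
      }
    }
  }
  # traceback one optimal structure
  struct <- rep(".", n)
  if (n >= 2L) {
    stack <- list(c(1L, n))
    while (length(stack)) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1L]; j <- ij[2L]
      if (i >= j || D[i, j] == 0L) next
      if (D[i, j] == D[i, j - 1L]) {
        stack[[length(stack) + 1L]] <- c(i, j - 1L)
        next
      }
      for (k in i:(j - min_loop - 1L)) {
        if (!can_pair(x[k], x[j])) next
        left <- if (k > i) D[i, k - 1L] else 0L
        inner <- if (k + 1L <= j - 1L) D[k + 1L, j - 1L] else 0L
        if (left + inner + 1L == D[i, j]) {
          struct[k] <- "("; struct[j] <- ")"
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          break
        }
      }
    }
  }
  pairs <- if (n >= 2L) D[1L, n] else 0L
  list(pairs = pairs, structure = paste(struct, collapse = ""),
       hairpin_capable = pairs >= threshold, threshold = threshold)
}

#' Assemble a slipped-strand-mispairing evidence record
#'
#' Bundles a detected insertion with its ancestral element, the flanking
#' direct repeat of the slippage unit's CDS, the hairpin capability of the
#' ancestral element's CDS, and (optionally) the insertion's origin node,
#' into one JSON-serializable record.
#'
#' @param insertion `repeat_insertion` (or `NULL`).
#' @param ancestral result of [infer_ancestral_unit()] (or `NULL`).
#' @param flank result of [find_flanking_direct_repeats()] (or `NULL`).
#' @param hairpin result of [nussinov_hairpin()] (or `NULL`).
#' @param origin_node node id from [map_origin_node()] (or `NULL`).
#' @param path optional path; when given the record is written as JSON.
#' @return a list (class `slippage_report`).
#' @export
slippage_report <- function(insertion = NULL, ancestral = NULL, flank = NULL,
                            hairpin = NULL, origin_node = NULL, path = NULL) {
  rec <- list(
    unit_length_aa = if (!is.null(insertion)) insertion$unit_length_aa else NULL,
    copies = if (!is.null(insertion)) as.list(insertion$copies) else NULL,
    consensus_unit = if (!is.null(insertion)) insertion$consensus_unit else NULL,
    n_variant_sites = if (!is.null(insertion)) nrow(insertion$variant_sites) else NULL,
    ancestral_unit = if (!is.null(ancestral)) ancestral$ancestral_unit else NULL,
    ancestral_length = if (!is.null(ancestral)) ancestral$length else NULL,
    flank_repeat_seq = if (!is.null(flank)) flank$seq else NULL,
    flank_repeat_len_bp = if (!is.null(flank)) flank$len else NULL,
    hairpin_pairs = if (!is.null(hairpin)) hairpin$pairs else NULL,
    hairpin_capable = if (!is.null(hairpin)) hairpin$hairpin_capable else NULL,
    origin_node = origin_node)
  class(rec) <- c("slippage_report", "list")
  if (!is.null(path)) {
    jsonlite::write_json(unclass(rec), path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  }
  rec
}
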