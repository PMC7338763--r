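IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Scan a promoter for a motif with IUPAC codes and mismatch tolerance
#'
#' Promoters are given on the coding strand with their 3' end abutting the
#' A of the start codon, and positions are reported as signed upstream
#' offsets: the base at offset -1 is immediately upstream of ATG, so a hit
#' whose 5' end is at offset -2783 starts 2,783 bp upstream of the start
#' codon. All windows matching the motif under IUPAC expansion with at most
#' `max_mismatch` substitutions are reported. Only the coding strand is
#' scanned (cis-module orientation convention); set `both_strands = TRUE`
#' to also scan the reverse complement.
#'
#' @param promoter promoter DNA string (or single-row sequence table).
#' @param motif motif string over the IUPAC alphabet.
#' @param max_mismatch maximum number of mismatching positions.
#' @param promoter_id,motif_id identifiers carried into the hit table.
#' @param both_strands also scan the reverse complement.
#' @return `data.frame` of hits: `promoter_id`, `motif_id`, `offset`
#'   (signed, 5'-most base of the window), `strand`, `mismatches`. A motif
#'   longer than the promoter yields zero hits.
#' @export
scan_motif <- function(promoter, motif, max_mismatch = 0L,
                       promoter_id = "promoter", motif_id = "motif",
                       both_strands = FALSE) {
  s <- extract_seq(promoter)
  motif <- toupper(motif)
  mchars <- strsplit(motif, "")[[1L]]
  if (!all(mchars %in% names(IUPAC_SETS))) {
    stop("non-IUPAC character in motif: ",
         paste(setdiff(mchars, names(IUPAC_SETS)), collapse = ", "))
  }
  empty <- data.frame(promoter_id = character(), motif_id = character(),
                      offset = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- empty
  for (strand in strands) {
    seq_use <- if (strand == "+") s else revcomp(s)
    hits <- scan_one_strand(seq_use, mchars, max_mismatch)
    if (nrow(hits)) {
      L <- nchar(s)
      m <- length(mchars)
      start_plus <- if (strand == "+") hits$start else L - (hits$start + m - 1L) + 1L
      out <- rbind(out, data.frame(
        promoter_id = promoter_id, motif_id = motif_id,
        offset = -(L - start_plus + 1L), strand = strand,
        mismatches = hits$mismatches, stringsAsFactors = FALSE))
    }
  }
  out[order(out$offset), , drop = FALSE]
}

scan_one_strand <- function(s, mchars, max_mismatch) {
  n <- nchar(s)
  m <- length(mchars)
  if (m > n) return(data.frame(start = integer(), mismatches = integer()))
  chars <- strsplit(s, "")[[1L]]
  n_win <- n - m + 1L
  mism <- integer(n_win)
  for (i in seq_len(m)) {
    ok <- chars[i:(i + n_win - 1L)] %in% IUPAC_SETS[[mchars[i]]]
    mism <- mism + !ok
  }
  hit <- which(mism <= max_mismatch)
  data.frame(start = hit, mismatches = mism[hit])
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

#' Convert signed upstream offsets to 0-based half-open slice indices
#'
#' Offset -1 is the base adjacent to the start codon; for a promoter of
#' length `L`, offset `o` maps to 0-based index `L + o`. The two
#' converters are exact inverses.
#'
#' @param offset signed offset (negative, -1 = immediately upstream).
#' @param promoter_length promoter length in bp.
#' @return 0-based index (or signed offset for the inverse).
#' @export
offset_to_index <- function(offset, promoter_length) {
  stopifnot(all(offset <= -1L), all(-offset <= promoter_length))
  promoter_length + offset
}

#' @rdname offset_to_index
#' @param index 0-based index within the promoter.
#' @export
index_to_offset <- function(index, promoter_length) {
  stopifnot(all(index >= 0L), all(index < promoter_length))
  index - promoter_length
}

#' Global percent identity between two promoters
#'
#' Delegates to [global_identity()]; alignment parameters are attached to
#' the result so downstream reports can state them.
#'
#' @inheritParams global_identity
#' @return percent identity with an attribute `params`.
#' @export
promoter_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  val <- global_identity(a, b, match = match, mismatch = mismatch, gap = gap)
  attr(val, "params") <- c(match = match, mismatch = mismatch, gap = gap)
  val
}

#' Find conserved blocks shared by two promoters
#'
#' Globally aligns the two promoters, scores identity in consecutive
#' non-overlapping windows of alignment columns, merges adjacent windows
#' that reach `min_identity`, and trims merged blocks to their first and
#' last matched column. An insertion in one promoter splits an otherwise
#' conserved region into two reported blocks.
#'
#' @param a,b promoter DNA strings (coding strand, 3' end at the start
#'   codon).
#' @param window window size in alignment columns.
#' @param min_identity percent identity a window must reach.
#' @return `data.frame` of blocks with signed start/end offsets in both
#'   promoters (`a_start`, `a_end`, `b_start`, `b_end`), `length`
#'   (alignment columns after trimming) and `identity` (percent, gap
#'   columns count as mismatches).
#' @export
find_conserved_blocks <- function(a, b, window = 50L, min_identity = 70) {
  a <- extract_seq(a); b <- extract_seq(b)
  al <- global_align(a, b)
  ca <- strsplit(al$aligned_a, "")[[1L]]
  cb <- strsplit(al$aligned_b, "")[[1L]]
  ncol_al <- length(ca)
  matched <- ca == cb & ca != GAP_CHAR
  n_win <- ceiling(ncol_al / window)
  win_start <- (seq_len(n_win) - 1L) * window + 1L
  win_end <- pmin(win_start + window - 1L, ncol_al)
  win_id <- vapply(seq_len(n_win), function(w)
    100 * sum(matched[win_start[w]:win_end[w]]) / (win_end[w] - win_start[w] + 1L),
    1.0)
  pass <- win_id >= min_identity
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      length = integer(), identity = numeric())
  if (!any(pass)) return(empty)
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos_a <- cumsum(ca != GAP_CHAR)   # alignment column -> position in a
  pos_b <- cumsum(cb != GAP_CHAR)
  La <- nchar(a); Lb <- nchar(b)
  blocks <- empty
  for (k in which(r$values)) {
    c1 <- win_start[starts[k]]
    c2 <- win_end[ends[k]]
    in_block <- which(matched[c1:c2]) + c1 - 1L
    if (!length(in_block)) next
    c1 <- in_block[1L]; c2 <- in_block[length(in_block)]
    blocks <- rbind(blocks, data.frame(
      a_start = -(La - pos_a[c1] + 1L), a_end = -(La - pos_a[c2] + 1L),
      b_start = -(Lb - pos_b[c1] + 1L), b_end = -(Lb - pos_b[c2] + 1L),
      length = c2 - c1 + 1L,
      identity = 100 * sum(matched[c1:c2]) / (c2 - c1 + 1L)))
  }
  blocks
}

#' Built-in cis-element motif library
#'
#' Ships the MEM1 B-submodule core, the 15-mer whose tandem duplication
#' marks mesophyll-expression modules in C4 Flaveria promoters. User
#' motifs can be loaded with [read_motifs()] and combined by `rbind`.
#'
#' @return `data.frame` with columns `motif_id`, `seq`, `length`,
#'   `description`.
#' @export
builtin_motifs <- function() {
  data.frame(
    motif_id = "MEM1_B_core",
    seq = "AAAACAAACAAAAAC",
    length = 15L,
    description = paste("Core 15-mer of the MEM1 B submodule; two tandem",
                        "copies within ~44 bp form the B submodule of the",
                        "mesophyll expression module 1 of C4 Flaveria",
                        "ppcA-type promoters"),
    stringsAsFactors = FALSE)
}

#' Look up a motif by id
#'
#' @param motif_id motif identifier.
#' @param motifs motif table; defaults to [builtin_motifs()].
#' @return single-row motif `data.frame`; unknown ids are an error.
#' @export
get_motif <- function(motif_id, motifs = builtin_motifs()) {
  row <- motifs[motifs$motif_id == motif_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown motif id: ", motif_id)
  row
}

#' Read user motifs from a TSV (columns motif_id, seq)
#'
#' @param path tab-separated file with columns `motif_id` and `seq`.
#' @return motif table compatible with [builtin_motifs()].
#' @export
read_motifs <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("motif_id", "seq") %in% names(md))) {
    stop("motif table must have columns motif_id, seq")
  }
  md$seq <- toupper(md$seq)
  md$length <- nchar(md$seq)
  if (!"description" %in% names(md)) md$description <- ""
  md[, c("motif_id", "seq", "length", "description")]
}

#' Is a MEM1 B-style submodule present in a promoter?
#'
#' The B submodule is called present when at least `min_copies` hits of
#' the core 15-mer fall within a window of `window` bp (the published
#' submodule is two tandem copies within a 44 bp region).
#'
#' @param promoter promoter DNA string.
#' @param motif core motif string.
#' @param max_mismatch mismatches tolerated per copy.
#' @param min_copies copies required.
#' @param window maximum span (bp, 5' end to 5' end plus motif length)
#'   containing the copies.
#' @return list with `present`, `n_hits`, and the hit table.
#' @export
submodule_present <- function(promoter, motif = builtin_motifs()$seq[1L],
                              max_mismatch = 0L, min_copies = 2L,
                              window = 60L) {
  hits <- scan_motif(promoter, motif, max_mismatch = max_mismatch)
  present <- FALSE
  if (nrow(hits) >= min_copies) {
    off <- sort(hits$offset)
    m <- nchar(motif)
    for (i in seq_len(length(off) - min_copies + 1L)) {
      span <- off[i + min_copies - 1L] + m - off[i]
      if (span <= window) { present <- TRUE; break }
    }
  }
  list(present = present, n_hits = nrow(hits), hits = hits)
}

#' Write motif hits as BED (promoter-local, 0-based half-open)
#'
#' @param hits hit table from [scan_motif()].
#' @param promoter_length promoter length in bp (needed to convert signed
#'   offsets to slice coordinates).
#' @param motif_length motif length in bp.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_hits_bed <- function(hits, promoter_length, motif_length, path) {
  start0 <- offset_to_index(hits$offset, promoter_length)
  bed <- data.frame(chrom = hits$promoter_id, start = start0,
                    end = start0 + motif_length, name = hits$motif_id,
                    score = hits$mismatches, strand = hits$strand,
                    offset = hits$offset)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
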