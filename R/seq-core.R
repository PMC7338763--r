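#' Read sequences from a FASTA file
#'
#' Reads protein or DNA sequences into a sequence table. FASTA headers may
#' carry species and photosynthetic-type labels as `id|species|ptype`
#' (e.g. `>ppt1_Ftri|Ftri|C4`); missing tokens default to `species = id`,
#' `ptype = NA`. Residues are uppercased; a terminal `*` stop is stripped
#' with a warning. Characters outside the molecule alphabet (plus the gap
#' character `-`) are an error that names the record and position; the `.`
#' gap dialect is rejected explicitly.
#'
#' @param path path to a FASTA file.
#' @param molecule `"protein"` or `"dna"`.
#' @return A `data.frame` with columns `id`, `species`, `ptype`, `molecule`,
#'   `seq`, in file order.
#' @seealso [write_fasta()], [apply_seq_metadata()]
#' @export
read_fasta <- function(path, molecule = c("protein", "dna")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  parts <- strsplit(headers, "|", fixed = TRUE)
  id <- vapply(parts, `[`, "", 1L)
  id <- trimws(vapply(strsplit(id, "[ \t]"), `[`, "", 1L))
  species <- vapply(parts, function(p) if (length(p) >= 2L) trimws(p[2L]) else NA_character_, "")
  ptype <- vapply(parts, function(p) if (length(p) >= 3L) trimws(p[3L]) else NA_character_, "")
  species[is.na(species) | species == ""] <- id[is.na(species) | species == ""]
  ptype[!is.na(ptype) & ptype == ""] <- NA_character_
  if (anyDuplicated(id)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  ends_star <- endsWith(seqs, "*")
  if (any(ends_star)) {
    warning("stripping terminal '*' stop from: ",
            paste(id[ends_star], collapse = ", "))
    seqs[ends_star] <- sub("\\*$", "", seqs[ends_star])
  }
  for (k in seq_along(seqs)) {
    check_alphabet(seqs[k], molecule, id[k])
  }
  out <- data.frame(id = id, species = species, ptype = check_ptype(ptype),
                    molecule = molecule, seq = seqs,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

check_ptype <- function(ptype) {
  bad <- !is.na(ptype) & !(ptype %in% PTYPE_LEVELS)
  if (any(bad)) {
    stop("unknown photosynthetic-type label(s): ",
         paste(unique(ptype[bad]), collapse = ", "),
         " (expected one of ", paste(PTYPE_LEVELS, collapse = ", "), ")")
  }
  ptype
}

check_alphabet <- function(seq, molecule, id, allow_gap = TRUE) {
  if (nchar(seq) == 0L) stop("record '", id, "': empty sequence")
  letters <- if (molecule == "protein") AA_LETTERS else DNA_LETTERS
  if (allow_gap) letters <- c(letters, GAP_CHAR)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% letters))
  if (length(bad)) {
    if (chars[bad[1L]] == ".") {
      stop("record '", id, "': '.' gap characters are not supported; use '-'")
    }
    stop("record '", id, "': illegal ", molecule, " character '",
         chars[bad[1L]], "' at position ", bad[1L])
  }
  invisible(TRUE)
}

#' Write a sequence table to FASTA
#'
#' Headers are written as `id|species|ptype`, omitting trailing missing
#' tokens, so that [read_fasta()] round-trips the table.
#'
#' @param seqs sequence table as returned by [read_fasta()].
#' @param path output path.
#' @param width line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  species <- if ("species" %in% names(seqs)) seqs$species else seqs$id
  ptype <- if ("ptype" %in% names(seqs)) seqs$ptype else NA_character_
  headers <- ifelse(!is.na(ptype), paste(seqs$id, species, ptype, sep = "|"),
                    ifelse(species != seqs$id, paste(seqs$id, species, sep = "|"),
                           seqs$id))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(seqs))) {
    writeLines(paste0(">", headers[k]), con)
    s <- seqs$seq[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and apply a sample-metadata sidecar table
#'
#' The sidecar TSV (columns `id`, `species`, `ptype`) overrides any labels
#' parsed from FASTA headers: headers are often mangled by alignment tools,
#' so the sidecar wins on conflict.
#'
#' @param seqs sequence table.
#' @param path path to a tab-separated file with columns `id`, `species`,
#'   `ptype`.
#' @return The sequence table with `species`/`ptype` replaced where the
#'   sidecar provides them.
#' @export
apply_seq_metadata <- function(seqs, path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "ptype")
  if (!all(need %in% names(md))) {
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  }
  check_ptype(md$ptype)
  idx <- match(seqs$id, md$id)
  hit <- !is.na(idx)
  seqs$species[hit] <- md$species[idx[hit]]
  seqs$ptype[hit] <- md$ptype[idx[hit]]
  seqs
}

#' Validate a sequence table as an alignment
#'
#' @param seqs sequence table; all sequences must have equal length and
#'   there must be at least two records.
#' @return `seqs` unchanged, invisibly usable as an alignment.
#' @export
as_alignment <- function(seqs) {
  stopifnot(is.data.frame(seqs), nrow(seqs) >= 2L)
  lens <- nchar(seqs$seq)
  if (length(unique(lens)) != 1L) {
    stop("not an alignment: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ")")
  }
  attr(seqs, "n_cols") <- lens[1L]
  seqs
}

#' Alignment as a character matrix (rows = records, columns = sites)
#'
#' @param aln alignment table.
#' @return character matrix with rownames = species.
#' @export
alignment_matrix <- function(aln) {
  aln <- as_alignment(aln)
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$species
  m
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param dna a DNA string (or single-row sequence table); length must be a
#'   multiple of 3 and contain only A/C/G/T. A terminal stop codon is
#'   removed; an internal stop codon is an error.
#' @return the protein string.
#' @export
translate_cds <- function(dna) {
  if (is.data.frame(dna)) dna <- dna$seq[1L]
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length (", n, ") is not a multiple of 3")
  }
  check_alphabet(dna, "dna", "<cds>", allow_gap = FALSE)
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stops <- which(aa == "*")
  if (length(stops)) {
    if (length(stops) > 1L || stops[1L] != length(aa)) {
      stop("internal stop codon at codon ", stops[1L])
    }
    aa <- aa[-length(aa)]
  }
  if (!length(aa)) stop("CDS consists of a stop codon only")
  paste(aa, collapse = "")
}

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and a linear
#' gap penalty of -1 by default; identity is the number of matched columns
#' divided by the alignment length, times 100. Traceback ties are broken
#' deterministically (diagonal, then up, then left).
#'
#' @param a,b sequences (plain strings or single-row sequence tables). Both
#'   must be the same molecule type; mixing DNA with protein is an error.
#' @param match,mismatch,gap alignment scores.
#' @return percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  al <- global_align(a, b, match = match, mismatch = mismatch, gap = gap)
  100 * al$matches / al$length
}

#' Global alignment of two sequences
#'
#' @inheritParams global_identity
#' @return list with `aligned_a`, `aligned_b`, `score`, `matches`, `length`.
#' @export
global_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- extract_seq(a)
  b <- extract_seq(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  if (xor(looks_dna(a), looks_dna(b))) {
    stop("mixed molecules: one sequence looks like DNA, the other does not")
  }
  .nw_align_cpp(a, b, match = match, mismatch = mismatch, gap = gap)
}

extract_seq <- function(x) {
  if (is.data.frame(x)) x <- x$seq[1L]
  toupper(as.character(x)[1L])
}

looks_dna <- function(s) {
  chars <- unique(strsplit(s, "", fixed = TRUE)[[1L]])
  all(chars %in% c(DNA_LETTERS, GAP_CHAR))
}

#' Read / write a Newick tree
#'
#' Thin wrappers over \pkg{ape} that validate what the pipeline relies on:
#' unique tip labels, and (on read) a parseable, rooted topology with
#' optional internal-node labels such as `"N7"` and branch lengths.
#'
#' @param path path to a Newick file.
#' @return `read_newick()`: an \pkg{ape} `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch lengths in ", path)
  }
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Node identifier (tip label or internal-node label) for a node index
#'
#' @param tree a `phylo` object.
#' @param node integer node index in \pkg{ape} numbering.
#' @return character id; unlabeled internal nodes get `"node<index>"`.
#' @export
node_id <- function(tree, node) {
  ntip <- length(tree$tip.label)
  vapply(node, function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    lab <- if (!is.null(tree$node.label)) tree$node.label[v - ntip] else ""
    if (is.na(lab) || lab == "") paste0("node", v) else lab
  }, "")
}

#' Bundle a protein alignment, per-species CDS and a species tree
#'
#' Validates the cross-references the downstream analyses assume: every
#' aligned species must be a tree tip, and each species' CDS must translate
#' (standard code) to its ungapped aligned protein.
#'
#' @param protein_alignment alignment table of protein sequences (one row
#'   per species).
#' @param cds sequence table of unaligned coding sequences, keyed by
#'   `species`; may be `NULL` for protein-only analyses.
#' @param tree a `phylo` species tree.
#' @return an object of class `ortholog_set`.
#' @export
ortholog_set <- function(protein_alignment, cds = NULL, tree = NULL) {
  aln <- as_alignment(protein_alignment)
  if (anyDuplicated(aln$species)) stop("duplicate species in alignment")
  if (!is.null(tree)) {
    missing_sp <- setdiff(aln$species, tree$tip.label)
    if (length(missing_sp)) {
      stop("species absent from tree: ", paste(missing_sp, collapse = ", "))
    }
  }
  if (!is.null(cds)) {
    for (k in seq_len(nrow(aln))) {
      sp <- aln$species[k]
      row <- cds[cds$species == sp, , drop = FALSE]
      if (nrow(row) == 0L) stop("no CDS for species ", sp)
      prot <- gsub("-", "", aln$seq[k], fixed = TRUE)
      tra <- translate_cds(row$seq[1L])
      if (tra != prot) {
        stop("CDS for ", sp, " does not translate to its aligned protein")
      }
    }
  }
  structure(list(protein = aln, cds = cds, tree = tree),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat("ortholog_set:", nrow(x$protein), "species,",
      attr(x$protein, "n_cols"), "aligned columns",
      if (!is.null(x$cds)) "(+CDS)" else "", "\n")
  invisible(x)
}
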