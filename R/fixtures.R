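#' Synthetic reconstruction of the Flaveria PPT1 tandem-insertion region
#'
#' Builds the protein-alignment region (plus region CDS and the species
#' tree) around the lineage-specific insertion reported in Flaveria PPT1:
#' a 13-aa element (`AAASVPDSADGGY`, variant at unit positions 3, 8, 10
#' and 13) repeated four times in *F. palmeri*, *F. bidentis*,
#' *F. trinervia* and *F. australasica* and five times in *F. vaginata*
#' and *F. kochiana*; a 12-aa ancestral element (the unit minus its
#' N-terminal alanine) present in every species immediately upstream; and
#' a triplet alanine following it. Alanine codons are pinned to `GCG`, so
#' the CDS of the 15-aa segment (12-aa element + triplet alanine) carries
#' the direct repeat `GCGGCG` at its head and tail. This is a synthetic
#' reconstruction assembled from those published descriptions, not
#' transcribed sequence data; flanking context is arbitrary.
#'
#' @param carriers_only restrict the alignment to one carrier
#'   (*F. trinervia*) and one C3 non-carrier (*F. robusta*) - the pairwise
#'   setting used to characterize the 4-copy form.
#' @return list with `set` (an [ortholog_set()] over the region),
#'   `element12`, `unit13`, `segment15`, their pinned CDS
#'   (`element12_cds`, `segment15_cds`), and `carriers`.
#' @export
ppt1_insertion_fixture <- function(carriers_only = FALSE) {
  unit <- "AAASVPDSADGGY"            # 13-aa element
  element12 <- substr(unit, 2L, 13L) # ancestral 12-aa element
  triplet <- "AAA"
  prefix <- "MVLSSNKEW"              # arbitrary context; must not end in A
  suffix <- "LPEKSNQV"
  # copy-level variants at unit positions 3 (A/P), 8 (S/K), 10 (D/Y), 13 (Y/D)
  vary <- function(copy_idx) {
    u <- strsplit(unit, "")[[1L]]
    if (copy_idx == 2L) u[3L] <- "P"
    if (copy_idx == 3L) { u[8L] <- "K"; u[10L] <- "Y" }
    if (copy_idx == 4L) u[13L] <- "D"
    paste(u, collapse = "")
  }
  copies <- c(Fpal = 4L, Fvag = 5L, Fkoc = 5L, Faus = 4L, Fbid = 4L,
              Ftri = 4L)
  tree <- flaveria_tree()
  species <- if (carriers_only) c("Frob", "Ftri") else tree$tip.label
  width <- max(copies) * nchar(unit)
  ptypes <- flaveria_ptypes()
  rows <- lapply(species, function(sp) {
    k <- if (sp %in% names(copies)) copies[[sp]] else 0L
    block <- if (k > 0L) paste(vapply(seq_len(k), vary, ""), collapse = "")
      else ""
    block <- paste0(block, strrep(GAP_CHAR, width - nchar(block)))
    data.frame(id = sp, species = sp, ptype = unname(ptypes[sp]),
               molecule = "protein",
               seq = paste0(prefix, element12, block, triplet, suffix),
               stringsAsFactors = FALSE)
  })
  prot <- do.call(rbind, rows)
  cds <- prot
  cds$molecule <- "dna"
  cds$seq <- vapply(prot$seq, function(s) {
    backtranslate(gsub(GAP_CHAR, "", s, fixed = TRUE),
                  codon_overrides = c(A = "GCG"))
  }, "", USE.NAMES = FALSE)
  if (carriers_only) {
    keep <- ape::keep.tip(tree, species)
  } else {
    keep <- tree
  }
  set <- ortholog_set(prot, cds, keep)
  list(set = set,
       element12 = element12, unit13 = unit,
       segment15 = paste0(element12, triplet),
       element12_cds = backtranslate(element12, c(A = "GCG")),
       segment15_cds = backtranslate(paste0(element12, triplet),
                                     c(A = "GCG")),
       carriers = names(copies),
       insertion_span = c(nchar(prefix) + nchar(element12) + 1L,
                          nchar(prefix) + nchar(element12) + width))
}

#' Synthetic reconstruction of the MEM1 B submodule region
#'
#' The published B submodule is two tandem copies of the 15-mer
#' `AAAACAAACAAAAAC` within a ~44 bp stretch of the C4 ppcA-type promoter.
#' The reconstruction places the two copies 29 bp apart (5' to 5') with a
#' G/T-rich spacer that cannot spuriously match the A/C-only core, giving
#' a 44 bp region with exactly two exact matches. This is a synthetic
#' reconstruction of the submodule geometry, not transcribed promoter
#' sequence.
#'
#' @return the 44-bp region as a DNA string.
#' @export
mem1b_region_fixture <- function() {
  core <- builtin_motifs()$seq[1L]
  spacer <- "GTTGGTGGTTGGTG"  # 14 bp, G/T only
  paste0(core, spacer, core)
}

#' Synthetic promoter carrying the MEM1 B submodule at its published offset
#'
#' Embeds the [mem1b_region_fixture()] region in a simulated promoter so
#' that the submodule occupies offsets -2783 to -2740 (the distal-region
#' placement reported for the C4 PPT1 promoter), with the 3' end of the
#' promoter at the start codon.
#'
#' @param length promoter length in bp (at least 2783).
#' @param seed background seed.
#' @return list with `seq` (promoter string) and `truth` (planted copy
#'   offsets).
#' @export
mem1b_promoter_fixture <- function(length = 3000L, seed = 1L) {
  stopifnot(length >= 2783L)
  region <- mem1b_region_fixture()
  core_len <- 15L
  offsets <- c(-2783L, -2783L + core_len + 14L)
  sim <- simulate_promoters(sim_config(
    seed = seed, n_promoters = 1L, promoter_length = length,
    promoter_gc = 0.35,
    promoter_motifs = data.frame(promoter_id = "promoter1",
                                 seq = region, offset = -2783L,
                                 stringsAsFactors = FALSE)))
  list(seq = sim$seqs$seq[1L],
       truth = data.frame(motif_id = "MEM1_B_core", offset = offsets))
}
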