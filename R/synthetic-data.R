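#' Evaluate an expression with a local, restorable RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Default 16-species two-clade Flaveria-style tree
#'
#' A 16-tip rooted tree mirroring the two-clade shape of the Flaveria
#' phylogeny: two basal C3 species, clade A containing the C4-like/C4
#' species whose stem node is labeled `"N7"`, and clade B containing
#' intermediates and a C4-like species but no true C4 species. Internal
#' nodes are labeled N1-N15.
#'
#' @return a `phylo` object.
#' @export
flaveria_tree <- function() {
  txt <- paste0(
    "((Fcro:0.05,Frob:0.05)N2:0.05,",
    "((Fram:0.1,((Fpal:0.05,(Fvag:0.03,Fkoc:0.03)N9:0.02)N8:0.02,",
    "(Faus:0.05,(Fbid:0.03,Ftri:0.03)N12:0.02)N11:0.02)N7:0.05)N6:0.05,",
    "((Fson:0.08,(Fano:0.05,Fpub:0.05)N14:0.03)N13:0.03,",
    "((Fchl:0.05,Fflo:0.05)N16:0.03,(Flin:0.05,Fbro:0.05)N17:0.03)N15:0.03",
    ")N10:0.05)N5:0.05)N1;")
  ape::read.tree(text = txt)
}

#' Photosynthetic-type labels for the default tree's species
#'
#' @return named character vector (species -> ptype).
#' @export
flaveria_ptypes <- function() {
  c(Fcro = "C3", Frob = "C3",
    Fram = "C3-C4-II", Fson = "C3-C4-I", Fano = "C3-C4-I",
    Fpub = "C3-C4-I", Fchl = "C3-C4-I", Fflo = "C3-C4-II",
    Flin = "C3-C4-I",
    Fbro = "C4-like", Fpal = "C4-like", Fvag = "C4-like",
    Fkoc = "C4", Faus = "C4", Fbid = "C4", Ftri = "C4")
}

# lexicographically first codon per amino acid (standard code)
first_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  aas <- unique(gc)
  sapply(aas, function(a) sort(names(gc)[gc == a])[1L])
}

#' Back-translate a protein with a deterministic codon choice
#'
#' Uses the lexicographically first codon per amino acid, with optional
#' per-amino-acid overrides (e.g. `c(A = "GCG")` to pin alanine codons,
#' needed when flanking direct repeats or hairpin-capable unit DNA must be
#' reproduced exactly).
#'
#' @param protein protein string (no gaps).
#' @param codon_overrides named character vector, amino acid -> codon.
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
backtranslate <- function(protein, codon_overrides = NULL) {
  tab <- first_codon_table()
  if (!is.null(codon_overrides)) {
    gc <- Biostrings::GENETIC_CODE
    for (a in names(codon_overrides)) {
      if (!identical(unname(gc[codon_overrides[[a]]]), a)) {
        stop("override codon ", codon_overrides[[a]],
             " does not encode ", a)
      }
      tab[a] <- codon_overrides[[a]]
    }
  }
  aas <- strsplit(protein, "")[[1L]]
  bad <- setdiff(unique(aas), names(tab))
  if (length(bad)) stop("cannot back-translate: ", paste(bad, collapse = ","))
  paste(tab[aas], collapse = "")
}

#' Simulation configuration
#'
#' Collects the knobs shared by the `simulate_*` generators, with defaults
#' chosen to emulate the comparative setting the package targets: a
#' 16-species two-clade tree, Poisson substitutions at 0.02
#' substitutions/site per branch-length unit, 3 kb promoters at 35% GC,
#' three replicates, a 0/0.5/2/4 h light course, and log-normal expression
#' noise with sdlog 0.3.
#'
#' @param seed integer seed; a fixed seed makes every generator's output
#'   byte-identical across runs.
#' @param tree species tree (`phylo`).
#' @param root_protein root protein string, or `NULL` to draw one of
#'   `n_sites` residues.
#' @param n_sites root protein length when `root_protein` is `NULL`.
#' @param subst_rate substitutions/site per branch-length unit.
#' @param planted_mods `data.frame` with columns `column`, `anc`,
#'   `derived`, `origin` (node id), or `NULL`.
#' @param insertion list(`column`, `unit_aa`, `copies` = named integer per
#'   carrier species, `unit_dna` optional pinned CDS of the unit), or
#'   `NULL`.
#' @param codon_overrides passed to [backtranslate()] for CDS generation.
#' @param promoter_length,promoter_gc,promoter_motifs promoter generator:
#'   length (bp), GC fraction, and a `data.frame` (`promoter_id`, `seq`,
#'   `offset` with negative upstream offsets) of motifs to plant.
#' @param n_promoters promoters to draw.
#' @param expression_spec `data.frame` (`gene`, `ptype`, `tissue`, `cell`,
#'   `mean`) of per-stratum mean abundances; default
#'   [default_expression_spec()].
#' @param expression_sdlog log-normal sdlog of expression noise.
#' @param replicates replicates per condition.
#' @param light_times light-course sampling times (h).
#' @param light_folds per-interval fold changes of the mean.
#' @param light_base mean abundance at time 0.
#' @param light_sdlog log-normal sdlog of replicate noise.
#' @param ct_reference reference-gene threshold cycle.
#' @param ct_noise_sd additive Ct noise standard deviation.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       tree = flaveria_tree(),
                       root_protein = NULL,
                       n_sites = 400L,
                       subst_rate = 0.02,
                       planted_mods = NULL,
                       insertion = NULL,
                       codon_overrides = NULL,
                       promoter_length = 3000L,
                       promoter_gc = 0.35,
                       promoter_motifs = NULL,
                       n_promoters = 1L,
                       expression_spec = default_expression_spec(),
                       expression_sdlog = 0.3,
                       replicates = 3L,
                       light_times = c(0, 0.5, 2, 4),
                       light_folds = c(1.5, 2.5, 1.6),
                       light_base = 1,
                       light_sdlog = 0.2,
                       ct_reference = 20,
                       ct_noise_sd = 0.15) {
  cfg <- as.list(environment())
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Simulate an ortholog set on a labeled tree
#'
#' Evolves the root protein tip-ward with Poisson substitutions (uniform
#' replacement kernel over the 20 amino acids - the downstream consistency
#' classifier is alphabet-agnostic, so no empirical exchange matrix is
#' used), overwrites planted C3-to-C4 modifications on all tips descending
#' from each modification's origin node (and the ancestral residue at the
#' root), applies an optional lineage-specific tandem insertion
#' (represented as gap columns in non-carriers), and back-translates each
#' tip to a CDS.
#'
#' @param cfg a [sim_config()].
#' @return list with `set` (an [ortholog_set()]), and `truth` (planted
#'   modification table with origin nodes, and the insertion's alignment
#'   span, carriers, unit and copies).
#' @export
simulate_ortholog_set <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    tree <- cfg$tree
    ntip <- length(tree$tip.label)
    root_protein <- cfg$root_protein
    if (is.null(root_protein)) {
      root_protein <- paste(sample(AA_LETTERS, cfg$n_sites, replace = TRUE),
                            collapse = "")
    }
    n_sites <- nchar(root_protein)
    mods <- cfg$planted_mods
    if (!is.null(mods)) {
      stopifnot(all(c("column", "anc", "derived", "origin") %in% names(mods)))
      if (any(mods$column < 1L | mods$column > n_sites)) {
        stop("planted modification column outside the root protein")
      }
    }
    ins <- cfg$insertion
    if (!is.null(ins)) {
      stopifnot(all(c("column", "unit_aa", "copies") %in% names(ins)))
      if (ins$column < 0L || ins$column > n_sites) {
        stop("insertion column outside the root protein")
      }
      if (!is.null(mods) && any(mods$column == ins$column)) {
        stop("planted modification conflicts with the insertion span")
      }
    }
    root <- strsplit(root_protein, "")[[1L]]
    if (!is.null(mods)) root[mods$column] <- mods$anc
    # preorder simulation of tip sequences
    edges <- ape::reorder.phylo(tree, "postorder")$edge
    blens <- ape::reorder.phylo(tree, "postorder")$edge.length
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[ntip + 1L]] <- root
    for (e in rev(seq_len(nrow(edges)))) {
      par <- edges[e, 1L]; ch <- edges[e, 2L]
      s <- seqs[[par]]
      n_sub <- rpois(1L, cfg$subst_rate * blens[e] * n_sites)
      if (n_sub > 0L) {
        pos <- sample.int(n_sites, n_sub, replace = TRUE)
        for (p in pos) s[p] <- sample(setdiff(AA_LETTERS, s[p]), 1L)
      }
      seqs[[ch]] <- s
    }
    tips <- setNames(seqs[seq_len(ntip)], tree$tip.label)
    # overwrite planted modifications on tips descending from each origin
    if (!is.null(mods)) {
      ids <- node_id(tree, seq_len(ntip + tree$Nnode))
      for (k in seq_len(nrow(mods))) {
        v <- which(ids == mods$origin[k])
        if (!length(v)) stop("unknown origin node: ", mods$origin[k])
        desc <- if (v <= ntip) v else
          intersect(seq_len(ntip), phangorn_free_descendants(tree, v))
        for (tp in desc) tips[[tp]][mods$column[k]] <- mods$derived[k]
      }
    }
    # assemble alignment, inserting the tandem block as extra columns
    ptypes <- flaveria_ptypes()
    aln_seq <- vapply(tree$tip.label, function(sp) {
      paste(tips[[sp]], collapse = "")
    }, "")
    ins_truth <- NULL
    if (!is.null(ins)) {
      max_copies <- max(ins$copies)
      width <- max_copies * nchar(ins$unit_aa)
      aln_seq <- vapply(tree$tip.label, function(sp) {
        k <- if (sp %in% names(ins$copies)) ins$copies[[sp]] else 0L
        block <- paste0(strrep(ins$unit_aa, k),
                        strrep(GAP_CHAR, width - k * nchar(ins$unit_aa)))
        paste0(substr(aln_seq[sp], 1L, ins$column), block,
               substr(aln_seq[sp], ins$column + 1L, n_sites))
      }, "")
      ins_truth <- list(span = c(ins$column + 1L, ins$column + width),
                        carriers = names(ins$copies),
                        unit_aa = ins$unit_aa, copies = ins$copies)
    }
    prot <- data.frame(id = tree$tip.label, species = tree$tip.label,
                       ptype = unname(ptypes[tree$tip.label]),
                       molecule = "protein", seq = unname(aln_seq),
                       stringsAsFactors = FALSE)
    cds <- prot
    cds$molecule <- "dna"
    cds$seq <- vapply(seq_len(nrow(prot)), function(i) {
      p <- gsub(GAP_CHAR, "", prot$seq[i], fixed = TRUE)
      dna <- backtranslate(p, cfg$codon_overrides)
      if (!is.null(ins) && !is.null(ins$unit_dna) &&
          prot$species[i] %in% names(ins$copies)) {
        k <- ins$copies[[prot$species[i]]]
        plain <- strrep(backtranslate(ins$unit_aa, cfg$codon_overrides), k)
        pinned <- strrep(ins$unit_dna, k)
        dna <- sub(plain, pinned, dna, fixed = TRUE)
      }
      dna
    }, "")
    set <- ortholog_set(prot, cds, tree)
    list(set = set,
         truth = list(planted_mods = mods, insertion = ins_truth,
                      root_protein = paste(root, collapse = "")))
  })
}

#' Draw a random planted-modification table
#'
#' Picks `k` distinct columns and, for each, an ancestral and a distinct
#' derived residue, all originating at `origin`.
#'
#' @param k number of modifications.
#' @param n_sites protein length.
#' @param origin origin node id.
#' @param avoid columns to avoid (e.g. an insertion point).
#' @return `data.frame` usable as `planted_mods` in [sim_config()].
#' @export
random_planted_mods <- function(k, n_sites = 400L, origin = "N7",
                                avoid = integer()) {
  cols <- sample(setdiff(seq_len(n_sites), avoid), k)
  anc <- sample(AA_LETTERS, k, replace = TRUE)
  derived <- vapply(anc, function(a) sample(setdiff(AA_LETTERS, a), 1L), "")
  data.frame(column = sort(cols), anc = anc, derived = unname(derived),
             origin = origin, stringsAsFactors = FALSE)
}

#' Simulate promoters with planted motifs
#'
#' Background bases are drawn i.i.d. at the configured GC fraction
#' (`promoter_gc = 0` gives an all-A/T background); configured motifs are
#' then written at their signed upstream offsets. The truth table of
#' planted offsets is returned for downstream recovery tests.
#'
#' @param cfg a [sim_config()]; uses `n_promoters`, `promoter_length`,
#'   `promoter_gc` and `promoter_motifs` (`data.frame` with `promoter_id`,
#'   `seq`, `offset`).
#' @return list with `seqs` (sequence table, molecule `"dna"`) and `truth`
#'   (the planted-motif table).
#' @export
simulate_promoters <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    L <- cfg$promoter_length
    gc <- cfg$promoter_gc
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    ids <- paste0("promoter", seq_len(cfg$n_promoters))
    seqs <- vapply(ids, function(id) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, "")
    truth <- cfg$promoter_motifs
    if (!is.null(truth)) {
      stopifnot(all(c("promoter_id", "seq", "offset") %in% names(truth)),
                all(truth$offset <= -1L))
      for (k in seq_len(nrow(truth))) {
        id <- truth$promoter_id[k]
        if (!id %in% ids) stop("unknown promoter id: ", id)
        start0 <- offset_to_index(truth$offset[k], L)
        if (start0 + nchar(truth$seq[k]) > L) {
          stop("planted motif extends past the start codon")
        }
        substr(seqs[id], start0 + 1L, start0 + nchar(truth$seq[k])) <-
          truth$seq[k]
      }
    }
    out <- data.frame(id = ids, species = ids, ptype = NA_character_,
                      molecule = "dna", seq = unname(seqs),
                      stringsAsFactors = FALSE)
    list(seqs = out, truth = truth)
  })
}

#' Default two-paralog expression design
#'
#' Encodes the qualitative recruitment pattern the pipeline is built to
#' detect: in the C3 stratum the `pptB` paralog dominates the leaf and
#' mesophyll while `pptA` dominates root and bundle sheath; in the C4
#' stratum `pptA` takes over leaf and mesophyll (a 4-fold or larger
#' handover) while root expression drops.
#'
#' @return `data.frame` with columns `gene`, `ptype`, `tissue`, `cell`,
#'   `mean`.
#' @export
default_expression_spec <- function() {
  spec <- rbind(
    data.frame(gene = "pptA", ptype = "C3",
               tissue = c("leaf", "root", "leaf", "leaf"),
               cell = c("whole", "whole", "MC", "BSC"),
               mean = c(50, 300, 30, 120)),
    data.frame(gene = "pptB", ptype = "C3",
               tissue = c("leaf", "root", "leaf", "leaf"),
               cell = c("whole", "whole", "MC", "BSC"),
               mean = c(200, 80, 160, 40)),
    data.frame(gene = "pptA", ptype = "C4",
               tissue = c("leaf", "root", "leaf", "leaf"),
               cell = c("whole", "whole", "MC", "BSC"),
               mean = c(800, 60, 900, 150)),
    data.frame(gene = "pptB", ptype = "C4",
               tissue = c("leaf", "root", "leaf", "leaf"),
               cell = c("whole", "whole", "MC", "BSC"),
               mean = c(200, 75, 180, 170)))
  spec
}

#' Simulate an expression matrix with replicate log-normal noise
#'
#' Values are `mean * exp(rnorm(0, sdlog))` per replicate, so
#' `expression_sdlog = 0` reproduces the configured means exactly and
#' values are strictly positive.
#'
#' @param cfg a [sim_config()]; uses `expression_spec`,
#'   `expression_sdlog`, `replicates`.
#' @return list with `values` (gene x sample matrix), `metadata` (sample
#'   table with `sample`, `ptype`, `tissue`, `cell`, `replicate`) and
#'   `truth` (the spec).
#' @export
simulate_expression <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    spec <- cfg$expression_spec
    genes <- unique(spec$gene)
    strata <- unique(spec[, c("ptype", "tissue", "cell")])
    meta <- do.call(rbind, lapply(seq_len(nrow(strata)), function(k) {
      data.frame(ptype = strata$ptype[k], tissue = strata$tissue[k],
                 cell = strata$cell[k], replicate = seq_len(cfg$replicates),
                 stringsAsFactors = FALSE)
    }))
    meta$sample <- paste(meta$ptype, meta$tissue, meta$cell, meta$replicate,
                         sep = "_")
    vals <- matrix(NA_real_, nrow = length(genes), ncol = nrow(meta),
                   dimnames = list(genes, meta$sample))
    for (g in genes) {
      for (k in seq_len(nrow(meta))) {
        mu <- spec$mean[spec$gene == g & spec$ptype == meta$ptype[k] &
                          spec$tissue == meta$tissue[k] &
                          spec$cell == meta$cell[k]]
        if (!length(mu)) stop("no configured mean for ", g, " in stratum")
        vals[g, k] <- mu * exp(rnorm(1L, 0, cfg$expression_sdlog))
      }
    }
    list(values = vals, metadata = meta[, c("sample", "ptype", "tissue",
                                            "cell", "replicate")],
         truth = spec)
  })
}

#' Simulate a light-induction time course
#'
#' Mean abundance starts at `light_base` and is multiplied by the
#' configured fold change at each interval; replicates add log-normal
#' noise (`light_sdlog = 0` gives the means exactly).
#'
#' @param cfg a [sim_config()]; uses `light_times`, `light_folds`,
#'   `light_base`, `light_sdlog`, `replicates`.
#' @return list with `series` (`data.frame`: `time`, `replicate`,
#'   `abundance`) and `truth` (mean per time point).
#' @export
simulate_light_course <- function(cfg = sim_config()) {
  stopifnot(length(cfg$light_folds) == length(cfg$light_times) - 1L,
            all(diff(cfg$light_times) > 0))
  with_seed(cfg$seed, {
    means <- cfg$light_base * cumprod(c(1, cfg$light_folds))
    series <- do.call(rbind, lapply(seq_along(cfg$light_times), function(k) {
      data.frame(time = cfg$light_times[k], replicate = seq_len(cfg$replicates),
                 abundance = means[k] * exp(rnorm(cfg$replicates, 0,
                                                  cfg$light_sdlog)))
    }))
    list(series = series,
         truth = data.frame(time = cfg$light_times, mean = means))
  })
}

#' Simulate a qRT-PCR Ct table from known relative abundances
#'
#' `Ct_target = Ct_reference - log2(abundance) + noise`, so with zero
#' noise [relative_abundance()] recovers the configured abundances
#' exactly (an abundance of 2x the reference gives a delta-Ct of exactly
#' -1).
#'
#' @param abundances named numeric vector of true relative abundances
#'   (one per sample).
#' @param cfg a [sim_config()]; uses `ct_reference`, `ct_noise_sd`,
#'   `replicates`.
#' @param gene gene label carried into the table.
#' @return `data.frame` with `gene`, `sample`, `replicate`, `ct_target`,
#'   `ct_reference`.
#' @export
simulate_qpcr_ct <- function(abundances, cfg = sim_config(), gene = "pptA") {
  stopifnot(!is.null(names(abundances)), all(abundances > 0))
  with_seed(cfg$seed, {
    do.call(rbind, lapply(names(abundances), function(s) {
      data.frame(gene = gene, sample = s, replicate = seq_len(cfg$replicates),
                 ct_target = cfg$ct_reference - log2(abundances[[s]]) +
                   rnorm(cfg$replicates, 0, cfg$ct_noise_sd),
                 ct_reference = cfg$ct_reference,
                 stringsAsFactors = FALSE)
    }))
  })
}
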