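#' Demo run configuration
#'
#' A self-contained configuration that exercises every stage on the
#' bundled synthetic reconstructions and simulators: the PPT1
#' tandem-insertion region, the MEM1 B promoter placement, simulated
#' expression and light-course tables, and (optionally) a simulated
#' branch-site selection test.
#'
#' @param outdir output directory.
#' @param seed global seed.
#' @param run_selection also run the (slower) branch-site selection stage.
#' @return a named list usable with [run_all()].
#' @export
demo_config <- function(outdir, seed = 1L, run_selection = FALSE) {
  list(
    seed = seed,
    outdir = outdir,
    simulate = TRUE,
    groups = list(
      c3 = c("Fcro", "Frob"),
      c4 = c("Fkoc", "Faus", "Fbid", "Ftri"),
      c4_like = c("Fbro", "Fpal", "Fvag")),
    include_c4_like = FALSE,
    n_planted_mods = 19L,
    subst_rate = 0.02,
    promoter_length = 3000L,
    motif = "MEM1_B_core",
    max_mismatch = 0L,
    run_selection = run_selection,
    selection = list(n_codons = 300L, kappa = 2, w0 = 0.2, w2 = 1,
                     p0 = 0.6, p1 = 0.2))
}

validate_config <- function(cfg) {
  need <- c("seed", "outdir", "groups")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("config validation: missing field(s): ", paste(miss, collapse = ", "))
  }
  if (!all(c("c3", "c4") %in% names(cfg$groups))) {
    stop("config validation: groups must define 'c3' and 'c4' membership")
  }
  if (length(cfg$groups$c3) < 2L || length(cfg$groups$c4) < 2L) {
    stop("config validation: each of c3/c4 needs at least 2 species")
  }
  invisible(cfg)
}

#' Run the full comparative pipeline
#'
#' Executes, in order: input simulation (or loading), consistent-
#' modification classification with origin mapping, tandem-repeat and
#' slippage analysis, promoter submodule scanning, expression and light-
#' response statistics, and (optionally) the branch-site selection test.
#' Every stage writes its own table under `outdir` and contributes to a
#' machine-readable JSON report; the configuration is echoed verbatim
#' into the report, and a fixed seed makes the whole bundle reproducible
#' byte for byte. A stage failure aborts with the stage name.
#'
#' @param cfg configuration list (see [demo_config()]) or the path of a
#'   YAML file holding one.
#' @return the report list, invisibly; the JSON is written to
#'   `file.path(cfg$outdir, "report.json")`.
#' @export
run_all <- function(cfg = demo_config(tempfile("c4run"))) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    tool = "c4recruit",
    version = as.character(utils::packageVersion("c4recruit")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "outdir")])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- inputs ---------------------------------------------------------------
  fx <- stage("simulate", {
    if (isTRUE(cfg$simulate)) {
      fixture <- ppt1_insertion_fixture()
      mods_cfg <- sim_config(
        seed = cfg$seed, subst_rate = cfg$subst_rate %||% 0.02,
        planted_mods = with_seed(cfg$seed, random_planted_mods(
          cfg$n_planted_mods %||% 19L, origin = "N7")))
      sim <- simulate_ortholog_set(mods_cfg)
      prom <- mem1b_promoter_fixture(length = cfg$promoter_length %||% 3000L,
                                     seed = cfg$seed)
      expr_sim <- simulate_expression(sim_config(seed = cfg$seed))
      light_sim <- simulate_light_course(sim_config(seed = cfg$seed))
      list(fixture = fixture, sim = sim, promoter = prom,
           expression = expr_sim, light = light_sim)
    } else {
      prot <- read_fasta(cfg$inputs$protein_fasta, "protein")
      if (!is.null(cfg$inputs$metadata)) {
        prot <- apply_seq_metadata(prot, cfg$inputs$metadata)
      }
      cds <- if (!is.null(cfg$inputs$cds_fasta))
        read_fasta(cfg$inputs$cds_fasta, "dna") else NULL
      tree <- read_newick(cfg$inputs$tree)
      prom_seqs <- if (!is.null(cfg$inputs$promoters))
        read_fasta(cfg$inputs$promoters, "dna") else NULL
      list(set = ortholog_set(prot, cds, tree), promoters = prom_seqs)
    }
  })

  # --- consistent modifications --------------------------------------------
  c4_group <- cfg$groups$c4
  if (isTRUE(cfg$include_c4_like)) c4_group <- c(c4_group, cfg$groups$c4_like)
  mods <- stage("consistent-mods", {
    set <- if (isTRUE(cfg$simulate)) fx$sim$set else fx$set
    classify_columns(set$protein, cfg$groups$c3, c4_group, tree = set$tree)
  })
  write.table(mods, file.path(cfg$outdir, "consistent_mods.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$consistent_mods <- list(
    n = nrow(mods), c4_group = c4_group,
    origin_nodes = as.list(table(mods$origin_node)))

  # --- repeats / slippage ---------------------------------------------------
  rep_report <- stage("repeats", {
    set <- if (isTRUE(cfg$simulate)) fx$fixture$set else fx$set
    ins_list <- detect_tandem_insertion(set)
    if (!length(ins_list)) return(slippage_report())
    ins <- ins_list[[1L]]
    anc <- infer_ancestral_unit(set, ins)
    seg_cds <- if (isTRUE(cfg$simulate)) fx$fixture$segment15_cds else NULL
    flank <- if (!is.null(seg_cds)) find_flanking_direct_repeats(seg_cds)
    hp_cds <- if (isTRUE(cfg$simulate)) fx$fixture$element12_cds else NULL
    hp <- if (!is.null(hp_cds)) nussinov_hairpin(hp_cds)
    states <- setNames(
      ifelse(set$tree$tip.label %in% ins$carrier_species, "present",
             "absent"), set$tree$tip.label)
    origin <- map_origin_node(set$tree, states, derived = "present")
    slippage_report(ins, anc, flank, hp, origin,
                    path = file.path(cfg$outdir, "slippage.json"))
  })
  report$repeats <- unclass(rep_report)

  # --- promoters ------------------------------------------------------------
  if (isTRUE(cfg$simulate) || !is.null(fx$promoters)) {
    prom_res <- stage("promoters", {
      motif <- get_motif(cfg$motif %||% "MEM1_B_core")
      pseq <- if (isTRUE(cfg$simulate)) fx$promoter$seq else fx$promoters$seq[1L]
      hits <- scan_motif(pseq, motif$seq,
                         max_mismatch = cfg$max_mismatch %||% 0L,
                         motif_id = motif$motif_id)
      sub <- submodule_present(pseq, motif$seq,
                               max_mismatch = cfg$max_mismatch %||% 0L)
      write.table(hits, file.path(cfg$outdir, "motif_hits.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_hits_bed(hits, nchar(pseq), motif$length,
                     file.path(cfg$outdir, "motif_hits.bed"))
      list(n_hits = nrow(hits), offsets = hits$offset,
           submodule_present = sub$present)
    })
    report$promoters <- prom_res
  }

  # --- expression -----------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    expr_res <- stage("expression", {
      sw <- recruitment_switch(fx$expression$values, fx$expression$metadata,
                               "pptA", "pptB")
      lt <- stepwise_light_test(fx$light$series)
      write.table(sw$by_stratum, file.path(cfg$outdir, "dominance.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(lt$intervals, file.path(cfg$outdir, "light_course.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(recruitment_switch = sw$switch, leaf_switch = sw$leaf_switch,
           mc_switch = sw$mc_switch,
           light_first_significant = lt$first_significant)
    })
    report$expression <- expr_res
  }

  # --- selection (optional) -------------------------------------------------
  if (isTRUE(cfg$run_selection)) {
    sel <- stage("selection", {
      ts <- selection_sim_tree()
      sc <- cfg$selection
      ca <- simulate_codon_alignment(ts$tree, ts$foreground,
                                     n_codons = sc$n_codons, kappa = sc$kappa,
                                     w0 = sc$w0, w2 = sc$w2, p0 = sc$p0,
                                     p1 = sc$p1, seed = cfg$seed)
      selection_scan(list(sim_gene = ca), n_starts = 1L)
    })
    write.table(sel, file.path(cfg$outdir, "selection.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$selection <- list(p = sel$p, p_bh = sel$p_bh,
                             positive_selection = sel$positive_selection)
  }

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
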