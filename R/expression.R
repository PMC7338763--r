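#' Convert read counts to TPM or FPKM
#'
#' Standard normalizations: TPM divides per-kilobase rates by their
#' per-sample sum (columns sum to one million); FPKM divides counts by
#' transcript length in kb and library size in millions.
#'
#' @param counts numeric matrix, genes x samples.
#' @param lengths transcript lengths in bp (one per gene).
#' @return matrix of the same shape.
#' @export
counts_to_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0),
            all(counts >= 0))
  rate <- counts / (lengths / 1e3)
  sweep(rate, 2L, colSums(rate), "/") * 1e6
}

#' @rdname counts_to_tpm
#' @param library_size mapped reads per sample; defaults to column sums.
#' @export
counts_to_fpkm <- function(counts, lengths, library_size = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0),
            length(library_size) == ncol(counts))
  sweep(counts / (lengths / 1e3), 2L, library_size / 1e6, "/")
}

#' qRT-PCR relative abundance against a reference gene
#'
#' Relative abundance is `2^-(Ct_target - Ct_reference)` (the delta-Ct
#' rule with an ACTIN7-style reference): one cycle earlier than the
#' reference means twice the abundance.
#'
#' @param ct_target threshold cycle(s) of the target gene (> 0).
#' @param ct_reference threshold cycle(s) of the reference gene (> 0).
#'   Alternatively pass a `data.frame` with columns `ct_target` and
#'   `ct_reference` as the first argument.
#' @return relative abundance(s), strictly positive.
#' @export
relative_abundance <- function(ct_target, ct_reference = NULL) {
  if (is.data.frame(ct_target)) {
    df <- ct_target
    stopifnot(all(c("ct_target", "ct_reference") %in% names(df)))
    ct_reference <- df$ct_reference
    ct_target <- df$ct_target
  }
  stopifnot(all(ct_target > 0), all(ct_reference > 0))
  2^(-(ct_target - ct_reference))
}

#' Star string for a p-value, using the qRT-PCR figure-legend convention
#'
#' `***` for p < 0.001, `**` for 0.001 <= p < 0.01, `*` for
#' 0.01 <= p < 0.05, `"(marginal)"` for 0.05 <= p < `marginal` (reported
#' separately because marginal responses are biologically discussed), and
#' `""` otherwise.
#'
#' @param p p-value(s).
#' @param marginal upper bound of the marginal band.
#' @return character vector of star strings.
#' @export
p_stars <- function(p, marginal = 0.10) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0.001) "***"
    else if (x < 0.01) "**"
    else if (x < 0.05) "*"
    else if (x < marginal) "(marginal)"
    else ""
  }, "")
}

#' Stepwise significance of a light-induction time course
#'
#' For each consecutive pair of time points, tests whether replicate
#' abundances differ by a Welch (unequal-variance) two-sample t-test -
#' unpaired and two-sided by default; the variant is configurable since
#' different labs differ here. Tests run on the raw relative abundances
#' (set `log = TRUE` to test log2 values). When both groups have zero
#' variance and equal means the p-value is 1 by convention.
#'
#' @param series `data.frame` with columns `time` (hours) and `abundance`
#'   (one row per replicate measurement); at least two replicates per time
#'   point.
#' @param marginal upper bound of the marginal significance band.
#' @param log test log2-transformed abundances.
#' @param alternative,paired passed to [stats::t.test()].
#' @param alpha significance level defining `first_significant`.
#' @return list with `intervals` (`data.frame`: `from`, `to`, `p`,
#'   `stars`, `direction`) and `first_significant` (earliest `to` time
#'   with p < `alpha`, or `NA`).
#' @export
stepwise_light_test <- function(series, marginal = 0.10, log = FALSE,
                                alternative = "two.sided", paired = FALSE,
                                alpha = 0.05) {
  stopifnot(all(c("time", "abundance") %in% names(series)))
  times <- sort(unique(series$time))
  if (length(times) < 2L) stop("need at least two time points")
  reps <- table(series$time)
  if (any(reps < 2L)) stop("need at least two replicates per time point")
  vals <- if (log) log2(series$abundance) else series$abundance
  out <- data.frame(from = times[-length(times)], to = times[-1L],
                    p = NA_real_, stars = NA_character_,
                    direction = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    x <- vals[series$time == out$from[k]]
    y <- vals[series$time == out$to[k]]
    p <- tryCatch(
      t.test(y, x, alternative = alternative, paired = paired,
             var.equal = FALSE)$p.value,
      error = function(e) {
        # both groups constant: equal means -> 1 by convention, else 0
        if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      })
    out$p[k] <- p
    out$stars[k] <- p_stars(p, marginal = marginal)
    out$direction[k] <- if (mean(y) > mean(x)) "up"
      else if (mean(y) < mean(x)) "down" else "flat"
  }
  first <- out$to[!is.na(out$p) & out$p < alpha]
  list(intervals = out,
       first_significant = if (length(first)) first[1L] else NA_real_)
}

check_expression_input <- function(values, metadata) {
  values <- as.matrix(values)
  stopifnot(all(values >= 0), ncol(values) == nrow(metadata))
  need <- c("sample", "ptype", "tissue", "cell")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), metadata$sample)) {
    values <- values[, metadata$sample, drop = FALSE]
  }
  values
}

#' Log2 dominance index between two genes within a sample stratum
#'
#' `log2(mean_a / mean_b)` over the samples selected by `stratum`;
#' positive values mean `gene_a` dominates. Antisymmetric in the two
#' genes.
#'
#' @param values expression matrix (genes x samples, FPKM or TPM - do not
#'   mix units across datasets).
#' @param metadata sample table with columns `sample`, `ptype`, `tissue`
#'   (`leaf`/`root`/`shoot`), `cell` (`MC`/`BSC`/`whole`).
#' @param gene_a,gene_b row names of the two genes.
#' @param stratum named list of metadata filters, e.g.
#'   `list(ptype = "C4", tissue = "leaf")`.
#' @return the log2 ratio of stratum means.
#' @export
dominance_index <- function(values, metadata, gene_a, gene_b, stratum) {
  values <- check_expression_input(values, metadata)
  keep <- rep(TRUE, nrow(metadata))
  for (nm in names(stratum)) {
    keep <- keep & metadata[[nm]] %in% stratum[[nm]]
  }
  if (!any(keep)) stop("empty stratum")
  log2(mean(values[gene_a, keep]) / mean(values[gene_b, keep]))
}

#' Detect a recruitment switch between two paralogs
#'
#' Compares which paralog dominates in leaf (and, when cell-resolved data
#' are present, in mesophyll cells) between the C3 and C4 strata. A
#' recruitment switch for `gene_a` is flagged when `gene_b` dominates the
#' C3 leaf but `gene_a` dominates the C4 leaf - the expression handover
#' that accompanies recruitment of a paralog into C4 photosynthesis - and,
#' if MC data exist in both strata, the same handover holds in MC.
#'
#' @inheritParams dominance_index
#' @param c3_types,c4_types photosynthetic-type labels forming the two
#'   strata (C4-like species are not counted as C4 by default).
#' @return list with `by_stratum` (`data.frame` of dominance indices and
#'   dominant gene per ptype-class/tissue/cell stratum), `leaf_switch`,
#'   `mc_switch` (`NA` when MC data are absent), and `switch` (the overall
#'   flag for `gene_a`).
#' @export
recruitment_switch <- function(values, metadata, gene_a, gene_b,
                               c3_types = "C3", c4_types = "C4") {
  values <- check_expression_input(values, metadata)
  strata <- expand.grid(class = c("C3", "C4"),
                        tissue = c("leaf", "root"),
                        cell = c("any", "MC", "BSC"),
                        stringsAsFactors = FALSE)
  strata <- strata[!(strata$tissue == "root" & strata$cell != "any"), ]
  rows <- list()
  for (k in seq_len(nrow(strata))) {
    ptypes <- if (strata$class[k] == "C3") c3_types else c4_types
    keep <- metadata$ptype %in% ptypes & metadata$tissue == strata$tissue[k]
    if (strata$cell[k] != "any") keep <- keep & metadata$cell == strata$cell[k]
    if (!any(keep)) next
    idx <- log2(mean(values[gene_a, keep]) / mean(values[gene_b, keep]))
    rows[[length(rows) + 1L]] <- data.frame(
      class = strata$class[k], tissue = strata$tissue[k],
      cell = strata$cell[k], n_samples = sum(keep),
      dominance = idx,
      dominant = if (idx > 0) gene_a else if (idx < 0) gene_b else "tie",
      stringsAsFactors = FALSE)
  }
  by_stratum <- do.call(rbind, rows)
  pick <- function(class, tissue, cell) {
    r <- by_stratum[by_stratum$class == class & by_stratum$tissue == tissue &
                      by_stratum$cell == cell, , drop = FALSE]
    if (nrow(r)) r$dominant[1L] else NA_character_
  }
  leaf_c3 <- pick("C3", "leaf", "any")
  leaf_c4 <- pick("C4", "leaf", "any")
  leaf_switch <- !is.na(leaf_c3) && !is.na(leaf_c4) &&
    leaf_c3 == gene_b && leaf_c4 == gene_a
  mc_c3 <- pick("C3", "leaf", "MC")
  mc_c4 <- pick("C4", "leaf", "MC")
  mc_switch <- if (is.na(mc_c3) || is.na(mc_c4)) NA else
    (mc_c3 == gene_b && mc_c4 == gene_a)
  list(by_stratum = by_stratum, leaf_switch = leaf_switch,
       mc_switch = mc_switch,
       switch = leaf_switch && (is.na(mc_switch) || mc_switch))
}
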