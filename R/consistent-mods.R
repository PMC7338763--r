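#' Classify alignment columns as consistent C3-to-C4 modifications
#'
#' A consistent modification is an alignment column that is fixed for one
#' residue in every C3 species and fixed for a different residue in every
#' C4 species; intermediate (C3-C4) and other species never veto the
#' criterion. Gaps are handled per `gap_policy`: as a 21st character state
#' (default; all-gap columns are skipped), or columns containing a gap in
#' either focal group can be skipped entirely. Columns that fall inside a
#' group-specific insertion (one group entirely gapped, the other entirely
#' ungapped) are excluded from the point-modification list - such spans are
#' insertions and belong to [detect_tandem_insertion()].
#'
#' @param aln protein alignment table (see [as_alignment()]).
#' @param c3,c4 character vectors of species names forming the two focal
#'   groups; must be disjoint, each with at least 2 species present in the
#'   alignment. To include C4-like species in the C4 group, pass them
#'   explicitly in `c4`.
#' @param gap_policy `"state"` (gap is a 21st state) or `"skip"` (ignore
#'   columns with a gap in either focal group).
#' @param min_indel_run runs of at least this many consecutive columns in
#'   which one focal group is entirely gapped and the other entirely
#'   residue-bearing are treated as insertion spans (excluded here, see
#'   [detect_tandem_insertion()]); shorter gap-state differences count as
#'   point modifications under `gap_policy = "state"`.
#' @param tree optional `phylo` tree; when given, each modification's
#'   origin node is mapped with [map_origin_node()] using all alignment
#'   species.
#' @return `data.frame` with one row per consistent modification: `column`
#'   (1-based), `c3_state`, `c4_state`, `origin_node` (NA without a tree),
#'   plus the supporting species lists collapsed with `","`.
#' @export
classify_columns <- function(aln, c3, c4, gap_policy = c("state", "skip"),
                             tree = NULL, min_indel_run = 2L) {
  gap_policy <- match.arg(gap_policy)
  m <- alignment_matrix(aln)
  if (length(c3) < 2L || length(c4) < 2L) {
    stop("each focal group needs at least 2 species")
  }
  if (length(intersect(c3, c4))) stop("c3 and c4 groups must be disjoint")
  missing_sp <- setdiff(c(c3, c4), rownames(m))
  if (length(missing_sp)) {
    stop("species missing from alignment: ", paste(missing_sp, collapse = ", "))
  }
  m3 <- m[c3, , drop = FALSE]
  m4 <- m[c4, , drop = FALSE]
  ncol_m <- ncol(m)
  s3 <- apply(m3, 2L, function(x) if (length(unique(x)) == 1L) x[1L] else NA_character_)
  s4 <- apply(m4, 2L, function(x) if (length(unique(x)) == 1L) x[1L] else NA_character_)
  consistent <- !is.na(s3) & !is.na(s4) & s3 != s4 &
    !apply(m == GAP_CHAR, 2L, all)
  group_indel <- consistent &
    ((s3 == GAP_CHAR & s4 != GAP_CHAR) | (s4 == GAP_CHAR & s3 != GAP_CHAR))
  if (gap_policy == "skip") {
    gap_any <- apply(m3 == GAP_CHAR, 2L, any) | apply(m4 == GAP_CHAR, 2L, any)
    consistent <- consistent & !gap_any
  } else if (any(group_indel)) {
    # exclude insertion spans: runs of >= min_indel_run group-indel columns
    r <- rle(group_indel)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_indel_run)) {
      consistent[starts[k]:ends[k]] <- FALSE
    }
  }
  hits <- which(consistent)
  if (length(hits)) {
    out <- data.frame(column = hits,
                      c3_state = unname(s3[hits]),
                      c4_state = unname(s4[hits]),
                      origin_node = NA_character_,
                      c3_species = paste(c3, collapse = ","),
                      c4_species = paste(c4, collapse = ","),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(column = integer(), c3_state = character(),
                      c4_state = character(), origin_node = character(),
                      c3_species = character(), c4_species = character(),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(tree) && nrow(out)) {
    for (k in seq_len(nrow(out))) {
      states <- m[, out$column[k]]
      names(states) <- rownames(m)
      states <- states[intersect(tree$tip.label, names(states))]
      out$origin_node[k] <- tryCatch(
        map_origin_node(tree, states, derived = out$c4_state[k]),
        error = function(e) NA_character_)
    }
  }
  out
}

# --- Fitch small parsimony ---------------------------------------------------

# postorder traversal index of internal nodes (children before parents)
postorder_internal <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  tree
}

#' Fitch parsimony score of a character on a tree
#'
#' @param tree a `phylo` object.
#' @param tip_states named character vector of states, one per tip.
#' @return the minimum number of state changes.
#' @export
fitch_score <- function(tree, tip_states) {
  fitch_pass(tree, tip_states)$score
}

# Fitch up-pass: state sets per node + number of union events (= score)
fitch_pass <- function(tree, tip_states) {
  if (!all(tree$tip.label %in% names(tip_states))) {
    stop("every tip needs a state")
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- unname(tip_states[tree$tip.label[i]])
  score <- 0L
  edges <- tr$edge
  # process parents in postorder; collect children per parent
  parents <- unique(edges[, 1L])
  for (p in parents) {
    kids <- edges[edges[, 1L] == p, 2L]
    s <- sets[[kids[1L]]]
    for (k in kids[-1L]) {
      inter <- intersect(s, sets[[k]])
      if (length(inter)) {
        s <- inter
      } else {
        s <- union(s, sets[[k]])
        score <- score + 1L
      }
    }
    sets[[p]] <- s
  }
  list(sets = sets, score = score, tree = tree)
}

#' Map the origin node of a derived character state by Fitch parsimony
#'
#' Assigns ancestral states by Fitch parsimony (ambiguities at the root are
#' resolved toward the ancestral state; below the root a node inherits its
#' parent's state whenever that state is in the node's Fitch set, a
#' deterministic minimal-change labeling). The origin is the root-most node
#' whose minimal-change label switches to the derived state on its parent
#' edge; when the derived state arises more than once, the origin covering
#' the most derived tips is reported. A derived state confined to one tip
#' maps to that tip (its pendant branch).
#'
#' @param tree a `phylo` object; internal nodes should be labeled (e.g.
#'   `"N7"`) - unlabeled nodes are reported as `"node<index>"`.
#' @param tip_states named character vector of states for every tip.
#' @param derived the derived state. Default: the minority state among the
#'   tips (ties broken toward the state absent from the first tip).
#' @return the node id (tip label or internal label) of the origin.
#' @export
map_origin_node <- function(tree, tip_states, derived = NULL) {
  states <- unique(unname(tip_states[tree$tip.label]))
  if (length(states) < 2L) {
    stop("fewer than 2 distinct tip states: no origin to map")
  }
  if (is.null(derived)) {
    tab <- sort(table(unname(tip_states[tree$tip.label])))
    cand <- names(tab)[tab == tab[1L]]
    first <- unname(tip_states[tree$tip.label[1L]])
    cand2 <- setdiff(cand, first)
    derived <- if (length(cand2)) cand2[1L] else cand[1L]
  }
  up <- fitch_pass(tree, tip_states)
  sets <- up$sets
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  final <- character(ntip + tree$Nnode)
  for (i in seq_len(ntip)) final[i] <- unname(tip_states[tree$tip.label[i]])
  # root: prefer a non-derived (ancestral) member of the set
  rs <- sets[[root]]
  anc_choice <- setdiff(sort(rs), derived)
  final[root] <- if (length(anc_choice)) anc_choice[1L] else derived
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  # preorder: reverse postorder of edges
  for (e in rev(seq_len(nrow(edges)))) {
    p <- edges[e, 1L]; ch <- edges[e, 2L]
    if (ch <= ntip) next
    if (final[p] %in% sets[[ch]]) {
      final[ch] <- final[p]
    } else {
      pick <- setdiff(sort(sets[[ch]]), derived)
      final[ch] <- if (final[p] != derived && length(pick)) pick[1L] else
        sort(sets[[ch]])[1L]
    }
  }
  # origin candidates: nodes labeled derived whose parent is not derived
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[edges[, 2L]] <- edges[, 1L]
  nodes <- seq_len(ntip + tree$Nnode)
  is_origin <- vapply(nodes, function(v) {
    if (final[v] != derived) return(FALSE)
    if (v == root) return(TRUE)
    final[parent_of[v]] != derived
  }, TRUE)
  cand <- nodes[is_origin]
  if (!length(cand)) stop("derived state '", derived, "' not reachable")
  # prefer candidates whose descendant tips are uniformly derived, then the
  # candidate covering the most derived tips, then the root-most one
  desc_tips <- lapply(cand, function(v) {
    if (v <= ntip) v else
      intersect(seq_len(ntip), phangorn_free_descendants(tree, v))
  })
  all_derived <- vapply(desc_tips, function(tp)
    all(unname(tip_states[tree$tip.label[tp]]) == derived), TRUE)
  n_tips <- vapply(desc_tips, length, 1L)
  depth <- vapply(cand, function(v) {
    d <- 0L
    while (v != root) { v <- parent_of[v]; d <- d + 1L }
    d
  }, 1L)
  ord <- order(-as.integer(all_derived), -n_tips, depth, cand)
  node_id(tree, cand[ord[1L]])
}

# descendant node indices of v (including tips), without extra deps
phangorn_free_descendants <- function(tree, v) {
  edges <- tree$edge
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- edges[edges[, 1L] == cur, 2L]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > length(tree$tip.label)])
  }
  out
}

#' Summarize consistent-modification counts per gene
#'
#' @param mods named list of modification tables from [classify_columns()],
#'   one per gene.
#' @param path optional output TSV path.
#' @return `data.frame` with columns `gene`, `n_modifications`.
#' @export
count_report <- function(mods, path = NULL) {
  stopifnot(is.list(mods))
  out <- data.frame(gene = names(mods),
                    n_modifications = vapply(mods, nrow, 1L),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!length(mods)) {
    out <- data.frame(gene = character(), n_modifications = integer(),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
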