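## Mapping mutations onto branches.
##
## A unit-cost Sankoff traceback assigns each site's changes to branches of
## a rooted (possibly multifurcating) tree. Tie-breaks are deterministic
## and ancestral-state-preferring: among minimal root states the reference
## base is chosen when available, and a child keeps its parent's state
## whenever that is within the per-site minimum, which pushes unavoidable
## changes toward the leaves and keeps deeper nodes at the ancestral
## (reference/outgroup-side) state. Total mapped changes always equal the
## tree's exact parsimony score (change conservation).

base_order_pref <- function(pref) {
  c(pref, setdiff(BASES, pref))
}

# exact per-column traceback; tip_masks: named bitmask per tip label
sankoff_traceback <- function(edge, n_tip, n_node, tip_bits, pref_base) {
  nn <- n_tip + n_node
  cost <- matrix(SANKOFF_BIG, 4, nn)
  for (i in seq_len(n_tip)) {
    for (s in 1:4) {
      if (bitwAnd(tip_bits[i], bitwShiftL(1L, s - 1L)) != 0L) cost[s, i] <- 0
    }
  }
  done <- logical(nn)
  for (k in seq_len(nrow(edge))) {        # edge is in postorder
    p <- edge[k, 1]; ch <- edge[k, 2]
    cmin <- min(cost[, ch])
    contrib <- pmin(cost[, ch], cmin + 1)
    cost[, p] <- if (done[p]) cost[, p] + contrib else contrib
    done[p] <- TRUE
  }
  root <- edge[nrow(edge), 1]
  state <- integer(nn)
  rootmin <- min(cost[, root])
  for (b in base_order_pref(pref_base)) {
    s <- match(b, BASES)
    if (cost[s, root] == rootmin) { state[root] <- s; break }
  }
  events <- list()
  for (k in rev(seq_len(nrow(edge)))) {   # preorder
    p <- edge[k, 1]; ch <- edge[k, 2]
    sp <- state[p]
    opts <- cost[, ch] + (seq_len(4) != sp)
    omin <- min(opts)
    pick <- if (opts[sp] == omin) sp else {
      cand <- which(opts == omin)
      cand[1L]                             # A < C < G < T tie-break
    }
    state[ch] <- pick
    if (pick != sp) {
      events[[length(events) + 1L]] <- c(k, sp, pick)
    }
  }
  list(state = state, events = events, score = rootmin)
}

#' Map mutations onto the branches of a tree
#'
#' Reconstructs ancestral states for every alignment column by an exact
#' unit-cost traceback, records each state change on its branch, and
#' annotates every change (transition/transversion, gene context,
#' synonymous/non-synonymous against the immediate ancestral codon
#' context, reversion flag). Sites needing more than one change tree-wide
#' are flagged recurrent and their successive hits numbered in preorder.
#'
#' @param tree a `phylo`; either already rooted, or `outgroup` must name
#'   the tip(s) to root on (the branch leading to the outgroup-side vertex)
#' @param aln a gap-free `mt_alignment` over the tree's tips
#' @param ref an `mt_reference`
#' @param genemap an `mt_genemap`
#' @param outgroup optional tip label(s) used to root `tree`
#' @param assume_rooted set `TRUE` to accept the tree's stored basal node
#'   as a genuine root (e.g. a star genealogy, whose basal polytomy would
#'   otherwise be indistinguishable from an unrooted trifurcation)
#' @return an `mt_annotated_tree`: list with `tree` (rooted), `edge_mutations`
#'   (per edge row of `tree$edge`, an `mt_variants` data frame with columns
#'   `hit_index`, `recurrent`, `label` added), `node_states` (nodes x columns
#'   character matrix), `total_changes`, `recurrent_positions`, `positions`
#' @export
map_mutations <- function(tree, aln, ref, genemap, outgroup = NULL,
                          assume_rooted = FALSE) {
  if (!setequal(tree$tip.label, taxa_labels(aln))) {
    stop_input("tree tip labels do not match alignment taxa")
  }
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else if (!ape::is.rooted(tree) && !assume_rooted) {
    stop_input("tree is unrooted; supply `outgroup` to fix the root")
  }
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  nn <- n_tip + n_node
  L <- ncol(aln$matrix)
  refbase <- ref$sequence[aln$positions]

  mat <- aln$matrix[tr$tip.label, , drop = FALSE]
  bits <- matrix(BASE_BITS[mat], nrow = n_tip)

  node_states <- matrix(NA_character_, nn, L)
  node_states[seq_len(n_tip), ] <- mat

  constant <- apply(mat, 2, function(col) length(unique(col)) == 1L)
  for (j in which(constant)) node_states[, j] <- mat[1L, j]

  # group variable columns by (tip pattern, reference base): identical
  # placement, identical root preference
  var_cols <- which(!constant)
  raw_events <- list()   # per column: list of (edge_k, from, to)
  if (length(var_cols)) {
    keys <- paste(apply(bits[, var_cols, drop = FALSE], 2, paste,
                        collapse = ","), refbase[var_cols])
    for (grp in split(var_cols, keys)) {
      j0 <- grp[1L]
      tb <- sankoff_traceback(edge, n_tip, n_node, bits[, j0],
                              refbase[j0])
      st <- BASES[tb$state]
      for (j in grp) {
        node_states[, j] <- st
        if (length(tb$events)) raw_events[[as.character(j)]] <- tb$events
      }
    }
  }

  # preorder rank of each edge row, for deterministic hit numbering
  pre_rank <- integer(nrow(edge))
  pre_rank[rev(seq_len(nrow(edge)))] <- seq_len(nrow(edge))

  flat <- data.frame(col = integer(), edge_k = integer(),
                     from = character(), to = character(),
                     stringsAsFactors = FALSE)
  for (jc in names(raw_events)) {
    for (ev in raw_events[[jc]]) {
      flat <- rbind(flat, data.frame(
        col = as.integer(jc), edge_k = ev[1],
        from = BASES[ev[2]], to = BASES[ev[3]],
        stringsAsFactors = FALSE))
    }
  }
  total <- nrow(flat)
  edge_mutations <- rep(list(NULL), nrow(edge))
  recurrent_positions <- integer(0)
  if (total > 0L) {
    flat$position <- aln$positions[flat$col]
    flat <- flat[order(flat$position, pre_rank[flat$edge_k]), , drop = FALSE]
    hits <- ave(seq_len(nrow(flat)), flat$position, FUN = seq_along)
    nhit <- ave(seq_len(nrow(flat)), flat$position, FUN = length)
    flat$hit_index <- ifelse(nhit > 1L, hits, NA_integer_)
    flat$recurrent <- nhit > 1L
    recurrent_positions <- sort(unique(flat$position[flat$recurrent]))
    for (k in unique(flat$edge_k)) {
      rows <- flat[flat$edge_k == k, , drop = FALSE]
      parent <- edge[k, 1]
      background <- ref$sequence
      background[aln$positions] <- node_states[parent, ]
      calls <- data.frame(position = rows$position, ref = rows$from,
                          obs = rows$to,
                          kind = ifelse((rows$from %in% c("A", "G")) ==
                                          (rows$to %in% c("A", "G")),
                                        "transition", "transversion"),
                          feature = NA_character_, gene = NA_character_,
                          effect = NA_character_, aa_from = NA_character_,
                          aa_to = NA_character_,
                          is_reversion = rows$to == ref$sequence[rows$position] &
                            rows$from != ref$sequence[rows$position],
                          stringsAsFactors = FALSE)
      class(calls) <- c("mt_variants", "data.frame")
      calls <- classify_coding_effect(calls, genemap, background)
      calls$hit_index <- rows$hit_index
      calls$recurrent <- rows$recurrent
      calls$label <- format_label(calls, hit_index = rows$hit_index,
                                  recurrent = rows$recurrent)
      ord <- order(calls$position)
      edge_mutations[[k]] <- calls[ord, , drop = FALSE]
    }
  }
  structure(list(tree = tr, edge_mutations = edge_mutations,
                 node_states = node_states, total_changes = total,
                 recurrent_positions = recurrent_positions,
                 positions = aln$positions),
            class = "mt_annotated_tree")
}

#' @export
print.mt_annotated_tree <- function(x, ...) {
  cat(sprintf("mt_annotated_tree: %d tips, %d mapped changes, %d recurrent site(s)\n",
              length(x$tree$tip.label), x$total_changes,
              length(x$recurrent_positions)))
  invisible(x)
}

#' Branch-mutation table
#'
#' One row per mapped change: branch (parent/child node ids, child tip
#' label where applicable) plus the full variant annotation and rendered
#' label.
#'
#' @param atree an `mt_annotated_tree`
#' @return data frame
#' @export
branch_mutation_table <- function(atree) {
  edge <- atree$tree$edge
  n_tip <- length(atree$tree$tip.label)
  out <- list()
  for (k in seq_len(nrow(edge))) {
    calls <- atree$edge_mutations[[k]]
    if (is.null(calls) || nrow(calls) == 0L) next
    calls$parent_node <- edge[k, 1]
    calls$child_node <- edge[k, 2]
    calls$child_tip <- if (edge[k, 2] <= n_tip)
      atree$tree$tip.label[edge[k, 2]] else NA_character_
    out[[length(out) + 1L]] <- calls
  }
  if (!length(out)) return(empty_variants())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
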