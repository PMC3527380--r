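## Exact parsimony scoring.
##
## Binary trees are scored by the Fitch set pass on bitmask-encoded states
## (exact for binary trees; a basal trifurcation is equivalent to rooting
## along one of its edges). Multifurcating trees are scored by the
## unit-cost Sankoff dynamic program, which is exact for any degree —
## required for the minimality certificate, where approximation would
## invalidate the proof.

SANKOFF_BIG <- 1e9

# encode a gap-free alignment as bitmask patterns with column weights;
# the key optionally includes extra per-column data so columns merged into
# one pattern are interchangeable for the caller
encode_patterns <- function(aln, extra_key = NULL) {
  mat <- aln$matrix
  if (any(!(mat %in% BASES))) {
    stop_input("parsimony scoring requires a gap-free A/C/G/T alignment")
  }
  bits <- matrix(BASE_BITS[mat], nrow = nrow(mat),
                 dimnames = list(rownames(mat), NULL))
  keys <- apply(bits, 2, paste, collapse = ",")
  if (!is.null(extra_key)) keys <- paste(keys, extra_key, sep = "|")
  first <- which(!duplicated(keys))
  pattern_of <- match(keys, keys[first])
  list(states = bits[, first, drop = FALSE],
       weights = as.numeric(tabulate(pattern_of, length(first))),
       pattern_of = pattern_of,
       columns_of = split(seq_along(keys), pattern_of))
}

# oriented (parent, child) edge matrix in preorder from an arbitrary
# unrooted edge list; root = internal node adjacent to tip 1
orient_edges <- function(edges, n_tips) {
  m <- nrow(edges)
  maxid <- max(edges)
  from <- c(edges[, 1], edges[, 2])
  to <- c(edges[, 2], edges[, 1])
  o <- order(from)
  from <- from[o]; to <- to[o]
  deg <- tabulate(from, maxid)
  stop_at <- cumsum(deg)
  start_at <- stop_at - deg + 1L
  root <- if (m == 1L) edges[1, 1] else to[start_at[1L]]
  out <- matrix(0L, m, 2)
  k <- 0L
  stack <- integer(m + 1L); stack[1L] <- root; sp <- 1L
  par <- integer(maxid)
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    p <- par[v]
    if (p != 0L) {
      k <- k + 1L
      out[k, 1L] <- p; out[k, 2L] <- v
    }
    if (deg[v] > 0L) {
      for (j in start_at[v]:stop_at[v]) {
        w <- to[j]
        if (w != p) {
          par[w] <- v
          sp <- sp + 1L
          stack[sp] <- w
        }
      }
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# Fitch pass over oriented edges (reverse preorder = postorder);
# exact for degree-3 internal nodes with a possibly trifurcating root
fitch_oriented <- function(oedges, states, weights) {
  maxid <- max(oedges)
  P <- ncol(states)
  S <- matrix(0L, maxid, P)
  set <- logical(maxid)
  nt <- nrow(states)
  S[seq_len(nt), ] <- states
  set[seq_len(nt)] <- TRUE
  score <- 0
  for (i in rev(seq_len(nrow(oedges)))) {
    p <- oedges[i, 1]; c <- oedges[i, 2]
    cs <- S[c, ]
    if (!set[p]) {
      S[p, ] <- cs
      set[p] <- TRUE
    } else {
      inter <- bitwAnd(S[p, ], cs)
      z <- inter == 0L
      if (any(z)) {
        score <- score + sum(weights[z])
        un <- bitwOr(S[p, ], cs)
        inter[z] <- un[z]
      }
      S[p, ] <- inter
    }
  }
  score
}

# unit-cost Sankoff over a rooted/unrooted phylo (any node degrees);
# returns total weighted score, or per-pattern minima if per_pattern
sankoff_phylo <- function(tree, states, weights, per_pattern = FALSE) {
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  nt <- length(tr$tip.label)
  nn <- nt + tr$Nnode
  P <- ncol(states)
  cost <- array(SANKOFF_BIG, dim = c(4, P, nn))
  for (i in seq_len(nt)) {
    for (s in 1:4) {
      hit <- bitwAnd(states[i, ], bitwShiftL(1L, s - 1L)) != 0L
      cost[s, hit, i] <- 0
    }
  }
  done <- logical(nn)
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    cc <- cost[, , ch, drop = FALSE]
    dim(cc) <- c(4, P)
    cmin <- pmin(cc[1, ], cc[2, ], cc[3, ], cc[4, ])
    contrib <- pmin(cc, rep(cmin + 1, each = 4))
    if (!done[p]) {
      cost[, , p] <- contrib
      done[p] <- TRUE
    } else {
      cost[, , p] <- cost[, , p] + contrib
    }
  }
  root <- edge[nrow(edge), 1]
  rc <- cost[, , root, drop = FALSE]
  dim(rc) <- c(4, P)
  mins <- pmin(rc[1, ], rc[2, ], rc[3, ], rc[4, ])
  if (per_pattern) mins else sum(mins * weights)
}

phylo_is_fitchable <- function(tree) {
  # every internal node degree <= 3 when viewed unrooted
  tab <- tabulate(tree$edge[, 1])
  kids <- tab[tab > 0]
  nt <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  all(tab[-root] %in% c(0L, 1L, 2L)) && tab[root] <= 3L
}

#' Parsimony length of a tree
#'
#' Minimum number of state changes needed on `tree` to explain the
#' alignment, minimized over all internal labelings. Binary trees use the
#' Fitch set pass; multifurcating trees use the exact unit-cost Sankoff
#' recursion, so scores remain exact certificates at any node degree. The
#' score is invariant under re-rooting.
#'
#' @param tree an `ape` `phylo` whose tip labels are exactly the
#'   alignment's taxa
#' @param aln a gap-free `mt_alignment`
#' @return integer parsimony score
#' @export
fitch_length <- function(tree, aln) {
  if (!setequal(tree$tip.label, taxa_labels(aln))) {
    stop_input("tree tip labels do not match alignment taxa")
  }
  enc <- encode_patterns(aln)
  states <- enc$states[tree$tip.label, , drop = FALSE]
  if (phylo_is_fitchable(tree)) {
    oe <- orient_edges(tree$edge, length(tree$tip.label))
    as.integer(round(fitch_oriented(oe, states, enc$weights)))
  } else {
    as.integer(round(sankoff_phylo(tree, states, enc$weights)))
  }
}

# canonical split-set key of an unrooted topology (for deduplication)
split_key <- function(tree) {
  tr <- ape::unroot(tree)
  labs <- sort(tr$tip.label)
  nt <- length(tr$tip.label)
  edge <- stats::reorder(tr, "postorder")$edge
  nn <- nt + tr$Nnode
  below <- vector("list", nn)
  for (i in seq_len(nt)) below[[i]] <- match(tr$tip.label[i], labs)
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  for (k in seq_len(nrow(edge))) {
    ch <- edge[k, 2]
    if (ch <= nt) next                     # trivial split
    side <- sort(below[[ch]])
    if (1L %in% side) side <- setdiff(seq_len(nt), side)
    if (length(side) < 2L) next
    keys <- c(keys, paste(side, collapse = "."))
  }
  paste(sort(unique(keys)), collapse = "|")
}

#' A set of equally parsimonious trees
#'
#' @param trees list of `phylo` trees (coerced to `multiPhylo`)
#' @param score their common parsimony score
#' @return list of class `mt_treeset` with elements `trees`, `score`
#' @export
new_treeset <- function(trees, score) {
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, score = as.integer(score)),
            class = "mt_treeset")
}

#' @export
print.mt_treeset <- function(x, ...) {
  cat(sprintf("mt_treeset: %d tree(s), parsimony score %d\n",
              length(x$trees), x$score))
  invisible(x)
}

#' Exhaustive search for all most-parsimonious trees
#'
#' Enumerates every unrooted binary topology on the alignment's taxa and
#' returns all topologies achieving the global minimum Fitch score. Serves
#' as the exact oracle against which the heuristic search is validated;
#' refuses more than `max_taxa` taxa (the topology count grows as
#' (2n-5)!!).
#'
#' @param aln a gap-free `mt_alignment`
#' @param max_taxa refuse enumeration above this many taxa (default 9)
#' @return an `mt_treeset` with all minimum-score topologies
#' @export
enumerate_mp_trees <- function(aln, max_taxa = 9L) {
  labs <- taxa_labels(aln)
  n <- length(labs)
  if (n < 2L) stop_input("need at least 2 taxa")
  if (n > max_taxa) {
    stop_input("too many taxa (", n, ") for exhaustive enumeration; ",
               "use heuristic_search()")
  }
  if (n <= 3L) {
    txt <- paste0("(", paste(labs, collapse = ","), ");")
    tr <- ape::read.tree(text = txt)
    return(new_treeset(list(tr), fitch_length(tr, aln)))
  }
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  enc <- encode_patterns(aln)
  scores <- vapply(seq_along(topos), function(i) {
    tr <- topos[[i]]                      # decompresses shared tip labels
    st <- enc$states[tr$tip.label, , drop = FALSE]
    fitch_oriented(orient_edges(tr$edge, n), st, enc$weights)
  }, numeric(1))
  best <- min(scores)
  new_treeset(lapply(which(scores == best), function(i) topos[[i]]),
              as.integer(round(best)))
}
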