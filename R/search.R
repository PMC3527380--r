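## Heuristic most-parsimonious tree search: stepwise addition in input
## ("simple") order builds the start tree, then tree bisection-reconnection
## (TBR) swapping climbs until no improving neighbor exists, collecting a
## deduplicated pool of all equal-best topologies encountered. The whole
## procedure is deterministic given the configuration: edge enumeration
## order is canonical, ties break on the first candidate, and a seed (if
## supplied) only perturbs the addition order of extra restarts.
##
## Trees are manipulated as raw undirected edge lists (tips 1..n, internal
## ids above n) and only converted to "phylo" when they enter the result
## pool; scoring goes through the same Fitch pass as fitch_length().

#' Search configuration
#'
#' @param max_equal_trees cap on the pool of equal-best topologies kept
#' @param max_explored cap on the number of pool trees whose full TBR
#'   neighborhood is expanded per restart
#' @param restarts additional stepwise-addition starts with rotated (or,
#'   with `seed`, randomly permuted) addition orders
#' @param seed optional integer; when set, restart addition orders are
#'   random permutations instead of deterministic rotations
#' @return a list of class `mt_search_config`
#' @export
search_config <- function(max_equal_trees = 100L, max_explored = 40L,
                          restarts = 1L, seed = NULL) {
  structure(list(max_equal_trees = as.integer(max_equal_trees),
                 max_explored = as.integer(max_explored),
                 restarts = as.integer(restarts), seed = seed),
            class = "mt_search_config")
}

graph_insert_tip <- function(edges, edge_i, tip, new_id) {
  u <- edges[edge_i, 1]; v <- edges[edge_i, 2]
  rbind(edges[-edge_i, , drop = FALSE],
        c(u, new_id), c(new_id, v), c(new_id, tip))
}

graph_to_phylo <- function(edges, tip_labels) {
  nt <- length(tip_labels)
  oe <- orient_edges(edges, nt)
  ids <- unique(as.vector(t(oe)))
  internal <- ids[ids > nt]
  remap <- integer(max(ids))
  remap[seq_len(nt)] <- seq_len(nt)
  remap[internal] <- nt + seq_along(internal)
  edge <- cbind(remap[oe[, 1]], remap[oe[, 2]])
  structure(list(edge = edge, tip.label = tip_labels,
                 Nnode = length(internal)),
            class = "phylo", order = "cladewise")
}

graph_score <- function(edges, enc_states, weights) {
  fitch_oriented(orient_edges(edges, nrow(enc_states)), enc_states, weights)
}

# connected component of `node` in the edge list, as edge-row indices
component_edges <- function(edges, node) {
  maxid <- max(edges)
  inset <- logical(maxid)
  inset[node] <- TRUE
  repeat {
    hit <- inset[edges[, 1]] | inset[edges[, 2]]
    newnodes <- unique(as.vector(edges[hit, , drop = FALSE]))
    if (all(inset[newnodes])) break
    inset[newnodes] <- TRUE
  }
  which(inset[edges[, 1]])
}

# detach at edge e and suppress the stranded degree-2 endpoint; returns the
# component's edges plus attachment descriptors (edge rows, or a bare node)
prep_component <- function(edges_rest, endpoint, n_tips) {
  rows <- component_edges(edges_rest, endpoint)
  comp <- edges_rest[rows, , drop = FALSE]
  if (nrow(comp) == 0L) {
    return(list(edges = comp, points = list(list(node = endpoint)),
                freed = integer(0)))
  }
  freed <- integer(0)
  if (endpoint > n_tips) {
    touching <- which(comp[, 1] == endpoint | comp[, 2] == endpoint)
    if (length(touching) == 2L) {
      others <- c(setdiff(comp[touching[1], ], endpoint),
                  setdiff(comp[touching[2], ], endpoint))
      comp <- rbind(comp[-touching, , drop = FALSE], others)
      freed <- endpoint
    }
  }
  pts <- lapply(seq_len(nrow(comp)), function(i) list(edge = i))
  list(edges = comp, points = pts, freed = freed)
}

# all TBR rearrangements of an unrooted binary tree (includes the original)
tbr_neighbors <- function(edges, n_tips) {
  out <- list()
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    rest <- edges[-e, , drop = FALSE]
    A <- prep_component(rest, u, n_tips)
    B <- prep_component(rest, v, n_tips)
    idA <- if (length(A$freed)) A$freed else u
    idB <- if (length(B$freed)) B$freed else v
    for (pa in A$points) {
      for (pb in B$points) {
        ea <- A$edges; eb <- B$edges
        if (!is.null(pa$edge)) {
          a1 <- ea[pa$edge, 1]; a2 <- ea[pa$edge, 2]
          ea <- rbind(ea[-pa$edge, , drop = FALSE], c(a1, idA), c(idA, a2))
          xa <- idA
        } else xa <- pa$node
        if (!is.null(pb$edge)) {
          b1 <- eb[pb$edge, 1]; b2 <- eb[pb$edge, 2]
          eb <- rbind(eb[-pb$edge, , drop = FALSE], c(b1, idB), c(idB, b2))
          xb <- idB
        } else xb <- pb$node
        out[[length(out) + 1L]] <- rbind(ea, eb, c(xa, xb))
      }
    }
  }
  out
}

graph_split_key <- function(edges, n_tips) {
  oe <- orient_edges(edges, n_tips)
  maxid <- max(oe)
  below <- vector("list", maxid)
  for (i in seq_len(n_tips)) below[[i]] <- i
  for (k in rev(seq_len(nrow(oe)))) {
    p <- oe[k, 1]; ch <- oe[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  for (k in seq_len(nrow(oe))) {
    ch <- oe[k, 2]
    if (ch <= n_tips) next
    side <- sort(unique(below[[ch]]))
    if (1L %in% side) side <- setdiff(seq_len(n_tips), side)
    if (length(side) >= 2L && length(side) <= n_tips - 2L) {
      keys <- c(keys, paste(side, collapse = "."))
    }
  }
  paste(sort(unique(keys)), collapse = "|")
}

stepwise_addition <- function(enc_states, weights, order_idx) {
  n <- nrow(enc_states)
  first3 <- order_idx[1:3]
  hub <- n + 1L
  edges <- cbind(rep(hub, 3L), first3)
  next_id <- n + 2L
  for (k in seq(4L, n)) {
    tip <- order_idx[k]
    best_s <- Inf; best_e <- NA_integer_
    for (ei in seq_len(nrow(edges))) {
      cand <- graph_insert_tip(edges, ei, tip, next_id)
      s <- graph_score(cand, enc_states, weights)
      if (s < best_s) { best_s <- s; best_e <- ei }
    }
    edges <- graph_insert_tip(edges, best_e, tip, next_id)
    next_id <- next_id + 1L
  }
  edges
}

#' Heuristic most-parsimonious tree search
#'
#' Stepwise addition in input order followed by TBR branch swapping.
#' Equal-best topologies are pooled (deduplicated by canonical split-set
#' key) and the pool is returned with its common score. Deterministic
#' given the configuration.
#'
#' @param aln a gap-free `mt_alignment` with at least 4 taxa (3 or fewer
#'   taxa have a single topology, returned directly)
#' @param config an [search_config()]
#' @return an `mt_treeset`
#' @export
heuristic_search <- function(aln, config = search_config()) {
  labs <- taxa_labels(aln)
  n <- length(labs)
  if (n <= 3L) return(enumerate_mp_trees(aln))
  enc <- encode_patterns(aln)
  states <- enc$states
  weights <- enc$weights

  orders <- list(seq_len(n))
  if (config$restarts > 0L) {
    for (r in seq_len(config$restarts)) {
      orders[[r + 1L]] <-
        if (is.null(config$seed)) {
          c(seq_len(n)[-seq_len(r)], seq_len(r))  # rotation
        } else {
          with_seed(config$seed + r, sample(n))
        }
    }
  }

  best_score <- Inf
  pool <- list()        # key -> edges
  for (ord in orders) {
    start <- stepwise_addition(states, weights, ord)
    s0 <- graph_score(start, states, weights)
    if (s0 < best_score) {
      best_score <- s0
      pool <- list()
      pool[[graph_split_key(start, n)]] <- start
      queue <- list(start)
    } else if (s0 == best_score) {
      k0 <- graph_split_key(start, n)
      queue <- list()
      if (is.null(pool[[k0]])) { pool[[k0]] <- start; queue <- list(start) }
    } else {
      queue <- list(start)  # still explore: TBR may reach the best score
    }
    explored <- 0L
    local_best <- s0
    while (length(queue) > 0L && explored < config$max_explored) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      explored <- explored + 1L
      for (nb in tbr_neighbors(cur, n)) {
        s <- graph_score(nb, states, weights)
        if (s < best_score) {
          best_score <- s
          pool <- list()
          key <- graph_split_key(nb, n)
          pool[[key]] <- nb
          queue <- list(nb)
          explored <- 0L
        } else if (s == best_score &&
                   length(pool) < config$max_equal_trees) {
          key <- graph_split_key(nb, n)
          if (is.null(pool[[key]])) {
            pool[[key]] <- nb
            queue[[length(queue) + 1L]] <- nb
          }
        }
      }
    }
  }
  keys <- sort(names(pool))
  trees <- lapply(pool[keys], graph_to_phylo, tip_labels = labs)
  names(trees) <- NULL
  new_treeset(trees, as.integer(round(best_score)))
}

#' Strict consensus of a tree set
#'
#' Keeps exactly the splits present in every member tree; conflicting or
#' unstable regions collapse to polytomies (e.g. the multi-way radiation
#' at the base of a star-like subclade). Also records, as attribute
#' `incompatible_splits`, the splits present in some but not all trees.
#'
#' @param ts an `mt_treeset` (trees share one leaf set)
#' @return a `phylo` (possibly multifurcating)
#' @export
strict_consensus <- function(ts) {
  trees <- ts$trees
  if (length(trees) == 0L) stop_input("empty tree set")
  labs <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), labs)) {
      stop_input("trees do not share a common leaf set")
    }
  }
  if (length(trees) == 1L) return(trees[[1]])
  cons <- ape::consensus(trees, p = 1, rooted = FALSE)
  all_keys <- lapply(trees, function(tr) {
    strsplit(split_key(tr), "|", fixed = TRUE)[[1]]
  })
  shared <- Reduce(intersect, all_keys)
  attr(cons, "incompatible_splits") <- setdiff(unique(unlist(all_keys)),
                                               shared)
  cons
}
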