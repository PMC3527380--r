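## Partition-based minimality certificates.
##
## The heuristic search score is an upper bound on the true minimum tree
## length. A lower bound comes from any partition of the variable columns
## into disjoint blocks: the sum over blocks of the exact minimum
## parsimony score of that block (minimized over ALL trees) can never
## exceed the best single tree's score, because that tree is one candidate
## for every block. When the two bounds meet, the heuristic trees are
## provably shortest. A single column with k states has block minimum
## k - 1; the gain comes from grouping mutually incompatible columns,
## whose joint minimum exceeds the sum of their individual minima (the
## "rectangle" argument: a cycle of conflicting splits cannot be embedded
## in a tree without an extra change on one of its sides).

variable_columns <- function(aln) {
  which(apply(aln$matrix, 2, function(col) length(unique(col)) >= 2L))
}

col_states <- function(aln, j) length(unique(aln$matrix[, j]))

#' Exact minimum parsimony score of a character block
#'
#' The minimum Fitch length of the block's columns over all unrooted
#' binary trees on the taxa, computed after collapsing taxa with identical
#' block patterns (the score only depends on distinct patterns). Exact by
#' construction: blocks whose collapsed taxon count exceeds `max_collapsed`
#' are refused rather than approximated.
#'
#' @param aln a gap-free `mt_alignment`
#' @param block integer vector of column indices
#' @param max_collapsed refusal threshold for exhaustive minimization
#' @return integer block minimum
#' @export
block_min_score <- function(aln, block, max_collapsed = 9L) {
  sub <- aln$matrix[, block, drop = FALSE]
  pat <- apply(sub, 1, paste, collapse = "")
  reps <- !duplicated(pat)
  cc <- sum(reps)
  if (cc <= 3L) {
    # any topology on <= 3 pattern-taxa realizes k-1 changes per column
    return(sum(apply(sub[reps, , drop = FALSE], 2,
                     function(col) length(unique(col)) - 1L)))
  }
  if (cc > max_collapsed) {
    stop_input("block collapses to ", cc, " distinct patterns ",
               "(> ", max_collapsed, "); split the block for exact ",
               "minimization")
  }
  collapsed <- sub[reps, , drop = FALSE]
  rownames(collapsed) <- paste0("p", seq_len(cc))
  sub_aln <- new_alignment(collapsed, seq_len(ncol(collapsed)))
  enumerate_mp_trees(sub_aln, max_taxa = max_collapsed)$score
}

# conflict screen for two columns: build the bipartite graph of observed
# joint states; a cycle (edges > vertices - components) certifies
# incompatibility, i.e. the pair needs more changes together than apart
columns_conflict <- function(aln, i, j) {
  a <- aln$matrix[, i]; b <- aln$matrix[, j]
  joint <- unique(paste(a, b))
  va <- unique(a); vb <- unique(b)
  n_vert <- length(va) + length(vb)
  n_edge <- length(joint)
  # count components of the bipartite graph by union-find
  parent <- seq_len(n_vert)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in joint) {
    ab <- strsplit(p, " ", fixed = TRUE)[[1]]
    x <- find(match(ab[1], va))
    y <- find(length(va) + match(ab[2], vb))
    if (x != y) parent[x] <- y
  }
  comps <- length(unique(vapply(seq_len(n_vert), find, integer(1))))
  n_edge > n_vert - comps
}

#' Group conflicting characters into shared blocks
#'
#' Builds a partition of the variable columns: each homoplasy-candidate
#' column is greedily merged with the columns it is incompatible with
#' (so that the extra change their conflict forces enters the lower
#' bound), and all remaining columns stay singleton blocks. Merges that
#' would exceed the exact-minimization size limit are skipped.
#'
#' @param aln a gap-free `mt_alignment`
#' @param recurrent_sites rCRS positions known to need more than one
#'   change (e.g. from [map_mutations()]); used to seed the conflict scan,
#'   which also screens all informative-column pairs
#' @param max_collapsed exactness limit forwarded to [block_min_score()]
#' @return list of class `mt_partition`: `blocks` (list of integer column
#'   index vectors), disjoint and covering all variable columns
#' @export
build_rectangle_blocks <- function(aln, recurrent_sites = integer(0),
                                   max_collapsed = 9L) {
  vc <- variable_columns(aln)
  rep <- informative_sites(aln)
  inf <- rep$informative_columns
  seed_cols <- union(intersect(match(recurrent_sites, aln$positions), inf),
                     inf)
  seed_cols <- sort(seed_cols[!is.na(seed_cols)])
  # union-find over variable columns
  comp <- setNames(seq_along(vc), vc)
  findc <- function(x) { while (comp[[x]] != x) x <- comp[[x]]; comp[[x]] }
  if (length(seed_cols) >= 2L) {
    pairs <- utils::combn(seed_cols, 2L)
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1, q]; j <- pairs[2, q]
      if (columns_conflict(aln, i, j)) {
        xi <- findc(match(i, vc)); xj <- findc(match(j, vc))
        if (xi != xj) {
          merged <- c(vc[vapply(seq_along(vc), findc, 1L) %in% c(xi, xj)])
          pat <- apply(aln$matrix[, merged, drop = FALSE], 1,
                       paste, collapse = "")
          if (length(unique(pat)) <= max_collapsed) comp[xi] <- xj
        }
      }
    }
  }
  roots <- vapply(seq_along(vc), findc, 1L)
  blocks <- unname(split(vc, roots))
  blocks <- blocks[order(vapply(blocks, min, 1L))]
  structure(list(blocks = blocks), class = "mt_partition")
}

partition_lower_bound <- function(aln, partition, max_collapsed = 9L) {
  minima <- vapply(partition$blocks, function(b)
    block_min_score(aln, b, max_collapsed), numeric(1))
  list(minima = as.integer(minima), lower = as.integer(sum(minima)))
}

#' Prove (or fail to prove) minimality of a parsimony score
#'
#' Searches over character partitions — singletons, then conflict-guided
#' merges, then a budgeted hill-climb over block merges — maximizing the
#' partition lower bound. If the lower bound reaches the upper bound the
#' score is certified globally minimal.
#'
#' @param aln a gap-free `mt_alignment`
#' @param upper_bound the heuristic search score
#' @param trees optional `mt_treeset` or list of trees claimed to achieve
#'   `upper_bound`; if supplied, the bound is recomputed and must be
#'   achieved by at least one tree
#' @param budget iteration cap on the merge hill-climb (deterministic)
#' @param max_collapsed exactness limit forwarded to [block_min_score()]
#' @return an `mt_certificate`: `upper_bound`, `partition` (blocks as rCRS
#'   position lists), `block_minima`, `lower_bound`, `status`
#'   (`"proven"` iff the bounds meet)
#' @export
squeeze <- function(aln, upper_bound, trees = NULL, budget = 200L,
                    max_collapsed = 9L) {
  upper_bound <- as.integer(upper_bound)
  if (!is.null(trees)) {
    tl <- if (inherits(trees, "mt_treeset")) trees$trees else trees
    achieved <- vapply(tl, function(tr) fitch_length(tr, aln), integer(1))
    if (!any(achieved == upper_bound)) {
      stop_input("upper_bound ", upper_bound,
                 " is not achieved by any provided tree (scores: ",
                 paste(achieved, collapse = ","), ")")
    }
  }
  part <- build_rectangle_blocks(aln, max_collapsed = max_collapsed)
  lb <- partition_lower_bound(aln, part, max_collapsed)

  # hill-climb: merge block pairs while the bound improves
  iter <- 0L
  improved <- TRUE
  while (improved && iter < budget && lb$lower < upper_bound) {
    improved <- FALSE
    nb <- length(part$blocks)
    multi <- which(lengths(part$blocks) > 1L)
    cand_pairs <- list()
    for (i in multi) for (j in seq_len(nb)) if (j != i) {
      cand_pairs[[length(cand_pairs) + 1L]] <- sort(c(i, j))
    }
    cand_pairs <- unique(cand_pairs)
    for (pr in cand_pairs) {
      iter <- iter + 1L
      if (iter >= budget) break
      bi <- part$blocks[[pr[1]]]; bj <- part$blocks[[pr[2]]]
      merged <- sort(c(bi, bj))
      pat <- apply(aln$matrix[, merged, drop = FALSE], 1, paste,
                   collapse = "")
      if (length(unique(pat)) > max_collapsed) next
      m <- block_min_score(aln, merged, max_collapsed)
      if (m > lb$minima[pr[1]] + lb$minima[pr[2]]) {
        part$blocks[[pr[1]]] <- merged
        part$blocks <- part$blocks[-pr[2]]
        lb <- partition_lower_bound(aln, part, max_collapsed)
        improved <- TRUE
        break
      }
    }
  }
  status <- if (lb$lower == upper_bound) "proven" else "unproven"
  structure(list(
    upper_bound = upper_bound,
    partition = lapply(part$blocks, function(b) aln$positions[b]),
    block_columns = part$blocks,
    block_minima = lb$minima,
    lower_bound = lb$lower,
    status = status), class = "mt_certificate")
}

#' @export
print.mt_certificate <- function(x, ...) {
  cat(sprintf("mt_certificate: upper %d, lower %d over %d block(s) -> %s\n",
              x$upper_bound, x$lower_bound, length(x$block_minima),
              x$status))
  invisible(x)
}

#' Independently re-check a minimality certificate
#'
#' Recomputes every block minimum from the certificate's partition and
#' verifies disjointness, coverage of all variable columns, the summed
#' lower bound, and the proven/unproven status.
#'
#' @param aln the alignment the certificate refers to
#' @param cert an `mt_certificate`
#' @return `TRUE` if the certificate verifies; otherwise a character
#'   vector of discrepancies
#' @export
check_certificate <- function(aln, cert) {
  problems <- character(0)
  cols <- unlist(cert$block_columns)
  if (anyDuplicated(cols)) problems <- c(problems, "blocks not disjoint")
  if (!setequal(cols, variable_columns(aln))) {
    problems <- c(problems, "blocks do not cover the variable columns")
  }
  minima <- vapply(cert$block_columns, function(b) block_min_score(aln, b),
                   numeric(1))
  if (!identical(as.integer(minima), cert$block_minima)) {
    problems <- c(problems, "stored block minima do not recompute")
  }
  if (sum(minima) != cert$lower_bound) {
    problems <- c(problems, "lower bound does not equal the block sum")
  }
  want <- if (cert$lower_bound == cert$upper_bound) "proven" else "unproven"
  if (!identical(want, cert$status)) {
    problems <- c(problems, "status inconsistent with bounds")
  }
  if (length(problems)) problems else TRUE
}

#' Serialize a certificate to JSON
#'
#' @param cert an `mt_certificate`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_certificate_json <- function(cert, path) {
  jsonlite::write_json(
    list(upper_bound = cert$upper_bound, lower_bound = cert$lower_bound,
         status = cert$status, block_minima = cert$block_minima,
         partition_positions = cert$partition),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
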