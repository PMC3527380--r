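## Rho-statistic founder-age estimation.
##
## rho is the mean number of (filtered) mutations on the paths from a
## clade's root to each of its leaves; multiplied by a calibration in
## years per mutation it estimates the clade's TMRCA. The synonymous-only
## clock counts only synonymous protein-gene substitutions at the average
## rate of 1 change per 6760 years; the complete-sequence clock counts all
## substitutions except a short list of hypervariable positions (16182,
## 16183, 16194, 16519) with a user-supplied rate. The standard error is
## the heritage estimator se_rho^2 = sum over clade branches of
## (n_b / n)^2 * m_b, with n_b leaves below the branch and m_b filtered
## mutations on it; for a star genealogy this reduces to sqrt(rho / n).

#' Calibration configuration for rho dating
#'
#' @param method `"kivisild_synonymous"` (synonymous protein-gene
#'   substitutions only, 1 change per 6760 years) or `"soares_complete"`
#'   (all substitutions minus excluded hypervariable positions;
#'   `years_per_change` must be supplied from an external rate fit)
#' @param years_per_change calibration in years per counted change
#' @param excluded_positions rCRS positions never counted (soares default
#'   16182, 16183, 16194, 16519)
#' @return list of class `mt_calibration`
#' @export
calibration_config <- function(method = c("kivisild_synonymous",
                                          "soares_complete"),
                               years_per_change = NULL,
                               excluded_positions = NULL) {
  method <- match.arg(method)
  if (method == "kivisild_synonymous") {
    years_per_change <- years_per_change %||% 6760
    excluded_positions <- excluded_positions %||% integer(0)
  } else {
    if (is.null(years_per_change)) {
      stop_input("soares_complete requires years_per_change (external rate)")
    }
    excluded_positions <- excluded_positions %||%
      c(16182L, 16183L, 16194L, 16519L)
  }
  if (years_per_change <= 0) stop_input("years_per_change must be > 0")
  if (length(excluded_positions) &&
      any(excluded_positions < 1L | excluded_positions > RCRS_LENGTH)) {
    stop_input("excluded positions must lie in 1..", RCRS_LENGTH)
  }
  structure(list(method = method, years_per_change = years_per_change,
                 excluded_positions = as.integer(excluded_positions)),
            class = "mt_calibration")
}

mutation_passes_filter <- function(calls, cal) {
  if (is.null(calls) || nrow(calls) == 0L) return(logical(0))
  if (cal$method == "kivisild_synonymous") {
    calls$kind != "deletion" & !is.na(calls$effect) &
      calls$effect == "synonymous"
  } else {
    calls$kind != "deletion" & !(calls$position %in% cal$excluded_positions)
  }
}

clade_leaves <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  sort(out)
}

# edges on the path node -> leaf, as rows of tree$edge
path_edges <- function(tree, node, leaf) {
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  rows <- integer(0)
  v <- leaf
  while (v != node) {
    k <- parent_of[v]
    if (k == 0L) stop_input("leaf is not below the requested clade root")
    rows <- c(rows, k)
    v <- tree$edge[k, 1]
  }
  rows
}

#' Filtered root-to-leaf mutation counts within a clade
#'
#' @param atree an `mt_annotated_tree` from [map_mutations()]
#' @param clade_root internal node id (or a tip id for a one-leaf clade,
#'   counted over its pendant branch)
#' @param cal an [calibration_config()]
#' @return named integer vector, one count per leaf of the clade
#' @export
count_path_changes <- function(atree, clade_root, cal) {
  if (!inherits(atree, "mt_annotated_tree")) {
    stop_input("count_path_changes needs a mutation-annotated tree; ",
               "run map_mutations() first")
  }
  tree <- atree$tree
  n_tip <- length(tree$tip.label)
  start <- clade_root
  if (clade_root <= n_tip) start <- tree$edge[tree$edge[, 2] == clade_root, 1]
  leaves <- clade_leaves(tree, clade_root)
  counts <- vapply(leaves, function(lf) {
    rows <- path_edges(tree, start, lf)
    sum(vapply(rows, function(k) {
      sum(mutation_passes_filter(atree$edge_mutations[[k]], cal))
    }, numeric(1)))
  }, numeric(1))
  setNames(as.integer(counts), tree$tip.label[leaves])
}

saillard_se <- function(atree, clade_root, cal) {
  tree <- atree$tree
  n_tip <- length(tree$tip.label)
  start <- clade_root
  if (clade_root <= n_tip) start <- tree$edge[tree$edge[, 2] == clade_root, 1]
  leaves <- clade_leaves(tree, clade_root)
  n <- length(leaves)
  rows <- unique(unlist(lapply(leaves, function(lf)
    path_edges(tree, start, lf))))
  v <- sum(vapply(rows, function(k) {
    m_b <- sum(mutation_passes_filter(atree$edge_mutations[[k]], cal))
    below <- clade_leaves(tree, tree$edge[k, 2])
    n_b <- length(intersect(below, leaves))
    (n_b / n)^2 * m_b
  }, numeric(1)))
  sqrt(v)
}

#' Rho estimate and calibrated age
#'
#' `rho` is the mean of the per-leaf counts; `age_years` is exactly
#' `rho * years_per_change`. The standard error uses the heritage
#' branch-weighted estimator when tree context is supplied (via
#' [date_named_clades()]), and its star-genealogy reduction
#' `sqrt(rho / n)` when only counts are available.
#'
#' @param counts per-leaf filtered change counts
#' @param cal an [calibration_config()]
#' @param se_rho optional externally computed standard error of rho
#' @return list of class `mt_rho_estimate`: `n_leaves`, `per_leaf_counts`,
#'   `rho`, `se_rho`, `age_years`, `se_years`, `method`
#' @export
estimate_age <- function(counts, cal, se_rho = NULL) {
  if (length(counts) < 1L) stop_input("empty clade")
  rho <- mean(counts)
  n <- length(counts)
  if (is.null(se_rho)) se_rho <- sqrt(rho / n)
  structure(list(n_leaves = n, per_leaf_counts = counts, rho = rho,
                 se_rho = se_rho,
                 age_years = rho * cal$years_per_change,
                 se_years = se_rho * cal$years_per_change,
                 method = cal$method),
            class = "mt_rho_estimate")
}

#' @export
print.mt_rho_estimate <- function(x, ...) {
  cat(sprintf("rho %.3f (se %.3f) over %d leaves -> %.0f +/- %.0f years [%s]\n",
              x$rho, x$se_rho, x$n_leaves, x$age_years, x$se_years,
              x$method))
  invisible(x)
}

#' Date named clades on an annotated tree
#'
#' @param atree an `mt_annotated_tree`
#' @param clade_specs named list of tip-label vectors; each must be
#'   monophyletic on the tree (a one-label spec dates that leaf's pendant
#'   branch)
#' @param cal an [calibration_config()]
#' @return named list of `mt_rho_estimate`
#' @export
date_named_clades <- function(atree, clade_specs, cal) {
  tree <- atree$tree
  out <- list()
  for (nm in names(clade_specs)) {
    tips <- clade_specs[[nm]]
    missing <- setdiff(tips, tree$tip.label)
    if (length(missing)) {
      stop_input("clade '", nm, "' names unknown taxa: ",
                 paste(missing, collapse = ", "))
    }
    if (length(tips) == 1L) {
      node <- match(tips, tree$tip.label)
    } else {
      node <- ape::getMRCA(tree, tips)
      actual <- tree$tip.label[clade_leaves(tree, node)]
      extra <- setdiff(actual, tips)
      if (length(extra)) {
        stop_input("clade '", nm, "' is not monophyletic; its MRCA also ",
                   "contains: ", paste(extra, collapse = ", "))
      }
    }
    counts <- count_path_changes(atree, node, cal)
    out[[nm]] <- estimate_age(counts, cal,
                              se_rho = saillard_se(atree, node, cal))
  }
  out
}

#' Dating table
#'
#' @param estimates named list of `mt_rho_estimate` (from
#'   [date_named_clades()])
#' @return data frame: clade, n_leaves, rho, se_rho, age_years, se_years,
#'   method
#' @export
dating_table <- function(estimates) {
  do.call(rbind, lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    data.frame(clade = nm, n_leaves = e$n_leaves, rho = e$rho,
               se_rho = e$se_rho, age_years = e$age_years,
               se_years = e$se_years, method = e$method,
               stringsAsFactors = FALSE)
  }))
}
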