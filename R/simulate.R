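## Synthetic mtDNA generator.
##
## Sequences evolve along a genealogy with branch durations in years and
## per-class Poisson mutation rates per lineage-year, anchored to the
## packaged reference frame. Class-conditional site choice is
## context-aware: a "synonymous" event is rejection-sampled until the
## proposed change really is synonymous in the lineage's current codon
## background, so classification stays correct under multiple hits. The
## full truth (tree, event list, per-clade TMRCA) is recorded so every
## downstream stage can be checked against it.

#' Simulation configuration
#'
#' @param n_leaves number of leaves (>= 2)
#' @param genealogy `"star"`, `"yule"` or `"coalescent"`
#' @param tmrca_years tree depth in years (required for `"star"`; for the
#'   others the standard construction is rescaled to this depth when set)
#' @param rates per-class mutation rates per lineage-year, named
#'   `synonymous`, `nonsynonymous`, `rna`, `control`; the synonymous
#'   default 1/6760 matches the synonymous-clock calibration
#' @param ts_tv transition:transversion weight (default 20, typical for
#'   human mtDNA)
#' @param recurrent_prob probability that an event re-uses an already
#'   mutated site (forcing parallelisms/reversions)
#' @param seed integer seed; all generator randomness derives from it
#' @return list of class `mt_sim_config`
#' @export
sim_config <- function(n_leaves = 7L,
                       genealogy = c("star", "yule", "coalescent"),
                       tmrca_years = 22430,
                       rates = c(synonymous = 1 / 6760, nonsynonymous = 0,
                                 rna = 0, control = 0),
                       ts_tv = 20, recurrent_prob = 0, seed = 1L) {
  genealogy <- match.arg(genealogy)
  if (n_leaves < 2L) stop_input("n_leaves must be >= 2")
  full <- c(synonymous = 0, nonsynonymous = 0, rna = 0, control = 0)
  full[names(rates)] <- rates
  if (any(full < 0)) stop_input("rates must be >= 0")
  structure(list(n_leaves = as.integer(n_leaves), genealogy = genealogy,
                 tmrca_years = tmrca_years, rates = full, ts_tv = ts_tv,
                 recurrent_prob = recurrent_prob, seed = as.integer(seed)),
            class = "mt_sim_config")
}

#' Simulate a genealogy with branch durations
#'
#' Star genealogies emit `n_leaves` branches of length `tmrca_years` from
#' a single root (the multi-way radiation regime); Yule and coalescent
#' genealogies use the standard constructions (coalescent branch lengths
#' are in coalescent units unless `tmrca_years` rescales them).
#' Deterministic given the seed.
#'
#' @param cfg an [sim_config()]
#' @return a rooted `phylo` with `edge.length` in years
#' @export
simulate_genealogy <- function(cfg) {
  n <- cfg$n_leaves
  labs <- sprintf("L%02d", seq_len(n))
  if (cfg$genealogy == "star") {
    if (is.null(cfg$tmrca_years)) stop_input("star genealogy needs tmrca_years")
    txt <- paste0("(", paste0(labs, ":", cfg$tmrca_years, collapse = ","),
                  ");")
    return(ape::read.tree(text = txt))
  }
  tr <- with_seed(cfg$seed, {
    if (cfg$genealogy == "yule") ape::rphylo(n, birth = 1, death = 0)
    else ape::rcoal(n)
  })
  tr$tip.label <- labs
  if (!is.null(cfg$tmrca_years)) {
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * cfg$tmrca_years / depth
  }
  tr
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

propose_base <- function(from, ts_tv) {
  tv <- setdiff(BASES, c(from, transition_of[[from]]))
  w <- c(ts_tv, 1, 1)
  pick <- sample.int(3L, 1L, prob = w / sum(w))
  c(transition_of[[from]], tv)[pick]
}

is_effect_change <- function(pos, from, to, genemap, background, want) {
  gene <- protein_gene_at(genemap, pos)
  code <- mito_genetic_code()
  aa_f <- translate_codon(codon_at(gene, pos, background, from), code)
  aa_t <- translate_codon(codon_at(gene, pos, background, to), code)
  if (want == "synonymous") aa_f == aa_t else aa_f != aa_t
}

#' Evolve sequences along a genealogy
#'
#' @param tree rooted `phylo` with durations in years
#' @param ref an `mt_reference` (the root sequence)
#' @param genemap an `mt_genemap`
#' @param cfg an [sim_config()]
#' @return list with `alignment` (full-length `mt_alignment` of the
#'   leaves) and `truth` (class `mt_sim_truth`: `tree`, `events` data
#'   frame with edge/position/from/to/class, `root_sequence`, `seed`)
#' @export
evolve_sequences <- function(tree, ref, genemap, cfg) {
  cls <- feature_classes(genemap)
  pools <- list(synonymous = which(cls == "protein"),
                nonsynonymous = which(cls == "protein"),
                rna = which(cls %in% c("rRNA", "tRNA")),
                control = which(cls == "control"))
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  pre <- rev(seq_len(nrow(edge)))
  n_tip <- length(tr$tip.label)
  nn <- n_tip + tr$Nnode

  with_seed(cfg$seed, {
    seqs <- vector("list", nn)
    root <- edge[nrow(edge), 1]
    seqs[[root]] <- ref$sequence
    mutated <- integer(0)
    ev <- list()
    for (k in pre) {
      p <- edge[k, 1]; ch <- edge[k, 2]
      s <- seqs[[p]]
      dur <- tr$edge.length[k]
      for (classname in names(cfg$rates)) {
        rate <- cfg$rates[[classname]]
        if (rate <= 0 || dur <= 0) next
        n_ev <- rpois(1L, rate * dur)
        for (e in seq_len(n_ev)) {
          placed <- FALSE
          for (attempt in 1:200) {
            reuse <- length(mutated) > 0 && runif(1) < cfg$recurrent_prob
            pool <- if (reuse) intersect(mutated, pools[[classname]])
                    else pools[[classname]]
            if (!length(pool)) pool <- pools[[classname]]
            pos <- pool[sample.int(length(pool), 1L)]
            from <- s[pos]
            to <- propose_base(from, cfg$ts_tv)
            ok <- if (classname %in% c("synonymous", "nonsynonymous")) {
              is_effect_change(pos, from, to, genemap, s, classname)
            } else TRUE
            if (ok) {
              s[pos] <- to
              mutated <- union(mutated, pos)
              ev[[length(ev) + 1L]] <- data.frame(
                edge = k, position = pos, from = from, to = to,
                class = classname, stringsAsFactors = FALSE)
              placed <- TRUE
              break
            }
          }
          if (!placed) warning("could not place a ", classname,
                               " event after 200 attempts")
        }
      }
      seqs[[ch]] <- s
    }
    leaf_mat <- do.call(rbind, seqs[seq_len(n_tip)])
    rownames(leaf_mat) <- tr$tip.label
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(edge = integer(), position = integer(),
                 from = character(), to = character(), class = character(),
                 stringsAsFactors = FALSE)
    truth <- structure(list(tree = tr, events = events,
                            root_sequence = ref$sequence, seed = cfg$seed),
                       class = "mt_sim_truth")
    list(alignment = new_alignment(leaf_mat, seq_len(RCRS_LENGTH)),
         truth = truth)
  })
}

#' Replay recorded mutation events
#'
#' Applies the truth's events along its tree from the root sequence and
#' returns the implied leaf matrix — must reproduce the emitted alignment
#' exactly (the generator's core invariant).
#'
#' @param truth an `mt_sim_truth`
#' @return character matrix of leaf sequences
#' @export
replay_truth <- function(truth) {
  tr <- truth$tree
  edge <- tr$edge
  n_tip <- length(tr$tip.label)
  seqs <- vector("list", n_tip + tr$Nnode)
  root <- edge[nrow(edge), 1]
  seqs[[root]] <- truth$root_sequence
  for (k in rev(seq_len(nrow(edge)))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    s <- seqs[[p]]
    rows <- truth$events[truth$events$edge == k, , drop = FALSE]
    if (nrow(rows)) {
      for (i in seq_len(nrow(rows))) s[rows$position[i]] <- rows$to[i]
    }
    seqs[[ch]] <- s
  }
  out <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(out) <- tr$tip.label
  out
}

Q2A_PRESET_NEWICK <- paste0(
  "(AUS:34650,(FA093:22430,PD047:22430,Q2a_g1:22430,Q2a_g2:22430,",
  "Q2a_g3:22430,(PB036:10000,FA064:10000):12430,",
  "(PD057:6760,K058:6760,KI018:6760):15670):12220);")

#' Star-radiation preset emulating a deeply structured Q2a-like clade
#'
#' Eleven leaves: a basal lineage (`AUS`) plus a subclade whose root is a
#' 7-way polytomy — two immediate descendants, three further singleton
#' lineages, a 2-leaf group and a 3-leaf group — with long private
#' branches. Known per-clade TMRCAs: subclade root 22,430 y, full clade
#' 34,650 y, the 3-leaf group 6,760 y, the 2-leaf group 10,000 y.
#' Mutation rates: synonymous 1/6760 per lineage-year (the clock
#' calibration), plus non-synonymous, RNA-gene and control-region classes
#' at realistic relative rates, transition bias 20:1, occasional
#' recurrent-site reuse.
#'
#' @param seed integer seed (fixed seed gives byte-identical output)
#' @return list with `alignment`, `truth` (with `clades`: tip sets and
#'   `tmrca`: true ages in years), and `config`
#' @export
q2a_preset <- function(seed = 1L) {
  lr <- load_reference()
  tree <- ape::read.tree(text = Q2A_PRESET_NEWICK)
  cfg <- sim_config(
    n_leaves = 11L, genealogy = "star", tmrca_years = 34650,
    rates = c(synonymous = 1 / 6760, nonsynonymous = 1 / 20000,
              rna = 1 / 25000, control = 1 / 9000),
    ts_tv = 20, recurrent_prob = 0.02, seed = seed)
  sim <- evolve_sequences(tree, lr$reference, lr$genemap, cfg)
  q2a_tips <- c("FA093", "PD047", "Q2a_g1", "Q2a_g2", "Q2a_g3",
                "PB036", "FA064", "PD057", "K058", "KI018")
  sim$truth$clades <- list(
    Q2 = c("AUS", q2a_tips),
    Q2a = q2a_tips,
    subB = c("PB036", "FA064"),
    subC = c("PD057", "K058", "KI018"))
  sim$truth$tmrca <- c(Q2 = 34650, Q2a = 22430, subB = 10000, subC = 6760)
  sim$config <- cfg
  sim
}

#' Write simulation truth as JSON
#'
#' @param truth an `mt_sim_truth`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(newick = ape::write.tree(truth$tree),
         events = truth$events,
         tmrca = as.list(truth$tmrca %||% numeric(0)),
         seed = truth$seed),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
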