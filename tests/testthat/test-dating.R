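# small annotated tree fixture built from an explicit simulation
make_annotated <- function(seed = 51, n = 6, tmrca = 30000,
                           rates = c(synonymous = 1 / 6760,
                                     rna = 1 / 20000,
                                     control = 1 / 9000)) {
  lr <- ref_fixture()
  cfg <- sim_config(n_leaves = n, genealogy = "star", tmrca_years = tmrca,
                    rates = rates, recurrent_prob = 0, seed = seed)
  tree <- simulate_genealogy(cfg)
  sim <- evolve_sequences(tree, lr$reference, lr$genemap, cfg)
  map_mutations(sim$truth$tree, sim$alignment, lr$reference, lr$genemap,
                assume_rooted = TRUE)
}

test_that("the synonymous clock maps rho = 1 to 6760 years exactly", {
  cal <- calibration_config("kivisild_synonymous")
  est <- estimate_age(rep(1L, 7), cal)
  expect_identical(est$rho, 1)
  expect_identical(est$age_years, 6760)
  expect_identical(est$se_rho, sqrt(1 / 7))
  # rho = 0 degenerates cleanly
  zero <- estimate_age(rep(0L, 5), cal)
  expect_identical(zero$age_years, 0)
  expect_identical(zero$se_years, 0)
  expect_error(estimate_age(integer(0), cal), "empty")
})

test_that("age scales linearly in the calibration rate", {
  counts <- c(2L, 3L, 1L, 4L)
  a1 <- estimate_age(counts, calibration_config(years_per_change = 6760))
  a2 <- estimate_age(counts, calibration_config(years_per_change = 13520))
  expect_equal(a2$age_years, 2 * a1$age_years)
  expect_equal(a2$se_years, 2 * a1$se_years)
})

test_that("path counts agree with an independent per-branch walk", {
  at <- make_annotated()
  cal <- calibration_config("kivisild_synonymous")
  root <- length(at$tree$tip.label) + 1L
  counts <- count_path_changes(at, root, cal)
  # independent: star tree, so each leaf's count is its pendant branch sum
  for (lf in seq_along(at$tree$tip.label)) {
    k <- which(at$tree$edge[, 2] == lf)
    m <- at$edge_mutations[[k]]
    manual <- if (is.null(m)) 0L else
      sum(m$kind != "deletion" & m$effect %in% "synonymous")
    expect_identical(unname(counts[at$tree$tip.label[lf]]),
                     as.integer(manual))
  }
})

test_that("filters: excluded positions and non-synonymous changes never count", {
  at <- make_annotated()
  n_tip <- length(at$tree$tip.label)
  root <- n_tip + 1L
  kiv <- calibration_config("kivisild_synonymous")
  soa <- calibration_config("soares_complete", years_per_change = 3624)
  base_kiv <- count_path_changes(at, root, kiv)
  base_soa <- count_path_changes(at, root, soa)
  # graft changes at excluded hypervariable positions onto the first
  # pendant branch: neither clock may move
  k <- which(at$tree$edge[, 2] == 1L)
  extra <- data.frame(position = c(16519L, 16182L), ref = c("T", "A"),
                      obs = c("C", "C"),
                      kind = c("transition", "transversion"),
                      feature = "control", gene = NA,
                      effect = "noncoding", aa_from = NA,
                      aa_to = NA, is_reversion = FALSE,
                      hit_index = NA, recurrent = FALSE,
                      label = c("16519C", "16182 AtvC"),
                      stringsAsFactors = FALSE)
  at$edge_mutations[[k]] <- rbind(
    if (is.null(at$edge_mutations[[k]])) NULL else at$edge_mutations[[k]],
    extra)
  expect_identical(count_path_changes(at, root, kiv), base_kiv)
  expect_identical(count_path_changes(at, root, soa), base_soa)
  # the same change at a non-excluded RNA position moves the soares count
  # (all substitutions) but still not the synonymous-only clock
  n_m <- nrow(at$edge_mutations[[k]])
  at$edge_mutations[[k]]$position[n_m] <- 1438L
  at$edge_mutations[[k]]$feature[n_m] <- "rRNA"
  at$edge_mutations[[k]]$effect[n_m] <- "rna"
  expect_identical(sum(count_path_changes(at, root, soa)) - sum(base_soa),
                   1L)
  expect_identical(count_path_changes(at, root, kiv), base_kiv)
})

test_that("nested clade estimates ignore mutations above the clade root", {
  lr <- ref_fixture()
  cfg <- sim_config(n_leaves = 5, genealogy = "coalescent",
                    tmrca_years = 40000,
                    rates = c(synonymous = 1 / 6760), seed = 8L)
  tree <- simulate_genealogy(cfg)
  sim <- evolve_sequences(tree, lr$reference, lr$genemap, cfg)
  at <- map_mutations(sim$truth$tree, sim$alignment, lr$reference,
                      lr$genemap, assume_rooted = TRUE)
  cal <- calibration_config()
  n_tip <- 5L
  # pick an internal node strictly below the root
  internal <- setdiff(unique(at$tree$edge[, 1]), n_tip + 1L)
  node <- internal[1]
  before <- count_path_changes(at, node, cal)
  # add a synonymous mutation on the edge above that node
  k <- which(at$tree$edge[, 2] == node)
  at$edge_mutations[[k]] <- rbind(
    at$edge_mutations[[k]],
    data.frame(position = 7000L, ref = "A", obs = "G", kind = "transition",
               feature = "protein", gene = "CO1", effect = "synonymous",
               aa_from = NA, aa_to = NA, is_reversion = FALSE,
               hit_index = NA, recurrent = FALSE, label = "7000G",
               stringsAsFactors = FALSE))
  expect_identical(count_path_changes(at, node, cal), before)
})

test_that("named clades are dated and non-monophyletic specs are refused", {
  at <- make_annotated()
  cal <- calibration_config()
  labs <- at$tree$tip.label
  ests <- date_named_clades(at, list(all = labs, one = labs[1]), cal)
  expect_identical(ests$all$n_leaves, length(labs))
  # one-leaf clade: its pendant-branch count times the calibration
  k <- which(at$tree$edge[, 2] == 1L)
  m <- at$edge_mutations[[k]]
  cnt <- if (is.null(m)) 0L else sum(m$effect %in% "synonymous")
  expect_equal(ests$one$age_years, cnt * 6760)
  expect_error(date_named_clades(at, list(bad = c(labs[1], "nope")), cal),
               "unknown taxa")
  # a star tree makes any proper subset non-monophyletic (if >1 leaf)
  expect_error(date_named_clades(at, list(sub = labs[1:2]), cal),
               "not monophyletic")
})

test_that("the estimator recovers simulated star-clade ages", {
  cal <- calibration_config()
  set.seed(123)
  lambda <- 22430 / 6760
  hit <- 0
  reps <- 60
  for (i in seq_len(reps)) {
    counts <- rpois(7, lambda)
    est <- estimate_age(counts, cal)
    if (abs(est$age_years - 22430) <= 2 * est$se_years ||
        (est$rho == 0 && lambda == 0)) hit <- hit + 1
  }
  expect_gte(hit / reps, 0.8)
})
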