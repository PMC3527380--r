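test_that("star genealogies have the requested geometry and are deterministic", {
  cfg <- sim_config(n_leaves = 7, genealogy = "star", tmrca_years = 22430,
                    seed = 3)
  tr <- simulate_genealogy(cfg)
  expect_length(tr$tip.label, 7L)
  expect_true(all(tr$edge.length == 22430))
  expect_identical(ape::write.tree(simulate_genealogy(cfg)),
                   ape::write.tree(tr))
  cfg2 <- sim_config(n_leaves = 10, genealogy = "coalescent",
                     tmrca_years = NULL, seed = 5)
  expect_identical(ape::write.tree(simulate_genealogy(cfg2)),
                   ape::write.tree(simulate_genealogy(cfg2)))
  expect_error(sim_config(n_leaves = 1), ">= 2")
})

test_that("coalescent depth matches the closed-form expectation", {
  n <- 20
  depths <- vapply(1:400, function(i) {
    tr <- simulate_genealogy(sim_config(n_leaves = n,
                                        genealogy = "coalescent",
                                        tmrca_years = NULL, seed = i))
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expect_lt(abs(mean(depths) - 2 * (1 - 1 / n)), 0.15)
})

test_that("zero rates leave every sequence identical to the root", {
  lr <- ref_fixture()
  cfg <- sim_config(n_leaves = 4, genealogy = "star", tmrca_years = 10000,
                    rates = c(synonymous = 0), seed = 2)
  sim <- evolve_sequences(simulate_genealogy(cfg), lr$reference,
                          lr$genemap, cfg)
  expect_identical(nrow(sim$truth$events), 0L)
  expect_true(all(apply(sim$alignment$matrix, 1,
                        identical, lr$reference$sequence)))
})

test_that("replaying recorded events reproduces the emitted sequences", {
  lr <- ref_fixture()
  for (seed in c(4, 9)) {
    cfg <- sim_config(n_leaves = 5, genealogy = "coalescent",
                      tmrca_years = 30000,
                      rates = c(synonymous = 1 / 6760, rna = 1 / 15000,
                                control = 1 / 8000),
                      recurrent_prob = 0.05, seed = seed)
    sim <- evolve_sequences(simulate_genealogy(cfg), lr$reference,
                            lr$genemap, cfg)
    expect_identical(replay_truth(sim$truth), sim$alignment$matrix)
    # generated alignments satisfy the container invariants as-is
    expect_s3_class(new_alignment(sim$alignment$matrix,
                                  sim$alignment$positions),
                    "mt_alignment")
  }
})

test_that("event classes land in their genomic compartments", {
  lr <- ref_fixture()
  cfg <- sim_config(n_leaves = 6, genealogy = "star", tmrca_years = 40000,
                    rates = c(synonymous = 1 / 5000,
                              nonsynonymous = 1 / 8000,
                              rna = 1 / 8000, control = 1 / 6000),
                    seed = 12)
  sim <- evolve_sequences(simulate_genealogy(cfg), lr$reference,
                          lr$genemap, cfg)
  ev <- sim$truth$events
  cls <- feature_classes(lr$genemap)
  expect_true(all(cls[ev$position[ev$class == "synonymous"]] == "protein"))
  expect_true(all(cls[ev$position[ev$class == "nonsynonymous"]] == "protein"))
  expect_true(all(cls[ev$position[ev$class == "rna"]] %in%
                    c("rRNA", "tRNA")))
  expect_true(all(cls[ev$position[ev$class == "control"]] == "control"))
})

test_that("synonymous event counts match the Poisson expectation", {
  lr <- ref_fixture()
  tm <- 3 * 6760
  means <- vapply(1:120, function(i) {
    cfg <- sim_config(n_leaves = 2, genealogy = "star", tmrca_years = tm,
                      rates = c(synonymous = 1 / 6760), seed = 1000 + i)
    sim <- evolve_sequences(simulate_genealogy(cfg), lr$reference,
                            lr$genemap, cfg)
    nrow(sim$truth$events) / 2
  }, numeric(1))
  lambda <- tm / 6760
  se <- sqrt(lambda / (2 * 120))
  expect_lt(abs(mean(means) - lambda), 4 * se)
})

test_that("doubling a class rate doubles its expected event count", {
  lr <- ref_fixture()
  count_events <- function(rate, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(n_leaves = 2, genealogy = "star",
                        tmrca_years = 20000,
                        rates = c(rna = rate), seed = s)
      nrow(evolve_sequences(simulate_genealogy(cfg), lr$reference,
                            lr$genemap, cfg)$truth$events)
    }, numeric(1))
  }
  m1 <- mean(count_events(1 / 10000, 1:80))
  m2 <- mean(count_events(2 / 10000, 81:160))
  expect_gt(m2 / m1, 1.5)
  expect_lt(m2 / m1, 2.5)
})

test_that("the star-radiation preset is reproducible and structured", {
  s1 <- q2a_preset(seed = 7)
  s2 <- q2a_preset(seed = 7)
  p1 <- tempfile(fileext = ".fasta"); p2 <- tempfile(fileext = ".fasta")
  write_fasta_alignment(s1$alignment, p1)
  write_fasta_alignment(s2$alignment, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical FASTA
  expect_false(identical(
    q2a_preset(seed = 8)$alignment$matrix, s1$alignment$matrix))
  expect_identical(sort(unname(unlist(s1$truth$clades$Q2))),
                   sort(rownames(s1$alignment$matrix)))
  expect_identical(unname(s1$truth$tmrca["subC"]), 6760)
})
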