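test_that("an M-vertex-like haplotype yields exactly the listed calls", {
  lr <- ref_fixture()
  mv <- c(`73` = "G", `263` = "G", `489` = "C", `750` = "G", `1438` = "G",
          `2706` = "G", `4769` = "G", `7028` = "T", `8701` = "G",
          `8860` = "G", `9540` = "C", `10398` = "G", `10400` = "T",
          `10873` = "C", `11719` = "A", `12705` = "T", `14766` = "T",
          `14783` = "C", `15043` = "A", `15301` = "A", `15326` = "G",
          `16223` = "T")
  s <- apply_changes(lr$reference$sequence, mv)
  calls <- call_variants(s, lr$reference)
  expect_identical(calls$position, sort(as.integer(names(mv))))
  expect_identical(calls$obs, unname(mv[order(as.integer(names(mv)))]))
  expect_true(all(calls$kind == "transition"))
  # labels render as position + derived base for transitions
  labels <- format_label(classify_coding_effect(calls, lr$genemap))
  expect_true("73G" %in% labels)
  expect_true("263G" %in% labels)
  expect_true("1438G~r" %in% labels)  # 12S rRNA change carries the suffix
})

test_that("a sequence identical to the reference yields no calls", {
  lr <- ref_fixture()
  expect_identical(nrow(call_variants(lr$reference$sequence, lr$reference)),
                   0L)
})

test_that("G->T at 228 is a transversion with the documented label", {
  lr <- ref_fixture()
  s <- apply_changes(lr$reference$sequence, c(`228` = "T"))
  calls <- call_variants(s, lr$reference)
  expect_identical(calls$kind, "transversion")
  expect_identical(format_label(calls), "228 GtvT")
})

test_that("transition/transversion classification is symmetric", {
  lr <- ref_fixture()
  for (a in c("A", "C", "G", "T")) for (b in setdiff(c("A", "C", "G", "T"), a)) {
    fwd <- call_variants(apply_changes(lr$reference$sequence,
                                       setNames(b, "6000")), lr$reference)
    # swap ref/obs by calling the reference against a mutated "reference"
    ref2 <- lr$reference
    ref2$sequence[6000] <- b
    rev <- call_variants(lr$reference$sequence, ref2)
    if (lr$reference$sequence[6000] == b) next
    expect_identical(fwd$kind, rev$kind)
  }
})

test_that("deletions are called and labelled with del", {
  lr <- ref_fixture()
  s <- lr$reference$sequence
  s[8281] <- "-"
  calls <- call_variants(s, lr$reference)
  expect_identical(calls$kind, "deletion")
  expect_identical(format_label(calls), "8281del")
  parsed <- parse_label("8281del")
  expect_identical(parsed$position, 8281L)
  expect_identical(parsed$kind, "deletion")
})

test_that("synonymous calls agree with an independent translation-table-2 oracle", {
  lr <- ref_fixture()
  oracle <- Biostrings::getGeneticCode("SGC1")
  names(oracle) <- chartr("U", "T", names(oracle))
  bases <- c("A", "C", "G", "T")

  check_gene <- function(gene_name, codon_index) {
    gene <- ref_fixture()$genemap
    gene <- gene[gene$name == gene_name, ]
    minus <- gene$strand == "-"
    for (c1 in bases) for (c2 in bases) for (c3 in bases) {
      codon <- c(c1, c2, c3)
      bg <- lr$reference$sequence
      if (minus) {
        p <- gene$end - 3L * codon_index - (0:2)
        bg[p] <- chartr("ACGT", "TGCA", codon)
      } else {
        p <- gene$start + 3L * codon_index + (0:2)
        bg[p] <- codon
      }
      for (k in 1:3) {
        for (alt in setdiff(bases, codon[k])) {
          mut <- codon; mut[k] <- alt
          want <- if (oracle[[paste(codon, collapse = "")]] ==
                      oracle[[paste(mut, collapse = "")]])
            "synonymous" else "nonsynonymous"
          obs_plus <- if (minus) chartr("ACGT", "TGCA", alt) else alt
          calls <- data.frame(
            position = p[k], ref = bg[p[k]], obs = obs_plus,
            kind = "transition", feature = NA, gene = NA, effect = NA,
            aa_from = NA, aa_to = NA, is_reversion = NA,
            stringsAsFactors = FALSE)
          got <- classify_coding_effect(calls, ref_fixture()$genemap, bg)
          expect_identical(got$effect, want,
                           label = paste(gene_name, paste(codon, collapse = ""),
                                         k, alt))
        }
      }
    }
  }
  check_gene("CO1", 10L)   # plus-strand protein gene
  check_gene("ND6", 10L)   # minus-strand protein gene
})

test_that("non-synonymous labels carry three-letter amino-acid codes", {
  lr <- ref_fixture()
  gene <- protein_gene_at(lr$genemap, 6000)
  # force a GCx (ala) codon and mutate its first base to ACx (thr)
  ci <- (6000 - gene$start) %/% 3
  p <- gene$start + 3L * ci + (0:2)
  bg <- lr$reference$sequence
  bg[p] <- c("G", "C", "C")
  calls <- data.frame(position = p[1], ref = "G", obs = "A",
                      kind = "transition", feature = NA, gene = NA,
                      effect = NA, aa_from = NA, aa_to = NA,
                      is_reversion = NA, stringsAsFactors = FALSE)
  got <- classify_coding_effect(calls, lr$genemap, bg)
  expect_identical(got$effect, "nonsynonymous")
  expect_identical(got$aa_from, "ala")
  expect_identical(got$aa_to, "thr")
  expect_match(format_label(got), "\\[ala-thr\\]$")
})

test_that("labels round-trip for randomized substitution calls", {
  set.seed(42)
  for (i in 1:1000) {
    pos <- sample.int(16569L, 1L)
    ref <- sample(c("A", "C", "G", "T"), 1)
    obs <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    kind <- if ((ref %in% c("A", "G")) == (obs %in% c("A", "G")))
      "transition" else "transversion"
    feature <- sample(c(NA, "rRNA", "tRNA"), 1)
    calls <- data.frame(position = pos, ref = ref, obs = obs, kind = kind,
                        feature = feature, gene = NA, effect = NA,
                        aa_from = NA, aa_to = NA,
                        is_reversion = sample(c(TRUE, FALSE), 1),
                        stringsAsFactors = FALSE)
    back <- parse_label(format_label(calls))
    expect_identical(back$position, pos)
    expect_identical(back$obs, obs)
    expect_identical(back$kind, kind)
    expect_identical(back$ref, ref)   # transitions imply their reference base
    expect_identical(back$is_reversion, calls$is_reversion)
    if (!is.na(feature)) expect_identical(back$feature, feature)
  }
})

test_that("recurrence decorations render and parse", {
  calls <- data.frame(position = 5460L, ref = "G", obs = "A",
                      kind = "transition", feature = NA, gene = NA,
                      effect = NA, aa_from = NA, aa_to = NA,
                      is_reversion = FALSE, stringsAsFactors = FALSE)
  lab <- format_label(calls, hit_index = 2L, recurrent = TRUE)
  expect_identical(lab, "5460A*(2)")
  back <- parse_label(lab)
  expect_true(back$recurrent)
  expect_identical(back$hit_index, 2L)
})
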