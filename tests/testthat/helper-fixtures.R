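# Programmatic fixtures: everything is generated in code at test time.

# random gap-free alignment with unique taxa; skewed base frequencies give
# shared states, so informative columns and homoplasy arise naturally
rand_aln <- function(n_taxa, n_cols, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_cols, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)),
              nrow = n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  new_alignment(m)
}

# alignment built from explicit column vectors (one string per taxon)
aln_from_strings <- function(strings) {
  m <- do.call(rbind, lapply(strings, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(strings)
  new_alignment(m)
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# reference + gene map, loaded once per test file
ref_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_reference()
    cache
  }
})

# apply named base changes (names = rCRS positions) to a full-length sequence
apply_changes <- function(seq, changes) {
  seq[as.integer(names(changes))] <- unname(changes)
  seq
}

# internal helpers exercised directly in tests
protein_gene_at <- mtparsimony:::protein_gene_at
codon_at <- mtparsimony:::codon_at
mito_genetic_code <- mtparsimony:::mito_genetic_code
translate_codon <- mtparsimony:::translate_codon
split_key <- mtparsimony:::split_key
variable_columns <- mtparsimony:::variable_columns

# independent per-column informative-site classifier (brute force)
brute_informative <- function(mat) {
  which(apply(mat, 2, function(col) {
    tab <- table(col)
    sum(tab >= 2) >= 2
  }))
}

# minimum parsimony score by scoring every topology with phangorn's
# independent implementation (the external oracle)
phangorn_min_score <- function(aln) {
  labs <- rownames(aln$matrix)
  dat <- phangorn::phyDat(aln$matrix, type = "DNA")
  topos <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  min(vapply(seq_along(topos), function(i)
    phangorn::fitch(topos[[i]], dat), numeric(1)))
}
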