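## Variant calling against the rCRS frame and branch-label rendering.
##
## Label convention (as used on branch-annotated haplogroup trees):
##   transitions      "73G"         position + derived base (ref implied)
##   transversions    "228 GtvT"    position + ref + "tv" + derived
##   RNA genes        suffix "~r" (rRNA) or "~t" (tRNA)
##   non-synonymous   "[ala-thr]" three-letter codes appended
##   deletions        "8281del"
##   recurrent sites  "*" plus "(1)", "(2)" numbering successive hits
##   reversions       rendered between underscores (stands in for italics)

# vertebrate mitochondrial code (translation table 2): TGA=Trp, ATA=Met,
# AGA/AGG=Stop. Codons ordered with base order T,C,A,G, first base slowest.
mito_genetic_code <- function() {
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRR",
    "IIMMTTTTNNKKSS**VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
}

AA3 <- c(A = "ala", R = "arg", N = "asn", D = "asp", C = "cys", Q = "gln",
         E = "glu", G = "gly", H = "his", I = "ile", L = "leu", K = "lys",
         M = "met", F = "phe", P = "pro", S = "ser", T = "thr", W = "trp",
         Y = "tyr", V = "val", `*` = "ter")

complement_base <- function(x) chartr("ACGT", "TGCA", x)

translate_codon <- function(codon, code = mito_genetic_code()) {
  unname(code[codon])
}

empty_variants <- function() {
  data.frame(position = integer(), ref = character(), obs = character(),
             kind = character(), feature = character(), gene = character(),
             effect = character(), aa_from = character(),
             aa_to = character(), is_reversion = logical(),
             stringsAsFactors = FALSE)
}

#' Call differences of an aligned sequence against the reference
#'
#' Emits one call per position where the sequence differs from the
#' reference: substitutions classified as transition (purine-purine or
#' pyrimidine-pyrimidine) or transversion, gaps as deletions. `N` columns
#' are skipped. Calls are ordered by rCRS position.
#'
#' @param seq character vector of aligned bases (A/C/G/T/-/N)
#' @param ref an `mt_reference` (or a bare character vector of bases)
#' @param positions rCRS position of each element of `seq`; defaults to
#'   `seq_along(seq)` for full-length sequences
#' @return data frame of class `mt_variants` (one row per call) with
#'   columns position, ref, obs, kind, feature, gene, effect, aa_from,
#'   aa_to, is_reversion; annotation columns are `NA` until
#'   [classify_coding_effect()] fills them
#' @export
call_variants <- function(seq, ref, positions = seq_along(seq)) {
  refseq <- if (inherits(ref, "mt_reference")) ref$sequence else ref
  seq <- toupper(seq)
  if (length(seq) != length(positions)) {
    stop_input("seq and positions must have equal length")
  }
  refbase <- refseq[positions]
  idx <- which(seq != refbase & seq != "N")
  out <- empty_variants()
  if (length(idx)) {
    obs <- seq[idx]
    rb <- refbase[idx]
    kind <- ifelse(obs == "-", "deletion",
                   ifelse((rb %in% c("A", "G")) == (obs %in% c("A", "G")),
                          "transition", "transversion"))
    out <- data.frame(position = positions[idx], ref = rb, obs = obs,
                      kind = kind, feature = NA_character_,
                      gene = NA_character_, effect = NA_character_,
                      aa_from = NA_character_, aa_to = NA_character_,
                      is_reversion = NA, stringsAsFactors = FALSE)
    out <- out[order(out$position), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("mt_variants", "data.frame")
  out
}

# codon containing `pos` in `gene`, read from `background` (full-length
# character vector in rCRS coordinates), with `pos` replaced by `base`.
# Minus-strand genes (ND6) are evaluated on the reverse complement.
# Incomplete terminal codons are A-padded (polyadenylation completes them).
codon_at <- function(gene, pos, background, base) {
  bg <- background
  bg[pos] <- base
  if (identical(gene$strand, "-")) {
    j <- gene$end - pos
    cn <- j %/% 3L
    p <- gene$end - 3L * cn - (0:2)
    raw <- ifelse(p >= gene$start, complement_base(bg[pmax(p, 1L)]), "A")
  } else {
    j <- pos - gene$start
    cn <- j %/% 3L
    p <- gene$start + 3L * cn + (0:2)
    raw <- ifelse(p <= gene$end, bg[pmin(p, RCRS_LENGTH)], "A")
  }
  paste(raw, collapse = "")
}

#' Fill feature class and coding effect of variant calls
#'
#' Protein-gene substitutions are classified synonymous or non-synonymous
#' by translating the codon (vertebrate mitochondrial code, table 2) in the
#' supplied background context — by default the reference, or the immediate
#' ancestral sequence when mutations are mapped on a tree. rRNA/tRNA
#' positions get effect `"rna"`, control region `"noncoding"`, unannotated
#' positions `"na"`. Deletions are located but not translated (effect
#' `"na"`).
#'
#' @param calls an `mt_variants` data frame
#' @param genemap an `mt_genemap`
#' @param background full-length character vector supplying codon context;
#'   defaults to the packaged reference sequence
#' @return `calls` with feature, gene, effect, aa_from, aa_to filled
#' @export
classify_coding_effect <- function(calls, genemap,
                                   background = load_reference()$reference$sequence) {
  if (nrow(calls) == 0L) return(calls)
  code <- mito_genetic_code()
  cls <- feature_class_at(genemap, calls$position)
  calls$feature <- cls
  for (i in seq_len(nrow(calls))) {
    if (calls$kind[i] == "deletion") {
      calls$effect[i] <- "na"
      next
    }
    f <- cls[i]
    if (f == "protein") {
      gene <- protein_gene_at(genemap, calls$position[i])
      calls$gene[i] <- gene$name
      from_codon <- codon_at(gene, calls$position[i], background, calls$ref[i])
      to_codon <- codon_at(gene, calls$position[i], background, calls$obs[i])
      aa_f <- translate_codon(from_codon, code)
      aa_t <- translate_codon(to_codon, code)
      if (aa_f == aa_t) {
        calls$effect[i] <- "synonymous"
      } else {
        calls$effect[i] <- "nonsynonymous"
        calls$aa_from[i] <- AA3[[aa_f]]
        calls$aa_to[i] <- AA3[[aa_t]]
      }
    } else if (f %in% c("rRNA", "tRNA")) {
      calls$effect[i] <- "rna"
      rows <- genemap[genemap$class == f & genemap$start <= calls$position[i] &
                        genemap$end >= calls$position[i], , drop = FALSE]
      if (nrow(rows)) calls$gene[i] <- rows$name[1L]
    } else if (f == "control") {
      calls$effect[i] <- "noncoding"
    } else {
      calls$effect[i] <- "na"
    }
  }
  calls
}

#' Render branch labels for variant calls
#'
#' @param calls an `mt_variants` data frame (effects classified)
#' @param hit_index optional integer vector: ordinal of this change among
#'   all changes at the same site on the tree (rendered as "(1)", "(2)")
#' @param recurrent optional logical vector: site needed >1 change
#'   tree-wide (rendered as "*")
#' @return character vector of labels, e.g. `"73G"`, `"228 GtvT"`,
#'   `"1438G~r"`, `"5460A[ala-thr]"`, `"8281del"`; reversions are wrapped
#'   in underscores (plain-text italics)
#' @export
format_label <- function(calls, hit_index = NULL, recurrent = NULL) {
  n <- nrow(calls)
  out <- character(n)
  for (i in seq_len(n)) {
    if (calls$kind[i] == "deletion") {
      lab <- paste0(calls$position[i], "del")
    } else if (calls$kind[i] == "transversion") {
      lab <- paste0(calls$position[i], " ", calls$ref[i], "tv", calls$obs[i])
    } else {
      lab <- paste0(calls$position[i], calls$obs[i])
    }
    if (!is.na(calls$feature[i])) {
      if (calls$feature[i] == "rRNA") lab <- paste0(lab, "~r")
      if (calls$feature[i] == "tRNA") lab <- paste0(lab, "~t")
    }
    if (!is.na(calls$effect[i]) && calls$effect[i] == "nonsynonymous") {
      lab <- paste0(lab, "[", calls$aa_from[i], "-", calls$aa_to[i], "]")
    }
    if (!is.null(recurrent) && isTRUE(recurrent[i])) lab <- paste0(lab, "*")
    if (!is.null(hit_index) && !is.na(hit_index[i])) {
      lab <- paste0(lab, "(", hit_index[i], ")")
    }
    if (isTRUE(calls$is_reversion[i])) lab <- paste0("_", lab, "_")
    out[i] <- lab
  }
  out
}

#' Parse a branch label back into a variant call
#'
#' Inverse of [format_label()] for substitutions: recovers position,
#' derived base, kind (reference base of a transition is implied by the
#' derived base), RNA suffix, amino-acid codes, recurrence decorations and
#' the reversion flag.
#'
#' @param label a single label string
#' @return one-row data frame with the recovered fields
#' @export
parse_label <- function(label) {
  raw <- label
  is_rev <- grepl("^_.*_$", raw)
  x <- sub("^_", "", sub("_$", "", raw))
  hit <- NA_integer_
  m <- regmatches(x, regexec("\\((\\d+)\\)$", x))[[1]]
  if (length(m)) { hit <- as.integer(m[2]); x <- sub("\\(\\d+\\)$", "", x) }
  recurrent <- grepl("\\*$", x)
  x <- sub("\\*$", "", x)
  aa_from <- aa_to <- NA_character_
  m <- regmatches(x, regexec("\\[([a-z]{3})-([a-z]{3})\\]$", x))[[1]]
  if (length(m)) {
    aa_from <- m[2]; aa_to <- m[3]
    x <- sub("\\[[a-z]{3}-[a-z]{3}\\]$", "", x)
  }
  feature <- NA_character_
  if (grepl("~r$", x)) { feature <- "rRNA"; x <- sub("~r$", "", x) }
  if (grepl("~t$", x)) { feature <- "tRNA"; x <- sub("~t$", "", x) }
  if (grepl("del$", x)) {
    pos <- as.integer(sub("del$", "", x))
    return(data.frame(position = pos, ref = NA_character_, obs = "-",
                      kind = "deletion", feature = feature,
                      is_reversion = is_rev, recurrent = recurrent,
                      hit_index = hit, aa_from = aa_from, aa_to = aa_to,
                      stringsAsFactors = FALSE))
  }
  m <- regmatches(x, regexec("^(\\d+) ([ACGT])tv([ACGT])$", x))[[1]]
  if (length(m)) {
    return(data.frame(position = as.integer(m[2]), ref = m[3], obs = m[4],
                      kind = "transversion", feature = feature,
                      is_reversion = is_rev, recurrent = recurrent,
                      hit_index = hit, aa_from = aa_from, aa_to = aa_to,
                      stringsAsFactors = FALSE))
  }
  m <- regmatches(x, regexec("^(\\d+)([ACGT])$", x))[[1]]
  if (!length(m)) stop_input("unparseable label: ", label)
  obs <- m[3]
  partner <- c(A = "G", G = "A", C = "T", T = "C")[[obs]]
  data.frame(position = as.integer(m[2]), ref = partner, obs = obs,
             kind = "transition", feature = feature, is_reversion = is_rev,
             recurrent = recurrent, hit_index = hit,
             aa_from = aa_from, aa_to = aa_to, stringsAsFactors = FALSE)
}

#' Write variant calls as TSV
#'
#' @param calls an `mt_variants` data frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_variants_tsv <- function(calls, path) {
  out <- calls
  out$label <- format_label(calls)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
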