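#' Alignment container
#'
#' An `mt_alignment` is a taxa-by-columns character matrix over
#' `A/C/G/T/-/N` plus an integer vector `positions` giving the rCRS
#' coordinate of each column (strictly increasing). Row names are the taxon
#' labels and must be unique.
#'
#' @param mat character matrix (rows = taxa, named; values A/C/G/T/-/N)
#' @param positions integer vector, one rCRS position per column
#' @return an `mt_alignment`
#' @export
new_alignment <- function(mat, positions = seq_len(ncol(mat))) {
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop_input("taxon labels must be present and unique")
  }
  positions <- as.integer(positions)
  if (length(positions) != ncol(mat)) {
    stop_input("positions length must equal column count")
  }
  if (ncol(mat) > 1L && any(diff(positions) <= 0L)) {
    stop_input("column positions must be strictly increasing")
  }
  mat <- toupper(mat)
  mat[!(mat %in% c("A", "C", "G", "T", "-"))] <- "N"  # other IUPAC -> N
  structure(list(matrix = mat, positions = positions),
            class = "mt_alignment")
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat(sprintf("mt_alignment: %d taxa x %d columns (rCRS %d..%d)\n",
              nrow(x$matrix), ncol(x$matrix),
              if (length(x$positions)) min(x$positions) else NA,
              if (length(x$positions)) max(x$positions) else NA))
  invisible(x)
}

n_taxa <- function(aln) nrow(aln$matrix)
taxa_labels <- function(aln) rownames(aln$matrix)

#' Read an aligned multi-FASTA
#'
#' Sequences must be pre-aligned (equal length) in rCRS coordinates.
#' Lowercase bases are uppercased; IUPAC ambiguity codes other than N are
#' read as N. An optional sidecar TSV (two columns: column index, rCRS
#' position) supplies the coordinate track for pre-trimmed alignments;
#' without it columns are numbered 1..L.
#'
#' @param path FASTA file
#' @param positions_path optional TSV mapping column index to rCRS position
#' @return an `mt_alignment`
#' @export
read_fasta_alignment <- function(path, positions_path = NULL) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  dna <- tryCatch(ape::read.FASTA(path),
                  error = function(e) stop_input("malformed FASTA: ",
                                                 conditionMessage(e)))
  if (length(dna) == 0L) stop_input("empty FASTA: ", path)
  if (anyDuplicated(names(dna))) stop_input("duplicate sequence labels")
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) {
    stop_input("sequences are not aligned: lengths ",
               paste(sort(unique(lens)), collapse = ", "))
  }
  mat <- toupper(do.call(rbind, as.character(dna)))
  rownames(mat) <- names(dna)
  positions <- seq_len(ncol(mat))
  if (!is.null(positions_path)) {
    tr <- read.delim(positions_path, header = FALSE)
    positions <- rep(NA_integer_, ncol(mat))
    positions[as.integer(tr[[1]])] <- as.integer(tr[[2]])
    if (anyNA(positions)) stop_input("position track does not cover all columns")
  }
  new_alignment(mat, positions)
}

#' Write an alignment as multi-FASTA
#'
#' @param aln an `mt_alignment`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_taxa(aln))) {
    writeLines(paste0(">", taxa_labels(aln)[i]), con)
    row <- paste(aln$matrix[i, ], collapse = "")
    writeLines(substring(row, seq(1, nchar(row), 70),
                         pmin(seq(1, nchar(row), 70) + 69, nchar(row))), con)
  }
  invisible(path)
}

#' Restrict an alignment to an rCRS coordinate range
#'
#' Keeps exactly the columns whose rCRS position lies in `[lo, hi]`
#' (1-based, inclusive), preserving order. The default analysis window of
#' the coding-region pipeline is 550..16050, which excludes the
#' hypervariable control region.
#'
#' @param aln an `mt_alignment`
#' @param lo,hi inclusive rCRS bounds, in 1..16569
#' @return an `mt_alignment`
#' @export
mask_to_range <- function(aln, lo, hi) {
  if (lo > hi || lo < 1L || hi > RCRS_LENGTH) {
    stop_input("mask range must satisfy 1 <= lo <= hi <= ", RCRS_LENGTH)
  }
  keep <- aln$positions >= lo & aln$positions <= hi
  new_alignment(aln$matrix[, keep, drop = FALSE], aln$positions[keep])
}

#' Remove columns containing gaps or ambiguous bases
#'
#' Whole-column exclusion: a column is dropped when *any* taxon carries
#' `-` or `N` there, leaving a matrix over A/C/G/T on which parsimony
#' scores are well-defined.
#'
#' @param aln an `mt_alignment`
#' @return a gap-free `mt_alignment`
#' @export
drop_gapped_columns <- function(aln) {
  bad <- colSums(aln$matrix == "-" | aln$matrix == "N") > 0L
  new_alignment(aln$matrix[, !bad, drop = FALSE], aln$positions[!bad])
}

#' Parsimony-informative site report
#'
#' A column is parsimony-informative when at least two distinct states are
#' each carried by at least two taxa; only such columns can differ in cost
#' between trees.
#'
#' @param aln a gap-free `mt_alignment`
#' @return list of class `mt_sitereport`: `informative_columns` (column
#'   indices), `informative_positions` (their rCRS positions), `counts`
#'   (4 x L matrix of residue counts), `n_variable` (count of non-constant
#'   columns)
#' @export
informative_sites <- function(aln) {
  if (any(aln$matrix == "-" | aln$matrix == "N")) {
    stop_input("informative_sites requires a gap-free alignment; ",
               "run drop_gapped_columns() first")
  }
  counts <- apply(aln$matrix, 2, function(col) tabulate(match(col, BASES), 4L))
  counts <- matrix(counts, nrow = 4L,
                   dimnames = list(BASES, NULL))
  informative <- which(colSums(counts >= 2L) >= 2L)
  variable <- which(colSums(counts > 0L) >= 2L)
  structure(list(informative_columns = informative,
                 informative_positions = aln$positions[informative],
                 counts = counts,
                 n_variable = length(variable)),
            class = "mt_sitereport")
}
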