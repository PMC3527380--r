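#' The rCRS coordinate frame
#'
#' All positions in this package are 1-based coordinates on the revised
#' Cambridge Reference Sequence (rCRS), the standard 16,569-bp human
#' mitochondrial reference frame. The packaged reference carries the
#' standard rCRS gene annotation. Its base sequence, however, is a
#' deterministic *synthetic stand-in*: real rCRS alleles are pinned at the
#' classic haplogroup-defining positions (73, 263, 489, 750, 1438, 2706,
#' 4769, 7028, 8701, 8860, 9540, 10398, 10400, 10873, 11719, 12705, 14766,
#' 14783, 15043, 15301, 15326, 16223, 228, 5460, ... ) while the remaining
#' bases are generated with rCRS-like composition. Every operation in the
#' package treats the reference purely as a coordinate/annotation frame, so
#' analyses of user-supplied alignments are unaffected; only variant calls
#' *against the packaged sequence itself* at non-pinned positions would
#' differ from calls against the true rCRS.
#'
#' @name rcrs-frame
NULL

RCRS_LENGTH <- 16569L

# real rCRS alleles at positions used throughout haplogroup nomenclature
.rcrs_pinned <- c(
  `73` = "A", `146` = "T", `152` = "T", `195` = "T", `228` = "G",
  `263` = "A", `489` = "T", `750` = "A", `1438` = "A", `2706` = "A",
  `3010` = "G", `4769` = "A", `5460` = "G", `6260` = "G", `7028` = "C",
  `8701` = "A", `8860` = "A", `9540` = "T", `10398` = "A", `10400` = "C",
  `10873` = "T", `11719` = "G", `12705` = "C", `13368` = "G",
  `14766` = "C", `14783` = "T", `15043` = "G", `15301` = "G",
  `15326` = "A", `16182` = "A", `16183` = "A", `16189` = "T",
  `16223` = "C", `16519` = "T"
)

build_synthetic_rcrs <- function() {
  # rCRS-like base composition (A/C/G/T = 30.9/31.3/13.1/24.7 %)
  u <- lcg_runif(RCRS_LENGTH, state = 20120)$u
  cum <- cumsum(c(0.309, 0.313, 0.131, 0.247))
  seq <- BASES[findInterval(u, cum) + 1L]
  seq[as.integer(names(.rcrs_pinned))] <- unname(.rcrs_pinned)
  seq
}

#' Load the packaged reference genome and gene map
#'
#' Returns the packaged 16,569-bp reference (see [rcrs-frame] for why its
#' sequence is a labelled synthetic stand-in) together with the standard
#' rCRS gene map. Deterministic: repeated calls return identical objects.
#'
#' @return a list with elements `reference` (class `mt_reference`: fields
#'   `sequence` — character vector of length 16569 over A/C/G/T —
#'   `circular`, `name`, `synthetic`) and `genemap` (class `mt_genemap`,
#'   a data frame with columns name, start, end, class, strand).
#' @export
#' @examples
#' ref <- load_reference()
#' length(ref$reference$sequence)
load_reference <- function() {
  path <- system.file("extdata", "rcrs_genemap.tsv", package = "mtparsimony")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged gene map fixture not found; installation is corrupted")
  }
  gm <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "start", "end", "class", "strand")
  if (!all(required %in% names(gm)) ||
      any(gm$start < 1L) || any(gm$end > RCRS_LENGTH) ||
      any(gm$start > gm$end)) {
    stop("packaged gene map fixture is corrupted")
  }
  class(gm) <- c("mt_genemap", "data.frame")
  seq <- build_synthetic_rcrs()
  ref <- structure(
    list(sequence = seq, circular = TRUE, name = "rCRS",
         synthetic = TRUE, length = RCRS_LENGTH),
    class = "mt_reference")
  list(reference = ref, genemap = gm)
}

#' Primary feature class per position
#'
#' Maps every rCRS position to a single feature class under the fixed
#' precedence protein > tRNA > rRNA > control > other, so that positions
#' covered by overlapping annotations (e.g. ATP8/ATP6) resolve
#' deterministically.
#'
#' @param genemap an `mt_genemap`
#' @return character vector of length 16569, values in
#'   `c("protein","tRNA","rRNA","control","other")`
#' @export
feature_classes <- function(genemap) {
  cached <- attr(genemap, ".class_vec")
  if (!is.null(cached)) return(cached)
  cls <- rep("other", RCRS_LENGTH)
  # ascending precedence: later assignments overwrite earlier ones
  for (want in c("control", "rRNA", "tRNA", "protein")) {
    rows <- genemap[genemap$class == want, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      cls[rows$start[i]:rows$end[i]] <- want
    }
  }
  cls
}

#' @rdname feature_classes
#' @param pos integer vector of rCRS positions
#' @export
feature_class_at <- function(genemap, pos) {
  if (any(pos < 1L | pos > RCRS_LENGTH)) {
    stop_input("positions must lie in 1..", RCRS_LENGTH)
  }
  feature_classes(genemap)[pos]
}

# the protein gene used for codon evaluation at a protein-class position:
# among covering protein genes, the one with the smallest start (then name)
protein_gene_at <- function(genemap, pos) {
  rows <- genemap[genemap$class == "protein" &
                    genemap$start <= pos & genemap$end >= pos, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  rows <- rows[order(rows$start, rows$name), , drop = FALSE]
  rows[1L, ]
}
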