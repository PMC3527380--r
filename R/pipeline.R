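## End-to-end orchestration: mask, search, squeeze, annotate, consense,
## date — with a reproducible JSON report. The search runs on the masked
## gap-free columns only; annotation afterwards maps mutations over the
## full gap-free alignment, so control-region changes appear on the tree
## ("added back") without ever influencing the score or the certificate.
## The report separates search sites from display-only sites.

#' Pipeline configuration
#'
#' @param input path to an aligned multi-FASTA (or supply `alignment`)
#' @param alignment an `mt_alignment` (alternative to `input`)
#' @param mask two integers, inclusive rCRS range searched
#'   (default 550..16050: control region excluded)
#' @param outgroup tip label(s) the tree is rooted on for mutation mapping
#' @param clades named list of tip-label vectors to date
#' @param calibration an [calibration_config()]
#' @param search an [search_config()]
#' @param squeeze_budget merge-iteration budget for [squeeze()]
#' @param seed integer recorded in the report and forwarded to any
#'   seed-consuming stage
#' @param outdir artifact directory (created if missing)
#' @return list of class `mt_pipeline_config`
#' @export
pipeline_config <- function(input = NULL, alignment = NULL,
                            mask = c(550L, 16050L), outgroup = NULL,
                            clades = list(),
                            calibration = calibration_config(),
                            search = search_config(),
                            squeeze_budget = 200L, seed = 1L,
                            outdir = tempfile("mtparsimony_run_")) {
  structure(list(input = input, alignment = alignment,
                 mask = as.integer(mask), outgroup = outgroup,
                 clades = clades, calibration = calibration,
                 search = search, squeeze_budget = squeeze_budget,
                 seed = as.integer(seed), outdir = outdir),
            class = "mt_pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns findings rather than throwing: each row has a level
#' (`"error"`/`"warning"`) and a message. The default configuration
#' yields no errors.
#'
#' @param cfg an [pipeline_config()]
#' @param aln optional alignment to check clade/outgroup labels against
#' @return data frame with columns `level`, `message` (zero rows if clean)
#' @export
validate_config <- function(cfg, aln = NULL) {
  findings <- list()
  add <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  if (length(cfg$mask) != 2L || cfg$mask[1] > cfg$mask[2] ||
      cfg$mask[1] < 1L || cfg$mask[2] > RCRS_LENGTH) {
    add("error", "mask must be an increasing pair within 1..16569")
  } else if (cfg$mask[1] > 1L || cfg$mask[2] < RCRS_LENGTH) {
    add("warning", paste0(
      "mask ", cfg$mask[1], "..", cfg$mask[2], " excludes part of the ",
      "genome (e.g. the control region) from the tree search; changes ",
      "there are annotated on the final tree but never affect the score ",
      "or the minimality certificate"))
  }
  if (is.null(cfg$input) && is.null(cfg$alignment)) {
    add("error", "no input: supply `input` (FASTA path) or `alignment`")
  }
  if (!is.null(aln)) {
    labs <- taxa_labels(aln)
    for (nm in names(cfg$clades)) {
      unknown <- setdiff(cfg$clades[[nm]], labs)
      if (length(unknown)) {
        add("error", paste0("clade '", nm, "' names unknown taxa: ",
                            paste(unknown, collapse = ", ")))
      }
    }
    if (!is.null(cfg$outgroup) && !all(cfg$outgroup %in% labs)) {
      add("error", "outgroup label(s) not present in the alignment")
    }
  }
  if (length(findings)) do.call(rbind, findings) else
    data.frame(level = character(), message = character(),
               stringsAsFactors = FALSE)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("mtp_stage_error", "error", "condition"),
                   list(message = paste0("stage '", stage, "': ",
                                         conditionMessage(e)),
                        stage = stage, call = NULL)))
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load, mask, search, squeeze, consense, annotate,
#' date, report. Artifacts (masked FASTA, Newick tree set and consensus,
#' certificate JSON, branch-mutation and dating TSVs, report JSON) are
#' written under `cfg$outdir`. Idempotent for a fixed configuration and
#' seed: re-running produces a byte-identical report. On failure a
#' `FAILED` marker naming the stage is left beside any partial artifacts.
#'
#' @param cfg an [pipeline_config()]
#' @return the run report (list of class `mt_run_report`), invisibly;
#'   also written as `report.json`
#' @export
run_pipeline <- function(cfg) {
  findings <- validate_config(cfg)
  if (any(findings$level == "error")) {
    stop_input("invalid configuration: ",
               paste(findings$message[findings$level == "error"],
                     collapse = "; "))
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  fail_marker <- file.path(cfg$outdir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  on_fail <- function(e) {
    writeLines(conditionMessage(e), fail_marker)
    stop(e)
  }
  tryCatch({
    lr <- with_stage("load", load_reference())
    aln <- with_stage("load", {
      if (!is.null(cfg$alignment)) cfg$alignment
      else read_fasta_alignment(cfg$input)
    })
    findings <- validate_config(cfg, aln)
    if (any(findings$level == "error")) {
      with_stage("load", stop_input(paste(
        findings$message[findings$level == "error"], collapse = "; ")))
    }
    digest <- with_stage("load", {
      tmp <- tempfile(fileext = ".fasta")
      write_fasta_alignment(aln, tmp)
      d <- unname(tools::md5sum(tmp))
      unlink(tmp)
      d
    })

    full_aln <- with_stage("mask", drop_gapped_columns(aln))
    search_aln <- with_stage("mask", drop_gapped_columns(
      mask_to_range(aln, cfg$mask[1], cfg$mask[2])))
    write_fasta_alignment(search_aln,
                          file.path(cfg$outdir, "search_alignment.fasta"))
    sites <- with_stage("mask", informative_sites(search_aln))

    ts <- with_stage("search", heuristic_search(search_aln, cfg$search))
    ape::write.tree(ts$trees, file.path(cfg$outdir, "mp_trees.nwk"))

    cert <- with_stage("squeeze", squeeze(search_aln, ts$score, trees = ts,
                                          budget = cfg$squeeze_budget))
    write_certificate_json(cert, file.path(cfg$outdir, "certificate.json"))

    cons <- with_stage("consense", strict_consensus(ts))
    ape::write.tree(cons, file.path(cfg$outdir, "consensus.nwk"))

    atree <- with_stage("annotate", map_mutations(
      cons, full_aln, lr$reference, lr$genemap, outgroup = cfg$outgroup))
    bmt <- branch_mutation_table(atree)
    write.table(bmt, file.path(cfg$outdir, "branch_mutations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    dates <- with_stage("date", {
      if (length(cfg$clades)) {
        date_named_clades(atree, cfg$clades, cfg$calibration)
      } else list()
    })
    dt <- if (length(dates)) dating_table(dates) else NULL
    if (!is.null(dt)) {
      write.table(dt, file.path(cfg$outdir, "dating.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    search_set <- aln$positions >= cfg$mask[1] & aln$positions <= cfg$mask[2]
    mapped_pos <- unique(bmt$position)
    report <- structure(list(
      tool = "mtparsimony",
      version = as.character(utils::packageVersion("mtparsimony")),
      seed = cfg$seed,
      input_digest = digest,
      n_taxa = n_taxa(aln),
      mask = cfg$mask,
      n_search_columns = ncol(search_aln$matrix),
      n_informative = length(sites$informative_columns),
      mp_score = ts$score,
      n_mp_trees = length(ts$trees),
      certificate = list(upper = cert$upper_bound,
                         lower = cert$lower_bound,
                         status = cert$status),
      consensus_newick = ape::write.tree(cons),
      total_mapped_changes = atree$total_changes,
      recurrent_positions = atree$recurrent_positions,
      n_search_site_changes = sum(mapped_pos >= cfg$mask[1] &
                                    mapped_pos <= cfg$mask[2]),
      n_display_only_changes = sum(mapped_pos < cfg$mask[1] |
                                     mapped_pos > cfg$mask[2]),
      dating = dt), class = "mt_run_report")
    with_stage("report", jsonlite::write_json(
      unclass(report), file.path(cfg$outdir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA))
    invisible(report)
  }, mtp_stage_error = on_fail, mtp_input_error = on_fail)
}

#' @export
print.mt_run_report <- function(x, ...) {
  cat(sprintf(paste0(
    "mtparsimony run: %d taxa, %d informative sites, MP score %d ",
    "(%d tree(s), certificate %s)\n"),
    x$n_taxa, x$n_informative, x$mp_score, x$n_mp_trees,
    x$certificate$status))
  if (!is.null(x$dating)) {
    print(x$dating)
  }
  invisible(x)
}
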