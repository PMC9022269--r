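#' Annotate loci against one promoter model
#'
#' One pass of the locus workflow for a single model/pattern: builds the
#' extended query, aligns every locus, applies the anchoring filters and
#' calls the 5' start bin of each passing locus.
#'
#' @param model a [promoter_model()].
#' @param loci named character vector (or `DNAStringSet`) of locus
#'   sequences in element orientation.
#' @param scoring a [scoring_scheme()].
#' @param filter_cfg a [filter_config()].
#' @param total_monomers query monomer count (default 11).
#' @return list with `query`, `hits` (all hits with `pass`/`reason`),
#'   `calls` (start calls for passing hits) and `unaligned`.
#' @export
annotate_loci <- function(model, loci, scoring = scoring_scheme(),
                          filter_cfg = filter_config(),
                          total_monomers = 11L) {
  query <- build_extended_query(model, total_monomers)
  hits <- align_loci(query, loci, scoring)
  unaligned <- attr(hits, "unaligned")
  hits <- filter_hits(hits, query, filter_cfg)
  calls <- call_start(hits[hits$pass, , drop = FALSE], query)
  list(query = query, hits = hits, calls = calls, unaligned = unaligned)
}

#' Run the locus census workflow
#'
#' Executes build-query, align, filter, call, pattern deduplication and
#' census for one subfamily, over one or several monomer-organization
#' patterns. Reports are deterministic given the inputs; rows are ordered
#' by bin (M11+ down to T) and locus id.
#'
#' @param models a [promoter_model()] or a list of them (one per
#'   pattern).
#' @param loci named character vector of locus sequences.
#' @param scoring,filter_cfg,total_monomers see [annotate_loci()].
#' @param precedence pattern precedence for deduplication, highest first;
#'   defaults to the order of `models`.
#' @param subfamily census label; defaults to the first model's
#'   subfamily.
#' @param outdir optional output directory for TSV/BED reports and a run
#'   log.
#' @return list with `calls` (deduplicated), `census`, `per_pattern`
#'   (annotate_loci results) and `unaligned`.
#' @export
run_locus_workflow <- function(models, loci, scoring = scoring_scheme(),
                               filter_cfg = filter_config(),
                               total_monomers = 11L, precedence = NULL,
                               subfamily = NULL, outdir = NULL) {
  if (inherits(models, "promoter_model")) models <- list(models)
  per_pattern <- lapply(models, annotate_loci,
    loci = loci, scoring = scoring,
    filter_cfg = filter_cfg, total_monomers = total_monomers
  )
  patterns <- vapply(models, function(m) m$pattern_id, character(1))
  names(per_pattern) <- patterns
  if (is.null(precedence)) precedence <- patterns
  if (is.null(subfamily)) subfamily <- models[[1L]]$subfamily
  all_calls <- do.call(rbind, lapply(per_pattern, `[[`, "calls"))
  calls <- dedup_patterns(all_calls, precedence)
  lv <- bin_levels()
  calls <- calls[order(match(calls$bin, lv), calls$locus_id), , drop = FALSE]
  rownames(calls) <- NULL
  cens <- census(calls, subfamily)
  unaligned <- sort(Reduce(intersect, lapply(per_pattern, `[[`, "unaligned")))
  result <- list(
    calls = calls, census = cens, per_pattern = per_pattern,
    unaligned = unaligned
  )
  if (!is.null(outdir)) {
    write_locus_reports(result, outdir)
  }
  result
}

write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
}

write_locus_reports <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$calls, file.path(outdir, "calls.tsv"))
  write_tsv(result$census$bin_table, file.path(outdir, "census_bins.tsv"))
  write_tsv(result$census$cumulative, file.path(outdir, "census_cumulative.tsv"))
  hist_df <- do.call(rbind, lapply(names(result$census$offset_hist), function(b) {
    tb <- result$census$offset_hist[[b]]
    if (length(tb) == 0L) {
      return(NULL)
    }
    data.frame(
      bin = b, offset = as.integer(names(tb)), count = as.integer(tb),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(hist_df)) {
    hist_df <- data.frame(bin = character(), offset = integer(), count = integer())
  }
  write_tsv(hist_df, file.path(outdir, "offset_histograms.tsv"))
  # BED-like truncation report on the subject loci (0-based half-open,
  # element orientation)
  beds <- do.call(rbind, lapply(result$per_pattern, function(p) {
    h <- p$hits[p$hits$pass, , drop = FALSE]
    if (nrow(h) == 0L) {
      return(NULL)
    }
    data.frame(
      chrom = h$sseqid, start = h$sstart - 1L, end = h$send,
      name = sprintf("aligned_%s", h$qseqid), score = h$score, strand = "+",
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(beds)) {
    beds <- beds[beds$chrom %in% result$calls$locus_id, , drop = FALSE]
    beds <- beds[!duplicated(beds$chrom), , drop = FALSE]
    beds <- beds[order(beds$chrom), , drop = FALSE]
    utils::write.table(beds, file.path(outdir, "truncation.bed"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  writeLines(result$unaligned, file.path(outdir, "unaligned.txt"))
  invisible(outdir)
}

#' Run the luciferase workflow
#'
#' Normalizes each plate against its no-promoter control, pools the
#' normalized wells, and runs pooled-SD pairwise t-tests with
#' Benjamini-Hochberg correction.
#'
#' @param wells data frame with `plate`, `well`, `construct`, `fluc`,
#'   `rluc`.
#' @param control no-promoter control construct id.
#' @param alpha significance level (default 0.05).
#' @param outdir optional output directory for TSV reports.
#' @return list with `wells` (normalized), `summaries` (per plate x
#'   construct) and `tests`.
#' @export
run_luciferase_workflow <- function(wells, control, alpha = 0.05,
                                    outdir = NULL) {
  if (!("plate" %in% names(wells))) wells$plate <- "plate1"
  plates <- split(wells, wells$plate)
  norm <- lapply(plates, normalize_plate, control = control)
  all_wells <- do.call(rbind, lapply(norm, `[[`, "wells"))
  summaries <- do.call(rbind, lapply(names(norm), function(p) {
    cbind(plate = p, norm[[p]]$summaries, stringsAsFactors = FALSE)
  }))
  rownames(all_wells) <- rownames(summaries) <- NULL
  tests <- pairwise_tests(all_wells$normalized, all_wells$construct, alpha)
  result <- list(wells = all_wells, summaries = summaries, tests = tests)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(summaries, file.path(outdir, "construct_summaries.tsv"))
    write_tsv(tests, file.path(outdir, "pairwise_tests.tsv"))
  }
  result
}

#' Run a configured pipeline
#'
#' Dispatches on `config$workflow`: `"loci"` reads promoter model files
#' and a locus FASTA and runs [run_locus_workflow()]; `"luciferase"`
#' reads a plate TSV and runs [run_luciferase_workflow()]. A run log with
#' a config hash and package version is written when `outdir` is set.
#' Stage errors abort with the failing stage named.
#'
#' @param config a list, or the path of a YAML config file, with fields:
#'   `workflow` (`"loci"` or `"luciferase"`); for loci: `models`
#'   (character vector of model YAML paths), `loci_fasta`, optional
#'   `precedence`, `total_monomers`, `scoring` (list of match, mismatch,
#'   gap_open, gap_extend), `filter` (tether_tail, subject_head),
#'   `subfamily`; for luciferase: `plate_tsv`, `control`, optional
#'   `alpha`; both: optional `outdir`.
#' @return the workflow result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }
  outdir <- config$outdir
  if (identical(config$workflow, "loci")) {
    models <- stage("read-models", lapply(config$models, read_promoter_model))
    loci <- stage("read-loci", read_fasta(config$loci_fasta))
    scoring <- if (is.null(config$scoring)) {
      scoring_scheme()
    } else {
      do.call(scoring_scheme, config$scoring)
    }
    fcfg <- if (is.null(config$filter)) {
      filter_config()
    } else {
      do.call(filter_config, config$filter)
    }
    result <- stage("census", run_locus_workflow(
      models, loci,
      scoring = scoring, filter_cfg = fcfg,
      total_monomers = if (is.null(config$total_monomers)) 11L else config$total_monomers,
      precedence = config$precedence,
      subfamily = config$subfamily, outdir = outdir
    ))
  } else if (identical(config$workflow, "luciferase")) {
    wells <- stage(
      "read-plate",
      utils::read.delim(config$plate_tsv, stringsAsFactors = FALSE)
    )
    result <- stage("luciferase", run_luciferase_workflow(
      wells, config$control,
      alpha = if (is.null(config$alpha)) 0.05 else config$alpha,
      outdir = outdir
    ))
  } else {
    stop("config$workflow must be 'loci' or 'luciferase'")
  }
  if (!is.null(outdir)) {
    cfg_file <- tempfile()
    on.exit(unlink(cfg_file))
    yaml::write_yaml(config, cfg_file)
    writeLines(
      c(
        sprintf("l1promoter %s", as.character(utils::packageVersion("l1promoter"))),
        sprintf("workflow: %s", config$workflow),
        sprintf("config md5: %s", unname(tools::md5sum(cfg_file)))
      ),
      file.path(outdir, "run_log.txt")
    )
  }
  result
}
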