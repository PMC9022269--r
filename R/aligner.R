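#' Alignment scoring scheme
#'
#' Integer affine-gap scoring. A length-L gap costs `gap_open + L *
#' gap_extend`. The defaults (+2 match, -3 mismatch, open 5, extend 2)
#' approximate default nucleotide BLAST behaviour; no identity threshold or
#' E-value model is applied anywhere in the pipeline.
#'
#' @param match per-base match reward (> 0).
#' @param mismatch per-base mismatch penalty (< 0).
#' @param gap_open gap opening cost (>= 0).
#' @param gap_extend per-base gap extension cost (> 0).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                           gap_extend = 2L) {
  if (match <= 0) stop("invalid scoring: match reward must be > 0")
  if (mismatch >= 0) stop("invalid scoring: mismatch penalty must be < 0")
  if (gap_open < 0) stop("invalid scoring: gap open cost must be >= 0")
  if (gap_extend <= 0) stop("invalid scoring: gap extend cost must be > 0")
  structure(
    list(
      match = as.numeric(match), mismatch = as.numeric(mismatch),
      gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend)
    ),
    class = "scoring_scheme"
  )
}

hit_columns <- c(
  "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "score", "minus"
)

#' Best local alignment of a subject against a query
#'
#' Exact affine-gap Smith-Waterman. Returns the maximum-scoring local
#' alignment, or `NULL` when the best score is not positive (no pair of
#' bases scores positively). Ties are broken by smallest subject start,
#' then smallest query start, then longest alignment. `N` is allowed in
#' subjects, scores as a mismatch against every base and never counts as
#' an identity; queries must be N-free.
#'
#' @param query an [build_extended_query()] result or an uppercase DNA
#'   string.
#' @param subject uppercase DNA string (N allowed).
#' @param scoring a [scoring_scheme()].
#' @param qseqid,sseqid ids recorded in the hit.
#' @return a one-row `alignment_hits` data frame (columns `qseqid`,
#'   `sseqid`, `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `score`, `minus`), or `NULL`.
#' @export
local_align <- function(query, subject, scoring = scoring_scheme(),
                        qseqid = "query", sseqid = "subject") {
  qseq <- if (inherits(query, "extended_query")) query$sequence else query
  assert_dna(qseq, "query")
  assert_dna(subject, "subject", allow_n = TRUE)
  stopifnot(inherits(scoring, "scoring_scheme"))
  res <- .sw_align_cpp(
    qseq, subject, scoring$match, scoring$mismatch,
    scoring$gap_open, scoring$gap_extend
  )
  if (!isTRUE(res$found)) {
    return(NULL)
  }
  hit <- data.frame(
    qseqid = qseqid, sseqid = sseqid,
    pident = 100 * res$matches / res$length,
    length = res$length, mismatch = res$mismatch, gapopen = res$gapopen,
    qstart = res$qstart, qend = res$qend,
    sstart = res$sstart, send = res$send,
    score = res$score, minus = FALSE,
    stringsAsFactors = FALSE
  )
  class(hit) <- c("alignment_hits", "data.frame")
  hit
}

#' Align a set of loci against an extended query
#'
#' Runs [local_align()] for every locus and keeps the best (and only)
#' reported alignment per locus. Loci with no positive-scoring alignment
#' are listed in the `"unaligned"` attribute.
#'
#' @param query extended query (or DNA string).
#' @param loci named character vector of locus sequences (element
#'   orientation, 5'->3'), or a `Biostrings::DNAStringSet`.
#' @param scoring a [scoring_scheme()].
#' @return an `alignment_hits` data frame, one row per aligned locus, with
#'   attribute `unaligned` (character vector of locus ids).
#' @export
align_loci <- function(query, loci, scoring = scoring_scheme()) {
  if (methods::is(loci, "DNAStringSet")) {
    loci <- stats::setNames(as.character(loci), names(loci))
  }
  if (is.null(names(loci)) || anyDuplicated(names(loci))) {
    stop("loci must have unique names")
  }
  qid <- if (inherits(query, "extended_query")) {
    sprintf("%s_%s", query$model$subfamily, query$model$pattern_id)
  } else {
    "query"
  }
  hits <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    hits[[i]] <- local_align(query, loci[[i]],
      scoring = scoring,
      qseqid = qid, sseqid = names(loci)[i]
    )
  }
  aligned <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(aligned)) {
    aligned <- empty_hits()
  }
  class(aligned) <- c("alignment_hits", "data.frame")
  attr(aligned, "unaligned") <- setdiff(names(loci), aligned$sseqid)
  aligned
}

empty_hits <- function() {
  df <- data.frame(
    qseqid = character(), sseqid = character(), pident = numeric(),
    length = integer(), mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(),
    send = integer(), score = numeric(), minus = logical(),
    stringsAsFactors = FALSE
  )
  class(df) <- c("alignment_hits", "data.frame")
  df
}

#' Import alignments in 12-column tabular format
#'
#' Parses the standard 12-column tab-separated alignment layout (qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore), so alignments computed externally can be fed into the
#' same filtering and binning steps. The bit score is carried as the hit
#' score. Hits with `sstart > send` are minus-orientation: their subject
#' coordinates are kept as printed and the `minus` flag is set so the
#' downstream filter can reject them. Parsing is fail-fast: a malformed
#' line aborts with its line number and no partial result.
#'
#' @param path path to the tabular alignment file (or a connection).
#' @return an `alignment_hits` data frame.
#' @export
import_hits_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 12L)) {
    bad <- which(n_fields < 12L)[1L]
    stop(sprintf(
      "parse error at line %d: expected >= 12 tab-separated fields, found %d",
      bad, n_fields[bad]
    ))
  }
  num_cols <- c(3:10, 12) # pident, length..send, bitscore
  parse_num <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", k)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf(
        "parse error at line %d: field %d is not numeric ('%s')",
        bad, k, fields[[bad]][k]
      ))
    }
    v
  }
  vals <- lapply(num_cols, parse_num)
  names(vals) <- c(
    "pident", "length", "mismatch", "gapopen", "qstart", "qend",
    "sstart", "send", "score"
  )
  hits <- data.frame(
    qseqid = vapply(fields, `[[`, "", 1L),
    sseqid = vapply(fields, `[[`, "", 2L),
    pident = vals$pident,
    length = as.integer(vals$length),
    mismatch = as.integer(vals$mismatch),
    gapopen = as.integer(vals$gapopen),
    qstart = as.integer(vals$qstart),
    qend = as.integer(vals$qend),
    sstart = as.integer(vals$sstart),
    send = as.integer(vals$send),
    score = vals$score,
    stringsAsFactors = FALSE
  )
  hits$minus <- hits$sstart > hits$send
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}

#' Select the best hit per subject
#'
#' Among hits satisfying `keep`, selects the maximal-score hit for each
#' subject; ties are broken by smallest subject start, then longest
#' alignment. Subjects whose hits all fail `keep` (or that have no hits)
#' are reported in the `unaligned` attribute.
#'
#' @param hits an `alignment_hits` data frame sharing one query id.
#' @param keep optional predicate: a function taking the hits data frame
#'   and returning a logical vector (or a logical vector directly).
#' @return `alignment_hits` with at most one row per `sseqid`, attribute
#'   `unaligned` listing subjects with no surviving hit.
#' @export
best_hit_per_subject <- function(hits, keep = NULL) {
  stopifnot(is.data.frame(hits))
  if (length(unique(hits$qseqid)) > 1L) {
    stop("invalid input: hits must share one query id")
  }
  ok <- if (is.null(keep)) {
    rep(TRUE, nrow(hits))
  } else if (is.function(keep)) {
    keep(hits)
  } else {
    as.logical(keep)
  }
  surviving <- hits[ok, , drop = FALSE]
  if (nrow(surviving) > 0L) {
    ord <- order(surviving$sseqid, -surviving$score, surviving$sstart,
      -surviving$length)
    surviving <- surviving[ord, , drop = FALSE]
    surviving <- surviving[!duplicated(surviving$sseqid), , drop = FALSE]
    rownames(surviving) <- NULL
  }
  class(surviving) <- c("alignment_hits", "data.frame")
  attr(surviving, "unaligned") <- setdiff(unique(hits$sseqid), surviving$sseqid)
  surviving
}
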