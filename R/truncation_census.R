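#' Alignment filter configuration
#'
#' The two anchoring windows that remove 3'-tether-truncated loci and loci
#' whose 5' end is not the start of the element: a passing alignment must
#' end within the last `tether_tail` bases of the query (i.e. reach the 3'
#' end of the tether) and start within the first `subject_head` bases of
#' the subject locus. Both default to 10 bp.
#'
#' @param tether_tail window at the query 3' end, bp (>= 1).
#' @param subject_head window at the subject 5' end, bp (>= 1).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(tether_tail = 10L, subject_head = 10L) {
  tether_tail <- as.integer(tether_tail)
  subject_head <- as.integer(subject_head)
  if (is.na(tether_tail) || tether_tail < 1L ||
    is.na(subject_head) || subject_head < 1L) {
    stop("invalid filter config: windows must be >= 1")
  }
  structure(
    list(tether_tail = tether_tail, subject_head = subject_head),
    class = "filter_config"
  )
}

#' Filter alignment hits on the anchoring windows
#'
#' A hit passes iff it is plus-orientation, `qend` lies in
#' `[Lq - tether_tail + 1, Lq]` (the last `tether_tail` bases of the
#' query, whose 3' end is the tether 3' end) and `sstart` lies in
#' `[1, subject_head]`. Failure reasons, checked in order:
#' `minus-orientation`, `tether-3'-truncated`, `not-5'-anchored`.
#'
#' @param hits an `alignment_hits` data frame (or a single hit row).
#' @param query the extended query the hits were computed against.
#' @param cfg a [filter_config()].
#' @return `hits` with logical column `pass` and character column `reason`
#'   (`NA` for passing hits).
#' @export
filter_hits <- function(hits, query, cfg = filter_config()) {
  stopifnot(is.data.frame(hits), inherits(cfg, "filter_config"))
  lq <- if (inherits(query, "extended_query")) nchar(query$sequence) else nchar(query)
  pass_tail <- hits$qend >= lq - cfg$tether_tail + 1L & hits$qend <= lq
  pass_head <- hits$sstart >= 1L & hits$sstart <= cfg$subject_head
  minus <- if ("minus" %in% names(hits)) hits$minus else rep(FALSE, nrow(hits))
  reason <- rep(NA_character_, nrow(hits))
  reason[!pass_head] <- "not-5'-anchored"
  reason[!pass_tail] <- "tether-3'-truncated"
  reason[minus] <- "minus-orientation"
  hits$pass <- is.na(reason)
  hits$reason <- reason
  hits
}

#' @rdname filter_hits
#' @param subject_length unused; subject coordinates are already validated
#'   against the subject on import, the head window only needs `sstart`.
#' @export
filter_hit <- function(hits, query, cfg = filter_config(),
                       subject_length = NULL) {
  out <- filter_hits(hits, query, cfg)
  list(pass = out$pass, reason = out$reason)
}

bin_levels <- function() c("M11+", paste0("M", 10:1), "T")

#' Call the 5' start bin and fractional monomer count of each locus
#'
#' Maps the query start of each passing hit to its domain and offset. A
#' start at offset `o` of monomer `Mi` (domain length `L_i`) yields bin
#' `Mi` and fractional monomer count `(i - 1) + (L_i - o + 1) / L_i`; a
#' start in the tether yields bin `T` and count 0; a start in the 11th or
#' a more 5' monomer slot yields bin `M11+`. `T` and `M11+` loci are
#' flagged `averaged = FALSE` and are excluded from average monomer
#' counts.
#'
#' @param hits filtered hits (rows with `pass == TRUE`; unfiltered input is
#'   a contract violation and is rejected).
#' @param query the extended query.
#' @return a `start_calls` data frame with columns `locus_id`,
#'   `pattern_id`, `bin`, `offset`, `monomer_count`, `averaged`.
#' @export
call_start <- function(hits, query) {
  stopifnot(is.data.frame(hits), inherits(query, "extended_query"))
  if (!("pass" %in% names(hits)) || !all(hits$pass)) {
    stop("contract violation: call_start requires hits that passed filter_hits")
  }
  if (nrow(hits) == 0L) {
    return(empty_calls())
  }
  mp <- map_query_position(query, hits$qstart)
  dom_len <- query$domains$length[match(mp$label, query$domains$label)]
  is_t <- mp$label == "T"
  mono_idx <- rep(NA_integer_, nrow(mp))
  mono_idx[!is_t] <- as.integer(sub("^M", "", mp$label[!is_t]))
  count <- ifelse(
    is_t, 0,
    (mono_idx - 1) + (dom_len - mp$offset + 1) / dom_len
  )
  bin <- ifelse(is_t, "T", ifelse(mono_idx >= 11L, "M11+", mp$label))
  calls <- data.frame(
    locus_id = hits$sseqid,
    pattern_id = query$model$pattern_id,
    bin = bin,
    offset = mp$offset,
    monomer_count = count,
    averaged = !is_t & mono_idx < 11L,
    stringsAsFactors = FALSE
  )
  class(calls) <- c("start_calls", "data.frame")
  calls
}

empty_calls <- function() {
  df <- data.frame(
    locus_id = character(), pattern_id = character(), bin = character(),
    offset = integer(), monomer_count = numeric(), averaged = logical(),
    stringsAsFactors = FALSE
  )
  class(df) <- c("start_calls", "data.frame")
  df
}

#' Deduplicate loci called under several monomer-organization patterns
#'
#' Gf_I loci can pass the filters under more than one pattern query; each
#' locus is retained once, under the highest-precedence pattern in which
#' it passed. The default precedence (II > I > IV) keeps shared loci under
#' pattern II; pattern III is excluded by default.
#'
#' @param calls a `start_calls` data frame, possibly with the same locus
#'   under several `pattern_id`s.
#' @param precedence ordered character vector of pattern ids, highest
#'   precedence first. Every pattern present in `calls` must be listed.
#' @return `start_calls` with one row per locus.
#' @export
dedup_patterns <- function(calls, precedence = c("II", "I", "IV")) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0L) {
    return(calls)
  }
  unknown <- setdiff(unique(calls$pattern_id), precedence)
  if (length(unknown) > 0L) {
    stop(sprintf(
      "invalid config: pattern id(s) not in precedence: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  rank <- match(calls$pattern_id, precedence)
  ord <- order(calls$locus_id, rank)
  out <- calls[ord, , drop = FALSE]
  out <- out[!duplicated(out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("start_calls", "data.frame")
  out
}

#' Census of 5' start bins for one subfamily
#'
#' Aggregates deduplicated start calls into the per-bin locus table,
#' percentages, cumulative intact-monomer categories, the average
#' fractional monomer count (excluding `T` and `M11+` loci), and per-bin
#' start-offset histograms. A locus has at least `k` intact (complete)
#' monomers iff it starts in `M(k+1)` or beyond, or exactly at offset 1 of
#' `Mk`.
#'
#' @param calls a deduplicated `start_calls` data frame (one row per
#'   locus, all from one subfamily or a pooled set).
#' @param subfamily label recorded in the census.
#' @return an object of class `subfamily_census` with elements
#'   `subfamily`, `total`, `bin_table` (bin, count, pct ordered M11+ to
#'   T), `cumulative` (k, count, pct of loci with >= k intact monomers),
#'   `avg_monomers`, `n_excluded`, `offset_hist` (named list of offset
#'   count tables per bin).
#' @export
census <- function(calls, subfamily = "pooled") {
  stopifnot(is.data.frame(calls))
  lv <- bin_levels()
  total <- nrow(calls)
  counts <- table(factor(calls$bin, levels = lv))
  bin_table <- data.frame(
    bin = lv,
    count = as.integer(counts),
    pct = if (total > 0L) percent(as.integer(counts), total) else NA_real_,
    stringsAsFactors = FALSE
  )
  # complete monomers per locus: starts at offset 1 keep the whole monomer
  intact <- integer(0)
  if (total > 0L) {
    idx <- rep(0L, total)
    idx[calls$bin == "M11+"] <- 11L
    plain <- !(calls$bin %in% c("T", "M11+"))
    idx[plain] <- as.integer(sub("^M", "", calls$bin[plain]))
    intact <- ifelse(calls$bin == "T", 0L, idx - 1L + (calls$offset == 1L))
  }
  ks <- 1:10
  cumulative <- data.frame(
    k = ks,
    count = vapply(ks, function(k) sum(intact >= k), integer(1)),
    pct = if (total > 0L) {
      vapply(ks, function(k) percent(sum(intact >= k), total), numeric(1))
    } else {
      NA_real_
    }
  )
  avg_set <- calls$monomer_count[calls$averaged]
  offset_hist <- lapply(
    stats::setNames(nm = lv[bin_table$count > 0L]),
    function(b) table(calls$offset[calls$bin == b])
  )
  structure(
    list(
      subfamily = subfamily,
      total = total,
      bin_table = bin_table,
      cumulative = cumulative,
      avg_monomers = if (length(avg_set) > 0L) mean(avg_set) else NA_real_,
      n_excluded = total - length(avg_set),
      offset_hist = offset_hist
    ),
    class = "subfamily_census"
  )
}

#' @export
print.subfamily_census <- function(x, ...) {
  cat(sprintf(
    "<subfamily_census> %s: %d loci, average %.1f monomers (%d excluded)\n",
    x$subfamily, x$total,
    if (is.na(x$avg_monomers)) NA else x$avg_monomers, x$n_excluded
  ))
  shown <- x$bin_table[x$bin_table$count > 0L, , drop = FALSE]
  if (nrow(shown) > 0L) print(shown, row.names = FALSE)
  invisible(x)
}

#' Pairwise identity of two aligned sequences
#'
#' Column-wise identity of one aligned (gapped) sequence pair: identical
#' columns are those with the same non-gap character on both rows; any
#' column involving `-` compares but never matches. The percentage uses
#' the one-decimal [percent()] convention with all columns as denominator
#' (e.g. 180/208 -> 86.5).
#'
#' @param a,b equal-length aligned sequences (gap character `-`).
#' @return list with `identical`, `columns`, `percent`.
#' @export
pairwise_identity <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L ||
    length(b) != 1L) {
    stop("invalid input: expected two strings")
  }
  if (nchar(a) != nchar(b)) {
    stop("invalid input: aligned sequences must have equal length")
  }
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ident <- sum(ca == cb & ca != "-")
  list(
    identical = ident,
    columns = nchar(a),
    percent = percent(ident, nchar(a))
  )
}

#' Regression of average monomer count on subfamily age
#'
#' Ordinary least squares of the average monomer count on subfamily age
#' (Myr). Reports the signed Pearson correlation `r` and the two-sided
#' p-value of the slope, equivalent to `t = r * sqrt(n - 2) / sqrt(1 -
#' r^2)` on `n - 2` degrees of freedom.
#'
#' @param age numeric vector of subfamily ages (Myr), or a two-column data
#'   frame `(age, avg_monomers)`.
#' @param avg_monomers numeric vector of average monomer counts.
#' @return an object of class `age_regression` with `slope`, `intercept`,
#'   `r`, `p`, `n`.
#' @export
age_regression <- function(age, avg_monomers = NULL) {
  if (is.data.frame(age)) {
    avg_monomers <- age[[2L]]
    age <- age[[1L]]
  }
  n <- length(age)
  if (n < 3L || length(avg_monomers) != n) {
    stop("insufficient data: need >= 3 (age, count) pairs")
  }
  if (stats::sd(age) == 0) {
    stop("degenerate regression: zero variance in age")
  }
  fit <- stats::lm(avg_monomers ~ age)
  coefs <- summary(fit)$coefficients
  structure(
    list(
      slope = unname(coefs["age", "Estimate"]),
      intercept = unname(coefs["(Intercept)", "Estimate"]),
      r = stats::cor(age, avg_monomers),
      p = unname(coefs["age", "Pr(>|t|)"]),
      n = n
    ),
    class = "age_regression"
  )
}

#' @export
print.age_regression <- function(x, ...) {
  cat(sprintf(
    "<age_regression> n = %d: count = %.3f %+.3f * age, R = %.2f, p = %.3g\n",
    x$n, x$intercept, x$slope, x$r, x$p
  ))
  invisible(x)
}
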