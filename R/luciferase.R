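#' Normalize a dual-luciferase plate
#'
#' Implements the stepwise dual-luciferase normalization: (1) each well's
#' firefly signal is divided by its Renilla signal (the per-well ratio
#' cancels transfection efficiency), (2) the mean ratio of the no-promoter
#' control construct is computed, (3) every well's ratio is divided by
#' that control mean, which sets the control's average to exactly 1 (the
#' assay background), and (4) per-construct means over replicate wells are
#' reported with their standard errors.
#'
#' Two uncertainties are reported per construct: `sem`, the replicate
#' standard error (standard deviation of the normalized wells divided by
#' the square root of the number of replicates, the quantity shown as
#' error bars), and `se_activity`, the delta-method standard error of the
#' normalized activity itself, which additionally propagates the
#' uncertainty of the control mean: `sqrt(sem^2 + (mean * sem_control)^2)`.
#' `se_activity` is the appropriate yardstick when comparing an estimated
#' activity with an external truth, since the control mean is itself
#' estimated from replicate wells.
#'
#' @param wells data frame with columns `plate`, `well`, `construct`,
#'   `fluc` (>= 0), `rluc` (> 0); extra columns are carried through.
#' @param control construct id of the no-promoter control; must be present
#'   with at least 2 wells.
#' @return list with `wells` (input plus `ratio` and `normalized` columns)
#'   and `summaries` (data frame `construct`, `n`, `mean_activity`, `sem`,
#'   `se_activity`, `mean_ratio`; control `mean_activity` is exactly 1).
#' @export
normalize_plate <- function(wells, control) {
  required <- c("construct", "fluc", "rluc")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0L) {
    stop(sprintf("wells table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!is.finite(wells$rluc) | wells$rluc <= 0)
  if (length(bad) > 0L) {
    id <- if ("well" %in% names(wells)) wells$well[bad[1L]] else bad[1L]
    stop(sprintf("invalid well '%s': rluc must be > 0", id))
  }
  if (any(!is.finite(wells$fluc) | wells$fluc < 0)) {
    stop("invalid well: fluc must be >= 0")
  }
  ctrl <- wells$construct == control
  if (sum(ctrl) < 2L) {
    stop(sprintf("missing control: construct '%s' needs >= 2 wells", control))
  }
  wells$ratio <- wells$fluc / wells$rluc
  c0 <- mean(wells$ratio[ctrl])
  wells$normalized <- wells$ratio / c0
  sem_ctrl_norm <- sem(wells$ratio[ctrl]) / c0
  constructs <- unique(wells$construct)
  summaries <- do.call(rbind, lapply(constructs, function(cc) {
    r <- wells$ratio[wells$construct == cc]
    m <- mean(r) / c0 # exactly 1 for the control
    s <- sem(r) / c0
    data.frame(
      construct = cc, n = length(r), mean_activity = m, sem = s,
      se_activity = if (cc == control) s else sqrt(s^2 + (m * sem_ctrl_norm)^2),
      mean_ratio = mean(r), stringsAsFactors = FALSE
    )
  }))
  rownames(summaries) <- NULL
  list(wells = wells, summaries = summaries, control = control)
}

#' Pairwise t-tests with Benjamini-Hochberg correction
#'
#' All-pairs two-sided t-tests of normalized activities between
#' constructs, using a standard deviation pooled across all groups
#' (residual degrees of freedom `N - k`), followed by Benjamini-Hochberg
#' adjustment across all reported pairs. This is the behaviour of
#' [stats::pairwise.t.test()] with `pool.sd = TRUE`, which is called
#' behind this interface.
#'
#' @param values numeric vector of per-well normalized activities.
#' @param groups construct label per well.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @return data frame `construct_a`, `construct_b`, `p_raw`, `p_adj`,
#'   `significant`, one row per unordered pair.
#' @export
pairwise_tests <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("insufficient groups: need >= 2 constructs")
  if (any(sizes < 2L)) {
    stop(sprintf(
      "insufficient replicates: construct(s) with < 2 wells: %s",
      paste(names(sizes)[sizes < 2L], collapse = ", ")
    ))
  }
  raw <- stats::pairwise.t.test(values, groups,
    p.adjust.method = "none", pool.sd = TRUE
  )$p.value
  pairs <- which(!is.na(raw), arr.ind = TRUE)
  out <- data.frame(
    construct_a = rownames(raw)[pairs[, 1L]],
    construct_b = colnames(raw)[pairs[, 2L]],
    p_raw = raw[pairs],
    stringsAsFactors = FALSE
  )
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adj < alpha
  out[order(out$p_raw), , drop = FALSE]
}

#' Relative activity of one construct versus a reference
#'
#' `100 * mean(a) / mean(reference)`, rounded half away from zero to one
#' decimal — the convention behind statements like an antisense promoter
#' being "11.6%" of its sense counterpart (106.2 / 914).
#'
#' @param a mean normalized activity of the construct (a number, or a row
#'   of the `summaries` table from [normalize_plate()]).
#' @param reference mean normalized activity of the reference (> 0).
#' @return percentage rounded to one decimal.
#' @export
relative_activity <- function(a, reference) {
  get_mean <- function(x) {
    if (is.data.frame(x)) x$mean_activity[1L] else as.numeric(x)
  }
  a <- get_mean(a)
  reference <- get_mean(reference)
  if (!is.finite(reference) || reference <= 0) {
    stop("invalid reference: mean activity must be > 0")
  }
  round_half_up(100 * a / reference, 1)
}

#' Summarize a plasmid-dose titration
#'
#' Per-dose mean and standard error of the firefly signal, Renilla signal
#' and their ratio, plus a linearity report: a least-squares line through
#' the origin is fitted to each signal's per-dose means over `fit_doses`
#' (by default all doses), and each dose's relative deviation from that
#' line is reported. No automatic plateau call is made; saturation shows
#' up as increasingly negative deviations at high dose.
#'
#' @param wells data frame with columns `construct`, `fluc`, `rluc`,
#'   `dose` (ng of plasmid); at least two distinct doses.
#' @param fit_doses doses used for the origin-line fit (default: all).
#' @return list with `summary` (dose, n, mean/sem of fluc, rluc, ratio)
#'   and `linearity` (signal, dose, observed mean, fitted, rel_deviation).
#' @export
summarize_titration <- function(wells, fit_doses = NULL) {
  if (!("dose" %in% names(wells))) stop("wells table lacks a 'dose' column")
  doses <- sort(unique(wells$dose))
  if (length(doses) < 2L) stop("insufficient doses: need >= 2 dose levels")
  wells$ratio <- wells$fluc / wells$rluc
  summarize_one <- function(d) {
    w <- wells[wells$dose == d, , drop = FALSE]
    data.frame(
      dose = d, n = nrow(w),
      fluc_mean = mean(w$fluc), fluc_sem = sem(w$fluc),
      rluc_mean = mean(w$rluc), rluc_sem = sem(w$rluc),
      ratio_mean = mean(w$ratio), ratio_sem = sem(w$ratio)
    )
  }
  summary <- do.call(rbind, lapply(doses, summarize_one))
  if (is.null(fit_doses)) fit_doses <- doses
  if (!all(fit_doses %in% doses)) stop("fit_doses must be observed dose levels")
  linearity <- do.call(rbind, lapply(c("fluc", "rluc"), function(sig) {
    means <- summary[[paste0(sig, "_mean")]]
    sel <- summary$dose %in% fit_doses
    b <- sum(means[sel] * summary$dose[sel]) / sum(summary$dose[sel]^2)
    fitted <- b * summary$dose
    data.frame(
      signal = sig, dose = summary$dose, observed = means, fitted = fitted,
      rel_deviation = means / fitted - 1,
      stringsAsFactors = FALSE
    )
  }))
  list(summary = summary, linearity = linearity)
}
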