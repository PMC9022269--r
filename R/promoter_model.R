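#' Promoter model for a mouse L1 subfamily
#'
#' A promoter model holds the consensus monomer sequences and the tether of
#' one L1 subfamily (for Gf_I, one monomer-organization pattern of that
#' subfamily). Monomers are ordered 5' to 3': the first element is the
#' 5'-most *full* monomer remaining after removal of the consensus's 5'
#' partial monomer, and the last element is the monomer adjacent to the
#' tether (M1). Monomer lengths may differ from one another, e.g. a 212-bp
#' duplicated monomer next to a 197-bp M1.
#'
#' @param subfamily subfamily name, e.g. `"Tf_I"`.
#' @param monomers character vector of uppercase DNA monomer sequences,
#'   5'-most full monomer first, M1 last.
#' @param tether uppercase DNA tether sequence (non-monomeric sequence
#'   between the monomer array and ORF1).
#' @param pattern_id monomer-organization pattern label (Gf_I has several);
#'   default `"default"`.
#' @param notes free-text annotation.
#' @return an object of class `promoter_model`.
#' @seealso [build_extended_query()], [read_promoter_model()]
#' @export
promoter_model <- function(subfamily, monomers, tether,
                           pattern_id = "default", notes = "") {
  if (!is.character(subfamily) || length(subfamily) != 1L || !nzchar(subfamily)) {
    stop("invalid model: 'subfamily' must be a non-empty string")
  }
  if (!is.character(monomers) || length(monomers) < 1L) {
    stop("invalid model: at least one monomer sequence is required")
  }
  for (i in seq_along(monomers)) {
    assert_dna(monomers[[i]], sprintf("monomer %d", i))
  }
  assert_dna(tether, "tether")
  structure(
    list(
      subfamily = subfamily,
      pattern_id = pattern_id,
      monomers = unname(monomers),
      tether = tether,
      notes = notes
    ),
    class = "promoter_model"
  )
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf(
    "<promoter_model> %s (pattern %s): %d monomer(s) [%s bp], tether %d bp\n",
    x$subfamily, x$pattern_id, length(x$monomers),
    paste(nchar(x$monomers), collapse = "+"), nchar(x$tether)
  ))
  invisible(x)
}

#' Build the extended tandem-monomer query
#'
#' Extends a promoter model to a fixed number of monomers by prepending
#' copies of the model's 5'-most full monomer until `total_monomers`
#' monomers precede the tether. Domains are labelled from the 5' end as
#' `M<total_monomers>`, ..., `M1`, `T`; M1 is immediately 5' of the tether.
#' The resulting query is the coordinate system in which locus 5' start
#' positions are interpreted.
#'
#' @param model a [promoter_model()].
#' @param total_monomers total monomer count of the query (default 11);
#'   must be at least the number of monomers in the model.
#' @return an object of class `extended_query` with elements `sequence`,
#'   `domains` (data frame with `label`, `length`, `start`, `end`),
#'   `total_monomers` and `model`.
#' @export
build_extended_query <- function(model, total_monomers = 11L) {
  if (!inherits(model, "promoter_model")) {
    stop("invalid model: expected a promoter_model")
  }
  k <- length(model$monomers)
  total_monomers <- as.integer(total_monomers)
  if (is.na(total_monomers) || total_monomers < k) {
    stop(sprintf(
      "invalid argument: total_monomers (%s) must be >= number of model monomers (%d)",
      total_monomers, k
    ))
  }
  prepended <- rep(model$monomers[[1L]], total_monomers - k)
  units <- c(prepended, model$monomers, model$tether)
  lens <- nchar(units)
  labels <- c(paste0("M", seq(total_monomers, 1L)), "T")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  structure(
    list(
      sequence = paste(units, collapse = ""),
      domains = data.frame(
        label = labels, length = lens, start = starts, end = ends,
        stringsAsFactors = FALSE
      ),
      total_monomers = total_monomers,
      model = model
    ),
    class = "extended_query"
  )
}

#' @export
print.extended_query <- function(x, ...) {
  cat(sprintf(
    "<extended_query> %s (pattern %s): %d bp, %d monomers + tether\n",
    x$model$subfamily, x$model$pattern_id, nchar(x$sequence), x$total_monomers
  ))
  invisible(x)
}

#' Map query positions to (domain, offset)
#'
#' Resolves 1-based positions in an extended query to the domain containing
#' them and the 1-based offset within that domain. The inverse of
#' [query_position()].
#'
#' @param query an [build_extended_query()] result.
#' @param pos integer vector of 1-based query positions.
#' @return data frame with columns `pos`, `label`, `offset`.
#' @export
map_query_position <- function(query, pos) {
  stopifnot(inherits(query, "extended_query"))
  pos <- as.integer(pos)
  len <- nchar(query$sequence)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > len)) {
    stop(sprintf("out of bounds: positions must be in [1, %d]", len))
  }
  idx <- findInterval(pos, query$domains$start)
  data.frame(
    pos = pos,
    label = query$domains$label[idx],
    offset = pos - query$domains$start[idx] + 1L,
    stringsAsFactors = FALSE
  )
}

#' Query position of a (domain, offset) pair
#'
#' Inverse of [map_query_position()]: round-trips exactly.
#'
#' @param query an extended query.
#' @param label domain label (`"M11"` ... `"M1"` or `"T"`).
#' @param offset 1-based offset within the domain.
#' @return 1-based query position(s).
#' @export
query_position <- function(query, label, offset) {
  stopifnot(inherits(query, "extended_query"))
  i <- match(label, query$domains$label)
  if (any(is.na(i))) {
    stop(sprintf("unknown domain label: %s", paste(label[is.na(i)], collapse = ", ")))
  }
  offset <- as.integer(offset)
  if (any(offset < 1L) || any(offset > query$domains$length[i])) {
    stop("out of bounds: offset exceeds domain length")
  }
  query$domains$start[i] + offset - 1L
}

#' Read a promoter model from a structured text file
#'
#' The model file is YAML with fields `subfamily`, `pattern_id` (optional),
#' `tether`, and either `monomers` (list of inline sequences, 5'-most full
#' monomer first) or `monomer_fasta` (path, relative to the model file, of
#' a FASTA whose records are the monomers in order). Sequences are
#' uppercased on read.
#'
#' @param path path to the YAML model file.
#' @return a [promoter_model()].
#' @export
read_promoter_model <- function(path) {
  spec <- yaml::read_yaml(path)
  for (f in c("subfamily", "tether")) {
    if (is.null(spec[[f]])) stop(sprintf("model file missing field '%s'", f))
  }
  if (!is.null(spec$monomers)) {
    monomers <- toupper(unlist(spec$monomers, use.names = FALSE))
  } else if (!is.null(spec$monomer_fasta)) {
    fa <- file.path(dirname(path), spec$monomer_fasta)
    monomers <- unname(read_fasta(fa))
  } else {
    stop("model file must provide 'monomers' or 'monomer_fasta'")
  }
  promoter_model(
    subfamily = spec$subfamily,
    monomers = monomers,
    tether = toupper(spec$tether),
    pattern_id = if (is.null(spec$pattern_id)) "default" else spec$pattern_id,
    notes = if (is.null(spec$notes)) "" else spec$notes
  )
}

#' Export the extended query as FASTA
#'
#' Writes the query sequence under the id
#' `<subfamily>_<pattern>_<total_monomers>mer`, ready for use with external
#' aligners.
#'
#' @param query an extended query.
#' @param path output FASTA path.
#' @return the record id, invisibly.
#' @export
write_query_fasta <- function(query, path) {
  stopifnot(inherits(query, "extended_query"))
  id <- sprintf(
    "%s_%s_%dmer", query$model$subfamily, query$model$pattern_id,
    query$total_monomers
  )
  seqs <- stats::setNames(query$sequence, id)
  write_fasta(seqs, path)
  invisible(id)
}
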