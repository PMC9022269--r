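#' Read a FASTA file
#'
#' Reads via Biostrings, uppercases sequences, and enforces unique ids and
#' non-empty records.
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf(
      "duplicate FASTA id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  if (any(nchar(seqs) == 0L)) {
    stop(sprintf(
      "empty FASTA record(s): %s",
      paste(ids[nchar(seqs) == 0L], collapse = ", ")
    ))
  }
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' Reads a BED file (via rtracklayer) into the 0-based half-open interval
#' table used by [extract_loci()]. Records without a strand are treated
#' as plus-strand.
#'
#' @param path BED path.
#' @return data frame `chrom`, `start` (0-based), `end` (exclusive),
#'   `name`, `strand`.
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_bed requires the rtracklayer package")
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  strand <- as.character(gr$strand)
  strand[strand == "*"] <- "+"
  nm <- if (!is.null(gr$name)) gr$name else sprintf("iv%d", seq_len(nrow(gr)))
  data.frame(
    chrom = as.character(gr$seqnames),
    start = gr$start - 1L,
    end = gr$end,
    name = nm,
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Extract loci from a genome in element orientation
#'
#' Strand-aware extraction: minus-strand intervals are
#' reverse-complemented so every extracted locus reads 5' to 3' in element
#' orientation. Intervals are 0-based half-open; record names carry the
#' coordinates.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param intervals data frame with columns `chrom`, `start`, `end`,
#'   `name`, `strand` (`+`/`-`), 0-based half-open.
#' @return named character vector of locus sequences.
#' @export
extract_loci <- function(genome, intervals) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(intervals))) {
    stop("intervals need columns chrom, start, end, strand")
  }
  if (is.null(intervals$name)) {
    intervals$name <- sprintf("iv%d", seq_len(nrow(intervals)))
  }
  out <- character(nrow(intervals))
  nms <- character(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    if (!(iv$chrom %in% names(genome))) {
      stop(sprintf("interval '%s': unknown chromosome '%s'", iv$name, iv$chrom))
    }
    clen <- nchar(genome[[iv$chrom]])
    if (iv$start < 0L || iv$end <= iv$start || iv$end > clen) {
      stop(sprintf(
        "interval '%s': [%d, %d) out of bounds for %s (length %d)",
        iv$name, iv$start, iv$end, iv$chrom, clen
      ))
    }
    if (!(iv$strand %in% c("+", "-"))) {
      stop(sprintf("interval '%s': strand must be '+' or '-'", iv$name))
    }
    s <- substr(genome[[iv$chrom]], iv$start + 1L, iv$end)
    if (iv$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    out[i] <- s
    nms[i] <- sprintf("%s::%s:%d-%d(%s)", iv$name, iv$chrom, iv$start, iv$end, iv$strand)
  }
  stats::setNames(out, nms)
}
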