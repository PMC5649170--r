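# BLAST tabular (outfmt 6) reading and writing.
#
# Internal hit coordinates are 0-based half-open on the forward strand with
# an explicit strand flag; the 1-based inclusive, possibly reversed blastx
# convention is confined to this file.

.HIT_COLS <- c("query_id", "ref_id", "pident", "length", "mismatch",
               "gapopen", "q_start", "q_end", "strand", "s_start", "s_end",
               "evalue", "bitscore")

#' Read translated-search hits from a BLAST tabular file
#'
#' Parses the 12-column `-outfmt 6` layout (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). Query
#' coordinates are converted from 1-based inclusive to 0-based half-open on
#' the forward strand; reverse-strand blastx rows (qstart > qend) are
#' normalized to forward coordinates with `strand = "-"`. Subject (protein)
#' coordinates become 0-based half-open amino-acid positions.
#'
#' @param path Path to a tab-separated hit table without header.
#' @return Data.frame of hits with columns query_id, ref_id, pident, length,
#'   mismatch, gapopen, q_start, q_end, strand, s_start, s_end, evalue,
#'   bitscore.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stopf("parse error at line %d of %s: expected 12 columns, found %d",
          which(nf != 12L)[1], path, nf[nf != 12L][1])
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(apply(num, 1, anyNA))[1]
    stopf("parse error at line %d of %s: non-numeric coordinate or score", bad, path)
  }
  qs <- num[, 5]; qe <- num[, 6]
  rev <- qs > qe
  hits <- data.frame(
    query_id = m[, 1], ref_id = m[, 2], pident = num[, 1],
    length = as.integer(num[, 2]), mismatch = as.integer(num[, 3]),
    gapopen = as.integer(num[, 4]),
    q_start = as.integer(ifelse(rev, qe, qs) - 1L),
    q_end = as.integer(ifelse(rev, qs, qe)),
    strand = ifelse(rev, "-", "+"),
    s_start = as.integer(num[, 7] - 1L), s_end = as.integer(num[, 8]),
    evalue = num[, 9], bitscore = num[, 10], stringsAsFactors = FALSE)
  bad <- hits$q_start >= hits$q_end | hits$s_start >= hits$s_end
  if (any(bad))
    stopf("parse error at line %d of %s: empty alignment interval",
          which(bad)[1], path)
  hits
}

#' Write hits back to BLAST tabular format
#'
#' Inverse of [read_blast_tab()]: restores 1-based inclusive coordinates and
#' the reversed-query convention for minus-strand hits.
#'
#' @param hits Hit data.frame as produced by [read_blast_tab()] or
#'   [builtin_search()].
#' @param path Output path.
#' @export
write_blast_tab <- function(hits, path) {
  minus <- hits$strand == "-"
  qstart <- ifelse(minus, hits$q_end, hits$q_start + 1L)
  qend <- ifelse(minus, hits$q_start + 1L, hits$q_end)
  out <- data.frame(hits$query_id, hits$ref_id, hits$pident, hits$length,
                    hits$mismatch, hits$gapopen, qstart, qend,
                    hits$s_start + 1L, hits$s_end,
                    format(hits$evalue, digits = 6, scientific = TRUE),
                    hits$bitscore)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @noRd
empty_hits <- function() {
  data.frame(query_id = character(0), ref_id = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), q_start = integer(0), q_end = integer(0),
             strand = character(0), s_start = integer(0), s_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}
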