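# Built-in six-frame translated local-alignment search.
#
# A correctness oracle for desk-scale fixtures (<= ~1 Mb of contig), not a
# BLAST replacement: each (contig frame, reference) pair contributes at most
# its single best Smith-Waterman alignment.

#' Six-frame translation of a nucleotide sequence
#'
#' Frames +1, +2, +3 translate the forward strand at offsets 0/1/2; frames
#' -1, -2, -3 the reverse complement. Stop codons are rendered `*` and
#' codons containing N are rendered `X`.
#'
#' @param seq A nucleotide sequence (character scalar or `DNAString`) over
#'   A, C, G, T, N.
#' @return Named character vector of six peptides (`"+1"`, `"+2"`, `"+3"`,
#'   `"-1"`, `"-2"`, `"-3"`).
#' @export
six_frame_translate <- function(seq) {
  if (is(seq, "DNAString")) seq <- as.character(seq)
  if (!nzchar(seq)) stopf("cannot translate an empty sequence")
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    n <- length(s)
    if (n - off < 3L) return("")
    sub <- Biostrings::subseq(s, off + 1L, off + ((n - off) %/% 3L) * 3L)
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
  }
  pep <- c(one(fwd, 0L), one(fwd, 1L), one(fwd, 2L),
           one(rev, 0L), one(rev, 1L), one(rev, 2L))
  names(pep) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  pep
}

# Karlin-Altschul parameters for BLOSUM62 with affine gaps 11/1 (the values
# blastp reports for this scoring system) and the derived statistics.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' @noRd
raw_to_bitscore <- function(raw) (.KA_LAMBDA * raw - log(.KA_K)) / log(2)

#' @noRd
bitscore_to_evalue <- function(bit, m, n) m * n * 2^(-bit)

#' Six-frame translated search of contigs against a transposase reference set
#'
#' Translates every contig in six frames and computes the best local
#' alignment (BLOSUM62, affine gap open 11 / extend 1) of each frame peptide
#' against each reference protein. Bit scores follow the Karlin-Altschul
#' transform of the raw score and E-values use `E = m * n * 2^-S'` with
#' `m` the frame peptide length and `n` the total amino-acid size of the
#' reference set. Hits failing the threshold (strict `evalue < max_evalue`,
#' or `bitscore >= min_bitscore` when given) are discarded; peptide
#' coordinates are mapped back to 0-based half-open forward-strand
#' nucleotide coordinates on the contig.
#'
#' @param contigs Named character vector or `DNAStringSet` of contigs.
#' @param refs Reference database (`transposase_ref` data.frame).
#' @param max_evalue Strict upper bound on the E-value (default `1e-6`).
#' @param min_bitscore Optional bit-score threshold used instead of
#'   `max_evalue`.
#' @return Hit data.frame in the same layout as [read_blast_tab()].
#' @export
builtin_search <- function(contigs, refs, max_evalue = 1e-6,
                           min_bitscore = NULL) {
  if (is(contigs, "DNAStringSet")) {
    contigs <- setNames(as.character(contigs), names(contigs))
  }
  if (length(contigs) == 0L || nrow(refs) == 0L)
    stopf("builtin_search needs nonempty contigs and references")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stopf("contigs must be named")
  db_aa <- sum(refs$aa_len)

  # all frame peptides of all contigs in one set
  pep_list <- lapply(contigs, six_frame_translate)
  pep_id <- unlist(lapply(names(contigs), function(cid)
    paste(cid, c("+1", "+2", "+3", "-1", "-2", "-3"), sep = "\r")))
  peps <- unlist(pep_list, use.names = FALSE)
  keep <- nchar(peps) > 0L
  peps <- peps[keep]; pep_id <- pep_id[keep]
  pat <- Biostrings::AAStringSet(setNames(peps, pep_id))
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B62 <- get("BLOSUM62", envir = data_env)

  contig_len <- nchar(contigs)
  out <- list()
  for (ri in seq_len(nrow(refs))) {
    aln <- Biostrings::pairwiseAlignment(
      pat, Biostrings::AAString(refs$aa_seq[ri]), type = "local",
      substitutionMatrix = B62, gapOpening = 11, gapExtension = 1)
    raw <- Biostrings::score(aln)
    bit <- raw_to_bitscore(raw)
    ev <- bitscore_to_evalue(bit, Biostrings::width(pat), db_aa)
    keep <- if (is.null(min_bitscore)) ev < max_evalue else bit >= min_bitscore
    keep <- keep & raw > 0
    if (!any(keep)) next
    idx <- which(keep)
    pa <- aln[idx]
    meta <- strsplit(pep_id[idx], "\r", fixed = TRUE)
    cid <- vapply(meta, `[[`, "", 1L)
    frame <- vapply(meta, `[[`, "", 2L)
    f_off <- as.integer(substr(frame, 2, 2)) - 1L
    f_strand <- substr(frame, 1, 1)
    aa_s <- Biostrings::start(Biostrings::pattern(pa))   # 1-based aa in frame
    aa_e <- Biostrings::end(Biostrings::pattern(pa))
    L <- contig_len[cid]
    q_start <- ifelse(f_strand == "+",
                      f_off + 3L * (aa_s - 1L),
                      L - (f_off + 3L * aa_e))
    q_end <- ifelse(f_strand == "+",
                    f_off + 3L * aa_e,
                    L - (f_off + 3L * (aa_s - 1L)))
    pat_al <- as.character(Biostrings::alignedPattern(pa))
    sub_al <- as.character(Biostrings::alignedSubject(pa))
    alen <- nchar(pat_al)
    nmatch <- Biostrings::nmatch(pa)
    nmis <- Biostrings::nmismatch(pa)
    gapopen <- vapply(seq_along(idx), function(i) {
      g <- function(s) sum(gregexpr("-+", s)[[1]] > 0)
      g(pat_al[i]) + g(sub_al[i])
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      query_id = cid, ref_id = refs$ref_id[ri],
      pident = round(100 * nmatch / alen, 2), length = as.integer(alen),
      mismatch = as.integer(nmis), gapopen = as.integer(gapopen),
      q_start = as.integer(q_start), q_end = as.integer(q_end),
      strand = ifelse(f_strand == "+", "+", "-"),
      s_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
      s_end = Biostrings::end(Biostrings::subject(pa)),
      evalue = ev[idx], bitscore = round(bit[idx], 1),
      stringsAsFactors = FALSE)
  }
  hits <- if (length(out)) do.call(rbind, out) else empty_hits()
  hits <- hits[order(hits$query_id, hits$q_start, hits$ref_id), ]
  rownames(hits) <- NULL
  hits
}
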