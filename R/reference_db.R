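# Synthetic IS reference protein database (ISfinder-like curated set).

# fixed reverse-translation table: one codon per amino acid, standard genetic
# code, so a planted ORF translates back to its source protein exactly
.CODON_OF <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT")

.AA20 <- names(.CODON_OF)

#' Reverse-translate a protein with a fixed codon table
#'
#' Uses one fixed codon per amino acid (standard genetic code) so that the
#' built-in translated search recovers planted ORFs without any aligner
#' stochasticity entering the ground truth.
#'
#' @param aa_seq Protein sequence (character scalar over the 20 standard
#'   amino acids).
#' @return Nucleotide sequence of length `3 * nchar(aa_seq)`.
#' @export
reverse_translate <- function(aa_seq) {
  aa <- strsplit(aa_seq, "")[[1]]
  bad <- setdiff(aa, .AA20)
  if (length(bad) > 0)
    stopf("cannot reverse-translate residue(s): %s", paste(bad, collapse = ","))
  paste(.CODON_OF[aa], collapse = "")
}

#' Generate a synthetic IS reference protein database
#'
#' Emulates a curated ISfinder-style set of transposase ORF protein
#' sequences: `n_ref_families` IS families (real family labels: IS3, IS5,
#' IS200/IS605, IS256, IS66, ...), each with `refs_per_family` members
#' derived from a family prototype by point substitution (30\% of positions),
#' so that members of one family cross-align while families are unrelated.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return Data.frame of class `transposase_ref` with columns `ref_id`,
#'   `family`, `aa_seq`, `aa_len`.
#' @export
generate_reference_db <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  families <- .IS_FAMILY_POOL[seq_len(cfg$n_ref_families)]
  rows <- list()
  for (fi in seq_along(families)) {
    len <- sample_range(cfg$ref_aa_length_range[1], cfg$ref_aa_length_range[2])
    proto <- sample(.AA20, len, replace = TRUE)
    for (mi in seq_len(cfg$refs_per_family)) {
      member <- proto
      mut <- runif(len) < 0.30
      member[mut] <- sample(.AA20, sum(mut), replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = sprintf("%s_m%02d", gsub("/", "-", families[fi]), mi),
        family = families[fi],
        aa_seq = paste(member, collapse = ""),
        aa_len = len, stringsAsFactors = FALSE)
    }
  }
  refs <- do.call(rbind, rows)
  class(refs) <- c("transposase_ref", "data.frame")
  refs
}

#' Write / read a reference database as FASTA plus a family table
#'
#' The FASTA holds the protein sequences (ids are `ref_id`); the family TSV
#' maps `ref_id` to its IS family label.
#'
#' @param refs A `transposase_ref` data.frame.
#' @param fasta_path,family_path Output paths.
#' @export
write_reference_db <- function(refs, fasta_path, family_path) {
  aa <- Biostrings::AAStringSet(setNames(refs$aa_seq, refs$ref_id))
  Biostrings::writeXStringSet(aa, fasta_path)
  write.table(refs[, c("ref_id", "family", "aa_len")], family_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, family_path))
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(fasta_path, family_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  fam <- read.table(family_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  refs <- data.frame(ref_id = names(aa), aa_seq = as.character(aa),
                     aa_len = Biostrings::width(aa), stringsAsFactors = FALSE)
  refs <- merge(refs, fam[, c("ref_id", "family")], by = "ref_id", sort = TRUE)
  refs <- refs[, c("ref_id", "family", "aa_seq", "aa_len")]
  class(refs) <- c("transposase_ref", "data.frame")
  refs
}
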