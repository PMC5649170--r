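# Synthetic taxon-structured community with planted transposase ORFs,
# single-copy marker intervals and per-sample interval read maps.

#' Generate a synthetic community with known ground truth
#'
#' Builds one contig pool per configuration (shared by the metagenome and the
#' metatranscriptome, which therefore share coordinates), plants
#' reverse-translated transposase ORFs on random strands, lays out one
#' single-copy marker interval per marker label per taxon "genome", and
#' emits an interval-based read map per sample. For a DNA sample the expected
#' transposase read fraction of a taxon equals the configured planted
#' fraction; for an RNA sample each planted ORF's read intensity is further
#' multiplied by `expression_multiplier[family, taxon]`. Background reads are
#' placed uniformly over the non-transposase part of each genome (covering
#' the marker intervals), so single-copy marker hit counts estimate genome
#' equivalents.
#'
#' @param cfg A [sim_config()].
#' @param refs Reference database from [generate_reference_db()].
#' @return A list of class `tnp_community` with elements
#'   \describe{
#'     \item{contigs}{`DNAStringSet` of contig sequences.}
#'     \item{taxonomy}{per-contig lineage (`contig_id`, `domain`, `phylum`,
#'       `class`, `order`, `genus`, `taxon`).}
#'     \item{samples}{the sample sheet.}
#'     \item{read_map}{`contig_id`, `start0`, `end0`, `sample_id`,
#'       `read_count` (0-based half-open intervals).}
#'     \item{truth}{ground truth: `planted` (per-contig transposase
#'       intervals with strand, ref, family, taxon), `markers` (per-contig
#'       marker intervals), `samples` (per-sample true transposase and
#'       bacterial read counts), `sample_taxa` (the same per taxon).}
#'   }
#' @export
generate_community <- function(cfg, refs) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  samples <- sample_sheet(cfg)
  rl <- cfg$read_length_nt

  ## ---- contig scaffolds and planted ORFs -------------------------------
  contig_rows <- list()   # contig_id, taxon, length
  planted <- list()       # contig_id, start0, end0, strand, ref_id, family, taxon
  marker_rows <- list()   # contig_id, start0, end0, marker, taxon
  seqs <- list()
  k_plant <- cfg$planted_orfs_per_contig
  if (k_plant > nrow(refs))
    stopf("configuration error: planted_orfs_per_contig exceeds reference count")

  for (ti in seq_len(nrow(cfg$taxa))) {
    taxon <- cfg$taxa$taxon[ti]
    free_by_contig <- list()  # free intervals per contig after planting
    for (cj in seq_len(cfg$n_contigs_per_taxon)) {
      cid <- sprintf("%s_c%02d", taxon, cj)
      len <- sample_range(cfg$contig_length_range[1], cfg$contig_length_range[2])
      base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      placed <- matrix(numeric(0), ncol = 2)
      if (k_plant > 0L) {
        ref_idx <- sample.int(nrow(refs), k_plant)
        for (ri in ref_idx) {
          orf_nt <- reverse_translate(refs$aa_seq[ri])
          olen <- nchar(orf_nt)
          if (olen > len)
            stopf("generation error: contig %s (length %d) too short to host a planted ORF of %d nt",
                  cid, len, olen)
          ok <- FALSE
          for (try in 1:100) {
            s0 <- sample.int(len - olen + 1L, 1L) - 1L
            e0 <- s0 + olen
            if (nrow(placed) == 0 ||
                all(e0 <= placed[, 1] | s0 >= placed[, 2])) { ok <- TRUE; break }
          }
          if (!ok)
            stopf("generation error: contig %s too short to host all planted ORFs", cid)
          strand <- sample(c("+", "-"), 1L)
          nt <- if (strand == "+") orf_nt else
            as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf_nt)))
          base[(s0 + 1L):e0] <- strsplit(nt, "")[[1]]
          placed <- rbind(placed, c(s0, e0))
          planted[[length(planted) + 1L]] <- data.frame(
            contig_id = cid, start0 = s0, end0 = e0, strand = strand,
            ref_id = refs$ref_id[ri], family = refs$family[ri],
            taxon = taxon, stringsAsFactors = FALSE)
        }
      }
      seqs[[cid]] <- paste(base, collapse = "")
      contig_rows[[length(contig_rows) + 1L]] <- data.frame(
        contig_id = cid, taxon = taxon, length = len, stringsAsFactors = FALSE)
      # free space left on this contig (for marker layout)
      free <- matrix(c(0, len), ncol = 2)
      if (nrow(placed) > 0)
        for (i in seq_len(nrow(placed)))
          free <- iv_subtract1(free, placed[i, 1], placed[i, 2])
      free_by_contig[[cid]] <- free
    }
    ## ---- single-copy markers: one interval per label per taxon genome --
    if (cfg$n_single_copy_markers > 0L) {
      labels <- sprintf("M%02d", seq_len(cfg$n_single_copy_markers))
      cids <- names(free_by_contig)
      next_contig <- 1L
      for (lab in labels) {
        placed_marker <- FALSE
        for (attempt in seq_along(cids)) {
          cid <- cids[next_contig]
          next_contig <- (next_contig %% length(cids)) + 1L
          free <- free_by_contig[[cid]]
          fits <- which(iv_width(free) >= cfg$marker_length_nt)
          if (length(fits) > 0) {
            g <- fits[1]
            s0 <- free[g, 1]; e0 <- s0 + cfg$marker_length_nt
            marker_rows[[length(marker_rows) + 1L]] <- data.frame(
              contig_id = cid, start0 = s0, end0 = e0, marker = lab,
              taxon = taxon, stringsAsFactors = FALSE)
            free_by_contig[[cid]] <- iv_subtract1(free, s0, e0)
            placed_marker <- TRUE
            break
          }
        }
        if (!placed_marker)
          stopf("generation error: no room for marker %s in taxon %s genome",
                lab, taxon)
      }
    }
  }

  contig_tbl <- do.call(rbind, contig_rows)
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(contig_id = character(0), start0 = numeric(0), end0 = numeric(0),
               strand = character(0), ref_id = character(0),
               family = character(0), taxon = character(0))
  markers <- if (length(marker_rows)) do.call(rbind, marker_rows) else
    data.frame(contig_id = character(0), start0 = numeric(0), end0 = numeric(0),
               marker = character(0), taxon = character(0))

  taxonomy <- merge(contig_tbl[, c("contig_id", "taxon")],
                    cbind(cfg$taxa, domain = "Bacteria"), by = "taxon")
  taxonomy <- taxonomy[, c("contig_id", "domain", "phylum", "class",
                           "order", "genus", "taxon")]
  taxonomy <- taxonomy[order(taxonomy$contig_id), ]
  rownames(taxonomy) <- NULL

  ## ---- per-taxon background placement domains --------------------------
  # start positions where a read of length rl overlaps any planted interval
  # by less than half the read (so it never counts as a transposase read
  # under the default read-assignment rule)
  half <- as.integer(ceiling(rl / 2))
  bg_domain <- list()  # per taxon: data.frame(contig_id, gap_start, gap_len)
  for (ti in seq_len(nrow(cfg$taxa))) {
    taxon <- cfg$taxa$taxon[ti]
    rows <- list()
    for (cid in contig_tbl$contig_id[contig_tbl$taxon == taxon]) {
      len <- contig_tbl$length[contig_tbl$contig_id == cid]
      allowed <- matrix(c(0, len - rl + 1), ncol = 2)  # valid start0 range
      pl <- planted[planted$contig_id == cid, , drop = FALSE]
      for (i in seq_len(nrow(pl)))
        allowed <- iv_subtract1(allowed, pl$start0[i] - rl + half,
                                pl$end0[i] - half + 1L)
      for (i in seq_len(nrow(allowed)))
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = cid, gap_start = allowed[i, 1],
          gap_len = allowed[i, 2] - allowed[i, 1], stringsAsFactors = FALSE)
    }
    dom <- do.call(rbind, rows)
    dom <- dom[dom$gap_len > 0, , drop = FALSE]
    if (nrow(dom) == 0)
      stopf("generation error: taxon %s has no background space for reads", taxon)
    bg_domain[[taxon]] <- dom
  }

  ## ---- read allocation per sample --------------------------------------
  map_contig <- character(0); map_start <- integer(0); map_sample <- character(0)
  map_end <- integer(0)
  truth_sample <- list(); truth_sample_taxa <- list()

  for (si in seq_len(nrow(samples))) {
    srow <- samples[si, ]
    n_taxa <- as.vector(rmultinom(1, cfg$reads_per_sample, cfg$taxa$weight))
    tnp_total <- 0L
    for (ti in seq_len(nrow(cfg$taxa))) {
      taxon <- cfg$taxa$taxon[ti]
      n_t <- n_taxa[ti]
      if (n_t == 0L) {
        truth_sample_taxa[[length(truth_sample_taxa) + 1L]] <- data.frame(
          sample_id = srow$sample_id, taxon = taxon, reads = 0L,
          tnp_reads = 0L, stringsAsFactors = FALSE)
        next
      }
      pl <- planted[planted$taxon == taxon, , drop = FALSE]
      k_t <- nrow(pl)
      m <- if (srow$molecule == "RNA" && k_t > 0)
        vapply(seq_len(k_t), function(i)
          expression_multiplier_for(cfg, pl$family[i], taxon), numeric(1))
      else rep(1, k_t)
      p <- if (k_t == 0L) numeric(0)
      else if (identical(cfg$planted_tnp_read_fraction, "uniform")) {
        # uniform genome depth: read weight proportional to planted length
        G_t <- sum(contig_tbl$length[contig_tbl$taxon == taxon])
        (pl$end0 - pl$start0) / G_t * m
      } else {
        f <- planted_fraction_for(cfg, srow$station, srow$fraction,
                                  srow$sample_id, taxon)
        f * m / k_t
      }
      if (sum(p) > 1)
        stopf("configuration error: transposase read weight %.3f exceeds 1 for taxon %s in sample %s",
              sum(p), taxon, srow$sample_id)
      cnt <- as.vector(rmultinom(1, n_t, c(p, 1 - sum(p))))
      tnp_cnt <- if (k_t > 0) cnt[seq_len(k_t)] else integer(0)
      bg_cnt <- cnt[length(cnt)]
      # transposase reads: uniform inside their planted interval
      for (i in seq_len(k_t)) {
        if (tnp_cnt[i] == 0L) next
        w <- pl$end0[i] - pl$start0[i]
        if (w >= rl) {
          st <- pl$start0[i] + sample.int(w - rl + 1L, tnp_cnt[i], replace = TRUE) - 1L
          en <- st + rl
        } else {
          st <- rep(pl$start0[i], tnp_cnt[i]); en <- rep(pl$end0[i], tnp_cnt[i])
        }
        map_contig <- c(map_contig, rep(pl$contig_id[i], tnp_cnt[i]))
        map_start <- c(map_start, st); map_end <- c(map_end, en)
        map_sample <- c(map_sample, rep(srow$sample_id, tnp_cnt[i]))
      }
      # background reads: uniform over the allowed start domain
      if (bg_cnt > 0L) {
        dom <- bg_domain[[taxon]]
        cum <- cumsum(dom$gap_len)
        u <- sample.int(cum[length(cum)], bg_cnt, replace = TRUE)
        gi <- findInterval(u - 1L, cum) + 1L
        off <- u - c(0L, cum)[gi] - 1L
        st <- dom$gap_start[gi] + off
        map_contig <- c(map_contig, dom$contig_id[gi])
        map_start <- c(map_start, st); map_end <- c(map_end, st + rl)
        map_sample <- c(map_sample, rep(srow$sample_id, bg_cnt))
      }
      tnp_t <- sum(tnp_cnt)
      tnp_total <- tnp_total + tnp_t
      truth_sample_taxa[[length(truth_sample_taxa) + 1L]] <- data.frame(
        sample_id = srow$sample_id, taxon = taxon, reads = n_t,
        tnp_reads = tnp_t, stringsAsFactors = FALSE)
    }
    truth_sample[[si]] <- data.frame(
      sample_id = srow$sample_id, bacterial_reads = cfg$reads_per_sample,
      tnp_reads = tnp_total, stringsAsFactors = FALSE)
  }

  ## ---- aggregate identical read intervals ------------------------------
  key <- paste(map_contig, map_start, map_end, map_sample, sep = "\r")
  cnt <- rowsum(rep(1L, length(key)), key)
  parts <- strsplit(rownames(cnt), "\r", fixed = TRUE)
  read_map <- data.frame(
    contig_id = vapply(parts, `[[`, "", 1L),
    start0 = as.integer(vapply(parts, `[[`, "", 2L)),
    end0 = as.integer(vapply(parts, `[[`, "", 3L)),
    sample_id = vapply(parts, `[[`, "", 4L),
    read_count = as.integer(cnt[, 1]), stringsAsFactors = FALSE)
  read_map <- read_map[order(read_map$sample_id, read_map$contig_id,
                             read_map$start0, read_map$end0), ]
  rownames(read_map) <- NULL

  out <- list(
    contigs = Biostrings::DNAStringSet(unlist(seqs)),
    taxonomy = taxonomy, samples = samples, read_map = read_map,
    truth = list(planted = planted, markers = markers,
                 samples = do.call(rbind, truth_sample),
                 sample_taxa = do.call(rbind, truth_sample_taxa)))
  class(out) <- "tnp_community"
  out
}

#' Write a synthetic community to plain-text files
#'
#' @param comm A `tnp_community` from [generate_community()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_community <- function(comm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(contigs = file.path(dir, "contigs.fna"),
         taxonomy = file.path(dir, "taxonomy.tsv"),
         samples = file.path(dir, "samples.tsv"),
         read_map = file.path(dir, "read_map.tsv"),
         truth_planted = file.path(dir, "truth_planted.tsv"),
         truth_markers = file.path(dir, "truth_markers.tsv"),
         truth_samples = file.path(dir, "truth_samples.tsv"))
  Biostrings::writeXStringSet(comm$contigs, p["contigs"])
  tsv <- function(df, path) write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  tsv(comm$taxonomy, p["taxonomy"]); tsv(comm$samples, p["samples"])
  tsv(comm$read_map, p["read_map"]); tsv(comm$truth$planted, p["truth_planted"])
  tsv(comm$truth$markers, p["truth_markers"])
  tsv(comm$truth$samples, p["truth_samples"])
  invisible(p)
}
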