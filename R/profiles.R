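# Sample profiles and the normalized abundance statistics derived from them.

#' Assign mapped read intervals to transposase calls
#'
#' A mapped read(-interval) counts as a transposase read when at least
#' `min_read_overlap_frac` of its length overlaps the union of call segments
#' on its contig (strand-agnostic). The IS family attributed to the read is
#' the family with the largest overlap (ties: lexicographically smallest
#' family label).
#'
#' @param read_map Read map data.frame (contig_id, start0, end0, sample_id,
#'   read_count).
#' @param calls Call data.frame from [call_transposases()].
#' @param contig_lengths Optional named vector to validate read intervals.
#' @param min_read_overlap_frac Minimum overlapped fraction of the read
#'   (default 0.5; use 0 + any-overlap via a small positive value).
#' @return The read map with logical `is_tnp` and character `family`
#'   (NA for non-transposase reads) columns.
#' @export
count_transposase_reads <- function(read_map, calls, contig_lengths = NULL,
                                    min_read_overlap_frac = 0.5) {
  if (!is.null(contig_lengths)) {
    L <- contig_lengths[read_map$contig_id]
    bad <- is.na(L) | read_map$start0 < 0 | read_map$end0 > L
    if (any(bad))
      stopf("read interval off contig: %s [%d, %d)",
            read_map$contig_id[which(bad)[1]],
            read_map$start0[which(bad)[1]], read_map$end0[which(bad)[1]])
  }
  read_map$is_tnp <- FALSE
  read_map$family <- NA_character_
  if (nrow(calls) == 0L || nrow(read_map) == 0L) return(read_map)

  reads_gr <- GenomicRanges::GRanges(
    read_map$contig_id,
    IRanges::IRanges(read_map$start0 + 1L, read_map$end0))
  segs_gr <- GenomicRanges::GRanges(
    calls$contig_id, IRanges::IRanges(calls$start0 + 1L, calls$end0),
    family = calls$family)
  # union of call segments (strand-agnostic) for the overlap threshold
  union_gr <- GenomicRanges::reduce(segs_gr, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(reads_gr, union_gr)
  if (length(ov) > 0) {
    qh <- S4Vectors::queryHits(ov)
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      reads_gr[qh], union_gr[S4Vectors::subjectHits(ov)]))
    tot <- rowsum(w, qh)
    ridx <- as.integer(rownames(tot))
    rw <- GenomicRanges::width(reads_gr)[ridx]
    read_map$is_tnp[ridx] <- tot[, 1] >= min_read_overlap_frac * rw
  }
  # family attribution by majority overlap
  tnp_idx <- which(read_map$is_tnp)
  if (length(tnp_idx) > 0) {
    ov2 <- GenomicRanges::findOverlaps(reads_gr[tnp_idx], segs_gr)
    if (length(ov2) > 0) {
      qh <- S4Vectors::queryHits(ov2)
      fam <- segs_gr$family[S4Vectors::subjectHits(ov2)]
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        reads_gr[tnp_idx][qh], segs_gr[S4Vectors::subjectHits(ov2)]))
      key <- paste(qh, fam, sep = "\r")
      agg <- rowsum(w, key)
      parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
      ai <- as.integer(vapply(parts, `[[`, "", 1L))
      af <- vapply(parts, `[[`, "", 2L)
      ord <- order(ai, -agg[, 1], af)
      first <- !duplicated(ai[ord])
      read_map$family[tnp_idx[ai[ord][first]]] <- af[ord][first]
    }
  }
  read_map
}

#' Build per-sample profiles of transposase and marker read counts
#'
#' Aggregates an assigned read map into one profile per sample: total
#' bacterial reads (reads on contigs whose domain is Bacteria; unclassified
#' contigs are excluded from the denominator), transposase reads, per-taxon
#' read and transposase-read counts at all lineage ranks, per-IS-family
#' transposase counts, and single-copy marker hit counts (reads overlapping
#' a marker interval by at least `min_read_overlap_frac` of their length).
#'
#' @param read_map Read map (contig_id, start0, end0, sample_id, read_count).
#' @param calls Transposase calls.
#' @param taxonomy Per-contig lineage (contig_id, domain, phylum, class,
#'   order, genus, optionally taxon).
#' @param samples Sample sheet (sample_id, station, depth_m, fraction,
#'   molecule).
#' @param markers Optional marker intervals (contig_id, start0, end0,
#'   marker, taxon).
#' @param min_read_overlap_frac Read-overlap rule, see
#'   [count_transposase_reads()].
#' @return Named list of `sample_profile` objects (class
#'   `sample_profile_list`).
#' @export
build_sample_profiles <- function(read_map, calls, taxonomy, samples,
                                  markers = NULL,
                                  min_read_overlap_frac = 0.5) {
  rm2 <- count_transposase_reads(read_map, calls,
                                 min_read_overlap_frac = min_read_overlap_frac)
  tx <- taxonomy
  if (!"taxon" %in% names(tx)) tx$taxon <- tx$genus
  idx <- match(rm2$contig_id, tx$contig_id)
  rm2$domain <- ifelse(is.na(idx), "unclassified", tx$domain[idx])
  for (r in c("phylum", "class", "order", "genus", "taxon"))
    rm2[[r]] <- ifelse(is.na(idx), "unclassified", tx[[r]][idx])

  # marker assignment (reads overlapping a marker interval >= frac)
  rm2$marker <- NA_character_
  if (!is.null(markers) && nrow(markers) > 0 && nrow(rm2) > 0) {
    reads_gr <- GenomicRanges::GRanges(
      rm2$contig_id, IRanges::IRanges(rm2$start0 + 1L, rm2$end0))
    mk_gr <- GenomicRanges::GRanges(
      markers$contig_id, IRanges::IRanges(markers$start0 + 1L, markers$end0),
      marker = markers$marker)
    ov <- GenomicRanges::findOverlaps(reads_gr, mk_gr)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov)
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        reads_gr[qh], mk_gr[S4Vectors::subjectHits(ov)]))
      ok <- w >= min_read_overlap_frac * GenomicRanges::width(reads_gr)[qh]
      rm2$marker[qh[ok]] <- mk_gr$marker[S4Vectors::subjectHits(ov)[ok]]
    }
  }

  lineage <- unique(tx[, c("taxon", "phylum", "class", "order", "genus")])
  n_markers <- if (!is.null(markers)) length(unique(markers$marker)) else 0L
  marker_labels <- if (n_markers) sort(unique(markers$marker)) else character(0)

  profiles <- list()
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    sm <- rm2[rm2$sample_id == sid, , drop = FALSE]
    bact <- sm[sm$domain == "Bacteria", , drop = FALSE]
    taxa_tot <- aggregate_counts(bact, "taxon")
    taxa_tnp <- aggregate_counts(bact[bact$is_tnp, , drop = FALSE], "taxon")
    taxa <- merge(taxa_tot, taxa_tnp, by = "taxon", all.x = TRUE,
                  suffixes = c("", "_tnp"))
    names(taxa) <- c("taxon", "reads", "tnp_reads")
    taxa$tnp_reads[is.na(taxa$tnp_reads)] <- 0
    taxa <- merge(taxa, lineage, by = "taxon", all.x = TRUE)
    fam <- aggregate_counts(bact[bact$is_tnp & !is.na(bact$family), ,
                                 drop = FALSE], "family")
    names(fam) <- c("family", "tnp_reads")
    mk <- bact[!is.na(bact$marker), , drop = FALSE]
    mk_counts <- if (nrow(mk)) {
      a <- stats::aggregate(mk$read_count,
                            by = list(marker = mk$marker, taxon = mk$taxon),
                            FUN = sum)
      names(a)[3] <- "count"
      a
    } else data.frame(marker = character(0), taxon = character(0),
                      count = numeric(0), stringsAsFactors = FALSE)
    prof <- list(
      sample_id = sid, station = samples$station[si],
      depth_m = samples$depth_m[si], fraction = samples$fraction[si],
      molecule = samples$molecule[si],
      total_bacterial_reads = sum(bact$read_count),
      transposase_reads = sum(bact$read_count[bact$is_tnp]),
      taxa = taxa, families = fam, marker_hits = mk_counts,
      marker_labels = marker_labels, lineage = lineage)
    class(prof) <- "sample_profile"
    profiles[[sid]] <- prof
  }
  class(profiles) <- c("sample_profile_list", "list")
  profiles
}

#' @noRd
aggregate_counts <- function(df, by) {
  if (nrow(df) == 0L)
    return(setNames(data.frame(character(0), numeric(0),
                               stringsAsFactors = FALSE), c(by, "reads")))
  a <- stats::aggregate(df$read_count, by = setNames(list(df[[by]]), by),
                        FUN = sum)
  names(a)[2] <- "reads"
  a
}

# restrict a profile's taxa/marker tables to a scope at a lineage rank;
# scope NULL / "all" means all bacteria
#' @noRd
scope_rows <- function(tbl, lineage_cols, scope, rank) {
  if (is.null(scope) || identical(scope, "all")) return(tbl)
  if (!rank %in% names(tbl)) {
    stopf("rank '%s' not available", rank)
  }
  tbl[tbl[[rank]] == scope, , drop = FALSE]
}

#' Transposase fraction of all bacterial reads
#'
#' The study's primary normalization: the quotient of all transposase reads
#' divided by the total number of bacterial reads of the sample.
#'
#' @param profile A `sample_profile`.
#' @return A fraction in [0, 1].
#' @export
fraction_of_bacterial_reads <- function(profile) {
  if (profile$total_bacterial_reads <= 0)
    stopf("undefined value: sample %s has no bacterial reads",
          profile$sample_id)
  profile$transposase_reads / profile$total_bacterial_reads
}

#' Transposase fraction within one taxon
#'
#' Transposase reads annotated to a taxon divided by all reads of that
#' taxon (e.g. cyanobacterial transposase transcripts over all
#' cyanobacterial transcripts).
#'
#' @param profile A `sample_profile`.
#' @param scope Taxon label at `rank`.
#' @param rank One of phylum, class, order, genus, taxon.
#' @return A fraction in [0, 1].
#' @export
per_taxon_fraction <- function(profile, scope, rank = "phylum") {
  tbl <- scope_rows(profile$taxa, NULL, scope, rank)
  if (nrow(tbl) == 0L || sum(tbl$reads) <= 0)
    stopf("undefined value: no %s reads for %s '%s' in sample %s",
          rank, rank, scope, profile$sample_id)
  sum(tbl$tnp_reads) / sum(tbl$reads)
}

#' Transposases per genome via single-copy markers
#'
#' Scope-restricted transposase read count divided by the mean hit count
#' over the single-copy marker labels. Markers with zero hits enter the mean
#' as zeros (the denominator is the fixed number of marker labels), unless
#' all are zero, which is an error.
#'
#' @param profile A `sample_profile`.
#' @param scope `"all"` (default) or a taxon label at `rank`.
#' @param rank Lineage rank of `scope`.
#' @return Estimated transposase copies per genome (real, >= 0).
#' @export
per_genome_count <- function(profile, scope = "all", rank = "taxon") {
  mh <- marker_mean(profile, scope, rank)
  tnp <- if (identical(scope, "all")) profile$transposase_reads else {
    tbl <- scope_rows(profile$taxa, NULL, scope, rank)
    sum(tbl$tnp_reads)
  }
  tnp / mh
}

#' @noRd
marker_mean <- function(profile, scope, rank) {
  n <- length(profile$marker_labels)
  if (n == 0L) stopf("profile %s has no single-copy marker data",
                     profile$sample_id)
  mk <- profile$marker_hits
  if (!identical(scope, "all") && !is.null(scope)) {
    mk <- merge(mk, profile$lineage, by = "taxon", all.x = TRUE)
    mk <- scope_rows(mk, NULL, scope, rank)
  }
  per_label <- setNames(rep(0, n), profile$marker_labels)
  if (nrow(mk) > 0) {
    agg <- rowsum(mk$count, mk$marker)
    per_label[rownames(agg)] <- agg[, 1]
  }
  m <- mean(per_label)
  if (m <= 0)
    stopf("undefined value: all single-copy markers have zero hits in scope '%s' of sample %s",
          paste(scope, collapse = ","), profile$sample_id)
  m
}

#' Relative genome-size proxy from single-copy markers
#'
#' Total (scope-restricted) reads divided by the mean single-copy marker hit
#' count: proportional to average genome length in arbitrary units, and
#' invariant to uniform sequencing-depth rescaling.
#'
#' @inheritParams per_genome_count
#' @return Relative genome size (arbitrary units).
#' @export
genome_size_proxy <- function(profile, scope = "all", rank = "taxon") {
  mh <- marker_mean(profile, scope, rank)
  tot <- if (identical(scope, "all")) profile$total_bacterial_reads else {
    tbl <- scope_rows(profile$taxa, NULL, scope, rank)
    sum(tbl$reads)
  }
  tot / mh
}

#' Transcript:gene expression ratio for a scope
#'
#' For each matched (station, depth, fraction) DNA/RNA sample pair, the
#' scope-restricted transposase fraction of the RNA sample divided by the
#' same fraction of the DNA sample; pairs with a zero DNA-side fraction are
#' excluded with a warning. The cross-sample aggregate is the median.
#'
#' @param dna_profiles,rna_profiles `sample_profile_list`s (or mixed lists;
#'   molecules are checked).
#' @param scope `"all"`, a taxon label (with `rank`), or an IS family label
#'   (with `rank = "family"`).
#' @param rank Lineage rank, or `"family"`.
#' @return List with `ratio` (median over pairs), `pair_ratios`, `n_pairs`.
#' @export
expression_ratio <- function(dna_profiles, rna_profiles, scope = "all",
                             rank = "phylum") {
  dna <- Filter(function(p) p$molecule == "DNA", dna_profiles)
  rna <- Filter(function(p) p$molecule == "RNA", rna_profiles)
  if (length(dna) == 0L || length(rna) == 0L)
    stopf("need at least one DNA and one RNA profile")
  key <- function(p) paste(p$station, p$depth_m, p$fraction, sep = "\r")
  rna_keys <- vapply(rna, key, "")
  ratios <- numeric(0)
  for (p in dna) {
    j <- match(key(p), rna_keys)
    if (is.na(j)) next
    q <- rna[[j]]
    fd <- scope_fraction(p, scope, rank)
    fr <- scope_fraction(q, scope, rank)
    if (is.na(fd) || is.na(fr)) next
    if (fd == 0) {
      warning(sprintf("zero DNA-side fraction for scope '%s' at %s/%s; pair excluded",
                      scope, p$station, p$fraction))
      next
    }
    ratios <- c(ratios, fr / fd)
  }
  if (length(ratios) == 0L)
    stopf("no usable DNA/RNA pairs for scope '%s'", scope)
  list(ratio = median(ratios), pair_ratios = ratios, n_pairs = length(ratios))
}

# scope-restricted transposase fraction; family scopes are normalized to all
# bacterial reads (a family is not a read denominator)
#' @noRd
scope_fraction <- function(profile, scope, rank) {
  if (identical(scope, "all")) return(fraction_of_bacterial_reads(profile))
  if (identical(rank, "family")) {
    fam <- profile$families
    tnp <- if (scope %in% fam$family) fam$tnp_reads[fam$family == scope] else 0
    if (profile$total_bacterial_reads <= 0) return(NA_real_)
    return(tnp / profile$total_bacterial_reads)
  }
  tbl <- scope_rows(profile$taxa, NULL, scope, rank)
  if (nrow(tbl) == 0L || sum(tbl$reads) <= 0) return(NA_real_)
  sum(tbl$tnp_reads) / sum(tbl$reads)
}

#' Transposases per Mbp of genome
#'
#' @param tnp_count Transposase gene count of a strain.
#' @param genome_size_mbp Genome size in Mbp (> 0).
#' @param digits Decimal places reported (default 1, as in strain tables).
#' @return `tnp_count / genome_size_mbp` rounded to `digits`.
#' @export
transposases_per_mbp <- function(tnp_count, genome_size_mbp, digits = 1) {
  if (any(genome_size_mbp <= 0)) stopf("genome size must be positive")
  round(tnp_count / genome_size_mbp, digits)
}

#' Tidy abundance table from sample profiles
#'
#' One row per (sample, scope, metric): the all-bacteria transposase read
#' fraction, per-phylum and per-genus within-scope fractions, per-IS-family
#' fractions of bacterial reads, and per-genome counts (all bacteria and
#' per genus) where marker data exist.
#'
#' @param profiles A `sample_profile_list`.
#' @return Data.frame with columns sample_id, scope, scope_label, metric,
#'   value.
#' @export
abundance_table <- function(profiles) {
  rows <- list()
  add <- function(sid, scope, label, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sid, scope = scope, scope_label = label, metric = metric,
      value = value, stringsAsFactors = FALSE)
  for (p in profiles) {
    sid <- p$sample_id
    if (p$total_bacterial_reads > 0)
      add(sid, "all", "all", "fraction_of_bacterial_reads",
          fraction_of_bacterial_reads(p))
    for (rank in c("phylum", "genus")) {
      for (lab in unique(p$taxa[[rank]])) {
        tbl <- p$taxa[p$taxa[[rank]] == lab, , drop = FALSE]
        if (sum(tbl$reads) > 0)
          add(sid, rank, lab, "fraction_of_scope_reads",
              sum(tbl$tnp_reads) / sum(tbl$reads))
      }
    }
    for (i in seq_len(nrow(p$families)))
      add(sid, "family", p$families$family[i], "fraction_of_bacterial_reads",
          p$families$tnp_reads[i] / p$total_bacterial_reads)
    if (length(p$marker_labels) > 0) {
      pg <- tryCatch(per_genome_count(p, "all"), error = function(e) NA_real_)
      if (!is.na(pg)) add(sid, "all", "all", "per_genome_count", pg)
      for (g in unique(p$taxa$genus)) {
        pg <- tryCatch(per_genome_count(p, g, "genus"),
                       error = function(e) NA_real_)
        if (!is.na(pg)) add(sid, "genus", g, "per_genome_count", pg)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
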