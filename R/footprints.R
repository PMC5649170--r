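# Footprint designation and iterative highest-score resolution of
# translated-search hits into transposase calls.
#
# A footprint is the maximal contig stretch covered by one or more hits on
# one strand. Within a footprint the occupying transposase(s) are assigned
# greedily: the highest-scoring hit claims its intersection with the
# still-unassigned region, and the process repeats until no unassigned
# stretch of at least `min_residual_nt` is touched by any hit.

#' Configuration of the transposase caller
#'
#' @param max_evalue Strict E-value cutoff (hits with `evalue < max_evalue`
#'   are used; an E-value exactly equal to the cutoff is rejected).
#' @param min_orf_coverage Minimum fraction of the reference transposase
#'   ORF's amino-acid length a call must cover; exactly this value is kept
#'   ("at least").
#' @param min_residual_nt Unassigned stretches shorter than this stop the
#'   iterative assignment (30 nt, about 10 aa, is below any meaningful
#'   transposase fragment).
#' @param merge_across_strands Merge hits from both strands into one
#'   footprint (default `FALSE`: opposite-strand hits represent different
#'   ORFs).
#' @param coverage_mode `"segment"` (default) prorates reference coverage to
#'   the assigned segment; `"hit"` scores the full originating hit.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(max_evalue = 1e-6, min_orf_coverage = 0.30,
                          min_residual_nt = 30L,
                          merge_across_strands = FALSE,
                          coverage_mode = c("segment", "hit")) {
  coverage_mode <- match.arg(coverage_mode)
  if (max_evalue <= 0) stopf("max_evalue must be positive")
  if (min_orf_coverage <= 0 || min_orf_coverage > 1)
    stopf("min_orf_coverage must be in (0, 1]")
  structure(list(max_evalue = max_evalue,
                 min_orf_coverage = min_orf_coverage,
                 min_residual_nt = as.integer(min_residual_nt),
                 merge_across_strands = merge_across_strands,
                 coverage_mode = coverage_mode),
            class = "caller_config")
}

#' Designate footprints from filtered hits
#'
#' Per contig (and per strand unless `merge_across_strands`), footprints are
#' the connected components of the hit-interval overlap graph; intervals
#' that overlap or touch end-to-start are connected. Every hit belongs to
#' exactly one footprint and footprints on one (contig, strand) are
#' pairwise disjoint.
#'
#' @param hits Hit data.frame, already filtered to `evalue < max_evalue`.
#' @param config A [caller_config()].
#' @return List with `footprints` (data.frame footprint_id, contig_id,
#'   strand, start0, end0) and `hits` (the input with a `footprint_id`
#'   column).
#' @export
build_footprints <- function(hits, config = caller_config()) {
  if (nrow(hits) == 0L) {
    return(list(footprints = data.frame(
      footprint_id = character(0), contig_id = character(0),
      strand = character(0), start0 = integer(0), end0 = integer(0),
      stringsAsFactors = FALSE), hits = cbind(hits, footprint_id = character(0))))
  }
  strand_key <- if (isTRUE(config$merge_across_strands)) "*" else hits$strand
  grp <- paste(hits$query_id, strand_key, sep = "\r")
  hits$footprint_id <- NA_character_
  fps <- list()
  for (g in unique(grp)) {
    sel <- which(grp == g)
    ir <- IRanges::IRanges(start = hits$q_start[sel] + 1L, end = hits$q_end[sel])
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    for (k in seq_along(red)) {
      fid <- sprintf("%s:%s:%d-%d", hits$query_id[sel[1]],
                     if (isTRUE(config$merge_across_strands)) "*" else hits$strand[sel[1]],
                     IRanges::start(red)[k] - 1L, IRanges::end(red)[k])
      hits$footprint_id[sel[revmap[[k]]]] <- fid
      fps[[length(fps) + 1L]] <- data.frame(
        footprint_id = fid, contig_id = hits$query_id[sel[1]],
        strand = if (isTRUE(config$merge_across_strands)) "*" else hits$strand[sel[1]],
        start0 = IRanges::start(red)[k] - 1L, end0 = IRanges::end(red)[k],
        stringsAsFactors = FALSE)
    }
  }
  fp <- do.call(rbind, fps)
  fp <- fp[order(fp$contig_id, fp$start0, fp$strand), ]
  rownames(fp) <- NULL
  list(footprints = fp, hits = hits)
}

# deterministic hit ranking: bitscore desc, evalue asc, query length desc,
# ref_id asc
#' @noRd
hit_order <- function(h) {
  order(-h$bitscore, h$evalue, -(h$q_end - h$q_start), h$ref_id)
}

#' Resolve one footprint into transposase call segments
#'
#' Iterative highest-score assignment: among the hits whose query interval
#' intersects an unassigned stretch of at least `min_residual_nt`, the one
#' with the highest bit score (ties broken by lower E-value, longer query
#' interval, then lexicographically smaller ref_id) claims its intersection
#' with the whole unassigned region; each disjoint piece of that
#' intersection becomes a call segment. The loop repeats until no
#' sufficiently long unassigned stretch is touched by any hit.
#'
#' @param fp One row of the footprint table.
#' @param hits Hits of this footprint (rows with matching `footprint_id`).
#' @param config A [caller_config()].
#' @return Data.frame of call segments (contig_id, strand, start0, end0,
#'   ref_id, family-less; family is joined later), ordered by start.
#' @export
resolve_footprint <- function(fp, hits, config = caller_config()) {
  if (nrow(hits) == 0L)
    stopf("internal error: footprint %s has no hits", fp$footprint_id)
  unassigned <- matrix(c(fp$start0, fp$end0), ncol = 2)
  segs <- list()
  repeat {
    active <- unassigned[iv_width(unassigned) >= config$min_residual_nt, ,
                         drop = FALSE]
    if (nrow(active) == 0L) break
    cand <- which(vapply(seq_len(nrow(hits)), function(i)
      nrow(iv_intersect1(hits$q_start[i], hits$q_end[i], active)) > 0,
      logical(1)))
    if (length(cand) == 0L) break
    best <- cand[hit_order(hits[cand, , drop = FALSE])[1]]
    pieces <- iv_intersect1(hits$q_start[best], hits$q_end[best], unassigned)
    for (k in seq_len(nrow(pieces))) {
      segs[[length(segs) + 1L]] <- data.frame(
        contig_id = hits$query_id[best], strand = hits$strand[best],
        start0 = pieces[k, 1], end0 = pieces[k, 2],
        ref_id = hits$ref_id[best], bitscore = hits$bitscore[best],
        evalue = hits$evalue[best],
        hit_q_start = hits$q_start[best], hit_q_end = hits$q_end[best],
        hit_s_start = hits$s_start[best], hit_s_end = hits$s_end[best],
        stringsAsFactors = FALSE)
    }
    unassigned <- iv_subtract1(unassigned, hits$q_start[best], hits$q_end[best])
  }
  if (length(segs) == 0L) return(NULL)
  out <- do.call(rbind, segs)
  out[order(out$start0), , drop = FALSE]
}

#' Apply the ORF-coverage filter to resolved calls
#'
#' The amino-acid coverage fraction of a call is the number of reference
#' residues its segment aligns (prorated from the originating hit under the
#' default `coverage_mode = "segment"`) divided by the reference ORF's
#' amino-acid length. Calls covering at least `min_orf_coverage` (default
#' 30\%) are retained; exactly 30\% is kept.
#'
#' @param calls Resolved call segments.
#' @param refs Reference database (for `aa_len` and `family`).
#' @param config A [caller_config()].
#' @return Filtered calls with `aa_coverage_fraction` and `family` columns.
#' @export
filter_calls <- function(calls, refs, config = caller_config()) {
  if (is.null(calls) || nrow(calls) == 0L) return(empty_calls())
  unknown <- setdiff(calls$ref_id, refs$ref_id)
  if (length(unknown) > 0)
    stopf("unknown reference id(s) in calls: %s",
          paste(unknown, collapse = ", "))
  ri <- match(calls$ref_id, refs$ref_id)
  hit_aa <- calls$hit_s_end - calls$hit_s_start
  seg_aa <- if (config$coverage_mode == "segment") {
    (calls$end0 - calls$start0) / (calls$hit_q_end - calls$hit_q_start) * hit_aa
  } else hit_aa
  calls$aa_coverage_fraction <- seg_aa / refs$aa_len[ri]
  calls$family <- refs$family[ri]
  calls[calls$aa_coverage_fraction >= config$min_orf_coverage, , drop = FALSE]
}

#' @noRd
empty_calls <- function() {
  data.frame(contig_id = character(0), strand = character(0),
             start0 = integer(0), end0 = integer(0), ref_id = character(0),
             bitscore = numeric(0), evalue = numeric(0),
             hit_q_start = integer(0), hit_q_end = integer(0),
             hit_s_start = integer(0), hit_s_end = integer(0),
             aa_coverage_fraction = numeric(0), family = character(0),
             stringsAsFactors = FALSE)
}

#' Call transposases from hits
#'
#' Full identification chain: strict E-value filter, footprint designation
#' ([build_footprints()]), iterative highest-score resolution
#' ([resolve_footprint()]), ORF-coverage filter ([filter_calls()]), and
#' taxonomic annotation of each call from its contig's lineage. Contigs
#' without taxonomy are recorded as "unclassified" with a warning.
#'
#' @param hits Hit data.frame ([read_blast_tab()] / [builtin_search()]).
#' @param refs Reference database.
#' @param taxonomy Optional per-contig lineage data.frame (columns
#'   contig_id, phylum, class, order, genus).
#' @param config A [caller_config()].
#' @return Call data.frame sorted by contig and start, one row per retained
#'   call segment, with coverage, scores, family and lineage columns.
#' @export
call_transposases <- function(hits, refs, taxonomy = NULL,
                              config = caller_config()) {
  hits <- hits[hits$evalue < config$max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(annotate_calls(empty_calls(), taxonomy))
  built <- build_footprints(hits, config)
  pieces <- list()
  for (k in seq_len(nrow(built$footprints))) {
    fp <- built$footprints[k, ]
    fph <- built$hits[built$hits$footprint_id == fp$footprint_id, , drop = FALSE]
    res <- resolve_footprint(fp, fph, config)
    if (!is.null(res)) pieces[[length(pieces) + 1L]] <- res
  }
  calls <- if (length(pieces)) do.call(rbind, pieces) else empty_calls()
  calls <- filter_calls(calls, refs, config)
  calls <- annotate_calls(calls, taxonomy)
  calls <- calls[order(calls$contig_id, calls$start0, calls$strand), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' @noRd
annotate_calls <- function(calls, taxonomy) {
  ranks <- c("phylum", "class", "order", "genus")
  if (is.null(taxonomy)) {
    for (r in ranks) calls[[r]] <- rep("unclassified", nrow(calls))
    return(calls)
  }
  idx <- match(calls$contig_id, taxonomy$contig_id)
  if (anyNA(idx) && nrow(calls) > 0)
    warning(sprintf("%d call(s) on contigs without taxonomy; recorded as unclassified",
                    sum(is.na(idx))))
  for (r in ranks)
    calls[[r]] <- ifelse(is.na(idx), "unclassified", taxonomy[[r]][idx])
  if ("taxon" %in% names(taxonomy))
    calls$taxon <- ifelse(is.na(idx), "unclassified", taxonomy$taxon[idx])
  calls
}

#' Compare calls against planted ground truth
#'
#' Interval-level precision and recall: a call matches a planted transposase
#' interval (and vice versa) when their Jaccard overlap on the same contig
#' is at least `min_jaccard`.
#'
#' @param calls Call data.frame.
#' @param truth_planted Ground-truth planted intervals
#'   (`comm$truth$planted`).
#' @param min_jaccard Minimum intersection/union ratio (default 0.5).
#' @return List with `precision`, `recall`, `n_calls`, `n_truth`.
#' @export
evaluate_calls <- function(calls, truth_planted, min_jaccard = 0.5) {
  match_one <- function(cid, s, e, other) {
    cand <- other[other$contig_id == cid, , drop = FALSE]
    if (nrow(cand) == 0L) return(FALSE)
    inter <- pmax(0, pmin(e, cand$end0) - pmax(s, cand$start0))
    uni <- (e - s) + (cand$end0 - cand$start0) - inter
    any(inter / uni >= min_jaccard)
  }
  n_calls <- nrow(calls); n_truth <- nrow(truth_planted)
  tp_call <- vapply(seq_len(n_calls), function(i)
    match_one(calls$contig_id[i], calls$start0[i], calls$end0[i],
              truth_planted), logical(1))
  tp_truth <- vapply(seq_len(n_truth), function(i)
    match_one(truth_planted$contig_id[i], truth_planted$start0[i],
              truth_planted$end0[i], calls), logical(1))
  list(precision = if (n_calls) mean(tp_call) else NA_real_,
       recall = if (n_truth) mean(tp_truth) else NA_real_,
       n_calls = n_calls, n_truth = n_truth)
}
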