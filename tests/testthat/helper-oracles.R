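# Independent oracles and fixture builders shared across the suite.

# ---- random hit sets ------------------------------------------------------

# random translated-search hits on one contig/strand; bit scores are drawn
# from a small discrete set so ties occur and exercise the tie-break chain
random_hits <- function(n, span = 600L, contig = "c1", strand = "+") {
  q_start <- sample(0:span, n, replace = TRUE)
  len <- sample(seq(30L, 300L, by = 3L), n, replace = TRUE)
  s_len <- pmax(10L, len %/% 3L)
  data.frame(
    query_id = contig, ref_id = sample(paste0("R", 1:6), n, replace = TRUE),
    pident = round(runif(n, 30, 100), 2), length = s_len,
    mismatch = 0L, gapopen = 0L,
    q_start = q_start, q_end = q_start + len, strand = strand,
    s_start = 0L, s_end = s_len,
    evalue = 10^-sample(7:30, n, replace = TRUE),
    bitscore = sample(seq(60, 300, by = 20), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# ---- footprint / resolver oracle (per-base logical mask) ------------------

# connected components of the overlap-or-touch graph by union-find
oracle_components <- function(hits) {
  n <- nrow(hits)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && hits$q_start[i] <= hits$q_end[j] &&
        hits$q_start[j] <= hits$q_end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# brute-force resolver: re-scans every hit each iteration against a per-base
# unassigned mask; independent of the package's interval arithmetic
oracle_resolve_component <- function(hits, min_residual = 30L) {
  fs <- min(hits$q_start); fe <- max(hits$q_end)
  mask <- rep(TRUE, fe - fs)      # index b means base fs + b - 1
  segs <- list()
  rank_of <- function(h) order(-h$bitscore, h$evalue,
                               -(h$q_end - h$q_start), h$ref_id)
  repeat {
    runs <- rle(mask)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    act <- which(runs$values & runs$lengths >= min_residual)
    if (length(act) == 0L) break
    active_pos <- unlist(lapply(act, function(k) starts[k]:ends[k]))
    cand <- which(vapply(seq_len(nrow(hits)), function(i) {
      pos <- (hits$q_start[i] - fs + 1L):(hits$q_end[i] - fs)
      any(pos %in% active_pos)
    }, logical(1)))
    if (length(cand) == 0L) break
    best <- cand[rank_of(hits[cand, , drop = FALSE])[1]]
    pos <- (hits$q_start[best] - fs + 1L):(hits$q_end[best] - fs)
    take <- pos[mask[pos]]
    if (length(take) > 0) {
      r <- rle(diff(take))
      brk <- c(0L, which(diff(take) > 1L), length(take))
      for (k in seq_len(length(brk) - 1L)) {
        piece <- take[(brk[k] + 1L):brk[k + 1L]]
        segs[[length(segs) + 1L]] <- data.frame(
          start0 = fs + piece[1] - 1L, end0 = fs + piece[length(piece)],
          ref_id = hits$ref_id[best], bitscore = hits$bitscore[best],
          stringsAsFactors = FALSE)
      }
      mask[take] <- FALSE
    }
  }
  if (length(segs) == 0L) return(NULL)
  out <- do.call(rbind, segs)
  out[order(out$start0), , drop = FALSE]
}

# full oracle: components then per-component mask resolution
oracle_calls <- function(hits, min_residual = 30L) {
  comp <- oracle_components(hits)
  pieces <- lapply(unique(comp), function(cc)
    oracle_resolve_component(hits[comp == cc, , drop = FALSE], min_residual))
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L) return(NULL)
  out <- do.call(rbind, pieces)
  out[order(out$start0), , drop = FALSE]
}

# package-side resolution without the coverage filter, for oracle comparison
package_calls <- function(hits, config = caller_config()) {
  built <- build_footprints(hits, config)
  pieces <- list()
  for (k in seq_len(nrow(built$footprints))) {
    fp <- built$footprints[k, ]
    fph <- built$hits[built$hits$footprint_id == fp$footprint_id, , drop = FALSE]
    res <- resolve_footprint(fp, fph, config)
    if (!is.null(res)) pieces[[length(pieces) + 1L]] <- res
  }
  if (length(pieces) == 0L) return(NULL)
  out <- do.call(rbind, pieces)
  out <- out[order(out$start0), c("start0", "end0", "ref_id", "bitscore")]
  rownames(out) <- NULL
  out
}

# ---- exhaustive rank-sum enumeration --------------------------------------

# two-sided p by enumerating every assignment of the pooled ranks
enum_wilcox_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  ranks <- seq_len(m + n)
  U_all <- apply(combs, 2, function(ix) sum(ranks[ix]) - m * (m + 1) / 2)
  p <- if (U_obs > m * n / 2) mean(U_all >= U_obs) else mean(U_all <= U_obs)
  min(2 * p, 1)
}

# ---- fixture profiles -----------------------------------------------------

# hand-built sample profile for arithmetic checks
make_profile <- function(sample_id = "s1", station = "GS1", depth_m = 0.3,
                         fraction = "medium", molecule = "DNA",
                         total = 1000, tnp = 0,
                         taxa = NULL, families = NULL,
                         marker_counts = NULL, n_markers = 35L) {
  lineage <- data.frame(taxon = "T1", phylum = "P1", class = "C1",
                        order = "O1", genus = "G1", stringsAsFactors = FALSE)
  if (is.null(taxa))
    taxa <- data.frame(taxon = "T1", reads = total, tnp_reads = tnp,
                       phylum = "P1", class = "C1", order = "O1",
                       genus = "G1", stringsAsFactors = FALSE)
  if (is.null(families))
    families <- data.frame(family = character(0), tnp_reads = numeric(0),
                           stringsAsFactors = FALSE)
  labels <- sprintf("M%02d", seq_len(n_markers))
  mk <- if (is.null(marker_counts))
    data.frame(marker = character(0), taxon = character(0),
               count = numeric(0), stringsAsFactors = FALSE)
  else data.frame(marker = labels, taxon = "T1", count = marker_counts,
                  stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, station = station, depth_m = depth_m,
                 fraction = fraction, molecule = molecule,
                 total_bacterial_reads = total, transposase_reads = tnp,
                 taxa = taxa, families = families, marker_hits = mk,
                 marker_labels = labels, lineage = lineage),
            class = "sample_profile")
}

# small community configuration used by several tests (fast to simulate)
small_sim_config <- function(seed = 1L, reads_per_sample = 10000L, ...) {
  sim_config(seed = seed, stations = "GS675", fractions = "medium",
             molecules = "DNA",
             taxa = data.frame(
               taxon = c("Synechococcus", "Pelagibacter"),
               phylum = c("Cyanobacteria", "Proteobacteria"),
               class = c("Cyanophyceae", "Alphaproteobacteria"),
               order = c("Chroococcales", "Pelagibacterales"),
               genus = c("Synechococcus", "Pelagibacter"),
               weight = c(0.5, 0.5), stringsAsFactors = FALSE),
             n_contigs_per_taxon = 3L, contig_length_range = c(1800L, 2400L),
             n_ref_families = 2L, refs_per_family = 1L,
             ref_aa_length_range = c(150L, 250L),
             n_single_copy_markers = 0L,
             reads_per_sample = reads_per_sample, ...)
}
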