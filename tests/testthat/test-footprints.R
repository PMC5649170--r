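# Footprint designation, greedy resolution and the call filters.

mk_hit <- function(qs, qe, bit = 100, ev = 1e-10, ref = "R1", contig = "c1",
                   strand = "+", ss = 0L, se = (qe - qs) %/% 3L) {
  data.frame(query_id = contig, ref_id = ref, pident = 90, length = se - ss,
             mismatch = 0L, gapopen = 0L, q_start = qs, q_end = qe,
             strand = strand, s_start = ss, s_end = se, evalue = ev,
             bitscore = bit, stringsAsFactors = FALSE)
}

test_that("overlapping hits merge into one footprint, disjoint hits do not", {
  one <- build_footprints(rbind(mk_hit(0, 300), mk_hit(200, 500, ref = "R2")))
  expect_equal(nrow(one$footprints), 1L)
  expect_equal(one$footprints$start0, 0)
  expect_equal(one$footprints$end0, 500)
  two <- build_footprints(rbind(mk_hit(0, 300), mk_hit(400, 700, ref = "R2")))
  expect_equal(nrow(two$footprints), 2L)
  # opposite strands are separate footprints by default
  ab <- build_footprints(rbind(mk_hit(0, 300), mk_hit(100, 400, strand = "-")))
  expect_equal(nrow(ab$footprints), 2L)
  merged <- build_footprints(rbind(mk_hit(0, 300), mk_hit(100, 400, strand = "-")),
                             caller_config(merge_across_strands = TRUE))
  expect_equal(nrow(merged$footprints), 1L)
})

test_that("a single spanning hit resolves to one call equal to the footprint", {
  h <- mk_hit(50, 650)
  built <- build_footprints(h)
  res <- resolve_footprint(built$footprints[1, ], built$hits)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start0, 50)
  expect_equal(res$end0, 650)
  expect_equal(res$ref_id, "R1")
})

test_that("the greedy loop assigns the best hit first, then the residual", {
  # A: bitscore 200 over the left 60%; B: bitscore 150 over the right 60%
  h <- rbind(mk_hit(0, 600, bit = 200, ref = "A"),
             mk_hit(400, 1000, bit = 150, ref = "B"))
  built <- build_footprints(h)
  res <- resolve_footprint(built$footprints[1, ], built$hits)
  expect_equal(res$ref_id, c("A", "B"))
  expect_equal(res$start0, c(0, 600))
  expect_equal(res$end0, c(600, 1000))
})

test_that("greedy resolution matches the brute-force mask oracle", {
  set.seed(2024)
  for (trial in 1:300) {
    h <- random_hits(sample(1:12, 1))
    got <- package_calls(h)
    want <- oracle_calls(h)
    expect_equal(got$start0, want$start0)
    expect_equal(got$end0, want$end0)
    expect_equal(got$ref_id, want$ref_id)
  }
})

test_that("footprint components match a union-find oracle", {
  set.seed(99)
  for (trial in 1:200) {
    h <- random_hits(sample(1:20, 1))
    built <- build_footprints(h)
    comp <- oracle_components(h)
    # same partition of hits into components
    got <- built$hits$footprint_id
    expect_equal(length(unique(got)), length(unique(comp)))
    expect_true(all(tapply(comp, got, function(v) length(unique(v))) == 1))
  }
})

test_that("ORF coverage is thresholded at exactly 30 percent", {
  refs <- data.frame(ref_id = "R1", family = "IS3",
                     aa_seq = paste(rep("A", 300), collapse = ""),
                     aa_len = 300L, stringsAsFactors = FALSE)
  seg <- function(s_aa) {
    r <- mk_hit(0, 3 * s_aa, se = s_aa)
    r$hit_q_start <- r$q_start; r$hit_q_end <- r$q_end
    r$hit_s_start <- r$s_start; r$hit_s_end <- r$s_end
    names(r)[names(r) == "q_start"] <- "start0"
    names(r)[names(r) == "q_end"] <- "end0"
    r
  }
  kept <- filter_calls(seg(90), refs)          # 90/300 = 0.30 exactly
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$aa_coverage_fraction, 0.30)
  gone <- filter_calls(seg(89), refs)          # 89/300 just below
  expect_equal(nrow(gone), 0L)
  full <- filter_calls(seg(300), refs)
  expect_equal(full$aa_coverage_fraction, 1.0)
  expect_error(filter_calls(transform(seg(90), ref_id = "nope"), refs), "nope")
})

test_that("an E-value exactly at the cutoff is rejected (strict <)", {
  refs <- data.frame(ref_id = "R1", family = "IS3",
                     aa_seq = paste(rep("A", 100), collapse = ""),
                     aa_len = 100L, stringsAsFactors = FALSE)
  at <- mk_hit(0, 300, ev = 1e-6)
  below <- mk_hit(0, 300, ev = 0.99e-6)
  expect_equal(nrow(call_transposases(at, refs)), 0L)
  expect_equal(nrow(call_transposases(below, refs)), 1L)
})

test_that("call_transposases is deterministic, annotated and monotone", {
  set.seed(55)
  h <- do.call(rbind, lapply(1:6, function(i) random_hits(5, contig = paste0("c", i))))
  refs <- data.frame(ref_id = paste0("R", 1:6), family = "IS3",
                     aa_seq = paste(rep("A", 100), collapse = ""),
                     aa_len = 100L, stringsAsFactors = FALSE)
  tax <- data.frame(contig_id = paste0("c", 1:5), domain = "Bacteria",
                    phylum = "P", class = "C", order = "O", genus = "G",
                    stringsAsFactors = FALSE)   # c6 missing on purpose
  expect_warning(a <- call_transposases(h, refs, tax), "unclassified")
  expect_warning(b <- call_transposases(h, refs, tax), "unclassified")
  expect_identical(a, b)
  expect_true(all(a$phylum[a$contig_id == "c6"] == "unclassified"))
  expect_false(is.unsorted(a$contig_id))
  # monotonicity: stricter thresholds never yield more calls
  for (cov in c(0.1, 0.3, 0.6, 0.9)) {
    n_loose <- nrow(suppressWarnings(call_transposases(
      h, refs, tax, caller_config(min_orf_coverage = cov))))
    n_tight <- nrow(suppressWarnings(call_transposases(
      h, refs, tax, caller_config(min_orf_coverage = min(cov + 0.2, 1)))))
    expect_lte(n_tight, n_loose)
  }
  n_hi_e <- nrow(suppressWarnings(call_transposases(
    h, refs, tax, caller_config(max_evalue = 1e-6))))
  n_lo_e <- nrow(suppressWarnings(call_transposases(
    h, refs, tax, caller_config(max_evalue = 1e-12))))
  expect_lte(n_lo_e, n_hi_e)
  # empty input
  expect_equal(nrow(call_transposases(h[0, ], refs, tax)), 0L)
})

test_that("exact planted copies are recovered with full recall", {
  cfg <- small_sim_config(seed = 31)
  refs <- generate_reference_db(cfg)
  comm <- generate_community(cfg, refs)
  hits <- builtin_search(comm$contigs, refs)
  calls <- call_transposases(hits, refs, comm$taxonomy)
  ev <- evaluate_calls(calls, comm$truth$planted)
  expect_equal(ev$recall, 1.0)
  expect_gte(ev$precision, 0.95)
  # resolved segments never overlap within one (contig, strand)
  for (key in unique(paste(calls$contig_id, calls$strand))) {
    cc <- calls[paste(calls$contig_id, calls$strand) == key, ]
    cc <- cc[order(cc$start0), ]
    if (nrow(cc) > 1) expect_true(all(cc$start0[-1] >= cc$end0[-nrow(cc)]))
  }
})
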