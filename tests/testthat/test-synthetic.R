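# Synthetic community generator: determinism, conservation, planted truth.

test_that("reference database has the requested shape and real family labels", {
  cfg <- sim_config(seed = 3, n_ref_families = 2, refs_per_family = 3)
  refs <- generate_reference_db(cfg)
  expect_equal(nrow(refs), 6L)
  expect_equal(length(unique(refs$family)), 2L)
  expect_true(all(refs$aa_len >= cfg$ref_aa_length_range[1] &
                  refs$aa_len <= cfg$ref_aa_length_range[2]))
  expect_equal(nchar(refs$aa_seq), refs$aa_len)

  cfg30 <- sim_config(seed = 3, n_ref_families = 30)
  refs30 <- generate_reference_db(cfg30)
  fams <- unique(refs30$family)
  expect_equal(length(fams), 30L)
  # all labels are real IS family names, including the prominent ones
  expect_true(all(c("IS3", "IS5", "IS200/IS605", "IS256", "IS66") %in% fams))
  expect_true(all(grepl("^(IS|Tn)", fams)))
})

test_that("identical configuration yields byte-identical outputs", {
  cfg <- small_sim_config(seed = 11)
  r1 <- generate_reference_db(cfg); r2 <- generate_reference_db(cfg)
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  t1 <- tempfile(); t2 <- tempfile()
  write_reference_db(r1, f1, t1); write_reference_db(r2, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  c1 <- generate_community(cfg, r1); c2 <- generate_community(cfg, r2)
  expect_identical(as.character(c1$contigs), as.character(c2$contigs))
  expect_identical(c1$read_map, c2$read_map)
  expect_identical(c1$truth, c2$truth)
})

test_that("read counts are conserved and ground truth is self-consistent", {
  cfg <- sim_config(seed = 5, stations = c("GS675", "GS694"),
                    n_contigs_per_taxon = 4L, marker_length_nt = 150L,
                    reads_per_sample = 4000L)
  refs <- generate_reference_db(cfg)
  comm <- generate_community(cfg, refs)
  # per-sample totals match the configured depth
  tot <- tapply(comm$read_map$read_count, comm$read_map$sample_id, sum)
  expect_true(all(tot == cfg$reads_per_sample))
  # per-taxon truth sums to the per-sample totals
  by_tax <- aggregate(reads ~ sample_id, comm$truth$sample_taxa, sum)
  expect_true(all(by_tax$reads == cfg$reads_per_sample))
  # recomputing transposase reads from map + planted intervals reproduces
  # the truth exactly (every sample)
  rm2 <- count_transposase_reads(comm$read_map, comm$truth$planted)
  recount <- tapply(rm2$read_count[rm2$is_tnp], rm2$sample_id[rm2$is_tnp], sum)
  tr <- comm$truth$samples
  for (i in seq_len(nrow(tr))) {
    got <- recount[tr$sample_id[i]]
    expect_equal(unname(ifelse(is.na(got), 0, got)), tr$tnp_reads[i])
  }
  # planted intervals lie within their contigs
  len <- setNames(Biostrings::width(comm$contigs), names(comm$contigs))
  pl <- comm$truth$planted
  expect_true(all(pl$start0 >= 0 & pl$end0 <= len[pl$contig_id]))
  # exactly one marker interval per label per taxon genome
  mk <- comm$truth$markers
  expect_equal(nrow(unique(mk[, c("marker", "taxon")])), nrow(mk))
  expect_equal(nrow(mk), cfg$n_single_copy_markers * nrow(cfg$taxa))
})

test_that("a zero planted fraction yields zero transposase reads", {
  cfg <- small_sim_config(seed = 2, planted_tnp_read_fraction = 0)
  refs <- generate_reference_db(cfg)
  comm <- generate_community(cfg, refs)
  expect_true(all(comm$truth$samples$tnp_reads == 0))
})

test_that("realized transposase fraction tracks the planted fraction", {
  # mean over seeds within 3 binomial SE of the target
  f <- 0.01; n <- 10000L; n_seeds <- 30L
  got <- vapply(seq_len(n_seeds), function(s) {
    cfg <- small_sim_config(seed = 100 + s, planted_tnp_read_fraction = f)
    refs <- generate_reference_db(cfg)
    comm <- generate_community(cfg, refs)
    comm$truth$samples$tnp_reads / comm$truth$samples$bacterial_reads
  }, numeric(1))
  se_mean <- sqrt(f * (1 - f) / n) / sqrt(n_seeds)
  expect_lt(abs(mean(got) - f), 3 * se_mean)
})

test_that("per-taxon planting restrictions are honoured", {
  # Synechococcus planted only in the larger fractions: small-fraction truth
  # carries (essentially) no Synechococcus transposase reads
  cfg <- sim_config(seed = 9, stations = "GS675", molecules = "DNA",
                    n_contigs_per_taxon = 3L, marker_length_nt = 150L,
                    tnp_fraction_by_taxon = list(
                      Synechococcus = c(small = 0, medium = 1, large = 1)),
                    reads_per_sample = 5000L)
  refs <- generate_reference_db(cfg)
  comm <- generate_community(cfg, refs)
  st <- comm$truth$sample_taxa
  small_syn <- st[st$taxon == "Synechococcus" &
                  grepl("_small_", st$sample_id), ]
  expect_true(all(small_syn$tnp_reads <= 2))
  med_syn <- st[st$taxon == "Synechococcus" &
                grepl("_medium_", st$sample_id), ]
  expect_true(all(med_syn$tnp_reads > 0))
})

test_that("a contig too short for its planted ORF is a named error", {
  cfg <- small_sim_config(seed = 1)
  cfg$contig_length_range <- c(200L, 250L)   # ORFs are 450-750 nt
  refs <- generate_reference_db(cfg)
  expect_error(generate_community(cfg, refs), "too short to host")
  expect_error(generate_community(cfg, refs), "_c0")  # names the contig
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(taxa = within(default_taxa(), weight <- weight * 2)),
               "weights")
  expect_error(sim_config(contig_length_range = c(500L, 100L)), "range")
  expect_error(sim_config(planted_tnp_read_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_ref_families = 0), "family")
})
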