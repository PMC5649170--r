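# Normalized abundance statistics: read assignment, fractions, per-genome
# counts, expression ratios and the strain-table arithmetic.

test_that("reads are assigned by the half-overlap rule", {
  calls <- data.frame(contig_id = "c1", strand = "+", start0 = 1000,
                      end0 = 2000, ref_id = "R1", family = "IS3",
                      stringsAsFactors = FALSE)
  rm <- data.frame(contig_id = "c1",
                   start0 = c(1200, 980, 1960, 100),
                   end0 = c(1300, 1080, 2060, 200),
                   sample_id = "s1", read_count = 1L,
                   stringsAsFactors = FALSE)
  got <- count_transposase_reads(rm, calls)
  # fully inside; exactly half in (100/100 >= 0.5); 40% in; far away
  expect_equal(got$is_tnp, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(got$family[1], "IS3")
  ten_pct <- data.frame(contig_id = "c1", start0 = 910, end0 = 1010,
                        sample_id = "s1", read_count = 1L,
                        stringsAsFactors = FALSE)
  expect_false(count_transposase_reads(ten_pct, calls)$is_tnp)
  # off-contig reads are an error when lengths are supplied
  expect_error(count_transposase_reads(
    data.frame(contig_id = "c1", start0 = 2950, end0 = 3050,
               sample_id = "s1", read_count = 1L),
    calls, contig_lengths = c(c1 = 3000)), "off contig")
})

test_that("family attribution uses majority overlap", {
  calls <- data.frame(contig_id = "c1", strand = "+",
                      start0 = c(0, 160), end0 = c(160, 400),
                      ref_id = c("A", "B"), family = c("IS5", "IS3"),
                      stringsAsFactors = FALSE)
  rm <- data.frame(contig_id = "c1", start0 = 100, end0 = 200,
                   sample_id = "s1", read_count = 1L, stringsAsFactors = FALSE)
  got <- count_transposase_reads(rm, calls)
  expect_true(got$is_tnp)
  expect_equal(got$family, "IS5")   # 60 nt in IS5 vs 40 nt in IS3
})

test_that("fraction of bacterial reads is the plain quotient", {
  expect_equal(fraction_of_bacterial_reads(make_profile(total = 1000, tnp = 7)),
               0.007)
  expect_equal(fraction_of_bacterial_reads(make_profile(total = 1000, tnp = 0)),
               0)
  expect_error(fraction_of_bacterial_reads(make_profile(total = 0)),
               "undefined")
})

test_that("per-taxon fractions are scoped quotients that conserve totals", {
  taxa <- data.frame(taxon = c("T1", "T2"), reads = c(1000, 500),
                     tnp_reads = c(50, 0),
                     phylum = c("P1", "P2"), class = "C", order = "O",
                     genus = c("G1", "G2"), stringsAsFactors = FALSE)
  p <- make_profile(total = 1500, tnp = 50, taxa = taxa)
  expect_equal(per_taxon_fraction(p, "P1"), 0.05)
  expect_equal(per_taxon_fraction(p, "P2"), 0)
  expect_error(per_taxon_fraction(p, "P3"), "undefined")
  # conservation: sum over taxa of fraction x reads equals transposase_reads
  tot <- sum(vapply(c("P1", "P2"), function(ph)
    per_taxon_fraction(p, ph) * sum(taxa$reads[taxa$phylum == ph]),
    numeric(1)))
  expect_equal(tot, p$transposase_reads)
})

test_that("per-genome counts follow the 35-marker mean", {
  p <- make_profile(total = 5000, tnp = 54,
                    marker_counts = rep(2, 35))
  expect_equal(per_genome_count(p, "all"), 27)
  p2 <- make_profile(total = 5000, tnp = 58, marker_counts = rep(1, 35))
  expect_equal(per_genome_count(p2, "all"), 58)
  # zero-hit markers stay in the denominator
  p3 <- make_profile(total = 5000, tnp = 35,
                     marker_counts = c(rep(2, 17), rep(0, 18)))
  expect_equal(per_genome_count(p3, "all"), 35 / (34 / 35))
  p4 <- make_profile(total = 5000, tnp = 10, marker_counts = rep(0, 35))
  expect_error(per_genome_count(p4, "all"), "zero hits")
  # invariance to uniform depth rescaling
  p5 <- make_profile(total = 10000, tnp = 108, marker_counts = rep(4, 35))
  expect_equal(per_genome_count(p5, "all"), per_genome_count(p, "all"))
})

test_that("genome size proxy is symmetric and scale invariant", {
  a <- make_profile(total = 6000, marker_counts = rep(3, 35))
  b <- make_profile(total = 6000, marker_counts = rep(3, 35))
  expect_equal(genome_size_proxy(a, "all"), genome_size_proxy(b, "all"))
  dbl <- make_profile(total = 12000, marker_counts = rep(6, 35))
  expect_equal(genome_size_proxy(dbl, "all"), genome_size_proxy(a, "all"))
})

test_that("expression ratios divide RNA by DNA scope fractions", {
  dna <- make_profile(sample_id = "d", molecule = "DNA", total = 1000, tnp = 10)
  rna <- make_profile(sample_id = "r", molecule = "RNA", total = 1000, tnp = 10)
  expect_equal(expression_ratio(list(dna), list(rna), "all")$ratio, 1)
  rna2 <- make_profile(sample_id = "r", molecule = "RNA", total = 1000, tnp = 20)
  expect_equal(expression_ratio(list(dna), list(rna2), "all")$ratio, 2)
  # 0.0046 / 0.0023 = 2.0
  dna3 <- make_profile(molecule = "DNA", total = 10000, tnp = 23)
  rna3 <- make_profile(molecule = "RNA", total = 10000, tnp = 46)
  expect_equal(expression_ratio(list(dna3), list(rna3), "all")$ratio, 2)
  # zero DNA-side fraction: pair excluded with a warning
  dna0 <- make_profile(molecule = "DNA", total = 1000, tnp = 0)
  expect_warning(expect_error(
    expression_ratio(list(dna0), list(rna), "all"), "no usable"),
    "excluded")
})

test_that("transposases per Mbp reproduces strain-table arithmetic", {
  expect_equal(transposases_per_mbp(15, 2.7), 5.6)
  expect_equal(transposases_per_mbp(22, 2.6), 8.5)
  expect_equal(transposases_per_mbp(0, 2.3), 0)
  expect_error(transposases_per_mbp(10, 0), "positive")
})

test_that("profiles built from a simulated community match its ground truth", {
  cfg <- small_sim_config(seed = 77, planted_tnp_read_fraction = 0.01)
  refs <- generate_reference_db(cfg)
  comm <- generate_community(cfg, refs)
  profs <- build_sample_profiles(comm$read_map, comm$truth$planted,
                                 comm$taxonomy, comm$samples)
  p <- profs[[1]]
  tr <- comm$truth$samples
  expect_equal(p$transposase_reads, tr$tnp_reads[1])
  expect_equal(p$total_bacterial_reads, tr$bacterial_reads[1])
  # per-taxon counts match the truth table
  st <- comm$truth$sample_taxa
  for (tx in p$taxa$taxon) {
    expect_equal(p$taxa$reads[p$taxa$taxon == tx],
                 st$reads[st$taxon == tx])
    expect_equal(p$taxa$tnp_reads[p$taxa$taxon == tx],
                 st$tnp_reads[st$taxon == tx])
  }
  # per-family counts sum to the total transposase count
  expect_equal(sum(p$families$tnp_reads), p$transposase_reads)
  ab <- abundance_table(profs)
  expect_true(all(ab$value[ab$metric == "fraction_of_bacterial_reads"] >= 0))
  expect_true(all(ab$value[grepl("fraction", ab$metric)] <= 1))
})
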