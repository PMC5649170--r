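# Simulation configuration for the synthetic size-fractionated community.

# IS family names as curated in the ISfinder nomenclature; the pool is larger
# than 30 so a 30-family reference database uses real labels throughout.
.IS_FAMILY_POOL <- c(
  "IS1", "IS3", "IS4", "IS5", "IS6", "IS21", "IS30", "IS66", "IS91",
  "IS110", "IS200/IS605", "IS256", "IS481", "IS607", "IS630", "IS701",
  "IS982", "IS1182", "IS1380", "IS1595", "IS1634", "ISAs1", "ISAzo13",
  "ISH3", "ISKra4", "ISL3", "ISLre2", "ISNCY", "IS1202", "IS1249",
  "IS1341", "Tn3")

#' Default taxa of the simulated brackish community
#'
#' Four taxa with full phylum-to-genus lineages spanning the groups that
#' dominate Baltic-Sea-like communities: a picocyanobacterium
#' (*Synechococcus*), two Alphaproteobacteria (free-living SAR11-like and a
#' particle-associated Rhodobacterales) and an actinobacterium. Weights are
#' relative community abundances and sum to one.
#'
#' @return A data.frame with columns `taxon`, `phylum`, `class`, `order`,
#'   `genus`, `weight`.
#' @export
default_taxa <- function() {
  data.frame(
    taxon  = c("Synechococcus", "Pelagibacter", "Rhodobacter", "Ilumatobacter"),
    phylum = c("Cyanobacteria", "Proteobacteria", "Proteobacteria", "Actinobacteria"),
    class  = c("Cyanophyceae", "Alphaproteobacteria", "Alphaproteobacteria", "Acidimicrobiia"),
    order  = c("Chroococcales", "Pelagibacterales", "Rhodobacterales", "Acidimicrobiales"),
    genus  = c("Synechococcus", "Pelagibacter", "Rhodobacter", "Ilumatobacter"),
    weight = c(0.20, 0.35, 0.25, 0.20),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic community generator
#'
#' Defines the sampling design (stations x size fractions x molecules), the
#' taxon-structured contig pool, the planted transposase ORFs and single-copy
#' marker intervals, and the per-sample read allocation. Defaults emulate a
#' brackish-to-marine transect: four Baltic-like stations and two marine
#' ("Skagerrak-like") stations, three size fractions (small 0.1–0.8,
#' medium 0.8–3.0, large 3.0–200 um), DNA and RNA samples, and planted
#' transposase read fractions of 0.2% (small), 0.7% (medium) and 1.0% (large)
#' at brackish stations versus 0.2% everywhere at marine stations.
#' RNA samples multiply read intensity over a planted ORF by
#' `expression_multiplier[family, taxon]` (default: 2.3 for all families in
#' Cyanobacteria, 1 elsewhere).
#'
#' @param seed Integer seed; the generator is byte-deterministic given the
#'   full configuration.
#' @param stations Character vector of station labels.
#' @param station_region Named character vector mapping station to
#'   `"baltic"` or `"marine"`; defaults put any station named `GS69x` in the
#'   marine group.
#' @param fractions Size-fraction labels, subset of small/medium/large.
#' @param molecules Subset of `c("DNA","RNA")`.
#' @param depth_m Sampling depth in metres recorded in the sample sheet.
#' @param taxa Data.frame as returned by [default_taxa()]; weights must sum
#'   to 1 (tolerance 1e-9).
#' @param n_contigs_per_taxon Contigs making up each simulated genome.
#' @param contig_length_range Nucleotide length interval for contigs.
#' @param n_ref_families,refs_per_family Size of the reference protein set.
#' @param ref_aa_length_range Amino-acid length interval for references.
#' @param planted_orfs_per_contig Transposase ORFs planted per contig.
#' @param planted_tnp_read_fraction Either a single fraction, a named vector
#'   keyed by size fraction (per region via a list
#'   `list(baltic=..., marine=...)`), or a named vector keyed by sample_id.
#'   All values in [0, 1]. The string `"uniform"` instead allocates
#'   transposase reads proportionally to planted length (uniform genome
#'   depth), as when estimating transposase copies per genome.
#' @param tnp_fraction_by_taxon Optional named list `taxon -> multiplier`
#'   applied to that taxon's planted read fraction (e.g. `list(Synechococcus =
#'   c(small = 0))` zeroes small-fraction planting for one genus); values are
#'   either a scalar or a vector named by size fraction.
#' @param expression_multiplier RNA:DNA intensity multiplier for planted
#'   ORFs; a single number, or a named list `taxon -> multiplier`, applied to
#'   all families of that taxon, or `(family|taxon)` matrix-like named list.
#' @param reads_per_sample Total bacterial reads per sample.
#' @param read_length_nt Length of simulated read intervals.
#' @param n_single_copy_markers Number of single-copy marker labels (default
#'   35, one labelled interval per marker per taxon genome).
#' @param marker_length_nt Length of each marker interval.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       stations = c("GS669", "GS675", "GS679", "GS683", "GS694", "GS695"),
                       station_region = NULL,
                       fractions = c("small", "medium", "large"),
                       molecules = c("DNA", "RNA"),
                       depth_m = 0.3,
                       taxa = default_taxa(),
                       n_contigs_per_taxon = 12L,
                       contig_length_range = c(2500L, 4000L),
                       n_ref_families = 5L,
                       refs_per_family = 2L,
                       ref_aa_length_range = c(200L, 350L),
                       planted_orfs_per_contig = 1L,
                       planted_tnp_read_fraction = list(
                         baltic = c(small = 0.002, medium = 0.007, large = 0.010),
                         marine = c(small = 0.002, medium = 0.002, large = 0.002)),
                       tnp_fraction_by_taxon = NULL,
                       expression_multiplier = list(Synechococcus = 2.3),
                       reads_per_sample = 10000L,
                       read_length_nt = 100L,
                       n_single_copy_markers = 35L,
                       marker_length_nt = 300L) {
  if (is.null(station_region)) {
    station_region <- setNames(
      ifelse(grepl("^GS69", stations), "marine", "baltic"), stations)
  }
  cfg <- list(
    seed = as.integer(seed), stations = stations,
    station_region = station_region, fractions = fractions,
    molecules = molecules, depth_m = depth_m, taxa = taxa,
    n_contigs_per_taxon = as.integer(n_contigs_per_taxon),
    contig_length_range = as.integer(contig_length_range),
    n_ref_families = as.integer(n_ref_families),
    refs_per_family = as.integer(refs_per_family),
    ref_aa_length_range = as.integer(ref_aa_length_range),
    planted_orfs_per_contig = as.integer(planted_orfs_per_contig),
    planted_tnp_read_fraction = planted_tnp_read_fraction,
    tnp_fraction_by_taxon = tnp_fraction_by_taxon,
    expression_multiplier = expression_multiplier,
    reads_per_sample = as.integer(reads_per_sample),
    read_length_nt = as.integer(read_length_nt),
    n_single_copy_markers = as.integer(n_single_copy_markers),
    marker_length_nt = as.integer(marker_length_nt))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  w <- cfg$taxa$weight
  if (abs(sum(w) - 1) > 1e-9)
    stopf("configuration error: taxon weights sum to %.12f, not 1", sum(w))
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2] && r[1] > 0
  if (!rng_ok(cfg$contig_length_range))
    stopf("configuration error: invalid contig_length_range")
  if (!rng_ok(cfg$ref_aa_length_range))
    stopf("configuration error: invalid ref_aa_length_range")
  if (cfg$n_ref_families < 1L || cfg$refs_per_family < 1L)
    stopf("configuration error: need >= 1 family and >= 1 reference per family")
  if (cfg$n_ref_families > length(.IS_FAMILY_POOL))
    stopf("configuration error: at most %d IS families available",
          length(.IS_FAMILY_POOL))
  if (!identical(cfg$planted_tnp_read_fraction, "uniform")) {
    fr <- unlist(cfg$planted_tnp_read_fraction)
    if (!is.numeric(fr) || any(fr < 0 | fr > 1))
      stopf("configuration error: planted transposase read fractions must be in [0, 1] (or \"uniform\")")
  }
  if (!all(cfg$fractions %in% c("small", "medium", "large")))
    stopf("configuration error: fractions must be among small/medium/large")
  if (!all(cfg$molecules %in% c("DNA", "RNA")))
    stopf("configuration error: molecules must be among DNA/RNA")
  invisible(cfg)
}

#' Sample sheet implied by a simulation configuration
#'
#' @param cfg A [sim_config()].
#' @return Data.frame with columns sample_id, station, depth_m, fraction,
#'   molecule.
#' @export
sample_sheet <- function(cfg) {
  grid <- expand.grid(molecule = cfg$molecules, fraction = cfg$fractions,
                      station = cfg$stations, stringsAsFactors = FALSE)
  data.frame(
    sample_id = paste(grid$station, grid$fraction, grid$molecule, sep = "_"),
    station = grid$station, depth_m = cfg$depth_m,
    fraction = grid$fraction, molecule = grid$molecule,
    stringsAsFactors = FALSE)
}

# resolve the planted transposase read fraction for one (sample, taxon)
#' @noRd
planted_fraction_for <- function(cfg, station, fraction, sample_id, taxon) {
  spec <- cfg$planted_tnp_read_fraction
  f <- if (is.numeric(spec) && length(spec) == 1L && is.null(names(spec))) {
    spec
  } else if (is.numeric(spec) && !is.null(names(spec)) && sample_id %in% names(spec)) {
    spec[[sample_id]]
  } else if (is.numeric(spec) && !is.null(names(spec)) && fraction %in% names(spec)) {
    spec[[fraction]]
  } else if (is.list(spec)) {
    region <- cfg$station_region[[station]]
    v <- spec[[region]]
    if (is.null(v)) stopf("no planted fraction for region '%s'", region)
    if (length(v) == 1L && is.null(names(v))) v else v[[fraction]]
  } else {
    stopf("cannot resolve planted fraction for sample '%s'", sample_id)
  }
  if (!is.null(cfg$tnp_fraction_by_taxon) && taxon %in% names(cfg$tnp_fraction_by_taxon)) {
    m <- cfg$tnp_fraction_by_taxon[[taxon]]
    m <- if (length(m) == 1L && is.null(names(m))) m else
      if (fraction %in% names(m)) m[[fraction]] else 1
    f <- f * m
  }
  f
}

# RNA expression multiplier for a (family, taxon) planted ORF
#' @noRd
expression_multiplier_for <- function(cfg, family, taxon) {
  em <- cfg$expression_multiplier
  if (is.null(em)) return(1)
  if (is.numeric(em) && length(em) == 1L) return(em)
  v <- em[[taxon]]
  if (is.null(v)) return(1)
  if (length(v) == 1L && is.null(names(v))) return(v)
  if (family %in% names(v)) return(v[[family]])
  1
}
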