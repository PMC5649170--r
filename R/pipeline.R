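# End-to-end reproducible run: simulate -> search -> call -> quantify ->
# stats -> report, with a JSON manifest and digest-based stage caching.

#' Default pipeline configuration
#'
#' A YAML-serializable list: the simulation configuration (see
#' [sim_config()]), caller thresholds, and the standard contrasts (small vs
#' medium+large size fraction; brackish vs marine stations; DNA metagenome
#' metric).
#'
#' @param seed Seed forwarded to [sim_config()].
#' @param ... Overrides forwarded to [sim_config()].
#' @return A list with elements `sim`, `caller`, `contrasts`.
#' @export
default_pipeline_config <- function(seed = 1L, ...) {
  cfg <- sim_config(seed = seed, ...)
  marine <- names(cfg$station_region)[cfg$station_region == "marine"]
  baltic <- names(cfg$station_region)[cfg$station_region == "baltic"]
  list(
    sim = cfg,
    caller = caller_config(),
    contrasts = list(
      list(name = "small_vs_larger_DNA",
           metric = "fraction_of_bacterial_reads",
           scope_label = "all",
           group_a = list(fraction = "small", molecule = "DNA"),
           group_b = list(fraction = c("medium", "large"), molecule = "DNA")),
      list(name = "baltic_vs_marine_DNA",
           metric = "fraction_of_bacterial_reads",
           scope_label = "all",
           group_a = list(station = baltic, molecule = "DNA"),
           group_b = list(station = marine, molecule = "DNA")),
      list(name = "baltic_vs_marine_RNA",
           metric = "fraction_of_bacterial_reads",
           scope_label = "all",
           group_a = list(station = baltic, molecule = "RNA"),
           group_b = list(station = marine, molecule = "RNA"))))
}

#' Run the full pipeline
#'
#' Executes simulate, search, call, quantify, stats and report in order
#' under `out_dir`, writing every stage result as TSV and a JSON run
#' manifest with MD5 digests of all stage files. A stage whose output files
#' already exist with digests recorded in a previous manifest of the same
#' configuration is skipped ("cached").
#'
#' @param config A list from [default_pipeline_config()], or a path to a
#'   YAML file with the same structure.
#' @param out_dir Output directory.
#' @param force Rerun all stages even if cached.
#' @return The run manifest (list), invisibly; stage outputs on disk.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         force = FALSE) {
  if (is.character(config)) config <- load_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config$sim
  ccfg <- config$caller %||% caller_config()
  cfg_digest <- digest_object(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  old <- if (file.exists(manifest_path))
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  else NULL
  cache_ok <- !force && !is.null(old) &&
    identical(old$config_digest, cfg_digest)
  manifest <- list(config_digest = cfg_digest, seed = cfg$seed,
                   tool = "tnpquant",
                   version = as.character(packageVersion("tnpquant")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  logmsg <- function(stage, what) message(sprintf("[%s] %s", stage, what))

  cached <- function(stage, paths) {
    if (!cache_ok || is.null(old$stages[[stage]])) return(FALSE)
    rec <- old$stages[[stage]]$files
    recorded <- setNames(vapply(rec, function(f) f$md5, ""),
                         vapply(rec, function(f) f$path, ""))
    if (!all(basename(paths) %in% names(recorded)) ||
        !all(file.exists(paths))) return(FALSE)
    all(unname(tools::md5sum(paths)) == unname(recorded[basename(paths)]))
  }
  record <- function(stage, paths, was_cached) {
    manifest$stages[[stage]] <<- list(
      cached = was_cached,
      files = lapply(paths, function(p)
        list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  }

  ## simulate -------------------------------------------------------------
  sim_paths <- file.path(out_dir, c("refs.faa", "ref_families.tsv",
                                    "contigs.fna", "taxonomy.tsv",
                                    "samples.tsv", "read_map.tsv",
                                    "truth_planted.tsv", "truth_markers.tsv",
                                    "truth_samples.tsv"))
  if (cached("simulate", sim_paths)) {
    logmsg("simulate", "cached")
    record("simulate", sim_paths, TRUE)
  } else {
    logmsg("simulate", "generating reference database and community")
    refs <- generate_reference_db(cfg)
    write_reference_db(refs, sim_paths[1], sim_paths[2])
    comm <- generate_community(cfg, refs)
    Biostrings::writeXStringSet(comm$contigs, sim_paths[3])
    tsv <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                       row.names = FALSE)
    tsv(comm$taxonomy, sim_paths[4]); tsv(comm$samples, sim_paths[5])
    tsv(comm$read_map, sim_paths[6]); tsv(comm$truth$planted, sim_paths[7])
    tsv(comm$truth$markers, sim_paths[8]); tsv(comm$truth$samples, sim_paths[9])
    record("simulate", sim_paths, FALSE)
  }

  refs <- read_reference_db(sim_paths[1], sim_paths[2])
  contigs <- Biostrings::readDNAStringSet(sim_paths[3])
  taxonomy <- read_tsv(sim_paths[4]); samples <- read_tsv(sim_paths[5])
  read_map <- read_tsv(sim_paths[6]); markers <- read_tsv(sim_paths[8])

  ## search ---------------------------------------------------------------
  hits_path <- file.path(out_dir, "hits.tsv")
  if (cached("search", hits_path)) {
    logmsg("search", "cached")
    record("search", hits_path, TRUE)
  } else {
    logmsg("search", sprintf("six-frame search of %d contigs vs %d references",
                             length(contigs), nrow(refs)))
    hits <- builtin_search(contigs, refs, max_evalue = ccfg$max_evalue)
    write_blast_tab(hits, hits_path)
    record("search", hits_path, FALSE)
  }
  hits <- read_blast_tab(hits_path)

  ## call -----------------------------------------------------------------
  calls_path <- file.path(out_dir, "calls.tsv")
  if (cached("call", calls_path)) {
    logmsg("call", "cached")
    record("call", calls_path, TRUE)
  } else {
    logmsg("call", "footprint designation and resolution")
    calls <- call_transposases(hits, refs, taxonomy, ccfg)
    write.table(calls, calls_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    record("call", calls_path, FALSE)
  }
  calls <- read_tsv(calls_path)

  ## quantify -------------------------------------------------------------
  ab_path <- file.path(out_dir, "abundance.tsv")
  if (cached("quantify", ab_path)) {
    logmsg("quantify", "cached")
    record("quantify", ab_path, TRUE)
    profiles <- build_sample_profiles(read_map, calls, taxonomy, samples,
                                      markers)
  } else {
    logmsg("quantify", "building sample profiles")
    profiles <- build_sample_profiles(read_map, calls, taxonomy, samples,
                                      markers)
    ab <- abundance_table(profiles)
    write.table(ab, ab_path, sep = "\t", quote = FALSE, row.names = FALSE)
    record("quantify", ab_path, FALSE)
  }
  abundance <- read_tsv(ab_path)

  ## stats ----------------------------------------------------------------
  stats_path <- file.path(out_dir, "contrasts.tsv")
  if (cached("stats", stats_path)) {
    logmsg("stats", "cached")
    record("stats", stats_path, TRUE)
  } else {
    logmsg("stats", sprintf("%d contrasts", length(config$contrasts)))
    ctr <- run_contrasts(abundance, samples, config$contrasts)
    write.table(ctr, stats_path, sep = "\t", quote = FALSE, row.names = FALSE)
    record("stats", stats_path, FALSE)
  }

  ## report ---------------------------------------------------------------
  report_paths <- pipeline_report(out_dir, profiles)
  record("report", report_paths, FALSE)

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' @noRd
read_tsv <- function(p) read.table(p, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE, quote = "",
                                   comment.char = "")

#' @noRd
digest_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass_rec(x), auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' @noRd
unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}

#' Summary report of a pipeline run
#'
#' Writes deterministic TSV summaries under `out_dir`: the per-station x
#' size-fraction transposase fractions for DNA and RNA, the per-phylum gene
#' and transcript fractions (medians over samples), the per-IS-family
#' transcript:gene expression ratios by size fraction, and a strain table
#' with transposases per Mbp computed from the bundled reference-strain
#' counts and genome sizes.
#'
#' @param out_dir Directory holding the stage outputs.
#' @param profiles A `sample_profile_list` (rebuilt from stage TSVs if
#'   omitted).
#' @param strain_table Path to a TSV with columns strain, tnp_count,
#'   size_mbp, origin (defaults to the bundled *Synechococcus* table).
#' @return Character vector of written paths, invisibly.
#' @export
pipeline_report <- function(out_dir, profiles = NULL, strain_table = NULL) {
  if (is.null(profiles)) {
    calls <- read_tsv(file.path(out_dir, "calls.tsv"))
    profiles <- build_sample_profiles(
      read_tsv(file.path(out_dir, "read_map.tsv")), calls,
      read_tsv(file.path(out_dir, "taxonomy.tsv")),
      read_tsv(file.path(out_dir, "samples.tsv")),
      read_tsv(file.path(out_dir, "truth_markers.tsv")))
  }
  if (length(profiles) == 0L) stopf("empty profile set; nothing to report")
  paths <- character(0)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  # per-station x fraction fractions
  rows <- lapply(profiles, function(p) data.frame(
    station = p$station, fraction = p$fraction, molecule = p$molecule,
    depth_m = p$depth_m,
    tnp_fraction = if (p$total_bacterial_reads > 0)
      fraction_of_bacterial_reads(p) else NA_real_,
    stringsAsFactors = FALSE))
  tsv(do.call(rbind, rows), "report_station_fraction.tsv")
  # per-phylum medians (gene and transcript)
  phyla <- sort(unique(unlist(lapply(profiles, function(p) p$taxa$phylum))))
  ph_rows <- list()
  for (ph in phyla) for (mol in c("DNA", "RNA")) {
    vals <- unlist(lapply(profiles, function(p) {
      if (p$molecule != mol) return(NULL)
      tryCatch(per_taxon_fraction(p, ph, "phylum"), error = function(e) NULL)
    }))
    if (length(vals))
      ph_rows[[length(ph_rows) + 1L]] <- data.frame(
        phylum = ph, molecule = mol, median_fraction = median(vals),
        n = length(vals), stringsAsFactors = FALSE)
  }
  tsv(do.call(rbind, ph_rows), "report_phylum.tsv")
  # per-family expression ratios by size fraction
  fams <- sort(unique(unlist(lapply(profiles, function(p) p$families$family))))
  fr_rows <- list()
  for (fam in fams) for (fr in unique(vapply(profiles, function(p) p$fraction, ""))) {
    sub <- Filter(function(p) p$fraction == fr, profiles)
    r <- tryCatch(suppressWarnings(expression_ratio(sub, sub, fam, "family")),
                  error = function(e) NULL)
    if (!is.null(r))
      fr_rows[[length(fr_rows) + 1L]] <- data.frame(
        family = fam, fraction = fr, expression_ratio = r$ratio,
        n_pairs = r$n_pairs, stringsAsFactors = FALSE)
  }
  if (length(fr_rows)) tsv(do.call(rbind, fr_rows), "report_family_expression.tsv")
  # strain table
  if (is.null(strain_table))
    strain_table <- system.file("extdata", "synechococcus_strains.tsv",
                                package = "tnpquant")
  if (nzchar(strain_table) && file.exists(strain_table)) {
    st <- read_tsv(strain_table)
    st$tnp_per_mbp <- transposases_per_mbp(st$tnp_count, st$size_mbp)
    tsv(st, "report_strains.tsv")
  }
  invisible(paths)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with top-level `sim`, `caller` and `contrasts`
#'   sections; missing sections take defaults.
#' @return Config list as used by [run_pipeline()].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$taxa)) sim_args$taxa <- as.data.frame(sim_args$taxa)
  cfg <- do.call(sim_config, sim_args)
  caller <- do.call(caller_config, y$caller %||% list())
  base <- default_pipeline_config(seed = cfg$seed)
  list(sim = cfg, caller = caller,
       contrasts = y$contrasts %||% base$contrasts)
}
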