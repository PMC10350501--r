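#' Default run configuration
#'
#' One flat list of every stage parameter with its standard value: QC
#' thresholds, population and bulk sizes, depth model, scan window/step/depth
#' and significance machinery, plus the global seed. Round-trips losslessly
#' through [write_run_config()] / [read_run_config()].
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    # simulate
    n_lines = 200,
    n_chrom = 3,
    chrom_length = 2e6,
    markers_per_chrom = 400,
    rate_cM_per_Mb = 1,
    indel_fraction = 0.1,
    impact_high = 0.01, impact_moderate = 0.04,
    impact_low = 0.1, impact_modifier = 0.85,
    mean_depth = 40,
    error_rate = 0.001,
    n_rep = 3,
    # synthetic reads
    n_reads = 2000,
    read_len = 150,
    adapter = "AGATCGGAAGAGC",
    p_adapter = 0.05, p_n_run = 0.05, p_tail3 = 0.05, p_lowq = 0.05,
    # qc
    q5 = 20, q3 = 3, qc_window = 4, window_q = 20,
    n_rate = 0.10, q_low = 15, low_frac = 0.40, min_len = 30,
    # bulks
    bulk_size = 30,
    bulk_traits = c("SFW", "SDW", "RFW"),
    # scan
    min_depth = 10,
    window = 1e6,
    step = 5000,
    min_sites = 5,
    reps = 10000,
    levels = c(0.95, 0.99, 0.999),
    call_level = 0.99
  ), class = "run_config")
}

#' Write / read a run configuration
#'
#' Flat YAML key/value file.
#'
#' @param cfg A `run_config` list.
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  base[names(cfg)] <- cfg
  validate_config(base)
  base
}

validate_config <- function(cfg) {
  if (cfg$window < cfg$step) stop("config invalid: window < step")
  if (cfg$n_lines < 2 * cfg$bulk_size) {
    stop("config invalid: n_lines must be >= 2 * bulk_size")
  }
  if (cfg$min_depth < 1) stop("config invalid: min_depth must be >= 1")
  if (!cfg$call_level %in% cfg$levels) {
    stop("config invalid: call_level must be one of levels")
  }
  invisible(cfg)
}

#' Run the full pipeline on simulated data
#'
#' Executes simulate -> read QC -> phenotype analysis -> variant summaries ->
#' SNP-index scan with one configuration and writes every artifact under
#' `out_dir`: synthetic FASTQ plus cleaned FASTQ and QC report, phenotype
#' TSVs (trait statistics, correlations, bulk membership), variant VCF and
#' summary TSVs, per-site/per-window scan TSVs, candidate-region BED, and a
#' JSON run manifest with seeds, parameters and per-stage record counts.
#' Identical configuration and seed give byte-identical TSV/BED outputs.
#'
#' @param cfg A `run_config` (default [default_config()]).
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir, quiet = FALSE) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[bsascan] ", ...)
  counts <- list()
  p <- function(f) file.path(out_dir, f)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- simulate ---------------------------------------------------------
  say("simulate: ", cfg$n_lines, " BC2F2 lines, ",
      cfg$n_chrom, " x ", cfg$markers_per_chrom, " markers")
  sim <- stage("simulate", {
    gm <- genome_model(cfg$n_chrom, cfg$chrom_length, cfg$markers_per_chrom,
                       indel_fraction = cfg$indel_fraction,
                       impact_probs = c(HIGH = cfg$impact_high,
                                        MODERATE = cfg$impact_moderate,
                                        LOW = cfg$impact_low,
                                        MODIFIER = cfg$impact_modifier),
                       seed = derive_seed(cfg$seed, "genome"))
    pop <- simulate_cross(gm, cfg$n_lines, cfg$rate_cM_per_Mb,
                          seed = derive_seed(cfg$seed, "cross"))
    qtl <- default_qtl(gm)
    traits <- simulate_traits(pop, qtl, n_rep = cfg$n_rep,
                              seed = derive_seed(cfg$seed, "traits"))
    utils::write.table(traits, p("phenotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fq <- synth_fastq(cfg$n_reads, cfg$read_len,
                      defect_spec(adapter = cfg$adapter,
                                  p_adapter = cfg$p_adapter,
                                  p_n_run = cfg$p_n_run,
                                  p_tail3 = cfg$p_tail3,
                                  p_lowq = cfg$p_lowq),
                      seed = derive_seed(cfg$seed, "fastq"),
                      path = p("raw.fq.gz"))
    list(gm = gm, pop = pop, qtl = qtl, traits = traits, fq = fq)
  })
  counts$simulate <- list(lines = cfg$n_lines,
                          markers = nrow(sim$gm$markers),
                          reads = cfg$n_reads)

  # --- qc ---------------------------------------------------------------
  say("qc: cleaning ", cfg$n_reads, " reads")
  report <- stage("qc", {
    pr <- qc_params(q5 = cfg$q5, q3 = cfg$q3, window = cfg$qc_window,
                    window_q = cfg$window_q, n_rate = cfg$n_rate,
                    q_low = cfg$q_low, low_frac = cfg$low_frac,
                    min_len = cfg$min_len)
    rep <- qc_stream(p("raw.fq.gz"), p("clean.fq.gz"),
                     adapter = cfg$adapter, params = pr)
    write_qc_report(rep, p("qc_report.tsv"))
    rep
  })
  counts$qc <- list(reads_in = report$reads_in, reads_out = report$reads_out)

  # --- phenotype --------------------------------------------------------
  say("phenotype: trait statistics and bulk selection")
  bulks <- stage("phenotype", {
    st <- trait_stats_table(sim$traits)
    utils::write.table(st, p("trait_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ct <- correlation_matrix(sim$traits)
    rmat <- matrix(paste0(format(round(ct$r, 3)), ct$stars),
                   nrow(ct$r), dimnames = dimnames(ct$r))
    utils::write.table(rmat, p("trait_correlations.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    sel <- select_bulks(sim$traits, traits = cfg$bulk_traits, n = cfg$bulk_size)
    memb <- tibble::tibble(
      line = c(sel$resistant, sel$susceptible),
      bulk = rep(c("resistant", "susceptible"), each = cfg$bulk_size)
    )
    utils::write.table(memb, p("bulk_membership.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sel
  })
  counts$phenotype <- list(lines = length(unique(sim$traits$line)),
                           bulk_size = cfg$bulk_size)

  # --- variants ---------------------------------------------------------
  say("variants: pooled depths and per-sample summaries")
  sites <- stage("variants", {
    dm <- depth_model(cfg$mean_depth, cfg$error_rate)
    sites <- simulate_bulk_depths(sim$pop, bulks$resistant, bulks$susceptible,
                                  dm, qtl = sim$qtl,
                                  seed = derive_seed(cfg$seed, "depths"))
    write_variant_vcf(sites, p("variants.vcf.gz"))
    truth <- attr(sites, "truth")
    utils::write.table(truth, p("marker_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(variant_summary_table(sites), p("variant_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sites
  })
  counts$variants <- list(records = nrow(sites) / length(unique(sites$sample)),
                          samples = length(unique(sites$sample)))

  # --- scan -------------------------------------------------------------
  say("scan: SNP-index windows and candidate regions")
  regions <- stage("scan", {
    rec <- filter_informative_sites(sites, min_depth = cfg$min_depth)
    utils::write.table(rec, p("snp_index.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    lens <- stats::setNames(sim$gm$chromosomes$length, sim$gm$chromosomes$name)
    win <- sliding_windows(rec, lens, cfg$window, cfg$step, cfg$min_sites)
    nm <- null_model(cfg$bulk_size, cfg$reps, cfg$levels)
    win <- attach_thresholds(win, nm, seed = derive_seed(cfg$seed, "null"))
    utils::write.table(win, p("windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    reg <- call_candidate_regions(win, level = cfg$call_level, sites = rec,
                                  step = cfg$step)
    write_regions_bed(reg, p("regions.bed"))
    utils::write.table(reg[, setdiff(names(reg), "effective")],
                       p("regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    counts$scan <- list(informative_sites = nrow(rec),
                        windows = nrow(win), regions = nrow(reg))
    reg
  })
  say("done: ", nrow(regions), " candidate region(s)")

  files <- c("phenotypes.tsv", "trait_stats.tsv", "trait_correlations.tsv",
             "bulk_membership.tsv", "qc_report.tsv", "marker_truth.tsv",
             "variant_summary.tsv", "snp_index.tsv", "windows.tsv",
             "regions.tsv", "regions.bed")
  manifest <- list(
    package = "bsascan",
    version = as.character(utils::packageVersion("bsascan")),
    seed = cfg$seed,
    parameters = unclass(cfg),
    stages = names(counts),
    counts = counts,
    digests = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$digests) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
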