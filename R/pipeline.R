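#' Pipeline run configuration
#'
#' Bundles everything one reproducible run needs: the calling design, the
#' caller and filter parameters, the data source (either a simulation
#' configuration or a counts TSV on disk), an output directory and the
#' single top-level seed from which all randomness flows.
#'
#' @param case Case sample label.
#' @param controls Zero, one or two control sample labels (zero selects
#'   unpaired mode).
#' @param caller A [caller_params()].
#' @param filters A [filter_config()].
#' @param sim Optional [sim_config()]; when given, input is simulated.
#' @param counts_tsv Optional path to a counts TSV (exclusive with `sim`).
#' @param regions Optional target regions (BED path or `GRanges`) to
#'   restrict the input to.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in every output.
#' @return A `run_config` list.
#' @export
run_config <- function(case, controls = character(0L),
                       caller = caller_params(),
                       filters = filter_config(),
                       sim = NULL, counts_tsv = NULL, regions = NULL,
                       out_dir = tempfile("lensmosaic_run_"),
                       seed = 1L) {
  if (is.null(sim) == is.null(counts_tsv)) {
    stop("exactly one of `sim` or `counts_tsv` must be supplied",
         call. = FALSE)
  }
  stopifnot(length(controls) <= 2L, is.character(case))
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    miss <- setdiff(c(case, controls), sim$samples)
    if (length(miss) > 0L) {
      stop("design references sample(s) absent from the simulation: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(case = case, controls = controls,
                 mode = if (length(controls) == 0L) "unpaired" else "paired",
                 caller = caller, filters = filters, sim = sim,
                 counts_tsv = counts_tsv, regions = regions,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the pipeline end to end
#'
#' Simulates (or reads) the pileup, calls variants for the configured
#' design, runs the filter cascade, and writes the run artifacts into the
#' output directory: `calls.vcf` (all calls, FILTER annotated),
#' `passed.vcf` (cascade survivors), `audit.tsv` (the complete per-call
#' filter audit) and `summary.json` (stage counts and survivor list).
#' Every output records the seed and a hash of the configuration, and the
#' run is deterministic given the seed.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `pileup`, `truth` (simulated runs only),
#'   `calls`, `passed`, `audit`, `summary` and `paths`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(...)
  cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  truth <- NULL
  if (!is.null(cfg$sim)) {
    say("simulating ", cfg$sim$n_sites, " sites x ",
        length(cfg$sim$samples), " samples")
    sim <- simulate_pileups(cfg$sim, seed = cfg$seed)
    pileup <- sim$pileup
    truth <- sim$truth
  } else {
    say("reading counts from ", cfg$counts_tsv)
    pileup <- read_counts_tsv(cfg$counts_tsv)
  }
  if (!is.null(cfg$regions)) pileup <- restrict_to_regions(pileup, cfg$regions)

  say("calling (", cfg$mode, " mode, case=", cfg$case,
      if (length(cfg$controls) > 0L) paste0(", controls=",
        paste(cfg$controls, collapse = "+")), ")")
  calls <- call_sample_set(pileup, cfg$case, cfg$controls, cfg$caller)
  say(nrow(calls), " putative variant call(s)")

  casc <- run_cascade(calls, pileup = pileup, cfg = cfg$filters,
                      mode = cfg$mode, n_controls = length(cfg$controls))
  say(nrow(casc$passed), " call(s) survive the cascade")

  paths <- list(calls_vcf = file.path(cfg$out_dir, "calls.vcf"),
                passed_vcf = file.path(cfg$out_dir, "passed.vcf"),
                audit_tsv = file.path(cfg$out_dir, "audit.tsv"),
                summary_json = file.path(cfg$out_dir, "summary.json"))
  if (!is.null(truth)) {
    paths$truth_tsv <- file.path(cfg$out_dir, "truth.tsv")
    write_truth_tsv(truth, paths$truth_tsv)
  }
  stamp <- c(paste0("##lensmosaic_seed=", cfg$seed),
             paste0("##lensmosaic_config_hash=", cfg_hash))
  write_vcf(casc$calls, paths$calls_vcf)
  write_vcf(casc$passed, paths$passed_vcf)
  for (p in c(paths$calls_vcf, paths$passed_vcf)) {
    lines <- readLines(p)
    writeLines(append(lines, stamp, after = 1L), p)
  }
  audit_lines <- c(paste0("# seed=", cfg$seed, " config_hash=", cfg_hash),
                   paste(names(casc$audit), collapse = "\t"),
                   do.call(paste, c(unname(casc$audit), sep = "\t")))
  writeLines(audit_lines, paths$audit_tsv)

  low_vaf <- sum(calls$vaf_case < cfg$filters$max_unpaired_freq &
                   !calls$status %in% "GERMLINE")
  survivors <- as.data.frame(casc$passed)[
    c("chrom", "pos", "ref", "alt", "sample_case", "vaf_case", "p_somatic",
      "status")]
  summary <- list(
    seed = cfg$seed,
    config_hash = cfg_hash,
    mode = cfg$mode,
    design = list(case = cfg$case, controls = cfg$controls),
    n_sites = nrow(mp_sites(pileup)),
    n_samples = length(mp_samples(pileup)),
    putative_variants = nrow(calls),
    low_vaf_candidates = low_vaf,
    stage_counts = as.list(casc$stage_counts),
    survivors = survivors
  )
  writeLines(
    as.character(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE, dataframe = "rows")),
    paths$summary_json)
  invisible(list(pileup = pileup, truth = truth, calls = casc$calls,
                 passed = casc$passed, audit = casc$audit,
                 summary = summary, paths = paths))
}
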