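#' Pipeline configuration
#'
#' Declarative configuration shared by the `run_*()` commands. Values come
#' from defaults, then an optional YAML file, then direct arguments, in
#' increasing precedence.
#'
#' @param path Optional YAML file of key–value settings.
#' @param ... Direct overrides (e.g. `tau = 2.5`).
#' @return A list of class `ripchip_pipeline_config` with fields `platform`,
#'   `tau`, `p`, `min_background`, `blacklist` (path or `NULL`), `annotation`
#'   (path or `NULL`), `seed`, `verbose`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    platform = "pcr",
    tau = 2,
    p = 0.05,
    min_background = 200,
    blacklist = NULL,
    annotation = NULL,
    seed = 1L,
    verbose = TRUE
  )
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort_ripchip(sprintf("config file '%s' does not exist", path),
                    "ripchip_io_error")
    }
    from_file <- yaml::read_yaml(path)
    cfg[names(from_file)] <- from_file
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  for (nm in c("tau", "p", "min_background", "seed")) {
    if (!is_number(cfg[[nm]])) {
      abort_ripchip(sprintf("pipeline config field '%s' must be numeric", nm),
                    "ripchip_config_error")
    }
  }
  as_platform(cfg$platform)  # validate early
  structure(cfg, class = "ripchip_pipeline_config")
}

say <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) rlang::inform(sprintf(fmt, ...))
}

#' Simulate an experiment to disk
#'
#' Writes one spot-table TSV per replicate, a `manifest.tsv` of experiment
#' descriptors, the probe annotation, `ground_truth.tsv` and the generating
#' config (`config.yml`). Re-running with the same config yields byte-identical
#' files.
#'
#' @param config A [ripchip_config()].
#' @param out_dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
run_simulate <- function(config = ripchip_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(config)
  manifest <- purrr::map_dfr(seq_along(sim$scans), function(i) {
    scan <- sim$scans[[i]]
    file <- paste0(attr(scan, "experiment_id"), ".tsv")
    write_scan(scan, file.path(out_dir, file))
    tibble(
      file = file,
      experiment_id = attr(scan, "experiment_id"),
      bait_gene = attr(scan, "bait_gene"),
      platform = attr(scan, "platform")$name,
      condition = attr(scan, "condition"),
      dye_swapped = as.integer(attr(scan, "dye_swapped")),
      replicate = i
    )
  })
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  ann <- simulated_annotation(config)
  ann$is_coding <- as.integer(ann$is_coding)
  readr::write_tsv(ann, file.path(out_dir, "annotation.tsv"), progress = FALSE)
  truth_tbl <- dplyr::bind_rows(
    tibble(gene_id = sim$truth$bait_gene, role = "bait"),
    tibble(gene_id = sim$truth$target_genes, role = "target"),
    tibble(gene_id = sim$truth$contaminant_genes, role = "contaminant")
  )
  truth_tbl$enriched_in_condition <-
    as.integer(truth_tbl$gene_id %in% sim$truth$enriched_genes)
  readr::write_tsv(truth_tbl, file.path(out_dir, "ground_truth.tsv"),
                   progress = FALSE)
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, file.path(out_dir, "config.yml"))
  invisible(file.path(out_dir, "manifest.tsv"))
}

read_manifest <- function(in_dir) {
  path <- file.path(in_dir, "manifest.tsv")
  if (!file.exists(path)) {
    abort_ripchip(sprintf("no input scans: '%s' has no manifest.tsv", in_dir),
                  "ripchip_no_input")
  }
  manifest <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (nrow(manifest) == 0) {
    abort_ripchip(sprintf("no input scans listed in '%s'", path),
                  "ripchip_no_input")
  }
  manifest
}

load_scans <- function(in_dir, manifest, config) {
  lapply(seq_len(nrow(manifest)), function(i) {
    read_spot_table(
      file.path(in_dir, manifest$file[i]),
      platform = manifest$platform[i] %||% config$platform,
      experiment_id = manifest$experiment_id[i],
      bait_gene = manifest$bait_gene[i],
      condition = manifest$condition[i],
      dye_swapped = manifest$dye_swapped[i] != 0
    )
  })
}

load_annotation <- function(in_dir, config) {
  path <- config$annotation %||% file.path(in_dir, "annotation.tsv")
  if (!file.exists(path)) {
    abort_ripchip(sprintf("annotation file '%s' not found", path),
                  "ripchip_io_error")
  }
  read_annotation(path)
}

#' Run spot QC over a directory of scans
#'
#' Writes one `<experiment_id>_qc.tsv` per scan with columns `probe_id`,
#' `kept`, `reason`, `ip_detectable`.
#'
#' @param in_dir Directory holding scan TSVs and a `manifest.tsv` (as written
#'   by [run_simulate()]).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Paths of the QC reports, invisibly.
#' @export
run_qc <- function(in_dir, config = pipeline_config(), out_dir = in_dir) {
  manifest <- read_manifest(in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scans <- load_scans(in_dir, manifest, config)
  paths <- vapply(seq_along(scans), function(i) {
    qc <- filter_scan(scans[[i]])
    out <- tibble(
      probe_id = qc$probe_id,
      kept = as.integer(qc$kept),
      reason = ifelse(is.na(qc$reason), "", qc$reason),
      ip_detectable = as.integer(qc$ip_detectable)
    )
    path <- file.path(out_dir, paste0(manifest$experiment_id[i], "_qc.tsv"))
    readr::write_tsv(out, path, progress = FALSE)
    say(config, "QC %s: %d/%d spots kept", manifest$experiment_id[i],
        sum(qc$kept), nrow(qc))
    path
  }, character(1))
  invisible(paths)
}

#' Call enriched targets from a directory of scans
#'
#' Groups scans by bait and condition, runs [call_targets()] on each group of
#' replicates, and writes a calls TSV plus a one-row-per-bait summary TSV.
#'
#' @inheritParams run_qc
#' @param out_path Output path for the calls TSV; the summary is written next
#'   to it as `<stem>_summary.tsv`.
#' @return The list of `ripchip_callset`s, invisibly.
#' @export
run_call <- function(in_dir, config = pipeline_config(),
                     out_path = file.path(in_dir, "calls.tsv")) {
  manifest <- read_manifest(in_dir)
  annotation <- load_annotation(in_dir, config)
  blacklist <- if (!is.null(config$blacklist)) {
    read_blacklist(config$blacklist)
  } else {
    character()
  }
  scans <- load_scans(in_dir, manifest, config)
  groups <- split(seq_along(scans),
                  paste(manifest$bait_gene, manifest$condition, sep = "|"))
  callsets <- lapply(groups, function(idx) {
    cs <- call_targets(scans[idx], annotation, blacklist = blacklist,
                       tau = config$tau, p = config$p,
                       min_background = config$min_background)
    say(config, "bait %s (%s): category '%s', %d consensus gene(s), tau = %g",
        cs$bait_gene, attr(scans[[idx[1]]], "condition"), cs$category,
        length(cs$consensus), config$tau)
    cs
  })
  calls <- dplyr::bind_rows(lapply(callsets, function(cs) cs$calls))
  write_callset(calls, out_path)
  summary <- dplyr::bind_rows(lapply(callsets, glance))
  readr::write_tsv(summary, paste0(sub("\\.tsv$", "", out_path), "_summary.tsv"),
                   progress = FALSE)
  invisible(callsets)
}

#' Build a perturbation report from a directory of scans
#'
#' Uses the consensus genes of the baseline (control/mock) arm as the reported
#' mRNAs unless `genes` is given, then scores every (mRNA, condition,
#' replicate) cell and writes the report (see [write_report()]).
#'
#' @inheritParams run_call
#' @param genes Optional character vector of mRNAs to report on.
#' @return The `ripchip_report`, invisibly.
#' @export
run_perturb <- function(in_dir, config = pipeline_config(),
                        out_path = file.path(in_dir, "perturbation.tsv"),
                        genes = NULL) {
  manifest <- read_manifest(in_dir)
  annotation <- load_annotation(in_dir, config)
  scans <- load_scans(in_dir, manifest, config)
  conditions <- vapply(scans, function(s) attr(s, "condition"), character(1))
  if (is.null(genes)) {
    baseline <- which(conditions %in% c("control", "mock"))
    if (length(baseline) == 0) {
      abort_ripchip("no control/mock scans to derive reported mRNAs from; pass `genes`",
                    "ripchip_no_input")
    }
    cs <- call_targets(scans[baseline], annotation,
                       tau = config$tau, p = config$p,
                       min_background = config$min_background)
    genes <- cs$consensus
  }
  report <- perturbation_report(scans, genes, annotation,
                                min_background = config$min_background,
                                tau = config$tau)
  write_report(report, out_path)
  invisible(report)
}

#' Summarise call sets: categories and per-bait enrichment distributions
#'
#' Writes (and returns) the per-bait category summary with the percentage of
#' baits pulling down non-cognate targets, and, when scans are available, a
#' per-experiment box-plot statistics table of the standardized enrichment
#' scores.
#'
#' @param in_dir Directory with scans (for box-plot statistics) or `NULL`.
#' @param callsets List of `ripchip_callset`s, or `NULL` to recompute from
#'   `in_dir` via [run_call()] semantics.
#' @param config A [pipeline_config()].
#' @param out_path Output path for the category summary TSV; box-plot stats
#'   go to `<stem>_boxstats.tsv`.
#' @return A list with `categories` (tibble), `pct_targets` and `boxstats`,
#'   invisibly.
#' @export
run_report <- function(in_dir = NULL, callsets = NULL,
                       config = pipeline_config(),
                       out_path = "report.tsv") {
  if (is.null(callsets)) {
    if (is.null(in_dir)) {
      abort_ripchip("run_report() needs `callsets` or `in_dir`",
                    "ripchip_no_input")
    }
    callsets <- withr::with_options(list(), run_call(in_dir, config,
      out_path = file.path(tempdir(), "run_report_calls.tsv")))
  }
  categories <- vapply(callsets, function(cs) cs$category, character(1))
  cat_tbl <- summarize_categories(categories)
  pct <- attr(cat_tbl, "pct_targets")
  summary <- dplyr::bind_rows(lapply(callsets, glance))
  readr::write_tsv(summary, out_path, progress = FALSE)
  boxstats <- NULL
  if (!is.null(in_dir)) {
    manifest <- read_manifest(in_dir)
    annotation <- load_annotation(in_dir, config)
    scans <- load_scans(in_dir, manifest, config)
    boxstats <- purrr::map_dfr(scans, function(scan) {
      std <- standardize_profile(enrichment_profile(scan, annotation),
                                 min_background = config$min_background)
      bs <- boxplot_stats(std$z)
      bs$outliers <- NULL
      dplyr::bind_cols(
        tibble(experiment_id = attr(scan, "experiment_id")), bs
      )
    })
    readr::write_tsv(boxstats, paste0(sub("\\.tsv$", "", out_path), "_boxstats.tsv"),
                     progress = FALSE)
  }
  say(config, "categories: %s; %.1f%% of baits pull down non-cognate targets",
      paste(sprintf("%s=%d", cat_tbl$category, cat_tbl$n), collapse = ", "), pct)
  invisible(list(categories = cat_tbl, pct_targets = pct, boxstats = boxstats))
}

#' Bundled bait–target association table
#'
#' A curated example of 12 fission-yeast bait proteins that reproducibly
#' co-purified with mRNAs other than their own in a published RIP-chip survey,
#' with their non-cognate target mRNAs (comma-separated). Useful as a worked
#' example for category arithmetic and target-multiplicity summaries.
#'
#' @return Tibble with columns `bait`, `bait_gene`, `targets`, and the
#'   unnested `n_targets`.
#' @export
example_bait_targets <- function() {
  path <- system.file("extdata", "pombe_bait_targets.tsv", package = "ripchip",
                      mustWork = TRUE)
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  tbl$n_targets <- lengths(strsplit(tbl$targets, ","))
  tbl
}
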