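#' Read a quantified spot table
#'
#' Reads one two-channel array scan from a tab-separated spot table with a
#' header row. Required columns: `probe_id`, `ip_signal`, `ref_signal`,
#' `ip_frac_above_bg`, `ref_frac_above_bg`, `flag`; optional grid coordinates
#' `block`, `row`, `col` are kept if present. `ip_*` columns refer to the
#' channel that carries the immunoprecipitate in an unswapped hybridisation;
#' for a dye-swapped scan the two samples occupy each other's channels and the
#' roles are exchanged on read (see `resolve_channels`), so that downstream
#' per-channel QC and ratios always see the true sample roles.
#'
#' Experiment descriptors (`bait_gene`, `condition`, `dye_swapped`) are taken
#' from the caller, never guessed from the file.
#'
#' @param path Path to the TSV file.
#' @param platform Platform spec or name (see [platform_spec()]).
#' @param experiment_id Identifier for the scan; defaults to the file name.
#' @param bait_gene Gene ID of the tagged bait protein.
#' @param condition One of `"control"`, `"minus_atg"`, `"puromycin"`,
#'   `"edta"`, `"mock"`.
#' @param dye_swapped Were the dyes swapped between IP and reference?
#' @param resolve Exchange the channel columns of a dye-swapped scan on read
#'   (default `TRUE`).
#'
#' @return A tibble of class `ripchip_scan`, one row per spot in file order,
#'   with the experiment descriptors stored as attributes.
#' @export
read_spot_table <- function(path,
                            platform = platform_spec("pcr"),
                            experiment_id = basename(path),
                            bait_gene = NA_character_,
                            condition = "control",
                            dye_swapped = FALSE,
                            resolve = TRUE) {
  if (!file.exists(path)) {
    abort_ripchip(sprintf("cannot read spot table: '%s' does not exist", path),
                  "ripchip_io_error")
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("probe_id", "ip_signal", "ref_signal",
                "ip_frac_above_bg", "ref_frac_above_bg", "flag")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_ripchip(
      sprintf("spot table '%s' is missing required column(s): %s",
              path, paste(missing, collapse = ", ")),
      "ripchip_format_error"
    )
  }
  if (nrow(raw) == 0) {
    abort_ripchip(sprintf("empty table: '%s' contains a header but no data rows", path),
                  "ripchip_format_error")
  }
  numeric_cols <- c("ip_signal", "ref_signal",
                    "ip_frac_above_bg", "ref_frac_above_bg", "flag",
                    intersect(c("block", "row", "col"), names(raw)))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      # +1 for the header row so the number matches the file line
      abort_ripchip(
        sprintf("non-numeric value '%s' in column '%s' (line %d of '%s')",
                raw[[col]][bad[1]], col, bad[1] + 1L, path),
        "ripchip_format_error"
      )
    }
    raw[[col]] <- v
  }
  raw$flag <- as.integer(raw$flag)
  spots <- as_tibble(raw[, c(required, intersect(c("block", "row", "col"), names(raw)))])
  scan <- new_scan(spots,
                   experiment_id = experiment_id,
                   bait_gene = bait_gene,
                   platform = as_platform(platform),
                   dye_swapped = dye_swapped,
                   condition = condition)
  if (resolve) scan <- resolve_channels(scan)
  scan
}

#' Construct an array scan from a spot tibble
#'
#' Low-level constructor used by [read_spot_table()] and the simulator.
#' Validates the per-spot invariants: pixel fractions in \[0, 1\] and
#' nonnegative signals.
#'
#' @param spots Tibble with the spot-table columns.
#' @inheritParams read_spot_table
#' @param channels_resolved Have dye-swapped channel columns already been
#'   exchanged into sample roles?
#' @return A `ripchip_scan` tibble.
#' @export
new_scan <- function(spots,
                     experiment_id,
                     bait_gene = NA_character_,
                     platform = platform_spec("pcr"),
                     dye_swapped = FALSE,
                     condition = "control",
                     channels_resolved = FALSE) {
  check_condition(condition)
  spots <- as_tibble(spots)
  for (col in c("ip_frac_above_bg", "ref_frac_above_bg")) {
    bad <- which(spots[[col]] < 0 | spots[[col]] > 1)
    if (length(bad) > 0) {
      abort_ripchip(
        sprintf("'%s' must lie in [0, 1]; first offending spot is row %d (value %g)",
                col, bad[1], spots[[col]][bad[1]]),
        "ripchip_validation_error"
      )
    }
  }
  for (col in c("ip_signal", "ref_signal")) {
    bad <- which(spots[[col]] < 0)
    if (length(bad) > 0) {
      abort_ripchip(
        sprintf("'%s' must be nonnegative; first offending spot is row %d (value %g)",
                col, bad[1], spots[[col]][bad[1]]),
        "ripchip_validation_error"
      )
    }
  }
  structure(
    spots,
    experiment_id = experiment_id,
    bait_gene = bait_gene,
    platform = as_platform(platform),
    dye_swapped = isTRUE(dye_swapped),
    condition = condition,
    channels_resolved = isTRUE(channels_resolved),
    class = c("ripchip_scan", class(spots))
  )
}

#' Resolve dye-swapped channels into sample roles
#'
#' For a scan recorded with `dye_swapped = TRUE`, the IP sample was measured in
#' the reference channel and vice versa. This exchanges the two signal and the
#' two pixel-fraction columns exactly once, so that `ip_*` columns refer to the
#' immunoprecipitate sample regardless of dye orientation. Idempotent.
#'
#' @param scan A `ripchip_scan`.
#' @return The scan with channel columns in sample roles and
#'   `channels_resolved = TRUE`.
#' @export
resolve_channels <- function(scan) {
  if (isTRUE(attr(scan, "channels_resolved"))) {
    return(scan)
  }
  if (isTRUE(attr(scan, "dye_swapped"))) {
    tmp <- scan$ip_signal
    scan$ip_signal <- scan$ref_signal
    scan$ref_signal <- tmp
    tmp <- scan$ip_frac_above_bg
    scan$ip_frac_above_bg <- scan$ref_frac_above_bg
    scan$ref_frac_above_bg <- tmp
  }
  attr(scan, "channels_resolved") <- TRUE
  scan
}

#' Read a probe-to-gene annotation table
#'
#' TSV with columns `probe_id`, `gene_id`, `is_coding` (0/1). Each probe must
#' map to exactly one gene.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with columns `probe_id`, `gene_id`, `is_coding` (logical).
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(
    path,
    col_types = readr::cols(
      probe_id = readr::col_character(),
      gene_id = readr::col_character(),
      is_coding = readr::col_character()
    ),
    progress = FALSE
  )
  missing <- setdiff(c("probe_id", "gene_id", "is_coding"), names(ann))
  if (length(missing) > 0) {
    abort_ripchip(
      sprintf("annotation '%s' is missing required column(s): %s",
              path, paste(missing, collapse = ", ")),
      "ripchip_format_error"
    )
  }
  coding <- ann$is_coding %in% c("1", "TRUE", "true")
  not_flag <- !coding & !ann$is_coding %in% c("0", "FALSE", "false")
  if (any(not_flag)) {
    abort_ripchip(
      sprintf("'is_coding' must be 0/1; got '%s'", ann$is_coding[which(not_flag)[1]]),
      "ripchip_format_error"
    )
  }
  ann$is_coding <- coding
  check_annotation(ann)
  ann
}

check_annotation <- function(annotation) {
  multi <- unique(annotation[, c("probe_id", "gene_id")])
  dup <- multi$probe_id[duplicated(multi$probe_id)]
  if (length(dup) > 0) {
    abort_ripchip(
      sprintf("annotation maps probe '%s' to more than one gene", dup[1]),
      "ripchip_annotation_error"
    )
  }
  invisible(annotation)
}

#' Attach gene IDs to spots and drop non-coding or unannotated probes
#'
#' Resolves each probe to its gene via the annotation. Probes with
#' `is_coding = FALSE` (only probes for coding sequences enter the enrichment
#' analysis) and probes absent from the annotation are excluded; the counts of
#' exclusions are recorded as attributes `n_noncoding` and `n_unmapped`.
#'
#' @param spots A `ripchip_scan` (or any tibble with a `probe_id` column).
#' @param annotation Annotation tibble as from [read_annotation()].
#' @return The input rows that map to coding genes, with a `gene_id` column
#'   added; one row per spot.
#' @export
map_probes_to_genes <- function(spots, annotation) {
  check_annotation(annotation)
  ann <- unique(annotation[, c("probe_id", "gene_id", "is_coding")])
  joined <- dplyr::left_join(as_tibble(spots), ann, by = "probe_id")
  unmapped <- is.na(joined$gene_id)
  noncoding <- !unmapped & !joined$is_coding
  out <- joined[!unmapped & !noncoding, setdiff(names(joined), "is_coding")]
  if (nrow(out) == 0) {
    rlang::warn("all probes were excluded (non-coding or unannotated); empty mapping",
                class = "ripchip_empty_mapping")
  }
  out <- restore_scan_attrs(out, spots)
  attr(out, "n_unmapped") <- sum(unmapped)
  attr(out, "n_noncoding") <- sum(noncoding)
  out
}

#' Read a contaminant blacklist
#'
#' Plain text, one gene ID per line; `#` starts a comment; duplicates are
#' collapsed (set semantics).
#'
#' @param path Path to the blacklist file.
#' @return Character vector of unique gene IDs.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) {
    abort_ripchip(sprintf("cannot read blacklist: '%s' does not exist", path),
                  "ripchip_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Write a contaminant blacklist
#'
#' @param gene_ids Character vector of gene IDs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blacklist <- function(gene_ids, path) {
  writeLines(sort(unique(gene_ids)), path)
  invisible(path)
}

.callset_cols <- c("bait", "gene_id", "replicate_support", "mean_s",
                   "is_bait_mrna", "category")

#' Write / read a call set table
#'
#' The calls TSV holds one row per consensus gene: `bait`, `gene_id`,
#' `replicate_support` (e.g. `"3/3"`), `mean_s` (mean SD-above-median score
#' across replicates), `is_bait_mrna` (0/1) and the bait `category`. Writing
#' is bit-stable for fixed input, and `read_callset(write_callset(x))`
#' round-trips the table exactly.
#'
#' @param callset A `ripchip_callset` (see [call_targets()]) or a tibble with
#'   the calls schema.
#' @param path Output / input path.
#' @return `write_callset()` returns `path` invisibly; `read_callset()` a
#'   tibble with the calls schema.
#' @export
write_callset <- function(callset, path) {
  if (inherits(callset, "ripchip_callset")) {
    callset <- callset$calls
  }
  missing <- setdiff(.callset_cols, names(callset))
  if (length(missing) > 0) {
    abort_ripchip(
      sprintf("call set is missing column(s): %s", paste(missing, collapse = ", ")),
      "ripchip_format_error"
    )
  }
  readr::write_tsv(callset[, .callset_cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_callset
#' @export
read_callset <- function(path) {
  if (!file.exists(path)) {
    abort_ripchip(sprintf("cannot read call set: '%s' does not exist", path),
                  "ripchip_io_error")
  }
  readr::read_tsv(
    path,
    col_types = readr::cols(
      bait = readr::col_character(),
      gene_id = readr::col_character(),
      replicate_support = readr::col_character(),
      mean_s = readr::col_double(),
      is_bait_mrna = readr::col_integer(),
      category = readr::col_character()
    ),
    progress = FALSE
  )
}

#' Write a perturbation report
#'
#' Writes the per-cell table (`bait`, `mRNA`, `condition`, `replicate`,
#' `value`, where `value` is a number or the code `"P"` / `"ND"`) to `path`,
#' and, when verdicts are present, a companion
#' `<stem>_verdicts.tsv` (`bait`, `mRNA`, `condition_pair`, `verdict`).
#'
#' @param report A `ripchip_report` (see [perturbation_report()]).
#' @param path Output path for the cell table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "ripchip_report")) {
    abort_ripchip("`report` must be a ripchip_report", "ripchip_format_error")
  }
  readr::write_tsv(report$cells, path, progress = FALSE)
  if (!is.null(report$verdicts) && nrow(report$verdicts) > 0) {
    stem <- sub("\\.tsv$", "", path)
    readr::write_tsv(report$verdicts, paste0(stem, "_verdicts.tsv"), progress = FALSE)
  }
  invisible(path)
}

#' Write a scan in the spot-table dialect
#'
#' Emits exactly the columns [read_spot_table()] consumes, in spot order.
#' Bit-stable for fixed input.
#'
#' @param scan A `ripchip_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  cols <- c("probe_id", "ip_signal", "ref_signal",
            "ip_frac_above_bg", "ref_frac_above_bg", "flag",
            intersect(c("block", "row", "col"), names(scan)))
  readr::write_tsv(as_tibble(scan)[, cols], path, progress = FALSE)
  invisible(path)
}
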