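#' Score an mRNA in one scan, or assign a P/ND code
#'
#' Reproduces the cell semantics of condition-comparison tables:
#'
#' * a numeric value — the gene's SD-above-median score `s` from the
#'   standardized profile of that scan;
#' * `"ND"` — the mRNA was not detectable in the immunoprecipitate: none of
#'   its spots reaches the platform's stand-alone IP threshold;
#' * `"P"` — the mRNA is clearly present in the IP, but too few mRNAs survive
#'   QC to compute the median-enrichment background (fewer than
#'   `min_background` genes), so no score can be formed.
#'
#' A gene absent from the array design (no annotated probe on the scan) is an
#' error, distinct from ND.
#'
#' @param gene Gene ID to score.
#' @param scan A `ripchip_scan`.
#' @param annotation Probe-to-gene annotation tibble.
#' @param platform Platform spec; defaults to the scan's own.
#' @param min_background Minimum number of profiled genes required for a
#'   numeric score (default 200).
#' @param tau Unused here; kept for interface symmetry with
#'   [compare_conditions()].
#' @return One-row tibble: `gene_id`, `score` (numeric or `NA`), `code`
#'   (`NA`, `"P"` or `"ND"`), `value` (the printable cell: the score formatted
#'   or the code).
#' @export
score_or_code <- function(gene, scan, annotation, platform = NULL,
                          min_background = 200, tau = 2) {
  probes <- annotation$probe_id[annotation$gene_id == gene & annotation$is_coding]
  scan <- resolve_channels(scan)
  on_array <- probes[probes %in% scan$probe_id]
  if (length(on_array) == 0) {
    abort_ripchip(
      sprintf("gene '%s' is absent from the array design of experiment '%s'",
              gene, attr(scan, "experiment_id") %||% "?"),
      "ripchip_gene_not_on_array"
    )
  }
  qc <- filter_scan(scan, platform = platform)
  gene_rows <- qc[qc$probe_id %in% on_array, , drop = FALSE]
  if (!any(gene_rows$ip_detectable)) {
    return(tibble(gene_id = gene, score = NA_real_, code = "ND", value = "ND"))
  }
  mapped <- map_probes_to_genes(qc, annotation)
  prof <- gene_log_ratios(mapped)
  std <- tryCatch(
    standardize_profile(prof, min_background = min_background),
    ripchip_background_too_small = function(e) NULL,
    ripchip_degenerate_profile = function(e) NULL
  )
  if (is.null(std) || !gene %in% std$gene_id) {
    # detectable in the IP but no usable background / surviving ratio
    return(tibble(gene_id = gene, score = NA_real_, code = "P", value = "P"))
  }
  s <- std$s[std$gene_id == gene]
  tibble(gene_id = gene, score = s, code = NA_character_,
         value = format(s, digits = 3))
}

# classify a vector of cells (numbers or "P"/"ND") as above/below threshold
# under one reading of the ambiguous code P
.cells_above <- function(cells, tau, p_as_above) {
  vapply(cells, function(cell) {
    if (is.na(cell)) {
      abort_ripchip("perturbation cells must be a number, 'P' or 'ND'",
                    "ripchip_validation_error")
    }
    cell <- as.character(cell)
    if (cell == "ND") return(FALSE)    # an undetectable mRNA cannot be enriched
    if (cell == "P") return(p_as_above)
    num <- suppressWarnings(as.numeric(cell))
    if (is.na(num)) {
      abort_ripchip(sprintf("cannot interpret perturbation cell '%s'", cell),
                    "ripchip_validation_error")
    }
    num >= tau
  }, logical(1))
}

.verdict_given <- function(ctrl_above, trt_above) {
  if (all(ctrl_above) && !any(trt_above)) {
    "lost"
  } else if (all(ctrl_above) && all(trt_above)) {
    "retained"
  } else {
    "inconclusive"
  }
}

#' Compare an mRNA's enrichment between two conditions
#'
#' Verdicts require unanimity across replicates, mirroring the every-replicate
#' calling rule:
#'
#' * `"lost"` — enriched (`>= tau`) in every control replicate and in no
#'   treated replicate (the pattern of a cotranslational interaction abolished
#'   by a −ATG mutation or by polysome disassembly);
#' * `"retained"` — enriched in every replicate of both arms;
#' * `"inconclusive"` — anything else, including interactions never enriched
#'   in the control arm. A gained interaction is reported as inconclusive.
#'
#' `"ND"` cells count as below threshold (an undetectable mRNA cannot be
#' enriched). `"P"` cells are ambiguous: the verdict stands only if it is
#' identical with P read as above and as below threshold; otherwise the
#' comparison is inconclusive.
#'
#' @param control_scores Vector of per-replicate cells for the control arm:
#'   numbers, `"P"` or `"ND"`.
#' @param treated_scores Same for the treated arm.
#' @param tau Enrichment threshold in SD units (default 2).
#' @return `"lost"`, `"retained"` or `"inconclusive"`.
#' @examples
#' compare_conditions(c(4.1, 3.8), c("ND", "0.3"))  # "lost"
#' compare_conditions(c(4.1, 3.8), c(3.5, 2.2))     # "retained"
#' @export
compare_conditions <- function(control_scores, treated_scores, tau = 2) {
  if (length(control_scores) == 0 || length(treated_scores) == 0) {
    abort_ripchip("both condition arms need at least one replicate",
                  "ripchip_validation_error")
  }
  v_hi <- .verdict_given(.cells_above(control_scores, tau, TRUE),
                         .cells_above(treated_scores, tau, TRUE))
  v_lo <- .verdict_given(.cells_above(control_scores, tau, FALSE),
                         .cells_above(treated_scores, tau, FALSE))
  if (identical(v_hi, v_lo)) v_hi else "inconclusive"
}

#' Paired raw reference-channel signals for one gene
#'
#' For checking that an untranslatable (−ATG) mRNA is still expressed at
#' wild-type levels: returns the raw total-RNA reference signals of every
#' probe of the gene on both scans, unnormalised and with no QC filtering.
#' Spots are paired by probe ID and occurrence order; the caller judges
#' comparability.
#'
#' @param plus_atg_scan Scan of the wild-type (+ATG) experiment.
#' @param minus_atg_scan Scan of the −ATG experiment.
#' @param gene Gene ID.
#' @param annotation Probe-to-gene annotation tibble.
#' @return Tibble with one row per paired probe occurrence: `probe_id`,
#'   `ref_plus`, `ref_minus`.
#' @export
compare_raw_expression <- function(plus_atg_scan, minus_atg_scan, gene,
                                   annotation) {
  probes <- annotation$probe_id[annotation$gene_id == gene]
  plus_atg_scan <- resolve_channels(plus_atg_scan)
  minus_atg_scan <- resolve_channels(minus_atg_scan)
  take <- function(scan, label) {
    rows <- as_tibble(scan)[scan$probe_id %in% probes,
                            c("probe_id", "ref_signal")]
    if (nrow(rows) == 0) {
      abort_ripchip(
        sprintf("gene '%s' is absent from the %s array design", gene, label),
        "ripchip_gene_not_on_array"
      )
    }
    rows <- rows[order(rows$probe_id), ]
    rows$occurrence <- stats::ave(seq_len(nrow(rows)), rows$probe_id,
                                  FUN = seq_along)
    rows
  }
  p <- take(plus_atg_scan, "+ATG")
  m <- take(minus_atg_scan, "-ATG")
  paired <- dplyr::inner_join(p, m, by = c("probe_id", "occurrence"),
                              suffix = c("_plus", "_minus"))
  tibble(
    probe_id = paired$probe_id,
    ref_plus = paired$ref_signal_plus,
    ref_minus = paired$ref_signal_minus
  )
}

#' Build a perturbation report across conditions
#'
#' Scores each requested mRNA in every scan (one cell per bait, mRNA,
#' condition and replicate; numeric `s`, `"P"` or `"ND"`), then forms
#' lost/retained verdicts for the standard condition pairs: −ATG against
#' control, and puromycin / EDTA against their mock (or control) baseline.
#'
#' @param scans List of `ripchip_scan`s covering the conditions; each scan
#'   carries its own `condition`, `bait_gene` and `experiment_id` metadata.
#' @param genes Character vector of mRNAs to report on.
#' @param annotation Probe-to-gene annotation tibble.
#' @param platform Platform spec; defaults to each scan's own.
#' @param min_background Minimum background size for a numeric score
#'   (default 200).
#' @param tau Enrichment threshold for verdicts (default 2).
#' @return An object of class `ripchip_report`: a list with the `cells` tibble
#'   (`bait`, `mRNA`, `condition`, `replicate`, `value`, `score`, `code`) and
#'   the `verdicts` tibble (`bait`, `mRNA`, `condition_pair`, `verdict`).
#' @export
perturbation_report <- function(scans, genes, annotation, platform = NULL,
                                min_background = 200, tau = 2) {
  if (length(scans) == 0 || length(genes) == 0) {
    abort_ripchip("`scans` and `genes` must be non-empty",
                  "ripchip_validation_error")
  }
  conditions <- vapply(scans, function(s) attr(s, "condition"), character(1))
  cells <- purrr::map_dfr(seq_along(scans), function(i) {
    scan <- scans[[i]]
    replicate <- sum(conditions[seq_len(i)] == conditions[i])
    purrr::map_dfr(genes, function(g) {
      cell <- score_or_code(g, scan, annotation, platform = platform,
                            min_background = min_background)
      tibble(
        bait = attr(scan, "bait_gene"),
        mRNA = g,
        condition = conditions[i],
        replicate = replicate,
        value = cell$value,
        score = cell$score,
        code = cell$code
      )
    })
  })
  pairs <- list(
    minus_atg = c(baseline = "control", treated = "minus_atg"),
    puromycin = c(baseline = "mock", treated = "puromycin"),
    edta = c(baseline = "mock", treated = "edta")
  )
  verdicts <- purrr::map_dfr(names(pairs), function(nm) {
    baseline <- pairs[[nm]][["baseline"]]
    treated <- pairs[[nm]][["treated"]]
    if (!treated %in% cells$condition) return(tibble())
    if (!baseline %in% cells$condition && baseline == "mock") {
      baseline <- "control"  # fall back when no mock arm was run
    }
    if (!baseline %in% cells$condition) return(tibble())
    purrr::map_dfr(unique(cells$mRNA), function(g) {
      ctrl <- cells$value[cells$mRNA == g & cells$condition == baseline]
      trt <- cells$value[cells$mRNA == g & cells$condition == treated]
      tibble(
        bait = cells$bait[1],
        mRNA = g,
        condition_pair = paste0(treated, "_vs_", baseline),
        verdict = compare_conditions(ctrl, trt, tau = tau)
      )
    })
  })
  structure(list(cells = cells, verdicts = verdicts), class = "ripchip_report")
}

#' @export
print.ripchip_report <- function(x, ...) {
  cat(sprintf("<ripchip_report> %d cell(s), %d verdict(s)\n",
              nrow(x$cells), nrow(x$verdicts)))
  if (nrow(x$verdicts) > 0) {
    print(x$verdicts)
  }
  invisible(x)
}
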