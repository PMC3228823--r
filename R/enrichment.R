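#' Per-gene median log10 enrichment ratios
#'
#' For every gene, the enrichment ratio is the median over its surviving
#' probes of `log10(ip_signal / ref_signal)`. Spots with a nonpositive signal
#' in either channel are excluded before the log (never clamped); genes whose
#' spots are all excluded are dropped from the profile and counted. The median
#' of an even number of spots is the mean of the two middle values.
#'
#' If the spots come from a scan whose channels were *not* resolved into
#' sample roles, set `dye_swapped = TRUE` to invert each per-spot ratio before
#' the log. The pipeline resolves channels at read time, so this is normally
#' left `FALSE`.
#'
#' @param spots Tibble of spots with a `gene_id` column (see
#'   [map_probes_to_genes()]). If a `kept` column is present (from
#'   [filter_scan()]) only kept spots are used.
#' @param dye_swapped Invert per-spot ratios (reference over IP) before the
#'   log.
#' @param experiment_id Identifier stored on the profile; defaults to the
#'   scan's.
#' @return A tibble of class `ripchip_profile` with columns `gene_id`, `R`
#'   (median log10 ratio) and `n_probes`, plus attributes `n_genes`,
#'   `n_nonpositive` (excluded spots) and `n_genes_dropped`.
#' @export
gene_log_ratios <- function(spots, dye_swapped = FALSE, experiment_id = NULL) {
  if (!"gene_id" %in% names(spots)) {
    abort_ripchip("`spots` has no 'gene_id' column; run map_probes_to_genes() first",
                  "ripchip_validation_error")
  }
  experiment_id <- experiment_id %||% attr(spots, "experiment_id")
  x <- as_tibble(spots)
  if ("kept" %in% names(x)) {
    x <- x[x$kept, , drop = FALSE]
  }
  genes_in <- unique(x$gene_id)
  usable <- x$ip_signal > 0 & x$ref_signal > 0
  n_nonpositive <- sum(!usable)
  x <- x[usable, , drop = FALSE]
  ratio <- if (isTRUE(dye_swapped)) {
    x$ref_signal / x$ip_signal
  } else {
    x$ip_signal / x$ref_signal
  }
  x$log_ratio <- log10(ratio)
  prof <- dplyr::summarise(
    dplyr::group_by(x, .data$gene_id),
    R = stats::median(.data$log_ratio),
    n_probes = dplyr::n(),
    .groups = "drop"
  )
  n_dropped <- length(setdiff(genes_in, prof$gene_id))
  if (n_dropped > 0) {
    rlang::inform(sprintf(
      "%d gene(s) dropped from profile '%s': all spots had nonpositive signals",
      n_dropped, experiment_id %||% "?"
    ))
  }
  structure(
    prof,
    experiment_id = experiment_id,
    bait_gene = attr(spots, "bait_gene"),
    condition = attr(spots, "condition"),
    n_genes = nrow(prof),
    n_nonpositive = n_nonpositive,
    n_genes_dropped = n_dropped,
    class = c("ripchip_profile", class(prof))
  )
}

#' Standardize an enrichment profile
#'
#' Adds the two score transforms used downstream:
#'
#' * `z = (R - mean(R)) / sd(R)` — the plotting/normalisation scale, with mean
#'   0 and SD 1 by construction;
#' * `s = (R - median(R)) / sd(R)` — the number of standard deviations above
#'   the *median* enrichment of all genes, the selection scale for target
#'   calling.
#'
#' Both use the same sample standard deviation (n − 1 denominator) about the
#' mean, so `s - z` is one constant across genes. A profile whose SD is zero
#' is degenerate and raises a classed error; a profile with fewer genes than
#' `min_background` raises a `ripchip_background_too_small` condition, which
#' the perturbation module converts into the code `"P"`.
#'
#' @param profile A `ripchip_profile` from [gene_log_ratios()].
#' @param min_background Minimum number of genes required to estimate the
#'   background distribution. The primitive defaults to 0 (permissive); the
#'   pipeline and [score_or_code()] use 200.
#' @return The profile with `z` and `s` columns added and attributes `mean_R`,
#'   `median_R`, `sd_R`; classed `ripchip_std_profile`.
#' @export
standardize_profile <- function(profile, min_background = 0) {
  n <- nrow(profile)
  if (n < max(min_background, 2L)) {
    abort_ripchip(
      sprintf("profile has %d gene(s); at least %d required to estimate the background",
              n, max(min_background, 2L)),
      "ripchip_background_too_small"
    )
  }
  mean_R <- mean(profile$R)
  median_R <- stats::median(profile$R)
  sd_R <- stats::sd(profile$R)
  if (sd_R == 0) {
    abort_ripchip("degenerate profile: all enrichment ratios are identical (sd = 0)",
                  "ripchip_degenerate_profile")
  }
  out <- profile
  out$z <- (profile$R - mean_R) / sd_R
  out$s <- (profile$R - median_R) / sd_R
  attr(out, "mean_R") <- mean_R
  attr(out, "median_R") <- median_R
  attr(out, "sd_R") <- sd_R
  class(out) <- unique(c("ripchip_std_profile", class(out)))
  out
}

#' Box-plot summary statistics
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7). Whiskers extend to the most extreme data
#' values within 1.5 times the interquartile range of the quartiles; values
#' beyond the whiskers are reported individually as outliers (the points drawn
#' as circles on the classic enrichment box plots).
#'
#' @param values Numeric vector, at least 2 values.
#' @return A one-row tibble: `lower_whisker`, `lower_quartile`, `median`,
#'   `upper_quartile`, `upper_whisker`, `n`, `n_outliers`, and `outliers`
#'   (list-column of the outlying values).
#' @examples
#' boxplot_stats(1:8)  # quartiles 2.75 and 6.25
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort_ripchip("boxplot_stats() needs at least 2 values",
                  "ripchip_validation_error")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  lower_whisker <- min(inside)
  upper_whisker <- max(inside)
  outliers <- sort(values[values < lower_whisker | values > upper_whisker])
  tibble(
    lower_whisker = lower_whisker,
    lower_quartile = q[1],
    median = q[2],
    upper_quartile = q[3],
    upper_whisker = upper_whisker,
    n = length(values),
    n_outliers = length(outliers),
    outliers = list(outliers)
  )
}

#' One-call enrichment profile from a raw scan
#'
#' Convenience composition of the per-scan steps: resolve dye-swapped
#' channels, apply spot QC, map probes to coding genes, and form median log10
#' ratios.
#'
#' @param scan A `ripchip_scan`.
#' @param annotation Probe-to-gene annotation tibble.
#' @param platform Platform spec; defaults to the scan's own.
#' @return A `ripchip_profile`.
#' @export
enrichment_profile <- function(scan, annotation, platform = NULL) {
  qc <- filter_scan(scan, platform = platform)
  mapped <- map_probes_to_genes(qc, annotation)
  gene_log_ratios(mapped)
}
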