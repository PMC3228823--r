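#' Call enriched genes in one replicate
#'
#' A gene is called enriched when its SD-above-median score meets the
#' threshold: `s >= tau` (inclusive — "at least" tau standard deviations above
#' the median enrichment of all genes). The default `tau = 2`.
#'
#' @param profile A `ripchip_std_profile` from [standardize_profile()].
#' @param tau Threshold in SD units, > 0.
#' @return Sorted character vector of enriched gene IDs.
#' @export
call_enriched <- function(profile, tau = 2) {
  if (!"s" %in% names(profile)) {
    abort_ripchip("`profile` has no 's' column; run standardize_profile() first",
                  "ripchip_validation_error")
  }
  if (!is_number(tau) || tau <= 0) {
    abort_ripchip("`tau` must be a single positive number", "ripchip_validation_error")
  }
  sort(unique(profile$gene_id[profile$s >= tau]))
}

#' Intersect per-replicate calls and remove blacklisted contaminants
#'
#' Only genes that pass the threshold in *every* independent biological
#' replicate enter the consensus; known unspecific contaminants are then
#' subtracted. When the consensus of a single-replicate experiment contains a
#' non-bait gene, a warning is raised: calls of mRNAs other than the bait's
#' own are expected to rest on at least two replicates.
#'
#' @param call_sets List of per-replicate character vectors of called genes.
#' @param blacklist Character vector of contaminant gene IDs.
#' @param bait_gene Optional bait gene ID (enables the single-replicate
#'   warning).
#' @return A tibble of class `ripchip_support` over the union of called genes,
#'   with columns `gene_id`, `n_called`, `replicate_support` (e.g. `"2/3"`),
#'   `blacklisted`, `in_consensus`; the consensus itself is stored in the
#'   `"consensus"` attribute (see [consensus_genes()]).
#' @export
intersect_replicates <- function(call_sets, blacklist = character(),
                                 bait_gene = NULL) {
  if (!is.list(call_sets) || length(call_sets) == 0) {
    abort_ripchip("`call_sets` must be a non-empty list of per-replicate gene sets",
                  "ripchip_validation_error")
  }
  call_sets <- lapply(call_sets, function(x) unique(as.character(x)))
  k <- length(call_sets)
  all_genes <- sort(unique(unlist(call_sets)))
  n_called <- vapply(
    all_genes,
    function(g) sum(vapply(call_sets, function(s) g %in% s, logical(1))),
    integer(1)
  )
  blacklisted <- all_genes %in% blacklist
  in_consensus <- n_called == k & !blacklisted
  consensus <- all_genes[in_consensus]
  if (k == 1 && !is.null(bait_gene) && any(consensus != bait_gene)) {
    rlang::warn(
      sprintf("consensus for bait '%s' contains non-bait gene(s) supported by a single replicate",
              bait_gene),
      class = "ripchip_single_replicate_warning"
    )
  }
  out <- tibble(
    gene_id = all_genes,
    n_called = n_called,
    replicate_support = sprintf("%d/%d", n_called, k),
    blacklisted = blacklisted,
    in_consensus = in_consensus
  )
  structure(out,
            consensus = consensus,
            k = k,
            class = c("ripchip_support", class(out)))
}

#' Extract the consensus gene set
#'
#' @param x A `ripchip_support` (from [intersect_replicates()]) or a
#'   `ripchip_callset`.
#' @return Character vector of consensus gene IDs.
#' @export
consensus_genes <- function(x) {
  if (inherits(x, "ripchip_callset")) {
    return(x$consensus)
  }
  attr(x, "consensus")
}

#' Classify a bait by its consensus
#'
#' `"empty"` — the bait co-purified no mRNA specifically; `"bait_only"` — only
#' its own (cognate) mRNA; `"targets"` — at least one non-cognate mRNA.
#'
#' @param consensus Character vector of consensus gene IDs.
#' @param bait_gene Gene ID of the bait's cognate mRNA.
#' @return One of `"empty"`, `"bait_only"`, `"targets"`.
#' @export
classify_bait <- function(consensus, bait_gene) {
  consensus <- unique(consensus)
  if (length(consensus) == 0) {
    "empty"
  } else if (all(consensus == bait_gene)) {
    "bait_only"
  } else {
    "targets"
  }
}

#' Expected false-positive fraction after replicate intersection
#'
#' Under a normal background, a per-replicate false-positive fraction `p`
#' (about 0.05 at the 2-SD threshold) drops to `p^k` when a gene must pass in
#' each of `k` independent replicates: 2.5e-3 at k = 2, down to 6.25e-6 at
#' k = 4. Vectorised over `k`.
#'
#' @param p Per-replicate false-positive fraction in \[0, 1\].
#' @param k Number of independent biological replicates, >= 1.
#' @return `p^k`.
#' @examples
#' expected_false_positive_fraction(0.05, k = 2)  # 0.0025
#' @export
expected_false_positive_fraction <- function(p = 0.05, k) {
  if (!is_number(p) || p < 0 || p > 1) {
    abort_ripchip("`p` must be a single number in [0, 1]", "ripchip_validation_error")
  }
  if (!is.numeric(k) || any(k < 1) || any(k != round(k))) {
    abort_ripchip("`k` must be integer(s) >= 1", "ripchip_validation_error")
  }
  p^k
}

#' Derive a contaminant blacklist from calls across unrelated baits
#'
#' mRNAs that co-purify with many unrelated baits are unspecific contaminants.
#' A gene enters the blacklist when it was called enriched for at least
#' `min_fraction` of the baits *unrelated* to it; a bait's cognate mRNA is
#' exempt for its own bait's experiments (self-enrichment via the nascent
#' chain is the expected biology, not contamination).
#'
#' @param call_sets Named list: one per-bait called gene set (pre-blacklist
#'   consensus), names are the baits' cognate gene IDs.
#' @param min_baits Minimum number of distinct baits required (default 4).
#' @param min_fraction Fraction of unrelated baits that must call the gene
#'   (default 0.5).
#' @return Character vector of blacklisted gene IDs.
#' @export
derive_contaminant_blacklist <- function(call_sets, min_baits = 4,
                                         min_fraction = 0.5) {
  if (!is.list(call_sets) || is.null(names(call_sets)) ||
      any(!nzchar(names(call_sets)))) {
    abort_ripchip("`call_sets` must be a named list (names = bait cognate gene IDs)",
                  "ripchip_validation_error")
  }
  baits <- names(call_sets)
  if (length(unique(baits)) < min_baits) {
    abort_ripchip(
      sprintf("blacklist derivation needs at least %d distinct baits; got %d",
              min_baits, length(unique(baits))),
      "ripchip_validation_error"
    )
  }
  genes <- sort(unique(unlist(call_sets)))
  blacklisted <- vapply(genes, function(g) {
    unrelated <- baits[baits != g]
    if (length(unrelated) == 0) return(FALSE)
    hits <- sum(vapply(unrelated, function(b) g %in% call_sets[[b]], logical(1)))
    hits / length(unrelated) >= min_fraction
  }, logical(1))
  genes[blacklisted]
}

#' Fraction of baits with non-cognate targets
#'
#' @param categories Character vector of per-bait categories (`"empty"`,
#'   `"bait_only"`, `"targets"`).
#' @return Percentage: `100 * #targets / #baits`.
#' @examples
#' summarize_fraction_with_targets(rep(c("empty", "bait_only", "targets"), c(10, 9, 12)))
#' @export
summarize_fraction_with_targets <- function(categories) {
  categories <- as.character(categories)
  if (length(categories) == 0) {
    abort_ripchip("`categories` must be non-empty", "ripchip_validation_error")
  }
  bad <- setdiff(unique(categories), c("empty", "bait_only", "targets"))
  if (length(bad) > 0) {
    abort_ripchip(sprintf("unknown category: %s", bad[1]),
                  "ripchip_validation_error")
  }
  100 * sum(categories == "targets") / length(categories)
}

#' Per-bait category summary
#'
#' @param categories Character vector of per-bait categories.
#' @return Tibble with one row per category (`category`, `n`) and the
#'   percentage of baits with targets as attribute `pct_targets`.
#' @export
summarize_categories <- function(categories) {
  counts <- table(factor(categories, levels = c("empty", "bait_only", "targets")))
  out <- tibble(category = names(counts), n = as.integer(counts))
  attr(out, "pct_targets") <- summarize_fraction_with_targets(categories)
  out
}

#' End-to-end target calling for one bait
#'
#' Runs the full per-replicate pipeline (channel resolution, spot QC, probe
#' mapping, median log10 ratios, standardization, thresholding) on each scan,
#' intersects the per-replicate calls, removes blacklisted contaminants,
#' classifies the bait and attaches the `p^k` false-positive estimate.
#'
#' @param scans List of `ripchip_scan` replicates for one bait.
#' @param annotation Probe-to-gene annotation tibble.
#' @param blacklist Character vector of contaminant gene IDs.
#' @param platform Platform spec; defaults to each scan's own.
#' @param tau Calling threshold in SD units (default 2).
#' @param p Assumed per-replicate false-positive fraction (default 0.05).
#' @param min_background Minimum profile size passed to
#'   [standardize_profile()] (default 200).
#' @return An object of class `ripchip_callset`: a list with `bait_gene`,
#'   `category`, `consensus`, `support` (per-gene replicate support),
#'   `replicate_sets`, `params`, `fp_expected` and the tidy `calls` table.
#' @seealso [tidy.ripchip_callset()], [glance.ripchip_callset()]
#' @export
call_targets <- function(scans, annotation, blacklist = character(),
                         platform = NULL, tau = 2, p = 0.05,
                         min_background = 200) {
  if (!is.list(scans) || length(scans) == 0) {
    abort_ripchip("`scans` must be a non-empty list of replicate scans",
                  "ripchip_validation_error")
  }
  bait_gene <- attr(scans[[1]], "bait_gene")
  profiles <- lapply(scans, function(scan) {
    standardize_profile(
      enrichment_profile(scan, annotation, platform = platform),
      min_background = min_background
    )
  })
  sets <- lapply(profiles, call_enriched, tau = tau)
  support <- intersect_replicates(sets, blacklist = blacklist,
                                  bait_gene = bait_gene)
  consensus <- consensus_genes(support)
  category <- classify_bait(consensus, bait_gene)
  k <- length(scans)
  # mean s across the replicates in which the gene was profiled
  s_by_rep <- dplyr::bind_rows(lapply(profiles, function(pr) {
    tibble(gene_id = pr$gene_id, s = pr$s)
  }))
  mean_s <- dplyr::summarise(dplyr::group_by(s_by_rep, .data$gene_id),
                             mean_s = mean(.data$s), .groups = "drop")
  calls <- tibble(gene_id = consensus)
  calls <- dplyr::left_join(calls, mean_s, by = "gene_id")
  calls <- dplyr::left_join(
    calls, support[, c("gene_id", "replicate_support")], by = "gene_id"
  )
  calls <- tibble(
    bait = bait_gene,
    gene_id = calls$gene_id,
    replicate_support = calls$replicate_support,
    mean_s = calls$mean_s,
    is_bait_mrna = as.integer(calls$gene_id == bait_gene),
    category = category
  )
  structure(
    list(
      bait_gene = bait_gene,
      category = category,
      consensus = consensus,
      support = support,
      replicate_sets = sets,
      params = list(tau = tau, p = p, k = k,
                    min_background = min_background),
      fp_expected = expected_false_positive_fraction(p, k),
      calls = calls
    ),
    class = "ripchip_callset"
  )
}

#' @export
print.ripchip_callset <- function(x, ...) {
  cat(sprintf(
    "<ripchip_callset> bait %s: category '%s', %d consensus gene(s) over %d replicate(s); expected FP fraction %.3g\n",
    x$bait_gene, x$category, length(x$consensus), x$params$k, x$fp_expected
  ))
  if (length(x$consensus) > 0) {
    cat("  consensus:", paste(x$consensus, collapse = ", "), "\n")
  }
  invisible(x)
}
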