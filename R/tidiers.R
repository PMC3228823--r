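#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a call set
#'
#' One row per consensus gene with the calls schema (`bait`, `gene_id`,
#' `replicate_support`, `mean_s`, `is_bait_mrna`, `category`).
#'
#' @param x A `ripchip_callset`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ripchip_callset <- function(x, ...) {
  x$calls
}

#' One-row summary of a call set
#'
#' @param x A `ripchip_callset`.
#' @param ... Unused.
#' @return A tibble with `bait`, `category`, `n_consensus`, `k`, `tau`, `p`,
#'   `fp_expected`.
#' @export
glance.ripchip_callset <- function(x, ...) {
  tibble(
    bait = x$bait_gene,
    category = x$category,
    n_consensus = length(x$consensus),
    k = x$params$k,
    tau = x$params$tau,
    p = x$params$p,
    fp_expected = x$fp_expected
  )
}

#' Tidy a perturbation report
#'
#' @param x A `ripchip_report`.
#' @param ... Unused.
#' @return The per-cell tibble (`bait`, `mRNA`, `condition`, `replicate`,
#'   `value`, `score`, `code`).
#' @export
tidy.ripchip_report <- function(x, ...) {
  x$cells
}

#' Verdict summary of a perturbation report
#'
#' @param x A `ripchip_report`.
#' @param ... Unused.
#' @return One row per condition pair with counts of lost / retained /
#'   inconclusive mRNAs.
#' @export
glance.ripchip_report <- function(x, ...) {
  if (is.null(x$verdicts) || nrow(x$verdicts) == 0) {
    return(tibble(condition_pair = character(), lost = integer(),
                  retained = integer(), inconclusive = integer()))
  }
  counts <- dplyr::count(x$verdicts, .data$condition_pair, .data$verdict)
  wide <- tidyr::pivot_wider(counts, names_from = "verdict",
                             values_from = "n", values_fill = 0L)
  for (col in c("lost", "retained", "inconclusive")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  wide[, c("condition_pair", "lost", "retained", "inconclusive")]
}
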