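#' Platform-specific spot-quality thresholds
#'
#' A RIP-chip spot is kept when enough of its foreground pixels rise above the
#' local background (median background + 2 SD) in both channels, or when the
#' immunoprecipitate (IP) channel alone is almost fully above background. The
#' two array platforms used in the field carry different thresholds:
#'
#' * `"pcr"` (PCR-spotted arrays): 55% of pixels in the IP channel and 90% in
#'   the total-RNA reference channel, or at least 90% in the IP channel alone.
#' * `"agilent"` (oligonucleotide arrays): 70%, 98% and 98%, respectively.
#'
#' The stand-alone IP threshold doubles as the operational definition of
#' "detectable in the immunoprecipitate" used for ND coding in perturbation
#' reports (see [score_or_code()]).
#'
#' @param name `"pcr"`, `"agilent"`, or `"custom"` (requires all three
#'   thresholds).
#' @param min_frac_ip Minimum fraction of above-background pixels in the IP
#'   channel (first clause).
#' @param min_frac_ref Minimum fraction in the total-RNA reference channel
#'   (first clause).
#' @param min_frac_ip_alone Stand-alone IP rescue threshold (second clause);
#'   must be at least `min_frac_ip`.
#'
#' @return An object of class `ripchip_platform`: a named list with fields
#'   `name`, `min_frac_ip`, `min_frac_ref`, `min_frac_ip_alone`.
#' @examples
#' platform_spec("pcr")
#' platform_spec("custom", 0.6, 0.95, 0.95)
#' @export
platform_spec <- function(name = c("pcr", "agilent", "custom"),
                          min_frac_ip = NULL,
                          min_frac_ref = NULL,
                          min_frac_ip_alone = NULL) {
  name <- match.arg(name)
  defaults <- list(
    pcr     = c(0.55, 0.90, 0.90),
    agilent = c(0.70, 0.98, 0.98)
  )
  if (name %in% names(defaults)) {
    d <- defaults[[name]]
    min_frac_ip <- min_frac_ip %||% d[[1]]
    min_frac_ref <- min_frac_ref %||% d[[2]]
    min_frac_ip_alone <- min_frac_ip_alone %||% d[[3]]
  }
  vals <- list(
    min_frac_ip = min_frac_ip,
    min_frac_ref = min_frac_ref,
    min_frac_ip_alone = min_frac_ip_alone
  )
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (is.null(v) || !is_number(v) || v < 0 || v > 1) {
      abort_ripchip(
        sprintf("`%s` must be a single number in [0, 1]", nm),
        "ripchip_invalid_platform"
      )
    }
  }
  if (min_frac_ip > min_frac_ip_alone) {
    abort_ripchip(
      "`min_frac_ip` must not exceed `min_frac_ip_alone` (the stand-alone IP clause is the stricter rescue rule)",
      "ripchip_invalid_platform"
    )
  }
  structure(
    list(
      name = name,
      min_frac_ip = min_frac_ip,
      min_frac_ref = min_frac_ref,
      min_frac_ip_alone = min_frac_ip_alone
    ),
    class = "ripchip_platform"
  )
}

#' Coerce to a platform specification
#'
#' @param x A `ripchip_platform` object or a platform name understood by
#'   [platform_spec()].
#' @return A `ripchip_platform` object.
#' @export
as_platform <- function(x) {
  if (inherits(x, "ripchip_platform")) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    return(platform_spec(x))
  }
  abort_ripchip("cannot interpret `x` as a platform specification",
                "ripchip_invalid_platform")
}

#' @export
print.ripchip_platform <- function(x, ...) {
  cat(sprintf(
    "<ripchip platform '%s'>  IP >= %.2f & ref >= %.2f, or IP alone >= %.2f\n",
    x$name, x$min_frac_ip, x$min_frac_ref, x$min_frac_ip_alone
  ))
  invisible(x)
}
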