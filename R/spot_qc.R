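#' Does a spot pass the platform's quality filter?
#'
#' A spot is kept when its fraction of foreground pixels above background
#' (median local background + 2 SD) meets the platform thresholds in both
#' channels, or when the IP channel alone meets the stricter stand-alone
#' threshold:
#'
#' \deqn{pass \iff (f_{IP} \ge m_{IP} \wedge f_{ref} \ge m_{ref}) \vee
#'       (f_{IP} \ge m_{IP,alone})}
#'
#' Comparisons are inclusive ("a minimum of 55%" includes 55%). Vectorised
#' over spots.
#'
#' @param ip_frac_above_bg Fraction of above-background pixels in the IP
#'   channel, in \[0, 1\].
#' @param ref_frac_above_bg Same for the total-RNA reference channel.
#' @param platform Platform spec or name (see [platform_spec()]).
#' @return Logical vector: `TRUE` where the spot passes.
#' @examples
#' spot_passes_qc(0.60, 0.95, "pcr")  # TRUE: both clauses of the joint rule
#' spot_passes_qc(0.92, 0.10, "pcr")  # TRUE: stand-alone IP rescue
#' spot_passes_qc(0.50, 0.95, "pcr")  # FALSE
#' @export
spot_passes_qc <- function(ip_frac_above_bg, ref_frac_above_bg,
                           platform = platform_spec("pcr")) {
  platform <- as_platform(platform)
  fr <- c(ip_frac_above_bg, ref_frac_above_bg)
  if (any(!is.finite(fr)) || any(fr < 0 | fr > 1)) {
    abort_ripchip("pixel fractions must be finite and lie in [0, 1]",
                  "ripchip_validation_error")
  }
  (ip_frac_above_bg >= platform$min_frac_ip &
     ref_frac_above_bg >= platform$min_frac_ref) |
    (ip_frac_above_bg >= platform$min_frac_ip_alone)
}

#' Apply spot quality control to a whole scan
#'
#' Scanner-flagged spots (`flag < 0`) are dropped before the pixel-fraction
#' rule is applied. Every spot receives:
#'
#' * `kept` — passed QC;
#' * `reason` — for removed spots, one of `"flagged"`, `"low_ip_frac"`,
#'   `"low_ref_frac"` in that fixed precedence; `NA` for kept spots;
#' * `ip_detectable` — the spot meets the stand-alone IP threshold. This is
#'   recorded for every spot regardless of pass/fail: it operationalises
#'   "detectable in the immunoprecipitate" for ND coding downstream.
#'
#' Dye-swapped scans are channel-resolved first so the per-channel thresholds
#' apply to the correct samples. Kept and removed spots partition the input.
#'
#' @param scan A `ripchip_scan`.
#' @param platform Platform spec; defaults to the scan's own.
#' @return The scan with columns `kept`, `reason`, `ip_detectable` added,
#'   classed `ripchip_qc`.
#' @export
filter_scan <- function(scan, platform = NULL) {
  if (nrow(scan) == 0) {
    abort_ripchip("cannot run QC on an empty scan", "ripchip_validation_error")
  }
  platform <- as_platform(platform %||% attr(scan, "platform") %||% "pcr")
  scan <- resolve_channels(scan)
  pass <- spot_passes_qc(scan$ip_frac_above_bg, scan$ref_frac_above_bg, platform)
  flagged <- scan$flag < 0
  kept <- !flagged & pass
  reason <- rep(NA_character_, nrow(scan))
  reason[!kept & flagged] <- "flagged"
  reason[!kept & !flagged & scan$ip_frac_above_bg < platform$min_frac_ip] <- "low_ip_frac"
  reason[!kept & !flagged & is.na(reason)] <- "low_ref_frac"
  out <- scan
  out$kept <- kept
  out$reason <- reason
  out$ip_detectable <- scan$ip_frac_above_bg >= platform$min_frac_ip_alone
  out <- restore_scan_attrs(out, scan)
  class(out) <- unique(c("ripchip_qc", class(out)))
  out
}

#' Spots that survived quality control
#'
#' @param qc Output of [filter_scan()].
#' @return The kept rows only.
#' @export
qc_kept <- function(qc) {
  if (!"kept" %in% names(qc)) {
    abort_ripchip("`qc` has no 'kept' column; run filter_scan() first",
                  "ripchip_validation_error")
  }
  restore_scan_attrs(qc[qc$kept, , drop = FALSE], qc)
}
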