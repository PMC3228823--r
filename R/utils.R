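# internal helpers shared across modules

#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

# closed vocabulary of experimental conditions
.ripchip_conditions <- c("control", "minus_atg", "puromycin", "edta", "mock")

abort_ripchip <- function(msg, class) {
  rlang::abort(msg, class = c(class, "ripchip_error"))
}

check_condition <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% .ripchip_conditions) {
    abort_ripchip(
      sprintf(
        "`condition` must be one of: %s",
        paste(.ripchip_conditions, collapse = ", ")
      ),
      "ripchip_invalid_condition"
    )
  }
  condition
}

# carry scan-level metadata through dplyr verbs that strip attributes
.scan_attr_names <- c(
  "experiment_id", "bait_gene", "platform", "dye_swapped",
  "condition", "channels_resolved"
)

restore_scan_attrs <- function(x, from) {
  for (a in .scan_attr_names) {
    attr(x, a) <- attr(from, a)
  }
  if (!inherits(x, "ripchip_scan")) {
    class(x) <- c("ripchip_scan", class(x))
  }
  x
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
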