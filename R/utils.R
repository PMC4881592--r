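#' Round half away from zero
#'
#' Base `round()` rounds half to even; published tables in this field are
#' conventionally rounded half-up (0.4285... -> 0.429). Used for report
#' display and for comparisons at printed precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() without the call, with sprintf-style formatting
mpm_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

mpm_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# informational logging to stderr (pipeline stages, exclusions, saturation)
mpm_log <- function(fmt, ...) message(sprintf(fmt, ...))

# collapse a character vector for error messages
mpm_join <- function(x, sep = ", ") paste(x, collapse = sep)
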