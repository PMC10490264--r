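# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Base R's \code{round} uses banker's rounding; summary tables here follow
#' the half-up convention so printed percentages match conventional
#' two-decimal reporting.
#' @param x numeric vector (non-negative).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# deterministic sub-stream seeds derived from one master seed; kept within
# 32-bit integer range
deriveSeed <- function(seed, stage) {
  s <- (as.numeric(seed) + stage * 99991) %% 2147483647
  as.integer(max(1, s))
}

# canonical study vocabulary (overridable wherever it is consumed)
.GENOTYPES <- c("parentA", "parentD", "Mix", "EUP", "X190")
.CONDITIONS <- c("mock-2d", "PEG6000-2d", "mock-5d", "NaCl-5d")
.SUBGENOMES <- c("A", "D")
.UNPLACED <- "unplaced"
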