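#' Round half away from zero
#'
#' Report-style rounding: 0.5 always rounds away from zero, unlike base
#' [round()] which rounds half to even. Used wherever tables are formatted
#' to the precision conventional in fermentation reports (1 decimal).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-away-from-zero.
#' @examples
#' round_half_up(0.15, 1)  # 0.2
#' round(0.15, 1)          # 0.1 or 0.2 depending on representation
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# deterministic per-stage seed derived from one config seed; keeps stages
# reproducible under partial re-runs
stage_seed <- function(seed, stage) {
  offsets <- c(design = 11L, gas = 101L, bags = 211L, effluent = 307L,
               panels = 401L, community = 503L, truth = 601L)
  if (!stage %in% names(offsets)) stop("unknown seed substream: ", stage)
  (as.integer(seed) %% 20000000L) * 97L + offsets[[stage]]
}

# lognormal multiplier with mean 1 and coefficient of variation cv
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
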