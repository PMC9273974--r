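#' Reported treatment means of the reference seaweed Rusitec study
#'
#' Treatment-level means from a 14-day, two-run Rusitec experiment testing
#' *Ascophyllum nodosum* and *Fucus vesiculosus* at 2.5% and 5% DM
#' inclusion in a total mixed ration. These serve two roles: default
#' setpoints for the synthetic-data generator (so simulated outputs are
#' magnitude-realistic) and inputs to derived summaries such as percent
#' reductions and VFA totals. They are measured quantities, not outputs the
#' package can re-derive.
#'
#' @return list of data.frames:
#' \describe{
#'   \item{gas}{`treatment`, `total_gas` (mL/d), `ch4_pct` (% of total
#'     gas, days 7-13), `ch4_per_om` (mL CH4 per g degraded OM, days 7-12).}
#'   \item{degradation}{`treatment`, percent degraded `dm`, `om`, `cp`,
#'     `adfom`, `andfom` (days 7-12), and `emps` (g microbial CP per kg
#'     degraded OM, days 7-13).}
#'   \item{effluent}{`treatment`, daily productions in mmol/d: `nh3_n`,
#'     `acetate`, `propionate`, `isobutyrate`, `butyrate`, `isovalerate`,
#'     `valerate`, printed `vfa_total` and acetate:propionate `c2c3`.}
#' }
#' @export
rusitec_reference_means <- function() {
  trt <- c("TMR", "AN2.5", "AN5", "FV2.5", "FV5")
  list(
    gas = data.frame(
      treatment = trt,
      total_gas = c(1386, 1238, 1114, 1177, 1114),
      ch4_pct = c(16.9, 16.6, 15.4, 16.6, 16.3),
      ch4_per_om = c(36.7, 35.1, 30.5, 35.9, 32.6),
      stringsAsFactors = FALSE),
    degradation = data.frame(
      treatment = trt,
      dm = c(44.8, 41.2, 39.5, 40.4, 37.7),
      om = c(44.3, 40.7, 39.2, 40.0, 37.3),
      cp = c(39.5, 30.6, 25.7, 30.4, 25.1),
      adfom = c(14.0, 11.5, 8.5, 11.1, 9.7),
      andfom = c(24.7, 21.8, 18.7, 20.5, 18.9),
      emps = c(120, 109, 100, 110, 100),
      stringsAsFactors = FALSE),
    effluent = data.frame(
      treatment = trt,
      nh3_n = c(5.40, 3.39, 2.73, 3.42, 2.84),
      acetate = c(19.7, 17.3, 16.4, 16.7, 15.4),
      propionate = c(7.00, 6.56, 6.57, 6.83, 6.78),
      isobutyrate = c(0.40, 0.28, 0.26, 0.27, 0.26),
      butyrate = c(7.85, 5.27, 5.86, 5.35, 5.39),
      isovalerate = c(1.40, 0.82, 0.89, 0.77, 0.89),
      valerate = c(3.08, 2.29, 2.97, 2.45, 2.98),
      vfa_total = c(39.3, 32.5, 32.9, 32.4, 31.7),
      c2c3 = c(2.86, 2.63, 2.47, 2.42, 2.25),
      stringsAsFactors = FALSE)
  )
}
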