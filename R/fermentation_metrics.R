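#' Nutrient degradation of a feed bag
#'
#' Degradation is the input-output difference relative to input,
#' expressed as a percentage of the nutrient mass placed in the bag.
#'
#' @param input_mass,output_mass nutrient masses (mg) entering and
#'   leaving a 48-h feed bag (or pooled over bags).
#' @return percent degraded, `100 * (input - output) / input`. Negative
#'   values (output above input, e.g. microbial contamination of the
#'   residue) are returned with a warning.
#' @export
degradation <- function(input_mass, output_mass) {
  if (any(input_mass <= 0))
    stop("undefined-input error: degradation needs input_mass > 0")
  out <- 100 * (input_mass - output_mass) / input_mass
  if (any(out < 0))
    warning("negative degradation (output exceeds input); value flagged, not dropped")
  out
}

#' Per-fermenter and per-treatment gas and methane means
#'
#' Arithmetic means over the available days of the span are formed per
#' fermenter first; treatment means are then means over fermenters
#' (day -> fermenter -> treatment hierarchy, matching pooling by the
#' fermenter). CH4 volume is same-day total gas times the same-day
#' fraction.
#'
#' @param gas fermenter-day records (columns `fermenter`, `day`,
#'   `total_gas` mL/d, `ch4_fraction` % of total gas).
#' @param design optional design table; when given, treatment means are
#'   attached as the `"treatment_means"` attribute.
#' @param span days to average over (default sampling days 7-13).
#' @return data.frame per fermenter: `total_gas` (mL/d), `ch4_pct` (%),
#'   `ch4_ml` (mL CH4/d), `n_days` available cases.
#' @export
methane_summary <- function(gas, design = NULL, span = 7:13) {
  if (!length(span)) stop("empty span")
  g <- gas[gas$day %in% span, , drop = FALSE]
  if (!nrow(g)) stop("no gas records inside the requested span")
  g$ch4_ml <- g$total_gas * g$ch4_fraction / 100
  agg <- stats::aggregate(g[c("total_gas", "ch4_fraction", "ch4_ml")],
                          by = list(fermenter = g$fermenter),
                          FUN = mean, na.rm = TRUE)
  names(agg)[names(agg) == "ch4_fraction"] <- "ch4_pct"
  agg$n_days <- stats::aggregate(g$day, by = list(g$fermenter),
                                 FUN = length)$x
  if (!is.null(design)) {
    m <- merge(agg, design[c("fermenter", "treatment")], by = "fermenter")
    tm <- stats::aggregate(m[c("total_gas", "ch4_pct", "ch4_ml")],
                           by = list(treatment = m$treatment), FUN = mean)
    attr(agg, "treatment_means") <- tm
  }
  agg
}

#' Methane production per gram of degraded organic matter
#'
#' @param mean_ch4_volume mean CH4 production, mL/d.
#' @param degraded_om degraded organic matter, g/d.
#' @return mL CH4 per g degraded OM.
#' @export
ch4_per_degraded_om <- function(mean_ch4_volume, degraded_om) {
  if (any(degraded_om <= 0)) stop("degraded OM must be > 0")
  mean_ch4_volume / degraded_om
}

#' Daily effluent production of an analyte
#'
#' Relates an analyzed concentration to the daily measured effluent
#' amount.
#'
#' @param concentration mmol/L.
#' @param effluent_volume L/d.
#' @return mmol/d.
#' @export
daily_production <- function(concentration, effluent_volume) {
  if (any(concentration < 0) || any(effluent_volume < 0))
    stop("concentration and effluent volume must be non-negative")
  concentration * effluent_volume
}

vfa_analytes <- c("acetate", "propionate", "isobutyrate", "butyrate",
                  "isovalerate", "valerate")

#' Total volatile fatty acid production
#'
#' Sum of the six individual VFA productions (acetate through valerate);
#' ammonia-N is not a VFA and is excluded. Summation order is fixed
#' (acetate first) so the total is reproducible.
#'
#' @param productions named numeric vector (or 1-row data.frame) of daily
#'   productions in mmol/d; must contain all six VFA names.
#' @return total VFA, mmol/d.
#' @export
total_vfa <- function(productions) {
  if (is.data.frame(productions)) productions <- unlist(productions[1, ])
  missing <- setdiff(vfa_analytes, names(productions))
  if (length(missing))
    stop("missing VFA analyte(s): ", paste(missing, collapse = ", "))
  sum(productions[vfa_analytes])
}

#' Acetate-to-propionate ratio (mean of daily ratios)
#'
#' The C2:C3 ratio is computed per fermenter-day and then averaged; this
#' is not the ratio of the mean productions (Jensen's inequality makes
#' the two differ whenever days vary).
#'
#' @param acetate,propionate daily productions (mmol/d), matched by day.
#' @return mean of the daily ratios. Days with zero propionate are
#'   excluded with a warning.
#' @export
acetate_propionate_ratio <- function(acetate, propionate) {
  if (length(acetate) != length(propionate))
    stop("acetate and propionate series must be matched by day")
  zero <- propionate <= 0
  if (any(zero)) {
    warning(sum(zero), " day(s) with zero propionate excluded from C2:C3")
    acetate <- acetate[!zero]
    propionate <- propionate[!zero]
  }
  if (!length(acetate)) stop("no valid days for C2:C3")
  mean(acetate / propionate)
}

#' Percent reduction of a treatment mean relative to control
#'
#' @param control_mean,treatment_mean trait means; control must be > 0.
#' @return `100 * (control - treatment) / control`.
#' @seealso [percent_retained()]
#' @export
percent_reduction <- function(control_mean, treatment_mean) {
  if (any(control_mean <= 0)) stop("control mean must be > 0")
  100 * (control_mean - treatment_mean) / control_mean
}

#' Percent of the control mean retained under treatment
#'
#' Complement of [percent_reduction()]; the two always sum to 100.
#' @inheritParams percent_reduction
#' @return `100 * treatment / control`.
#' @export
percent_retained <- function(control_mean, treatment_mean) {
  if (any(control_mean <= 0)) stop("control mean must be > 0")
  100 * treatment_mean / control_mean
}

#' Pooled nutrient degradation per fermenter
#'
#' Feed bags removed within the degradation span are pooled by fermenter
#' (masses summed per nutrient) before computing the degraded fraction,
#' matching the pooling of dried bags in the reference workflow.
#'
#' @param bags long bag records (`fermenter`, `day_in`, `day_out`,
#'   `nutrient`, `mass_in`, `mass_out` in mg).
#' @param design optional design; attaches treatment means as the
#'   `"treatment_means"` attribute.
#' @param span removal days pooled (default 7-12).
#' @return data.frame `fermenter`, `nutrient`, `mass_in`, `mass_out`
#'   (mg pooled), `degraded_pct`.
#' @export
degradation_summary <- function(bags, design = NULL, span = 7:12) {
  b <- bags[bags$day_out %in% span, , drop = FALSE]
  if (!nrow(b)) stop("no feed bags removed inside the requested span")
  agg <- stats::aggregate(b[c("mass_in", "mass_out")],
                          by = b[c("fermenter", "nutrient")], FUN = sum)
  agg$degraded_pct <- degradation(agg$mass_in, agg$mass_out)
  if (!is.null(design)) {
    m <- merge(agg, design[c("fermenter", "treatment")], by = "fermenter")
    tm <- stats::aggregate(list(degraded_pct = m$degraded_pct),
                           by = m[c("treatment", "nutrient")], FUN = mean)
    attr(agg, "treatment_means") <- tm
  }
  agg
}

#' Per-fermenter effluent metabolite summary
#'
#' Converts analyzed concentrations to daily productions using the
#' same-day effluent volume, averages days within fermenter, and derives
#' total VFA and the C2:C3 ratio (mean of daily ratios).
#'
#' @param effluent long records (`fermenter`, `day`, `analyte`,
#'   `concentration` in mmol/L).
#' @param gas fermenter-day records providing `effluent_volume` (L/d).
#' @param design optional design; attaches treatment means attribute.
#' @param span days averaged (default 7-13).
#' @return data.frame, one row per fermenter: mean daily production of
#'   each analyte (mmol/d), `vfa_total`, `c2c3`.
#' @export
effluent_summary <- function(effluent, gas, design = NULL, span = 7:13) {
  e <- effluent[effluent$day %in% span, , drop = FALSE]
  if (!nrow(e)) stop("no effluent records inside the requested span")
  e <- merge(e, gas[c("fermenter", "day", "effluent_volume")],
             by = c("fermenter", "day"))
  e$production <- daily_production(e$concentration, e$effluent_volume)
  wide <- stats::reshape(e[c("fermenter", "day", "analyte", "production")],
                         idvar = c("fermenter", "day"),
                         timevar = "analyte", direction = "wide")
  names(wide) <- sub("^production\\.", "", names(wide))
  analytes <- setdiff(names(wide), c("fermenter", "day"))
  per_day_ratio <- wide$acetate / wide$propionate
  means <- stats::aggregate(wide[analytes],
                            by = list(fermenter = wide$fermenter), FUN = mean)
  means$vfa_total <- apply(means[, vfa_analytes, drop = FALSE], 1, total_vfa)
  c2c3 <- vapply(split(seq_len(nrow(wide)), wide$fermenter), function(idx)
    acetate_propionate_ratio(wide$acetate[idx], wide$propionate[idx]),
    numeric(1))
  means$c2c3 <- c2c3[means$fermenter]
  if (!is.null(design)) {
    m <- merge(means, design[c("fermenter", "treatment")], by = "fermenter")
    num <- setdiff(names(m), c("fermenter", "treatment"))
    tm <- stats::aggregate(m[num], by = list(treatment = m$treatment),
                           FUN = mean)
    attr(means, "treatment_means") <- tm
  }
  means
}
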