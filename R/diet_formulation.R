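#' Analyzed composition of a feed ingredient
#'
#' Nutrient fractions are on a dry-matter basis except `dm` itself
#' (percent of fresh matter). Trace constituents (e.g. iodine mg/kg DM,
#' bromoform ug/kg DM, total phenolic content g/100 g) live in a named
#' `trace` list and may be absent.
#'
#' @param name ingredient label.
#' @param dm dry matter, percent of fresh matter.
#' @param om,ca,cp,adfom,andfom,ee organic matter, crude ash, crude
#'   protein, acid/neutral detergent fiber (ash-free) and ether extract,
#'   percent of DM. Any may be NA.
#' @param trace named list of trace concentrations (units caller-defined,
#'   must be consistent across mixed ingredients).
#' @return an `ingredient_composition` list.
#' @export
ingredient_composition <- function(name, dm, om = NA, ca = NA, cp = NA,
                                   adfom = NA, andfom = NA, ee = NA,
                                   trace = list()) {
  vals <- vapply(list(dm, om, ca, cp, adfom, andfom, ee),
                 function(v) as.numeric(v)[1], numeric(1))
  names(vals) <- nutrient_fields
  bad <- names(vals)[!is.na(vals) & (vals < 0 | vals > 100)]
  if (length(bad))
    stop("validation error in ingredient '", name, "': ",
         paste(bad, collapse = ", "), " outside [0,100]")
  if (!is.na(om) && !is.na(ca) && abs(om + ca - 100) > 0.5)
    stop("validation error in ingredient '", name,
         "': OM + CA = ", om + ca, " (must be 100 +/- 0.5)")
  structure(c(list(name = name), as.list(vals), list(trace = trace)),
            class = "ingredient_composition")
}

#' Define a diet as proportions of ingredients on a DM basis
#'
#' @param name diet label.
#' @param components named numeric vector of DM proportions; must be
#'   non-negative and sum to 1 (tolerance 1e-9).
#' @return a `diet_spec` list.
#' @export
diet_spec <- function(name, components) {
  if (is.null(names(components)) || any(!nzchar(names(components))))
    stop("diet spec error: components must be a named proportion vector")
  if (any(components < 0))
    stop("diet spec error in '", name, "': negative proportion")
  if (abs(sum(components) - 1) > 1e-9)
    stop("diet spec error in '", name, "': proportions sum to ",
         sum(components), ", not 1")
  structure(list(name = name, components = components), class = "diet_spec")
}

nutrient_fields <- c("dm", "om", "ca", "cp", "adfom", "andfom", "ee")

#' Mix ingredient compositions into a diet composition
#'
#' Every nutrient fraction of the mixture is the proportion-weighted mean
#' of the ingredient values (DM included, mixed on the same linear basis).
#' A nutrient that is NA in any component is NA in the mixture. Trace
#' constituents are mixed identically when present in all components and
#' marked unavailable (dropped) otherwise.
#'
#' @param spec a [diet_spec()].
#' @param ingredients named list of [ingredient_composition()] objects;
#'   every component of `spec` must resolve here.
#' @return an `ingredient_composition` for the mixed diet.
#' @export
mix_composition <- function(spec, ingredients) {
  unknown <- setdiff(names(spec$components), names(ingredients))
  if (length(unknown))
    stop("lookup error: unknown ingredient(s): ",
         paste(unknown, collapse = ", "))
  comps <- ingredients[names(spec$components)]
  w <- spec$components
  mixed <- vapply(nutrient_fields, function(f) {
    vals <- vapply(comps, function(ing) as.numeric(ing[[f]]), numeric(1))
    if (anyNA(vals)) NA_real_ else sum(w * vals)
  }, numeric(1))
  trace_names <- Reduce(intersect, lapply(comps, function(i) names(i$trace)))
  trace <- lapply(trace_names %||% character(0), function(tn)
    sum(w * vapply(comps, function(i) as.numeric(i$trace[[tn]]), numeric(1))))
  names(trace) <- trace_names
  ingredient_composition(spec$name, dm = mixed["dm"], om = mixed["om"],
                         ca = mixed["ca"], cp = mixed["cp"],
                         adfom = mixed["adfom"], andfom = mixed["andfom"],
                         ee = mixed["ee"], trace = trace)
}

#' Trace constituent concentration in a mixed diet
#'
#' @inheritParams mix_composition
#' @param trace name of the trace constituent (e.g. `"iodine"`).
#' @return proportion-weighted concentration in diet DM, or `NA` with a
#'   warning if the trace is not analyzed in every component (unavailable
#'   is not zero).
#' @export
diet_trace_level <- function(spec, ingredients, trace) {
  unknown <- setdiff(names(spec$components), names(ingredients))
  if (length(unknown))
    stop("lookup error: unknown ingredient(s): ",
         paste(unknown, collapse = ", "))
  comps <- ingredients[names(spec$components)]
  vals <- vapply(comps, function(i) {
    v <- i$trace[[trace]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (anyNA(vals)) {
    warning("trace '", trace, "' unavailable for: ",
            paste(names(vals)[is.na(vals)], collapse = ", "))
    return(NA_real_)
  }
  sum(spec$components * vals)
}

#' Analyzed ingredient assays of the reference seaweed study
#'
#' Compositions (DM basis) of the total mixed ration and the two brown
#' North Atlantic seaweeds (*Ascophyllum nodosum*, *Fucus vesiculosus*)
#' used as the default formulation inputs. Trace entries carry bromoform
#' (ug/kg DM), total phenolic content (g/100 g) for the seaweeds, and
#' iodine (mg/kg DM) backed out of the reported diet concentrations
#' (35 mg/kg at 2.5% A. nodosum; 2.75 mg/kg at 2.5% F. vesiculosus).
#'
#' @return named list of [ingredient_composition()] objects
#'   (`TMR`, `AN`, `FV`).
#' @export
rusitec_ingredients <- function() {
  list(
    TMR = ingredient_composition("TMR", dm = 91.8, om = 94.0, ca = 6.0,
                                 cp = 17.8, adfom = 14.8, andfom = 29.6,
                                 ee = 2.9, trace = list(iodine = 0)),
    AN = ingredient_composition("AN", dm = 93.0, om = 70.0, ca = 30.0,
                                cp = 10.7, adfom = 18.6, andfom = 24.1,
                                ee = 2.0,
                                trace = list(iodine = 1400, bromoform = 8.0,
                                             tpc = 7.9)),
    FV = ingredient_composition("FV", dm = 89.5, om = 75.0, ca = 25.0,
                                cp = 9.3, adfom = 25.0, andfom = 19.8,
                                ee = 1.8,
                                trace = list(iodine = 110, bromoform = 0.8,
                                             tpc = 7.4))
  )
}

#' Diet specifications of the five experimental treatments
#'
#' TMR alone plus each seaweed at 2.5% and 5% DM inclusion in exchange
#' for TMR.
#'
#' @return named list of [diet_spec()] objects.
#' @export
rusitec_diet_specs <- function() {
  list(
    TMR = diet_spec("TMR", c(TMR = 1)),
    AN2.5 = diet_spec("AN2.5", c(TMR = 0.975, AN = 0.025)),
    AN5 = diet_spec("AN5", c(TMR = 0.95, AN = 0.05)),
    FV2.5 = diet_spec("FV2.5", c(TMR = 0.975, FV = 0.025)),
    FV5 = diet_spec("FV5", c(TMR = 0.95, FV = 0.05))
  )
}

#' Formulate all diets into a report table
#'
#' Computes the mixed composition of every diet and formats a
#' treatment-by-nutrient table. Internal values are unrounded; the
#' report is rounded half-away-from-zero to 1 decimal, the precision
#' conventional for these tables.
#'
#' @param specs named list of [diet_spec()]s.
#' @param ingredients named list of [ingredient_composition()]s.
#' @param digits decimals in the report (default 1); `NA` for unrounded.
#' @return data.frame with columns `treatment`, `dm`, `om`, `ca`, `cp`,
#'   `adfom`, `andfom`, `ee`.
#' @export
formulate_diets <- function(specs = rusitec_diet_specs(),
                            ingredients = rusitec_ingredients(),
                            digits = 1) {
  rows <- lapply(specs, function(sp) {
    mx <- mix_composition(sp, ingredients)
    vals <- vapply(nutrient_fields, function(f) as.numeric(mx[[f]]), numeric(1))
    if (!is.na(digits)) vals <- round_half_up(vals, digits)
    c(list(treatment = sp$name), as.list(vals))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}
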