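#' Configuration for the synthetic Rusitec experiment generator
#'
#' Defaults emulate the reference study design: 2 runs of 10 fermenters,
#' 5 treatments replicated twice per run, 2 circulation-thermostat blocks
#' per run, days 0-13 with sampling days 7-13. Treatment setpoints default
#' to the reported treatment means ([rusitec_reference_means()]) so
#' simulated outputs are magnitude-realistic; noise is multiplicative
#' lognormal (positivity-preserving) at run, block, fermenter and day
#' level, with additive Gaussian noise truncated at the natural
#' background for isotope abundances.
#'
#' @param seed integer master seed; named substreams per stage keep each
#'   stage reproducible under partial re-runs.
#' @param runs,blocks_per_run,treatments design parameters.
#' @param zero_effects if TRUE, every treatment uses the control (TMR)
#'   setpoints — the null configuration for type-I calibration.
#' @param effects named list of multiplicative treatment effects applied
#'   to the control setpoint, e.g. `list(ch4_pct = c(AN5 = 0.911))`;
#'   overrides the table-derived setpoint for those cells.
#' @param noise named list of coefficients of variation: `run_cv`,
#'   `block_cv`, `fermenter_cv`, `day_cv`, `volume_cv`, `abundance_cv`.
#'   Set all to 0 (`noise = NULL`) for a noise-free experiment.
#' @param feed_g_per_day grams (as fed) of diet per daily feed bag.
#' @param effluent_volume_l mean daily effluent/buffer volume (L/d;
#'   default 75% of the 950 mL fermenter capacity).
#' @param isotope list: `lam_share` (share of microbial N leaving via
#'   effluent LAM), `n15_lam_e_abund`, `n15_sam_abund` (ug/mg),
#'   `n_pct_sam` (%), `nh4cl_conc` (g/L), `enrichment` (mg 15N/g N).
#' @param community list: `organism` ("archaea" or "bacteria"),
#'   `concentration` (Dirichlet concentration), `depth_meanlog`,
#'   `depth_sdlog` (log-normal sequencing depths straddling the
#'   rarefaction thresholds), `fold_changes` (treatment -> named genus
#'   fold-change vector applied in fermenter-derived samples).
#' @param ar1_rho optional AR(1) correlation of day-level noise
#'   (default 0, independent days).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              runs = 2, blocks_per_run = 2,
                              treatments = c("TMR", "AN2.5", "AN5",
                                             "FV2.5", "FV5"),
                              zero_effects = FALSE,
                              effects = list(),
                              noise = list(),
                              feed_g_per_day = 15,
                              effluent_volume_l = 0.75 * 0.950,
                              isotope = list(),
                              community = list(),
                              ar1_rho = 0) {
  noise_def <- list(run_cv = 0.03, block_cv = 0.015, fermenter_cv = 0.03,
                    day_cv = 0.05, volume_cv = 0.03, abundance_cv = 0.02)
  if (is.null(noise)) noise_def[] <- 0 else noise_def[names(noise)] <- noise
  iso_def <- list(lam_share = 0.7, n15_lam_e_abund = 12,
                  n15_sam_abund = 13.66303, n_pct_sam = 8,
                  nh4cl_conc = 0.0378, enrichment = 104)
  iso_def[names(isotope)] <- isotope
  com_def <- list(organism = "archaea", concentration = 200,
                  depth_meanlog = log(9000), depth_sdlog = 0.45,
                  fold_changes = list(
                    FV5 = c(Methanimicrococcus = 2.0,
                            "Methanomethylophilaceae (family)" = 1.5),
                    AN5 = c(Methanobrevibacter = 0.8)))
  com_def[names(community)] <- community

  ref <- rusitec_reference_means()
  setp <- list(gas = ref$gas, degradation = ref$degradation,
               effluent = ref$effluent)
  if (zero_effects) {
    for (tab in names(setp)) {
      num <- vapply(setp[[tab]], is.numeric, logical(1))
      setp[[tab]][num] <- lapply(setp[[tab]][num], function(col)
        rep(col[setp[[tab]]$treatment == "TMR"], length(col)))
    }
  }
  for (trait in names(effects)) {
    tab <- if (trait %in% names(setp$gas)) "gas"
    else if (trait %in% names(setp$degradation)) "degradation"
    else if (trait %in% names(setp$effluent)) "effluent"
    else stop("unknown trait in effects: ", trait)
    ctrl <- setp[[tab]][[trait]][setp[[tab]]$treatment == "TMR"]
    for (trt in names(effects[[trait]])) {
      i <- match(trt, setp[[tab]]$treatment)
      if (is.na(i)) stop("unknown treatment in effects: ", trt)
      setp[[tab]][[trait]][i] <- ctrl * effects[[trait]][[trt]]
    }
  }
  if (any(setp$degradation[, c("dm", "om", "cp", "adfom", "andfom")] > 100))
    stop("infeasible config: degradation setpoint above 100%")

  structure(list(seed = seed, runs = runs, blocks_per_run = blocks_per_run,
                 treatments = treatments, setpoints = setp,
                 noise = noise_def, feed_g_per_day = feed_g_per_day,
                 effluent_volume_l = effluent_volume_l, isotope = iso_def,
                 community = com_def, ar1_rho = ar1_rho,
                 days = 0:13, sampling_span = 7:13,
                 degradation_span = 7:12),
            class = "simulation_config")
}

# one lognormal multiplier per unit x trait
unit_mult <- function(units, traits, cv) {
  m <- matrix(lnorm_noise(length(units) * length(traits), cv),
              nrow = length(units), dimnames = list(units, traits))
  m
}

day_noise_series <- function(n_days, cv, rho) {
  if (cv <= 0) return(rep(1, n_days))
  sdlog <- sqrt(log(1 + cv^2))
  if (rho == 0) z <- stats::rnorm(n_days) else {
    z <- numeric(n_days)
    z[1] <- stats::rnorm(1)
    for (t in 2:n_days)
      z[t] <- rho * z[t - 1] + sqrt(1 - rho^2) * stats::rnorm(1)
  }
  exp(z * sdlog - sdlog^2 / 2)
}

#' Simulate a complete Rusitec experiment with known ground truth
#'
#' Generates the design, daily gas/CH4/effluent-volume records (days
#' 0-13), 48-h feed-bag nutrient masses consistent with the configured
#' degradation, and effluent analyte concentrations consistent with the
#' configured daily productions. The per-treatment true values and the
#' per-fermenter noise multipliers are stored in the `truth` element so
#' every estimator can be checked against the generator.
#'
#' @param config a [simulation_config()].
#' @param stages which record tables to generate; restricting to the
#'   stages a simulation study needs keeps large replicate loops cheap.
#'   Stage seed substreams are independent, so the gas records are
#'   identical whether or not bags/effluent are generated.
#' @return a `rusitec_bundle` with `truth` attached.
#' @export
simulate_experiment <- function(config,
                                stages = c("gas", "bags", "effluent")) {
  stopifnot(inherits(config, "simulation_config"))
  design <- rusitec_design(config$runs, config$treatments,
                           config$blocks_per_run, seed = config$seed)
  nz <- config$noise
  setp <- config$setpoints
  diets <- formulate_diets(digits = NA)

  gas_traits <- c("total_gas", "ch4_pct", "ph", "redox", "temperature")
  deg_traits <- c("dm", "om", "cp", "adfom", "andfom")
  eff_traits <- setdiff(names(setp$effluent), c("treatment", "vfa_total", "c2c3"))
  all_traits <- c(gas_traits, deg_traits, eff_traits)

  set.seed(stage_seed(config$seed, "gas"))
  run_m <- unit_mult(unique(design$run), all_traits, nz$run_cv)
  block_m <- unit_mult(unique(design$block), all_traits, nz$block_cv)
  ferm_m <- unit_mult(design$fermenter, all_traits, nz$fermenter_cv)
  mult <- function(f, trait) {
    i <- match(f, design$fermenter)
    run_m[design$run[i], trait] * block_m[design$block[i], trait] *
      ferm_m[f, trait]
  }
  sp <- function(tab, trait, trt)
    setp[[tab]][[trait]][match(trt, setp[[tab]]$treatment)]

  ph_set <- function(trt) if (trt == "TMR") 6.82 else 6.85
  gas_rows <- lapply(seq_len(nrow(design)), function(i) {
    f <- design$fermenter[i]; trt <- design$treatment[i]
    nd <- length(config$days)
    adapt <- ifelse(config$days < min(config$sampling_span),
                    0.85 + 0.15 * config$days / min(config$sampling_span), 1)
    data.frame(
      fermenter = f, day = config$days,
      total_gas = sp("gas", "total_gas", trt) * mult(f, "total_gas") *
        adapt * day_noise_series(nd, nz$day_cv, config$ar1_rho),
      ch4_fraction = pmin(100, sp("gas", "ch4_pct", trt) *
        mult(f, "ch4_pct") * day_noise_series(nd, nz$day_cv, config$ar1_rho)),
      effluent_volume = config$effluent_volume_l *
        lnorm_noise(nd, nz$volume_cv),
      ph = ph_set(trt) + stats::rnorm(nd, 0, 0.02 * (nz$day_cv > 0)),
      redox = -241 + stats::rnorm(nd, 0, 4 * (nz$day_cv > 0)),
      temperature = 38.6 + stats::rnorm(nd, 0, 0.1 * (nz$day_cv > 0)),
      stringsAsFactors = FALSE)
  })
  gas <- do.call(rbind, gas_rows)

  set.seed(stage_seed(config$seed, "bags"))
  nutrient_key <- c(dm = "dm", om = "om", cp = "cp", adfom = "adfom",
                    andfom = "andfom")
  bag_days_in <- config$days[config$days <= max(config$days) - 2]
  bags <- list()
  if ("bags" %in% stages) for (i in seq_len(nrow(design))) {
    f <- design$fermenter[i]; trt <- design$treatment[i]
    diet <- diets[diets$treatment == trt, ]
    dm_in <- config$feed_g_per_day * 1000 * diet$dm / 100
    mass_in <- c(dm = dm_in, om = dm_in * diet$om / 100,
                 cp = dm_in * diet$cp / 100, adfom = dm_in * diet$adfom / 100,
                 andfom = dm_in * diet$andfom / 100)
    for (d in bag_days_in) {
      for (nu in names(nutrient_key)) {
        deg <- sp("degradation", nu, trt) * mult(f, nu) *
          lnorm_noise(1, nz$day_cv)
        deg <- min(deg, 100)
        bags[[length(bags) + 1L]] <- data.frame(
          fermenter = f, day_in = d, day_out = d + 2, nutrient = toupper(nu),
          mass_in = mass_in[[nu]], mass_out = mass_in[[nu]] * (1 - deg / 100),
          stringsAsFactors = FALSE)
      }
    }
  }
  bags <- if (length(bags)) do.call(rbind, bags) else NULL
  if (!is.null(bags))
    bags$nutrient <- c(DM = "DM", OM = "OM", CP = "CP", ADFOM = "ADFom",
                       ANDFOM = "aNDFom")[bags$nutrient]

  set.seed(stage_seed(config$seed, "effluent"))
  eff <- list()
  if ("effluent" %in% stages) for (i in seq_len(nrow(design))) {
    f <- design$fermenter[i]; trt <- design$treatment[i]
    vol <- gas$effluent_volume[gas$fermenter == f]
    for (an in eff_traits) {
      prod <- sp("effluent", an, trt) * mult(f, an) *
        day_noise_series(length(config$days), nz$day_cv, config$ar1_rho)
      eff[[length(eff) + 1L]] <- data.frame(
        fermenter = f, day = config$days, analyte = an,
        concentration = prod / vol, stringsAsFactors = FALSE)
    }
  }
  effluent <- if (length(eff)) do.call(rbind, eff) else NULL

  truth <- list(setpoints = setp,
                effluent_volume_l = config$effluent_volume_l,
                noise = nz,
                fermenter_mult = ferm_m, run_mult = run_m,
                block_mult = block_m)

  structure(list(design = design, gas = gas, bags = bags,
                 effluent = effluent, panels = NULL, truth = truth,
                 missing_days = NULL),
            class = "rusitec_bundle")
}

#' Simulate 15N isotope panels by running the dilution model forward
#'
#' For each fermenter the true microbial N outflow is fixed from the
#' configured EMPS setpoint and the bundle's bag-derived degraded OM,
#' split into LAM and SAM shares; abundances and masses are then chosen
#' so that the isotope-dilution estimator inverts them exactly in the
#' noise-free case. Optional additive Gaussian noise (CV
#' `noise$abundance_cv`) perturbs the analyzed abundances, truncated at
#' the natural background.
#'
#' @param config a [simulation_config()].
#' @param bundle a simulated `rusitec_bundle` (provides design and bags).
#' @return the bundle with a `panels` data.frame attached and true
#'   per-fermenter fluxes stored in `truth$isotope` (`n_lam_e`, `n_sam`,
#'   `n_m`, `emps`).
#' @export
simulate_isotope_panels <- function(config, bundle) {
  iso <- config$isotope
  bg <- 3.66303
  if (iso$n15_sam_abund <= bg)
    stop("config error: SAM abundance at or below natural background")
  set.seed(stage_seed(config$seed, "panels"))
  design <- bundle$design
  degsum <- degradation_summary(bundle$bags, span = config$degradation_span)
  ndays <- length(config$degradation_span)
  ferm_cv <- config$noise$fermenter_cv
  ferm_emps_mult <- stats::setNames(lnorm_noise(nrow(design), ferm_cv),
                                    design$fermenter)
  k_oms <- (100 / iso$n_pct_sam) * (100 - 12) / 100 * 0.93
  s <- iso$lam_share
  buffer_in <- buffer_n15_input(config$effluent_volume_l, iso$nh4cl_conc,
                                iso$enrichment)
  rows <- list(); truth <- list()
  for (i in seq_len(nrow(design))) {
    f <- design$fermenter[i]; trt <- design$treatment[i]
    dg <- degsum[degsum$fermenter == f, ]
    om_deg <- (dg$mass_in[dg$nutrient == "OM"] -
                 dg$mass_out[dg$nutrient == "OM"]) / ndays
    cp_in_d <- dg$mass_in[dg$nutrient == "CP"] / ndays
    cp_out_d <- dg$mass_out[dg$nutrient == "CP"] / ndays
    emps_true <- config$setpoints$degradation$emps[
      match(trt, config$setpoints$degradation$treatment)] *
      ferm_emps_mult[[f]]
    e <- emps_true / 1000
    n_m_true <- e * om_deg / (6.25 - e * k_oms * (1 - s))
    n_lam_true <- s * n_m_true
    n_sam_true <- (1 - s) * n_m_true
    n_feed <- cp_in_d / 6.25
    n_fr <- cp_out_d / 6.25
    n15_feed <- bg
    n15_in <- buffer_in + n_feed * n15_feed
    n15_out <- n15_in - n_lam_true * iso$n15_lam_e_abund
    if (n15_out < 0) stop("infeasible config: tracer balance negative")
    n15_fr <- n15_feed + n_sam_true * (iso$n15_sam_abund - bg) / n_fr
    noisy <- function(x) {
      cvv <- config$noise$abundance_cv
      if (cvv <= 0) return(x)
      max(bg + 1e-9, x + stats::rnorm(1, 0, cvv * x))
    }
    rows[[i]] <- data.frame(
      fermenter = f,
      n15_in = n15_in, n15_out = n15_out,
      n15_lam_e = noisy(iso$n15_lam_e_abund),
      n_fr = n_fr, n15_fr = noisy(n15_fr), n15_feed = n15_feed,
      n15_sam = noisy(iso$n15_sam_abund),
      n_pct_sam = iso$n_pct_sam, om_deg = om_deg,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(fermenter = f, n_lam_e = n_lam_true,
                             n_sam = n_sam_true, n_m = n_m_true,
                             emps = emps_true, stringsAsFactors = FALSE)
  }
  bundle$panels <- do.call(rbind, rows)
  bundle$truth$isotope <- do.call(rbind, truth)
  bundle
}

# Dirichlet draw via the gamma construction
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

archaea_profiles <- function() {
  genera <- c("Methanobrevibacter", "Methanomicrobium",
              "Methanomethylophilaceae (family)",
              "Candidatus Methanomethylophilus", "Methanimicrococcus",
              "Methanosphaera", "Methanomassiliicoccus", "Methanosarcina")
  list(genera = genera,
       inoculum = c(0.62, 0.01, 0.08, 0.05, 0.02, 0.14, 0.04, 0.04),
       day7 = c(0.30, 0.32, 0.13, 0.08, 0.06, 0.05, 0.03, 0.03),
       day13 = c(0.14, 0.48, 0.15, 0.09, 0.07, 0.03, 0.02, 0.02))
}

bacteria_profiles <- function() {
  genera <- c("Lactobacillus", "Pseudoscardovia", "F082 (family)",
              "Limosilactobacillus", "Prevotella", "Ruminobacter",
              "Fibrobacter", "Succiniclasticum")
  list(genera = genera,
       inoculum = c(0.02, 0.02, 0.10, 0.03, 0.45, 0.08, 0.15, 0.15),
       day7 = c(0.22, 0.15, 0.30, 0.10, 0.08, 0.05, 0.04, 0.06),
       day13 = c(0.24, 0.16, 0.32, 0.10, 0.05, 0.06, 0.03, 0.04))
}

community_taxonomy <- function(organism, genera) {
  fam_only <- grepl("\\(family\\)$", genera)
  genus <- ifelse(fam_only, NA_character_, genera)
  family <- ifelse(fam_only, sub(" \\(family\\)$", "", genera),
                   paste0(genera, "aceae"))
  data.frame(taxon = sprintf("asv_%02d", seq_along(genera)),
             domain = if (organism == "archaea") "Archaea" else "Bacteria",
             phylum = if (organism == "archaea") "Euryarchaeota" else "Firmicutes",
             class = NA_character_, order = NA_character_,
             family = family, genus = genus,
             stringsAsFactors = FALSE)
}

#' Simulate an amplicon feature table for the experiment
#'
#' Per-sample counts are drawn Dirichlet-multinomial around sample-type
#' and day dependent base profiles that implement the inoculum-to-Rusitec
#' dominance shift (e.g. Methanobrevibacter declining while
#' Methanomicrobium rises between day 0 and day 13). Treatment-responsive
#' genera receive the configured fold-changes in fermenter-derived
#' samples. Sequencing depths are drawn log-normally so that some samples
#' fall below the rarefaction thresholds.
#'
#' @param config a [simulation_config()].
#' @param design optional design table (defaults to the configured
#'   design); determines fermenter-derived samples.
#' @return a [feature_table()] with true sample proportions stored in the
#'   `"true_proportions"` attribute.
#' @export
simulate_community <- function(config, design = NULL) {
  com <- config$community
  prof <- if (com$organism == "archaea") archaea_profiles()
          else bacteria_profiles()
  if (abs(sum(prof$inoculum) - 1) > 1e-9)
    stop("config error: base profile not on the simplex")
  if (is.null(design))
    design <- rusitec_design(config$runs, config$treatments,
                             config$blocks_per_run, seed = config$seed)
  set.seed(stage_seed(config$seed, "community"))

  meta <- list(); k <- 0L
  add <- function(sample, type, day, trt, ferm) {
    k <<- k + 1L
    meta[[k]] <<- data.frame(sample = sample, sample_type = type, day = day,
                             treatment = trt, fermenter = ferm,
                             stringsAsFactors = FALSE)
  }
  for (r in unique(design$run)) for (cow in 1:3) {
    add(sprintf("%s_RF_c%d", r, cow), "RF", 0, "none", "none")
    add(sprintf("%s_RSP_c%d", r, cow), "RSP", 0, "none", "none")
  }
  for (i in seq_len(nrow(design))) {
    f <- design$fermenter[i]; trt <- design$treatment[i]
    for (d in c(7, 13)) {
      add(sprintf("%s_FL_d%02d", f, d), "FL", d, trt, f)
      add(sprintf("%s_E_d%02d", f, d), "E", d, trt, f)
    }
    add(sprintf("%s_FR_d13", f), "FR", 13, trt, f)
    add(sprintf("%s_SAM_d13", f), "SAM", 13, trt, f)
  }
  meta <- do.call(rbind, meta)

  base_profile <- function(type, day, trt) {
    p <- if (type %in% c("RF", "RSP")) prof$inoculum else {
      w <- (day - 7) / 6
      (1 - w) * prof$day7 + w * prof$day13
    }
    names(p) <- prof$genera
    fc <- com$fold_changes[[trt]]
    if (!is.null(fc) && !type %in% c("RF", "RSP"))
      p[names(fc)] <- p[names(fc)] * fc
    p / sum(p)
  }
  n_taxa <- length(prof$genera)
  counts <- matrix(0L, nrow(meta), n_taxa,
                   dimnames = list(meta$sample, sprintf("asv_%02d",
                                                        seq_len(n_taxa))))
  true_p <- matrix(0, nrow(meta), n_taxa, dimnames = dimnames(counts))
  for (i in seq_len(nrow(meta))) {
    p <- base_profile(meta$sample_type[i], meta$day[i], meta$treatment[i])
    true_p[i, ] <- p
    pi <- if (is.infinite(com$concentration)) p else
      rdirichlet1(com$concentration * p)
    depth <- max(500L, round(stats::rlnorm(1, com$depth_meanlog,
                                           com$depth_sdlog)))
    counts[i, ] <- stats::rmultinom(1, depth, pi)[, 1]
  }
  tax <- community_taxonomy(com$organism, prof$genera)
  ft <- feature_table(counts, tax, meta)
  attr(ft, "true_proportions") <- true_p
  ft
}
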