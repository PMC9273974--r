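test_that("the generator is deterministic given a seed", {
  cfg <- simulation_config(seed = 101)
  b1 <- simulate_isotope_panels(cfg, simulate_experiment(cfg))
  b2 <- simulate_isotope_panels(cfg, simulate_experiment(cfg))
  expect_identical(b1$gas, b2$gas)
  expect_identical(b1$bags, b2$bags)
  expect_identical(b1$effluent, b2$effluent)
  expect_identical(b1$panels, b2$panels)
  expect_identical(simulate_community(cfg)$counts,
                   simulate_community(cfg)$counts)
  b3 <- simulate_experiment(simulation_config(seed = 102))
  expect_false(identical(b1$gas$total_gas, b3$gas$total_gas))
})

test_that("zero-noise setpoints pass through the metrics stage exactly", {
  cfg <- simulation_config(seed = 103, noise = NULL)
  b <- simulate_experiment(cfg)
  tm <- attr(methane_summary(b$gas, b$design), "treatment_means")
  expect_equal(tm$total_gas[tm$treatment == "TMR"], 1386, tolerance = 1e-12)
  expect_equal(tm$ch4_pct[tm$treatment == "TMR"], 16.9, tolerance = 1e-12)
  # moving a setpoint moves the output: the means are inputs, not
  # quantities the pipeline could re-derive on its own
  cfg2 <- simulation_config(seed = 103, noise = NULL,
                            effects = list(total_gas = c(TMR = 0.9)))
  b2 <- simulate_experiment(cfg2)
  tm2 <- attr(methane_summary(b2$gas, b2$design), "treatment_means")
  expect_equal(tm2$total_gas[tm2$treatment == "TMR"], 1386 * 0.9,
               tolerance = 1e-12)
})

test_that("a multiplicative methane effect yields its percent reduction", {
  cfg <- simulation_config(seed = 104, noise = NULL, zero_effects = TRUE,
                           effects = list(ch4_pct = c(AN5 = 0.911)))
  b <- simulate_experiment(cfg)
  tm <- attr(methane_summary(b$gas, b$design), "treatment_means")
  red <- percent_reduction(tm$ch4_pct[tm$treatment == "TMR"],
                           tm$ch4_pct[tm$treatment == "AN5"])
  expect_equal(red, 8.9, tolerance = 1e-9)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(effects = list(cp = c(AN5 = 3))),
               "above 100")
  expect_error(simulation_config(effects = list(banana = c(AN5 = 1))),
               "unknown trait")
  expect_error(
    simulate_isotope_panels(
      simulation_config(isotope = list(n15_sam_abund = 3.0)),
      simulate_experiment(simulation_config())),
    "background")
})

test_that("feed bags are consistent with configured degradation", {
  cfg <- simulation_config(seed = 105, noise = NULL)
  b <- simulate_experiment(cfg)
  ds <- degradation_summary(b$bags, b$design)
  tm <- attr(ds, "treatment_means")
  ref <- rusitec_reference_means()$degradation
  for (nu in c("DM", "OM", "CP", "ADFom", "aNDFom")) {
    got <- tm$degraded_pct[tm$nutrient == nu]
    names(got) <- tm$treatment[tm$nutrient == nu]
    want <- ref[[c(DM = "dm", OM = "om", CP = "cp", ADFom = "adfom",
                   aNDFom = "andfom")[[nu]]]]
    expect_equal(unname(got[ref$treatment]), want, tolerance = 1e-9)
  }
  expect_true(all(b$bags$day_out - b$bags$day_in == 2))
})

test_that("the community generator implements the dominance shift", {
  cfg <- simulation_config(seed = 106,
                           community = list(concentration = Inf,
                                            depth_meanlog = log(50000),
                                            depth_sdlog = 0))
  ft <- simulate_community(cfg)
  gen <- collapse_to_genus(ft)
  rel <- relative_abundance(gen)
  meta <- gen$metadata[match(rownames(rel), gen$metadata$sample), ]
  mbb <- rel[, "Methanobrevibacter"]
  # inoculum is Methanobrevibacter-dominated; day-13 Rusitec samples are not
  expect_gt(mean(mbb[meta$sample_type == "RF"]), 0.5)
  expect_lt(mean(mbb[meta$day == 13 & meta$sample_type %in% c("FL", "E")]),
            0.25)
  mmb <- rel[, "Methanomicrobium"]
  expect_gt(mean(mmb[meta$day == 13 & meta$sample_type %in% c("FL", "E")]),
            mean(mmb[meta$sample_type == "RF"]))

  # the decline is detectable by the rank-based group test
  grp <- ifelse(meta$sample_type %in% c("RF", "RSP"), "day0", "rusitec")
  kw <- kruskal_dunn_bh(mbb, grp)
  expect_lt(kw$p_overall, 0.01)
})

test_that("simulated depths straddle the rarefaction thresholds", {
  cfg <- simulation_config(seed = 107,
                           community = list(depth_meanlog = log(5000),
                                            depth_sdlog = 0.5))
  ft <- simulate_community(cfg)
  expect_warning(r <- rarefy_counts(ft$counts, 3580, seed = 1), "dropping")
  expect_true(all(rowSums(r) == 3580))
  expect_lt(nrow(r), nrow(ft$counts))
})

test_that("treatment fold-changes reach the simulated composition", {
  cfg <- simulation_config(seed = 108,
                           community = list(concentration = Inf,
                                            depth_meanlog = log(100000),
                                            depth_sdlog = 0))
  ft <- simulate_community(cfg)
  gen <- collapse_to_genus(ft)
  rel <- relative_abundance(gen)
  meta <- gen$metadata[match(rownames(rel), gen$metadata$sample), ]
  sel <- meta$sample_type %in% c("FL", "E")
  mmc <- rel[sel, "Methanimicrococcus"]
  trt <- meta$treatment[sel]
  # FV5 doubles Methanimicrococcus relative to TMR (before renormalization)
  expect_gt(mean(mmc[trt == "FV5"]), 1.5 * mean(mmc[trt == "TMR"]))
})
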