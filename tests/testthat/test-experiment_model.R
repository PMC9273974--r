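test_that("design registry enforces the replicated block layout", {
  d <- rusitec_design()
  s <- design_summary(d)
  expect_setequal(s$treatment, c("TMR", "AN2.5", "AN5", "FV2.5", "FV5"))
  expect_true(all(s$total == 4))  # 2 runs x 2 replicates
  occ <- attr(s, "block_occupancy")
  expect_true(all(occ == 1))      # each treatment once per block

  single <- rusitec_design(runs = 1, blocks_per_run = 1)
  expect_true(all(design_summary(single)$total == 1))

  bad <- d
  bad$treatment[2] <- bad$treatment[1]  # duplicate within a block
  expect_error(design_summary(bad), "once in each block")
})

test_that("randomized designs stay valid and are seed-reproducible", {
  d1 <- rusitec_design(seed = 5)
  d2 <- rusitec_design(seed = 5)
  expect_identical(d1, d2)
  expect_true(all(design_summary(d1)$total == 4))
})

test_that("bundle write/read round-trips", {
  cfg <- simulation_config(seed = 11)
  b <- simulate_isotope_panels(cfg, simulate_experiment(cfg))
  dir1 <- withr::local_tempdir()
  write_bundle(b, dir1)
  b2 <- expect_silent(read_experiment(dir1))
  expect_equal(b2$gas$total_gas, b$gas$total_gas, tolerance = 1e-12)
  expect_equal(b2$bags$mass_out, b$bags$mass_out, tolerance = 1e-12)
  expect_equal(b2$panels$n15_fr, b$panels$n15_fr, tolerance = 1e-12)
  expect_identical(b2$design$treatment, b$design$treatment)
  # write(read(x)) is byte-identical to write(x) for the canonical dialect
  dir2 <- withr::local_tempdir()
  write_bundle(b2, dir2)
  for (f in c("design.tsv", "gas.tsv", "bags.tsv", "effluent.tsv",
              "panels.tsv"))
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir1, f)))
})

test_that("validation failures carry a record locator", {
  cfg <- simulation_config(seed = 12)
  b <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  b$gas$ch4_fraction[3] <- 105  # out of [0,100]
  write_bundle(b, dir)
  expect_error(read_experiment(dir), "ch4_fraction.*record 3")

  b$gas$ch4_fraction[3] <- 15
  b$gas$total_gas <- NULL  # mandatory column gone
  write_bundle(b, dir)
  expect_error(read_experiment(dir), "missing column\\(s\\): total_gas")
})

test_that("absent sampling-span fermenter-days are flagged, not dropped silently", {
  cfg <- simulation_config(seed = 13)
  b <- simulate_experiment(cfg)
  b$gas <- b$gas[!(b$gas$fermenter == b$design$fermenter[1] &
                     b$gas$day == 9), ]
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_warning(b2 <- read_experiment(dir), "fermenter-day")
  expect_identical(nrow(b2$missing_days), 1L)
})

test_that("unit declarations convert at read time", {
  cfg <- simulation_config(seed = 14)
  b <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  b_ml <- b
  b_ml$gas$effluent_volume <- b_ml$gas$effluent_volume * 1000  # stored as mL
  write_bundle(b_ml, dir)
  b2 <- read_experiment(dir, rusitec_config(
    units = list(gas = list(effluent_volume = "mL"))))
  expect_equal(b2$gas$effluent_volume, b$gas$effluent_volume,
               tolerance = 1e-9)
})

test_that("feature tables validate labels, taxonomy and metadata coverage", {
  counts <- matrix(c(5L, 3L, 0L, 2L), 2, 2,
                   dimnames = list(c("s1", "s2"), c("t1", "t2")))
  tax <- data.frame(taxon = c("t1", "t2"), domain = "Archaea",
                    phylum = NA, class = NA, order = NA,
                    family = c("Methanobacteriaceae", NA),
                    genus = c("Methanobrevibacter", NA))
  meta <- data.frame(sample = c("s1", "s2"), sample_type = "FL",
                     day = 7, treatment = "TMR", fermenter = "F01")
  expect_s3_class(feature_table(counts, tax, meta), "feature_table")
  expect_error(feature_table(counts, tax, meta[1, ]), "does not cover")
  expect_error(feature_table(counts, tax[1, ], meta), "taxonomy missing")
  expect_error(feature_table(-counts, tax, meta), "non-negative")
})

test_that("feature tables read from taxa-by-samples text with Silva lineages", {
  dir <- withr::local_tempdir()
  writeLines(c("taxon\ts1\ts2", "t1\t5\t0", "t2\t3\t2"),
             file.path(dir, "counts.tsv"))
  writeLines(c("taxon\tlineage",
               "t1\td__Archaea; p__Euryarchaeota; c__Methanobacteria; o__Methanobacteriales; f__Methanobacteriaceae; g__Methanobrevibacter",
               "t2\td__Bacteria; p__Bacteroidota; c__Bacteroidia; o__Bacteroidales; f__F082"),
             file.path(dir, "taxonomy.tsv"))
  writeLines(c("sample,sample_type,day,treatment,fermenter",
               "s1,FL,7,TMR,F01", "s2,E,13,AN5,F02"),
             file.path(dir, "metadata.csv"))
  ft <- read_feature_table(file.path(dir, "counts.tsv"),
                           file.path(dir, "taxonomy.tsv"),
                           file.path(dir, "metadata.csv"))
  expect_identical(dim(ft$counts), c(2L, 2L))
  expect_identical(ft$counts["s1", "t1"], 5L)
  expect_identical(ft$taxonomy$genus, c("Methanobrevibacter", NA))
  expect_identical(ft$taxonomy$family[2], "F082")
})
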