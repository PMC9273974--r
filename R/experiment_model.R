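#' Experiment configuration defaults
#'
#' Central registry of spans, constants and thresholds used across the
#' pipeline. Values can be overridden from a YAML file and/or by named
#' arguments (arguments win). Canonical units are fixed: gas in mL/d,
#' effluent in L/d, masses in mg, concentrations in mmol/L, isotope
#' abundances in ug 15N per mg N.
#'
#' @param path optional path to a YAML file with overrides.
#' @param ... named overrides applied after the file.
#' @return a named list with elements
#'   `sampling_span` (days 7-13), `degradation_span` (feed-bag removal days
#'   7-12), `cp_factor` (6.25 N-to-CP), `n15_background` (3.66303 ug 15N/mg N
#'   natural abundance), `sam_ash_pct` (12), `sam_dm_prop` (0.93),
#'   `genus_filter_pct` (1), `plot_filter_pct` (3.5), `cor_r_min` (0.3),
#'   `cor_p_max` (0.05), `permutations` (999),
#'   `rarefaction_depths` (archaea 3580, bacteria 5856),
#'   `effluent_volume_l` (0.7125, i.e. 75% of the 950 mL fermenter capacity).
#' @export
rusitec_config <- function(path = NULL, ...) {
  cfg <- list(
    sampling_span = 7:13,
    degradation_span = 7:12,
    cp_factor = 6.25,
    n15_background = 3.66303,
    sam_ash_pct = 12,
    sam_dm_prop = 0.93,
    genus_filter_pct = 1,
    plot_filter_pct = 3.5,
    cor_r_min = 0.3,
    cor_p_max = 0.05,
    permutations = 999,
    rarefaction_depths = c(archaea = 3580, bacteria = 5856),
    effluent_volume_l = 0.75 * 0.950,
    units = list()
  )
  if (!is.null(path)) {
    ov <- yaml::read_yaml(path)
    cfg[names(ov)] <- ov
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Build the replicated block design of a Rusitec run series
#'
#' Two runs of ten fermenters, five fermenters per circulation thermostat
#' (the blocking factor), every treatment occurring exactly once per block
#' and replicated in two fermenters per run, giving four replicates per
#' treatment in the default design.
#'
#' @param runs number of experimental runs.
#' @param treatments character vector of treatment labels.
#' @param blocks_per_run number of thermostat blocks per run.
#' @param seed optional seed; when given, treatment order is randomized
#'   within each block (fermenters were randomized in each run).
#' @return data.frame with columns `fermenter`, `run`, `block`, `treatment`,
#'   class `rusitec_design`. Fermenter and block ids are unique across runs.
#' @export
rusitec_design <- function(runs = 2,
                           treatments = c("TMR", "AN2.5", "AN5", "FV2.5", "FV5"),
                           blocks_per_run = 2,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(stage_seed(seed, "design"))
  rows <- list()
  for (r in seq_len(runs)) {
    for (b in seq_len(blocks_per_run)) {
      trt <- if (is.null(seed)) treatments else sample(treatments)
      rows[[length(rows) + 1L]] <- data.frame(
        run = sprintf("R%d", r),
        block = sprintf("R%dB%d", r, b),
        treatment = trt,
        stringsAsFactors = FALSE
      )
    }
  }
  design <- do.call(rbind, rows)
  design$fermenter <- sprintf("%sF%02d", design$run,
                              stats::ave(seq_len(nrow(design)), design$run,
                                         FUN = seq_along))
  design <- design[, c("fermenter", "run", "block", "treatment")]
  class(design) <- c("rusitec_design", "data.frame")
  validate_design(design)
  design
}

validate_design <- function(design) {
  need <- c("fermenter", "run", "block", "treatment")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(design$fermenter))
    stop("design error: duplicated fermenter id(s): ",
         paste(unique(design$fermenter[duplicated(design$fermenter)]),
               collapse = ", "))
  dup <- stats::aggregate(list(n = design$treatment),
                          by = design[c("block", "treatment")], FUN = length)
  bad <- dup[dup$n > 1, , drop = FALSE]
  if (nrow(bad))
    stop("design error: treatment '", bad$treatment[1],
         "' occurs ", bad$n[1], " times in block '", bad$block[1],
         "' (each treatment must be used once in each block)")
  invisible(design)
}

#' Tabulate treatment occupancy across runs and blocks
#'
#' @param design a `rusitec_design` data.frame.
#' @return data.frame with one row per treatment: replicates per run,
#'   per block, and `total` replication (= runs x replicates per run).
#' @export
design_summary <- function(design) {
  validate_design(design)
  tab_run <- table(design$treatment, design$run)
  tab_block <- table(design$treatment, design$block)
  out <- data.frame(treatment = rownames(tab_run),
                    as.data.frame.matrix(tab_run),
                    total = rowSums(tab_run),
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "block_occupancy") <- as.data.frame.matrix(tab_block)
  rownames(out) <- NULL
  out
}

# ---- record validation ------------------------------------------------------

loc_msg <- function(file, row) sprintf(" [%s, record %d]", file, row)

validate_gas <- function(gas, span, file = "gas") {
  need <- c("fermenter", "day", "total_gas", "ch4_fraction")
  miss <- setdiff(need, names(gas))
  if (length(miss)) stop("schema error in '", file, "': missing column(s): ",
                         paste(miss, collapse = ", "))
  for (i in seq_len(nrow(gas))) {
    g <- gas[i, ]
    if (!is.na(g$total_gas) && g$total_gas < 0)
      stop("validation error: total_gas < 0", loc_msg(file, i))
    if (!is.na(g$ch4_fraction) &&
        (g$ch4_fraction < 0 || g$ch4_fraction > 100))
      stop("validation error: ch4_fraction outside [0,100]", loc_msg(file, i))
  }
  invisible(gas)
}

validate_bags <- function(bags, file = "bags") {
  need <- c("fermenter", "day_in", "day_out", "nutrient", "mass_in", "mass_out")
  miss <- setdiff(need, names(bags))
  if (length(miss)) stop("schema error in '", file, "': missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(bags$day_out - bags$day_in != 2)
  if (length(bad))
    stop("validation error: feed bag residence is not 48 h (day_out - day_in != 2)",
         loc_msg(file, bad[1]))
  neg <- which(!is.na(bags$mass_in) & bags$mass_in < 0)
  if (length(neg))
    stop("validation error: negative mass_in", loc_msg(file, neg[1]))
  over <- which(!is.na(bags$mass_out) & !is.na(bags$mass_in) &
                  bags$mass_out > bags$mass_in)
  if (length(over))
    warning("feed bag output exceeds input (possible contamination)",
            loc_msg(file, over[1]))
  invisible(bags)
}

validate_effluent <- function(eff, file = "effluent") {
  need <- c("fermenter", "day", "analyte", "concentration")
  miss <- setdiff(need, names(eff))
  if (length(miss)) stop("schema error in '", file, "': missing column(s): ",
                         paste(miss, collapse = ", "))
  neg <- which(!is.na(eff$concentration) & eff$concentration < 0)
  if (length(neg))
    stop("validation error: negative concentration", loc_msg(file, neg[1]))
  invisible(eff)
}

validate_panels <- function(panels, background = 3.66303, file = "panels") {
  need <- c("fermenter", "n15_in", "n15_out", "n15_lam_e", "n_fr",
            "n15_fr", "n15_feed", "n15_sam", "n_pct_sam", "om_deg")
  miss <- setdiff(need, names(panels))
  if (length(miss)) stop("schema error in '", file, "': missing column(s): ",
                         paste(miss, collapse = ", "))
  tol <- 1e-9
  for (col in c("n15_lam_e", "n15_fr", "n15_feed", "n15_sam")) {
    bad <- which(!is.na(panels[[col]]) & panels[[col]] < background - tol)
    if (length(bad))
      stop("validation error: ", col, " below natural 15N background",
           loc_msg(file, bad[1]))
  }
  bad <- which(!is.na(panels$n_pct_sam) &
                 (panels$n_pct_sam <= 0 | panels$n_pct_sam > 100))
  if (length(bad))
    stop("validation error: n_pct_sam outside (0,100]", loc_msg(file, bad[1]))
  invisible(panels)
}

# ---- bundle I/O -------------------------------------------------------------

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_file <- function(path) {
  utils::read.table(path, sep = detect_delim(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), fileEncoding = "UTF-8")
}

# minimal unit conversion at read time; canonical units are documented in
# rusitec_config(); no unit inference
convert_unit <- function(x, from, to) {
  key <- paste(from, to, sep = "->")
  factor <- switch(key,
    "mL->L" = 1e-3, "L->mL" = 1e3,
    "g->mg" = 1e3, "mg->g" = 1e-3,
    "L->L" = 1, "mL->mL" = 1, "mg->mg" = 1, "g->g" = 1,
    stop("unsupported unit conversion: ", key))
  x * factor
}

#' Read a validated experiment bundle from a directory of delimited tables
#'
#' Expects long-format (tidy) tables `design`, `gas`, `bags`, `effluent`,
#' `panels` (`.tsv` or `.csv`; comma or tab auto-detected from the header
#' line), plus an optional `truth.yml` ground-truth sidecar written by the
#' simulator. Every record is validated against the type invariants;
#' violations raise an error carrying the file and record number.
#'
#' @param dir directory containing the tables.
#' @param config configuration list from [rusitec_config()]; `config$units`
#'   may declare per-table column units (e.g. `list(gas = list(
#'   effluent_volume = "mL"))`) which are converted to canonical units at
#'   read time.
#' @return a `rusitec_bundle`: list with `design`, `gas`, `bags`,
#'   `effluent`, `panels` (NULL if absent) and `truth` (NULL if absent).
#' @export
read_experiment <- function(dir, config = rusitec_config()) {
  find_table <- function(stem, required = TRUE) {
    for (ext in c(".tsv", ".csv")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    if (required) stop("missing mandatory table '", stem, "' in ", dir)
    NULL
  }
  read_tab <- function(stem, required = TRUE) {
    p <- find_table(stem, required)
    if (is.null(p)) return(NULL)
    x <- read_delim_file(p)
    units <- config$units[[stem]]
    for (col in names(units)) {
      if (!col %in% names(x))
        stop("schema error in '", stem, "': unit declared for absent column '",
             col, "'")
      canonical <- c(effluent_volume = "L", total_gas = "mL",
                     mass_in = "mg", mass_out = "mg")
      x[[col]] <- convert_unit(x[[col]], units[[col]],
                               canonical[[col]] %||% units[[col]])
    }
    x
  }
  design <- read_tab("design")
  class(design) <- c("rusitec_design", "data.frame")
  validate_design(design)
  gas <- validate_gas(read_tab("gas"), config$sampling_span)
  bags <- validate_bags(read_tab("bags"))
  effluent <- validate_effluent(read_tab("effluent"))
  panels_path <- find_table("panels", required = FALSE)
  panels <- if (is.null(panels_path)) NULL else
    validate_panels(read_delim_file(panels_path), config$n15_background)
  truth_path <- file.path(dir, "truth.yml")
  truth <- if (file.exists(truth_path)) yaml::read_yaml(truth_path) else NULL

  # flag fermenter-days of the sampling span that are absent
  expected <- expand.grid(fermenter = design$fermenter,
                          day = config$sampling_span,
                          stringsAsFactors = FALSE)
  have <- paste(gas$fermenter, gas$day)
  missing_days <- expected[!paste(expected$fermenter, expected$day) %in% have, ,
                           drop = FALSE]
  if (nrow(missing_days))
    warning(nrow(missing_days),
            " fermenter-day(s) of the sampling span absent from 'gas'; ",
            "downstream means use available cases")

  structure(list(design = design, gas = gas, bags = bags,
                 effluent = effluent, panels = panels, truth = truth,
                 missing_days = missing_days),
            class = "rusitec_bundle")
}

#' Write an experiment bundle as delimited tables
#'
#' Inverse of [read_experiment()]: writes tab-separated UTF-8 tables with
#' full numeric precision so that a write/read cycle reproduces the
#' in-memory objects and a read/write cycle reproduces the files.
#'
#' @param bundle a `rusitec_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, stem) {
    if (is.null(x)) return()
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = FALSE))
    utils::write.table(x, file.path(dir, paste0(stem, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(bundle$design, "design")
  wr(bundle$gas, "gas")
  wr(bundle$bags, "bags")
  wr(bundle$effluent, "effluent")
  wr(bundle$panels, "panels")
  if (!is.null(bundle$truth))
    yaml::write_yaml(bundle$truth, file.path(dir, "truth.yml"))
  invisible(dir)
}

#' @export
print.rusitec_bundle <- function(x, ...) {
  cat("Rusitec experiment bundle\n")
  cat("  fermenters:", nrow(x$design),
      " treatments:", length(unique(x$design$treatment)),
      " runs:", length(unique(x$design$run)), "\n")
  cat("  gas records:", nrow(x$gas),
      " bag records:", nrow(x$bags),
      " effluent records:", nrow(x$effluent), "\n")
  if (!is.null(x$panels)) cat("  isotope panels:", nrow(x$panels), "\n")
  if (!is.null(x$truth)) cat("  ground truth sidecar present\n")
  invisible(x)
}

# ---- feature table ----------------------------------------------------------

#' Construct a samples-by-taxa feature table
#'
#' @param counts non-negative integer matrix, samples in rows, taxa in
#'   columns, unique dimnames.
#' @param taxonomy data.frame with column `taxon` plus ranked lineage
#'   columns (`domain`, `phylum`, `class`, `order`, `family`, `genus`,
#'   optionally `species`); NA for unassigned ranks.
#' @param metadata data.frame with columns `sample`, `sample_type` (one of
#'   RF, RSP, E, FL, FR, SAM), `day`, `treatment`, `fermenter`; must cover
#'   every sample in `counts`.
#' @return a `feature_table` (list of the three validated components).
#' @export
feature_table <- function(counts, taxonomy, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and taxon column names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("validation error: duplicated sample or taxon labels")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("validation error: counts must be non-negative integers")
  if (!"taxon" %in% names(taxonomy)) stop("taxonomy needs a 'taxon' column")
  missing_tax <- setdiff(colnames(counts), taxonomy$taxon)
  if (length(missing_tax))
    stop("taxonomy missing for taxon/taxa: ",
         paste(utils::head(missing_tax, 3), collapse = ", "))
  need <- c("sample", "sample_type", "day", "treatment", "fermenter")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  uncovered <- setdiff(rownames(counts), metadata$sample)
  if (length(uncovered))
    stop("validation error: metadata does not cover sample(s): ",
         paste(utils::head(uncovered, 3), collapse = ", "))
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "feature_table")
}

silva_ranks <- c("domain", "phylum", "class", "order", "family", "genus",
                 "species")

# "d__Archaea; p__...; g__Methanobrevibacter" or plain semicolon lineage
parse_lineage <- function(strings) {
  out <- matrix(NA_character_, nrow = length(strings),
                ncol = length(silva_ranks),
                dimnames = list(NULL, silva_ranks))
  for (i in seq_along(strings)) {
    parts <- trimws(strsplit(strings[i], ";")[[1]])
    parts <- sub("^[a-z]__", "", parts)
    parts[parts == ""] <- NA_character_
    n <- min(length(parts), length(silva_ranks))
    out[i, seq_len(n)] <- parts[seq_len(n)]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a feature table from delimited files
#'
#' The counts file is taxa-by-samples with a leading taxon-id column (the
#' common export orientation); it is transposed to samples-by-taxa. The
#' taxonomy file either has ranked columns or a single Silva-style
#' semicolon `lineage` column.
#'
#' @param counts_file,taxonomy_file,metadata_file delimited text files
#'   (comma or tab auto-detected).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(counts_file, taxonomy_file, metadata_file) {
  raw <- read_delim_file(counts_file)
  taxa <- raw[[1]]
  counts <- t(as.matrix(raw[, -1, drop = FALSE]))
  colnames(counts) <- taxa
  tax <- read_delim_file(taxonomy_file)
  if (!"taxon" %in% names(tax)) names(tax)[1] <- "taxon"
  if ("lineage" %in% names(tax))
    tax <- cbind(tax["taxon"], parse_lineage(tax$lineage))
  meta <- read_delim_file(metadata_file)
  feature_table(counts, tax, meta)
}
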