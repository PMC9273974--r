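#' Collapse a feature table to genus level
#'
#' Counts of features sharing a genus are summed. Features not annotated
#' to genus level are labeled by the last available taxonomy unit with
#' the rank appended in parentheses (e.g. `"F082 (family)"`); features
#' with no assigned rank at all are grouped under `"Unassigned"`.
#' Per-sample totals are preserved.
#'
#' @param table a [feature_table()].
#' @return a genus-level `feature_table`; its taxonomy keeps one row per
#'   collapsed label with a `rank` column naming the annotation level.
#' @export
collapse_to_genus <- function(table) {
  tax <- table$taxonomy
  ranks <- intersect(silva_ranks[seq_len(6)], names(tax))  # domain..genus
  labels <- vapply(seq_len(nrow(tax)), function(i) {
    row <- tax[i, ranks, drop = FALSE]
    avail <- which(!is.na(unlist(row)) & nzchar(unlist(row)))
    if (!length(avail)) return("Unassigned")
    last <- max(avail)
    val <- as.character(row[[last]])
    if (ranks[last] == "genus") val else paste0(val, " (", ranks[last], ")")
  }, character(1))
  names(labels) <- tax$taxon
  lab <- labels[colnames(table$counts)]
  collapsed <- t(rowsum(t(table$counts), group = lab))
  new_tax <- data.frame(taxon = colnames(collapsed),
                        rank = vapply(colnames(collapsed), function(l) {
                          i <- match(l, lab)
                          r <- which(!is.na(tax[i, ranks]) &
                                       nzchar(as.character(tax[i, ranks])))
                          if (!length(r)) "none" else ranks[max(r)]
                        }, character(1)),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(counts = collapsed, taxonomy = new_tax,
                 metadata = table$metadata), class = "feature_table")
}

ft_counts <- function(x) if (inherits(x, "feature_table")) x$counts else as.matrix(x)

ft_rebuild <- function(x, counts) {
  if (!inherits(x, "feature_table")) return(counts)
  tax <- x$taxonomy[x$taxonomy$taxon %in% colnames(counts), , drop = FALSE]
  structure(list(counts = counts, taxonomy = tax, metadata = x$metadata),
            class = "feature_table")
}

#' Relative abundances per sample
#'
#' @param x feature table or samples-by-taxa count matrix.
#' @return matrix of proportions; each row sums to 1.
#' @export
relative_abundance <- function(x) {
  m <- ft_counts(x)
  tot <- rowSums(m)
  if (any(tot == 0)) stop("sample(s) with zero total counts")
  sweep(m, 1, tot, "/")
}

#' Filter taxa by minimum relative abundance
#'
#' Default policy retains a taxon if its relative abundance reaches the
#' threshold in at least one sample (`mode = "max"`); `mode = "mean"`
#' filters on the mean relative abundance across samples instead.
#'
#' @param x feature table or count matrix.
#' @param threshold percent (default 1; the plotting variant uses 3.5).
#' @param mode `"max"` (default) or `"mean"`.
#' @return object of the same type restricted to retained taxa.
#' @export
filter_min_relative <- function(x, threshold = 1, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (threshold < 0 || threshold > 100) stop("threshold must be in [0,100]")
  m <- ft_counts(x)
  rel <- relative_abundance(m)
  stat <- if (mode == "max") apply(rel, 2, max) else colMeans(rel)
  ft_rebuild(x, m[, stat >= threshold / 100, drop = FALSE])
}

#' Rarefy samples to a fixed depth
#'
#' Subsamples each sample's counts without replacement to exactly
#' `depth` reads. Samples with fewer total reads than `depth` are
#' dropped with a warning naming them.
#'
#' @param counts samples-by-taxa count matrix (or feature table).
#' @param depth target depth (> 0); conventional defaults are 3580
#'   (archaea) and 5856 (bacteria), see [rusitec_config()].
#' @param seed optional seed for reproducible subsampling.
#' @return count matrix of retained samples, each row summing to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  if (depth <= 0) stop("depth must be > 0")
  m <- ft_counts(counts)
  tot <- rowSums(m)
  drop <- tot < depth
  if (any(drop))
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(rownames(m)[drop], collapse = ", "))
  m <- m[!drop, , drop = FALSE]
  if (!nrow(m)) stop("no samples reach the rarefaction depth")
  if (!is.null(seed)) set.seed(seed)
  # vegan warns heuristically when the smallest count exceeds 1; depth
  # feasibility is already checked above
  out <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  out
}

#' Shannon diversity
#'
#' Shannon entropy of the per-sample composition, base 2 by default
#' (bits), configurable since reporting conventions differ.
#'
#' @param x count vector, or samples-by-taxa matrix (per-sample values).
#' @param base logarithm base (default 2).
#' @return entropy value(s).
#' @export
shannon_diversity <- function(x, base = 2) {
  m <- ft_counts(if (is.null(dim(x))) t(as.matrix(x)) else x)
  if (any(rowSums(m) <= 0)) stop("sample(s) with zero total counts")
  h <- vegan::diversity(m, index = "shannon", base = base)
  if (is.null(dim(x))) unname(h[1]) else h
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `sum(|x - y|) / sum(x + y)`; a semi-metric in [0,1].
#'
#' @param x,y count (or abundance) vectors over the same taxon set.
#' @return dissimilarity in [0,1].
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Jaccard distance between two samples (presence/absence)
#'
#' `1 - |A intersect B| / |A union B|` on the sets of present taxa.
#'
#' @inheritParams bray_curtis
#' @return distance in [0,1].
#' @export
jaccard <- function(x, y) {
  check_pair(x, y)
  as.numeric(vegan::vegdist(rbind(x, y), method = "jaccard", binary = TRUE))
}

check_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("samples must share one taxon set (equal length)")
  if (sum(x) == 0 && sum(y) == 0)
    stop("both samples empty; distance undefined")
  invisible(NULL)
}

#' Pairwise distance matrix of a community table
#'
#' @param counts samples-by-taxa matrix or feature table.
#' @param method `"bray"` or `"jaccard"` (presence/absence).
#' @return a `dist` object.
#' @export
community_distance <- function(counts, method = c("bray", "jaccard")) {
  method <- match.arg(method)
  m <- ft_counts(counts)
  vegan::vegdist(m, method = method, binary = method == "jaccard")
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F
#' statistic compares between- to within-group sums of squared
#' distances; its null distribution is obtained by permuting group
#' labels. The P-value convention counts the observed statistic among
#' the permutations: `P = (1 + #(F_perm >= F_obs)) / (1 + permutations)`,
#' so the smallest attainable P at 999 permutations is 0.001.
#'
#' @param dm a `dist` or symmetric distance matrix.
#' @param groups group labels, one per sample.
#' @param permutations number of label permutations (default 999).
#' @param seed optional seed for the permutation stream.
#' @return list: `f` (pseudo-F), `r2`, `p`, `permutations`.
#' @export
permanova <- function(dm, groups, permutations = 999, seed = NULL) {
  d2 <- as.matrix(dm)^2
  n <- nrow(d2)
  groups <- factor(groups)
  if (length(groups) != n) stop("one group label per sample required")
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (all(table(groups) < 2)) stop("groups are all singletons")
  k <- nlevels(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw_of <- function(g) {
    s <- 0
    for (lv in levels(g)) {
      idx <- which(g == lv)
      if (length(idx) > 1)
        s <- s + sum(d2[idx, idx]) / 2 / length(idx)
    }
    s
  }
  fstat <- function(ssw) ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  f_obs <- fstat(ssw_of(groups))
  if (!is.null(seed)) set.seed(seed)
  f_perm <- replicate(permutations, fstat(ssw_of(sample(groups))))
  list(f = f_obs, r2 = (sst - ssw_of(groups)) / sst,
       p = (1 + sum(f_perm >= f_obs)) / (1 + permutations),
       permutations = permutations)
}

#' Spearman correlations between genera and fermentation traits
#'
#' Correlates genus abundances with fermentation traits and retains only
#' pairs passing both the effect-size filter (|r| at or above `r_min`)
#' and the significance filter (P at or below `p_max`). Constant genera
#' or traits are skipped with a warning (correlation undefined).
#'
#' @param abundances samples-by-genera matrix (or feature table);
#'   absolute or relative abundances.
#' @param traits data.frame of numeric traits, rows matching samples.
#' @param r_min minimum |Spearman r| retained (default 0.3).
#' @param p_max maximum P retained (default 0.05).
#' @return data.frame: `genus`, `trait`, `r`, `p`, `sign`.
#' @export
trait_correlations <- function(abundances, traits, r_min = 0.3, p_max = 0.05) {
  m <- ft_counts(abundances)
  if (nrow(m) != nrow(traits))
    stop("abundances and traits must cover the same samples")
  if (nrow(m) < 4) stop("need at least 4 paired observations")
  res <- list()
  for (gname in colnames(m)) for (tname in names(traits)) {
    gv <- m[, gname]; tv <- traits[[tname]]
    ok <- stats::complete.cases(gv, tv)
    if (length(unique(gv[ok])) < 2 || length(unique(tv[ok])) < 2) {
      warning("constant series skipped: ", gname, " vs ", tname)
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(gv[ok], tv[ok], method = "spearman", exact = FALSE))
    if (abs(ct$estimate) >= r_min && ct$p.value <= p_max)
      res[[length(res) + 1L]] <- data.frame(
        genus = gname, trait = tname, r = unname(ct$estimate),
        p = ct$p.value, sign = ifelse(ct$estimate > 0, "+", "-"),
        stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(genus = character(), trait = character(),
                      r = numeric(), p = numeric(), sign = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
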