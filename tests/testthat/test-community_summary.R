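make_ft <- function() {
  counts <- matrix(c(3L, 7L, 5L, 2L,
                     1L, 0L, 4L, 6L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"),
                                   c("a1", "a2", "a3", "a4")))
  tax <- data.frame(
    taxon = c("a1", "a2", "a3", "a4"),
    domain = c("Bacteria", "Bacteria", "Bacteria", NA),
    phylum = c("Bacteroidota", "Bacteroidota", "Bacteroidota", NA),
    class = c("Bacteroidia", "Bacteroidia", "Bacteroidia", NA),
    order = c("Bacteroidales", "Bacteroidales", "Bacteroidales", NA),
    family = c("Prevotellaceae", "Prevotellaceae", "F082", NA),
    genus = c("Prevotella", "Prevotella", NA, NA),
    stringsAsFactors = FALSE)
  meta <- data.frame(sample = c("s1", "s2"), sample_type = c("FL", "E"),
                     day = 7, treatment = "TMR", fermenter = "F01")
  feature_table(counts, tax, meta)
}

test_that("genus collapse sums counts and falls back to the last rank", {
  ft <- collapse_to_genus(make_ft())
  expect_setequal(colnames(ft$counts),
                  c("Prevotella", "F082 (family)", "Unassigned"))
  expect_equal(unname(ft$counts["s1", "Prevotella"]), 10)  # 3 + 7
  expect_equal(unname(ft$counts["s1", "F082 (family)"]), 5)
  # conservation of per-sample totals
  expect_equal(rowSums(ft$counts), rowSums(make_ft()$counts))
  expect_identical(ft$taxonomy$rank[ft$taxonomy$taxon == "F082 (family)"],
                   "family")
})

test_that("relative-abundance filter keeps taxa reaching the threshold", {
  m <- matrix(c(99, 1), 1, dimnames = list("s1", c("A", "B")))
  expect_identical(colnames(filter_min_relative(m, 2)), "A")
  expect_identical(colnames(filter_min_relative(m, 0)), c("A", "B"))
  # per-sample-max vs mean policy differ when abundance is concentrated
  m2 <- rbind(s1 = c(A = 50, B = 50), s2 = c(A = 100, B = 0),
              s3 = c(A = 100, B = 0))
  expect_identical(colnames(filter_min_relative(m2, 40, mode = "max")),
                   c("A", "B"))
  expect_identical(colnames(filter_min_relative(m2, 40, mode = "mean")), "A")
  expect_error(filter_min_relative(m, 150), "\\[0,100\\]")
})

test_that("plotting-threshold filter matches known composition", {
  # multinomial draws around known proportions; 3.5% separates cleanly
  set.seed(71)
  p <- c(g1 = 0.50, g2 = 0.30, g3 = 0.15, g4 = 0.03, g5 = 0.02)
  counts <- t(replicate(6, rmultinom(1, 50000, p)[, 1]))
  colnames(counts) <- names(p); rownames(counts) <- paste0("s", 1:6)
  kept <- colnames(filter_min_relative(counts, 3.5))
  expect_setequal(kept, c("g1", "g2", "g3"))
})

test_that("rarefaction subsamples without replacement to exact depth", {
  m <- rbind(s1 = c(A = 1000, B = 0), s2 = c(A = 4, B = 4))
  expect_warning(r <- rarefy_counts(m, 10, seed = 1), "s2")
  expect_equal(unname(r["s1", ]), c(10, 0))
  expect_equal(rarefy_counts(rbind(s1 = c(3, 7)), 10), rbind(s1 = c(3L, 7L)),
               ignore_attr = TRUE)
  expect_error(rarefy_counts(m, 0), "> 0")

  # default depths: every retained sample sums exactly to depth
  cfg <- simulation_config(seed = 9)
  ft <- simulate_community(cfg)
  for (depth in c(3580, 5856)) {
    r <- suppressWarnings(rarefy_counts(ft$counts, depth, seed = 2))
    expect_true(all(rowSums(r) == depth))
  }
})

test_that("rarefaction preserves expected proportions (hypergeometric)", {
  m <- rbind(s = c(A = 300, B = 700))
  props <- vapply(1:300, function(s)
    rarefy_counts(m, 100, seed = s)[1, "A"] / 100, numeric(1))
  expect_lt(abs(mean(props) - 0.30), 0.01)  # ~4 Monte-Carlo SEs
})

test_that("Shannon entropy in bits behaves on canonical compositions", {
  expect_equal(shannon_diversity(c(5, 5, 5, 5)), 2)
  expect_equal(shannon_diversity(c(10, 0, 0)), 0)
  expect_equal(shannon_diversity(c(2, 2, 1)), 1.521928, tolerance = 1e-6)
  expect_equal(shannon_diversity(c(4, 4), base = exp(1)), log(2))
  expect_error(shannon_diversity(c(0, 0)), "zero total")
})

test_that("Bray-Curtis and Jaccard distances match hand values", {
  expect_equal(bray_curtis(c(5, 3), c(5, 3)), 0)
  expect_equal(jaccard(c(5, 3), c(5, 3)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 3)), 1)
  expect_equal(jaccard(c(5, 0), c(0, 3)), 1)
  expect_equal(bray_curtis(c(6, 0, 2), c(2, 2, 0)), 8 / 12)
  expect_equal(jaccard(c(6, 0, 2), c(2, 2, 0)), 1 - 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "empty")
  expect_error(jaccard(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("PERMANOVA matches vegan and hits the permutation floor", {
  set.seed(81)
  x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 4), 10))
  rownames(x) <- paste0("s", 1:20)
  g <- rep(c("a", "b"), each = 10)
  d <- community_distance(abs(x), "bray")
  res <- permanova(d, g, permutations = 999, seed = 1)
  expect_equal(res$p, 0.001)  # minimum attainable at 999 permutations

  ref <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(res$f, ref$F[1], tolerance = 1e-9)
  expect_equal(res$r2, ref$R2[1], tolerance = 1e-9)

  # pseudo-F invariant to relabeling of the distance matrix
  perm <- sample(20)
  res2 <- permanova(as.matrix(d)[perm, perm], g[perm],
                    permutations = 9, seed = 1)
  expect_equal(res2$f, res$f, tolerance = 1e-12)

  # reproducible for a fixed seed
  expect_identical(permanova(d, g, 199, seed = 7)$p,
                   permanova(d, g, 199, seed = 7)$p)
  expect_error(permanova(d, rep("a", 20), 99), "two groups")
})

test_that("trait correlations apply both the effect-size and P filters", {
  set.seed(91)
  n <- 20
  ch4 <- seq(10, 20, length.out = n)
  genus_up <- rank(ch4) + 0  # perfectly monotone
  genus_noise <- rnorm(n)
  ab <- cbind(Methanobrevibacter = genus_up, Other = genus_noise)
  rownames(ab) <- paste0("s", 1:n)
  res <- trait_correlations(ab, data.frame(ch4 = ch4))
  expect_true("Methanobrevibacter" %in% res$genus)
  expect_equal(res$r[res$genus == "Methanobrevibacter"], 1)
  expect_identical(res$sign[res$genus == "Methanobrevibacter"], "+")

  # |r| below 0.3 is excluded even with the P filter disabled
  set.seed(5)
  x <- 1:20
  y <- rnorm(20)
  r_weak <- cor(x, y, method = "spearman")
  stopifnot(abs(r_weak) < 0.3)  # oracle confirms the construction
  weak <- cbind(weak = y)
  rownames(weak) <- paste0("s", 1:20)
  expect_false("weak" %in%
                 trait_correlations(weak, data.frame(t = x), p_max = 1)$genus)
  expect_warning(trait_correlations(cbind(const = rep(1, 20),
                                          ok = rnorm(20)),
                                    data.frame(t = rnorm(20))),
                 "constant")
})
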