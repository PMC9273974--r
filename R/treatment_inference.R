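build_mixed_formula <- function(response, treatment, random, data) {
  # a grouping factor needs >1 level to carry variance, and fewer levels
  # than observations, else it is confounded with the residual
  usable <- random[vapply(random, function(r) {
    if (!r %in% names(data)) return(FALSE)
    nl <- length(unique(data[[r]]))
    nl > 1 && nl < nrow(data)
  }, logical(1))]
  dropped <- setdiff(random, usable)
  rhs <- paste(c(treatment,
                 sprintf("(1 | %s)", usable)), collapse = " + ")
  list(formula = stats::as.formula(paste(response, "~", rhs)),
       random = usable, dropped = dropped)
}

fit_lmm <- function(formula, data) {
  suppressMessages(suppressWarnings(
    lmerTest::lmer(formula, data = data,
                   control = lme4::lmerControl(
                     calc.derivs = FALSE,
                     check.conv.singular = "ignore",
                     check.conv.grad = "ignore",
                     check.conv.hess = "ignore"))))
}

#' Overall treatment P-value from the mixed-design ANOVA
#'
#' Lightweight path for simulation studies: fits the mixed model and
#' returns only the F-test P-value for treatment (Satterthwaite
#' denominator df).
#'
#' @inheritParams fit_treatment_model
#' @return numeric P-value.
#' @export
treatment_anova_p <- function(data, response, treatment = "treatment",
                              random = c("run", "block", "fermenter", "day")) {
  if (stats::var(data[[response]]) == 0) return(1)
  bf <- build_mixed_formula(response, treatment, random, data)
  m <- fit_lmm(bf$formula, data)
  a <- suppressMessages(stats::anova(m))
  a[treatment, "Pr(>F)"]
}

#' One-way treatment ANOVA in a mixed design
#'
#' Fits the trait as a linear mixed model with treatment as the fixed
#' effect and run, circulation-thermostat block, fermenter and day as
#' random intercepts (those with fewer than two levels in the data are
#' dropped with a note). Treatment means and their standard errors come
#' from the estimated marginal means; pairwise comparisons are unadjusted
#' t-tests (Fisher's LSD), protected: they are only interpreted into
#' letter groups when the overall F-test is significant. Denominator
#' degrees of freedom use the Satterthwaite approximation.
#'
#' @param data data.frame with the response and grouping columns.
#' @param response name of the response column.
#' @param treatment name of the fixed-effect column.
#' @param random candidate random-intercept columns.
#' @param alpha significance level gating the protected LSD (default 0.05).
#' @return a `rusitec_inference` list: `means` (data.frame treatment,
#'   mean, se, letters), `pooled_sem`, `p_overall`, `p_pairwise`
#'   (symmetric matrix), `dropped_random`, `alpha`, plus `residuals` and
#'   `fitted` for graphical normality/homogeneity checks (diagnostics are
#'   reported, never used as an automatic gate).
#' @export
fit_treatment_model <- function(data, response, treatment = "treatment",
                                random = c("run", "block", "fermenter", "day"),
                                alpha = 0.05) {
  k <- length(unique(data[[treatment]]))
  if (k < 2) stop("need at least two treatments")
  data[[treatment]] <- factor(data[[treatment]])
  if (stats::var(data[[response]]) == 0) {
    lv <- levels(data[[treatment]])
    mtab <- data.frame(treatment = lv, mean = data[[response]][1], se = 0,
                       letters = "a", stringsAsFactors = FALSE)
    return(structure(list(means = mtab, pooled_sem = 0, p_overall = 1,
                          p_pairwise = matrix(1, k, k, dimnames = list(lv, lv)),
                          dropped_random = character(), alpha = alpha,
                          residuals = rep(0, nrow(data)),
                          fitted = data[[response]], response = response),
                     class = "rusitec_inference"))
  }
  bf <- build_mixed_formula(response, treatment, random, data)
  m <- fit_lmm(bf$formula, data)
  a <- suppressMessages(stats::anova(m))
  p_overall <- a[treatment, "Pr(>F)"]
  if (is.na(p_overall)) p_overall <- 1  # zero residual variation

  emm <- suppressMessages(
    emmeans::emmeans(m, stats::as.formula(paste("~", treatment)),
                     lmer.df = "satterthwaite"))
  emm_df <- as.data.frame(emm)
  prs <- as.data.frame(suppressMessages(
    emmeans::contrast(emm, method = "pairwise", adjust = "none")))
  lv <- levels(data[[treatment]])
  pmat <- matrix(1, k, k, dimnames = list(lv, lv))
  for (i in seq_len(nrow(prs))) {
    pair <- strsplit(prs$contrast[i], " - ")[[1]]
    pair <- gsub("^\\(|\\)$", "", pair)
    pv <- prs$p.value[i]
    if (is.na(pv)) pv <- 1
    pmat[pair[1], pair[2]] <- pv
    pmat[pair[2], pair[1]] <- pv
  }
  diag(pmat) <- 1

  means <- stats::setNames(emm_df$emmean, as.character(emm_df[[treatment]]))
  if (!is.na(p_overall) && p_overall <= alpha) {
    letters <- lsd_letters(means, pmat, alpha)
  } else {
    letters <- stats::setNames(rep("a", k), names(means))
  }
  mtab <- data.frame(treatment = names(means), mean = unname(means),
                     se = emm_df$SE[match(names(means),
                                          as.character(emm_df[[treatment]]))],
                     letters = letters[names(means)],
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(means = mtab, pooled_sem = mean(mtab$se),
                 p_overall = p_overall, p_pairwise = pmat,
                 dropped_random = bf$dropped, alpha = alpha,
                 residuals = stats::residuals(m), fitted = stats::fitted(m),
                 response = response),
            class = "rusitec_inference")
}

#' @export
print.rusitec_inference <- function(x, ...) {
  cat("Mixed-design treatment ANOVA:", x$response, "\n")
  m <- x$means
  m$mean <- signif(m$mean, 4)
  m$se <- signif(m$se, 3)
  print(m, row.names = FALSE)
  cat(sprintf("Pooled SEM %.4g; overall P = %.4g\n", x$pooled_sem,
              x$p_overall))
  if (length(x$dropped_random))
    cat("Random effect(s) dropped (no estimable variance):",
        paste(x$dropped_random, collapse = ", "), "\n")
  invisible(x)
}

#' Compact letter display for pairwise comparisons
#'
#' Insert-and-absorb algorithm: starting from one group containing all
#' treatments, every significant pair splits the sets containing both
#' members; redundant subsets are absorbed. Groups sharing a letter do
#' not differ at `alpha`; groups with no common letter do. Letters are
#' assigned in descending order of the set's largest mean, so the output
#' is deterministic for a given input.
#'
#' @param means named numeric vector of group means.
#' @param pairwise_p symmetric matrix of pairwise P-values with matching
#'   dimnames.
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter strings, one per group.
#' @export
lsd_letters <- function(means, pairwise_p, alpha = 0.05) {
  g <- names(means)
  if (is.null(g)) stop("means must be named")
  if (!isTRUE(all.equal(pairwise_p, t(pairwise_p), tolerance = 1e-12)))
    stop("pairwise P matrix must be symmetric")
  pairwise_p <- pairwise_p[g, g, drop = FALSE]
  sets <- list(g)
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i >= j || pairwise_p[i, j] > alpha) next
    a <- g[i]; b <- g[j]
    new_sets <- list()
    for (s in sets) {
      if (all(c(a, b) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) for (v in seq_along(new_sets)) {
      if (u != v && keep[u] &&
          all(new_sets[[u]] %in% new_sets[[v]]) &&
          (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v))
        keep[u] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  ord <- order(-vapply(sets, function(s) max(means[s]), numeric(1)))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(sets))
    out[sets[[k]]] <- paste0(out[sets[[k]]], letters[k])
  out
}

#' Kruskal-Wallis test with Dunn's pairwise z-tests and BH correction
#'
#' Rank-based group testing for compositional traits: overall H-test
#' (mid-ranks, tie-corrected), followed by Dunn's pairwise z-statistics
#' with the tie correction, and Benjamini-Hochberg step-up adjustment
#' applied within the pairwise family.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @return list: `H`, `p_overall`, `pairwise` data.frame (`group1`,
#'   `group2`, `z`, `p`, `p_adj`). All-tied data yield `H = 0`,
#'   `p_overall = 1` and no significant pairs.
#' @export
kruskal_dunn_bh <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  if (length(unique(values)) == 1L) {
    lv <- levels(groups)
    cmb <- utils::combn(lv, 2)
    return(list(H = 0, p_overall = 1,
                pairwise = data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                                      z = 0, p = 1, p_adj = 1)))
  }
  kw <- stats::kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- table(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  cmb <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(cmb))
  for (i in seq_len(ncol(cmb))) {
    a <- cmb[1, i]; b <- cmb[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ng[[a]] + 1 / ng[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  list(H = unname(kw$statistic), p_overall = kw$p.value,
       pairwise = data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                             z = z, p = p,
                             p_adj = stats::p.adjust(p, method = "BH")))
}
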