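#' Two-way factorial ANOVA for genotype-by-diet comparisons
#'
#' Fits the fixed-effects 2 x 2 model with interaction
#' `outcome ~ genotype * diet` and reports sums of squares, F statistics and
#' p values for the genotype and diet main effects and their interaction.
#' Type II sums of squares are used by default so unbalanced cell sizes are
#' handled; on balanced designs Type II coincides with the sequential
#' decomposition. If `diet` is omitted a one-way ANOVA on `genotype` is
#' returned (useful for collapsed two-group comparisons).
#'
#' If the residual variance is exactly zero the F ratio is undefined; the
#' function then reports the limit values (p = 1 for a zero effect sum of
#' squares, p = 0 otherwise) with an exact-separation warning.
#'
#' @param outcome numeric vector of per-specimen values.
#' @param genotype,diet factor-coercible label vectors (two levels each; every
#'   cell of the design must hold >= 2 observations).
#' @param ss_type sums-of-squares type for unbalanced data (2 or 3;
#'   default 2).
#' @return An object of class `anova_result`: data.frame with columns
#'   `effect`, `sum_sq`, `df`, `F`, `p`, one row per effect plus a
#'   `Residuals` row.
#' @export
#' @examples
#' set.seed(1)
#' g <- rep(c("Control", "DbDb"), each = 10)
#' d <- rep(rep(c("CD", "WD"), each = 5), 2)
#' y <- rnorm(20) + (g == "DbDb") * 1.5
#' two_way_anova(y, g, d)
two_way_anova <- function(outcome, genotype, diet = NULL, ss_type = 2) {
  outcome <- as.numeric(outcome)
  genotype <- factor(genotype)
  if (anyNA(outcome)) {
    keep <- !is.na(outcome)
    outcome <- outcome[keep]; genotype <- genotype[keep]
    if (!is.null(diet)) diet <- diet[keep]
  }
  if (is.null(diet)) {
    if (nlevels(genotype) < 2L)
      stop("need at least two factor levels", call. = FALSE)
    fit <- stats::lm(outcome ~ genotype)
    a <- stats::anova(fit)
    tab <- data.frame(effect = c("genotype", "Residuals"),
                      sum_sq = a$`Sum Sq`, df = a$Df,
                      F = a$`F value`, p = a$`Pr(>F)`)
  } else {
    diet <- factor(diet)
    if (nlevels(genotype) != 2L || nlevels(diet) != 2L)
      stop("two_way_anova expects exactly two levels per factor",
           call. = FALSE)
    cells <- table(genotype, diet)
    if (any(cells == 0L))
      stop("design degenerate: empty genotype x diet cell", call. = FALSE)
    if (any(cells < 2L))
      stop("design degenerate: every cell needs >= 2 observations",
           call. = FALSE)
    fit <- stats::lm(outcome ~ genotype * diet)
    rss <- sum(stats::residuals(fit)^2)
    a <- if (rss < 1e-12 * max(sum(outcome^2), 1)) {
      # car::Anova refuses a saturated fit; the sequential table carries the
      # same zero/non-zero SS structure, which is all the limit values need
      a1 <- suppressWarnings(stats::anova(fit))
      rownames(a1)[rownames(a1) == "genotype:diet"] <- "genotype:diet"
      a1[, c("Sum Sq", "Df", "F value", "Pr(>F)")]
    } else {
      suppressWarnings(car::Anova(fit, type = ss_type))
    }
    nm <- trimws(rownames(a))
    nm[nm == "genotype:diet"] <- "interaction"
    tab <- data.frame(effect = nm, sum_sq = a$`Sum Sq`, df = a$Df,
                      F = a$`F value`, p = a$`Pr(>F)`)
  }
  # zero residual variance: report limit values
  res <- tab$effect == "Residuals"
  scale <- max(sum(outcome^2), 1)
  if (tab$sum_sq[res] < 1e-12 * scale) {
    eff <- !res
    zero_eff <- eff & tab$sum_sq < 1e-12 * scale
    tab$F[eff] <- ifelse(zero_eff[eff], 0, Inf)
    tab$p[eff] <- ifelse(zero_eff[eff], 1, 0)
    warning("zero residual variance; p values reported as limit values",
            call. = FALSE)
  }
  rownames(tab) <- NULL
  structure(tab, class = c("anova_result", "data.frame"))
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' All-pairs comparisons among group means using the studentized range
#' distribution, with the Tukey-Kramer correction for unequal group sizes
#' (the standard `stats::TukeyHSD` machinery on a one-way fit of the group
#' factor). Adjusted p values are monotone in the absolute mean difference at
#' fixed variance.
#'
#' @param outcome numeric vector of per-specimen values.
#' @param group factor-coercible label vector (>= 2 groups, each with >= 2
#'   observations). For the 2 x 2 design pass the genotype-diet cell label.
#' @param conf_level confidence level for the reported intervals.
#' @return Data.frame of class `tukey_result` with columns `pair`, `diff`,
#'   `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(outcome, group, conf_level = 0.95) {
  outcome <- as.numeric(outcome)
  group <- factor(group)
  if (anyNA(outcome)) {
    keep <- !is.na(outcome)
    outcome <- outcome[keep]; group <- group[keep]
  }
  if (nlevels(group) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(table(group) < 2L))
    stop("every group needs >= 2 observations", call. = FALSE)
  fit <- stats::aov(outcome ~ group)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  if (mse < 1e-12 * max(sum(outcome^2), 1)) {
    # degenerate: identical within-group values
    means <- tapply(outcome, group, mean)
    cmb <- utils::combn(levels(group), 2)
    diffs <- means[cmb[2, ]] - means[cmb[1, ]]
    warning("zero within-group variance; p values reported as limit values",
            call. = FALSE)
    out <- data.frame(pair = paste(cmb[2, ], cmb[1, ], sep = "-"),
                      diff = as.numeric(diffs), lwr = as.numeric(diffs),
                      upr = as.numeric(diffs),
                      p_adj = ifelse(abs(diffs) < 1e-12, 1, 0))
    return(structure(out, class = c("tukey_result", "data.frame")))
  }
  th <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  out <- data.frame(pair = rownames(th), diff = th[, "diff"],
                    lwr = th[, "lwr"], upr = th[, "upr"],
                    p_adj = th[, "p adj"])
  rownames(out) <- NULL
  structure(out, class = c("tukey_result", "data.frame"))
}

#' Per-group n, mean and standard deviation
#'
#' Summarizes an outcome by group the way factorial results tables are
#' reported: group labels, n, mean and sample standard deviation (n - 1
#' denominator). Groups with a single observation get `sd = NA` and are
#' flagged in the `degenerate` column.
#'
#' @param outcome numeric vector.
#' @param labels data.frame (or vector) of grouping labels, one row/value per
#'   observation.
#' @return Data.frame with the label columns plus `n`, `mean`, `sd`,
#'   `degenerate`.
#' @export
summarize_groups <- function(outcome, labels) {
  outcome <- as.numeric(outcome)
  if (!is.data.frame(labels)) labels <- data.frame(group = labels)
  if (nrow(labels) != length(outcome))
    stop("labels must have one row per observation", call. = FALSE)
  key <- interaction(labels, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_along(outcome), key)
  rows <- lapply(idx, function(i) {
    cbind(labels[i[1], , drop = FALSE],
          data.frame(n = length(i),
                     mean = mean(outcome[i], na.rm = TRUE),
                     sd = if (length(i) > 1L) stats::sd(outcome[i]) else NA_real_,
                     degenerate = length(i) < 2L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
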