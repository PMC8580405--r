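# Statistical procedures: mixed-design (split-plot) ANOVA with sphericity
# check and Greenhouse-Geisser correction, Tukey-Kramer post-hoc comparisons,
# Pearson correlation, and the Mann-Whitney U test with normal z
# approximation.

#' Mixed-design ANOVA with sphericity check and Greenhouse-Geisser correction
#'
#' Two-way mixed (split-plot) ANOVA: one between-subject factor (group), one
#' within-subject factor (time) with repeated measures. Fits a multivariate
#' linear model on the subject-by-time response matrix and derives the
#' univariate group, time, and group-by-time tests, Mauchly's sphericity test
#' on the within factor, and the Greenhouse-Geisser epsilon with corrected
#' p-values. Both uncorrected and corrected p are always reported; `p_report`
#' applies the usual rule of using the corrected value only when Mauchly's
#' test rejects sphericity at 0.05 (with two within levels sphericity holds
#' trivially: W = 1, epsilon = 1). When the data contain a single group the
#' model reduces to a one-way repeated-measures ANOVA (within effect only),
#' the form used for within-group analyses.
#'
#' @param data Long data frame.
#' @param subject,between,within,response Column names (defaults `"subject"`,
#'   `"group"`, `"time"`, `"value"`). Every subject must have exactly one
#'   observation per within level (balanced), at least two subjects per
#'   group, and belong to one group.
#' @return Data frame of class `anova_result` with one row per effect
#'   (between, within, interaction): `effect`, `F`, `df1`, `df2`, `p`,
#'   `mauchly_W`, `mauchly_p`, `gg_eps`, `p_gg`, `p_report`.
#' @export
mixed_anova <- function(data, subject = "subject", between = "group",
                        within = "time", response = "value") {
  data <- as.data.frame(data)
  for (col in c(subject, between, within, response)) {
    if (!col %in% names(data)) stop("missing column: ", col)
  }
  subj <- factor(data[[subject]])
  grp <- factor(data[[between]])
  tm <- if (is.factor(data[[within]])) droplevels(data[[within]]) else factor(data[[within]])
  y <- data[[response]]
  if (anyNA(y)) stop("missing responses are not allowed")
  k <- nlevels(tm)
  tab <- table(subj, tm)
  if (any(tab != 1L))
    stop("unbalanced within-subject design: every subject needs exactly one observation per ",
         within, " level")
  gmap <- tapply(as.character(grp), subj, function(g) {
    u <- unique(g)
    if (length(u) != 1L) stop("a subject appears in more than one group")
    u
  })
  if (any(table(gmap) < 2L)) stop("need at least 2 subjects per group")
  one_group <- nlevels(droplevels(grp)) < 2L

  # wide response matrix, rows = subjects (sorted), cols = within levels
  subj_levels <- levels(subj)
  Y <- matrix(NA_real_, length(subj_levels), k,
              dimnames = list(subj_levels, levels(tm)))
  Y[cbind(match(subj, subj_levels), match(tm, levels(tm)))] <- y
  gfac <- factor(gmap[subj_levels], levels = levels(grp))

  # type-3 tests require sum-to-zero contrasts
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op), add = TRUE)
  mod <- if (one_group) lm(Y ~ 1) else lm(Y ~ gfac)
  idata <- data.frame(time = factor(levels(tm), levels = levels(tm)))
  aov_tab <- car::Anova(mod, idata = idata, idesign = ~time, type = 3)
  s <- suppressWarnings(summary(aov_tab, multivariate = FALSE))
  ut <- s$univariate.tests
  rows <- rownames(ut)
  eff_between <- "gfac"
  eff_within <- "time"
  eff_inter <- "gfac:time"

  get_row <- function(eff) {
    i <- match(eff, rows)
    c(F = ut[i, "F value"], df1 = ut[i, "num Df"], df2 = ut[i, "den Df"],
      p = ut[i, "Pr(>F)"])
  }
  if (k >= 3 && !is.null(s$sphericity.tests) && nrow(s$sphericity.tests) > 0) {
    W <- s$sphericity.tests["time", "Test statistic"]
    W_p <- s$sphericity.tests["time", "p-value"]
    eps <- s$pval.adjustments["time", "GG eps"]
    p_gg_within <- s$pval.adjustments["time", "Pr(>F[GG])"]
    p_gg_inter <- if (one_group) NA_real_ else s$pval.adjustments[eff_inter, "Pr(>F[GG])"]
  } else {
    W <- 1; W_p <- 1; eps <- 1
    p_gg_within <- get_row(eff_within)["p"]
    p_gg_inter <- if (one_group) NA_real_ else get_row(eff_inter)["p"]
  }

  build <- function(name, eff, is_within, p_gg) {
    r <- get_row(eff)
    correct <- is_within && W_p < 0.05
    data.frame(effect = name, F = unname(r["F"]), df1 = unname(r["df1"]),
               df2 = unname(r["df2"]), p = unname(r["p"]),
               mauchly_W = if (is_within) W else NA_real_,
               mauchly_p = if (is_within) W_p else NA_real_,
               gg_eps = if (is_within) eps else NA_real_,
               p_gg = if (is_within) unname(p_gg) else NA_real_,
               p_report = unname(if (correct) p_gg else r["p"]))
  }
  out <- if (one_group) {
    build(within, eff_within, TRUE, p_gg_within)
  } else {
    rbind(build(between, eff_between, FALSE, NA),
          build(within, eff_within, TRUE, p_gg_within),
          build(paste0(between, ":", within), eff_inter, TRUE, p_gg_inter))
  }
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Tukey-Kramer pairwise comparisons
#'
#' All pairwise mean differences between groups with the Tukey-Kramer
#' unequal-n adjustment: the studentized-range statistic for pair (i, j) is
#' `q = |mi - mj| / sqrt(MSE/2 * (1/ni + 1/nj))` with the pooled error mean
#' square, and adjusted p-values come from the studentized-range distribution
#' with `k` groups and `N - k` error degrees of freedom. With two groups this
#' reduces to the two-sample t test via `q = sqrt(2) |t|`.
#'
#' @param groups Named list of numeric vectors (one per group, each with at
#'   least 2 observations).
#' @return Data frame with columns `group1`, `group2`, `diff`, `se`
#'   (standard error of the difference), `q`, `p_adj`.
#' @export
tukey_kramer <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need a list of >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ni <- lengths(groups)
  if (any(ni < 2)) stop("every group needs at least 2 observations")
  k <- length(groups)
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, var, numeric(1))
  df <- sum(ni) - k
  mse <- sum((ni - 1) * vi) / df
  pairs <- combn(k, 2)
  out <- data.frame(
    group1 = names(groups)[pairs[1, ]], group2 = names(groups)[pairs[2, ]],
    diff = mi[pairs[2, ]] - mi[pairs[1, ]],
    se = sqrt(mse * (1 / ni[pairs[1, ]] + 1 / ni[pairs[2, ]])),
    row.names = NULL)
  out$q <- abs(out$diff) / sqrt(mse / 2 * (1 / ni[pairs[1, ]] + 1 / ni[pairs[2, ]]))
  out$p_adj <- ptukey(out$q, nmeans = k, df = df, lower.tail = FALSE)
  out
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `r`, `p`, `n`, `df`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

#' Mann-Whitney U test with normal z approximation
#'
#' U counts the pairs where an x observation exceeds a y observation (ties
#' counted 1/2), so identical samples give `U = n1 n2 / 2` and complete
#' separation gives `U = n1 n2`. The z statistic uses the tie-corrected
#' normal approximation
#' `z = (U - n1 n2 / 2) / sqrt(n1 n2 / 12 * ((N + 1) - sum(t^3 - t) / (N (N - 1))))`
#' with a two-sided p. Continuity correction is off by default (switchable).
#' `exact = TRUE` replaces the normal p by the exact permutation p from full
#' enumeration of the `choose(N, n1)` group assignments (small samples only).
#'
#' @param x,y Numeric samples (both non-empty).
#' @param continuity Apply 0.5 continuity correction to z. Default `FALSE`.
#' @param exact Compute the permutation p by enumeration. Default `FALSE`.
#' @return List with `U`, `z`, `p` and (if `exact`) `p_exact`.
#' @export
mann_whitney_z <- function(x, y, continuity = FALSE, exact = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  mu <- n1 * n2 / 2
  z <- if (v > 0) {
    num <- U - mu
    if (continuity) num <- sign(num) * max(0, abs(num) - 0.5)
    num / sqrt(v)
  } else 0
  out <- list(U = U, z = z, p = 2 * pnorm(-abs(z)))
  if (exact) {
    if (choose(N, n1) > 2e5) stop("exact enumeration infeasible for these sample sizes")
    pooled_r <- r
    idx <- combn(N, n1)
    u_all <- colSums(matrix(pooled_r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    out$p_exact <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
  }
  out
}
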