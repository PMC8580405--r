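make_long <- function(values, groups, times) {
  n <- length(values) / length(times)
  data.frame(subject = rep(seq_len(n), times = length(times)),
             group = rep(groups, times = length(times)),
             time = rep(times, each = n),
             value = values)
}

test_that("mixed ANOVA F values match the split-plot sums-of-squares oracle", {
  # 2 groups x 2 times x 3 subjects, integer responses
  d <- data.frame(
    subject = rep(1:6, each = 2),
    group = rep(c("A", "B"), each = 6),
    time = rep(c("t1", "t2"), 6),
    value = c(3, 5, 4, 7, 5, 6, 7, 9, 6, 6, 8, 10))
  a <- mixed_anova(d)
  # independent route: base-R split-plot aov
  o <- summary(aov(value ~ group * time + Error(factor(subject) / time), data = d))
  o_between <- o[["Error: factor(subject)"]][[1]]
  o_within <- o[["Error: factor(subject):time"]][[1]]
  expect_equal(a$F[a$effect == "group"], o_between["group", "F value"], tolerance = 1e-10)
  expect_equal(a$F[a$effect == "time"], o_within["time", "F value"], tolerance = 1e-10)
  expect_equal(a$F[a$effect == "group:time"], o_within["group:time", "F value"],
               tolerance = 1e-10)
  expect_equal(a$p[a$effect == "group"], o_between["group", "Pr(>F)"], tolerance = 1e-10)
  # two within levels: sphericity trivially satisfied
  expect_equal(a$mauchly_W[a$effect == "time"], 1)
  expect_equal(a$gg_eps[a$effect == "time"], 1)
})

test_that("GG correction is conservative in the rejection tail", {
  # reducing both df can lower mid-range p-values, so conservativeness
  # (p_gg >= p) is a tail property: it is asserted where the test can reject,
  # together with "the correction never creates significance at 0.05"
  set.seed(31)
  checked <- 0L
  for (r in 1:20) {
    v <- rnorm(36) + rep(c(0, 0.4, 0.9), each = 12) * rep(rnorm(1) + 1, 36)
    d <- make_long(v, rep(c("A", "B"), each = 6), c("t1", "t2", "t3"))
    a <- mixed_anova(d)
    within <- a[a$effect %in% c("time", "group:time"), ]
    tail_rows <- within[within$p <= 0.1, ]
    if (nrow(tail_rows)) {
      expect_true(all(tail_rows$p_gg >= tail_rows$p - 1e-12))
      checked <- checked + nrow(tail_rows)
    }
    expect_false(any(within$p >= 0.05 & within$p_gg < 0.05))
    expect_true(all(a[!is.na(a$gg_eps), "gg_eps"] > 0 &
                      a[!is.na(a$gg_eps), "gg_eps"] <= 1))
    expect_true(all(a$p >= 0 & a$p <= 1))
  }
  expect_gt(checked, 5)
})

test_that("mixed ANOVA is invariant to row and subject ordering", {
  set.seed(32)
  d <- make_long(rnorm(45), rep(c("A", "B", "C"), each = 5), c("t1", "t2", "t3"))
  a1 <- mixed_anova(d)
  a2 <- mixed_anova(d[sample(nrow(d)), ])
  expect_equal(a1, a2)
})

test_that("mixed ANOVA rejects unbalanced or underpowered designs", {
  set.seed(33)
  d <- make_long(rnorm(24), rep(c("A", "B"), each = 4), c("t1", "t2", "t3"))
  expect_error(mixed_anova(d[-1, ]), "unbalanced")
  d2 <- make_long(rnorm(9), c("A", "A", "B"), c("t1", "t2", "t3"))
  expect_error(mixed_anova(d2), "at least 2 subjects")
})

test_that("a single-group design reduces to one-way repeated measures", {
  set.seed(34)
  d <- make_long(rnorm(24), rep("A", 8), c("t1", "t2", "t3"))
  a <- mixed_anova(d)
  expect_equal(a$effect, "time")
  expect_true(is.finite(a$F) && a$p >= 0 && a$p <= 1)
})

test_that("Tukey-Kramer matches its closed-form reductions and TukeyHSD", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_gt(tukey_kramer(same)$p_adj, 0.999)

  set.seed(35)
  two <- list(a = rnorm(6), b = rnorm(8, 1))
  tk <- tukey_kramer(two)
  tt <- t.test(two$a, two$b, var.equal = TRUE)
  expect_equal(tk$q, sqrt(2) * abs(tt$statistic), ignore_attr = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-10)

  three <- list(a = rnorm(5), b = rnorm(7, 0.5), c = rnorm(6, 1))
  tk3 <- tukey_kramer(three)
  df <- data.frame(y = unlist(three), g = rep(names(three), lengths(three)))
  hsd <- TukeyHSD(aov(y ~ g, df))$g
  expect_equal(tk3$p_adj, unname(hsd[, "p adj"]), tolerance = 1e-8)
  expect_equal(tk3$diff, unname(hsd[, "diff"]), tolerance = 1e-10)

  expect_error(tukey_kramer(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("Pearson correlation handles exact, orthogonal, and fixed cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)

  xc <- x - mean(x)
  y_orth <- c(1, -1, 0, -1, 1)  # orthogonal to centered x
  expect_equal(abs(pearson_cor(xc, y_orth)$r), 0, tolerance = 1e-12)

  set.seed(36)
  a <- rnorm(8); b <- rnorm(8)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_cor(a, b)$r, direct, tolerance = 1e-12)

  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("Mann-Whitney U and z match their closed forms", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  mw <- mann_whitney_z(x, y)
  expect_equal(mw$U, length(x) * length(y) / 2)
  expect_equal(mw$z, 0)

  set.seed(37)
  sep <- mann_whitney_z(rnorm(10) + 100, rnorm(14))
  expect_equal(sep$U, 140)
  expect_equal(sep$z, 70 / sqrt(10 * 14 * 25 / 12), tolerance = 1e-12)  # 4.0988
  expect_lt(sep$p, 0.001)
})

test_that("exact Mann-Whitney p matches full enumeration with ties", {
  # independent oracle: U for every group assignment via pairwise counting
  oracle_exact_p <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x); N <- length(pooled)
    u_of <- function(idx) {
      xs <- pooled[idx]; ys <- pooled[-idx]
      sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    }
    u_all <- combn(N, n1, u_of)
    mu <- n1 * (N - n1) / 2
    u_obs <- u_of(seq_len(n1))
    mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  }
  cases <- list(
    list(x = c(1, 2, 2, 3), y = c(2, 3, 3, 4)),
    list(x = c(5, 5, 6), y = c(4, 5, 7, 7)),
    list(x = c(1, 1, 2, 2, 3, 3), y = c(2, 2, 4)))
  for (cs in cases) {
    mw <- mann_whitney_z(cs$x, cs$y, exact = TRUE)
    expect_equal(mw$p_exact, oracle_exact_p(cs$x, cs$y))
  }
})
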