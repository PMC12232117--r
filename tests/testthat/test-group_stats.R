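test_that("one-way within-subjects F matches the aov error-stratum oracle", {
  set.seed(31)
  d <- expand.grid(subject = paste0("s", 1:8),
                   condition = paste0("c", 1:4))
  d$value <- rnorm(nrow(d)) + as.numeric(factor(d$condition)) * 0.4
  r <- rm_anova(d, within = "condition")
  a <- summary(aov(value ~ condition + Error(subject / condition),
                   data = d))[["Error: subject:condition"]][[1]]
  expect_equal(r$F, a[1, "F value"], tolerance = 1e-10)
  expect_equal(r$p, a[1, "Pr(>F)"], tolerance = 1e-10)
  expect_equal(r$df1, 3)
  expect_equal(r$df2, 21)
})

test_that("two-level F equals the squared paired t and epsilon is 1", {
  set.seed(32)
  d <- expand.grid(subject = paste0("s", 1:9),
                   condition = c("a", "b"))
  d$value <- rnorm(nrow(d)) + (d$condition == "b") * 0.7
  r <- rm_anova(d, within = "condition")
  tt <- t.test(d$value[d$condition == "a"], d$value[d$condition == "b"],
               paired = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r$gg_epsilon, 1)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 8)
})

test_that("hand-computed 3x3 worked example reproduces F and epsilon", {
  # subjects s1..s3 with responses (1,2,3), (2,4,6), (3,6,9):
  # grand = 4; SS_condition = 24 (df 2), SS_subject = 24,
  # SS_error = 52 - 24 - 24 = 4 (df 4); F = 12/1 = 12.
  # The column covariance is rank one, so epsilon hits its 1/(k-1) bound.
  d <- data.frame(subject = rep(paste0("s", 1:3), 3),
                  condition = rep(paste0("c", 1:3), each = 3),
                  value = c(1, 2, 3, 2, 4, 6, 3, 6, 9))
  r <- rm_anova(d, within = "condition")
  expect_equal(r$F, 12, tolerance = 1e-12)
  expect_equal(r$df1, 2)
  expect_equal(r$df2, 4)
  expect_equal(r$gg_epsilon, 0.5, tolerance = 1e-12)
  expect_equal(r$p_gg, pf(12, 1, 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("two-way within design matches aov and flags each effect", {
  set.seed(33)
  d <- expand.grid(subject = paste0("s", 1:8), A = paste0("a", 1:5),
                   B = c("b1", "b2"))
  d$value <- rnorm(nrow(d)) + as.numeric(factor(d$A)) * 0.3 +
    (d$B == "b2") * 1
  r <- rm_anova(d, within = c("A", "B"))
  a <- summary(aov(value ~ A * B + Error(subject / (A * B)), data = d))
  expect_equal(r$F[r$effect == "A"],
               a[["Error: subject:A"]][[1]][1, "F value"],
               tolerance = 1e-10)
  expect_equal(r$F[r$effect == "B"],
               a[["Error: subject:B"]][[1]][1, "F value"],
               tolerance = 1e-10)
  expect_equal(r$F[r$effect == "A:B"],
               a[["Error: subject:A:B"]][[1]][1, "F value"],
               tolerance = 1e-10)
  expect_true(all(r$gg_epsilon >= 1 / r$df1 - 1e-12))
  expect_true(all(r$gg_epsilon <= 1 + 1e-12))
})

test_that("epsilon equals 1 exactly under a spherical sample covariance", {
  set.seed(34)
  n <- 12; k <- 5
  g <- matrix(rnorm(n * k), n, k)
  gc <- scale(g, scale = FALSE)
  X <- gc %*% solve(chol(cov(gc)))  # sample covariance exactly identity
  d <- data.frame(subject = rep(paste0("s", 1:n), k),
                  condition = rep(paste0("c", 1:k), each = n),
                  value = as.vector(X))
  r <- rm_anova(d, within = "condition")
  expect_equal(r$gg_epsilon, 1, tolerance = 1e-9)
})

test_that("incomplete or degenerate designs are rejected", {
  d <- expand.grid(subject = paste0("s", 1:4), condition = c("a", "b"))
  d$value <- rnorm(8)
  expect_error(rm_anova(d[-1, ], within = "condition"), "incomplete")
  d1 <- d[d$condition == "a", ]
  expect_error(rm_anova(d1, within = "condition"), "2 levels")
})

test_that("Holm step-down adjustment matches the hand-worked example", {
  expect_equal(holm_correct(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(holm_correct(0.2), 0.2)
  set.seed(35)
  for (rep in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_correct(p)
    expect_equal(adj, p.adjust(p, "holm"))  # independent oracle
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(holm_correct(c(0.5, 0)), "0, 1")
  expect_error(holm_correct(c(0.5, 1.2)), "0, 1")
})

test_that("planned paired comparisons handle regular and degenerate pairs", {
  set.seed(36)
  d <- expand.grid(subject = paste0("s", 1:8),
                   treatment = c("veh", "drug"))
  d$value <- rnorm(nrow(d)) - (d$treatment == "drug") * 1.2
  pc <- planned_paired_comparisons(d, factor_name = "treatment",
                                   pairs = list(c("drug", "veh")))
  tt <- t.test(d$value[d$treatment == "drug"],
               d$value[d$treatment == "veh"], paired = TRUE)
  expect_equal(pc$t, unname(tt$statistic))
  expect_equal(pc$p, tt$p.value)
  expect_equal(pc$df, 7)
  # identical columns: t = 0, p = 1
  d2 <- d; d2$value <- rep(rnorm(8), 2)
  pc2 <- planned_paired_comparisons(d2, factor_name = "treatment",
                                    pairs = list(c("drug", "veh")))
  expect_equal(pc2$t, 0)
  expect_equal(pc2$p, 1)
  # constant non-zero difference: degenerate
  d3 <- d2; d3$value[d3$treatment == "drug"] <-
    d3$value[d3$treatment == "drug"] + 2
  expect_warning(pc3 <- planned_paired_comparisons(
    d3, factor_name = "treatment", pairs = list(c("drug", "veh"))),
    "degenerate")
  expect_true(pc3$degenerate)
  expect_true(is.na(pc3$p))
  expect_error(planned_paired_comparisons(
    d, factor_name = "treatment", pairs = list(c("drug", "nope"))),
    "unknown")
})

test_that("Welch ANOVA matches oneway.test and the two-group t identity", {
  set.seed(37)
  g <- list(a = rnorm(10), b = rnorm(12, 1), c = rnorm(8, 0, 2))
  res <- welch_anova_dunnett(g, n_mc = 1000, seed = 2)
  ow <- oneway.test(v ~ grp,
                    data = data.frame(v = unlist(g),
                                      grp = rep(names(g), lengths(g))))
  expect_equal(res$F, unname(ow$statistic), tolerance = 1e-9)
  expect_equal(res$df2, unname(ow$parameter[2]), tolerance = 1e-9)
  expect_equal(res$p, ow$p.value, tolerance = 1e-9)
  g2 <- g[1:2]
  res2 <- welch_anova_dunnett(g2, n_mc = 1000, seed = 2)
  t2 <- t.test(g2[[1]], g2[[2]])
  expect_equal(res2$F, unname(t2$statistic)^2, tolerance = 1e-9)
})

test_that("single-comparison Dunnett converges to the Welch t-test p", {
  set.seed(38)
  g <- list(ctl = rnorm(15), trt = rnorm(15, 0.8))
  res <- welch_anova_dunnett(g, n_mc = 200000, seed = 4)
  tt <- t.test(g$trt, g$ctl)
  expect_equal(res$dunnett$p_adj, tt$p.value, tolerance = 0.01)
})

test_that("identical groups give null Welch and Dunnett results", {
  g <- list(a = rep(2, 5), b = rep(2, 6), c = rep(2, 4))
  res <- welch_anova_dunnett(g, seed = 1, n_mc = 1000)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$dunnett$p_adj == 1))
  expect_error(welch_anova_dunnett(list(rnorm(5), 3)), "at least 2")
})

test_that("outlier filter removes only 2-SD violators in a single pass", {
  out <- outlier_filter(c(0, 0, 0, 0, 10))
  expect_equal(out$removed, 5L)
  expect_equal(out$kept, rep(0, 4))
  same <- outlier_filter(rep(3, 6))
  expect_length(same$removed, 0)
  expect_equal(same$kept, rep(3, 6))
  expect_error(outlier_filter(c(1, 2)), "3 values")
  # order independence
  set.seed(39)
  v <- rnorm(30)
  o1 <- outlier_filter(v)
  o2 <- outlier_filter(rev(v))
  expect_equal(sort(o1$kept), sort(o2$kept))
})

test_that("normal-tail removal rate sits near the 2-SD expectation", {
  set.seed(40)
  rates <- replicate(300, length(outlier_filter(rnorm(30))$removed) / 30)
  expect_equal(mean(rates), 0.046, tolerance = 0.35)
})
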