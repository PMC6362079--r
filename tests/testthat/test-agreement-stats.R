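test_that("within-subject sd matches hand-computed repeatability", {
  # identical duplicates: zero
  expect_equal(within_subject_sd(c(2, 2, 3, 3), c("a", "a", "b", "b")), 0)
  # pairs (1,2) and (3,3): sqrt((0.5 + 0) / 2) = 0.5
  expect_equal(within_subject_sd(c(1, 2, 3, 3), c("a", "a", "b", "b")), 0.5)
  # pairs (0,1) twice: sqrt(0.5)
  expect_equal(within_subject_sd(c(0, 1, 0, 1), c("a", "a", "b", "b")),
               sqrt(0.5))
  # duplicate-pair shortcut sqrt(sum d^2 / 2J) agrees on random data
  set.seed(2)
  x <- rnorm(20); g <- rep(1:10, each = 2)
  d <- x[seq(1, 19, 2)] - x[seq(2, 20, 2)]
  expect_equal(within_subject_sd(x, g), sqrt(sum(d^2) / 20))
  expect_error(within_subject_sd(1:3, c("a", "b", "c")), "replicate")
})

test_that("Bland-Altman limits and their confidence intervals", {
  # identical raters: degenerate zero-width limits
  b0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(b0$mean_diff, 0)
  expect_equal(c(b0$loa_low, b0$loa_high), c(0, 0))

  # differences (-0.1, 0.1, -0.1, 0.1): hand-derived sd and limits
  a <- c(0.9, 1.1, 0.9, 1.1); b <- c(1, 1, 1, 1)
  ba <- bland_altman(a, b)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(0.04 / 3), tolerance = 1e-10)
  expect_equal(ba$loa_high, 1.96 * sqrt(0.04 / 3), tolerance = 1e-6)
  expect_equal(ba$loa_low, -ba$loa_high)
  # CI of each limit: LoA +/- t(0.975, 3) * sd * sqrt(3/4)
  half <- qt(0.975, 3) * ba$sd_diff * sqrt(3 / 4)
  expect_equal(ba$ci_high_pair, ba$loa_high + c(-1, 1) * half)
  expect_equal(ba$ci_low_pair, ba$loa_low + c(-1, 1) * half)
  # the intervals bracket their limits; limits bracket the mean
  expect_lte(ba$loa_low, ba$mean_diff)
  expect_gte(ba$loa_high, ba$mean_diff)

  # antisymmetry under swapping raters
  set.seed(8)
  x <- rnorm(30); y <- rnorm(30)
  f <- bland_altman(x, y); g <- bland_altman(y, x)
  expect_equal(f$mean_diff, -g$mean_diff)
  expect_equal(f$loa_low, -g$loa_high)
  expect_equal(f$loa_high, -g$loa_low)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("Pearson correlation handles exact and hand-derived cases", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  pc <- pearson_cor(c(1, 2, 3), c(1, 2, 4))
  expect_equal(pc$r, 0.98198, tolerance = 1e-5)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("rm_anova reproduces textbook structure on simple designs", {
  # response constant within every level of A: zero effect, F = 0, p = 1
  d <- expand.grid(subject = 1:4, A = c("x", "y"), B = c("u", "v"))
  d$y <- ifelse(d$B == "u", 1, 2) + as.integer(d$subject) / 10
  tab <- rm_anova(d, "y", c("A", "B"))
  expect_equal(tab$ss[tab$effect == "A"], 0)
  expect_equal(tab$F[tab$effect == "A"], 0)
  expect_equal(tab$p[tab$effect == "A"], 1)
  # B carries the whole effect, consistently across subjects: F = Inf
  expect_equal(tab$F[tab$effect == "B"], Inf)
  expect_equal(tab$p[tab$effect == "B"], 0)

  # two-level factor: F equals the squared paired-t statistic
  set.seed(14)
  d2 <- expand.grid(subject = 1:8, A = c("x", "y"))
  d2$y <- rnorm(16)
  f <- rm_anova(d2, "y", "A")
  tt <- t.test(d2$y[d2$A == "x"], d2$y[d2$A == "y"], paired = TRUE)
  expect_equal(f$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(f$p, tt$p.value, tolerance = 1e-8)

  # replicates are averaged per cell before the decomposition
  d3 <- rbind(d2, d2)
  d3$y[17:32] <- d3$y[17:32] + rnorm(16, sd = 0.1)
  f3 <- rm_anova(d3, "y", "A")
  d3m <- aggregate(y ~ subject + A, d3, mean)
  expect_equal(f3$ss, rm_anova(d3m, "y", "A")$ss)

  # unbalanced grids are refused, naming a missing cell
  expect_error(rm_anova(d2[-1, ], "y", "A"), "missing cells")
})

test_that("rm_anova agrees with aov error strata and conserves SS and df", {
  set.seed(90)
  for (rep in 1:5) {
    d <- expand.grid(subject = 1:4, A = c("a1", "a2", "a3"),
                     B = c("b1", "b2"), C = c("c1", "c2"))
    d$y <- rnorm(nrow(d))
    tab <- rm_anova(d, "y", c("A", "B", "C"))

    fit <- summary(stats::aov(
      y ~ A * B * C + Error(factor(subject) / (A * B * C)), data = d))
    for (stratum in fit) {
      s <- stratum[[1]]
      eff <- rownames(s)[!grepl("Residuals|Intercept", rownames(s))]
      if (length(eff) != 1L) next
      name <- gsub(" ", "", eff)
      i <- match(name, tab$effect)
      expect_false(is.na(i), info = name)
      expect_equal(tab$ss[i], s[eff, "Sum Sq"], tolerance = 1e-8)
      expect_equal(tab$df[i], s[eff, "Df"])
      expect_equal(tab$error_ss[i], s["Residuals", "Sum Sq"],
                   tolerance = 1e-8)
      expect_equal(tab$F[i], s[eff, "F value"], tolerance = 1e-8)
    }

    # conservation: effects + error strata + subject = total, same for df
    expect_equal(sum(tab$ss) + sum(tab$error_ss) + attr(tab, "subject_ss"),
                 attr(tab, "total_ss"), tolerance = 1e-8)
    expect_equal(sum(tab$df) + sum(tab$error_df) + attr(tab, "subject_df"),
                 attr(tab, "total_df"))
  }
})

test_that("rm_anova matches the brute-force cell-mean oracle", {
  set.seed(33)
  for (rep in 1:5) {
    d <- expand.grid(subject = sprintf("s%d", 1:4),
                     camera = c("bq", "iphone", "nexus"),
                     lighting = c("high", "low"),
                     magnification = c("m6", "m10"),
                     calibration = c("pre", "post"),
                     stringsAsFactors = FALSE)
    d$y <- rnorm(nrow(d))
    factors <- c("camera", "lighting", "magnification", "calibration")
    tab <- rm_anova(d, "y", factors)
    oracle <- brute_rm_anova(d, "y", factors)
    i <- match(oracle$effect, tab$effect)
    expect_false(anyNA(i))
    expect_equal(tab$ss[i], oracle$ss, tolerance = 1e-8)
    expect_equal(tab$error_ss[i], oracle$error_ss, tolerance = 1e-8)
  }
})

test_that("Greenhouse-Geisser epsilon shrinks df and caps at 1", {
  set.seed(4)
  d <- expand.grid(subject = 1:10, A = c("a", "b", "c", "d"))
  d$y <- rnorm(40)
  tab <- rm_anova(d, "y", "A", sphericity = "greenhouse-geisser")
  expect_gte(tab$gg_epsilon, 1 / 3)
  expect_lte(tab$gg_epsilon, 1)
  expect_gte(tab$p_gg, tab$p)  # adjusted p never smaller

  # a 2-level factor is sphericity-exempt: epsilon = 1, p unchanged
  d2 <- expand.grid(subject = 1:6, A = c("x", "y"))
  d2$y <- rnorm(12)
  t2 <- rm_anova(d2, "y", "A", sphericity = "greenhouse-geisser")
  expect_equal(t2$gg_epsilon, 1)
  expect_equal(t2$p_gg, t2$p)
})

test_that("Bonferroni pairwise comparisons count pairs within the factor", {
  set.seed(6)
  d <- expand.grid(subject = 1:6, A = c("x", "y"))
  d$y <- rnorm(12)
  # 2 levels: single pair, adjustment is a no-op
  pw <- bonferroni_pairwise(d, "A", "y")
  expect_equal(nrow(pw), 1L)
  expect_equal(pw$p_adj, pw$p)

  d3 <- expand.grid(subject = 1:6, A = c("x", "y", "z"))
  d3$y <- rnorm(18)
  pw3 <- bonferroni_pairwise(d3, "A", "y")
  expect_equal(nrow(pw3), 3L)
  expect_equal(pw3$p_adj, pmin(1, pw3$p * 3))

  # identical level means: all adjusted p-values are 1
  d3$y <- rep(1:6, 3) / 10
  pweq <- bonferroni_pairwise(d3, "A", "y")
  expect_true(all(pweq$p_adj == 1))
  expect_error(bonferroni_pairwise(d, "A", "y", subject = "nope"), "nope")
})

test_that("clinician ANOVA is the single-factor special case", {
  # all raters identical: no rater effect
  g <- matrix(rep(c(1, 2, 3, 2.5), 3), ncol = 3)
  tab <- clinician_anova(g)
  expect_equal(tab$F, 0)

  # rater = image mean + fixed offsets, no noise: error stratum vanishes
  base <- c(0.5, 1.5, 2.5, 3 , 1)
  g2 <- cbind(base, base + 0.5, base + 1.0)
  t2 <- clinician_anova(g2)
  expect_equal(t2$F, Inf)
  expect_equal(t2$p, 0)

  # agrees with rm_anova on the same long data
  set.seed(10)
  g3 <- matrix(rnorm(30, mean = 2), ncol = 3,
               dimnames = list(NULL, c("r1", "r2", "r3")))
  long <- data.frame(image = rep(1:10, 3), rater = rep(c("r1", "r2", "r3"),
                                                       each = 10),
                     grade = as.vector(g3))
  expect_equal(clinician_anova(g3)$F,
               rm_anova(long, "grade", "rater", subject = "image")$F,
               tolerance = 1e-10)
})
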