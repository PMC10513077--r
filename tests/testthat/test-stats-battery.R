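test_that("grubbs test flags a gross outlier and spares clean samples", {
  g <- grubbs_test(c(1, 2, 3, 100))
  expect_equal(g$index, 4L)
  expect_equal(g$statistic, 1.4998, tolerance = 1e-4)
  expect_equal(g$critical, 1.4812, tolerance = 1e-4)
  g2 <- grubbs_test(c(1, 2, 3))
  expect_true(is.na(g2$index))
  expect_equal(g2$statistic, 1)
  expect_warning(g3 <- grubbs_test(c(5, 5, 5, 5)), "constant")
  expect_true(is.na(g3$index))
  expect_error(grubbs_test(c(1, 2)), "n >= 3")
})

test_that("significance codes reproduce the printed thresholds", {
  expect_equal(annotate_p(c(0.2, 0.03, 0.005, 5e-4, 1e-5)),
               c("ns", "*", "**", "***", "****"))
  # strict inequalities at every boundary
  expect_equal(annotate_p(c(0.05, 0.01, 0.001, 0.0001)),
               c("ns", "*", "**", "***"))
  expect_error(annotate_p(1.2), "\\[0, 1\\]")
})

test_that("games-howell reproduces an independent reference to 1e-3", {
  # fixed canonical samples; reference values from an established
  # implementation of the Games-Howell procedure
  a <- c(23.1, 25.3, 21.8, 26.4, 24.9, 22.7, 25.8, 23.3)
  b <- c(28.2, 31.7, 26.9, 33.5, 30.1, 29.4, 27.8, 32.2, 30.9)
  c_ <- c(24.5, 27.1, 25.2, 26.8, 25.9, 24.1, 26.3)
  gh <- games_howell(c(a, b, c_), rep(c("a", "b", "c"), c(8, 9, 7)))
  expect_equal(gh$diff, c(-5.9152777778, -1.5375, 4.3777777778),
               tolerance = 1e-6)
  expect_equal(gh$se, c(0.9382075519, 0.7263585383, 0.8514796749),
               tolerance = 1e-6)
  expect_equal(gh$statistic, c(-6.3048712043, -2.1167232419, 5.1413767199),
               tolerance = 1e-6)
  expect_equal(gh$df, c(14.6348082362, 12.4106477333, 12.4947681109),
               tolerance = 1e-6)
  expect_equal(gh$p_adj, c(0.0000444023, 0.1266635979, 0.0005841086),
               tolerance = 1e-3)
  # two identical groups: statistic 0, p = 1
  gh0 <- games_howell(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3))
  expect_equal(gh0$statistic, 0)
  expect_equal(gh0$p_adj, 1)
  # symmetry under group exchange (sign flips, p unchanged)
  gh1 <- games_howell(c(a, b), rep(c("a", "b"), c(8, 9)))
  gh2 <- games_howell(c(b, a), rep(c("b", "a"), c(9, 8)))
  expect_equal(gh1$p_adj, gh2$p_adj)
  expect_equal(abs(gh1$statistic), abs(gh2$statistic))
})

test_that("bonferroni adjustment is min(1, m p) and monotone", {
  sp <- split(c(rnorm(10), rnorm(10, 3), rnorm(10, 6)), rep(1:3, each = 10))
  pw <- podometrics:::pairwise_t_bonferroni(sp)
  expect_equal(pw$p_adj, pmin(1, 3 * pw$p_raw))
  expect_true(all(diff(pw$p_adj[order(pw$p_raw)]) >= 0))
  # cross-check against the stock pairwise.t.test with pooled sd
  ref <- pairwise.t.test(unlist(sp), rep(1:3, each = 10),
                         p.adjust.method = "bonferroni", pool.sd = TRUE)
  expect_equal(pw$p_adj[1], ref$p.value[1, 1], tolerance = 1e-10)
  expect_equal(pw$p_adj[2], ref$p.value[2, 1], tolerance = 1e-10)
  expect_equal(pw$p_adj[3], ref$p.value[2, 2], tolerance = 1e-10)
})

test_that("screens agree with the reference implementations they wrap", {
  withr::with_seed(3, x <- c(rnorm(20), rexp(20)))
  g <- rep(c("a", "b"), each = 20)
  ch <- suppressWarnings(choose_branch(x, g,
                                       stats_config(remove_outliers = FALSE)))
  sw <- shapiro.test(x[21:40])$p.value
  ad <- nortest::ad.test(x[21:40])$p.value
  expect_equal(ch$normality$shapiro_p[ch$normality$group == "b"], sw,
               tolerance = 1e-10)
  expect_equal(ch$normality$ad_p[ch$normality$group == "b"], ad,
               tolerance = 1e-10)
  bf <- car::leveneTest(x ~ factor(g), center = median)[["Pr(>F)"]][1]
  expect_equal(ch$variance_p, bf, tolerance = 1e-10)
})

test_that("the branch rules route constructed datasets as specified", {
  # clean normal homoscedastic data takes the parametric branch
  withr::with_seed(10, v <- rnorm(90))
  g <- rep(c("a", "b", "c"), each = 30)
  r <- run_stats_battery(v, g)
  expect_equal(r$branch, "ANOVA_Bonferroni")
  expect_equal(nrow(r$pairwise), 3L)           # each pair exactly once
  expect_true(all(r$pairwise$p_adj >= 0 & r$pairwise$p_adj <= 1))
  # grossly heteroscedastic normal data is routed to Games-Howell
  withr::with_seed(12, v2 <- c(rnorm(40), rnorm(40, 0, 10)))
  r2 <- run_stats_battery(v2, rep(c("a", "b"), each = 40))
  expect_equal(r2$branch, "ANOVA_GamesHowell")
  # heavily skewed data is routed to the nonparametric branch
  withr::with_seed(13, v3 <- c(rexp(40)^2, rnorm(40)))
  r3 <- run_stats_battery(v3, rep(c("a", "b"), each = 40))
  expect_equal(r3$branch, "KW_MWU")
  # undersized groups fail loudly, naming the group
  expect_error(choose_branch(c(1, 2, 1, 2, 3), c("a", "a", "b", "b", "b")),
               "a")
})

test_that("stat reports serialise to JSON and CSV", {
  withr::with_seed(4, v <- c(rnorm(12), rnorm(12, 5)))
  r <- run_stats_battery(v, rep(c("a", "b"), each = 12))
  pre <- file.path(withr::local_tempdir(), "report")
  paths <- write_stat_report(r, pre)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1])
  expect_equal(js$branch, r$branch)
  csv <- read.csv(paths[2])
  expect_equal(nrow(csv), nrow(r$pairwise))
})
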