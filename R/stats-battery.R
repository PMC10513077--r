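#' Configuration of the test-selection battery
#'
#' `alpha` governs the hypothesis tests themselves (omnibus, pairwise,
#' Grubbs). The distributional screens (normality, homoscedasticity) use
#' their own, stricter `screen_alpha`: with two normality tests applied
#' to every group in conjunction, screening at the testing alpha would
#' route about a fifth of perfectly normal datasets away from the
#' parametric branch (six independent screens at 0.05 pass jointly only
#' ~74% of the time), so the screens guard against gross violations at
#' 0.01 instead.
#'
#' @param alpha significance level for the tests.
#' @param screen_alpha level for the normality and variance screens.
#' @param remove_outliers remove (once per group) a Grubbs-flagged value
#'   before branching.
#' @return list of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, screen_alpha = 0.01,
                         remove_outliers = TRUE) {
  assert_scalar(alpha, "alpha", 1e-9, 1 - 1e-9)
  assert_scalar(screen_alpha, "screen_alpha", 1e-9, 1 - 1e-9)
  structure(list(alpha = alpha, screen_alpha = screen_alpha,
                 remove_outliers = remove_outliers),
            class = "stats_config")
}

#' Two-sided Grubbs outlier test
#'
#' `G = max |x - mean| / sd` compared against the t-based critical value
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n-2)`. At most one value is flagged per call.
#'
#' @param x numeric sample (n >= 3).
#' @param alpha significance level.
#' @return list: `statistic` G, `critical`, `index` of the flagged value
#'   (or `NA` when none), `value`. Constant samples flag nothing and
#'   warn.
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  assert_that(length(x) >= 3, "Grubbs test needs n >= 3")
  n <- length(x)
  s <- sd(x)
  if (s == 0) {
    warning("grubbs_test: constant sample, no outlier test possible")
    return(list(statistic = NA_real_, critical = NA_real_,
                index = NA_integer_, value = NA_real_))
  }
  dev <- abs(x - mean(x))
  G <- max(dev) / s
  tcrit <- qt(1 - alpha / (2 * n), n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  idx <- if (G > crit) which.max(dev) else NA_integer_
  list(statistic = G, critical = crit, index = idx,
       value = if (is.na(idx)) NA_real_ else x[idx])
}

#' Significance code for a p-value
#'
#' Strict thresholds: `p < 0.0001` gives `****`, `< 0.001` `***`,
#' `< 0.01` `**`, `< 0.05` `*`, otherwise `ns`.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of codes.
#' @export
annotate_p <- function(p) {
  assert_that(all(is.finite(p)) && all(p >= 0 & p <= 1),
              "p-values must lie in [0, 1]")
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out
}

group_split_check <- function(values, groups, min_n = 2L) {
  g <- factor(groups)
  assert_that(nlevels(g) >= 2, "need at least 2 groups")
  sp <- split(as.numeric(values), g)
  ns <- vapply(sp, length, 0L)
  bad <- names(sp)[ns < min_n]
  if (length(bad))
    stop("group(s) too small (n < ", min_n, "): ",
         paste(bad, collapse = ", "), call. = FALSE)
  sp
}

#' Games-Howell pairwise comparisons
#'
#' For unequal variances: statistic `(mi - mj) / sqrt(si^2/ni + sj^2/nj)`
#' with Welch-Satterthwaite degrees of freedom; the p-value comes from
#' the studentized range distribution with `k` means
#' (`ptukey(|t| * sqrt(2), k, df)`).
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups, each n >= 2, nonconstant
#'   overall).
#' @return data.frame: `group_i`, `group_j`, `diff`, `se`, `statistic`,
#'   `df`, `p_adj`, `code`.
#' @export
games_howell <- function(values, groups) {
  sp <- group_split_check(values, groups, min_n = 2L)
  assert_that(any(vapply(sp, var, 0) > 0),
              "zero variance in every group: Games-Howell undefined")
  k <- length(sp)
  nm <- names(sp)
  means <- vapply(sp, mean, 0); vars <- vapply(sp, var, 0)
  ns <- vapply(sp, length, 0L)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- vars[i] / ns[i] + vars[j] / ns[j]
    se <- sqrt(se2)
    t <- if (se > 0) (means[i] - means[j]) / se else 0
    df <- if (se2 > 0)
      se2^2 / ((vars[i] / ns[i])^2 / (ns[i] - 1) +
                 (vars[j] / ns[j])^2 / (ns[j] - 1))
    else ns[i] + ns[j] - 2
    p <- if (se > 0) ptukey(abs(t) * sqrt(2), k, df, lower.tail = FALSE) else 1
    data.frame(group_i = nm[i], group_j = nm[j],
               diff = means[i] - means[j], se = se, statistic = t,
               df = df, p_adj = p)
  })
  out <- do.call(rbind, rows)
  out$code <- annotate_p(out$p_adj)
  rownames(out) <- NULL
  out
}

# pooled-variance pairwise t tests with Bonferroni adjustment
pairwise_t_bonferroni <- function(sp) {
  k <- length(sp); nm <- names(sp)
  ns <- vapply(sp, length, 0L)
  means <- vapply(sp, mean, 0)
  mse <- sum(vapply(sp, function(x) sum((x - mean(x))^2), 0)) / (sum(ns) - k)
  df <- sum(ns) - k
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    t <- if (se > 0) (means[i] - means[j]) / se else 0
    p <- 2 * pt(-abs(t), df)
    data.frame(group_i = nm[i], group_j = nm[j], diff = means[i] - means[j],
               se = se, statistic = t, df = df, p_raw = p,
               p_adj = min(1, m * p))
  })
  out <- do.call(rbind, rows)
  out$code <- annotate_p(out$p_adj)
  rownames(out) <- NULL
  out
}

pairwise_mwu_bonferroni <- function(sp) {
  k <- length(sp); nm <- names(sp)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    wt <- suppressWarnings(wilcox.test(sp[[i]], sp[[j]], exact = FALSE))
    data.frame(group_i = nm[i], group_j = nm[j],
               diff = median(sp[[i]]) - median(sp[[j]]),
               se = NA_real_, statistic = unname(wt$statistic),
               df = NA_real_, p_raw = wt$p.value,
               p_adj = min(1, m * wt$p.value))
  })
  out <- do.call(rbind, rows)
  out$code <- annotate_p(out$p_adj)
  rownames(out) <- NULL
  out
}

#' Select the analysis branch from pre-test screens
#'
#' Screens every group for outliers (Grubbs at the screening level;
#' flagged values optionally removed once), normality
#' (Anderson-Darling and Shapiro-Wilk -- a
#' dataset counts as normal only when BOTH tests pass in EVERY group),
#' and homoscedasticity (Brown-Forsythe). Branches:
#' `ANOVA_Bonferroni` (normal + homoscedastic), `ANOVA_GamesHowell`
#' (normal + heteroscedastic), `KW_MWU` (not normal). For groups of
#' n < 8 the Anderson-Darling screen is undefined and Shapiro-Wilk alone
#' decides.
#'
#' @param values numeric vector of measurements.
#' @param groups group labels (>= 2 groups, each n >= 3).
#' @param config a [stats_config()].
#' @return list of class `branch_choice`: `branch`, `values`, `groups`
#'   (after any outlier removal), `outliers` (data.frame), `normality`
#'   (per-group p-values), `variance_p`, `normal`, `homoscedastic`.
#' @export
choose_branch <- function(values, groups, config = stats_config()) {
  stopifnot(inherits(config, "stats_config"))
  sp <- group_split_check(values, groups, min_n = 3L)
  alpha <- config$alpha
  s_alpha <- config$screen_alpha
  outliers <- list()
  for (g in names(sp)) {
    if (sd(sp[[g]]) == 0) next
    gr <- grubbs_test(sp[[g]], s_alpha)
    if (!is.na(gr$index)) {
      outliers[[g]] <- data.frame(group = g, value = gr$value,
                                  statistic = gr$statistic,
                                  critical = gr$critical,
                                  removed = config$remove_outliers)
      if (config$remove_outliers) sp[[g]] <- sp[[g]][-gr$index]
    }
  }
  outliers <- if (length(outliers)) do.call(rbind, outliers) else
    data.frame(group = character(0), value = numeric(0),
               statistic = numeric(0), critical = numeric(0),
               removed = logical(0))
  rownames(outliers) <- NULL

  norm <- do.call(rbind, lapply(names(sp), function(g) {
    x <- sp[[g]]
    swp <- if (sd(x) > 0) shapiro.test(x)$p.value else 0
    adp <- if (length(x) >= 8 && sd(x) > 0) nortest::ad.test(x)$p.value
    else NA_real_
    data.frame(group = g, n = length(x), shapiro_p = swp, ad_p = adp)
  }))
  normal <- all(norm$shapiro_p > s_alpha) &&
    all(is.na(norm$ad_p) | norm$ad_p > s_alpha)

  vals2 <- unlist(sp, use.names = FALSE)
  grps2 <- factor(rep(names(sp), vapply(sp, length, 0L)))
  bf <- car::leveneTest(vals2 ~ grps2, center = median)
  variance_p <- bf[["Pr(>F)"]][1]
  homosc <- variance_p > s_alpha

  branch <- if (normal && homosc) "ANOVA_Bonferroni"
  else if (normal) "ANOVA_GamesHowell"
  else "KW_MWU"
  structure(list(branch = branch, values = vals2, groups = grps2,
                 outliers = outliers, normality = norm,
                 variance_p = variance_p, normal = normal,
                 homoscedastic = homosc, alpha = alpha),
            class = "branch_choice")
}

#' Run the full test-selection battery
#'
#' Applies [choose_branch()] and then the branch's omnibus and pairwise
#' tests: one-way ANOVA with Bonferroni-adjusted pooled t comparisons;
#' Welch's ANOVA with Games-Howell comparisons; or Kruskal-Wallis with
#' Bonferroni-adjusted Mann-Whitney-U comparisons. Every unordered group
#' pair appears exactly once.
#'
#' @inheritParams choose_branch
#' @return list of class `stat_report`: `branch`, `screens` (the
#'   `branch_choice`), `omnibus` (statistic, df, p, code), `pairwise`
#'   data.frame with adjusted p and significance codes.
#' @export
run_stats_battery <- function(values, groups, config = stats_config()) {
  ch <- choose_branch(values, groups, config)
  sp <- split(ch$values, ch$groups)
  if (ch$branch == "ANOVA_Bonferroni") {
    om <- stats::oneway.test(ch$values ~ ch$groups, var.equal = TRUE)
    pw <- pairwise_t_bonferroni(sp)
  } else if (ch$branch == "ANOVA_GamesHowell") {
    om <- stats::oneway.test(ch$values ~ ch$groups, var.equal = FALSE)
    pw <- games_howell(ch$values, ch$groups)
  } else {
    om <- kruskal.test(ch$values, ch$groups)
    pw <- pairwise_mwu_bonferroni(sp)
  }
  omnibus <- list(method = om$method, statistic = unname(om$statistic),
                  p = om$p.value, code = annotate_p(om$p.value))
  structure(list(branch = ch$branch, screens = ch, omnibus = omnibus,
                 pairwise = pw),
            class = "stat_report")
}

#' Write a stat report to JSON and CSV
#'
#' @param report a `stat_report`.
#' @param path_prefix output prefix; writes `<prefix>.json` and
#'   `<prefix>_pairwise.csv`.
#' @return invisibly, the paths written.
#' @export
write_stat_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "stat_report"))
  js <- list(branch = report$branch,
             omnibus = report$omnibus,
             normality = report$screens$normality,
             variance_p = report$screens$variance_p,
             outliers = report$screens$outliers,
             pairwise = report$pairwise)
  p1 <- paste0(path_prefix, ".json")
  p2 <- paste0(path_prefix, "_pairwise.csv")
  jsonlite::write_json(js, p1, auto_unbox = TRUE, dataframe = "rows",
                       digits = NA)
  write.csv(report$pairwise, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
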