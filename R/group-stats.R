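#' Per-group mean and standard error of per-cell measurements
#'
#' Measurements enter at one value per cell and metric — frame-level values
#' must already be averaged within each cell (the hierarchy used
#' throughout: frames are averaged per cell, then cells are the replicates).
#'
#' @param measurements Data frame with columns `cell_id`, `group`, `metric`,
#'   `value` (and optionally more, ignored here).
#' @return Data frame with one row per (group, metric): `n`, `mean`, `sem`
#'   (sample SD / sqrt(n); `NA` with `sem_defined = FALSE` when `n = 1`).
#' @examples
#' m <- data.frame(cell_id = 1:6, group = rep(c("a", "b"), each = 3),
#'                 metric = "x", value = c(5, 5, 5, 1, 2, 3))
#' summarise_groups(m)
#' @export
summarise_groups <- function(measurements) {
  check_measurements(measurements)
  sp <- split(measurements,
              list(measurements$group, measurements$metric), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    n <- nrow(d)
    data.frame(group = d$group[1], metric = d$metric[1], n = n,
               mean = mean(d$value),
               sem = if (n > 1) stats::sd(d$value) / sqrt(n) else NA_real_,
               sem_defined = n > 1)
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$group), , drop = FALSE]
}

check_measurements <- function(m) {
  stopifnot(is.data.frame(m),
            all(c("cell_id", "group", "metric", "value") %in% names(m)))
  dup <- duplicated(m[, c("cell_id", "group", "metric")])
  if (any(dup)) stop("more than one value per (cell, metric)")
  invisible(m)
}

lsd_pairs <- function(means, ns, labels, mse, df_res, alpha) {
  cmb <- utils::combn(length(means), 2)
  est <- means[cmb[1, ]] - means[cmb[2, ]]
  se <- sqrt(mse * (1 / ns[cmb[1, ]] + 1 / ns[cmb[2, ]]))
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df_res)
  data.frame(group1 = labels[cmb[1, ]], group2 = labels[cmb[2, ]],
             estimate = est, se = se, t = tval, p = p,
             significant = p < alpha, row.names = NULL)
}

#' One-way fixed-effects ANOVA with Fisher's LSD post-hoc comparisons
#'
#' Standard one-way decomposition over treatment groups (cells as
#' replicates), followed by all pairwise least-significant-difference
#' t-tests using the pooled residual mean square and residual degrees of
#' freedom.  Fisher's LSD applies no multiplicity correction — each
#' comparison is tested at `alpha` as-is.
#'
#' @param measurements Data frame as in [summarise_groups()].
#' @param metric Which metric to analyse.
#' @param alpha Per-comparison significance level.
#' @return An object of class `anova_result`: `design`, `table` (term,
#'   df, sum_sq, mean_sq, F, p), `residual_ms`, `residual_df` and
#'   `comparisons` (pairwise LSD table).
#' @examples
#' m <- data.frame(cell_id = 1:9, group = rep(c("a", "b", "c"), each = 3),
#'                 metric = "x", value = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
#' one_way_anova_lsd(m, "x")$table
#' @export
one_way_anova_lsd <- function(measurements, metric, alpha = 0.05) {
  check_measurements(measurements)
  d <- measurements[measurements$metric == metric, , drop = FALSE]
  if (nrow(d) == 0) stop(sprintf("no measurements for metric '%s'", metric))
  d$group <- factor(d$group)
  ns <- table(d$group)
  if (length(ns) < 2) stop("need at least 2 groups")
  if (any(ns < 2)) stop("need at least 2 values per group")
  fit <- stats::aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  mse <- s["Residuals", "Mean Sq"]
  df_res <- s["Residuals", "Df"]
  if (mse <= .Machine$double.eps * max(abs(d$value), 1)^2)
    stop("zero residual variance: LSD comparisons undefined")
  means <- tapply(d$value, d$group, mean)
  tab <- data.frame(term = trimws(rownames(s)), df = s[["Df"]],
                    sum_sq = s[["Sum Sq"]], mean_sq = s[["Mean Sq"]],
                    F = s[["F value"]], p = s[["Pr(>F)"]], row.names = NULL)
  structure(list(design = "one_way", metric = metric, table = tab,
                 residual_ms = mse, residual_df = df_res,
                 group_means = means,
                 comparisons = lsd_pairs(as.vector(means), as.vector(ns),
                                         levels(d$group), mse, df_res, alpha),
                 alpha = alpha),
            class = "anova_result")
}

#' Two-way fixed-effects ANOVA with Fisher's LSD comparisons
#'
#' Crossed fixed-effects model with both main effects and their
#' interaction, used for event dynamics where each cell contributes one
#' averaged value per event type (factors: treatment group x event type).
#' LSD comparisons are made between treatment groups within each level of
#' the second factor, using the pooled residual mean square.
#'
#' @param measurements Data frame with the columns of [summarise_groups()]
#'   plus the second factor column.
#' @param metric Which metric to analyse.
#' @param factor2 Name of the second factor column (default `"event_type"`).
#' @param alpha Per-comparison significance level.
#' @return An `anova_result`; `table` has rows for both main effects, the
#'   interaction and residuals, and `comparisons` gains a `within` column
#'   naming the level of `factor2` each comparison is conditioned on.
#' @export
two_way_anova_lsd <- function(measurements, metric, factor2 = "event_type",
                              alpha = 0.05) {
  stopifnot(is.data.frame(measurements), factor2 %in% names(measurements))
  d <- measurements[measurements$metric == metric, , drop = FALSE]
  if (nrow(d) == 0) stop(sprintf("no measurements for metric '%s'", metric))
  d$group <- factor(d$group)
  d$f2 <- factor(d[[factor2]])
  cross <- table(d$group, d$f2)
  if (any(cross < 2)) {
    bad <- which(cross < 2, arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete crossing: combination (%s, %s) has fewer than 2 replicates",
                 rownames(cross)[bad[1]], colnames(cross)[bad[2]]))
  }
  fit <- stats::aov(value ~ group * f2, data = d)
  s <- summary(fit)[[1]]
  mse <- s["Residuals", "Mean Sq"]
  df_res <- s["Residuals", "Df"]
  if (mse <= .Machine$double.eps * max(abs(d$value), 1)^2)
    stop("zero residual variance: LSD comparisons undefined")
  term_names <- trimws(rownames(s))
  term_names[term_names == "group"] <- "group"
  term_names[term_names == "f2"] <- factor2
  term_names[term_names == "group:f2"] <- paste0("group:", factor2)
  tab <- data.frame(term = term_names, df = s[["Df"]],
                    sum_sq = s[["Sum Sq"]], mean_sq = s[["Mean Sq"]],
                    F = s[["F value"]], p = s[["Pr(>F)"]], row.names = NULL)
  comps <- do.call(rbind, lapply(levels(d$f2), function(lv) {
    dd <- d[d$f2 == lv, , drop = FALSE]
    mns <- tapply(dd$value, dd$group, mean)
    nns <- table(dd$group)
    cbind(within = lv,
          lsd_pairs(as.vector(mns), as.vector(nns), levels(dd$group),
                    mse, df_res, alpha))
  }))
  structure(list(design = "two_way", metric = metric, factor2 = factor2,
                 table = tab, residual_ms = mse, residual_df = df_res,
                 comparisons = comps, alpha = alpha),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s ANOVA of '%s'\n", gsub("_", "-", x$design),
              x$metric))
  print(x$table, digits = 4)
  nsig <- sum(x$comparisons$significant)
  cat(sprintf("Fisher's LSD: %d of %d pairwise comparisons significant at alpha = %g\n",
              nsig, nrow(x$comparisons), x$alpha))
  invisible(x)
}
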