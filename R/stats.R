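# Statistical layer: Welch's t, Greenhouse-Geisser epsilon, mixed
# repeated-measures ANOVA, Tukey HSD and Fisher LSD post-hocs, and simple
# linear regression summaries.

#' Welch's two-sample t-test
#'
#' Two-sided Welch test with Welch-Satterthwaite fractional degrees of
#' freedom (thin wrapper over \code{stats::t.test}).
#'
#' @param x,y Numeric samples, each of length >= 2 with finite variance.
#' @return List with \code{t}, \code{df} (fractional), \code{p},
#'   \code{mean_x}, \code{mean_y}.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs n >= 2")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("samples must be finite")
  if (stats::var(x) + stats::var(y) == 0) {
    # degenerate: identical constants give t = 0, p = 1 by convention
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                mean_x = mean(x), mean_y = mean(y)))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), mean_x = mean(x), mean_y = mean(y))
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity correction factor computed from a within-subject covariance
#' matrix via an orthonormal contrast basis:
#' \eqn{\epsilon = tr(C S C')^2 / ((k-1) tr((C S C')^2))}. Always within
#' \eqn{[1/(k-1), 1]}; exactly 1 for k = 2 and for compound-symmetric
#' covariance.
#'
#' @param S Symmetric positive semi-definite k x k covariance matrix,
#'   k >= 2.
#' @return Epsilon.
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (k < 2L || ncol(S) != k) stop("S must be k x k with k >= 2")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S must be symmetric")
  C <- contrast_basis(k)
  M <- C %*% S %*% t(C)
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M * M))
  min(1, max(1 / (k - 1), eps))
}

# Orthonormal (k-1) x k contrast basis (normalized Helmert rows).
contrast_basis <- function(k) {
  H <- stats::contr.helmert(k)
  t(H) / sqrt(colSums(H^2))
}

#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical univariate sum-of-squares decomposition for a design with one
#' between-subjects factor (group) and one within-subjects factor (e.g.
#' session or phase), balanced within (every subject observed at every
#' level). Group sizes may differ. The within-subject effects (within
#' factor and its interaction with group) have their degrees of freedom
#' multiplied by the Greenhouse-Geisser epsilon estimated from the pooled
#' within-group covariance; the group effect is uncorrected and tested
#' against the subject-within-group mean square.
#'
#' @param values Numeric matrix, subjects x within-levels (columns in
#'   within-factor order).
#' @param group Factor or character vector of length \code{nrow(values)}
#'   with >= 2 subjects per group.
#' @param within_name,between_name Labels used in the output table.
#' @return Object of class \code{"rm_anova"}: a data frame \code{table}
#'   with effects (\code{group}, within, interaction), F, df1, df2
#'   (fractional for corrected effects), p and epsilon, plus the error mean
#'   squares and cell means needed by post-hoc procedures.
#' @export
rm_mixed_anova <- function(values, group, within_name = "session",
                           between_name = "drug") {
  values <- as.matrix(values)
  group <- factor(group)
  n <- nrow(values)
  k <- ncol(values)
  if (length(group) != n) stop("group length must match rows of values")
  if (any(is.na(values))) stop("unbalanced design: missing cells")
  ng <- table(group)
  if (any(ng < 2L)) stop("every group needs >= 2 subjects")
  g <- nlevels(group)

  grand <- mean(values)
  subj_means <- rowMeans(values)
  group_means <- tapply(subj_means, group, mean)
  col_means <- colMeans(values)
  cell_means <- apply(values, 2, function(col) tapply(col, group, mean))
  if (g == 1L) cell_means <- matrix(cell_means, nrow = 1)

  ss_total <- sum((values - grand)^2)
  ss_group <- k * sum(ng * (group_means - grand)^2)
  ss_subj <- k * sum((subj_means - group_means[group])^2)
  ss_within_lvl <- n * sum((col_means - grand)^2)
  inter_dev <- sweep(sweep(cell_means, 1, group_means - grand, "-"),
                     2, col_means, "-")
  ss_inter <- sum(rep(ng, times = k) * inter_dev^2)
  ss_err <- ss_total - ss_group - ss_subj - ss_within_lvl - ss_inter

  df_group <- g - 1
  df_subj <- n - g
  df_within <- k - 1
  df_inter <- (g - 1) * (k - 1)
  df_err <- (n - g) * (k - 1)

  # pooled within-group covariance of the k within-levels
  centered <- values
  for (lev in levels(group))
    centered[group == lev, ] <- sweep(values[group == lev, , drop = FALSE],
                                      2, cell_means[lev, ], "-")
  S <- crossprod(centered) / (n - g)
  eps <- gg_epsilon(S)

  ms_group <- ss_group / df_group
  ms_subj <- ss_subj / df_subj
  ms_within <- ss_within_lvl / df_within
  ms_inter <- ss_inter / df_inter
  ms_err <- ss_err / df_err

  f_group <- ms_group / ms_subj
  f_within <- ms_within / ms_err
  f_inter <- ms_inter / ms_err

  tab <- data.frame(
    effect = c(between_name, within_name,
               paste0(between_name, ":", within_name)),
    F = c(f_group, f_within, f_inter),
    df1 = c(df_group, eps * df_within, eps * df_inter),
    df2 = c(df_subj, eps * df_err, eps * df_err),
    epsilon = c(NA, eps, eps),
    p = c(stats::pf(f_group, df_group, df_subj, lower.tail = FALSE),
          stats::pf(f_within, eps * df_within, eps * df_err,
                    lower.tail = FALSE),
          stats::pf(f_inter, eps * df_inter, eps * df_err,
                    lower.tail = FALSE)))
  structure(list(table = tab, epsilon = eps,
                 ss = c(group = ss_group, subj = ss_subj,
                        within = ss_within_lvl, inter = ss_inter,
                        error = ss_err, total = ss_total),
                 ms_subj = ms_subj, ms_err = ms_err,
                 df_subj = df_subj, df_err = df_err,
                 cell_means = cell_means, n_per_group = as.vector(ng),
                 group_levels = levels(group), k = k,
                 within_name = within_name, between_name = between_name),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-16s F(%.2f, %.2f) = %.3f, p = %.4g\n", tab$effect[i],
                tab$df1[i], tab$df2[i], tab$F[i], tab$p[i]))
  cat(sprintf("  epsilon = %.3f\n", x$epsilon))
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted p-values for all pairwise comparisons among
#' cell means sharing an error term (Tukey-Kramer for unequal n).
#'
#' @param cell_means Named numeric vector of cell means.
#' @param error_ms Error mean square.
#' @param df_error Error degrees of freedom.
#' @param n_per_cell Cell sizes (scalar or vector matching
#'   \code{cell_means}).
#' @return Data frame: comparison, difference, p (adjusted), method.
#' @export
tukey_hsd <- function(cell_means, error_ms, df_error, n_per_cell) {
  posthoc_pairs(cell_means, error_ms, df_error, n_per_cell, method = "tukey")
}

#' Fisher's LSD pairwise comparisons
#'
#' Unadjusted pairwise t-tests on the pooled error term.
#' @inheritParams tukey_hsd
#' @return Data frame: comparison, difference, p (unadjusted), method.
#' @export
fisher_lsd <- function(cell_means, error_ms, df_error, n_per_cell) {
  posthoc_pairs(cell_means, error_ms, df_error, n_per_cell,
                method = "fisher_lsd")
}

posthoc_pairs <- function(cell_means, error_ms, df_error, n_per_cell,
                          method) {
  m <- length(cell_means)
  if (m < 2L) stop("need at least two cells")
  if (is.null(names(cell_means))) names(cell_means) <- paste0("c", seq_len(m))
  if (!is.finite(error_ms) || error_ms < 0 || df_error <= 0)
    stop("post-hoc tests require a valid ANOVA error term")
  if (length(n_per_cell) == 1L) n_per_cell <- rep(n_per_cell, m)
  rows <- list()
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    diff <- cell_means[i] - cell_means[j]
    se <- sqrt(error_ms * (1 / n_per_cell[i] + 1 / n_per_cell[j]))
    if (se == 0) {
      p <- if (diff == 0) 1 else 0
    } else if (method == "tukey") {
      q <- abs(diff) / (se / sqrt(2))
      p <- stats::ptukey(q, m, df_error, lower.tail = FALSE)
    } else {
      tt <- diff / se
      p <- 2 * stats::pt(abs(tt), df_error, lower.tail = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = paste(names(cell_means)[i], "-", names(cell_means)[j]),
      difference = unname(diff), p = unname(p), method = method)
  }
  do.call(rbind, rows)
}

#' Simple linear regression summary
#'
#' Ordinary least squares of \code{y} on \code{x} with the F-test of the
#' slope; \code{r_squared} is the squared Pearson correlation. A constant
#' outcome returns slope 0, r_squared 0 and p = 1 by convention.
#'
#' @param x Predictor (length >= 3, not constant).
#' @param y Outcome, same length.
#' @return List: slope, intercept, r_squared, F, df1, df2, p.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  if (stats::var(x) == 0) stop("constant predictor")
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                F = 0, df1 = 1, df2 = n - 2, p = 1))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       F = unname(sm$fstatistic[1]), df1 = 1, df2 = n - 2,
       p = unname(stats::pf(sm$fstatistic[1], 1, n - 2, lower.tail = FALSE)))
}
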