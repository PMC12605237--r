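#' Simple-effects post-hoc comparisons for a mixed RM ANOVA
#'
#' Between-group comparisons at each within-factor level use the pooled
#' error term \eqn{(MS_{subj} + (k-1) MS_{err}) / k} with Satterthwaite
#' degrees of freedom; within-group comparisons between two within levels
#' use the paired error \eqn{2 MS_{err} / n_g}. Tukey adjustment uses the
#' studentized range over the number of groups (so with two groups it
#' coincides with the unadjusted test); \code{fisher_lsd} leaves p
#' unadjusted.
#'
#' @param fit An \code{"rm_anova"} object.
#' @param method \code{"fisher_lsd"} or \code{"tukey"}.
#' @param within_labels Optional labels of the within levels.
#' @return Data frame of comparisons with difference, t/q-equivalent p and
#'   scope (\code{between_at_level} or \code{within_group}).
#' @export
simple_effects <- function(fit, method = c("fisher_lsd", "tukey"),
                           within_labels = NULL) {
  stopifnot(inherits(fit, "rm_anova"))
  method <- match.arg(method)
  k <- fit$k
  cm <- fit$cell_means
  gl <- fit$group_levels
  ng <- fit$n_per_group
  if (is.null(within_labels)) within_labels <- colnames(cm)
  if (is.null(within_labels)) within_labels <- paste0("L", seq_len(k))
  ms_b <- (fit$ms_subj + (k - 1) * fit$ms_err) / k
  df_b <- (fit$ms_subj + (k - 1) * fit$ms_err)^2 /
    (fit$ms_subj^2 / fit$df_subj + ((k - 1) * fit$ms_err)^2 / fit$df_err)
  rows <- list()
  # between-group comparisons at each within level
  for (j in seq_len(k)) {
    for (a in seq_len(length(gl) - 1L)) for (b in (a + 1L):length(gl)) {
      diff <- cm[a, j] - cm[b, j]
      se <- sqrt(ms_b * (1 / ng[a] + 1 / ng[b]))
      p <- if (method == "tukey")
        stats::ptukey(abs(diff) / (se / sqrt(2)), length(gl), df_b,
                      lower.tail = FALSE)
      else 2 * stats::pt(abs(diff) / se, df_b, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        scope = "between_at_level", level = within_labels[j],
        comparison = paste(gl[a], "-", gl[b]), difference = diff,
        p = p, method = method)
    }
  }
  # within-group comparisons between pairs of within levels
  for (g in seq_along(gl)) {
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      diff <- cm[g, a] - cm[g, b]
      se <- sqrt(2 * fit$ms_err / ng[g])
      p <- if (method == "tukey")
        stats::ptukey(abs(diff) / (se / sqrt(2)), k, fit$df_err,
                      lower.tail = FALSE)
      else 2 * stats::pt(abs(diff) / se, fit$df_err, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        scope = "within_group", level = gl[g],
        comparison = paste(within_labels[a], "-", within_labels[b]),
        difference = diff, p = p, method = method)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Wide subjects x levels matrix from a long frame.
long_to_wide <- function(d, key, value = "value") {
  mice <- sort(unique(d$mouse_id))
  levs <- sort(unique(d[[key]]))
  m <- matrix(NA_real_, length(mice), length(levs),
              dimnames = list(mice, levs))
  m[cbind(match(d$mouse_id, mice), match(d[[key]], levs))] <- d[[value]]
  grp <- d$group[match(mice, d$mouse_id)]
  list(values = m, group = grp, mice = mice)
}

#' Two-group x two-phase test on phase composites
#'
#' Mixed ANOVA (group between, phase within, k = 2 so no sphericity
#' correction is needed) followed by Fisher LSD simple effects: the group
#' difference within each phase and the phase difference within each group.
#'
#' @param comp Phase-composite rows (\code{mouse_id, group, phase, value})
#'   for a single measure or combined score.
#' @return List: \code{anova} (an \code{"rm_anova"}), \code{posthoc}
#'   (simple effects, Fisher LSD).
#' @export
phase_group_test <- function(comp) {
  w <- long_to_wide(comp, "phase")
  w$values <- w$values[, c("early", "late"), drop = FALSE]
  fit <- rm_mixed_anova(w$values, w$group, within_name = "phase")
  list(anova = fit,
       posthoc = simple_effects(fit, "fisher_lsd",
                                within_labels = c("early", "late")))
}

#' Longitudinal incubation analysis of a cohort measures table
#'
#' The full inference layer: Z-score standardization to the saline baseline,
#' early/late phase composites, combined social and motor scores, mixed
#' repeated-measures ANOVA over sessions per measure (Greenhouse-Geisser
#' corrected, Tukey post-hocs for the per-session group comparisons),
#' 2 x 2 group-by-phase ANOVAs with Fisher LSD simple effects on the social
#' measures and the combined social score, and the prediction regressions
#' (early motor score vs early/late social score, early vs late social
#' score, and weight loss vs social scores when weights are supplied).
#'
#' @param measures Long measures table.
#' @param manifest A \code{\link{cohort_manifest}} (for groups and weight
#'   loss).
#' @param session_measures Measures given a per-session RM ANOVA (default: a
#'   core set covering exploration and social counts present in the table).
#' @param drop_degenerate Drop (with a warning) measures whose saline
#'   baseline variance is zero instead of erroring; useful on very short
#'   sessions (default FALSE).
#' @return Object of class \code{"incubation_analysis"}.
#' @export
incubation_analysis <- function(measures, manifest,
                                session_measures = NULL,
                                drop_degenerate = FALSE) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  if (drop_degenerate) {
    ref <- measures[measures$group == "saline" & measures$session == "S0", ]
    bad <- names(which(tapply(ref$value, ref$measure, stats::sd) == 0))
    if (length(bad)) {
      warning("dropping zero-baseline-variance measure(s): ",
              paste(bad, collapse = ", "), call. = FALSE)
      measures <- measures[!measures$measure %in% bad, ]
    }
  }
  have <- unique(measures$measure)
  if (is.null(session_measures))
    session_measures <- intersect(
      c("hab_distance_cm", "hab_center_distance_cm", "hab_pct_time_center",
        "hab_rear_count", "int_distance_cm", "int_move_count",
        "int_move_isolated_count", "int_move_in_contact_count",
        "int_contact_count", "int_approach_count",
        "int_total_dyadic_count"), have)
  zt <- zscore_normalize(measures)
  comp <- phase_composites(zt)

  session_measures <- intersect(session_measures, have)
  has_social <- all(SOCIAL_MEASURES %in% have)
  has_motor <- all(MOTOR_MEASURES %in% have)
  social_comb <- if (has_social)
    combined_zscore(comp, "social", by = c("group", "phase")) else NULL
  motor_comb <- if (has_motor)
    combined_zscore(comp, "motor", by = c("group", "phase")) else NULL

  session_anova <- lapply(session_measures, function(ms) {
    w <- long_to_wide(measures[measures$measure == ms, ], "session")
    fit <- rm_mixed_anova(w$values, w$group, within_name = "session")
    list(fit = fit,
         posthoc = simple_effects(fit, "tukey",
                                  within_labels = colnames(w$values)))
  })
  names(session_anova) <- session_measures

  phase_tests <- list()
  if (has_social) {
    for (ms in SOCIAL_MEASURES)
      phase_tests[[ms]] <- phase_group_test(comp[comp$measure == ms, ])
    phase_tests[["combined_social"]] <- phase_group_test(social_comb)
  }
  if (has_motor)
    phase_tests[["combined_motor"]] <- phase_group_test(motor_comb)

  regressions <- list()
  if (has_social && has_motor) {
    sw <- long_to_wide(social_comb, "phase")$values
    mw <- long_to_wide(motor_comb, "phase")$values
    regressions$early_motor_vs_early_social <-
      linear_fit(mw[, "early"], sw[, "early"])
    regressions$early_motor_vs_late_social <-
      linear_fit(mw[, "early"], sw[, "late"])
    regressions$early_social_vs_late_social <-
      linear_fit(sw[, "early"], sw[, "late"])
  }
  wl <- weight_loss(manifest)
  groups <- manifest$mice$group
  weight_test <- if (stats::var(wl) > 0)
    welch_t(wl[groups == "morphine"], wl[groups == "saline"]) else NULL
  if (has_social && any(wl != 0)) {
    sw <- long_to_wide(social_comb, "phase")$values
    wlo <- wl[rownames(sw)]
    regressions$weight_loss_vs_early_social <- linear_fit(wlo, sw[, "early"])
    regressions$weight_loss_vs_late_social <- linear_fit(wlo, sw[, "late"])
  }

  structure(list(zscores = zt, composites = comp,
                 combined_social = social_comb, combined_motor = motor_comb,
                 session_anova = session_anova, phase_tests = phase_tests,
                 regressions = regressions, weight_test = weight_test,
                 manifest = manifest),
            class = "incubation_analysis")
}

#' @export
print.incubation_analysis <- function(x, ...) {
  cat("Incubation analysis\n")
  cat(sprintf("  %d mice, measures standardized to the saline baseline\n",
              nrow(x$manifest$mice)))
  if (!is.null(x$phase_tests$combined_social)) {
    pt <- x$phase_tests$combined_social
    tab <- pt$anova$table
    cat("  Combined social Z (group x phase):\n")
    for (i in seq_len(nrow(tab)))
      cat(sprintf("    %-12s F(%.2f, %.2f) = %.3f, p = %.4g\n",
                  tab$effect[i], tab$df1[i], tab$df2[i], tab$F[i], tab$p[i]))
    ph <- pt$posthoc
    sel <- ph$scope == "between_at_level"
    for (i in which(sel))
      cat(sprintf("    group difference at %s phase: p = %.4g\n",
                  ph$level[i], ph$p[i]))
  }
  if (!is.null(x$weight_test))
    cat(sprintf("  Weight loss (Welch): t(%.2f) = %.3f, p = %.4g\n",
                x$weight_test$df, x$weight_test$t, x$weight_test$p))
  if (length(x$regressions)) {
    cat("  Regressions:\n")
    for (nm in names(x$regressions)) {
      r <- x$regressions[[nm]]
      cat(sprintf("    %-28s slope = %+.3f, r^2 = %.3f, p = %.4g\n",
                  nm, r$slope, r$r_squared, r$p))
    }
  }
  invisible(x)
}

#' Group-by-phase test on the combined social Z-score
#'
#' Convenience wrapper: standardizes the measures table, forms phase
#' composites, averages the social member measures into the combined social
#' score and runs \code{\link{phase_group_test}} on it.
#'
#' @param measures Long measures table including the social measures.
#' @return As \code{\link{phase_group_test}}, plus element
#'   \code{combined} (the per-mouse combined social phase values).
#' @export
combined_social_phase_test <- function(measures) {
  zt <- zscore_normalize(measures)
  comp <- phase_composites(zt)
  sc <- combined_zscore(comp, "social", by = c("group", "phase"))
  out <- phase_group_test(sc)
  out$combined <- sc
  out
}
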