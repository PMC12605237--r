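# Z-score standardization to the control baseline, phase composites, and
# combined social / motor scores.

#' Standardize measures to the control-group baseline
#'
#' For every measure, computes the reference mean and sample (n-1) standard
#' deviation from the saline group at the baseline session (S0) and
#' standardizes every row of the table as \eqn{z = (X - \mu) / \sigma}.
#' By construction the saline S0 cells of each measure have mean 0 and
#' standard deviation 1 exactly.
#'
#' @param measures Long measures table (\code{mouse_id, group, session,
#'   measure, value}).
#' @param baseline_session Reference session label (default "S0").
#' @param reference_group Reference group (default "saline").
#' @return Object of class \code{"zscore_table"}: the long table with a
#'   \code{z} column, plus the reference \code{(mu, sigma)} per measure.
#' @export
zscore_normalize <- function(measures, baseline_session = "S0",
                             reference_group = "saline") {
  ref_rows <- measures[measures$group == reference_group &
                         measures$session == baseline_session, ]
  if (!nrow(ref_rows))
    stop("missing ", reference_group, " baseline rows")
  ref <- do.call(rbind, lapply(split(ref_rows, ref_rows$measure), function(d) {
    if (nrow(d) < 2L)
      stop("need >= 2 reference mice for measure ", d$measure[1])
    data.frame(measure = d$measure[1], mu = mean(d$value),
               sigma = stats::sd(d$value))
  }))
  rownames(ref) <- NULL
  if (any(ref$sigma == 0))
    stop("zero baseline variance for measure(s): ",
         paste(ref$measure[ref$sigma == 0], collapse = ", "))
  idx <- match(measures$measure, ref$measure)
  if (anyNA(idx)) stop("measure(s) missing from the reference")
  z <- (measures$value - ref$mu[idx]) / ref$sigma[idx]
  out <- measures
  out$z <- z
  structure(list(z = out, reference = ref), class = "zscore_table")
}

#' Early/late phase composites of Z-scores
#'
#' Per mouse and measure, the early composite is the mean Z over sessions
#' S1-S2 (24 h and week 1) and the late composite the mean over S3-S5
#' (weeks 2-4).
#'
#' @param zt A \code{"zscore_table"} from \code{\link{zscore_normalize}}.
#' @return Data frame \code{(mouse_id, group, measure, phase, value)} with
#'   phase in \code{early}/\code{late}.
#' @export
phase_composites <- function(zt) {
  stopifnot(inherits(zt, "zscore_table"))
  z <- zt$z
  phases <- list(early = c("S1", "S2"), late = c("S3", "S4", "S5"))
  need <- unlist(phases)
  missing_s <- setdiff(need, unique(z$session))
  if (length(missing_s))
    stop("missing session(s): ", paste(missing_s, collapse = ", "))
  out <- list()
  for (ph in names(phases)) {
    d <- z[z$session %in% phases[[ph]], ]
    agg <- stats::aggregate(z ~ mouse_id + group + measure, data = d,
                            FUN = mean)
    k_expected <- length(phases[[ph]])
    cnt <- stats::aggregate(z ~ mouse_id + group + measure, data = d,
                            FUN = length)
    if (any(cnt$z != k_expected))
      stop("incomplete sessions for phase ", ph)
    out[[ph]] <- data.frame(mouse_id = agg$mouse_id, group = agg$group,
                            measure = agg$measure, phase = ph,
                            value = agg$z)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mouse_id, res$measure, res$phase), ]
  rownames(res) <- NULL
  res
}

#' Combined social or motor Z-score
#'
#' Unweighted mean of the member measures' Z-scores (or phase composites):
#' the social set is the number of contacts, social approaches and total
#' dyadic events; the motor set is the habituation total distance, center
#' distance and rearing count.
#'
#' @param scores Long data frame with columns \code{mouse_id},
#'   \code{measure} and a score column (\code{z} or \code{value}), e.g. a
#'   z-table or phase composites.
#' @param measure_set \code{"social"}, \code{"motor"}, or a character
#'   vector of measure names.
#' @param by Extra grouping columns present in \code{scores} to retain
#'   (e.g. \code{"session"} or \code{"phase"}).
#' @return Data frame with the grouping columns and the combined
#'   \code{value}.
#' @export
combined_zscore <- function(scores, measure_set = c("social", "motor"),
                            by = intersect(c("group", "session", "phase"),
                                           names(scores))) {
  members <- if (is.character(measure_set) && length(measure_set) == 1L &&
                 measure_set %in% c("social", "motor")) {
    if (measure_set == "social") SOCIAL_MEASURES else MOTOR_MEASURES
  } else measure_set
  val_col <- if ("z" %in% names(scores)) "z" else "value"
  d <- scores[scores$measure %in% members, , drop = FALSE]
  present <- unique(d$measure)
  if (length(setdiff(members, present)))
    stop("missing member measure(s): ",
         paste(setdiff(members, present), collapse = ", "))
  keys <- c("mouse_id", by)
  fml <- stats::as.formula(paste(val_col, "~",
                                 paste(keys, collapse = "+")))
  cnt <- stats::aggregate(fml, data = d, FUN = length)
  if (any(cnt[[val_col]] != length(members)))
    stop("missing member measure for some mouse")
  agg <- stats::aggregate(fml, data = d, FUN = mean)
  names(agg)[names(agg) == val_col] <- "value"
  agg[do.call(order, agg[keys]), , drop = FALSE]
}
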