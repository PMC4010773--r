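# Statistical layer: within-group paired t-tests, the 2x2 repeated-measures
# interaction, per-band Benjamini-Hochberg FDR flags, and report tables.

#' Paired t-test between two conditions
#'
#' Classical paired t on the per-subject differences `post - pre`, two-sided,
#' df = n - 1. A positive statistic means `pre > post` under the convention
#' used here (t is computed on `pre - post` so that a decrease after the
#' intervention gives a positive t, matching the usual clinical-table sign).
#'
#' @param values_pre,values_post Equal-length paired numeric vectors, n >= 3.
#' @param measure,band Optional labels carried into the result.
#' @return A one-row data.frame (a `StatResult` row): `test`, `measure`,
#'   `band`, `statistic`, `df`, `p`.
#' @export
paired_t <- function(values_pre, values_post,
                     measure = NA_character_, band = NA_character_) {
  stopifnot(length(values_pre) == length(values_post))
  if (length(values_pre) < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(values_pre)) || any(!is.finite(values_post)))
    stop("non-finite values")
  d <- values_pre - values_post
  if (stats::sd(d) == 0) {
    # identical conditions: no effect, t = 0 by convention; a constant
    # nonzero difference is genuinely degenerate (t undefined)
    if (all(d == 0))
      return(data.frame(test = "paired_t", measure = measure, band = band,
                        statistic = 0, df = length(d) - 1L, p = 1,
                        stringsAsFactors = FALSE))
    stop("zero variance of paired differences: t statistic undefined")
  }
  ht <- stats::t.test(values_pre, values_post, paired = TRUE)
  data.frame(test = "paired_t", measure = measure, band = band,
             statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, stringsAsFactors = FALSE)
}

#' Group-by-condition interaction from a 2x2 repeated-measures ANOVA
#'
#' With one within-subject factor at two levels (condition) and one
#' between-subject factor at two levels (group), the interaction F is
#' computed exactly via the difference-score identity: it equals the square
#' of the pooled two-sample t statistic comparing the per-subject
#' condition differences between groups, with df = (1, n1 + n2 - 2). The
#' test suite verifies the identity against a full `aov` error-stratum fit.
#'
#' @param records Data.frame with columns `subject_id`, `group`
#'   (patient/control), `condition` (routine/sleep_deprived), `value`, for a
#'   single measure in a single band. Every subject must have both
#'   conditions.
#' @param measure,band Optional labels carried into the result.
#' @return A one-row data.frame: `test`, `measure`, `band`, `statistic` (F),
#'   `df1`, `df2`, `p`, plus `mean_diff_patient` and `mean_diff_control`
#'   (mean sleep_deprived - routine change per group, for sign checks).
#' @export
rm_anova_interaction <- function(records, measure = NA_character_,
                                 band = NA_character_) {
  need <- c("subject_id", "group", "condition", "value")
  stopifnot(all(need %in% names(records)))
  wide <- stats::reshape(records[, need], direction = "wide",
                         idvar = c("subject_id", "group"),
                         timevar = "condition")
  vr <- "value.routine"; vs <- "value.sleep_deprived"
  if (!all(c(vr, vs) %in% names(wide)) ||
      any(is.na(wide[[vr]])) || any(is.na(wide[[vs]])))
    stop("every subject needs a value for both conditions; missing for: ",
         paste(wide$subject_id[is.na(wide[[vr]]) | is.na(wide[[vs]])],
               collapse = ", "))
  d <- wide[[vs]] - wide[[vr]]
  g <- wide$group
  n1 <- sum(g == "patient"); n2 <- sum(g == "control")
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per group")
  d1 <- d[g == "patient"]; d2 <- d[g == "control"]
  sp2 <- ((n1 - 1) * stats::var(d1) + (n2 - 1) * stats::var(d2)) /
    (n1 + n2 - 2)
  df2 <- n1 + n2 - 2L
  if (sp2 == 0) {
    # all difference scores constant within group: an exactly parallel shift
    # gives F = 0; differing constant shifts leave the statistic undefined
    if (mean(d1) == mean(d2)) {
      Fstat <- 0
    } else {
      stop("zero variance of difference scores with unequal group means: ",
           "interaction F undefined")
    }
  } else {
    tstat <- (mean(d1) - mean(d2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    Fstat <- tstat^2
  }
  data.frame(test = "rm_anova_interaction", measure = measure, band = band,
             statistic = Fstat, df1 = 1L, df2 = df2,
             p = stats::pf(Fstat, 1, df2, lower.tail = FALSE),
             mean_diff_patient = mean(d1), mean_diff_control = mean(d2),
             stringsAsFactors = FALSE)
}

#' Per-band Benjamini-Hochberg significance flags
#'
#' Applies the BH step-up procedure independently within each frequency band
#' (the correction family is the set of measures tested in one band, since
#' each band reflects a distinct functional network), flagging results whose
#' BH-adjusted p-value is at most `q`.
#'
#' @param results Data.frame of stat results with columns `band` and `p`.
#' @param q Target false discovery rate (default 0.05).
#' @return `results` with columns `p_adj` and `fdr_significant` appended.
#' @export
fdr_correct <- function(results, q = 0.05) {
  stopifnot(is.data.frame(results), all(c("band", "p") %in% names(results)))
  if (!nrow(results)) {
    results$p_adj <- numeric(0)
    results$fdr_significant <- logical(0)
    return(results)
  }
  stopifnot(all(is.na(results$p) | (results$p >= 0 & results$p <= 1)))
  results$p_adj <- NA_real_
  for (b in unique(results$band)) {
    i <- which(results$band == b)
    results$p_adj[i] <- stats::p.adjust(results$p[i], method = "BH")
  }
  results$fdr_significant <- !is.na(results$p_adj) & results$p_adj <= q
  results
}

#' Build the report tables of the full analysis
#'
#' Produces the four standard outputs from a long measure table:
#' \describe{
#'   \item{power_paired}{Per group, paired t between conditions for relative
#'     power in each power band (with group means and SDs per condition).}
#'   \item{paired_patients / paired_controls}{Paired t between conditions for
#'     the network measures (path length, clustering coefficient, and their
#'     normalized forms) and tree measures (diameter, leaf number), per band,
#'     FDR-flagged within band.}
#'   \item{interaction}{Group-by-condition interaction F per measure per
#'     band, both on the full cohort and on the subset restricted to
#'     added-value patients plus all controls, FDR-flagged within band and
#'     scope.}
#' }
#'
#' @param measures Long data.frame of measure records: `subject_id`, `group`,
#'   `condition`, `band`, `measure`, `value`, and (for the subset analysis)
#'   `added_value`.
#' @param q False discovery rate per band family (default 0.05).
#' @param table_measures Network/tree measures to tabulate (rows of the
#'   paired and interaction tables); the FDR family in those tables is these
#'   measures within one band.
#' @return Named list of data.frames as described above.
#' @export
build_tables <- function(measures, q = 0.05,
                         table_measures = c("path_length",
                                            "clustering_coefficient",
                                            "diameter", "leaf_number")) {
  need <- c("subject_id", "group", "condition", "band", "measure", "value")
  stopifnot(all(need %in% names(measures)))
  power_measures <- intersect(unique(measures$measure), "relative_power")
  net_measures <- intersect(unique(measures$measure), table_measures)

  paired_rows <- function(df) {
    out <- list()
    for (b in unique(df$band)) for (m in unique(df$measure)) {
      sub <- df[df$band == b & df$measure == m, ]
      if (!nrow(sub)) next
      wide <- stats::reshape(sub[, need[c(1, 3, 6)]], direction = "wide",
                             idvar = "subject_id", timevar = "condition")
      pre <- wide$value.routine; post <- wide$value.sleep_deprived
      # degenerate measures (e.g. a constant discrete count in a tiny
      # cohort) yield an NA row rather than aborting the whole table
      row <- tryCatch(paired_t(pre, post, measure = m, band = b),
                      error = function(e) {
                        warning("paired t for ", m, " (", b, "): ",
                                conditionMessage(e), call. = FALSE)
                        data.frame(test = "paired_t", measure = m, band = b,
                                   statistic = NA_real_,
                                   df = length(pre) - 1L, p = NA_real_,
                                   stringsAsFactors = FALSE)
                      })
      row$mean_pre <- mean(pre); row$sd_pre <- stats::sd(pre)
      row$mean_post <- mean(post); row$sd_post <- stats::sd(post)
      out[[length(out) + 1L]] <- row
    }
    do.call(rbind, out)
  }
  paired_for <- function(df) fdr_correct(paired_rows(df), q = q)

  net <- measures[measures$measure %in% net_measures, ]
  pw <- measures[measures$measure %in% power_measures, ]

  tables <- list()
  if (nrow(pw)) {
    # the power-table correction family is the set of power bands per group
    tables$power_paired <- do.call(rbind, lapply(c("patient", "control"),
      function(g) {
        tab <- paired_rows(pw[pw$group == g, ])
        tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
        tab$fdr_significant <- tab$p_adj <= q
        tab$group <- g
        tab
      }))
  }
  tables$paired_patients <- paired_for(net[net$group == "patient", ])
  tables$paired_controls <- paired_for(net[net$group == "control", ])

  interaction_for <- function(df, scope) {
    out <- list()
    for (b in unique(df$band)) for (m in unique(df$measure)) {
      sub <- df[df$band == b & df$measure == m, ]
      if (!nrow(sub)) next
      row <- rm_anova_interaction(sub, measure = m, band = b)
      row$scope <- scope
      out[[length(out) + 1L]] <- row
    }
    fdr_correct(do.call(rbind, out), q = q)
  }
  tables$interaction <- interaction_for(net, "all")
  if ("added_value" %in% names(measures)) {
    keep <- net$group == "control" | net$added_value
    sub <- net[keep, ]
    if (any(sub$group == "patient")) {
      tables$interaction <- rbind(tables$interaction,
                                  interaction_for(sub, "added_value"))
    } else {
      warning("no added-value patients; subset interaction omitted")
    }
  }
  tables
}
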