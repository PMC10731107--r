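#' Validate a cohort metrics table
#'
#' One row per subject-session with sessions in `preflight`, `postflight`,
#' `followup`; every subject must have a preflight row.
#' @param cohort data frame.
#' @keywords internal
validate_cohort_table <- function(cohort) {
  req <- c("subject_id", "session", "global_tb_vbmd", "rbmd_superior",
           "rbmd_transverse", "rbmd_inferior", "total_muscle_csa",
           "total_muscle_density", "mission_months", "readapt_months")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols) > 0) {
    stop(sprintf("cohort table missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(cohort$session), c("preflight", "postflight", "followup"))
  if (length(bad) > 0) {
    stop(sprintf("unknown session label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(duplicated(cohort[, c("subject_id", "session")]))) {
    stop("cohort table has duplicated subject-session rows", call. = FALSE)
  }
  no_pre <- setdiff(unique(cohort$subject_id),
                    cohort$subject_id[cohort$session == "preflight"])
  if (length(no_pre) > 0) {
    stop(sprintf("subjects missing a preflight session: %s",
                 paste(no_pre, collapse = ", ")), call. = FALSE)
  }
  invisible(cohort)
}

session_frame <- function(cohort, session) {
  sub <- cohort[cohort$session == session, , drop = FALSE]
  sub[match(unique(cohort$subject_id), sub$subject_id), , drop = FALSE]
}

#' Build the longitudinal cohort report
#'
#' Computes, for every metric (global trabecular vBMD, the three regional
#' densities, total muscle CSA and size-weighted muscle density):
#' preflight mean and SD; flight percent change (postflight vs preflight,
#' paired t-test) and its monthly rate (divided by each subject's mission
#' duration; one-sample t-test vs 0); readaptation percent change (follow-up
#' vs postflight) with its monthly rate; the follow-up-vs-preflight percent
#' difference; and per-session bone-muscle regressions (global vBMD on muscle
#' density and on muscle CSA). Subjects without a follow-up session never
#' contribute to readaptation statistics; flight statistics use all subjects.
#'
#' @param cohort cohort metrics table (see [validate_cohort_table()]).
#' @param readapt_denominator `"readapt"` (default) divides readaptation
#'   percent changes by elapsed readaptation months; `"mission"` divides by
#'   mission duration instead.
#' @param alpha significance threshold for flagging, default 0.05.
#' @return An object of class `qct_report` with data-frame components
#'   `preflight`, `flight`, `readaptation`, `followup_vs_preflight`,
#'   `regressions`.
#' @export
build_report <- function(cohort, readapt_denominator = c("readapt", "mission"),
                         alpha = 0.05) {
  validate_cohort_table(cohort)
  readapt_denominator <- match.arg(readapt_denominator)
  metrics <- c(global_tb_vbmd = "Global Tb.vBMD (mg/cm^3)",
               rbmd_superior = "Superior rBMD (mg/cm^3)",
               rbmd_transverse = "Transverse rBMD (mg/cm^3)",
               rbmd_inferior = "Inferior rBMD (mg/cm^3)",
               total_muscle_csa = "Total paraspinal muscle CSA (mm^2)",
               total_muscle_density = "Total paraspinal muscle density (HU)")
  pre <- session_frame(cohort, "preflight")
  post <- session_frame(cohort, "postflight")
  fup <- session_frame(cohort, "followup")

  pre_tab <- data.frame(metric = unname(metrics),
                        mean = vapply(names(metrics), function(m) mean(pre[[m]]), 0),
                        sd = vapply(names(metrics), function(m) sd(pre[[m]]), 0),
                        n = nrow(pre), row.names = NULL)

  # degenerate metrics (zero variance, e.g. a perfectly constant measure)
  # yield NA p-values rather than aborting the whole report
  safe_p <- function(expr) tryCatch(expr$p_two_sided, error = function(e) NA_real_)

  change_block <- function(base, later, months, label) {
    rows <- lapply(names(metrics), function(m) {
      pct <- percent_change(base[[m]], later[[m]])
      rate <- monthly_rate(pct, months)
      ok <- !is.na(pct)
      pp <- safe_p(paired_ttest(base[[m]], later[[m]], comparison = label))
      rp <- safe_p(one_sample_ttest(rate, comparison = paste(label, "rate vs 0")))
      data.frame(metric = metrics[[m]],
                 pct_mean = mean(pct[ok]), pct_sd = sd(pct[ok]),
                 pct_p = pp,
                 rate_mean = mean(rate[ok]), rate_sd = sd(rate[ok]),
                 rate_p = rp, n = sum(ok), row.names = NULL)
    })
    out <- do.call(rbind, rows)
    out$pct_significant <- !is.na(out$pct_p) & out$pct_p <= alpha
    out$rate_significant <- !is.na(out$rate_p) & out$rate_p <= alpha
    out
  }

  flight <- change_block(pre, post, post$mission_months, "postflight vs preflight")

  readapt <- NULL
  fup_vs_pre <- NULL
  if (any(!is.na(fup$subject_id))) {
    has_fup <- !is.na(fup$subject_id)
    months <- if (readapt_denominator == "readapt") {
      fup$readapt_months
    } else {
      fup$mission_months
    }
    readapt <- change_block(post[has_fup, , drop = FALSE],
                            fup[has_fup, , drop = FALSE],
                            months[has_fup], "followup vs postflight")
    rows <- lapply(names(metrics), function(m) {
      pct <- percent_change(pre[[m]][has_fup], fup[[m]][has_fup])
      pp <- safe_p(paired_ttest(pre[[m]][has_fup], fup[[m]][has_fup],
                                comparison = "followup vs preflight"))
      data.frame(metric = metrics[[m]], pct_mean = mean(pct), pct_sd = sd(pct),
                 pct_p = pp, n = sum(has_fup), row.names = NULL)
    })
    fup_vs_pre <- do.call(rbind, rows)
    fup_vs_pre$pct_significant <- !is.na(fup_vs_pre$pct_p) &
      fup_vs_pre$pct_p <= alpha
  }

  reg_rows <- list()
  for (sess in c("preflight", "postflight", "followup")) {
    sf <- session_frame(cohort, sess)
    sf <- sf[!is.na(sf$subject_id), , drop = FALSE]
    if (nrow(sf) < 3) next
    for (pred in c("total_muscle_density", "total_muscle_csa")) {
      r <- linear_regression(sf[[pred]], sf$global_tb_vbmd)
      reg_rows[[length(reg_rows) + 1L]] <-
        data.frame(session = sess, response = "global_tb_vbmd",
                   predictor = pred, slope = r$slope, intercept = r$intercept,
                   r_squared = r$r_squared, p = r$p, n = r$n,
                   significant = r$p <= alpha, row.names = NULL)
    }
  }
  regressions <- if (length(reg_rows)) do.call(rbind, reg_rows) else NULL

  structure(list(preflight = pre_tab, flight = flight, readaptation = readapt,
                 followup_vs_preflight = fup_vs_pre, regressions = regressions,
                 options = list(readapt_denominator = readapt_denominator,
                                alpha = alpha)),
            class = "qct_report")
}

fmt_block <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  print(df, row.names = FALSE)
}

#' @export
print.qct_report <- function(x, digits = 3, ...) {
  cat("== Preflight values (mean +/- SD) ==\n")
  fmt_block(x$preflight, digits)
  cat("\n== Spaceflight changes (percent and %/month) ==\n")
  fmt_block(x$flight, digits)
  if (!is.null(x$readaptation)) {
    cat("\n== Readaptation changes (percent and %/month) ==\n")
    fmt_block(x$readaptation, digits)
    cat("\n== Follow-up vs preflight (percent) ==\n")
    fmt_block(x$followup_vs_preflight, digits)
  }
  if (!is.null(x$regressions)) {
    cat("\n== Bone-muscle regressions (global Tb.vBMD as response) ==\n")
    fmt_block(x$regressions, digits)
  }
  invisible(x)
}

#' @export
summary.qct_report <- function(object, ...) object

#' Plot a cohort report
#'
#' Box plots of per-metric percent changes would need the per-subject values,
#' so the plot shows the reported means with +/- SD whiskers for flight (and
#' readaptation when present), mirroring the cohort-level figures of a
#' longitudinal QCT study.
#'
#' @param x A `qct_report`.
#' @param ... unused.
#' @export
plot.qct_report <- function(x, ...) {
  fl <- x$flight
  has_re <- !is.null(x$readaptation)
  old <- graphics::par(mar = c(10, 4, 2, 1))
  on.exit(graphics::par(old))
  n <- nrow(fl)
  at <- seq_len(n)
  ylim <- range(c(fl$pct_mean - fl$pct_sd, fl$pct_mean + fl$pct_sd,
                  if (has_re) x$readaptation$pct_mean - x$readaptation$pct_sd,
                  if (has_re) x$readaptation$pct_mean + x$readaptation$pct_sd, 0))
  graphics::plot(at - 0.1, fl$pct_mean, pch = 19, col = "firebrick",
                 xaxt = "n", xlab = "", ylab = "Percent change (%)",
                 xlim = c(0.5, n + 0.5), ylim = ylim,
                 main = "Cohort percent changes (mean +/- SD)")
  graphics::arrows(at - 0.1, fl$pct_mean - fl$pct_sd, at - 0.1,
                   fl$pct_mean + fl$pct_sd, angle = 90, code = 3,
                   length = 0.03, col = "firebrick")
  if (has_re) {
    re <- x$readaptation
    graphics::points(at + 0.1, re$pct_mean, pch = 17, col = "steelblue")
    graphics::arrows(at + 0.1, re$pct_mean - re$pct_sd, at + 0.1,
                     re$pct_mean + re$pct_sd, angle = 90, code = 3,
                     length = 0.03, col = "steelblue")
    graphics::legend("bottomright", legend = c("flight", "readaptation"),
                     pch = c(19, 17), col = c("firebrick", "steelblue"),
                     bty = "n")
  }
  graphics::abline(h = 0, lty = 3)
  graphics::axis(1, at = at, labels = fl$metric, las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Write report tables to CSV and JSON
#'
#' @param report A `qct_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "qct_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("preflight", "flight", "readaptation", "followup_vs_preflight",
               "regressions")) {
    if (!is.null(report[[nm]])) {
      write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  jsonlite::write_json(report[!vapply(report, is.null, TRUE)],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
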