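#' Analysis window relative to an event
#'
#' Describes the 3-day (by default) window extracted on either side of the
#' induction event (or of the recording start) for band-power comparison.
#'
#' @param side `"before"` or `"after"` the reference event.
#' @param duration Window length in seconds (default 3 days).
#' @param reference `"induction"` (requires `induction_time` on the
#'   channel) or `"recording_start"`.
#' @return A list of class `myco_segment_spec`.
#' @export
segment_spec <- function(side = c("before", "after"),
                         duration = 3 * 86400,
                         reference = c("induction", "recording_start")) {
  side <- match.arg(side)
  reference <- match.arg(reference)
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be > 0")
  structure(list(side = side, duration = duration, reference = reference),
            class = "myco_segment_spec")
}

#' Locate an analysis window on a recording set
#'
#' Computes the `[start, end)` interval the segment spec describes,
#' anchored at the set's induction time (which must be shared across the
#' channels being compared) or at the recording start. Intervals running
#' past the recording are clipped; clipping by more than 1% of the window
#' raises a warning.
#'
#' @param set A `myco_recordings` tibble.
#' @param spec A [segment_spec()].
#' @return Numeric `c(start, end)` in seconds.
#' @export
extract_segment <- function(set, spec) {
  validate_recording_set(set)
  span <- recording_span(set)
  if (spec$reference == "induction") {
    it <- unique(set$induction_time[!is.na(set$induction_time)])
    if (length(it) == 0) {
      abort("no channel carries an induction_time; cannot anchor the window")
    }
    if (length(it) > 1) {
      abort(sprintf("channels disagree on induction_time (%s); split the set first",
                    paste(signif(it, 6), collapse = ", ")))
    }
    anchor <- it
  } else {
    anchor <- 0
  }
  raw <- if (spec$side == "before") {
    c(anchor - spec$duration, anchor)
  } else {
    c(anchor, anchor + spec$duration)
  }
  clipped <- c(max(0, raw[1]), min(span, raw[2]))
  if (clipped[2] <= clipped[1]) {
    abort(sprintf("window [%.6g, %.6g) lies outside the recording span [0, %.6g]",
                  raw[1], raw[2], span))
  }
  lost <- (spec$duration - diff(clipped)) / spec$duration
  if (lost > 0.01) {
    warn(sprintf("analysis window clipped by %.1f%% to [%.6g, %.6g)",
                 100 * lost, clipped[1], clipped[2]))
  }
  clipped
}

#' Shapiro-Wilk normality check that degrades gracefully
#'
#' Wraps [stats::shapiro.test()] so that undersized or degenerate groups
#' yield a flag instead of an exception, letting a multi-condition pipeline
#' report what it can.
#'
#' @param values Numeric vector.
#' @return A list with `W`, `p`, and `flag` (`NA` when the test ran;
#'   otherwise `"insufficient n"` or `"zero variance"`).
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    return(list(W = NA_real_, p = NA_real_, flag = "insufficient n"))
  }
  if (sd(values) == 0) {
    return(list(W = NA_real_, p = NA_real_, flag = "zero variance"))
  }
  st <- shapiro.test(values)
  list(W = unname(st$statistic), p = unname(st$p.value), flag = NA_character_)
}

#' Welch's two-sample t-test
#'
#' Location test that does not assume equal group variances:
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df`, `p`.
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("Welch's t-test needs at least 2 observations per group")
  }
  if (var(a) == 0 && var(b) == 0) {
    abort("both groups have zero variance; the t statistic is undefined")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Percent change between two mean powers
#'
#' `(treated_mean / control_mean - 1) * 100`, the effect summary used to
#' report how band power differs between conditions. Reported values are
#' conventionally rounded to 3 decimals; this function returns the
#' unrounded number.
#'
#' @param treated_mean,control_mean Mean band powers (V^2);
#'   `control_mean` must be positive.
#' @return Percent change (dimensionless).
#' @examples
#' percent_change(3.44429e-7, 2.0204e-8) # ~1604.76
#' @export
percent_change <- function(treated_mean, control_mean) {
  if (any(control_mean <= 0)) abort("`control_mean` must be > 0")
  (treated_mean / control_mean - 1) * 100
}

group_summary <- function(label, powers, channel_ids) {
  list(
    label = label, n = length(powers),
    channel_ids = channel_ids, channel_powers = powers,
    mean_power = mean(powers),
    shapiro = shapiro_wilk(powers)
  )
}

#' Compare band power between two channel groups
#'
#' The quantitative core of the analysis: per-channel band-integrated
#' average power over one analysis window, averaged within each group,
#' checked for normality (Shapiro-Wilk), compared by Welch's t-test, and
#' summarised as a percent change of group A relative to group B. Groups
#' with fewer than 2 channels get `percent_change` but flagged test
#' fields rather than an error, mirroring how single-replicate conditions
#' are reported.
#'
#' @param set A cleaned `myco_recordings` tibble (see [drop_missing()]).
#' @param a,b Logical predicates on the metadata columns selecting the two
#'   groups, e.g. `a = inoculated`, `b = !inoculated` or
#'   `a = treatment == "voriconazole"`.
#' @param segment A [segment_spec()]; default 3 days before induction.
#' @param band Frequency band `c(low, high)` in Hz integrated for each
#'   channel (default the full 0-4 Hz analyzed spectrum).
#' @param label Comparison label for reports.
#' @param resample,params Passed to [segment_average_power()].
#' @return An object of class `myco_comparison`; see [tidy.myco_comparison()]
#'   and [glance.myco_comparison()].
#' @export
compare_conditions <- function(set, a, b,
                               segment = segment_spec("before"),
                               band = c(0, 4),
                               label = NULL,
                               resample = TRUE,
                               params = stft_params()) {
  validate_recording_set(set)
  qa <- enquo(a); qb <- enquo(b)
  sel_a <- eval_tidy(qa, data = set)
  sel_b <- eval_tidy(qb, data = set)
  if (!any(sel_a)) abort(sprintf("empty group a: no channel matches %s", as_label(qa)))
  if (!any(sel_b)) abort(sprintf("empty group b: no channel matches %s", as_label(qb)))
  if (is.null(label)) label <- sprintf("%s vs %s", as_label(qa), as_label(qb))

  window <- extract_segment(set, segment)
  members <- set[sel_a | sel_b, ]
  pw <- segment_average_power(members, window[1], window[2], band = band,
                              resample = resample, params = params)
  pw_a <- pw[match(set$channel_id[sel_a], pw$channel_id), ]
  pw_b <- pw[match(set$channel_id[sel_b], pw$channel_id), ]
  ga <- group_summary(as_label(qa), pw_a$power, pw_a$channel_id)
  gb <- group_summary(as_label(qb), pw_b$power, pw_b$channel_id)

  test <- NULL
  test_flag <- NA_character_
  if (ga$n >= 2 && gb$n >= 2) {
    if (var(ga$channel_powers) == 0 && var(gb$channel_powers) == 0) {
      test_flag <- "zero variance in both groups"
    } else {
      test <- welch_t_test(ga$channel_powers, gb$channel_powers)
    }
  } else {
    test_flag <- "insufficient replicates"
  }
  if (!is.na(ga$shapiro$p) && !is.na(gb$shapiro$p) &&
      min(ga$shapiro$p, gb$shapiro$p) < 0.05) {
    warn(sprintf(
      "Shapiro-Wilk rejects normality for '%s' (p = %.3g, %.3g); the Welch test is still reported",
      label, ga$shapiro$p, gb$shapiro$p
    ))
  }
  structure(
    list(
      label = label,
      group_a = ga, group_b = gb,
      window = window, segment = segment, band = band,
      welch = test, test_flag = test_flag,
      percent_change = percent_change(ga$mean_power, gb$mean_power)
    ),
    class = "myco_comparison"
  )
}

#' Pooled fungi-versus-no-fungi comparison before induction
#'
#' Pools every inoculated channel's pre-induction band power against every
#' non-inoculated channel's, quantifying colonization across all
#' conditions at once (the headline comparison of the analysis).
#'
#' @inheritParams compare_conditions
#' @return A `myco_comparison`.
#' @export
pool_pre_induction <- function(set,
                               segment = segment_spec("before"),
                               band = c(0, 4),
                               resample = TRUE,
                               params = stft_params()) {
  compare_conditions(set, a = inoculated, b = !inoculated,
                     segment = segment, band = band,
                     label = "fungi vs no fungi (pre-induction pooled)",
                     resample = resample, params = params)
}

#' @export
print.myco_comparison <- function(x, ...) {
  cat(sprintf("<comparison> %s\n", x$label))
  cat(sprintf("  window [%.6g, %.6g) s, band [%g, %g) Hz\n",
              x$window[1], x$window[2], x$band[1], x$band[2]))
  cat(sprintf("  %s: n = %d, mean power = %.6g V^2\n",
              x$group_a$label, x$group_a$n, x$group_a$mean_power))
  cat(sprintf("  %s: n = %d, mean power = %.6g V^2\n",
              x$group_b$label, x$group_b$n, x$group_b$mean_power))
  if (!is.null(x$welch)) {
    cat(sprintf("  Welch t = %.4g, df = %.4g, p = %.4g\n",
                x$welch$t, x$welch$df, x$welch$p))
  } else {
    cat(sprintf("  test not run: %s\n", x$test_flag))
  }
  cat(sprintf("  percent change = %.3f%%\n", x$percent_change))
  invisible(x)
}

#' Tidy and one-line summaries of a comparison
#'
#' `tidy()` gives one row per group (sizes, mean powers, Shapiro-Wilk
#' diagnostics); `glance()` gives the one-row test summary (Welch t, df,
#' p, percent change), in the spirit of broom.
#'
#' @param x A `myco_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy myco_comparison
#' @export
tidy.myco_comparison <- function(x, ...) {
  g <- function(gr, which) tibble::tibble(
    comparison = x$label, group = which, label = gr$label,
    n = gr$n, mean_power = gr$mean_power,
    shapiro_W = gr$shapiro$W, shapiro_p = gr$shapiro$p,
    shapiro_flag = gr$shapiro$flag
  )
  dplyr::bind_rows(g(x$group_a, "a"), g(x$group_b, "b"))
}

#' @rdname tidy.myco_comparison
#' @method glance myco_comparison
#' @export
glance.myco_comparison <- function(x, ...) {
  tibble::tibble(
    comparison = x$label,
    n_a = x$group_a$n, n_b = x$group_b$n,
    mean_a = x$group_a$mean_power, mean_b = x$group_b$mean_power,
    t = if (is.null(x$welch)) NA_real_ else x$welch$t,
    df = if (is.null(x$welch)) NA_real_ else x$welch$df,
    p_value = if (is.null(x$welch)) NA_real_ else x$welch$p,
    percent_change = x$percent_change,
    test_flag = x$test_flag
  )
}

#' Write comparison results as a table-shaped CSV plus a provenance JSON
#'
#' The CSV has one row per comparison (`comparison`, `replicates`,
#' `mean_a`, `mean_b`, `p_value`, `percent_change`, with means at 6
#' significant figures and percent change at 3 decimals); the JSON carries
#' full provenance (channel ids, windows, per-channel powers, diagnostics).
#'
#' @param comparisons A `myco_comparison` or list of them.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return A tibble of the CSV rows, invisibly.
#' @export
write_comparison_report <- function(comparisons, csv_path = NULL, json_path = NULL) {
  if (inherits(comparisons, "myco_comparison")) comparisons <- list(comparisons)
  rows <- purrr::map_dfr(comparisons, function(x) {
    tibble::tibble(
      comparison = x$label,
      replicates = sprintf("%d vs %d", x$group_a$n, x$group_b$n),
      mean_a = as.numeric(sprintf("%.6g", x$group_a$mean_power)),
      mean_b = as.numeric(sprintf("%.6g", x$group_b$mean_power)),
      p_value = if (is.null(x$welch)) NA_real_ else x$welch$p,
      percent_change = round(x$percent_change, 3)
    )
  })
  if (!is.null(csv_path)) readr::write_csv(rows, csv_path)
  if (!is.null(json_path)) {
    prov <- lapply(comparisons, function(x) {
      list(
        comparison = x$label,
        window = x$window, band = x$band,
        segment = unclass(x$segment),
        groups = lapply(list(x$group_a, x$group_b), function(g) {
          list(label = g$label, n = g$n, channel_ids = g$channel_ids,
               channel_powers = g$channel_powers, mean_power = g$mean_power,
               shapiro = g$shapiro)
        }),
        welch = x$welch, test_flag = x$test_flag,
        percent_change = x$percent_change
      )
    })
    jsonlite::write_json(prov, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(rows)
}
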