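#' Published PSD comparison table (printed values)
#'
#' The printed group mean powers, p-values and percent changes of the
#' published multi-condition PSD analysis, bundled as a static fixture so
#' the percent-change convention can be checked without any data download.
#' Means are as printed (5-6 significant figures); `phase` distinguishes
#' the pre-induction rows from the post-induction ones.
#'
#' @return A tibble with columns `comparison`, `phase`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `p_value`, `percent_change`.
#' @export
published_psd_table <- function() {
  tibble::tribble(
    ~comparison,               ~phase,      ~n_a, ~n_b, ~mean_a,     ~mean_b,     ~p_value, ~percent_change,
    "Fungi/No fungi",          "before",    24L,  8L,   3.44429e-07, 2.0204e-08,  0.000,    1604.752,
    "Cycloheximide/MQwater",   "before",    3L,   3L,   5.98197e-07, 3.13556e-07, 0.317,    90.779,
    "Voriconazole/MQwater",    "before",    3L,   3L,   2.72814e-07, 3.41486e-07, 0.786,    -20.110,
    "Calcimycin/DMSO",         "before",    3L,   3L,   4.50667e-07, 2.51333e-07, 0.179,    79.310,
    "Sodium Azide/MQwater",    "before",    3L,   3L,   3.5809e-07,  1.69289e-07, 0.286,    111.526,
    "Cycloheximide/MQwater",   "induction", 3L,   3L,   1.81389e-06, 7.03443e-06, 0.327,    -74.214,
    "Voriconazole/MQwater",    "induction", 3L,   3L,   3.53236e-06, 2.71344e-07, 0.391,    1201.803,
    "Calcimycin/DMSO",         "induction", 3L,   3L,   1.58093e-06, 9.97417e-07, 0.580,    58.503,
    "Sodium Azide/MQwater",    "induction", 3L,   3L,   3.41499e-06, 2.34075e-07, 0.116,    1358.933
  )
}

#' Recompute the published percent-change column from the printed means
#'
#' Applies [percent_change()] to each printed (treated mean, control mean)
#' pair and reports the difference from the printed percent change. Because
#' the published means are printed at 5-6 significant figures while the
#' published percent changes were computed from unrounded values, the
#' achievable agreement is bounded by the propagated printing error: about
#' 0.001 for the small-ratio rows and 0.005 for the large-ratio rows. The
#' per-row bound is included as `tolerance`.
#'
#' @return The [published_psd_table()] tibble with extra columns
#'   `recomputed`, `difference`, `tolerance`, `within_tolerance`.
#' @examples
#' check_published_percent_change()
#' @export
check_published_percent_change <- function() {
  tab <- published_psd_table()
  rel_print_err <- function(x) {
    # half-ulp of the printed decimal representation, relative
    digits <- vapply(x, function(v) {
      s <- sub("[eE].*$", "", formatC(v, format = "e", digits = 12))
      nchar(gsub("[^0-9]", "", sub("0+$", "", s)))
    }, numeric(1))
    0.5 * 10^(-(digits - 1))
  }
  rel <- rel_print_err(tab$mean_a) + rel_print_err(tab$mean_b)
  recomputed <- percent_change(tab$mean_a, tab$mean_b)
  tab$recomputed <- round(recomputed, 3)
  tab$difference <- tab$recomputed - tab$percent_change
  tab$tolerance <- pmax(0.001, (recomputed + 100) * rel + 0.0005)
  tab$within_tolerance <- abs(tab$difference) <= tab$tolerance
  tab
}
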