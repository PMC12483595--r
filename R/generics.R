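#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Keep the recording-set class and its acquisition attributes through
# base subsetting and dplyr verbs.

#' @export
`[.myco_recordings` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("channel_id", "samples") %in% names(out))) {
    attr(out, "acq") <- attr(x, "acq")
    attr(out, "experiment_id") <- attr(x, "experiment_id")
    if (!is.null(attr(x, "gap_log"))) attr(out, "gap_log") <- attr(x, "gap_log")
    class(out) <- class(x)
  }
  out
}

#' @exportS3Method dplyr::dplyr_reconstruct
dplyr_reconstruct.myco_recordings <- function(data, template) {
  out <- NextMethod()
  if (all(c("channel_id", "samples") %in% names(out))) {
    attr(out, "acq") <- attr(template, "acq")
    attr(out, "experiment_id") <- attr(template, "experiment_id")
    if (!is.null(attr(template, "gap_log"))) {
      attr(out, "gap_log") <- attr(template, "gap_log")
    }
    class(out) <- class(template)
  } else {
    class(out) <- setdiff(class(template), "myco_recordings")
  }
  out
}
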