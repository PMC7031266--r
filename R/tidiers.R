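#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an APA result into a long pixel grid
#'
#' @param x An `apa_result`.
#' @param ... Unused.
#' @return Tibble `offset1`, `offset2` (bins relative to the loop pixel),
#'   `value` (corner-scaled aggregate signal).
#' @export
tidy.apa_result <- function(x, ...) {
  w <- x$window_bins
  offs <- -w:w
  tibble::tibble(
    offset1 = rep(offs, times = length(offs)),
    offset2 = rep(offs, each = length(offs)),
    value = as.vector(x$aggregate))
}

#' @rdname tidy.apa_result
#' @export
glance.apa_result <- function(x, ...) {
  tibble::tibble(center_score = x$center_score, corner_mean = x$corner_mean,
                 n_loops_used = x$n_loops_used)
}

#' Tidy a TAD set (boundaries) or glance at it
#' @param x A `tad_set`.
#' @param ... Unused.
#' @export
tidy.tad_set <- function(x, ...) x$boundaries

#' @rdname tidy.tad_set
#' @export
glance.tad_set <- function(x, ...) {
  d <- x$domains
  tibble::tibble(n_boundaries = nrow(x$boundaries), n_domains = nrow(d),
                 mean_domain_bp = mean(d$end - d$start),
                 median_domain_bp = stats::median(d$end - d$start))
}

#' Tidy a shuffle overlap test
#' @param x A `shuffle_test`.
#' @param ... Unused.
#' @export
tidy.shuffle_test <- function(x, ...) {
  tibble::tibble(observed = x$observed, n_query = x$n_query,
                 null_mean = mean(x$null_counts),
                 null_sd = stats::sd(x$null_counts),
                 n_iter = x$n_iter, p_value = x$p_value)
}

#' Tidy a signal profile into its mean curve
#' @param x A `signal_profile`.
#' @param ... Unused.
#' @export
tidy.signal_profile <- function(x, ...) x$mean_curve

#' Tidy an expression-by-loop-count analysis
#' @param x An `expression_loops` or `expression_strata` object.
#' @param ... Unused.
#' @export
tidy.expression_loops <- function(x, ...) x$tests

#' @rdname tidy.expression_loops
#' @export
glance.expression_loops <- function(x, ...) x$summary

#' @rdname tidy.expression_loops
#' @export
tidy.expression_strata <- function(x, ...) x$tests

#' @rdname tidy.expression_loops
#' @export
glance.expression_strata <- function(x, ...) x$summary
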