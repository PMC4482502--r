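# Sequential Grubbs outlier screening of the range-change vector.

#' Grubbs statistic
#'
#' `G = max_i |x_i - mean(x)| / s` with `s` the sample (n-1 denominator)
#' standard deviation; the two-sided single-outlier test statistic.
#'
#' @param x numeric vector, length >= 3, non-constant.
#' @return list with `G` (the statistic) and `index` (position of the most
#'   extreme value).
#' @export
grubbs_statistic <- function(x) {
  n <- length(x)
  if (n < 3) stop("at least 3 values are required", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("constant vector; Grubbs statistic undefined",
                   call. = FALSE)
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  list(G = dev[i] / s, index = i)
}

#' Grubbs p-value
#'
#' One-sided maximum-deviation form: `G` is mapped to
#' `t = sqrt(n (n-2) G^2 / ((n-1)^2 - n G^2))` and
#' `p = n * P(T_{n-2} > t)`, capped at 1.  If `n G^2 >= (n-1)^2` (the sharp
#' upper bound for `G`), `p = 0`.
#'
#' @param G Grubbs statistic.
#' @param n sample size at the current step, >= 3.
#' @return p-value in `[0, 1]`.
#' @export
grubbs_p <- function(G, n) {
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  denom <- (n - 1) ^ 2 - n * G ^ 2
  if (denom <= 0) return(0)
  t <- sqrt(n * (n - 2) * G ^ 2 / denom)
  min(1, n * stats::pt(t, df = n - 2, lower.tail = FALSE))
}

#' Sequential Grubbs outlier screen
#'
#' Repeatedly computes the Grubbs statistic, and while its p-value is below
#' `alpha`, flags and removes the most extreme value, retesting the
#' remainder.  Stops when no further value is significant or fewer than 3
#' values remain.
#'
#' @param x numeric vector, length >= 4.
#' @param alpha significance threshold for the stop rule (default 0.05).
#' @param labels optional labels (e.g. species names); defaults to
#'   `names(x)` or positions.
#' @return data frame of class `grubbs_screen` with one row per flagged
#'   value, in removal order: `step`, `label`, `n` (sample size at that
#'   step), `G`, `p`.
#' @export
sequential_grubbs <- function(x, alpha = 0.05, labels = NULL) {
  if (length(x) < 4) stop("at least 4 values are required", call. = FALSE)
  if (is.null(labels)) {
    labels <- if (!is.null(names(x))) names(x) else as.character(seq_along(x))
  }
  out <- data.frame(step = integer(0), label = character(0), n = integer(0),
                    G = numeric(0), p = numeric(0))
  step <- 0L
  while (length(x) >= 3) {
    g <- grubbs_statistic(x)
    p <- grubbs_p(g$G, length(x))
    if (p >= alpha) break
    step <- step + 1L
    out <- rbind(out, data.frame(step = step, label = labels[g$index],
                                 n = length(x), G = g$G, p = p))
    x <- x[-g$index]
    labels <- labels[-g$index]
  }
  class(out) <- c("grubbs_screen", "data.frame")
  out
}

#' @export
print.grubbs_screen <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Sequential Grubbs screen: no outliers flagged\n")
  } else {
    cat("Sequential Grubbs screen:", nrow(x), "outlier(s) flagged\n")
    print.data.frame(cbind(x[1:3], G = round(x$G, 2), p = signif(x$p, 2)),
                     row.names = FALSE)
  }
  invisible(x)
}
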