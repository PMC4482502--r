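# Range-change indices: empirical-logit occupancy change ("uncorrected")
# and the relative index defined as the standardized residual of the
# cross-species regression of later-period on earlier-period logit
# occupancy ("corrected", robust to overall changes in recording effort).

#' Round half away from zero
#'
#' Unlike [round()] (banker's rounding), ties are rounded away from zero,
#' matching the convention used for the printed summary tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10 ^ digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Empirical logit of a proportion
#'
#' Computes `log((x + adjust) / (n - x + adjust))`.  The default
#' `adjust = 0.5` is the empirical logit, finite for `x = 0` and `x = n`;
#' `adjust = 0` gives the plain logit, which is undefined at the boundary
#' and raises a domain error there.
#'
#' @param x occupied count(s), `0 <= x <= n`.
#' @param n total count, `> 0`.
#' @param adjust additive adjustment (default 0.5; use 0 for plain logit).
#' @return numeric vector of transformed proportions.
#' @export
empirical_logit <- function(x, n, adjust = 0.5) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n", call. = FALSE)
  if (adjust == 0 && any(x == 0 | x == n)) {
    stop("plain logit undefined at x = 0 or x = n; use adjust = 0.5",
         call. = FALSE)
  }
  log((x + adjust) / (n - x + adjust))
}

#' Uncorrected range-change index
#'
#' The difference in (empirical-)logit-transformed proportion of surveyed
#' squares occupied between the second and first period.
#'
#' @param x1,x2 occupied surveyed-square counts in periods 1 and 2.
#' @param n total number of surveyed squares.
#' @param adjust logit adjustment, see [empirical_logit()].
#' @return numeric vector, `logit(x2/n) - logit(x1/n)`.
#' @export
uncorrected_change <- function(x1, x2, n, adjust = 0.5) {
  empirical_logit(x2, n, adjust) - empirical_logit(x1, n, adjust)
}

#' Percentage change in range size
#'
#' `100 * (x2 - x1) / x1`, rounded half away from zero to an integer.
#'
#' @param x1,x2 occupied counts in periods 1 and 2; `x1` must be positive.
#' @return integer percentage change.
#' @export
percent_change <- function(x1, x2) {
  if (any(x1 <= 0)) {
    stop("percent change undefined for x1 = 0", call. = FALSE)
  }
  round_half_away(100 * (x2 - x1) / x1)
}

#' Relative (Telfer) range-change index
#'
#' Regresses the period-2 logit proportions on the period-1 values by
#' ordinary least squares across species and returns standardized
#' residuals.  Because any uniform change in recording effort shifts all
#' species' period-2 values together, the residuals measure change
#' *relative* to the cross-species trend and are robust to overall effort
#' change.
#'
#' @param L1,L2 numeric vectors of logit-transformed proportions for
#'   periods 1 and 2 (same length, >= 3 species; `L1` must not be constant).
#' @param standardize `"studentized"` (default): internally studentized
#'   residuals `e_i / (sigma_hat * sqrt(1 - h_ii))` with leverage `h_ii` and
#'   `sigma_hat^2 = RSS / (m - 2)`; `"sd"`: raw residuals divided by their
#'   sample standard deviation.
#' @return numeric vector of standardized residuals (the index), with names
#'   taken from `L1`.
#' @export
telfer_index <- function(L1, L2, standardize = c("studentized", "sd")) {
  standardize <- match.arg(standardize)
  m <- length(L1)
  if (length(L2) != m) stop("L1 and L2 must have equal length", call. = FALSE)
  if (m < 3) stop("at least 3 species are required", call. = FALSE)
  if (stats::sd(L1) == 0) stop("L1 is constant; index undefined", call. = FALSE)
  X <- cbind(1, L1)
  qx <- qr(X)
  beta <- qr.coef(qx, L2)
  e <- L2 - X %*% beta
  out <- if (standardize == "studentized") {
    h <- rowSums(qr.Q(qx)[, 1:2, drop = FALSE] ^ 2)
    sigma <- sqrt(sum(e ^ 2) / (m - 2))
    e / (sigma * sqrt(1 - h))
  } else {
    e / stats::sd(e)
  }
  out <- as.numeric(out)
  names(out) <- names(L1)
  out
}

#' Per-species range-change table
#'
#' Builds the full per-species summary from period counts: proportions,
#' logit values, the uncorrected and corrected indices, and percentage
#' change.
#'
#' @param species character vector of species names.
#' @param x1,x2 occupied surveyed-square counts in periods 1 and 2.
#' @param n total number of surveyed squares.
#' @param adjust logit adjustment, see [empirical_logit()].
#' @param exclude optional character vector of species to drop *before*
#'   computing anything (the corrected index is then the refit on the
#'   reduced species set, and only those species are reported).
#' @param standardize residual standardization, see [telfer_index()].
#' @return data frame of class `range_change_table` with columns `species`,
#'   `x1`, `x2`, `n`, `p1`, `p2`, `L1`, `L2`, `uncorrected`, `corrected`,
#'   `pct_change`.
#' @export
range_change_table <- function(species, x1, x2, n, adjust = 0.5,
                               exclude = NULL,
                               standardize = c("studentized", "sd")) {
  stopifnot(length(species) == length(x1), length(x1) == length(x2))
  if (!is.null(exclude)) {
    unknown <- setdiff(exclude, species)
    if (length(unknown) > 0) {
      stop("exclude names not in species list: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- !(species %in% exclude)
    species <- species[keep]; x1 <- x1[keep]; x2 <- x2[keep]
  }
  L1 <- empirical_logit(x1, n, adjust)
  L2 <- empirical_logit(x2, n, adjust)
  names(L1) <- species
  out <- data.frame(
    species = species, x1 = x1, x2 = x2, n = n,
    p1 = x1 / n, p2 = x2 / n, L1 = L1, L2 = L2,
    uncorrected = L2 - L1,
    corrected = telfer_index(L1, L2, standardize),
    pct_change = percent_change(x1, x2),
    row.names = NULL)
  class(out) <- c("range_change_table", "data.frame")
  out
}

#' Range-change table from occupancy matrices
#'
#' Counts occupied surveyed squares per species in each period, applies the
#' minimum-range inclusion filter, and delegates to [range_change_table()].
#'
#' @param occ list of two `period_occupancy` objects.
#' @param squares `surveyed_squares` object defining the analysis hectads.
#' @param min_hectads inclusion filter: minimum period-1 occupied surveyed
#'   squares (default 5).
#' @param ... further arguments passed to [range_change_table()].
#' @return a `range_change_table`.
#' @export
range_change_from_occupancy <- function(occ, squares, min_hectads = 5L, ...) {
  cols1 <- colnames(occ[[1]]$presence) %in% squares$hectads
  m1 <- occ[[1]]$presence[, cols1, drop = FALSE]
  m2 <- occ[[2]]$presence[, cols1, drop = FALSE]
  keep <- apply_inclusion_filter(occ[[1]], squares, min_hectads)
  range_change_table(species = keep,
                     x1 = rowSums(m1[keep, , drop = FALSE]),
                     x2 = rowSums(m2[keep, , drop = FALSE]),
                     n = squares$n, ...)
}

#' Species' average latitude of occupied squares
#'
#' The unweighted mean centroid latitude of the hectads a species occupied
#' in the first period, within the surveyed-square set.  This is the
#' distributional trait used in the trait models.
#'
#' @param occ1 `period_occupancy` for period 1.
#' @param squares `surveyed_squares` object.
#' @param lookup optional data frame with columns `hectad` and `latitude`;
#'   if `NULL`, centroid latitudes are computed with
#'   [hectad_centroid_latitude()].
#' @return named numeric vector of degrees north, one per species.
#' @export
average_latitude <- function(occ1, squares, lookup = NULL) {
  m <- occ1$presence[, colnames(occ1$presence) %in% squares$hectads,
                     drop = FALSE]
  hectads <- colnames(m)
  if (is.null(lookup)) {
    lats <- hectad_centroid_latitude(hectads)
  } else {
    idx <- match(hectads, lookup$hectad)
    if (anyNA(idx)) {
      stop("hectad(s) missing from latitude lookup: ",
           paste(hectads[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    lats <- lookup$latitude[idx]
  }
  apply(m, 1, function(row) mean(lats[row]))
}
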