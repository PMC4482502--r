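# All-subsets Gaussian linear modelling of range change on traits,
# information-criterion top-set selection, and Akaike-weighted averaging of
# coefficients, standard errors, fit statistics and fitted values.

#' Enumerate all non-empty predictor subsets
#'
#' @param predictors character vector of trait identifiers (at most ~20).
#' @return list of `2^k - 1` character vectors, one per non-empty subset.
#'   Every fitted model additionally includes an intercept; the
#'   intercept-only model is not part of the candidate set.
#' @export
enumerate_models <- function(predictors) {
  k <- length(predictors)
  if (k < 1) stop("at least one predictor is required", call. = FALSE)
  if (k > 20) stop("more than 20 predictors: enumeration too large",
                   call. = FALSE)
  lapply(seq_len(2 ^ k - 1), function(m) {
    predictors[bitwAnd(m, 2 ^ (seq_len(k) - 1)) > 0]
  })
}

#' Fit a Gaussian linear model by least squares
#'
#' Ordinary least squares on an explicit design matrix (first column the
#' intercept, factors treatment-coded).  The log-likelihood uses the
#' maximum-likelihood variance `RSS/s`; AIC counts all coefficients plus
#' the variance parameter.  Deviance explained `D2` is `1 - RSS/null
#' deviance` and the adjusted version is `1 - [(s-1)/(s-t)](1 - D2)` where
#' by convention `t` counts predictors (a multi-column factor counts once);
#' pass `t` explicitly for that convention, otherwise `t` defaults to the
#' number of non-intercept columns.
#'
#' @param design numeric design matrix including an intercept column; rows
#'   are the modelled species.
#' @param y response vector.
#' @param t predictor count used in the adjusted-D2 penalty.
#' @return object of class `gaussian_fit`: `coefficients`, `se`, `cov`
#'   (coefficient covariance, unbiased-variance scaled), `rss`, `loglik`,
#'   `aic`, `D2`, `adjD2`, `fitted`, `residuals`, `n`, `p`.
#' @export
fit_gaussian_lm <- function(design, y, t = NULL) {
  X <- as.matrix(design)
  s <- length(y)
  if (nrow(X) != s) stop("design rows must match length(y)", call. = FALSE)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  e <- y - fitted
  rss <- sum(e ^ 2)
  R <- qr.R(qx)
  V <- chol2inv(R)
  ord <- order(qx$pivot)
  V <- V[ord, ord, drop = FALSE]
  sigma2_hat <- if (s > p) rss / (s - p) else NA_real_
  cov <- V * sigma2_hat
  dimnames(cov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(cov))
  sigma2_ml <- rss / s
  loglik <- -s / 2 * (log(2 * pi * sigma2_ml) + 1)
  aic <- -2 * loglik + 2 * (p + 1)
  nulldev <- sum((y - mean(y)) ^ 2)
  D2 <- 1 - rss / nulldev
  if (is.null(t)) t <- p - 1
  adjD2 <- 1 - ((s - 1) / (s - t)) * (1 - D2)
  structure(list(coefficients = beta, se = se, cov = cov, rss = rss,
                 loglik = loglik, aic = aic, D2 = D2, adjD2 = adjD2,
                 fitted = fitted, residuals = e, n = s, p = p),
            class = "gaussian_fit")
}

# Build the full treatment-coded design matrix for the 11 traits and the
# per-column trait assignment (0 = intercept).
.trait_design <- function(data) {
  # A factor level with no observations contributes an all-zero dummy and
  # no estimable contrast, so unused levels are dropped before coding.
  # Factors collapsing to a single observed level keep their declared
  # levels; their models are then dropped by the rank-deficiency screen.
  d <- data[.TRAITS]
  for (nm in names(d)) {
    if (is.factor(d[[nm]]) && nlevels(droplevels(d[[nm]])) >= 2) {
      d[[nm]] <- droplevels(d[[nm]])
    }
  }
  X <- stats::model.matrix(~ ., data = d)
  list(X = X, assign = attr(X, "assign"))
}

#' Fit every non-empty trait-subset model
#'
#' Applies the modelling transforms, builds the treatment-coded design, and
#' fits a Gaussian linear model for every non-empty subset of the traits.
#' Factors enter and leave models as whole terms (all dummy columns
#' together).
#'
#' @param traits a `trait_table` for the modelled species (rows aligned
#'   with `y`).
#' @param y response vector (a range-change index), named by species if
#'   possible.
#' @param ic information criterion: `"AIC"` (default) or small-sample
#'   `"AICc"`.
#' @param base log base for the trait transforms (see [model_transforms()]).
#' @return object of class `model_set`: `subsets` (list of trait subsets),
#'   `fits` (list of `gaussian_fit`), `table` (per-model data frame with
#'   `n_traits`, `n_params`, `rss`, `aic`, `ic`), plus `y`, `data`, and the
#'   criterion name.  Rank-deficient subsets (possible with sparse factor
#'   levels) are dropped with a warning.
#' @export
fit_all_subsets <- function(traits, y, ic = c("AIC", "AICc"), base = 10) {
  ic <- match.arg(ic)
  traits <- as_trait_table(traits)
  s <- length(y)
  if (nrow(traits) != s) stop("traits rows must match length(y)", call. = FALSE)
  if (is.null(names(y))) names(y) <- traits$species
  data <- model_transforms(traits, base = base)
  des <- .trait_design(data)
  subsets <- enumerate_models(.TRAITS)
  fits <- vector("list", length(subsets))
  icv <- rep(NA_real_, length(subsets))
  dropped <- 0L
  for (i in seq_along(subsets)) {
    tr_idx <- match(subsets[[i]], .TRAITS)
    cols <- des$assign == 0L | des$assign %in% tr_idx
    f <- tryCatch(
      fit_gaussian_lm(des$X[, cols, drop = FALSE], y,
                      t = length(subsets[[i]])),
      error = function(e) NULL)
    if (is.null(f)) { dropped <- dropped + 1L; next }
    f$traits <- subsets[[i]]
    f$assign <- des$assign[cols]
    fits[[i]] <- f
    icv[i] <- if (ic == "AICc") {
      K <- f$p + 1
      if (s - K - 1 <= 0) Inf else f$aic + 2 * K * (K + 1) / (s - K - 1)
    } else {
      f$aic
    }
  }
  if (dropped > 0) {
    warning(dropped, " rank-deficient model(s) dropped from the candidate set")
  }
  ok <- !is.na(icv)
  tab <- data.frame(
    model = seq_along(subsets)[ok],
    n_traits = vapply(subsets[ok], length, integer(1)),
    n_params = vapply(fits[ok], function(f) f$p, numeric(1)),
    rss = vapply(fits[ok], function(f) f$rss, numeric(1)),
    aic = vapply(fits[ok], function(f) f$aic, numeric(1)),
    ic = icv[ok])
  structure(list(subsets = subsets[ok], fits = fits[ok], table = tab,
                 y = y, data = data, ic_name = ic),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("All-subsets model set:", length(x$fits), "models (",
      x$ic_name, "), best", x$ic_name, "=",
      round(min(x$table$ic), 2), "\n")
  invisible(x)
}

#' Select the top model set by information-criterion difference
#'
#' Models whose criterion value is strictly within `delta` of the minimum
#' form the top set; Akaike weights `w_i` proportional to `exp(-Delta_i/2)`
#' are computed within the selected set and sum to 1.
#'
#' @param ms a `model_set` from [fit_all_subsets()].
#' @param delta criterion-difference threshold (default 4, strict `<`).
#' @return object of class `top_set`: `fits`, `subsets`, `delta_ic`,
#'   `weights`, plus `y` and `data` carried over.
#' @export
select_top <- function(ms, delta = 4) {
  icv <- ms$table$ic
  d <- icv - min(icv)
  sel <- which(d < delta)
  w <- exp(-d[sel] / 2)
  w <- w / sum(w)
  structure(list(fits = ms$fits[sel], subsets = ms$subsets[sel],
                 delta_ic = d[sel], weights = w, y = ms$y, data = ms$data,
                 ic_name = ms$ic_name),
            class = "top_set")
}

#' @export
print.top_set <- function(x, ...) {
  cat("Top model set:", length(x$fits), "models with delta", x$ic_name,
      "< threshold; best subset:",
      paste(x$subsets[[which.max(x$weights)]], collapse = " + "), "\n")
  invisible(x)
}

#' Pairwise level contrasts of a factor trait in one fit
#'
#' With treatment coding, contrasts against the reference level are the
#' dummy coefficients themselves; the remaining pairwise contrast of a
#' 3-level factor is the difference of the two dummies, with its standard
#' error from the coefficient covariance.
#'
#' @param fit a `gaussian_fit` (or `pgls_fit`) containing the factor.
#' @param factor_name name of a categorical trait in the fit.
#' @return data frame with columns `term`, `estimate`, `se`, one row per
#'   level pair.  Contrasts involving a level absent from the fitted data
#'   are reported as `NA`.
#' @export
factor_contrasts <- function(fit, factor_name) {
  levs <- .TRAIT_LEVELS[[factor_name]]
  if (is.null(levs)) stop("'", factor_name, "' is not a categorical trait",
                          call. = FALSE)
  cn <- names(fit$coefficients)
  dummy <- paste0(factor_name, levs[-1])
  out <- list()
  for (j in seq_along(dummy)) {
    term <- paste0(factor_name, ": ", levs[j + 1], " vs ", levs[1])
    if (dummy[j] %in% cn) {
      out[[term]] <- c(fit$coefficients[dummy[j]], fit$se[dummy[j]])
    } else {
      out[[term]] <- c(NA_real_, NA_real_)
    }
  }
  if (length(levs) == 3 && all(dummy %in% cn)) {
    est <- fit$coefficients[dummy[2]] - fit$coefficients[dummy[1]]
    v <- fit$cov[dummy[2], dummy[2]] + fit$cov[dummy[1], dummy[1]] -
      2 * fit$cov[dummy[1], dummy[2]]
    out[[paste0(factor_name, ": ", levs[3], " vs ", levs[2])]] <-
      c(est, sqrt(v))
  }
  data.frame(term = names(out),
             estimate = vapply(out, `[`, numeric(1), 1),
             se = vapply(out, `[`, numeric(1), 2),
             row.names = NULL)
}

# Extract (estimate, se) rows for every averaged term of one fit:
# intercept, continuous traits, and factor level contrasts.
.fit_terms <- function(fit) {
  rows <- list()
  rows[["(Intercept)"]] <- data.frame(
    term = "(Intercept)", trait = "(Intercept)",
    estimate = unname(fit$coefficients["(Intercept)"]),
    se = unname(fit$se["(Intercept)"]))
  for (tr in fit$traits) {
    if (tr %in% names(.TRAIT_LEVELS)) {
      fc <- factor_contrasts(fit, tr)
      fc$trait <- tr
      rows[[tr]] <- fc[c("term", "trait", "estimate", "se")]
    } else {
      rows[[tr]] <- data.frame(term = tr, trait = tr,
                               estimate = unname(fit$coefficients[tr]),
                               se = unname(fit$se[tr]))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Akaike-weighted model-averaged coefficients
#'
#' For every term appearing in the top set, weights are renormalized over
#' the models containing the term (models lacking it contribute nothing,
#' not zero), giving the weighted mean coefficient
#' `b_all = sum(w_i b_i)` and the weighted unconditional standard error
#' `SE(b_all) = sum(w_i sqrt(SE(b_i)^2 + (b_i - b_all)^2))`.  Confidence
#' intervals use z multipliers 1.96, 2.58 and 3.29 (95/99/99.9%), with
#' significance stars for the narrowest interval excluding zero.  Factor
#' traits are reported as all pairwise level contrasts.
#'
#' @param top a `top_set` from [select_top()].
#' @return data frame of class `averaged_coefficients` with columns `term`,
#'   `trait`, `n_models` (count of top models containing the trait),
#'   `inclusion_pct` (the Akaike-weight share of top models containing the
#'   trait, x100 -- relative variable importance), `b_all`, `se_all`,
#'   `ci95_lower`, `ci95_upper`, `ci99_lower`, `ci99_upper`,
#'   `ci999_lower`, `ci999_upper`, `stars`.
#' @export
average_coefficients <- function(top) {
  if (length(top$fits) == 0) stop("empty top set", call. = FALSE)
  per_fit <- lapply(top$fits, .fit_terms)
  all_terms <- unique(do.call(rbind, per_fit)[c("term", "trait")])
  rows <- lapply(seq_len(nrow(all_terms)), function(r) {
    term <- all_terms$term[r]; trait <- all_terms$trait[r]
    has <- vapply(seq_along(top$fits), function(i) {
      ft <- per_fit[[i]]
      any(ft$term == term & !is.na(ft$estimate))
    }, logical(1))
    if (!any(has)) return(NULL)
    w <- top$weights[has] / sum(top$weights[has])
    b <- vapply(per_fit[has], function(ft) ft$estimate[ft$term == term],
                numeric(1))
    se <- vapply(per_fit[has], function(ft) ft$se[ft$term == term],
                 numeric(1))
    b_all <- sum(w * b)
    se_all <- sum(w * sqrt(se ^ 2 + (b - b_all) ^ 2))
    trait_in <- if (trait == "(Intercept)") {
      rep(TRUE, length(top$fits))
    } else {
      vapply(top$subsets, function(s) trait %in% s, logical(1))
    }
    stars <- if (abs(b_all) > 3.29 * se_all) "***"
      else if (abs(b_all) > 2.58 * se_all) "**"
      else if (abs(b_all) > 1.96 * se_all) "*"
      else ""
    data.frame(term = term, trait = trait,
               n_models = sum(trait_in),
               inclusion_pct = 100 * sum(top$weights[trait_in]),
               b_all = b_all, se_all = se_all,
               ci95_lower = b_all - 1.96 * se_all,
               ci95_upper = b_all + 1.96 * se_all,
               ci99_lower = b_all - 2.58 * se_all,
               ci99_upper = b_all + 2.58 * se_all,
               ci999_lower = b_all - 3.29 * se_all,
               ci999_upper = b_all + 3.29 * se_all,
               stars = stars)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("averaged_coefficients", "data.frame")
  out
}

#' Akaike-weighted adjusted deviance explained
#'
#' @param top a `top_set`.
#' @return named numeric vector: `weighted` (the Akaike-weighted mean
#'   adjusted D2 over the full top set), `min` and `max` (range across
#'   member models).
#' @export
weighted_adjusted_D2 <- function(top) {
  adj <- vapply(top$fits, function(f) f$adjD2, numeric(1))
  c(weighted = sum(top$weights * adj), min = min(adj), max = max(adj))
}

#' Akaike-weighted fitted values and residual ranking
#'
#' Weighted mean fitted value per species over the top set (weights over
#' the full set), with observed-minus-fitted residuals; a positive residual
#' means the species' range change is underestimated by the models.
#'
#' @param top a `top_set`.
#' @return data frame with columns `species`, `observed`, `fitted`,
#'   `residual`, `residual_rank` (1 = largest positive residual).
#' @export
weighted_fitted <- function(top) {
  fit_mat <- vapply(top$fits, function(f) f$fitted,
                    numeric(length(top$y)))
  fitted <- drop(fit_mat %*% top$weights)
  resid <- top$y - fitted
  data.frame(species = if (!is.null(names(top$y))) names(top$y)
                       else rownames(top$data),
             observed = unname(top$y), fitted = fitted, residual = resid,
             residual_rank = rank(-resid), row.names = NULL)
}

#' Shapiro-Wilk residual normality checks across the top set
#'
#' @param top a `top_set`.
#' @return list with `p` (per-model Shapiro-Wilk p-values), `median_p`, and
#'   `prop_nonsignificant` (fraction of models with p >= 0.05).  Models
#'   with (near-)constant residuals are reported as `NA`.
#' @export
residual_normality <- function(top) {
  p <- vapply(top$fits, function(f) {
    tryCatch(stats::shapiro.test(f$residuals)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  list(p = p, median_p = stats::median(p, na.rm = TRUE),
       prop_nonsignificant = mean(p >= 0.05, na.rm = TRUE))
}

#' All-subsets trait analysis in one call
#'
#' Convenience driver: fits all trait subsets, selects the top set, and
#' returns the averaged-coefficient table with fit summaries.
#'
#' @inheritParams fit_all_subsets
#' @param delta top-set criterion-difference threshold (default 4).
#' @return list with `model_set`, `top`, `coefficients` (averaged table),
#'   `adjusted_D2`, `fitted`, `normality`.
#' @export
trait_model_average <- function(traits, y, ic = "AIC", base = 10, delta = 4) {
  ms <- fit_all_subsets(traits, y, ic = ic, base = base)
  top <- select_top(ms, delta = delta)
  list(model_set = ms, top = top,
       coefficients = average_coefficients(top),
       adjusted_D2 = weighted_adjusted_D2(top),
       fitted = weighted_fitted(top),
       normality = residual_normality(top))
}
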