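# Phylogenetic robustness checks: taxonomy-based working phylogeny,
# shared-path covariance, Moran's I on model residuals, and generalized
# least squares with Pagel's lambda.

#' Build a working phylogeny from a taxonomy table
#'
#' Constructs a rooted, possibly multifurcating tree from nested taxonomic
#' ranks, with every branch segment of unit length: one internal node per
#' distinct rank group, species as tips.  Chains of single-child nodes are
#' collapsed with their branch lengths summed, so the tree is ultrametric
#' with every root-to-tip distance equal to the number of rank levels plus
#' one.
#'
#' @param taxonomy data frame with a `species` column and one column per
#'   rank, ordered root-most first (e.g. `suborder`, `family`, `subfamily`,
#'   `genus`, `species`).
#' @return an [ape::read.tree()] `phylo` object; tip labels are the species
#'   names with spaces replaced by underscores.
#' @export
build_working_phylogeny <- function(taxonomy) {
  if (!"species" %in% names(taxonomy)) {
    stop("taxonomy must have a 'species' column", call. = FALSE)
  }
  if (anyDuplicated(taxonomy$species)) {
    stop("duplicate species names in taxonomy", call. = FALSE)
  }
  ranks <- setdiff(names(taxonomy), "species")
  if (any(is.na(taxonomy[ranks])) || anyNA(taxonomy$species)) {
    stop("every species needs a complete rank path", call. = FALSE)
  }
  build <- function(df, ranks) {
    if (length(ranks) == 0) {
      return(paste0(gsub(" ", "_", df$species), ":1"))
    }
    groups <- split(df, df[[ranks[1]]], drop = TRUE)
    vapply(groups, function(g) {
      paste0("(", paste(build(g, ranks[-1]), collapse = ","), "):1")
    }, character(1))
  }
  parts <- build(taxonomy, ranks)
  # the zero-length root edge marks the tree as rooted even when the top
  # rank has more than two groups (a basal polytomy)
  newick <- if (length(parts) == 1) {
    paste0(parts, ";")
  } else {
    paste0("(", paste(parts, collapse = ","), "):0;")
  }
  tree <- ape::read.tree(text = newick)
  ape::collapse.singles(tree)
}

#' Expected phylogenetic covariance matrix
#'
#' `C[a, b]` is the summed branch length of the path shared by tips `a` and
#' `b` from the root (their most recent common ancestor's depth); the
#' diagonal is each tip's root-to-tip distance.  Computed directly from the
#' edge table rather than delegating to an existing implementation, so it
#' can be cross-validated independently.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @return symmetric positive semi-definite species x species matrix with
#'   tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  # Root-ward path of each tip as the set of edges (indexed by child node).
  paths <- lapply(seq_len(ntip), function(tip) {
    node <- tip
    path <- integer(0)
    while (node != root) {
      path <- c(path, node)
      node <- parent[node]
    }
    path
  })
  C <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (a in seq_len(ntip)) {
    for (b in a:ntip) {
      shared <- intersect(paths[[a]], paths[[b]])
      C[a, b] <- C[b, a] <- sum(elen[shared])
    }
  }
  diag(C) <- vapply(paths, function(p) sum(elen[p]), numeric(1))
  C
}

#' Moran's I autocorrelation of residuals under a covariance weight matrix
#'
#' `I = (n/S0) * sum_ab(w_ab z_a z_b) / sum_a(z_a^2)` with `z` the centred
#' values and `w` the phylogenetic covariance with its diagonal zeroed
#' (raw, unscaled weights by default; a row-normalized variant is
#' available).  The expectation under no autocorrelation is `-1/(n-1)`.
#'
#' @param x numeric vector (typically model residuals), length n >= 3.
#' @param C covariance matrix used as weights (diagonal ignored).
#' @param method variance convention for the two-sided p-value:
#'   `"normality"` (default, analytic variance assuming normal data),
#'   `"randomization"` (analytic variance under permutation, with a
#'   kurtosis correction), or `"permutation"` (Monte-Carlo p from
#'   `n_perm` random permutations of `x`).
#' @param weight `"raw"` (default) or `"row"` (row-normalized weights).
#' @param n_perm number of permutations for `method = "permutation"`.
#' @return list of class `moran_result`: `I`, `expected`, `sd` (analytic;
#'   `NA` for the permutation method), `p`, `method`.
#' @export
morans_I <- function(x, C, method = c("normality", "randomization",
                                      "permutation"),
                     weight = c("raw", "row"), n_perm = 10000) {
  method <- match.arg(method)
  weight <- match.arg(weight)
  n <- length(x)
  if (n < 3) stop("at least 3 values are required", call. = FALSE)
  W <- as.matrix(C)
  if (!all(dim(W) == n)) stop("C must be n x n", call. = FALSE)
  diag(W) <- 0
  if (weight == "row") {
    rs <- rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  S0 <- sum(W)
  if (S0 == 0) stop("all weights are zero", call. = FALSE)
  obs_I <- function(z) (n / S0) * sum(W * tcrossprod(z)) / sum(z ^ 2)
  z <- x - mean(x)
  I <- obs_I(z)
  EI <- -1 / (n - 1)
  if (method == "permutation") {
    perm <- replicate(n_perm, {
      zp <- sample(z)
      obs_I(zp)
    })
    p <- (1 + sum(abs(perm - EI) >= abs(I - EI))) / (n_perm + 1)
    sdI <- NA_real_
  } else {
    S1 <- 0.5 * sum((W + t(W)) ^ 2)
    S2 <- sum((rowSums(W) + colSums(W)) ^ 2)
    if (method == "normality") {
      varI <- (n ^ 2 * S1 - n * S2 + 3 * S0 ^ 2) /
        ((n ^ 2 - 1) * S0 ^ 2) - EI ^ 2
    } else {
      b2 <- n * sum(z ^ 4) / (sum(z ^ 2) ^ 2)
      varI <- (n * ((n ^ 2 - 3 * n + 3) * S1 - n * S2 + 3 * S0 ^ 2) -
               b2 * ((n ^ 2 - n) * S1 - 2 * n * S2 + 6 * S0 ^ 2)) /
        ((n - 1) * (n - 2) * (n - 3) * S0 ^ 2) - EI ^ 2
    }
    sdI <- sqrt(varI)
    p <- 2 * stats::pnorm(abs(I - EI) / sdI, lower.tail = FALSE)
  }
  structure(list(I = I, expected = EI, sd = sdI, p = p, method = method),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Moran's I = ", round(x$I, 4), " (expected ", round(x$expected, 4),
      "), p = ", signif(x$p, 3), " [", x$method, "]\n", sep = "")
  invisible(x)
}

# Log-likelihood, coefficients and covariance of a GLS fit with a fixed
# covariance matrix V (ML variance profiled out).
.gls_core <- function(X, y, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) stop("singular covariance matrix", call. = FALSE)
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, y, transpose = TRUE)
  qx <- qr(Xi)
  if (qx$rank < ncol(X)) {
    stop("rank-deficient design in GLS fit", call. = FALSE)
  }
  beta <- qr.coef(qx, yi)
  names(beta) <- colnames(X)
  e <- yi - Xi %*% beta
  rss <- sum(e ^ 2)
  logdet <- 2 * sum(log(diag(ch)))
  sigma2_ml <- rss / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n)
  R <- qr.R(qx)
  Vb <- chol2inv(R)
  ord <- order(qx$pivot)
  Vb <- Vb[ord, ord, drop = FALSE]
  p <- ncol(X)
  sigma2_hat <- if (n > p) rss / (n - p) else NA_real_
  cov <- Vb * sigma2_hat
  dimnames(cov) <- list(colnames(X), colnames(X))
  list(beta = beta, cov = cov, loglik = loglik, rss = rss)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y = X beta + e` with `e ~ N(0, sigma^2 V(lambda))` where
#' `V(lambda)` is the phylogenetic covariance with its off-diagonal entries
#' multiplied by `lambda` (diagonal unchanged).  `lambda` is estimated by
#' maximum profile likelihood over the bounded interval, or fixed if
#' supplied; at the lower bound the fit coincides with ordinary least
#' squares.
#'
#' @param design design matrix including an intercept column.
#' @param y response vector.
#' @param C phylogenetic covariance matrix aligned with `y`.
#' @param lambda fixed lambda, or `NULL` (default) to estimate.
#' @param bounds search interval for lambda (default `c(1e-6, 1)`).
#' @param t predictor count for the adjusted-D2 convention (see
#'   [fit_gaussian_lm()]).
#' @return object of class `pgls_fit` (fields compatible with
#'   `gaussian_fit`: `coefficients`, `se`, `cov`, `loglik`, `aic`, `D2`,
#'   `adjD2`, `fitted`, `residuals`, `n`, `p`) plus `lambda`.  AIC counts
#'   the coefficients, the variance, and lambda.
#' @export
pgls_fit <- function(design, y, C, lambda = NULL, bounds = c(1e-6, 1),
                     t = NULL) {
  X <- as.matrix(design)
  n <- length(y)
  V_of <- function(lam) {
    V <- C * lam
    diag(V) <- diag(C)
    V
  }
  ll <- function(lam) .gls_core(X, y, V_of(lam))$loglik
  if (is.null(lambda)) {
    opt <- stats::optimize(ll, interval = bounds, maximum = TRUE)
    # optimize() never returns an exact endpoint; compare with the bounds so
    # likelihoods maximized at a boundary pin lambda there reproducibly.
    cand <- c(opt$maximum, bounds)
    vals <- c(opt$objective, ll(bounds[1]), ll(bounds[2]))
    lambda <- cand[which.max(vals)]
  }
  core <- .gls_core(X, y, V_of(lambda))
  p <- ncol(X)
  aic <- -2 * core$loglik + 2 * (p + 2)
  fitted <- drop(X %*% core$beta)
  resid <- y - fitted
  nulldev <- sum((y - mean(y)) ^ 2)
  D2 <- 1 - sum(resid ^ 2) / nulldev
  if (is.null(t)) t <- p - 1
  adjD2 <- 1 - ((n - 1) / (n - t)) * (1 - D2)
  structure(list(coefficients = core$beta, se = sqrt(diag(core$cov)),
                 cov = core$cov, rss = core$rss, loglik = core$loglik,
                 aic = aic, D2 = D2, adjD2 = adjD2, fitted = fitted,
                 residuals = resid, n = n, p = p, lambda = lambda),
            class = c("pgls_fit", "gaussian_fit"))
}

# All-subsets PGLS analogue of fit_all_subsets(), used for the rerun when
# residual autocorrelation is flagged.
.fit_all_subsets_pgls <- function(traits, y, C, base = 10,
                                  bounds = c(1e-6, 1)) {
  traits <- as_trait_table(traits)
  if (is.null(names(y))) names(y) <- traits$species
  data <- model_transforms(traits, base = base)
  des <- .trait_design(data)
  subsets <- enumerate_models(.TRAITS)
  fits <- vector("list", length(subsets))
  icv <- rep(NA_real_, length(subsets))
  for (i in seq_along(subsets)) {
    tr_idx <- match(subsets[[i]], .TRAITS)
    cols <- des$assign == 0L | des$assign %in% tr_idx
    f <- tryCatch(
      pgls_fit(des$X[, cols, drop = FALSE], y, C, bounds = bounds,
               t = length(subsets[[i]])),
      error = function(e) NULL)
    if (is.null(f)) next
    f$traits <- subsets[[i]]
    f$assign <- des$assign[cols]
    fits[[i]] <- f
    icv[i] <- f$aic
  }
  ok <- !is.na(icv)
  tab <- data.frame(model = seq_along(subsets)[ok],
                    n_traits = vapply(subsets[ok], length, integer(1)),
                    ic = icv[ok])
  structure(list(subsets = subsets[ok], fits = fits[ok], table = tab,
                 y = y, data = data, ic_name = "AIC"),
            class = "model_set")
}

#' Phylogenetic robustness check of a top model set
#'
#' Computes Moran's I on the residuals of every top model using the
#' working-phylogeny covariance as weights.  If any model's p-value falls
#' below the near-significance trigger, the whole all-subsets /
#' top-set / averaging procedure is rerun under PGLS with Pagel's lambda
#' and both summaries are returned.
#'
#' @param top a `top_set` (with `data` rows named by species).
#' @param tree working phylogeny whose tips cover the modelled species.
#' @param traits the `trait_table` used for the original analysis (needed
#'   for the PGLS rerun).
#' @param trigger p-value threshold for "significant or near-significant"
#'   (default 0.1).
#' @param method Moran's I variance convention (see [morans_I()]).
#' @param base,delta passed to the PGLS rerun.
#' @return list with `moran` (per-model data frame: `model`, `I`,
#'   `expected`, `sd`, `p`), `prop_nonsignificant` (share of top models
#'   with p >= 0.05), `rerun_triggered`, and when triggered `pgls` (list
#'   with `top`, `coefficients`, `adjusted_D2`, `lambda` per top model).
#' @export
phylo_pipeline <- function(top, tree, traits, trigger = 0.1,
                           method = "normality", base = 10, delta = 4) {
  species <- if (!is.null(names(top$y))) names(top$y) else rownames(top$data)
  # tips match either verbatim or with underscores standing in for spaces
  tips <- tree$tip.label
  tip_for <- vapply(species, function(sp) {
    hit <- which(tips == sp | gsub("_", " ", tips) == sp)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  if (anyNA(tip_for)) {
    stop("tree tips do not cover the modelled species: missing ",
         paste(species[is.na(tip_for)], collapse = ", "), call. = FALSE)
  }
  C <- phylo_covariance(tree)
  C <- C[tip_for, tip_for, drop = FALSE]
  rownames(C) <- colnames(C) <- species
  moran <- do.call(rbind, lapply(seq_along(top$fits), function(i) {
    m <- morans_I(top$fits[[i]]$residuals, C, method = method)
    data.frame(model = i, I = m$I, expected = m$expected, sd = m$sd, p = m$p)
  }))
  out <- list(moran = moran,
              prop_nonsignificant = mean(moran$p >= 0.05),
              rerun_triggered = any(moran$p < trigger))
  if (out$rerun_triggered) {
    ms <- .fit_all_subsets_pgls(traits, top$y, C, base = base)
    ptop <- select_top(ms, delta = delta)
    out$pgls <- list(
      top = ptop,
      coefficients = average_coefficients(ptop),
      adjusted_D2 = weighted_adjusted_D2(ptop),
      lambda = vapply(ptop$fits, function(f) f$lambda, numeric(1)))
  }
  out
}
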