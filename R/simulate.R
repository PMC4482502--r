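# Synthetic atlas-data generator: trait tables, trait-linked range change,
# occurrence records with an effort shift between periods, and random
# taxonomies.  Defaults mirror the packaged 23-species study setting
# (23 species, 844 hectads, a doubling of recording effort, and the
# observed grid-reference precision mix).

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's state afterwards; seed = NULL leaves the RNG alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || seed != as.integer(seed)) {
    stop("seed must be an integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Collects the generator settings.  The defaults reproduce the packaged
#' study's conditions: 23 species, 844 hectads, periods 1980--89 and
#' 2000--09, an overall doubling of recording effort between the periods,
#' and the observed precision mix of grid references (55% 100 m, 27% 1 km,
#' 3% 2 km tetrads, 15% 10 km).
#'
#' @param n_species number of species (>= 5 for trait simulation).
#' @param n_hectads number of hectads in the simulated region.
#' @param periods named list of two year ranges.
#' @param beta named vector of true coefficients on the modelling scale
#'   (names are design-matrix terms, e.g. `"(Intercept)"`,
#'   `"habitat_breadth"`, `"oviposition_siteVegetation"`,
#'   `"average_latitude"`); missing terms are zero.  The default plants
#'   effects of habitat breadth, vegetation oviposition and average
#'   latitude at magnitudes comparable to the packaged dataset's fitted
#'   values, with the intercept centring the index near zero.
#' @param sigma residual standard deviation of the true index.
#' @param detection probability that an occupied hectad yields at least one
#'   record in period 1.
#' @param effort_multiplier period-2 recording effort relative to period 1
#'   (default 2); period-2 detection is `1 - (1 - detection)^multiplier`.
#' @param precision_mix named numeric vector of grid-reference precision
#'   proportions; names are precisions in metres.
#' @param seed integer random seed making the full pipeline reproducible.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 23,
                              n_hectads = 844,
                              periods = list("1980-89" = c(1980, 1989),
                                             "2000-09" = c(2000, 2009)),
                              beta = c("(Intercept)" = 37.6,
                                       habitat_breadth = 1.4,
                                       oviposition_siteVegetation = 1.0,
                                       average_latitude = -0.75),
                              sigma = 0.6,
                              detection = 0.6,
                              effort_multiplier = 2,
                              precision_mix = c("100" = 0.55, "1000" = 0.27,
                                                "2000" = 0.03,
                                                "10000" = 0.15),
                              seed = 1L) {
  stopifnot(n_species >= 2, n_hectads >= 1,
            detection > 0, detection <= 1,
            effort_multiplier > 0, sigma >= 0,
            abs(sum(precision_mix) - 1) < 1e-8)
  structure(list(n_species = n_species, n_hectads = n_hectads,
                 periods = periods, beta = beta, sigma = sigma,
                 detection = detection,
                 effort_multiplier = effort_multiplier,
                 precision_mix = precision_mix, seed = as.integer(seed)),
            class = "simulation_config")
}

# Lognormal meanlog/sdlog matching a target mean and sd.
.lognormal_pars <- function(m, s) {
  sdlog <- sqrt(log(1 + s ^ 2 / m ^ 2))
  c(meanlog = log(m) - sdlog ^ 2 / 2, sdlog = sdlog)
}

#' Simulate a species trait table
#'
#' Categorical traits are drawn with the packaged fixture's level
#' frequencies; continuous traits are lognormal (habitat breadth, body
#' size, wing load) or normal (phenology) matched to the fixture's reported
#' marginal means and standard deviations; average latitude is uniform on
#' [50.6, 52.3].
#'
#' @param n_species number of species (>= 5).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a `trait_table` with species named `species_01`, ...
#' @export
simulate_traits <- function(n_species, seed = NULL) {
  if (n_species < 5) stop("n_species must be >= 5", call. = FALSE)
  .with_seed(seed, {
    fix <- orthoptera_traits()
    df <- data.frame(species = sprintf("species_%02d", seq_len(n_species)))
    for (tr in names(.TRAIT_LEVELS)) {
      freq <- table(factor(fix[[tr]], levels = .TRAIT_LEVELS[[tr]]))
      df[[tr]] <- sample(.TRAIT_LEVELS[[tr]], n_species, replace = TRUE,
                         prob = as.numeric(freq))
    }
    hb <- .lognormal_pars(5.3, 3.1)
    df$habitat_breadth <- pmax(1, round(stats::rlnorm(n_species,
                                                      hb[1], hb[2])))
    bs <- .lognormal_pars(16.9, 5.9)
    df$body_size <- round(stats::rlnorm(n_species, bs[1], bs[2]), 1)
    wl <- .lognormal_pars(0.051, 0.043)
    df$wing_load <- stats::rlnorm(n_species, wl[1], wl[2])
    df$phenology <- pmin(8, pmax(3.5,
      round(stats::rnorm(n_species, 6.6, 1.2) * 4) / 4))
    df$average_latitude <- round(stats::runif(n_species, 50.6, 52.3), 2)
    as_trait_table(df[c("species", .TRAITS)])
  })
}

#' Simulate trait-linked true range change
#'
#' `y = X beta + e` with `X` the transformed treatment-coded design of the
#' trait table and `e` iid Normal(0, sigma^2).
#'
#' @param traits a `trait_table`.
#' @param beta named coefficient vector; every name must be a design-matrix
#'   term (unknown names raise an error), missing terms are zero.
#' @param sigma residual standard deviation.
#' @param seed integer seed, or `NULL`.
#' @param base log base for the trait transforms.
#' @return named numeric vector of true index values, one per species.
#' @export
simulate_range_change <- function(traits, beta, sigma = 0.6, seed = NULL,
                                  base = 10) {
  traits <- as_trait_table(traits)
  des <- .trait_design(model_transforms(traits, base = base))
  unknown <- setdiff(names(beta), colnames(des$X))
  if (length(unknown) > 0) {
    stop("unknown term(s) in beta: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  b <- stats::setNames(numeric(ncol(des$X)), colnames(des$X))
  b[names(beta)] <- beta
  mu <- drop(des$X %*% b)
  y <- .with_seed(seed, mu + stats::rnorm(nrow(traits), 0, sigma))
  names(y) <- traits$species
  y
}

# Deterministic pool of valid British hectad codes, row-major over the
# 100 km squares of the national grid.
.hectad_pool <- function(n) {
  if (n > 7 * 13 * 100) stop("at most 9100 hectads available", call. = FALSE)
  pairs <- expand.grid(l1 = .GRID_LETTERS, l2 = .GRID_LETTERS,
                       stringsAsFactors = FALSE)
  two <- paste0(pairs$l1, pairs$l2)
  sq <- .letters_to_100km(two)
  keep <- sq[, "e100"] >= 0 & sq[, "e100"] <= 6 &
    sq[, "n100"] >= 0 & sq[, "n100"] <= 12
  two <- two[keep]
  codes <- as.vector(t(outer(two, sprintf("%d%d",
                                          rep(0:9, each = 10),
                                          rep(0:9, times = 10)),
                             paste0)))
  codes[seq_len(n)]
}

# Random grid reference inside a hectad at a given precision (metres).
.random_ref <- function(hectad, precision) {
  if (precision == 10000) return(hectad)
  letters2 <- substr(hectad, 1, 2)
  e1 <- substr(hectad, 3, 3)
  n1 <- substr(hectad, 4, 4)
  if (precision == 2000) {
    return(paste0(hectad, sample(.TETRAD_LETTERS, 1)))
  }
  extra <- if (precision == 1000) 1L else if (precision == 100) 2L
    else if (precision == 10) 3L else 4L
  digits <- function() paste(sample(0:9, extra, replace = TRUE),
                             collapse = "")
  paste0(letters2, e1, digits(), n1, digits())
}

#' Simulate occurrence records
#'
#' Period-1 occupancy is drawn per species with a logit-normal baseline
#' occupancy probability; period-2 occupancy probability is the period-1
#' probability shifted on the logit scale by the species' true index `y`.
#' Each occupied hectad yields a record in a period with the configured
#' detection probability; period-2 detection reflects the effort multiplier
#' (`1 - (1 - d)^multiplier`).  Each detection is emitted as one record
#' with a uniformly drawn year in the period and a grid reference drawn at
#' the configured precision mix.
#'
#' @param traits a `trait_table` (supplies species names).
#' @param y named true index vector from [simulate_range_change()].
#' @param config a `simulation_config`; its `seed` drives this function.
#' @return data frame of records with columns `species`, `gridref`, `year`.
#' @export
simulate_records <- function(traits, y, config = simulation_config()) {
  traits <- as_trait_table(traits)
  stopifnot(length(y) == nrow(traits))
  .with_seed(config$seed, {
    hectads <- .hectad_pool(config$n_hectads)
    d1 <- config$detection
    d2 <- 1 - (1 - d1) ^ config$effort_multiplier
    # Baseline occupancy spread comparable to the packaged dataset's
    # period-1 logit proportions (mean about -2.3, sd about 1.2).
    l1 <- stats::rnorm(nrow(traits), -2.3, 1.2)
    p1 <- stats::plogis(l1)
    p2 <- stats::plogis(l1 + y)
    prec <- as.numeric(names(config$precision_mix))
    rows <- list()
    for (i in seq_len(nrow(traits))) {
      for (per in 1:2) {
        occ_p <- if (per == 1) p1[i] else p2[i]
        det <- if (per == 1) d1 else d2
        present <- stats::runif(config$n_hectads) < occ_p
        detected <- present & (stats::runif(config$n_hectads) < det)
        if (!any(detected)) next
        hs <- hectads[detected]
        yrs <- sample(seq.int(config$periods[[per]][1],
                              config$periods[[per]][2]),
                      length(hs), replace = TRUE)
        pr <- sample(prec, length(hs), replace = TRUE,
                     prob = config$precision_mix)
        refs <- vapply(seq_along(hs),
                       function(j) .random_ref(hs[j], pr[j]), character(1))
        rows[[length(rows) + 1L]] <- data.frame(
          species = traits$species[i], gridref = refs, year = yrs)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a nested taxonomy
#'
#' Assigns species at random to genera and genera to families, permitting
#' polytomies, for use with [build_working_phylogeny()].
#'
#' @param n_species number of species (>= 2).
#' @param seed integer seed, or `NULL`.
#' @param species optional species names; defaults to `species_01`, ...
#' @return data frame with columns `family`, `genus`, `species`.
#' @export
simulate_taxonomy <- function(n_species, seed = NULL, species = NULL) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  if (is.null(species)) {
    species <- sprintf("species_%02d", seq_len(n_species))
  }
  .with_seed(seed, {
    n_genera <- max(2L, ceiling(n_species / 3))
    genus <- sprintf("genus_%02d", sample.int(n_genera, n_species,
                                              replace = TRUE))
    n_fam <- max(2L, ceiling(n_genera / 3))
    fam_of_genus <- sprintf("family_%02d", sample.int(n_fam, n_genera,
                                                      replace = TRUE))
    family <- fam_of_genus[as.integer(sub("genus_", "", genus))]
    data.frame(family = family, genus = genus, species = species)
  })
}
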