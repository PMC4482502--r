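# The 11-trait data model, derived-trait computation, modelling transforms,
# and the pairwise collinearity pre-screen.

# Modelled trait columns, in canonical order.
.TRAITS <- c("habitat_breadth", "vegetation_structure", "oviposition_site",
             "diet", "body_size", "generations_per_year", "winter_stage",
             "phenology", "wing_morph", "wing_load", "average_latitude")

# Canonical level order per categorical trait.  The first level is the
# modelling reference level; the same order defines the integer coding used
# by the Kendall tests in the collinearity screen.
.TRAIT_LEVELS <- list(
  vegetation_structure = c("Short", "Medium", "Tall"),
  oviposition_site     = c("Ground", "Vegetation", "GroundOrVegetation"),
  diet                 = c("Herbivorous", "NotHerbivorous"),
  generations_per_year = c("One", "Half", "HalfOrOne"),
  winter_stage         = c("Egg", "NotEgg"),
  wing_morph           = c("Short", "Long", "Dimorphic")
)

.CONTINUOUS_TRAITS <- setdiff(.TRAITS, names(.TRAIT_LEVELS))

#' Trait column dictionary
#'
#' @return named character vector describing each modelled trait column.
#' @export
trait_dictionary <- function() {
  c(habitat_breadth = "number of habitat types occupied (positive count; log-transformed for modelling)",
    vegetation_structure = "typical vegetation structure: Short, Medium or Tall",
    oviposition_site = "egg-laying substrate: Ground, Vegetation or GroundOrVegetation",
    diet = "Herbivorous or NotHerbivorous",
    body_size = "body length in mm, mean of minimum and maximum (log-transformed for modelling)",
    generations_per_year = "voltinism: One, Half (two-year life cycle) or HalfOrOne",
    winter_stage = "overwintering stage: Egg or NotEgg",
    phenology = "adult peak as decimal month quarter (e.g. 7.75)",
    wing_morph = "Short, Long or Dimorphic wing form",
    wing_load = "wing length squared over body length cubed (dimensionless)",
    average_latitude = "mean latitude (degrees N) of hectads occupied in period 1")
}

#' Validate and canonicalise a trait table
#'
#' Checks that all 11 trait columns are present and complete, restricts
#' categorical columns to their allowed level sets, and converts them to
#' factors with the canonical (reference-first) level order.
#'
#' @param df data frame with a `species` column and the 11 trait columns
#'   (see [trait_dictionary()]).
#' @return the validated data frame, classed `trait_table`, with
#'   categorical columns as factors.
#' @export
as_trait_table <- function(df) {
  missing_cols <- setdiff(c("species", .TRAITS), names(df))
  if (length(missing_cols) > 0) {
    stop("trait table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$species)) {
    stop("duplicate species in trait table", call. = FALSE)
  }
  for (tr in .TRAITS) {
    if (anyNA(df[[tr]])) {
      stop("missing values in trait '", tr, "'", call. = FALSE)
    }
  }
  for (tr in names(.TRAIT_LEVELS)) {
    vals <- as.character(df[[tr]])
    bad <- setdiff(unique(vals), .TRAIT_LEVELS[[tr]])
    if (length(bad) > 0) {
      stop("invalid level(s) in '", tr, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    df[[tr]] <- factor(vals, levels = .TRAIT_LEVELS[[tr]])
  }
  if (any(df$wing_load <= 0)) stop("wing_load must be positive", call. = FALSE)
  class(df) <- unique(c("trait_table", class(df)))
  df
}

#' Packaged 23-species trait and count dataset
#'
#' Loads the packaged dataset of 23 British Orthoptera and allied species:
#' the 11 modelled traits plus the per-species occupied surveyed-square
#' counts `x1` (1980--89) and `x2` (2000--09) out of `n = 844` level-1
#' surveyed squares.
#'
#' @return a `trait_table` data frame with columns `species`, the 11 traits,
#'   `x1` and `x2`.
#' @export
orthoptera_traits <- function() {
  path <- system.file("extdata", "orthoptera_table1.csv",
                      package = "rangetraits", mustWork = TRUE)
  as_trait_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Packaged taxonomy for the 23-species dataset
#'
#' @return data frame with columns `suborder`, `family`, `subfamily`,
#'   `genus`, `species`, suitable for [build_working_phylogeny()].
#' @export
orthoptera_taxonomy <- function() {
  path <- system.file("extdata", "orthoptera_taxonomy.csv",
                      package = "rangetraits", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Wing load
#'
#' The ratio of the square of mean wing length to the cube of mean body
#' length (both in mm).  For wing-dimorphic species the long-winged
#' (macropter) wing length should be supplied.
#'
#' @param wing_length,body_length positive lengths in mm.
#' @return dimensionless ratio `wing_length^2 / body_length^3`.
#' @export
wing_load <- function(wing_length, body_length) {
  if (any(wing_length <= 0) || any(body_length <= 0)) {
    stop("wing and body lengths must be positive", call. = FALSE)
  }
  wing_length ^ 2 / body_length ^ 3
}

#' Modelling transforms for the trait table
#'
#' Log-transforms the two right-skewed traits, habitat breadth and body
#' size, and passes all other traits through unchanged.  The default base
#' is 10; natural log is available via `base = exp(1)`.  (Base only rescales
#' these two coefficients; model fit, selection and significance are
#' unaffected.)
#'
#' @param traits a `trait_table` (see [as_trait_table()]).
#' @param base logarithm base for habitat breadth and body size (default 10).
#' @return data frame of the 11 modelling columns in canonical order, with
#'   `habitat_breadth` and `body_size` log-transformed, rownames = species.
#' @export
model_transforms <- function(traits, base = 10) {
  traits <- as_trait_table(traits)
  if (any(traits$habitat_breadth <= 0) || any(traits$body_size <= 0)) {
    stop("habitat_breadth and body_size must be positive for the log transform",
         call. = FALSE)
  }
  out <- traits[.TRAITS]
  out$habitat_breadth <- log(traits$habitat_breadth, base = base)
  out$body_size <- log(traits$body_size, base = base)
  rownames(out) <- traits$species
  class(out) <- "data.frame"
  out
}

#' Pairwise trait collinearity screen
#'
#' Tests every pair of the 11 traits (55 tests): Pearson correlation
#' between continuous traits, Kendall correlation between categorical
#' traits (integer-coded in canonical level order -- arbitrary for
#' unordered traits, so results are a pre-screen only), and Kruskal-Wallis
#' tests between a continuous and a categorical trait.  P-values are
#' adjusted by Holm's sequential Bonferroni across all tests.  Continuous
#' traits are tested on the modelling (log-transformed) scale.
#'
#' @param traits a `trait_table`.
#' @param alpha significance level applied to the Holm-adjusted p-values
#'   (default 0.05).
#' @param base log base passed to [model_transforms()].
#' @return data frame with columns `trait1`, `trait2`, `test`, `statistic`,
#'   `p`, `p_holm`, `significant`.  Pairs involving a categorical trait
#'   with a single observed level are skipped with a warning (`NA` rows).
#' @export
collinearity_screen <- function(traits, alpha = 0.05, base = 10) {
  traits <- as_trait_table(traits)
  if (nrow(traits) < 3) stop("at least 3 species are required", call. = FALSE)
  d <- model_transforms(traits, base = base)
  is_cat <- .TRAITS %in% names(.TRAIT_LEVELS)
  pairs <- utils::combn(.TRAITS, 2)
  res <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    cat_a <- a %in% names(.TRAIT_LEVELS)
    cat_b <- b %in% names(.TRAIT_LEVELS)
    for (tr in pr[c(cat_a, cat_b)]) {
      if (length(unique(d[[tr]])) < 2) {
        warning("trait '", tr, "' has a single observed level; test skipped")
        return(data.frame(trait1 = a, trait2 = b, test = NA_character_,
                          statistic = NA_real_, p = NA_real_))
      }
    }
    if (!cat_a && !cat_b) {
      ct <- stats::cor.test(d[[a]], d[[b]], method = "pearson")
      data.frame(trait1 = a, trait2 = b, test = "pearson",
                 statistic = unname(ct$estimate), p = ct$p.value)
    } else if (cat_a && cat_b) {
      ct <- suppressWarnings(stats::cor.test(as.integer(d[[a]]),
                                             as.integer(d[[b]]),
                                             method = "kendall"))
      data.frame(trait1 = a, trait2 = b, test = "kendall",
                 statistic = unname(ct$estimate), p = ct$p.value)
    } else {
      cont <- if (cat_a) b else a
      cat_ <- if (cat_a) a else b
      kt <- stats::kruskal.test(d[[cont]], d[[cat_]])
      data.frame(trait1 = a, trait2 = b, test = "kruskal-wallis",
                 statistic = unname(kt$statistic), p = kt$p.value)
    }
  })
  res <- do.call(rbind, res)
  res$p_holm <- stats::p.adjust(res$p, method = "holm")
  res$significant <- !is.na(res$p_holm) & res$p_holm < alpha
  res
}
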