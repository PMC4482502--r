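# Occurrence-record input, hectad/period occupancy summaries, and
# effort-stratified surveyed-square sets.

#' Read occurrence records from delimited text
#'
#' Reads a comma- or tab-delimited UTF-8 file with a header naming at least
#' the columns `species`, `gridref` and `year` (any order, case-insensitive).
#' Grid references are parsed and each record is resolved to its hectad;
#' references coarser than a hectad, and malformed references, raise an
#' error.
#'
#' @param path path to the input file, or a connection.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param window optional length-2 integer vector of study-window years;
#'   records outside it are dropped with a message.
#' @return data frame with columns `species`, `gridref`, `year`, `hectad`,
#'   `precision_m`.
#' @export
read_records <- function(path, sep = NULL, window = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           fileEncoding = "UTF-8", comment.char = "")
  names(raw) <- tolower(names(raw))
  needed <- c("species", "gridref", "year")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- raw[needed]
  rec$year <- as.integer(rec$year)
  if (anyNA(rec$year)) {
    stop("non-integer year values in input", call. = FALSE)
  }
  parsed <- parse_gridref(rec$gridref)
  rec$hectad <- parsed$hectad
  rec$precision_m <- parsed$precision_m
  if (!is.null(window)) {
    keep <- rec$year >= window[1] & rec$year <= window[2]
    if (any(!keep)) {
      message(sum(!keep), " record(s) outside the study window ",
              window[1], "-", window[2], " dropped")
    }
    rec <- rec[keep, , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

#' Summarise records into per-period occupancy matrices
#'
#' A species is marked present in a hectad for a period if it has at least
#' one record there within the period's years; duplicate records are
#' idempotent.  All matrices share the same species rows and hectad columns
#' (the union over all records) so that periods are directly comparable.
#'
#' @param records data frame with columns `species`, `year`, and `hectad`
#'   (as returned by [read_records()]) or `gridref` (hectads are then
#'   derived with [parse_gridref()]).
#' @param periods named list of length-2 integer vectors giving inclusive
#'   year ranges, e.g. `list("1980-89" = c(1980, 1989))`.  Periods must not
#'   overlap.
#' @return a list (one element per period) of `period_occupancy` objects:
#'   each has `$period` (label), `$years`, and `$presence`, a logical
#'   species x hectad matrix.
#' @export
summarize_occupancy <- function(records, periods) {
  if (is.null(records$hectad)) {
    if (is.null(records$gridref)) {
      stop("records need a 'hectad' or 'gridref' column", call. = FALSE)
    }
    records$hectad <- parse_gridref(records$gridref)$hectad
  }
  if (is.null(names(periods)) || any(!nzchar(names(periods)))) {
    names(periods) <- vapply(periods, function(p) paste(p, collapse = "-"),
                             character(1))
  }
  yrs <- lapply(periods, function(p) seq.int(p[1], p[2]))
  all_years <- unlist(yrs)
  if (anyDuplicated(all_years)) {
    stop("periods overlap", call. = FALSE)
  }
  species <- sort(unique(as.character(records$species)))
  hectads <- sort(unique(as.character(records$hectad)))
  out <- lapply(names(periods), function(lab) {
    m <- matrix(FALSE, nrow = length(species), ncol = length(hectads),
                dimnames = list(species, hectads))
    in_p <- records$year >= periods[[lab]][1] & records$year <= periods[[lab]][2]
    if (any(in_p)) {
      idx <- cbind(match(records$species[in_p], species),
                   match(records$hectad[in_p], hectads))
      m[idx] <- TRUE
    }
    structure(list(period = lab, years = periods[[lab]], presence = m),
              class = "period_occupancy")
  })
  names(out) <- names(periods)
  out
}

#' @export
print.period_occupancy <- function(x, ...) {
  cat("Period occupancy ", x$period, ": ", nrow(x$presence), " species x ",
      ncol(x$presence), " hectads, ", sum(x$presence), " presences\n",
      sep = "")
  invisible(x)
}

#' Effort-stratified surveyed-square set
#'
#' A hectad is a "surveyed square" at effort level `k` if at least `k`
#' species were recorded in it in *both* periods; the species need not be
#' the same in the two periods.  Restricting the analysis to surveyed
#' squares controls for uneven spatial recording coverage.  The sets are
#' nested and non-increasing in `k`.
#'
#' @param occ list of exactly two `period_occupancy` objects sharing hectad
#'   columns (from [summarize_occupancy()]).
#' @param k minimum species count, an integer >= 1.
#' @return a `surveyed_squares` object: `$effort_level`, `$hectads`
#'   (character vector), `$n`.
#' @export
surveyed_squares <- function(occ, k = 1L) {
  if (length(occ) != 2L) {
    stop("exactly two periods are required", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("k must be a single integer >= 1", call. = FALSE)
  }
  m1 <- occ[[1]]$presence
  m2 <- occ[[2]]$presence
  if (!identical(colnames(m1), colnames(m2))) {
    stop("the two occupancy matrices must share hectad columns",
         call. = FALSE)
  }
  keep <- colSums(m1) >= k & colSums(m2) >= k
  structure(list(effort_level = as.integer(k),
                 hectads = colnames(m1)[keep],
                 n = sum(keep)),
            class = "surveyed_squares")
}

#' @export
print.surveyed_squares <- function(x, ...) {
  cat("Surveyed squares at effort level k=", x$effort_level, ": ", x$n,
      " hectads\n", sep = "")
  invisible(x)
}

#' Filter species by minimum period-1 range size
#'
#' Species occupying fewer than `min_hectads` surveyed squares in the first
#' period are excluded from the analysis (their indices would be dominated
#' by sampling noise).
#'
#' @param occ1 `period_occupancy` for the first period.
#' @param squares `surveyed_squares` object.
#' @param min_hectads minimum number of occupied surveyed squares (default 5).
#' @return character vector of retained species names.
#' @export
apply_inclusion_filter <- function(occ1, squares, min_hectads = 5L) {
  m <- occ1$presence[, colnames(occ1$presence) %in% squares$hectads,
                     drop = FALSE]
  rownames(m)[rowSums(m) >= min_hectads]
}

#' Annual relative number of recorded hectads per species
#'
#' For each year, a species' value is the number of hectads with at least
#' one record of it, divided by the total number of species-hectad record
#' pairs across all species that year.  The divisor is a whole-group proxy
#' for annual recording effort; years with no records at all are reported as
#' missing rather than raising a division error.
#'
#' @param records record data frame (columns `species`, `hectad`, `year`).
#' @param species optional character vector restricting which species'
#'   series are returned (the divisor always uses all species).
#' @param window optional length-2 year range for the returned series;
#'   defaults to the observed range of years.
#' @return data frame with a `year` column and one column per species.
#' @export
annual_relative_series <- function(records, species = NULL, window = NULL) {
  if (is.null(window)) window <- range(records$year)
  years <- seq.int(window[1], window[2])
  uniq <- unique(records[c("species", "hectad", "year")])
  all_species <- sort(unique(uniq$species))
  if (is.null(species)) species <- all_species
  counts <- table(factor(uniq$species, levels = all_species),
                  factor(uniq$year, levels = years))
  totals <- colSums(counts)
  rel <- sweep(counts, 2, totals, "/")
  rel[, totals == 0] <- NA_real_
  out <- data.frame(year = years)
  for (s in species) out[[s]] <- as.numeric(rel[s, ])
  out
}

#' Write an occupancy matrix to delimited text
#'
#' @param occ `period_occupancy` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(occ, path) {
  df <- data.frame(species = rownames(occ$presence),
                   occ$presence * 1L, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a surveyed-square set as one hectad per line
#'
#' @param squares `surveyed_squares` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_squares <- function(squares, path) {
  writeLines(squares$hectads, path)
  invisible(path)
}
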