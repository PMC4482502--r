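# Ordnance-Survey-style grid reference handling: parsing to hectads and
# converting hectad centres to latitude via the inverse transverse Mercator
# projection of the British national grid.

# Grid letters run A..Z omitting I, in a 5x5 block layout.
.GRID_LETTERS <- strsplit("ABCDEFGHJKLMNOPQRSTUVWXYZ", "")[[1]]

# Tetrad (2 km) suffix letters: A..Z omitting O.
.TETRAD_LETTERS <- setdiff(LETTERS, "O")

#' Decode a two-letter 100 km square code to grid offsets
#'
#' @param letters character vector of two-letter codes (e.g. `"SU"`).
#' @return integer matrix with columns `e100` and `n100`: the easting and
#'   northing of the square's south-west corner in 100 km units.
#' @noRd
.letters_to_100km <- function(letters) {
  chars <- strsplit(toupper(letters), "")
  bad <- vapply(chars, function(ch) {
    length(ch) != 2L || !all(ch %in% .GRID_LETTERS)
  }, logical(1))
  if (any(bad)) {
    stop("invalid grid letters: ", paste(unique(letters[bad]), collapse = ", "),
         call. = FALSE)
  }
  i1 <- vapply(chars, function(ch) match(ch[1], .GRID_LETTERS), integer(1)) - 1L
  i2 <- vapply(chars, function(ch) match(ch[2], .GRID_LETTERS), integer(1)) - 1L
  e100 <- ((i1 - 2L) %% 5L) * 5L + (i2 %% 5L)
  n100 <- 19L - 5L * (i1 %/% 5L) - (i2 %/% 5L)
  cbind(e100 = e100, n100 = n100)
}

#' Parse grid references to hectads and precision
#'
#' Accepts Ordnance-Survey-style alphanumeric grid references: two grid
#' letters followed by an even number of digits (1 to 5 digits of easting and
#' the same of northing), or two letters, two digits and a tetrad suffix
#' letter (A--Z excluding O) denoting a 2 km square.  Each reference is
#' resolved to the 10 km square ("hectad") containing it, which is the
#' spatial unit of the analysis.
#'
#' @param ref character vector of grid references.
#' @return a data frame with one row per input: `ref` (the input), `hectad`
#'   (two letters plus one easting and one northing digit, e.g. `"SU14"`) and
#'   `precision_m` (the side length in metres of the square the reference
#'   names: 10000 for a bare hectad, 2000 for a tetrad, 1000, 100, 10 or 1
#'   for 4, 6, 8 or 10 digits).
#' @details References coarser than a hectad (letters only) are rejected,
#'   since the hectad is the analysis unit.  Grid letters must fall inside
#'   the national grid (easting 0--700 km, northing 0--1300 km).
#' @examples
#' parse_gridref(c("SU123456", "SU12", "SU13K"))
#' @export
parse_gridref <- function(ref) {
  if (length(ref) == 0) {
    return(data.frame(ref = character(0), hectad = character(0),
                      precision_m = numeric(0)))
  }
  ref0 <- as.character(ref)
  r <- toupper(trimws(ref0))
  ok_digits <- grepl("^[A-Z]{2}[0-9]{2,10}$", r) &
    nchar(r) %% 2 == 0
  ok_tetrad <- grepl("^[A-Z]{2}[0-9]{2}[A-Z]$", r)
  coarse <- grepl("^[A-Z]{2}([0-9]{0})$", r)
  bad <- !(ok_digits | ok_tetrad)
  if (any(bad)) {
    why <- ifelse(coarse[bad], " (coarser than 10 km)", "")
    stop("malformed grid reference: ",
         paste0("'", ref0[bad], "'", why, collapse = ", "), call. = FALSE)
  }
  if (any(ok_tetrad)) {
    suff <- substr(r[ok_tetrad], 5, 5)
    badt <- !(suff %in% .TETRAD_LETTERS)
    if (any(badt)) {
      stop("malformed grid reference (invalid tetrad letter): ",
           paste0("'", ref0[ok_tetrad][badt], "'", collapse = ", "),
           call. = FALSE)
    }
  }
  letters2 <- substr(r, 1, 2)
  sq <- .letters_to_100km(letters2)
  out_of_grid <- sq[, "e100"] < 0L | sq[, "e100"] > 6L |
    sq[, "n100"] < 0L | sq[, "n100"] > 12L
  if (any(out_of_grid)) {
    stop("grid letters outside the national grid: ",
         paste0("'", unique(letters2[out_of_grid]), "'", collapse = ", "),
         call. = FALSE)
  }
  digits <- ifelse(ok_tetrad, substr(r, 3, 4), substring(r, 3))
  half <- nchar(digits) %/% 2
  e_digits <- substr(digits, 1, half)
  n_digits <- substr(digits, half + 1, 2 * half)
  hectad <- paste0(letters2, substr(e_digits, 1, 1), substr(n_digits, 1, 1))
  precision <- 10 ^ (5 - half)
  precision[ok_tetrad] <- 2000
  data.frame(ref = ref0, hectad = hectad, precision_m = precision,
             stringsAsFactors = FALSE)
}

#' Easting and northing of a hectad centre
#'
#' @param hectad character vector of 4-character hectad codes.
#' @return matrix with columns `easting` and `northing` in metres (centre of
#'   the 10 km square).
#' @export
hectad_centre <- function(hectad) {
  h <- toupper(trimws(as.character(hectad)))
  bad <- !grepl("^[A-Z]{2}[0-9]{2}$", h)
  if (any(bad)) {
    stop("not a hectad code: ", paste0("'", hectad[bad], "'", collapse = ", "),
         call. = FALSE)
  }
  sq <- .letters_to_100km(substr(h, 1, 2))
  out_of_grid <- sq[, "e100"] < 0L | sq[, "e100"] > 6L |
    sq[, "n100"] < 0L | sq[, "n100"] > 12L
  if (any(out_of_grid)) {
    stop("grid letters outside the national grid: ",
         paste0("'", unique(substr(h[out_of_grid], 1, 2)), "'",
                collapse = ", "), call. = FALSE)
  }
  e <- sq[, "e100"] * 1e5 + as.integer(substr(h, 3, 3)) * 1e4 + 5e3
  n <- sq[, "n100"] * 1e5 + as.integer(substr(h, 4, 4)) * 1e4 + 5e3
  cbind(easting = e, northing = n)
}

#' Inverse transverse Mercator for the British national grid
#'
#' Converts projected easting/northing (metres, national grid / OSGB36) to
#' geographic latitude and longitude in decimal degrees, using the standard
#' Ordnance Survey series expansion on the Airy 1830 ellipsoid.  The small
#' OSGB36 to WGS84 datum shift (under 0.002 degrees of latitude in Britain)
#' is ignored; the documented accuracy of derived hectad latitudes is
#' +-0.01 degrees.
#'
#' @param easting,northing numeric vectors of projected coordinates in metres.
#' @return data frame with columns `latitude` and `longitude` (degrees).
#' @export
osgb_inverse <- function(easting, northing) {
  if (length(easting) != length(northing)) {
    stop("easting and northing must have equal length", call. = FALSE)
  }
  # Airy 1830 ellipsoid and national grid projection constants.
  a <- 6377563.396; b <- 6356256.909
  F0 <- 0.9996012717
  phi0 <- 49 * pi / 180; lam0 <- -2 * pi / 180
  E0 <- 400000; N0 <- -100000
  e2 <- 1 - (b ^ 2) / (a ^ 2)
  nn <- (a - b) / (a + b)

  meridional_arc <- function(phi) {
    b * F0 * (
      (1 + nn + 5 / 4 * nn ^ 2 + 5 / 4 * nn ^ 3) * (phi - phi0) -
      (3 * nn + 3 * nn ^ 2 + 21 / 8 * nn ^ 3) *
        sin(phi - phi0) * cos(phi + phi0) +
      (15 / 8 * nn ^ 2 + 15 / 8 * nn ^ 3) *
        sin(2 * (phi - phi0)) * cos(2 * (phi + phi0)) -
      (35 / 24 * nn ^ 3) * sin(3 * (phi - phi0)) * cos(3 * (phi + phi0))
    )
  }

  lat <- numeric(length(easting))
  lon <- numeric(length(easting))
  for (i in seq_along(easting)) {
    E <- easting[i]; N <- northing[i]
    phi <- phi0
    M <- 0
    repeat {
      phi <- (N - N0 - M) / (a * F0) + phi
      M <- meridional_arc(phi)
      if (abs(N - N0 - M) < 1e-5) break
    }
    sp2 <- sin(phi) ^ 2
    nu <- a * F0 / sqrt(1 - e2 * sp2)
    rho <- a * F0 * (1 - e2) * (1 - e2 * sp2) ^ (-1.5)
    eta2 <- nu / rho - 1
    tp <- tan(phi); tp2 <- tp ^ 2; tp4 <- tp ^ 4
    sec <- 1 / cos(phi)
    VII <- tp / (2 * rho * nu)
    VIII <- tp / (24 * rho * nu ^ 3) * (5 + 3 * tp2 + eta2 - 9 * tp2 * eta2)
    IX <- tp / (720 * rho * nu ^ 5) * (61 + 90 * tp2 + 45 * tp4)
    X <- sec / nu
    XI <- sec / (6 * nu ^ 3) * (nu / rho + 2 * tp2)
    XII <- sec / (120 * nu ^ 5) * (5 + 28 * tp2 + 24 * tp4)
    XIIA <- sec / (5040 * nu ^ 7) * (61 + 662 * tp2 + 1320 * tp4 + 720 * tp ^ 6)
    dE <- E - E0
    lat[i] <- phi - VII * dE ^ 2 + VIII * dE ^ 4 - IX * dE ^ 6
    lon[i] <- lam0 + X * dE - XI * dE ^ 3 + XII * dE ^ 5 - XIIA * dE ^ 7
  }
  data.frame(latitude = lat * 180 / pi, longitude = lon * 180 / pi)
}

#' Latitude of a hectad centroid
#'
#' @param hectad character vector of hectad codes (e.g. `"SU14"`).
#' @return numeric vector of decimal degrees north of the 10 km square
#'   centres, accurate to +-0.01 degrees.
#' @examples
#' hectad_centroid_latitude("SU14")
#' @export
hectad_centroid_latitude <- function(hectad) {
  en <- hectad_centre(hectad)
  osgb_inverse(en[, "easting"], en[, "northing"])$latitude
}
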