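#' Read a fossil occurrence table
#'
#' Expects a CSV with columns `taxon`, `rank`, `paleo_lat`, `paleo_lon`,
#' `age_max`, `age_min` (ages in Ma, latitudes/longitudes in degrees at
#' the time of deposition). Each row is one occurrence with an age
#' uncertainty interval `[age_min, age_max]`.
#'
#' @param path CSV file path.
#' @return a `data.frame` of validated occurrences.
#' @export
read_fossils <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  validate_fossils(x)
}

validate_fossils <- function(x) {
  need <- c("taxon", "rank", "paleo_lat", "paleo_lon", "age_max", "age_min")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("fossil table lacks columns: ", paste(miss, collapse = ", "))
  if (any(x$age_max < x$age_min) || any(x$age_min < 0))
    stop("fossil ages must satisfy age_max >= age_min >= 0")
  if (any(abs(x$paleo_lat) > 90)) stop("paleo_lat out of range")
  x
}

overlapping <- function(fossils, age_Ma) {
  # closed-interval overlap: include when age_min <= age <= age_max
  fossils[fossils$age_min <= age_Ma & fossils$age_max >= age_Ma, ,
          drop = FALSE]
}

#' Tropical latitudinal limit from fossil occurrences
#'
#' The limit at a given age is the 95th percentile (linear interpolation
#' between order statistics, rank `0.95 * (n - 1)`) of the absolute
#' paleo-latitude of all occurrences whose age interval contains the age.
#' One percentile of `|lat|` is used and applied symmetrically about the
#' equator, which is robust to hemisphere-biased fossil sampling.
#'
#' @param fossils occurrence table as returned by [read_fossils()].
#' @param age_Ma query age (Ma).
#' @param prob percentile (default 0.95).
#' @return the latitude limit in degrees (non-negative).
#' @export
tropical_limit <- function(fossils, age_Ma, prob = 0.95) {
  f <- overlapping(validate_fossils(fossils), age_Ma)
  if (nrow(f) == 0) stop(sprintf("no fossils for slice at %g Ma", age_Ma))
  unname(quantile(abs(f$paleo_lat), prob, type = 7))
}

#' Restrict a habitat slice to tropical latitudes
#'
#' Habitat cells whose centroid latitude exceeds `limit` in absolute value
#' are removed; everything else (including the land mask) is unchanged.
#' Masking is idempotent and monotone in `limit`.
#'
#' @param slice a [habitat_slice()].
#' @param limit latitude limit in degrees, in `[0, 90]`.
#' @return the masked [habitat_slice()].
#' @export
apply_tropical_mask <- function(slice, limit) {
  stopifnot(inherits(slice, "habitat_slice"), limit >= 0, limit <= 90)
  lat <- cell_centroid(slice$spec, slice$habitat)[, 2]
  habitat_slice(slice$age_Ma, slice$habitat[abs(lat) <= limit],
                slice$spec, slice$land)
}

#' Mask every slice of a landscape by its fossil-derived tropical limit
#'
#' @param landscape a [paleo_landscape()].
#' @param fossils occurrence table; the limit is recomputed per slice age.
#' @return the masked [paleo_landscape()].
#' @export
mask_landscape <- function(landscape, fossils) {
  slices <- lapply(landscape$slices, function(s)
    apply_tropical_mask(s, tropical_limit(fossils, s$age_Ma)))
  paleo_landscape(landscape$spec, slices)
}

#' Windowed fossil diversity map
#'
#' For each grid cell, counts the distinct species (occurrences resolved
#' to species rank) with at least one occurrence inside the
#' `window_deg` x `window_deg` box centred on the cell centroid and an age
#' interval overlapping `age_Ma`, then min-max rescales the counts to
#' `[0, 1]`. Windows wrap in longitude on a global grid and truncate at
#' the poles. When every cell counts zero species the rescaling is
#' undefined; an all-zero map is returned with a warning.
#'
#' @param fossils occurrence table.
#' @param age_Ma query age (Ma).
#' @param spec target [grid_spec()] (the reference analysis uses 5-degree
#'   cells with a 40-degree window).
#' @param window_deg window edge in degrees (multiple of the resolution).
#' @return numeric vector of length `spec$n_cell` in `[0, 1]`.
#' @export
fossil_diversity_map <- function(fossils, age_Ma, spec, window_deg = 40) {
  stopifnot(inherits(spec, "grid_spec"))
  if (abs(window_deg / spec$res - round(window_deg / spec$res)) > 1e-9)
    stop("window_deg must be a multiple of the grid resolution")
  f <- overlapping(validate_fossils(fossils), age_Ma)
  f <- f[f$rank == "species", , drop = FALSE]
  if (nrow(f) == 0) stop("no species-rank occurrences for this age")
  half <- window_deg / 2
  ctr <- cell_centroid(spec, seq_len(spec$n_cell))
  counts <- numeric(spec$n_cell)
  for (sp in unique(f$taxon)) {
    occ <- f[f$taxon == sp, , drop = FALSE]
    hit <- rep(FALSE, spec$n_cell)
    for (i in seq_len(nrow(occ))) {
      dlon <- abs(ctr[, 1] - occ$paleo_lon[i])
      if (spec$global) dlon <- pmin(dlon, 360 - dlon)
      hit <- hit | (dlon <= half & abs(ctr[, 2] - occ$paleo_lat[i]) <= half)
    }
    counts <- counts + hit
  }
  rng <- range(counts)
  if (rng[2] == rng[1]) {
    warning("constant diversity counts; returning an all-zero map")
    return(numeric(spec$n_cell))
  }
  (counts - rng[1]) / (rng[2] - rng[1])
}
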