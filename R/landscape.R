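#' A single-age habitat map
#'
#' One slice of a dynamic landscape: the set of cells that are tropical
#' shallow-reef habitat at a given age, plus (optionally) the set of
#' emerged-land cells. A cell cannot be both habitat and land.
#'
#' @param age_Ma age of the slice in millions of years before present (> 0).
#' @param habitat integer cell ids of reef habitat, or a logical vector of
#'   length `spec$n_cell`.
#' @param spec the [grid_spec()] of the parent landscape.
#' @param land integer cell ids of emerged land (optional; empty when the
#'   input carries no land mask).
#' @return an object of class `habitat_slice`.
#' @export
habitat_slice <- function(age_Ma, habitat, spec, land = integer(0)) {
  stopifnot(inherits(spec, "grid_spec"), age_Ma > 0)
  if (is.logical(habitat)) {
    stopifnot(length(habitat) == spec$n_cell)
    habitat <- which(habitat)
  }
  if (is.logical(land)) land <- which(land)
  habitat <- as.integer(sort(unique(habitat)))
  land <- as.integer(sort(unique(land)))
  stopifnot(valid_cells(spec, habitat) || length(habitat) == 0,
            valid_cells(spec, land) || length(land) == 0)
  if (length(intersect(habitat, land)))
    stop("a cell cannot be both reef habitat and emerged land")
  structure(list(age_Ma = age_Ma, habitat = habitat, land = land,
                 spec = spec),
            class = "habitat_slice")
}

#' An ordered stack of habitat slices
#'
#' Slices must have strictly decreasing ages at a uniform step (1 Myr by
#' convention), oldest first; at least two slices are required. All slices
#' share one [grid_spec()].
#'
#' @param spec a [grid_spec()].
#' @param slices list of [habitat_slice()] objects (any age order; they are
#'   sorted to decreasing age).
#' @return an object of class `paleo_landscape`.
#' @export
paleo_landscape <- function(spec, slices) {
  stopifnot(inherits(spec, "grid_spec"), length(slices) >= 2)
  ok <- vapply(slices, inherits, logical(1), "habitat_slice")
  if (!all(ok)) stop("all slices must be habitat_slice objects")
  ages <- vapply(slices, `[[`, numeric(1), "age_Ma")
  if (anyDuplicated(ages)) stop("duplicated slice ages")
  slices <- slices[order(ages, decreasing = TRUE)]
  ages <- sort(ages, decreasing = TRUE)
  steps <- diff(ages)
  if (length(unique(round(steps, 9))) != 1)
    stop("non-uniform time step in slice ages")
  for (s in slices)
    if (!same_spec(s$spec, spec))
      stop(sprintf("slice at %g Ma has a different grid than the landscape",
                   s$age_Ma))
  structure(list(spec = spec, slices = slices, ages = ages,
                 step = -steps[1]),
            class = "paleo_landscape")
}

#' @export
print.paleo_landscape <- function(x, ...) {
  cat(sprintf("paleo_landscape: %d slices, %g -> %g Ma (step %g Myr), grid %dx%d @ %g deg\n",
              length(x$slices), x$ages[1], x$ages[length(x$ages)], x$step,
              x$spec$n_lon, x$spec$n_lat, x$spec$res))
  invisible(x)
}

#' @rdname paleo_landscape
#' @param x a `paleo_landscape`.
#' @export
landscape_ages <- function(x) x$ages

slice_at <- function(landscape, age_Ma) {
  i <- match(age_Ma, landscape$ages)
  if (is.na(i)) stop(sprintf("no slice at %g Ma", age_Ma))
  landscape$slices[[i]]
}

#' @rdname paleo_landscape
#' @param age_Ma a slice age present in the stack.
#' @export
habitat_cells <- function(x, age_Ma) slice_at(x, age_Ma)$habitat

#' Write / read a landscape as a directory of ASCII grids
#'
#' The on-disk format is a directory of per-age ESRI ASCII grids named
#' `habitat_<age>.asc` (0/1 values, rows north to south), with optional
#' companion `land_<age>.asc` files. The grid geometry is carried by the
#' standard header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`); round-tripping reproduces all masks bit for bit.
#'
#' @param x a [paleo_landscape()].
#' @param path directory to write to (created if needed) / read from.
#' @return `write_landscape` returns `path` invisibly; `read_landscape`
#'   returns a validated `paleo_landscape` with slices in decreasing-age
#'   order. Missing ages (a non-uniform step) or shape mismatches between
#'   slices raise an error naming the offending slice.
#' @export
write_landscape <- function(x, path) {
  stopifnot(inherits(x, "paleo_landscape"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (s in x$slices) {
    write_asc(file.path(path, sprintf("habitat_%g.asc", s$age_Ma)),
              s$habitat, x$spec)
    if (length(s$land))
      write_asc(file.path(path, sprintf("land_%g.asc", s$age_Ma)),
                s$land, x$spec)
  }
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  files <- list.files(path, pattern = "^habitat_.*\\.asc$", full.names = TRUE)
  if (length(files) < 2) stop("need at least two habitat_<age>.asc slices")
  ages <- as.numeric(sub("^habitat_(.*)\\.asc$", "\\1", basename(files)))
  ord <- order(ages, decreasing = TRUE)
  files <- files[ord]; ages <- ages[ord]
  first <- read_asc(files[1])
  spec <- first$spec
  slices <- vector("list", length(files))
  for (i in seq_along(files)) {
    g <- read_asc(files[i])
    if (!same_spec(g$spec, spec))
      stop(sprintf("shape mismatch in slice %s", basename(files[i])))
    lf <- file.path(path, sprintf("land_%g.asc", ages[i]))
    land <- if (file.exists(lf)) read_asc(lf)$cells else integer(0)
    slices[[i]] <- habitat_slice(ages[i], g$cells, spec, land)
  }
  paleo_landscape(spec, slices)
}

write_asc <- function(file, cells, spec) {
  m <- matrix(0L, spec$n_lat, spec$n_lon)
  m[cbind((cells - 1) %/% spec$n_lon + 1, (cells - 1) %% spec$n_lon + 1)] <- 1L
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", spec$n_lon),
               sprintf("nrows %d", spec$n_lat),
               sprintf("xllcorner %g", spec$lon_min),
               sprintf("yllcorner %g", spec$lat_min),
               sprintf("cellsize %g", spec$res),
               "NODATA_value -9999"), con)
  # ESRI ASCII rows run north -> south; internal rows run south -> north
  for (r in spec$n_lat:1)
    writeLines(paste(m[r, ], collapse = " "), con)
  invisible(file)
}

read_asc <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- setNames(vapply(hdr, `[`, "", 2), tolower(vapply(hdr, `[`, "", 1)))
  n_lon <- as.integer(kv[["ncols"]])
  n_lat <- as.integer(kv[["nrows"]])
  res <- as.numeric(kv[["cellsize"]])
  lon_min <- as.numeric(kv[["xllcorner"]])
  lat_min <- as.numeric(kv[["yllcorner"]])
  spec <- grid_spec(res, lon_min, lon_min + n_lon * res,
                    lat_min, lat_min + n_lat * res)
  body <- lines[7:length(lines)]
  if (length(body) != n_lat)
    stop(sprintf("shape mismatch in %s: expected %d rows, found %d",
                 basename(file), n_lat, length(body)))
  vals <- lapply(strsplit(trimws(body), "\\s+"), as.integer)
  if (any(lengths(vals) != n_lon))
    stop(sprintf("shape mismatch in %s: ragged rows", basename(file)))
  m <- do.call(rbind, vals)[n_lat:1, , drop = FALSE]  # back to south-first
  list(spec = spec, cells = which(t(m) == 1) |> as.integer() |> sort_cells(n_lon))
}

# column-major 'which' over t(m) gives row-major ids already; keep sorted
sort_cells <- function(ids, n_lon) as.integer(sort(ids))
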