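#' Describe a drifting habitat province
#'
#' A province is a rectangular patch of shelf habitat that can drift,
#' appear at a given age, and lose area from one edge over an interval
#' (emulating, for example, the progressive closure of a seaway).
#'
#' @param lon_min,lon_max,lat_min,lat_max province bounds (degrees) at the
#'   start age.
#' @param drift_lon,drift_lat drift velocity in degrees per Myr (positive =
#'   east / north) applied over elapsed time since the start age.
#' @param appear_age age (Ma) at which the province first exists
#'   (`Inf` = always).
#' @param erode optional list `(edge, start_age, end_age, rate)`: from
#'   `start_age` the named edge (`"west"`, `"east"`, `"south"`, `"north"`)
#'   moves inward at `rate` degrees per Myr until `end_age`.
#' @return a `province` description used by
#'   [generate_synthetic_landscape()].
#' @export
province <- function(lon_min, lon_max, lat_min, lat_max,
                     drift_lon = 0, drift_lat = 0,
                     appear_age = Inf, erode = NULL) {
  stopifnot(lon_max > lon_min, lat_max > lat_min)
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 drift_lon = drift_lon, drift_lat = drift_lat,
                 appear_age = appear_age, erode = erode),
            class = "province")
}

province_box <- function(p, age, start_age) {
  el <- start_age - age
  box <- c(lon_min = p$lon_min + p$drift_lon * el,
           lon_max = p$lon_max + p$drift_lon * el,
           lat_min = p$lat_min + p$drift_lat * el,
           lat_max = p$lat_max + p$drift_lat * el)
  if (!is.null(p$erode)) {
    e <- p$erode
    amount <- e$rate * max(0, min(e$start_age, start_age) - max(age, e$end_age))
    switch(e$edge,
           west = box["lon_min"] <- box["lon_min"] + amount,
           east = box["lon_max"] <- box["lon_max"] - amount,
           south = box["lat_min"] <- box["lat_min"] + amount,
           north = box["lat_max"] <- box["lat_max"] - amount,
           stop("unknown erode edge"))
  }
  box
}

box_cells <- function(spec, box) {
  lon <- spec$lon_min + (seq_len(spec$n_lon) - 0.5) * spec$res
  lat <- spec$lat_min + (seq_len(spec$n_lat) - 0.5) * spec$res
  cols <- which(lon >= box["lon_min"] & lon <= box["lon_max"])
  rows <- which(lat >= box["lat_min"] & lat <= box["lat_max"])
  if (!length(cols) || !length(rows)) return(integer(0))
  as.integer(outer(cols, (rows - 1) * spec$n_lon, `+`))
}

# split a box into n fragments along longitude with inter-fragment gaps
# wide enough that the nearest-centroid great-circle separation is >= gap
fragment_boxes <- function(spec, box, n, gap) {
  philim <- max(abs(box[c("lat_min", "lat_max")]))
  g_lon <- gap / max(cos(philim * pi / 180), 1e-6)
  g_lon <- ceiling(g_lon / spec$res) * spec$res
  repeat {
    w <- (box["lon_max"] - box["lon_min"] - (n - 1) * g_lon) / n
    if (w < spec$res)
      stop("fragmentation episode leaves fragments narrower than one cell")
    boxes <- lapply(seq_len(n) - 1, function(i) {
      b <- box
      b["lon_min"] <- box["lon_min"] + i * (w + g_lon)
      b["lon_max"] <- b["lon_min"] + w
      b
    })
    cells <- lapply(boxes, box_cells, spec = spec)
    if (any(lengths(cells) == 0))
      stop("fragmentation episode produced an empty fragment")
    ok <- TRUE
    for (i in seq_len(n - 1)) {
      a <- cell_centroid(spec, cells[[i]])
      b <- cell_centroid(spec, cells[[i + 1]])
      if (cpp_min_cross_dist(a[, 1], a[, 2], b[, 1], b[, 2]) < gap) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(cells)
    g_lon <- g_lon + spec$res
  }
}

#' Generate a synthetic dynamic paleo-landscape
#'
#' Builds a deterministic [paleo_landscape()] from drifting rectangular
#' shelf provinces, scripted fragmentation/reconnection episodes, and an
#' optional two-province collision in which an approaching province closes
#' its gap linearly and becomes adjacent to its partner at the merge age.
#' All geometry is deterministic given the parameters and `seed`; the seed
#' only controls the optional edge raggedness pattern (drawn once per
#' province, drifting with it, so per-slice habitat area stays continuous
#' away from scripted episodes).
#'
#' @param spec a [grid_spec()].
#' @param start_age,end_age oldest and youngest slice ages (Ma).
#' @param step_Myr slice spacing (default 1 Myr).
#' @param provinces list of [province()] descriptions (at least one).
#' @param frag_episodes list of episodes, each a list with fields `age`
#'   (episode onset, Ma), `province` (index into `provinces`),
#'   `n_fragments`, `gap_deg` (minimum great-circle separation between
#'   fragments, degrees of arc), and `duration_Myr` (default 2): for slice
#'   ages in `(age - duration, age]` the province is split; afterwards it
#'   is whole again (reconnection).
#' @param collision optional list `(province, other, merge_age)`: the
#'   named province is repositioned each slice so its western edge sits a
#'   linearly shrinking gap east of `other`'s eastern edge, touching
#'   (adjacent cells, zero-cell gap) for ages at or below `merge_age` and
#'   strictly disjoint before.
#' @param seed integer seed for the raggedness pattern.
#' @param notch_frac fraction of edge columns notched one cell inward
#'   (0 disables; default 0).
#' @return a [paleo_landscape()].
#' @export
generate_synthetic_landscape <- function(spec, start_age = 140, end_age = 1,
                                         step_Myr = 1,
                                         provinces,
                                         frag_episodes = list(),
                                         collision = NULL,
                                         seed = 1, notch_frac = 0) {
  stopifnot(inherits(spec, "grid_spec"), start_age > end_age, step_Myr > 0)
  if (length(provinces) == 0) stop("at least one province is required")
  ages <- seq(start_age, end_age, by = -step_Myr)
  notches <- lapply(seq_along(provinces), function(i) {
    if (notch_frac <= 0) return(integer(0))
    set.seed(derive_seed(seed, 911L, i))
    ncol_loc <- max(1, round((provinces[[i]]$lon_max - provinces[[i]]$lon_min) /
                               spec$res))
    sort(sample.int(ncol_loc, max(0, round(notch_frac * ncol_loc))))
  })
  slices <- vector("list", length(ages))
  for (k in seq_along(ages)) {
    a <- ages[k]
    hab <- integer(0)
    for (i in seq_along(provinces)) {
      p <- provinces[[i]]
      if (a > p$appear_age) next
      box <- province_box(p, a, start_age)
      if (!is.null(collision) && collision$province == i) {
        other_box <- province_box(provinces[[collision$other]], a, start_age)
        width <- box["lon_max"] - box["lon_min"]
        gap0 <- box["lon_min"] - other_box["lon_max"]
        frac <- (a - collision$merge_age) / (start_age - collision$merge_age)
        gap <- if (a > collision$merge_age)
          max(spec$res, round(gap0 * frac / spec$res) * spec$res) else 0
        box["lon_min"] <- other_box["lon_max"] + gap
        box["lon_max"] <- box["lon_min"] + width
      }
      epi <- Filter(function(e) {
        dur <- if (is.null(e$duration_Myr)) 2 else e$duration_Myr
        e$province == i && a <= e$age && a > e$age - dur
      }, frag_episodes)
      cells <- if (length(epi)) {
        unlist(fragment_boxes(spec, box, epi[[1]]$n_fragments,
                              epi[[1]]$gap_deg))
      } else {
        box_cells(spec, box)
      }
      if (length(cells) == 0)
        stop(sprintf("province %d drifts off the grid at %g Ma", i, a))
      if (length(notches[[i]])) {
        col0 <- floor((box["lon_min"] - spec$lon_min) / spec$res)
        top_row <- max((cells - 1) %/% spec$n_lon)
        loc <- ((cells - 1) %% spec$n_lon) - col0 + 1
        drop <- ((cells - 1) %/% spec$n_lon) == top_row & loc %in% notches[[i]]
        cells <- cells[!drop]
      }
      hab <- union(hab, cells)
    }
    slices[[k]] <- habitat_slice(a, hab, spec)
  }
  paleo_landscape(spec, slices)
}

#' Canned synthetic landscape scenarios
#'
#' Fixed scenarios used throughout the package's examples and validation:
#'
#' * `scenario_static()`: one connected province, nothing changes — a
#'   landscape on which a purely parapatric clade can never diversify.
#' * `scenario_fragmentation()`: one province split once into
#'   `n_fragments` patches separated by at least `gap_deg`, for
#'   `duration_Myr`, then reconnected.
#' * `scenario_fragmentation_cycles()`: the parameter-recovery landscape —
#'   a 36 x 18-cell, 1-degree window holding one wide province that
#'   undergoes eight split/reconnect episodes (gaps cycling 6, 4, 8
#'   degrees) over 140 Myr, plus a small offshore island 6 degrees east
#'   appearing at 100 Ma, so that both the split threshold and the
#'   dispersal cap leave separate signatures in richness maps.
#' * `scenario_corridor_closure()`: an east-west corridor whose western
#'   end erodes away through time, pushing habitat (and the diversity it
#'   carries) monotonically eastward — a minimal hopping-hotspot setting.
#' * `scenario_collision()`: two provinces, initially ~20 degrees apart,
#'   that converge linearly and become adjacent at `merge_age` — the
#'   two-fauna fusion setting.
#'
#' @param start_age,end_age simulated interval (Ma).
#' @param seed seed forwarded to [generate_synthetic_landscape()].
#' @return a [paleo_landscape()].
#' @export
scenario_static <- function(start_age = 140, end_age = 1, seed = 1) {
  spec <- grid_spec(1, 0, 36, -9, 9)
  generate_synthetic_landscape(spec, start_age, end_age,
                               provinces = list(province(2, 34, -6, 6)),
                               seed = seed)
}

#' @rdname scenario_static
#' @param n_fragments,gap_deg,split_age,duration_Myr episode shape: the
#'   province splits into `n_fragments` patches separated by at least
#'   `gap_deg` degrees for slices in `(split_age - duration_Myr, split_age]`.
#' @export
scenario_fragmentation <- function(n_fragments = 3, gap_deg = 7,
                                   split_age = 15, duration_Myr = 2,
                                   start_age = 30, end_age = 1, seed = 1) {
  spec <- grid_spec(1, 0, 36, -9, 9)
  generate_synthetic_landscape(
    spec, start_age, end_age,
    provinces = list(province(1, 35, -6, 6)),
    frag_episodes = list(list(age = split_age, province = 1,
                              n_fragments = n_fragments, gap_deg = gap_deg,
                              duration_Myr = duration_Myr)),
    seed = seed)
}

#' @rdname scenario_static
#' @export
scenario_fragmentation_cycles <- function(start_age = 140, end_age = 1,
                                          seed = 1) {
  spec <- grid_spec(1, 0, 36, -9, 9)
  gaps <- c(6, 4, 8, 6, 4, 8, 6, 4)
  epis <- Map(function(age, gap)
    list(age = age, province = 1, n_fragments = 2, gap_deg = gap,
         duration_Myr = 3),
    seq(120, 15, by = -15), gaps)
  generate_synthetic_landscape(
    spec, start_age, end_age,
    provinces = list(province(2, 28, -6, 6),
                     province(33, 36, -1, 2, appear_age = 100)),
    frag_episodes = epis, seed = seed)
}

#' @rdname scenario_static
#' @export
scenario_corridor_closure <- function(start_age = 140, end_age = 1,
                                      seed = 1) {
  spec <- grid_spec(1, 0, 40, -5, 5)
  generate_synthetic_landscape(
    spec, start_age, end_age,
    provinces = list(province(2, 38, -3, 3,
                              erode = list(edge = "west", start_age = 140,
                                           end_age = 1, rate = 0.2))),
    seed = seed)
}

#' @rdname scenario_static
#' @param merge_age age (Ma) at which the two provinces first touch.
#' @export
scenario_collision <- function(merge_age = 15, start_age = 140, end_age = 1,
                               seed = 1) {
  spec <- grid_spec(1, 0, 40, -6, 6)
  generate_synthetic_landscape(
    spec, start_age, end_age,
    provinces = list(province(2, 14, -4, 4),
                     province(26, 38, -4, 4)),
    collision = list(province = 2, other = 1, merge_age = merge_age),
    seed = seed)
}
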