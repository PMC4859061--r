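#' Distance model between grid cells
#'
#' Two modes are supported. `great_circle` measures the central angle
#' between cell centroids, in degrees of arc, taking the short way around
#' the globe. `sea_graph` measures the length of the shortest path over
#' non-land cells (8-neighbour moves, each edge weighted by the central
#' angle between the two centroids); cell pairs with no sea path are at
#' infinite distance. `sea_graph` therefore dominates `great_circle` for
#' every pair.
#'
#' @param mode `"great_circle"` (default) or `"sea_graph"`.
#' @param spec the [grid_spec()] the model operates on.
#' @param land for `sea_graph`, integer ids of emerged-land cells (may be
#'   empty); required so the traversable graph can be built.
#' @return an object of class `distance_model`.
#' @export
distance_model <- function(mode = c("great_circle", "sea_graph"),
                           spec, land = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "grid_spec"))
  m <- list(mode = mode, spec = spec)
  if (mode == "sea_graph") {
    if (is.null(land)) stop("sea_graph mode requires a land mask (use integer(0) for no land)")
    stopifnot(valid_cells(spec, land) || length(land) == 0)
    m$land <- as.integer(sort(unique(land)))
    m$graph <- build_sea_graph(spec, m$land)
  }
  class(m) <- "distance_model"
  m
}

# 8-neighbour graph over sea (non-land) cells; longitude wraps on global grids
build_sea_graph <- function(spec, land) {
  sea <- setdiff(seq_len(spec$n_cell), land)
  vid <- integer(spec$n_cell)        # cell id -> vertex index (0 = land)
  vid[sea] <- seq_along(sea)
  row <- (sea - 1) %/% spec$n_lon
  col <- (sea - 1) %% spec$n_lon
  from <- integer(0); to <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr < 0 || (dr == 0 && dc <= 0)) next  # each undirected edge once
    r2 <- row + dr
    c2 <- col + dc
    if (spec$global) c2 <- c2 %% spec$n_lon
    ok <- r2 >= 0 & r2 < spec$n_lat & c2 >= 0 & c2 < spec$n_lon
    nb <- as.integer(r2[ok] * spec$n_lon + c2[ok] + 1)
    keep <- vid[nb] > 0
    from <- c(from, sea[ok][keep])
    to <- c(to, nb[keep])
  }
  xy1 <- cell_centroid(spec, from)
  xy2 <- cell_centroid(spec, to)
  w <- cpp_arc_deg(xy1[, 1], xy1[, 2], xy2[, 1], xy2[, 2])
  g <- igraph::make_empty_graph(n = length(sea), directed = FALSE)
  g <- igraph::add_edges(g, rbind(vid[from], vid[to]))
  igraph::E(g)$weight <- w
  list(graph = g, vid = vid, sea = sea)
}

#' Distance between grid cells
#'
#' @param a,b integer cell ids (vectors are paired elementwise, recycled).
#' @param model a [distance_model()].
#' @return distances in degrees of arc; `Inf` for sea-graph pairs with no
#'   sea path.
#' @export
cell_distance <- function(a, b, model) {
  stopifnot(inherits(model, "distance_model"))
  spec <- model$spec
  stopifnot(valid_cells(spec, a), valid_cells(spec, b))
  if (model$mode == "great_circle") {
    xy1 <- cell_centroid(spec, a)
    xy2 <- cell_centroid(spec, b)
    return(as.numeric(cpp_arc_deg(xy1[, 1], xy1[, 2], xy2[, 1], xy2[, 2])))
  }
  if (any(model$graph$vid[c(a, b)] == 0))
    stop("sea_graph distance requested for a land cell")
  d <- sea_cross_distance(model, unique(a), unique(b))
  d[cbind(match(a, unique(a)), match(b, unique(b)))]
}

# |A| x |B| distance matrix under the model
cross_distance <- function(a, b, model) {
  spec <- model$spec
  if (model$mode == "great_circle") {
    xy1 <- cell_centroid(spec, a)
    xy2 <- cell_centroid(spec, b)
    cpp_cross_dist(xy1[, 1], xy1[, 2], xy2[, 1], xy2[, 2])
  } else {
    sea_cross_distance(model, a, b)
  }
}

sea_cross_distance <- function(model, a, b) {
  g <- model$graph
  if (any(g$vid[c(a, b)] == 0))
    stop("sea_graph distance requested for a land cell")
  igraph::distances(g$graph, v = g$vid[a], to = g$vid[b],
                    algorithm = "dijkstra")
}

lonlat_trig <- function(lon, lat) {
  lonr <- lon * pi / 180
  latr <- lat * pi / 180
  list(sp = sin(latr), cp = cos(latr), sl = sin(lonr), cl = cos(lonr))
}

#' Partition a species range into distance-threshold clusters
#'
#' Cells belong to the same block iff they are connected by a chain of
#' pairwise distances at most `d_s` (single-linkage blocks at threshold
#' `d_s`; the comparison is closed, so pairs exactly at the threshold are
#' linked). A range fragmented into `n` such blocks is the condition for a
#' parapatric split into `n` daughter species.
#'
#' @param cells integer cell ids of the range (may be empty).
#' @param d_s distance threshold in degrees of arc (> 0).
#' @param model a [distance_model()].
#' @return list of integer vectors, the blocks (disjoint, covering
#'   `cells`), ordered by first-encountered cell; empty list for an empty
#'   range.
#' @export
range_clusters <- function(cells, d_s, model) {
  stopifnot(d_s > 0, inherits(model, "distance_model"))
  cells <- as.integer(cells)
  if (length(cells) == 0) return(list())
  if (length(cells) == 1) return(list(cells))
  if (model$mode == "great_circle") {
    xy <- cell_centroid(model$spec, cells)
    tg <- lonlat_trig(xy[, 1], xy[, 2])
    lab <- cpp_components_trig(xy[, 2], tg$sp, tg$cp, tg$sl, tg$cl, d_s)
  } else {
    d <- sea_cross_distance(model, cells, cells)
    adj <- d <= d_s
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    lab <- igraph::components(g)$membership
  }
  unname(split(cells, factor(lab, levels = unique(lab))))
}

#' Habitat cells reachable from a source set
#'
#' Returns every habitat cell whose distance to the *nearest* source cell
#' is at most `r`: a single expansion hop from the occupied set, not
#' iterated chaining within one call. Chains across time steps emerge from
#' repeated calls during a simulation.
#'
#' @param sources integer cell ids of the occupied set.
#' @param habitat integer cell ids of available habitat.
#' @param r reach in degrees of arc (>= 0).
#' @param model a [distance_model()].
#' @return integer vector, the subset of `habitat` within `r` of a source.
#' @export
reachable_cells <- function(sources, habitat, r, model) {
  stopifnot(r >= 0, inherits(model, "distance_model"))
  sources <- as.integer(sources)
  habitat <- as.integer(habitat)
  if (length(sources) == 0 || length(habitat) == 0) return(integer(0))
  if (model$mode == "great_circle") {
    xy1 <- cell_centroid(model$spec, sources)
    xy2 <- cell_centroid(model$spec, habitat)
    t1 <- lonlat_trig(xy1[, 1], xy1[, 2])
    t2 <- lonlat_trig(xy2[, 1], xy2[, 2])
    habitat[cpp_reachable_trig(xy1[, 2], t1$sp, t1$cp, t1$sl, t1$cl,
                               xy2[, 2], t2$sp, t2$cp, t2$sl, t2$cl,
                               r, habitat %in% sources)]
  } else {
    d <- sea_cross_distance(model, sources, habitat)
    habitat[apply(d, 2, min) <= r]
  }
}
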