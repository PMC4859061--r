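#' Configure a diversification simulation
#'
#' Holds every tunable of the time-stepped engine. Speciation can be
#' parapatric (a range fragmented into blocks separated by more than `d_s`
#' degrees of sea distance splits into one daughter per block), sympatric
#' (each occupied cell spawns a single-cell daughter with per-step
#' probability `P_s`), or both (`"combined"`, parapatric checked first
#' within the speciation phase). Dispersal each step draws a per-species
#' reach `r = min(x, d)` with `x ~ Weibull(shape, scale = scale_ratio * d)`
#' and extends the range to every next-step habitat cell within `r`;
#' a species dies only when its entire occupied habitat disappears and no
#' habitat lies within reach.
#'
#' The plausible regimes are `d` and `d_s` in 1-40 degrees and `P_s` in
#' 1e-5 to 1e-4 per cell per Myr; values outside these ranges are allowed
#' but trigger a warning, since they tend to produce either total
#' extinction or runaway richness (especially when `d > d_s`).
#'
#' @param mode `"parapatric"`, `"sympatric"` or `"combined"`.
#' @param d dispersal cap in degrees of arc per Myr step.
#' @param d_s parapatric split threshold in degrees (parapatric/combined).
#' @param P_s per-cell per-step sympatric speciation probability
#'   (sympatric/combined).
#' @param weibull_shape,weibull_scale_ratio dispersal kernel shape and the
#'   ratio scale/d (defaults 2 and 0.5: mean reach well inside the cap
#'   with a tail that occasionally hits it).
#' @param seed integer root seed; all stochasticity derives from it via
#'   [derive_seed()].
#' @param start_age,end_age simulated interval in Ma (default: the full
#'   landscape extent at run time).
#' @param forced_extinctions list of `list(age, fraction)` events: at each
#'   listed age, `round(fraction * n_extant)` extant species are removed
#'   uniformly at random (a scripted mass extinction).
#' @param snapshot_ages ages at which site-by-species occupancy matrices
#'   are recorded (after the speciation phase of that age).
#' @param distance_mode `"great_circle"` (default) or `"sea_graph"`.
#' @param start_region optional integer cell ids: the root species starts
#'   on the intersection of this region with the first slice's habitat
#'   (for younger-clade experiments); default is all habitat.
#' @param species_cap abort threshold on extant richness (default 20000).
#' @param split_events `"per_split"` (default; one parapatric split counts
#'   as one speciation event regardless of the number of daughters) or
#'   `"per_daughter"` (counts n - 1).
#' @param parent_convention `"close"` (default; the fragmented parent is
#'   closed as a pseudo-extinct internal node and every block founds a
#'   daughter) or `"largest_keeps"` (the largest block keeps the parent
#'   identity).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(mode = c("parapatric", "sympatric", "combined"),
                       d, d_s = NULL, P_s = NULL,
                       weibull_shape = 2, weibull_scale_ratio = 0.5,
                       seed = 1, start_age = NULL, end_age = NULL,
                       forced_extinctions = list(),
                       snapshot_ages = numeric(0),
                       distance_mode = c("great_circle", "sea_graph"),
                       start_region = NULL,
                       species_cap = 20000,
                       split_events = c("per_split", "per_daughter"),
                       parent_convention = c("close", "largest_keeps")) {
  mode <- match.arg(mode)
  distance_mode <- match.arg(distance_mode)
  split_events <- match.arg(split_events)
  parent_convention <- match.arg(parent_convention)
  stopifnot(is.numeric(d), d > 0, weibull_shape > 0, weibull_scale_ratio > 0)
  if (mode %in% c("parapatric", "combined")) {
    if (is.null(d_s)) stop("d_s is required for the parapatric/combined modes")
    if (d_s < 1 || d_s > 40)
      warning("d_s outside the plausible 1-40 degree range")
  }
  if (mode %in% c("sympatric", "combined")) {
    if (is.null(P_s)) stop("P_s is required for the sympatric/combined modes")
    if (P_s < 0 || P_s > 1) stop("P_s must be a probability")
    if (P_s > 0 && (P_s < 1e-5 || P_s > 1e-4))
      warning("P_s outside the plausible 1e-5 to 1e-4 range")
  }
  if (d < 1 || d > 40) warning("d outside the plausible 1-40 degree range")
  for (fe in forced_extinctions) {
    stopifnot(!is.null(fe$age), !is.null(fe$fraction))
    if (fe$fraction < 0 || fe$fraction > 1)
      stop("forced extinction fraction must be in [0, 1]")
  }
  structure(list(mode = mode, d = d, d_s = d_s, P_s = P_s,
                 weibull_shape = weibull_shape,
                 weibull_scale_ratio = weibull_scale_ratio,
                 seed = as.integer(seed),
                 start_age = start_age, end_age = end_age,
                 forced_extinctions = forced_extinctions,
                 snapshot_ages = snapshot_ages,
                 distance_mode = distance_mode,
                 start_region = start_region,
                 species_cap = species_cap,
                 split_events = split_events,
                 parent_convention = parent_convention),
            class = "sim_config")
}

# --- internal mutable state (environment-based for speed) ----------------

new_species <- function(st, parent, birth, origin, range) {
  st$n <- st$n + 1L
  id <- st$n
  if (id > length(st$parent)) {  # grow
    grow <- max(64L, length(st$parent))
    st$parent <- c(st$parent, integer(grow))
    st$birth <- c(st$birth, numeric(grow))
    st$death <- c(st$death, rep(NA_real_, grow))
    st$origin <- c(st$origin, character(grow))
    st$closed <- c(st$closed, logical(grow))
    st$ranges <- c(st$ranges, vector("list", grow))
  }
  st$parent[id] <- parent
  st$birth[id] <- birth
  st$death[id] <- NA_real_
  st$origin[id] <- origin
  st$closed[id] <- FALSE
  st$ranges[[id]] <- range
  id
}

log_event <- function(st, age, type, species, parent = NA_integer_) {
  st$ne <- st$ne + 1L
  if (st$ne > length(st$ev_age)) {
    grow <- max(256L, length(st$ev_age))
    st$ev_age <- c(st$ev_age, numeric(grow))
    st$ev_type <- c(st$ev_type, character(grow))
    st$ev_species <- c(st$ev_species, integer(grow))
    st$ev_parent <- c(st$ev_parent, integer(grow))
  }
  st$ev_age[st$ne] <- age
  st$ev_type[st$ne] <- type
  st$ev_species[st$ne] <- species
  st$ev_parent[st$ne] <- parent
  invisible(st)
}

#' Initialise a simulation state
#'
#' Creates one root species occupying every habitat cell of the start
#' slice (or its intersection with `config$start_region`).
#'
#' @param landscape a [paleo_landscape()].
#' @param config a [sim_config()].
#' @return an environment of class `sim_state`.
#' @export
initialize_sim <- function(landscape, config) {
  stopifnot(inherits(landscape, "paleo_landscape"),
            inherits(config, "sim_config"))
  ages <- landscape$ages
  start <- if (is.null(config$start_age)) ages[1] else config$start_age
  end <- if (is.null(config$end_age)) ages[length(ages)] else config$end_age
  ii <- match(c(start, end), ages)
  if (anyNA(ii) || ii[1] >= ii[2])
    stop("landscape does not cover the configured [start_age, end_age]")
  idx <- ii[1]:ii[2]
  spec <- landscape$spec
  st <- new.env(parent = emptyenv())
  st$spec <- spec
  st$cfg <- config
  st$ages <- ages[idx]
  land0 <- landscape$slices[[idx[1]]]$land
  st$model <- if (config$distance_mode == "sea_graph")
    distance_model("sea_graph", spec, land = land0)
  else distance_model("great_circle", spec)
  ctr <- cell_centroid(spec, seq_len(spec$n_cell))
  st$clon <- ctr[, 1]; st$clat <- ctr[, 2]
  tg <- lonlat_trig(st$clon, st$clat)
  st$tsp <- tg$sp; st$tcp <- tg$cp; st$tsl <- tg$sl; st$tcl <- tg$cl
  # below the closest possible centroid spacing, dispersal cannot add cells
  maxlat <- max(abs(c(spec$lat_min, spec$lat_max)))
  st$min_spacing <- spec$res * cos(maxlat * pi / 180) * 0.999
  st$hab <- lapply(landscape$slices[idx], `[[`, "habitat")
  st$hmask <- lapply(st$hab, function(h) {
    m <- logical(spec$n_cell); m[h] <- TRUE; m
  })
  st$k <- 1L
  st$age <- st$ages[1]
  st$n <- 0L; st$ne <- 0L
  st$parent <- integer(0); st$birth <- numeric(0); st$death <- numeric(0)
  st$origin <- character(0); st$closed <- logical(0)
  st$ranges <- list(); st$alive <- integer(0)
  st$ev_age <- numeric(0); st$ev_type <- character(0)
  st$ev_species <- integer(0); st$ev_parent <- integer(0)
  st$counts <- list()
  st$snapshots <- list()
  h0 <- st$hab[[1]]
  if (!is.null(config$start_region))
    h0 <- intersect(h0, as.integer(config$start_region))
  if (length(h0) == 0) stop("empty habitat at the start age")
  root <- new_species(st, NA_integer_, st$age, "root", as.integer(h0))
  st$alive <- root
  log_event(st, st$age, "origin", root)
  class(st) <- c("sim_state", "environment")
  st
}

# Exact fast equivalent of range_clusters() for the great-circle model:
# cells joined by 8-neighbour grid adjacency are always within d_s when
# d_s exceeds the diagonal centroid spacing, so flood-fill components can
# be found in linear time and only the few components need pairwise
# threshold merging (single linkage between sets uses their minimum
# distance). Falls back to the full pairwise kernel for small d_s.
cluster_range_fast <- function(rng, d_s, st) {
  spec <- st$spec
  if (d_s < spec$res * sqrt(2) * 1.001) {
    lab <- cpp_components_trig(st$clat[rng], st$tsp[rng], st$tcp[rng],
                               st$tsl[rng], st$tcl[rng], d_s)
    return(unname(split(rng, factor(lab, levels = unique(lab)))))
  }
  glab <- cpp_grid_components(rng, spec$n_lon, spec$global)
  k <- max(glab)
  if (k == 1) return(list(rng))
  comp <- unname(split(rng, factor(glab, levels = seq_len(k))))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (find(i) == find(j)) next
    a <- comp[[i]]; b <- comp[[j]]
    if (cpp_sets_within(st$clat[a], st$tsp[a], st$tcp[a], st$tsl[a],
                        st$tcl[a],
                        st$clat[b], st$tsp[b], st$tcp[b], st$tsl[b],
                        st$tcl[b], d_s))
      parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(k), find, integer(1))
  unname(lapply(split(seq_len(k), factor(roots, levels = unique(roots))),
                function(ii) sort(unlist(comp[ii], use.names = FALSE))))
}

#' Speciation phase of one time step
#'
#' Parapatric/combined: every extant species whose range falls into two or
#' more blocks under [range_clusters()] at threshold `d_s` speciates —
#' under the default convention the parent is closed as a pseudo-extinct
#' internal node and each block founds one daughter. Sympatric/combined:
#' each occupied cell of each extant species independently spawns a
#' single-cell daughter with probability `P_s` (so a species of area `A`
#' has expected event count `P_s * A` per step); the parent keeps its full
#' range, including the originating cell. In the combined mode the
#' parapatric check runs first.
#'
#' Because ranges at the start of a step are the post-dispersal ranges of
#' the previous step, a range must have been fragmented for a full 1-Myr
#' step before it speciates.
#'
#' @param st a `sim_state` (modified in place).
#' @return the state, invisibly. Per-step event counts are accumulated on
#'   the state.
#' @export
speciation_phase <- function(st) {
  cfg <- st$cfg
  age <- st$age
  n_para <- 0L; n_para_births <- 0L; n_symp <- 0L
  if (cfg$mode %in% c("parapatric", "combined")) {
    gc_mode <- st$model$mode == "great_circle"
    als <- st$alive
    dead <- logical(length(als))
    n0 <- st$n
    labs <- if (gc_mode)
      cpp_cluster_all(st$ranges[als], st$spec$n_lon, st$spec$global,
                      cfg$d_s, st$clat, st$tsp, st$tcp, st$tsl, st$tcl,
                      st$spec$res * sqrt(2) * 1.001)
    else NULL
    for (ii in seq_along(als)) {
      sid <- als[ii]
      rng <- st$ranges[[sid]]
      if (length(rng) < 2) next
      blocks <- if (gc_mode) {
        lab <- labs[[ii]]
        if (max(lab) == 1L) next
        unname(split(rng, factor(lab, levels = seq_len(max(lab)))))
      } else {
        range_clusters(rng, cfg$d_s, st$model)
      }
      nb <- length(blocks)
      if (nb < 2) next
      n_para <- n_para + if (cfg$split_events == "per_split") 1L else nb - 1L
      if (cfg$parent_convention == "close") {
        st$death[sid] <- age
        st$closed[sid] <- TRUE
        st$ranges[[sid]] <- integer(0)
        dead[ii] <- TRUE
        log_event(st, age, "pseudo_extinction", sid)
        for (b in blocks) {
          did <- new_species(st, sid, age, "parapatric", b)
          log_event(st, age, "speciation_parapatric", did, sid)
          n_para_births <- n_para_births + 1L
        }
      } else {
        sizes <- lengths(blocks)
        keep <- which.max(sizes)
        st$ranges[[sid]] <- blocks[[keep]]
        for (b in blocks[-keep]) {
          did <- new_species(st, sid, age, "parapatric", b)
          log_event(st, age, "speciation_parapatric", did, sid)
          n_para_births <- n_para_births + 1L
        }
      }
    }
    st$alive <- c(als[!dead], seq_len(st$n - n0) + n0)
  }
  if (cfg$mode %in% c("sympatric", "combined") && cfg$P_s > 0) {
    n0 <- st$n
    for (sid in st$alive) {
      rng <- st$ranges[[sid]]
      set.seed(derive_seed(cfg$seed, 5L, sid, st$k))
      hits <- rng[runif(length(rng)) < cfg$P_s]
      for (cell in hits) {
        did <- new_species(st, sid, age, "sympatric", cell)
        log_event(st, age, "speciation_sympatric", did, sid)
        n_symp <- n_symp + 1L
      }
    }
    st$alive <- c(st$alive, seq_len(st$n - n0) + n0)
  }
  st$step_para <- n_para
  st$step_para_births <- n_para_births
  st$step_symp <- n_symp
  invisible(st)
}

#' Dispersal phase into the next time slice
#'
#' Each extant species draws its reach `r = min(x, d)`,
#' `x ~ Weibull(shape, scale_ratio * d)`, from its own random stream, then
#' occupies every habitat cell of the next slice within `r` degrees of its
#' current range (which subsumes the surviving part of the current range,
#' at distance zero). A species whose new range is empty is recorded
#' extinct at the next slice's age: extinction happens only through
#' habitat loss out of dispersal reach.
#'
#' @param st a `sim_state` (modified in place).
#' @return the state, invisibly.
#' @export
dispersal_phase <- function(st) {
  cfg <- st$cfg
  k2 <- st$k + 1L
  if (k2 > length(st$ages)) stop("no next slice to disperse into")
  next_age <- st$ages[k2]
  hab <- st$hab[[k2]]
  hmask <- st$hmask[[k2]]
  gc_mode <- st$model$mode == "great_circle"
  n_ext <- 0L
  scale <- cfg$weibull_scale_ratio * cfg$d
  als <- st$alive
  dead <- logical(length(als))
  u <- cpp_stream_uniform(cfg$seed, 4L, als, st$k)
  r <- pmin(qweibull(u, cfg$weibull_shape, scale), cfg$d)
  newranges <- if (gc_mode)
    cpp_dispersal_all(st$ranges[als], hab, r, st$clat, st$tsp, st$tcp,
                      st$tsl, st$tcl, hmask, st$min_spacing)
  else
    lapply(seq_along(als), function(ii) {
      rng <- st$ranges[[als[ii]]]
      sort(union(rng[hmask[rng]], reachable_cells(rng, hab, r[ii], st$model)))
    })
  for (ii in seq_along(als)) {
    sid <- als[ii]
    newr <- newranges[[ii]]
    if (length(newr) == 0) {
      st$death[sid] <- next_age
      st$ranges[[sid]] <- integer(0)
      dead[ii] <- TRUE
      log_event(st, next_age, "extinction", sid)
      n_ext <- n_ext + 1L
    } else {
      st$ranges[[sid]] <- newr
    }
  }
  st$alive <- als[!dead]
  st$step_ext_disp <- n_ext
  st$k <- k2
  st$age <- next_age
  invisible(st)
}

#' Forced (scripted) mass extinction
#'
#' Removes `round(fraction * n_extant)` extant species, chosen uniformly
#' without replacement from the forced-extinction random stream, and
#' records them as extinctions at the current age.
#'
#' @param st a `sim_state` (modified in place).
#' @param fraction fraction of extant species to remove, in `[0, 1]`.
#' @return the state, invisibly.
#' @export
forced_extinction <- function(st, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  k <- round(fraction * length(st$alive))
  if (k > 0) {
    set.seed(derive_seed(st$cfg$seed, 6L, st$k))
    victims <- sort(st$alive[sample.int(length(st$alive), k)])
    for (sid in victims) {
      st$death[sid] <- st$age
      st$ranges[[sid]] <- integer(0)
      log_event(st, st$age, "forced_extinction", sid)
    }
    st$alive <- setdiff(st$alive, victims)
  }
  st$step_ext_forced <- (st$step_ext_forced %||% 0L) + as.integer(k)
  invisible(st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

take_snapshot <- function(st) {
  ids <- sort(st$alive)
  cells <- sort(unique(unlist(st$ranges[ids], use.names = FALSE)))
  m <- matrix(0L, length(cells), length(ids),
              dimnames = list(cells, sprintf("s%d", ids)))
  for (j in seq_along(ids))
    m[match(st$ranges[[ids[j]]], cells), j] <- 1L
  attr(m, "habitat") <- st$hab[[st$k]]
  st$snapshots[[sprintf("%g", st$age)]] <- m
  invisible(st)
}

#' Run a full landscape-constrained diversification simulation
#'
#' Iterates from the start age down to the end age; at each age the
#' scripted forced extinctions due at that age are applied, then the
#' speciation phase runs, occupancy snapshots are recorded if requested,
#' and the dispersal phase carries every surviving species into the next
#' slice. The run is deterministic given the configuration seed. A run
#' whose extant richness exceeds `species_cap` aborts with an error of
#' class `reefdyn_overflow` (runaway regime, typically `d > d_s`); total
#' extinction ends the run early with a warning.
#'
#' @param landscape a [paleo_landscape()].
#' @param config a [sim_config()].
#' @return an object of class `sim_result`: `species` (one row per
#'   lineage: id, parent, birth/death ages, origin mode, pseudo-extinction
#'   flag), `events` (age, event_type, species, parent), `counts`
#'   (per-step richness and event tallies), `snapshots` (site-by-species
#'   matrices keyed by age), `final_ranges`, and the config echo.
#' @export
run_simulation <- function(landscape, config) {
  st <- initialize_sim(landscape, config)
  forced <- config$forced_extinctions
  forced_ages <- vapply(forced, `[[`, numeric(1), "age")
  K <- length(st$ages)
  counts <- vector("list", K)
  for (k in seq_len(K)) {
    st$step_para <- 0L; st$step_para_births <- 0L
    st$step_symp <- 0L; st$step_ext_disp <- 0L; st$step_ext_forced <- 0L
    age <- st$age
    rich_start <- length(st$alive)
    for (i in which(forced_ages == age)) forced_extinction(st, forced[[i]]$fraction)
    speciation_phase(st)
    if (age %in% config$snapshot_ages) take_snapshot(st)
    if (length(st$alive) > config$species_cap)
      stop(errorCondition(
        sprintf("extant richness %d exceeds the species cap (%d) at %g Ma",
                length(st$alive), config$species_cap, age),
        class = c("reefdyn_overflow", "error", "condition")))
    if (k < K && length(st$alive) > 0) dispersal_phase(st)
    counts[[k]] <- c(age = age, richness_start = rich_start,
                     speciation_parapatric = st$step_para,
                     births_parapatric = st$step_para_births,
                     speciation_sympatric = st$step_symp,
                     extinction_dispersal = st$step_ext_disp,
                     extinction_forced = st$step_ext_forced,
                     richness_end = length(st$alive))
    if (length(st$alive) == 0) {
      warning(sprintf("full extinction at %g Ma", st$age))
      counts <- counts[seq_len(k)]
      break
    }
  }
  n <- st$n
  species <- data.frame(id = seq_len(n),
                        parent = st$parent[seq_len(n)],
                        birth = st$birth[seq_len(n)],
                        death = st$death[seq_len(n)],
                        origin = st$origin[seq_len(n)],
                        closed = st$closed[seq_len(n)],
                        origin_tag = NA_character_)
  events <- data.frame(age = st$ev_age[seq_len(st$ne)],
                       event_type = st$ev_type[seq_len(st$ne)],
                       species = st$ev_species[seq_len(st$ne)],
                       parent = st$ev_parent[seq_len(st$ne)])
  res <- list(species = species, events = events,
              counts = as.data.frame(do.call(rbind, counts)),
              snapshots = st$snapshots,
              final_ranges = st$ranges[st$alive],
              final_alive = st$alive,
              end_age = st$age,
              spec = st$spec,
              config = config)
  names(res$final_ranges) <- sprintf("s%d", st$alive)
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: mode %s, %d lineages total, %d extant at %g Ma, %d snapshots\n",
              x$config$mode, nrow(x$species), length(x$final_alive),
              x$end_age, length(x$snapshots)))
  invisible(x)
}

#' Per-step diversification rate series
#'
#' Rates are events per extant lineage per Myr, dividing each step's event
#' tallies by the richness at the start of the step (one parapatric split
#' counts as the number of events set by `config$split_events`; forced
#' extinctions count as extinction events; pseudo-extinctions at splits do
#' not). The net diversification rate is speciation minus extinction.
#' Steps with zero extant lineages yield `NA` rates.
#'
#' @param result a `sim_result`.
#' @return data.frame with columns `age`, `richness`, `speciation_rate`,
#'   `extinction_rate`, `net_rate`.
#' @export
diversification_series <- function(result) {
  ct <- result$counts
  rich <- ct$richness_start
  spec_ev <- ct$speciation_parapatric + ct$speciation_sympatric
  ext_ev <- ct$extinction_dispersal + ct$extinction_forced
  s <- ifelse(rich > 0, spec_ev / rich, NA_real_)
  e <- ifelse(rich > 0, ext_ev / rich, NA_real_)
  data.frame(age = ct$age, richness = rich,
             speciation_rate = s, extinction_rate = e, net_rate = s - e)
}

#' Richness map at a snapshot age
#'
#' @param result a `sim_result` with a snapshot at `age`.
#' @param age a snapshot age (Ma).
#' @return named numeric vector of species counts over every habitat cell
#'   of that slice (names are cell ids; unoccupied habitat counts 0).
#' @export
richness_at <- function(result, age) {
  m <- result$snapshots[[sprintf("%g", age)]]
  if (is.null(m)) stop(sprintf("no snapshot at %g Ma", age))
  hab <- attr(m, "habitat")
  v <- setNames(numeric(length(hab)), hab)
  v[rownames(m)] <- rowSums(m)
  v
}

#' Richness-weighted centroid of a snapshot
#'
#' The mean cell-centroid position weighted by per-cell richness; a simple
#' summary of where the diversity hotspot sits. Computed arithmetically,
#' so it is intended for windowed grids that do not span the antimeridian.
#'
#' @param result a `sim_result`.
#' @param age a snapshot age (Ma).
#' @return named numeric vector `c(lon, lat)`.
#' @export
diversity_centroid <- function(result, age) {
  r <- richness_at(result, age)
  ctr <- cell_centroid(result$spec, as.integer(names(r)))
  c(lon = sum(ctr[, 1] * r) / sum(r), lat = sum(ctr[, 2] * r) / sum(r))
}

#' Tag lineage origins by region and propagate to descendants
#'
#' Every species extant at `tag_age` is labelled with the region holding
#' the majority of its range cells (ties broken by the lexicographically
#' first region name, with a message); species outside all regions are
#' labelled `"untagged"`. Descendants born after the tag age inherit their
#' ancestor's tag, so later snapshots can be decomposed into faunas of
#' different geographic origin.
#'
#' @param result a `sim_result` with a snapshot at `tag_age`.
#' @param regions named list of disjoint integer cell-id sets.
#' @param tag_age the tagging age (Ma; must be a snapshot age).
#' @return the `sim_result` with `species$origin_tag` filled in.
#' @export
tag_origins <- function(result, regions, tag_age) {
  stopifnot(length(names(regions)) == length(regions))
  all_cells <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_cells)) stop("regions must be disjoint")
  m <- result$snapshots[[sprintf("%g", tag_age)]]
  if (is.null(m)) stop(sprintf("tag_age %g Ma is not a snapshot age", tag_age))
  cells <- as.integer(rownames(m))
  ids <- as.integer(sub("^s", "", colnames(m)))
  tags <- rep(NA_character_, nrow(result$species))
  rnames <- sort(names(regions))
  for (j in seq_along(ids)) {
    occ <- cells[m[, j] == 1]
    votes <- vapply(rnames, function(rn) length(intersect(occ, regions[[rn]])),
                    integer(1))
    if (all(votes == 0)) {
      tags[ids[j]] <- "untagged"
    } else {
      best <- which(votes == max(votes))
      if (length(best) > 1)
        message(sprintf("species s%d ties between regions; tagged '%s'",
                        ids[j], rnames[best[1]]))
      tags[ids[j]] <- rnames[best[1]]
    }
  }
  sp <- result$species
  for (i in seq_len(nrow(sp))) {
    if (!is.na(tags[i])) next
    if (sp$birth[i] < tag_age && !is.na(sp$parent[i]))
      tags[i] <- tags[sp$parent[i]]
  }
  result$species$origin_tag <- tags
  result
}

#' Per-tag richness maps at a snapshot age
#'
#' @param result a tagged `sim_result` (see [tag_origins()]).
#' @param age a snapshot age (Ma).
#' @return named list (one element per tag) of named per-cell richness
#'   vectors.
#' @export
tag_richness_map <- function(result, age) {
  if (all(is.na(result$species$origin_tag)))
    stop("result has no origin tags; run tag_origins() first")
  m <- result$snapshots[[sprintf("%g", age)]]
  if (is.null(m)) stop(sprintf("no snapshot at %g Ma", age))
  ids <- as.integer(sub("^s", "", colnames(m)))
  tg <- result$species$origin_tag[ids]
  out <- list()
  for (t in sort(unique(tg[!is.na(tg)]))) {
    sub <- m[, tg == t & !is.na(tg), drop = FALSE]
    out[[t]] <- rowSums(sub)
  }
  out
}
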