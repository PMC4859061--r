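spec12 <- grid_spec(1, 0, 24, -3, 3)

# state with one root species on an explicit habitat set
make_state <- function(cells, mode = "parapatric", spec = spec12, ...) {
  L <- tiny_landscape(spec, cells)
  cfg <- sim_config(mode, d = 4, d_s = 5, seed = 1, ...)
  initialize_sim(L, cfg)
}

test_that("initialisation seeds one species on all (or a sub-region of) habitat", {
  st <- make_state(1:12)
  expect_equal(length(st$alive), 1)
  expect_equal(st$ranges[[1]], 1:12)
  L <- tiny_landscape(spec12, 1:12)
  cfg <- sim_config("parapatric", d = 4, d_s = 5, start_region = 4:6)
  st2 <- initialize_sim(L, cfg)
  expect_equal(st2$ranges[[1]], 4:6)
  cfg3 <- sim_config("parapatric", d = 4, d_s = 5, start_region = 100:101)
  expect_error(initialize_sim(L, cfg3), "empty")
})

test_that("a fragmented range speciates parapatrically, the parent closing as a pseudo-extinct node", {
  far <- c(cell_at(spec12, c(0.5, 1.5), 0.5), cell_at(spec12, c(18.5, 19.5), 0.5))
  st <- make_state(far)
  speciation_phase(st)
  expect_equal(st$step_para, 1L)
  expect_equal(sort(st$alive), c(2L, 3L))
  expect_true(st$closed[1])
  expect_equal(st$death[1], st$age)
  expect_equal(canon_partition(st$ranges[2:3]),
               canon_partition(list(far[1:2], far[3:4])))
  # a connected range never speciates parapatrically
  st2 <- make_state(1:12)
  speciation_phase(st2)
  expect_equal(st2$step_para, 0L)
  expect_equal(st2$alive, 1L)
})

test_that("the largest-fragment-keeps-parent convention is available", {
  far <- c(cell_at(spec12, c(0.5, 1.5, 2.5), 0.5), cell_at(spec12, 19.5, 0.5))
  L <- tiny_landscape(spec12, far)
  cfg <- sim_config("parapatric", d = 4, d_s = 5,
                    parent_convention = "largest_keeps")
  st <- initialize_sim(L, cfg)
  speciation_phase(st)
  expect_equal(sort(st$alive), c(1L, 2L))
  expect_false(st$closed[1])
  expect_equal(st$ranges[[1]], sort(far[1:3]))
})

test_that("sympatric daughters are single-cell and certain when P_s = 1", {
  st <- suppressWarnings(make_state(1:3, mode = "sympatric", P_s = 1))
  speciation_phase(st)
  expect_equal(st$step_symp, 3L)
  expect_equal(length(st$alive), 4)
  expect_true(all(lengths(st$ranges[2:4]) == 1))
  expect_equal(sort(unlist(st$ranges[2:4])), 1:3)  # one per occupied cell
  expect_equal(st$ranges[[1]], 1:3)  # parent keeps its range
})

test_that("dispersal never shrinks a range when habitat persists", {
  L <- scenario_static(start_age = 20, end_age = 1)
  cfg <- sim_config("parapatric", d = 3, d_s = 10, seed = 5,
                    start_region = habitat_cells(L, 20)[1:5])
  st <- initialize_sim(L, cfg)
  for (k in 1:15) {
    before <- st$ranges[[1]]
    speciation_phase(st)
    dispersal_phase(st)
    expect_true(all(before %in% st$ranges[[1]]))
  }
})

test_that("habitat loss beyond dispersal reach kills; nearby habitat rescues", {
  spec <- grid_spec(1, 0, 60, -2, 2)
  mk <- function(d) {
    slices <- list(habitat_slice(10, cell_at(spec, c(0.5, 1.5), 0.5), spec),
                   habitat_slice(9, cell_at(spec, c(45.5, 46.5), 0.5), spec))
    L <- paleo_landscape(spec, slices)
    cfg <- sim_config("parapatric", d = d, d_s = 5, seed = 3)
    st <- initialize_sim(L, cfg)
    dispersal_phase(st)
    st
  }
  st <- mk(4)  # nearest new habitat ~44 degrees away, reach capped at 4
  expect_length(st$alive, 0)
  expect_equal(st$ev_type[st$ne], "extinction")
  # habitat 2 degrees away, generous cap: the draw exceeds 2 and the species hops
  spec2 <- grid_spec(1, 0, 12, -2, 2)
  slices <- list(habitat_slice(10, cell_at(spec2, 0.5, 0.5), spec2),
                 habitat_slice(9, cell_at(spec2, 2.5, 0.5), spec2))
  L2 <- paleo_landscape(spec2, slices)
  cfg2 <- sim_config("parapatric", d = 40, d_s = 5, seed = 3)
  st2 <- initialize_sim(L2, cfg2)
  dispersal_phase(st2)
  expect_equal(st2$alive, 1L)
  expect_equal(st2$ranges[[1]], cell_at(spec2, 2.5, 0.5))
})

test_that("forced extinction removes round(fraction * extant) species", {
  st <- make_state(1:12)
  for (i in 2:10) reefdyn:::new_species(st, 1L, st$age, "sympatric", i)
  st$alive <- 1:10
  forced_extinction(st, 0.8)
  expect_length(st$alive, 2)
  expect_equal(sum(st$ev_type[seq_len(st$ne)] == "forced_extinction"), 8)
  st2 <- make_state(1:12)
  forced_extinction(st2, 0)
  expect_equal(st2$alive, 1L)
  st3 <- make_state(1:12)
  forced_extinction(st3, 1)
  expect_length(st3$alive, 0)
})

test_that("a static connected landscape stays monospecific for the whole run", {
  L <- scenario_static()
  cfg <- sim_config("parapatric", d = 4, d_s = 5, seed = 2)
  res <- run_simulation(L, cfg)
  expect_equal(nrow(res$species), 1)
  expect_true(all(res$counts$richness_end == 1))
  expect_true(all(res$counts$speciation_parapatric == 0))
})

test_that("identical configuration and seed reproduce the run exactly", {
  L <- scenario_fragmentation(start_age = 40)
  cfg <- sim_config("combined", d = 4, d_s = 5, P_s = 5e-5, seed = 11,
                    snapshot_ages = c(20, 1),
                    forced_extinctions = list(list(age = 25, fraction = 0.5)))
  r1 <- run_simulation(L, cfg)
  r2 <- run_simulation(L, cfg)
  expect_identical(r1$species, r2$species)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(genealogy_newick(r1), genealogy_newick(r2))
})

test_that("occupancy stays inside habitat and richness bookkeeping balances exactly", {
  L <- scenario_fragmentation_cycles()
  cfg <- sim_config("combined", d = 4, d_s = 5, P_s = 6e-5, seed = 7,
                    snapshot_ages = c(70, 35, 1),
                    forced_extinctions = list(list(age = 66, fraction = 0.8)))
  res <- run_simulation(L, cfg)
  for (a in c(70, 35, 1)) {
    m <- res$snapshots[[as.character(a)]]
    expect_true(all(as.integer(rownames(m)) %in% habitat_cells(L, a)))
  }
  ct <- res$counts
  expect_equal(ct$richness_end,
               ct$richness_start - ct$extinction_forced +
                 ct$births_parapatric - ct$speciation_parapatric +
                 ct$speciation_sympatric - ct$extinction_dispersal)
  # the 80% pulse is visible at 66 Ma
  i66 <- which(ct$age == 66)
  expect_equal(ct$extinction_forced[i66],
               round(0.8 * ct$richness_start[i66]))
})

test_that("the batched range clustering equals the public single-range clustering", {
  L <- scenario_fragmentation_cycles()
  cfg <- sim_config("parapatric", d = 4, d_s = 5, seed = 1)
  st <- initialize_sim(L, cfg)
  model <- distance_model("great_circle", L$spec)
  set.seed(13)
  for (i in 1:30) {
    rng <- sort(sample(habitat_cells(L, sample(landscape_ages(L), 1)),
                       sample(5:120, 1)))
    d_s <- runif(1, 1, 12)
    labs <- reefdyn:::cpp_cluster_all(list(rng), L$spec$n_lon, L$spec$global,
                                      d_s, st$clat, st$tsp, st$tcp, st$tsl,
                                      st$tcl, L$spec$res * sqrt(2) * 1.001)[[1]]
    got <- unname(split(rng, factor(labs, levels = seq_len(max(labs)))))
    expect_equal(canon_partition(got),
                 canon_partition(range_clusters(rng, d_s, model)))
  }
})

test_that("raising the dispersal cap never shrinks any range (species streams are isolated)", {
  L <- scenario_corridor_closure(start_age = 60)
  snaps <- c(40, 20, 1)
  ranges <- lapply(c(2, 4, 8), function(d) {
    cfg <- sim_config("parapatric", d = d, d_s = 39, seed = 9,
                      snapshot_ages = snaps)
    res <- run_simulation(L, cfg)
    lapply(as.character(snaps), function(a) res$snapshots[[a]])
  })
  for (i in 1:2) for (s in 1:3) {
    lo <- as.integer(rownames(ranges[[i]][[s]]))
    hi <- as.integer(rownames(ranges[[i + 1]][[s]]))
    expect_true(all(lo %in% hi))
  }
})

test_that("sympatric event counts follow the binomial law", {
  spec <- grid_spec(1, 0, 50, -20, 20)
  L <- tiny_landscape(spec, seq_len(2000))
  cfg <- suppressWarnings(sim_config("sympatric", d = 4, P_s = 5e-4, seed = 1))
  st <- initialize_sim(L, cfg)
  n_rep <- 10000
  counts <- integer(n_rep)
  for (rep in seq_len(n_rep)) {
    st$cfg$seed <- rep          # fresh replicate stream
    st$n <- 1L; st$alive <- 1L  # rewind to the single root species
    speciation_phase(st)
    counts[rep] <- st$step_symp
  }
  # chi-squared goodness of fit against Binomial(2000, 5e-4)
  br <- c(0, 1, 2, Inf)
  obs <- table(cut(counts, breaks = c(-1, 0, 1, 2, Inf)))
  p <- c(dbinom(0:2, 2000, 5e-4), 1 - pbinom(2, 2000, 5e-4))
  gof <- chisq.test(as.numeric(obs), p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("diversification rates are events per lineage with NA when the clade is gone", {
  counts <- data.frame(age = c(10, 9, 8),
                       richness_start = c(10, 10, 0),
                       speciation_parapatric = c(1, 0, 0),
                       births_parapatric = c(2, 0, 0),
                       speciation_sympatric = c(0, 0, 0),
                       extinction_dispersal = c(0, 0, 0),
                       extinction_forced = c(0, 8, 0),
                       richness_end = c(11, 2, 0))
  fake <- structure(list(counts = counts), class = "sim_result")
  ds <- diversification_series(fake)
  expect_equal(ds$speciation_rate, c(0.1, 0, NA))
  expect_equal(ds$extinction_rate, c(0, 0.8, NA))
  expect_equal(ds$net_rate, c(0.1, -0.8, NA))
})

test_that("origin tags follow the range majority and are inherited", {
  L <- scenario_collision(merge_age = 15, start_age = 40)
  regions <- list(west = which(cell_centroid(L$spec, seq_len(L$spec$n_cell))[, 1] < 20),
                  east = which(cell_centroid(L$spec, seq_len(L$spec$n_cell))[, 1] >= 20))
  cfg <- sim_config("parapatric", d = 4, d_s = 5, seed = 2,
                    snapshot_ages = c(20, 1))
  res <- run_simulation(L, cfg)
  res <- tag_origins(res, regions, 20)
  tags <- res$species$origin_tag
  expect_true(all(!is.na(tags[res$species$birth <= 20 | !is.na(res$species$parent)])))
  maps <- tag_richness_map(res, 1)
  expect_true(all(c("west", "east") %in% names(maps)))
  # untagged appears when a species sits outside all regions
  res2 <- tag_origins(res, list(nowhere = 1L), 20)
  expect_true(all(res2$species$origin_tag[!is.na(res2$species$origin_tag)] ==
                    "untagged"))
})

test_that("genealogies are valid trees that round-trip through Newick", {
  L <- scenario_fragmentation_cycles()
  cfg <- sim_config("combined", d = 4, d_s = 5, P_s = 6e-5, seed = 3)
  res <- run_simulation(L, cfg)
  tr <- genealogy_tree(res)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.rooted(tr))
  sp <- res$species
  # closed parapatric parents are internal nodes; everyone else is a leaf
  tips <- sp$id[!sp$closed]
  expect_equal(sort(tr$tip.label), sort(sprintf("s%d", tips)))
  # children are never older than their parents
  kids <- sp[!is.na(sp$parent), ]
  expect_true(all(kids$birth <= sp$birth[kids$parent]))
  # round-trip through ape preserves topology and branch lengths
  tr2 <- ape::read.tree(text = ape::write.tree(tr))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)),
               structure(0, Size = length(tr$tip.label)), ignore_attr = TRUE)
  # extant pruning keeps exactly the extant species as leaves
  ext <- genealogy_tree(res, extant_only = TRUE)
  expect_equal(sort(ext$tip.label),
               sort(sprintf("s%d", sp$id[is.na(sp$death)])))
})

test_that("runaway richness aborts with a classed condition", {
  L <- scenario_fragmentation_cycles()
  cfg <- sim_config("parapatric", d = 8, d_s = 3, seed = 1, species_cap = 50)
  expect_error(suppressWarnings(run_simulation(L, cfg)),
               class = "reefdyn_overflow")
})
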