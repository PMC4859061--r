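n_params <- function(mode) switch(mode, parapatric = 2L, sympatric = 2L,
                                  combined = 3L)

#' Describe a simulation parameter sweep
#'
#' A sweep runs every combination of mode and parameter values for a
#' number of replicates, fits each combination's replicate-averaged
#' richness maps to the comparison targets, and ranks combinations by
#' summed BIC. Per-run seeds derive deterministically from the base seed
#' and the combination's parameters via [derive_seed()], so results do not
#' depend on execution order and interrupted sweeps resume bit-identically.
#'
#' @param modes character vector of speciation modes.
#' @param d,d_s,P_s parameter grids (use `NA` for parameters a mode does
#'   not need; irrelevant parameters are collapsed per mode).
#' @param replicates replicates per combination (reference setting: 20).
#' @param base_seed integer base seed.
#' @param targets named list of comparison targets, each a list with
#'   `age` (snapshot age, Ma) and `observed` (named per-cell map).
#' @param config_args extra arguments passed to every [sim_config()].
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(modes = "parapatric", d, d_s = NA, P_s = NA,
                       replicates = 20, base_seed = 1, targets,
                       config_args = list()) {
  stopifnot(length(targets) >= 1, !is.null(names(targets)))
  grid <- expand.grid(mode = modes, d = d, d_s = d_s, P_s = P_s,
                      stringsAsFactors = FALSE)
  grid$d_s[!grid$mode %in% c("parapatric", "combined")] <- NA
  grid$P_s[!grid$mode %in% c("sympatric", "combined")] <- NA
  grid <- unique(grid)
  ok <- !(grid$mode %in% c("parapatric", "combined") & is.na(grid$d_s)) &
    !(grid$mode %in% c("sympatric", "combined") & is.na(grid$P_s))
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0) stop("no valid parameter combinations")
  grid$model <- sprintf("%s_d%g%s%s", grid$mode, grid$d,
                        ifelse(is.na(grid$d_s), "",
                               sprintf("_ds%g", grid$d_s)),
                        ifelse(is.na(grid$P_s), "",
                               sprintf("_Ps%g", grid$P_s)))
  rownames(grid) <- NULL
  structure(list(grid = grid, replicates = replicates,
                 base_seed = as.integer(base_seed), targets = targets,
                 config_args = config_args),
            class = "sweep_spec")
}

run_seed <- function(sw, row, rep) {
  derive_seed(sw$base_seed, mode_code(row$mode), round(row$d * 8),
              round((if (is.na(row$d_s)) 0 else row$d_s) * 8),
              round((if (is.na(row$P_s)) 0 else row$P_s) * 1e7), rep)
}

#' Execute a parameter sweep
#'
#' Runs `replicates` simulations per parameter combination, averages each
#' combination's per-cell richness maps at the target ages across
#' replicates, fits every comparison with [model_fit()], and ranks
#' combinations with [rank_models()]. When `out_dir` is given, each run's
#' maps are written as CSV and recorded in `manifest.csv`; an interrupted
#' sweep rerun with the same arguments skips completed runs and produces
#' identical numbers. Runs that abort (e.g. runaway richness above the
#' species cap) are recorded as failed and their combination is excluded
#' from the ranking with a warning.
#'
#' @param landscape a [paleo_landscape()].
#' @param sw a [sweep_spec()].
#' @param out_dir optional output directory for resumable execution.
#' @param per_replicate fit each replicate separately instead of the
#'   replicate-averaged map (default `FALSE`).
#' @return list with `fits` (one row per model x comparison), `ranking`
#'   (from [rank_models()]), `best` (top-ranked model label) and
#'   `manifest`.
#' @export
run_sweep <- function(landscape, sw, out_dir = NULL, per_replicate = FALSE) {
  stopifnot(inherits(sw, "sweep_spec"))
  ages <- vapply(sw$targets, `[[`, numeric(1), "age")
  manifest <- data.frame()
  fits <- list()
  for (i in seq_len(nrow(sw$grid))) {
    row <- sw$grid[i, ]
    maps <- vector("list", sw$replicates)
    failed <- FALSE
    for (rep in seq_len(sw$replicates)) {
      seed <- run_seed(sw, row, rep)
      run_id <- sprintf("%s_r%d", row$model, rep)
      if (!is.null(out_dir) && is.list(cc <- load_run_maps(out_dir, run_id, ages))) {
        maps[[rep]] <- cc
        manifest <- rbind(manifest, data.frame(run = run_id, seed = seed,
                                               status = "cached"))
        next
      }
      cfg <- do.call(sim_config, c(list(
        mode = row$mode, d = row$d,
        d_s = if (is.na(row$d_s)) NULL else row$d_s,
        P_s = if (is.na(row$P_s)) NULL else row$P_s,
        seed = seed, snapshot_ages = ages), sw$config_args))
      res <- tryCatch(suppressWarnings(run_simulation(landscape, cfg)),
                      reefdyn_overflow = function(e) e)
      if (inherits(res, "condition")) {
        manifest <- rbind(manifest, data.frame(run = run_id, seed = seed,
                                               status = "failed"))
        failed <- TRUE
        break
      }
      maps[[rep]] <- lapply(ages, function(a)
        tryCatch(richness_at(res, a), error = function(e) NULL))
      names(maps[[rep]]) <- names(sw$targets)
      if (!is.null(out_dir)) save_run_maps(out_dir, run_id, maps[[rep]])
      manifest <- rbind(manifest, data.frame(run = run_id, seed = seed,
                                             status = "done"))
    }
    if (failed || any(vapply(maps, function(m)
      is.null(m) || any(vapply(m, is.null, logical(1))), logical(1)))) {
      warning(sprintf("model %s excluded (failed or incomplete runs)",
                      row$model))
      next
    }
    fit_rows <- tryCatch({
      rows <- list()
      for (tn in names(sw$targets)) {
        obs <- sw$targets[[tn]]$observed
        k <- n_params(row$mode)
        if (per_replicate) {
          for (rep in seq_len(sw$replicates)) {
            f <- model_fit(maps[[rep]][[tn]], obs, k)
            rows[[length(rows) + 1]] <- data.frame(
              model = row$model, replicate = rep, comparison = tn,
              n = f$n, k = k, RSS = f$RSS, R2 = f$R2, BIC = f$BIC)
          }
        } else {
          avg <- average_maps(lapply(maps, `[[`, tn))
          f <- model_fit(avg, obs, k)
          rows[[length(rows) + 1]] <- data.frame(
            model = row$model, replicate = NA_integer_, comparison = tn,
            n = f$n, k = k, RSS = f$RSS, R2 = f$R2, BIC = f$BIC)
        }
      }
      rows
    }, error = function(e) {
      warning(sprintf("model %s excluded (%s)", row$model,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(fit_rows)) fits <- c(fits, fit_rows)
  }
  if (length(fits) == 0) stop("no successful sweep runs")
  fits <- do.call(rbind, fits)
  rk_in <- if (per_replicate)
    aggregate(cbind(BIC, k) ~ model + comparison, fits,
              function(x) mean(x))
  else fits
  ranking <- rank_models(rk_in)
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  list(fits = fits, ranking = ranking, best = ranking$model[1],
       manifest = manifest)
}

# cells are union of replicate maps; missing cells count as 0
average_maps <- function(maps) {
  cells <- sort(unique(unlist(lapply(maps, names))))
  acc <- setNames(numeric(length(cells)), cells)
  for (m in maps) acc[names(m)] <- acc[names(m)] + m
  acc / length(maps)
}

save_run_maps <- function(dir, run_id, maps) {
  dir.create(file.path(dir, "runs"), showWarnings = FALSE, recursive = TRUE)
  for (tn in names(maps)) {
    f <- file.path(dir, "runs", sprintf("%s_%s.csv", run_id, tn))
    write.csv(data.frame(cell_id = names(maps[[tn]]),
                         value = unname(maps[[tn]])), f, row.names = FALSE)
  }
}

load_run_maps <- function(dir, run_id, ages) {
  if (is.null(names(ages))) return(FALSE)
  files <- file.path(dir, "runs",
                     sprintf("%s_%s.csv", run_id, names(ages)))
  if (!all(file.exists(files))) return(FALSE)
  out <- lapply(files, function(f) {
    x <- read.csv(f)
    setNames(x$value, x$cell_id)
  })
  names(out) <- names(ages)
  out
}

#' Write simulation outputs to a directory
#'
#' Writes the Newick genealogy (`genealogy.nwk`, with `extant.nwk` when at
#' least two extant tips remain), the event log and per-step counts as
#' CSV, each occupancy snapshot as a site-by-species CSV plus a long-form
#' occupancy table, per-snapshot richness maps, and a YAML echo of the
#' configuration (including the seed).
#'
#' @param result a `sim_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(genealogy_newick(result), file.path(dir, "genealogy.nwk"))
  tr <- tryCatch(genealogy_tree(result, extant_only = TRUE),
                 error = function(e) NULL)
  if (!is.null(tr)) ape::write.tree(tr, file.path(dir, "extant.nwk"))
  write.csv(result$events, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(result$counts, file.path(dir, "counts.csv"), row.names = FALSE)
  for (a in names(result$snapshots)) {
    m <- result$snapshots[[a]]
    write.csv(as.data.frame(m),
              file.path(dir, sprintf("snapshot_%s.csv", a)))
    idx <- which(m == 1, arr.ind = TRUE)
    long <- data.frame(age_Ma = as.numeric(a),
                       species_id = colnames(m)[idx[, 2]],
                       cell_id = rownames(m)[idx[, 1]])
    write.csv(long[order(long$species_id, long$cell_id), ],
              file.path(dir, sprintf("occupancy_%s.csv", a)),
              row.names = FALSE)
    r <- richness_at(result, as.numeric(a))
    write.csv(data.frame(cell_id = names(r), richness = unname(r)),
              file.path(dir, sprintf("richness_%s.csv", a)),
              row.names = FALSE)
  }
  cfg <- result$config
  cfg_list <- unclass(cfg)
  cfg_list <- cfg_list[!vapply(cfg_list, is.null, logical(1))]
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file with [sim_config()] fields.
#' @return a `sim_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, x)
}
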