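# shared fixtures and independent oracles used across test files

# cell id of the 1-degree global cell whose centroid is (lon + 0.5, lat + 0.5)
gcell <- function(spec, lon, lat) cell_at(spec, lon + spec$res / 2,
                                          lat + spec$res / 2)

# brute-force union-find over all pairwise distances: the independent
# clustering oracle (single linkage at a closed threshold)
oracle_clusters <- function(cells, d_s, model) {
  n <- length(cells)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    d <- reefdyn:::cross_distance(cells, cells, model)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (d[i, j] <= d_s) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(cells, factor(roots, levels = unique(roots))))
}

# canonical form for comparing partitions as sets of sets
canon_partition <- function(blocks) {
  blocks <- lapply(blocks, sort)
  blocks[order(vapply(blocks, min, numeric(1)))]
}

# brute-force paired-overlap / decreasing-fill NODF over site pairs
oracle_nodf <- function(m) {
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    fi <- sum(m[i, ]); fj <- sum(m[j, ])
    vals <- c(vals, if (fi == fj) 0 else {
      if (fi < fj) { tmp <- fi; fi <- fj; fj <- tmp; poor <- i } else poor <- j
      100 * sum(m[i, ] == 1 & m[j, ] == 1) / sum(m[poor, ])
    })
  }
  mean(vals)
}

# random binary site-by-species matrix with no empty rows/columns
random_psmatrix <- function(nr, nc, p = 0.4) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      rownames(m) <- paste0("site", seq_len(nr))
      colnames(m) <- paste0("sp", seq_len(nc))
      return(m)
    }
  }
}

# small fossil table builder
make_fossils <- function(lat, lon = 0, taxon = paste0("sp", seq_along(lat)),
                         rank = "species", age_max = 100, age_min = 0) {
  data.frame(taxon = taxon, rank = rank, paleo_lat = lat, paleo_lon = lon,
             age_max = age_max, age_min = age_min)
}

# static two-slice landscape from explicit cell sets
tiny_landscape <- function(spec, cells, ages = c(10, 9)) {
  paleo_landscape(spec, lapply(ages, habitat_slice, habitat = cells,
                               spec = spec))
}

# all n! permutations of 1:n as rows (tiny n only)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
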