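check_psmatrix <- function(m, drop_empty = TRUE) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("site-by-species matrix must be binary")
  storage.mode(m) <- "integer"
  if (drop_empty && any(rowSums(m) == 0)) {
    warning("dropping sites with zero species")
    m <- m[rowSums(m) > 0, , drop = FALSE]
  }
  m
}

#' Per-site species richness
#'
#' @param m binary site-by-species matrix (rows = sites/cells, columns =
#'   species).
#' @return named vector of row sums.
#' @export
richness_map <- function(m) rowSums(check_psmatrix(m, drop_empty = FALSE))

# shared a/b/c components for pairwise beta metrics
abc_components <- function(m) {
  m <- check_psmatrix(m, drop_empty = FALSE)
  a <- tcrossprod(m)                # shared species
  fill <- rowSums(m)
  b <- outer(fill, fill, function(x, y) x) - a  # unique to row i
  cc <- outer(fill, fill, function(x, y) y) - a # unique to row j
  list(a = a, b = b, c = cc)
}

#' Pairwise Jaccard dissimilarity between sites
#'
#' For sites i, j with `a` shared species and `b`, `c` unique species,
#' the dissimilarity is `1 - a / (a + b + c)`. Pairs of empty sites are
#' undefined and returned as `NA`.
#'
#' @param m binary site-by-species matrix.
#' @return symmetric site-by-site matrix with zero diagonal.
#' @export
jaccard_dissimilarity <- function(m) {
  p <- abc_components(m)
  tot <- p$a + p$b + p$c
  d <- 1 - p$a / tot
  d[tot == 0] <- NA_real_
  diag(d) <- ifelse(rowSums(as.matrix(m)) > 0, 0, NA_real_)
  d
}

#' Pairwise species turnover (richness-independent)
#'
#' The turnover component of Jaccard dissimilarity,
#' `2 * min(b, c) / (a + 2 * min(b, c))`: perfectly nested pairs score 0,
#' so the metric isolates true species replacement from richness
#' differences. Never exceeds the Jaccard dissimilarity.
#'
#' @param m binary site-by-species matrix.
#' @return symmetric site-by-site matrix with zero diagonal; `NA` where
#'   `a = b = c = 0`.
#' @export
turnover_jtu <- function(m) {
  p <- abc_components(m)
  mn <- pmin(p$b, p$c)
  den <- p$a + 2 * mn
  d <- 2 * mn / den
  d[den == 0] <- NA_real_
  diag(d) <- ifelse(rowSums(as.matrix(m)) > 0, 0, NA_real_)
  d
}

#' Among-site nestedness (NODF)
#'
#' Paired-overlap / decreasing-fill nestedness over site (row) pairs: for
#' each pair with strictly different fills, the percentage of the poorer
#' site's species also present in the richer site; pairs with equal fills
#' contribute zero. The index is the mean over all site pairs, from 0 (no
#' nesting) to 100 (every poorer site a perfect subset of every richer
#' one). Zero-fill rows are dropped (with a warning) before computation.
#'
#' @param m binary site-by-species matrix with at least two non-empty
#'   rows.
#' @return a value in `[0, 100]`.
#' @export
nodf_sites <- function(m) {
  m <- check_psmatrix(m)
  n <- nrow(m)
  if (n < 2) stop("need at least two non-empty sites")
  fill <- rowSums(m)
  shared <- tcrossprod(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (fill[i] == fill[j]) next
    poor <- if (fill[i] > fill[j]) j else i
    tot <- tot + 100 * shared[i, j] / fill[poor]
  }
  unname(tot) / (n * (n - 1) / 2)
}

#' Sequential-swap null distribution for NODF
#'
#' Generates null matrices by sequential 2x2 checkerboard swaps that
#' preserve row and column sums exactly (the chain is burnt in for
#' `burnin` swaps and thinned by `thin` swaps between samples), computes
#' [nodf_sites()] on each, and returns the one-tailed probability of the
#' observed value, `p = (1 + #(null >= observed)) / (n_null + 1)`.
#' A matrix with no swappable checkerboard has a degenerate null; `p = 1`
#' is returned with a warning.
#'
#' @param m binary site-by-species matrix.
#' @param n_null number of null matrices (reference analyses use 9999).
#' @param seed integer seed for the swap chain.
#' @param burnin,thin chain settings; default 10 x (number of presences).
#' @return list with `observed`, `null` (numeric vector), `p`.
#' @export
swap_null <- function(m, n_null = 9999, seed = 1,
                      burnin = NULL, thin = NULL) {
  m <- check_psmatrix(m)
  s0 <- sum(m)
  if (is.null(burnin)) burnin <- 10 * s0
  if (is.null(thin)) thin <- 10 * s0
  obs <- nodf_sites(m)
  sims <- tryCatch({
    nm <- vegan::nullmodel(m, "swap")
    stats::simulate(nm, nsim = n_null, seed = seed,
                    burnin = burnin, thin = thin)
  }, error = function(e) NULL)
  if (is.null(sims)) {
    warning("no swappable checkerboard; degenerate null distribution")
    return(list(observed = obs, null = rep(obs, n_null), p = 1))
  }
  null <- apply(sims, 3, function(x) suppressWarnings(nodf_sites(x)))
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (n_null + 1))
}

#' Maximally packed site order and rank congruence
#'
#' `packed_order` ranks sites as in the maximally packed matrix: by
#' decreasing fill, ties broken by decreasing total overlap with strictly
#' richer sites, then by site label. `rank_congruence` compares the packed
#' orders of two matrices over their shared sites with a Spearman rank
#' correlation (average ranks for ties).
#'
#' @param m binary site-by-species matrix with row names.
#' @return `packed_order`: character vector of site labels, most packed
#'   (richest) first.
#' @export
packed_order <- function(m) {
  m <- check_psmatrix(m, drop_empty = FALSE)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  fill <- rowSums(m)
  shared <- tcrossprod(m)
  overlap_rich <- vapply(seq_len(nrow(m)), function(i) {
    richer <- fill > fill[i]
    if (!any(richer)) 0 else sum(shared[i, richer])
  }, numeric(1))
  rownames(m)[order(-fill, -overlap_rich, rownames(m))]
}

#' @rdname packed_order
#' @param m_a,m_b two site-by-species matrices sharing site labels.
#' @return `rank_congruence`: list with Spearman `rho` and `p`.
#' @export
rank_congruence <- function(m_a, m_b) {
  oa <- packed_order(m_a)
  ob <- packed_order(m_b)
  common <- intersect(oa, ob)
  if (length(common) < 3) stop("need at least three shared sites")
  ct <- cor.test(match(common, oa), match(common, ob),
                 method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(common))
}

#' Mantel test between two site distance matrices
#'
#' Pearson correlation of the lower triangles, with a one-tailed
#' (positive) permutation p-value obtained by permuting the site labels of
#' one matrix; the observed statistic is included in the tail count
#' (the +1 convention). Used for distance-decay comparisons of observed
#' and simulated assemblage dissimilarity.
#'
#' @param dist_a,dist_b symmetric dissimilarity/distance matrices over the
#'   same sites.
#' @param n_perm number of permutations (reference analyses use 999).
#' @param seed integer seed.
#' @return list with `r` (Mantel correlation) and `p`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = 1) {
  dist_a <- as.matrix(dist_a); dist_b <- as.matrix(dist_b)
  stopifnot(nrow(dist_a) == nrow(dist_b))
  la <- dist_a[lower.tri(dist_a)]
  lb <- dist_b[lower.tri(dist_b)]
  if (stats::sd(la) == 0 || stats::sd(lb) == 0)
    stop("zero-variance distance triangle; Mantel correlation undefined")
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(dist_a), stats::as.dist(dist_b),
                      permutations = n_perm)
  list(r = unname(mt$statistic), p = mt$signif)
}

#' Fit a simulated map to an observed map
#'
#' Both maps are min-max rescaled to `[0, 1]` over their shared cells
#' (cells with data in both maps), making the fit invariant to affine
#' rescaling of either input. The residual sum of squares is the direct
#' squared difference of the scaled maps, the coefficient of
#' determination comes from an ordinary least-squares regression of
#' observed on predicted, and
#' `BIC = n * ln(RSS / n) + k * ln(n)` with the RSS floored at 1e-12.
#'
#' @param predicted,observed named numeric vectors (names are cell ids) or
#'   unnamed vectors of equal length.
#' @param k number of free model parameters (2 for the single-mode
#'   models, 3 for the combined model).
#' @return an object of class `model_fit`: list with `n`, `k`, `RSS`,
#'   `R2`, `BIC`.
#' @export
model_fit <- function(predicted, observed, k) {
  if (!is.null(names(predicted)) && !is.null(names(observed))) {
    common <- intersect(names(predicted), names(observed))
    predicted <- predicted[common]
    observed <- observed[common]
  }
  keep <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[keep]; observed <- observed[keep]
  n <- length(predicted)
  if (n < k + 2) stop("maps share too few cells with data")
  rescale01 <- function(x) {
    r <- range(x)
    if (r[2] == r[1]) stop("constant map; fit undefined")
    (x - r[1]) / (r[2] - r[1])
  }
  p <- rescale01(predicted)
  o <- rescale01(observed)
  rss <- max(sum((o - p)^2), 1e-12)
  r2 <- summary(lm(o ~ p))$r.squared
  structure(list(n = n, k = k, RSS = rss, R2 = r2,
                 BIC = n * log(rss / n) + k * log(n)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: n=%d k=%d RSS=%.4g R2=%.3f BIC=%.2f\n",
              x$n, x$k, x$RSS, x$R2, x$BIC))
  invisible(x)
}

#' Rank simulations by summed BIC across comparisons
#'
#' @param fits data.frame with columns `model` (simulation label),
#'   `comparison`, `BIC` and `k`; every model must have a fit for every
#'   comparison.
#' @return data.frame of models sorted by ascending total BIC, ties broken
#'   by fewer parameters then by label.
#' @export
rank_models <- function(fits) {
  stopifnot(all(c("model", "comparison", "BIC", "k") %in% names(fits)))
  tab <- table(fits$model, fits$comparison)
  if (any(tab != 1))
    stop("every model needs exactly one fit per comparison")
  tot <- aggregate(BIC ~ model, fits, sum)
  kk <- aggregate(k ~ model, fits, function(x) x[1])
  out <- merge(tot, kk, by = "model")
  names(out)[names(out) == "BIC"] <- "total_BIC"
  out <- out[order(out$total_BIC, out$k, out$model), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
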