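test_that("richness is the per-site row sum", {
  expect_equal(unname(richness_map(diag(3))), c(1, 1, 1))
  expect_equal(unname(richness_map(matrix(1, 2, 4))), c(4, 4))
  set.seed(41)
  m <- random_psmatrix(20, 30)
  expect_equal(richness_map(m), apply(m, 1, function(r) sum(r == 1)))
})

test_that("Jaccard dissimilarity matches its definition and vegan", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(0, 1, 1, 0), c = c(1, 1, 0, 0),
             d = c(0, 0, 0, 1))
  J <- jaccard_dissimilarity(m)
  expect_equal(J["a", "c"], 0)          # identical sites
  expect_equal(J["a", "d"], 1)          # disjoint sites
  expect_equal(J["a", "b"], 2 / 3)      # {A,B} vs {B,C}
  expect_true(isSymmetric(J))
  set.seed(42)
  r <- random_psmatrix(12, 18)
  expect_equal(as.dist(jaccard_dissimilarity(r)),
               vegan::vegdist(r, "jaccard", binary = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("turnover isolates replacement and never exceeds Jaccard", {
  m <- rbind(rich = c(1, 1, 1, 0), nested = c(1, 1, 0, 0),
             other = c(1, 0, 0, 1))
  B <- turnover_jtu(m)
  expect_equal(B["rich", "nested"], 0)  # nested pair: no turnover
  expect_equal(B["rich", "other"], 2 / 3)  # a=1, min(b,c)=1
  set.seed(43)
  for (i in 1:10) {
    r <- random_psmatrix(10, 15)
    expect_true(all(turnover_jtu(r) <= jaccard_dissimilarity(r) + 1e-12))
  }
})

test_that("NODF scores nesting from perfect to none and matches the brute force", {
  expect_equal(nodf_sites(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))), 100)
  expect_equal(nodf_sites(rbind(c(1, 1, 0), c(0, 1, 1))), 0)
  expect_equal(nodf_sites(rbind(c(1, 1, 1), c(1, 0, 1), c(0, 1, 0))),
               mean(c(100, 100, 0)))
  expect_warning(v <- nodf_sites(rbind(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0))),
                 "zero species")
  expect_equal(v, 100)
  set.seed(44)
  for (i in 1:20) {
    m <- random_psmatrix(6, 8)
    expect_equal(nodf_sites(m), oracle_nodf(m))
    # independent cross-check against the community-ecology reference
    expect_equal(nodf_sites(m),
                 unname(vegan::nestednodf(m, order = TRUE)$statistic["N.rows"]))
  }
})

test_that("sequential swap preserves margins and flags maximal nestedness", {
  set.seed(45)
  m <- random_psmatrix(8, 10)
  out <- swap_null(m, n_null = 199, seed = 1)
  expect_length(out$null, 199)
  expect_true(out$p >= 1 / 200 && out$p <= 1)
  # a perfectly nested matrix has no checkerboard: its swap class is itself
  nested <- outer(1:6, 1:6, function(i, j) as.integer(j <= 8 - i))
  expect_warning(outn <- swap_null(nested, n_null = 199, seed = 2),
                 "checkerboard")
  expect_equal(outn$p, 1)
  expect_true(all(outn$null == outn$observed))
})

test_that("swap-null tail probabilities agree with exhaustive enumeration on a toy", {
  m <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 1))
  rs <- rowSums(m); cs <- colSums(m)
  # enumerate every 4x4 binary matrix with the same margins
  pool <- list()
  for (bits in 0:65535) {
    cand <- matrix(as.integer(intToBits(bits))[1:16], 4, 4)
    if (all(rowSums(cand) == rs) && all(colSums(cand) == cs))
      pool[[length(pool) + 1]] <- cand
  }
  null_ex <- vapply(pool, nodf_sites, numeric(1))
  obs <- nodf_sites(m)
  p_ex <- mean(null_ex >= obs)
  out <- swap_null(m, n_null = 999, seed = 3)
  se <- sqrt(p_ex * (1 - p_ex) / 999)
  expect_lt(abs(out$p - p_ex), 3 * se + 2 / 1000)
  # every draw preserved the margins (checked via the sampled distribution of
  # NODF values, all of which must come from the enumerated class)
  expect_true(all(out$null %in% null_ex))
})

test_that("packed order ranks by fill with documented tie-breaking", {
  nested <- rbind(s1 = c(1, 1, 1), s2 = c(1, 1, 0), s3 = c(1, 0, 0))
  expect_equal(packed_order(nested), c("s1", "s2", "s3"))
  rc <- rank_congruence(nested, nested)
  expect_equal(rc$rho, 1)
  # ties: equal fill broken by overlap with richer sites, then label
  m <- rbind(rich = c(1, 1, 1, 0), tied_in = c(1, 1, 0, 0),
             tied_out = c(1, 0, 0, 1))
  expect_equal(packed_order(m), c("rich", "tied_in", "tied_out"))
})

test_that("rank congruence equals the direct Spearman formula", {
  set.seed(46)
  ma <- random_psmatrix(20, 12)
  mb <- random_psmatrix(20, 12)
  rc <- rank_congruence(ma, mb)
  oa <- packed_order(ma); ob <- packed_order(mb)
  expect_equal(rc$rho,
               unname(cor(match(rownames(ma), oa), match(rownames(ma), ob),
                          method = "spearman")))
})

test_that("the Mantel statistic hits the +-1 bounds and matches exhaustive permutation", {
  set.seed(47)
  x <- matrix(runif(36), 6, 6); x <- (x + t(x)) / 2; diag(x) <- 0
  expect_equal(mantel_test(x, x, n_perm = 99)$r, 1)
  expect_equal(mantel_test(x, max(x) - x + diag(diag(x)) * 0, n_perm = 99)$r |>
                 round(10) * -1, 1)
  y <- matrix(runif(36), 6, 6); y <- (y + t(y)) / 2; diag(y) <- 0
  got <- mantel_test(x, y, n_perm = 999, seed = 5)
  # exhaustive permutation oracle over all 720 label orders
  allp <- all_permutations(6)
  stat <- function(perm) {
    yy <- y[perm, perm]
    cor(x[lower.tri(x)], yy[lower.tri(yy)])
  }
  stats <- apply(allp, 1, stat)
  p_ex <- mean(stats >= got$r - 1e-12)
  se <- sqrt(p_ex * (1 - p_ex) / 999)
  expect_lt(abs(got$p - p_ex), 3 * se + 2 / 1000)
  expect_error(mantel_test(matrix(0, 4, 4), x[1:4, 1:4]), "zero-variance")
})

test_that("Mantel p-values are conservative under the null", {
  set.seed(48)
  hits <- 0; trials <- 200
  ps <- numeric(trials)
  for (i in seq_len(trials)) {
    a <- as.matrix(dist(runif(7)))
    b <- as.matrix(dist(runif(7)))
    ps[i] <- mantel_test(a, b, n_perm = 199, seed = i)$p
  }
  for (alpha in c(0.05, 0.2)) {
    se <- sqrt(alpha * (1 - alpha) / trials)
    expect_lte(mean(ps <= alpha), alpha + 3 * se)
  }
})

test_that("model fits floor the RSS, recover R2 from OLS and are affine-invariant", {
  obs <- c(a = 0, b = 0.5, c = 1, d = 0.2, e = 0.9)
  f <- suppressWarnings(model_fit(obs, obs, k = 2))  # lm's perfect-fit note
  expect_equal(f$R2, 1)
  expect_equal(f$RSS, 1e-12)
  expect_equal(f$BIC, 5 * log(1e-12 / 5) + 2 * log(5))
  pred <- c(a = 0, b = 0.4, c = 0.9, d = 0.25, e = 0.7)
  f2 <- model_fit(pred, obs, k = 2)
  p <- (pred - min(pred)) / diff(range(pred))
  o <- (obs - min(obs)) / diff(range(obs))
  expect_equal(f2$RSS, sum((o - p)^2))
  expect_equal(f2$R2, summary(lm(o ~ p))$r.squared)
  expect_equal(f2$BIC, 5 * log(f2$RSS / 5) + 2 * log(5))
  # affine rescaling of either input changes nothing
  f3 <- model_fit(3 + 10 * pred, -2 + 5 * obs, k = 2)
  expect_equal(f3[c("RSS", "R2", "BIC")], f2[c("RSS", "R2", "BIC")],
               ignore_attr = TRUE)
  expect_error(model_fit(rep(1, 5), obs, k = 2), "constant")
  # uncorrelated maps give near-zero R2
  set.seed(49)
  r2 <- replicate(40, model_fit(runif(100), runif(100), k = 2)$R2)
  expect_lt(quantile(r2, 0.95), 0.1)
})

test_that("model ranking sums BIC with parameter-count tie-breaking", {
  fits <- data.frame(model = rep(c("m1", "m2"), each = 2),
                     comparison = rep(c("c1", "c2"), 2),
                     BIC = c(-10, -20, -5, -8), k = c(2, 2, 3, 3))
  rk <- rank_models(fits)
  expect_equal(rk$model, c("m1", "m2"))
  expect_equal(rk$total_BIC, c(-30, -13))
  # ties broken by fewer parameters
  tie <- data.frame(model = c("big", "small"), comparison = "c1",
                    BIC = c(-10, -10), k = c(3, 2))
  expect_equal(rank_models(tie)$model, c("small", "big"))
  expect_error(rank_models(fits[-1, ]), "every model")
  # random tables equal brute-force sum-and-sort
  set.seed(50)
  rnd <- expand.grid(model = paste0("m", 1:6), comparison = paste0("c", 1:3),
                     stringsAsFactors = FALSE)
  rnd$BIC <- rnorm(18); rnd$k <- 2
  rk2 <- rank_models(rnd)
  sums <- tapply(rnd$BIC, rnd$model, sum)
  expect_equal(rk2$model, names(sort(sums)))
})
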