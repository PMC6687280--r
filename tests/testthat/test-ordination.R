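test_that("hellinger transform matches hand values and guards its input", {
  expect_equal(as.numeric(hellinger(matrix(7, 1, 1))), 1)
  h <- hellinger(matrix(c(1, 3), 1, 2))
  expect_equal(as.numeric(h), c(0.5, sqrt(3) / 2), tolerance = 1e-12)
  m <- matrix(rpois(30, 4) + 1, 5, 6)
  hm <- hellinger(m)
  expect_equal(rowSums(hm^2), rep(1, 5), tolerance = 1e-12)
  expect_error(hellinger(hm), "already")
  expect_error(hellinger(matrix(-1, 1, 1)), "negative")
  mz <- matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE,
               dimnames = list(c("sA", "sB"), NULL))
  expect_error(hellinger(mz), "sA")
})

test_that("hellinger agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(5)
  m <- matrix(rpois(60, 6), 6, 10) + 1
  expect_equal(unname(hellinger(m)),
               unname(as.matrix(vegan::decostand(m, "hellinger"))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rda recovers degenerate R2 values", {
  set.seed(11)
  y <- matrix(rnorm(40), 10, 4)
  expect_equal(rda_fit(y, y[, 1:3])$r2 >= 0, TRUE)
  # X = Y (full rank): perfect self-prediction
  expect_equal(rda_fit(y, y)$r2, 1, tolerance = 1e-10)
  # X orthogonal to (centered) Y: zero
  x <- qr.resid(qr(cbind(1, y)), rnorm(10))
  expect_equal(rda_fit(y, x)$r2, 0, tolerance = 1e-10)
})

test_that("rda R2 equals the variance-weighted per-column regression oracle", {
  set.seed(13)
  for (rep in 1:5) {
    y <- matrix(rnorm(13 * 10), 13, 10)
    x <- data.frame(a = rnorm(13), b = rnorm(13), c = rnorm(13))
    fit <- rda_fit(y, x)
    # oracle: column-wise OLS R2 weighted by column variance
    yc <- scale(y, scale = FALSE)
    r2_cols <- apply(yc, 2, function(col) summary(lm(col ~ a + b + c,
                                                     data = x))$r.squared)
    w <- apply(yc, 2, function(col) sum(col^2))
    expect_equal(fit$r2, sum(r2_cols * w) / sum(w), tolerance = 1e-8)
  }
})

test_that("rda matches vegan and is invariant to predictor reparameterization", {
  skip_if_not_installed("vegan")
  set.seed(19)
  y <- hellinger(matrix(rpois(13 * 8, 5) + 1, 13, 8))
  x <- data.frame(a = rnorm(13), b = rnorm(13))
  fit <- rda_fit(y, x)
  v <- vegan::rda(y ~ a + b, data = x)
  expect_equal(fit$r2, vegan::RsquareAdj(v)$r.squared, tolerance = 1e-10)
  expect_equal(fit$r2_adj, vegan::RsquareAdj(v)$adj.r.squared,
               tolerance = 1e-10)
  # invertible linear reparameterization of X leaves R2 unchanged
  x2 <- data.frame(a = 3 * x$a - x$b, b = 0.5 * x$b + x$a)
  expect_equal(rda_fit(y, x2)$r2, fit$r2, tolerance = 1e-8)
  # collinear column dropped with a warning
  x3 <- cbind(as.matrix(x), dup = x$a)
  expect_warning(f3 <- rda_fit(y, x3), "collinear")
  expect_equal(f3$r2, fit$r2, tolerance = 1e-10)
})

test_that("adjusted R2 follows the Ezekiel formula", {
  expect_equal(adjusted_r2(1, 13, 3), 1)
  expect_equal(adjusted_r2(0, 13, 1), -1 / 11)
  expect_equal(adjusted_r2(0.5, 20, 0), 0.5)
  expect_error(adjusted_r2(0.5, 4, 3), "n > m")
})

test_that("partial rda honours its fraction identities", {
  set.seed(23)
  y <- hellinger(matrix(rpois(13 * 9, 5) + 1, 13, 9))
  x <- data.frame(a = rnorm(13))
  z <- data.frame(c = rnorm(13), d = rnorm(13))
  # empty conditioning set: identical to plain rda
  expect_equal(partial_rda(y, x, NULL)$r2, rda_fit(y, x)$r2, tolerance = 1e-12)
  # X inside span(Z): nothing left to explain
  x_in <- data.frame(a = 2 * z$c - z$d)
  expect_equal(suppressWarnings(partial_rda(y, x_in, z))$r2, 0,
               tolerance = 1e-10)
  # fraction identity: adj(X|Z) + adjR2(Z) = adjR2(X u Z)
  p <- partial_rda(y, x, z)
  expect_equal(p$r2_adj + rda_fit(y, z)$r2_adj,
               rda_fit(y, cbind(a = x$a, z))$r2_adj, tolerance = 1e-10)
})

test_that("permutation p-values have the configured resolution and floor", {
  set.seed(29)
  y <- matrix(rnorm(13 * 5), 13, 5)
  x <- rnorm(13)
  p99 <- permutation_test(y, x, n_perm = 99, seed = 1)$p
  expect_gte(p99, 1 / 100)
  expect_equal(p99 * 100, round(p99 * 100), tolerance = 1e-9)
  # a strong signal reaches the minimum attainable p
  ys <- cbind(x + rnorm(13, sd = 0.01), matrix(rnorm(13 * 2, sd = 0.01), 13))
  expect_equal(permutation_test(ys, x, n_perm = 999, seed = 2)$p, 1 / 1000)
})

test_that("exhaustive enumeration matches an independent oracle on 4 rows", {
  set.seed(31)
  y <- matrix(rnorm(12), 4, 3)
  x <- rnorm(4)
  out <- permutation_test(y, x, exhaustive = TRUE)
  expect_equal(out$n_perm, 24)
  # independent enumeration via per-permutation R2 (F is monotone in R2)
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  yc <- scale(y, scale = FALSE)
  xc <- scale(matrix(x))
  r2 <- apply(perms, 1, function(p) {
    yp <- yc[p, , drop = FALSE]
    sum(qr.fitted(qr(xc), yp)^2) / sum(yp^2)
  })
  r2_obs <- sum(qr.fitted(qr(xc), yc)^2) / sum(yc^2)
  expect_equal(out$p, mean(r2 >= r2_obs - 1e-12))
  # monte-carlo estimate converges to the enumerated value (small-n warning
  # expected)
  expect_warning(permutation_test(y, x, n_perm = 9, seed = 3), "coarse")
  mc <- suppressWarnings(permutation_test(y, x, n_perm = 9999, seed = 3))$p
  expect_lt(abs(mc - out$p), 0.02)
})

test_that("permutation test agrees with vegan on a clear signal", {
  skip_if_not_installed("vegan")
  set.seed(37)
  x <- rnorm(13)
  y <- cbind(2 * x + rnorm(13, sd = 0.4), -x + rnorm(13, sd = 0.4),
             matrix(rnorm(13 * 3), 13))
  mine <- permutation_test(y, x, n_perm = 999, seed = 4)
  v <- vegan::anova.cca(vegan::rda(y ~ x), permutations = 999)
  expect_equal(mine$statistic, v$F[1], tolerance = 1e-8)
  expect_lt(abs(mine$p - v$`Pr(>F)`[1]), 0.05)
})

test_that("variance partition sums exactly and types combinations", {
  b <- small_bundle(seed = 44)
  y <- hellinger(site_community_matrix(b$abundance))
  sst <- aggregate(b$stressors[c("pt", "ne", "se", "temp")],
                   by = list(site = b$stressors$site), FUN = mean)
  sst <- sst[match(rownames(y), sst$site), ]
  vp <- variance_partition(y, sst$pt, sst$ne, sst[c("se", "temp")],
                           n_perm = 0)
  expect_equal(sum(vp$fractions[setdiff(names(vp$fractions), "residual")]),
               vp$adj[["PT+NE+HA"]], tolerance = 1e-10)
  expect_equal(vp$fractions[["residual"]], 1 - vp$adj[["PT+NE+HA"]],
               tolerance = 1e-12)
  tab <- vp$table
  expect_equal(tab$AD[tab$variables == "PT x NE"],
               vp$adj[["PT"]] + vp$adj[["NE"]], tolerance = 1e-12)
  combo <- tab[!is.na(tab$AD), ]
  expect_true(all(combo$type == ifelse(combo$r2adj > combo$AD, "S", "A")))
  # degrees of freedom mirror (m, n - m - 1)
  expect_equal(tab$df_resid, nrow(y) - tab$df_model - 1)
})

test_that("venn fractions agree with the vegan varpart oracle", {
  skip_if_not_installed("vegan")
  b <- small_bundle(seed = 44)
  y <- hellinger(site_community_matrix(b$abundance))
  sst <- aggregate(b$stressors[c("pt", "ne", "se", "temp")],
                   by = list(site = b$stressors$site), FUN = mean)
  sst <- sst[match(rownames(y), sst$site), ]
  vp <- variance_partition(y, sst$pt, sst$ne, sst[c("se", "temp")],
                           n_perm = 0)
  vv <- vegan::varpart(y, ~ pt, ~ ne, ~ se + temp, data = sst)
  ind <- vv$part$indfract$Adj.R.square
  expect_equal(unname(vp$fractions[c("unique_pt", "unique_ne", "unique_ha",
                                     "shared_pt_ne", "shared_ne_ha",
                                     "shared_pt_ha", "all_three",
                                     "residual")]),
               ind, tolerance = 1e-10)
})

test_that("additive expectation and fraction typing reproduce the rule", {
  expect_equal(additive_expectation(0.13, 0.51), 0.64)
  expect_equal(additive_expectation(0.13, 0.51, 0.37), 1.01)
  expect_error(additive_expectation(0.5), "two components")
  expect_equal(classify_fraction(0.55, 0.50), "S")
  expect_equal(classify_fraction(0.50, 0.64), "A")
})
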