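# Constrained ordination: Hellinger transform, RDA / partial RDA, Ezekiel
# adjusted R-squared, variance partitioning with additive-expectation
# interaction typing, and permutation tests of the pseudo-F statistic.

#' Average a long-format abundance table to a site-by-family matrix
#'
#' Campaign-level counts are averaged (arithmetic mean over the campaigns in
#' which the site was sampled; `fun = median` is available) to a single
#' community profile per site, the input expected by the ordination stage.
#'
#' @param abundance long-format data frame `site`, `campaign`, `family`,
#'   `count`.
#' @param fun averaging function over campaigns (default `mean`).
#' @return numeric matrix, sites in rows (rownames), families in columns.
#' @export
site_community_matrix <- function(abundance, fun = mean) {
  agg <- aggregate(count ~ site + campaign + family, data = abundance,
                   FUN = sum)
  avg <- aggregate(count ~ site + family, data = agg, FUN = fun)
  sites <- sort(unique(avg$site))
  fams <- sort(unique(avg$family))
  m <- matrix(0, length(sites), length(fams), dimnames = list(sites, fams))
  m[cbind(match(avg$site, sites), match(avg$family, fams))] <- avg$count
  m
}

#' Hellinger transform of a community matrix
#'
#' Each entry becomes the square root of its row-relative abundance:
#' `sqrt(x_ij / sum_j x_ij)`; every transformed row has unit sum of squares.
#' The transform makes Euclidean-based ordination appropriate for species
#' count data. The result carries a `"hellinger"` attribute and re-applying
#' the transform to an already-transformed matrix is an error, never a silent
#' double transform.
#'
#' @param x non-negative matrix (sites x families); rows summing to zero are
#'   an error naming the offending sites.
#' @return the transformed matrix with attribute `hellinger = TRUE`.
#' @export
hellinger <- function(x) {
  x <- as.matrix(x)
  if (isTRUE(attr(x, "hellinger"))) {
    stop("matrix is already Hellinger-transformed", call. = FALSE)
  }
  if (any(x < 0)) stop("negative entries are not allowed", call. = FALSE)
  rs <- rowSums(x)
  if (any(rs == 0)) {
    bad <- rownames(x)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("all-zero rows (empty sites): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- sqrt(sweep(x, 1, rs, "/"))
  attr(out, "hellinger") <- TRUE
  out
}

# Center columns; optionally scale to unit SD (constant columns left centered).
center_cols <- function(x, scale = FALSE) {
  x <- as.matrix(x)
  x <- sweep(x, 2, colMeans(x), "-")
  if (scale) {
    s <- apply(x, 2, sd)
    s[s == 0] <- 1
    x <- sweep(x, 2, s, "/")
  }
  x
}

# Drop residualized columns whose norm is numerically zero relative to the
# original column: they lie inside the conditioning span and projecting onto
# their round-off noise would fabricate explained variance.
drop_null_columns <- function(xr, x_orig, tol = 1e-8) {
  ref <- sqrt(colSums(x_orig^2))
  ref[ref == 0] <- 1
  keep <- sqrt(colSums(xr^2)) > tol * ref
  xr[, keep, drop = FALSE]
}

# Projection machinery shared by rda_fit and permutation_test: returns the QR
# of the (column-centered, rank-reduced) predictor matrix.
qr_full_rank <- function(x, warn = TRUE) {
  qx <- qr(x)
  if (qx$rank < ncol(x) && warn) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    warning("collinear predictor columns dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  qx
}

#' Ezekiel adjusted R-squared
#'
#' `1 - (1 - R^2) (n - 1) / (n - m - 1)`; the unbiased basis for variance
#' partitioning fractions. May be negative. With `m = 0` it returns `R^2`
#' unchanged.
#'
#' @param r2 unadjusted R-squared.
#' @param n number of observations (rows).
#' @param m number of predictor columns (model degrees of freedom).
#' @return adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (m == 0) return(r2)
  if (n <= m + 1) stop("adjusted R2 requires n > m + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Redundancy analysis
#'
#' Regresses a (column-centered) multivariate response matrix on a predictor
#' matrix and decomposes the fitted values into canonical axes. `R^2` is the
#' trace ratio `tr(Yhat' Yhat) / tr(Y' Y)`; `R^2_adj` applies the Ezekiel
#' correction with `m = rank(X)`. Predictor columns are z-standardized by
#' default (this never affects `R^2`). Collinear predictor columns are dropped
#' with a warning.
#'
#' @param y response matrix (e.g. a Hellinger-transformed site-by-family
#'   matrix); columns are centered internally.
#' @param x predictor data frame or matrix, rows aligned with `y`.
#' @param scale_x z-standardize predictor columns before fitting.
#' @return object of class `rda_fit`: list with `r2`, `r2_adj`, `eig`
#'   (canonical eigenvalues), `site_scores`, `species_scores`,
#'   `biplot_scores` (predictor correlations with the site scores),
#'   `df_model`, `df_resid`, `n`, `rank`.
#' @export
rda_fit <- function(y, x, scale_x = TRUE) {
  y <- as.matrix(y)
  x <- as.matrix(as.data.frame(x))
  if (nrow(y) != nrow(x)) stop("y and x rows must align", call. = FALSE)
  n <- nrow(y)
  if (n <= ncol(x) + 1) {
    stop("need n > number of predictors + 1", call. = FALSE)
  }
  yc <- center_cols(y)
  xc <- center_cols(x, scale = scale_x)
  qx <- qr_full_rank(xc)
  fitted <- qr.fitted(qx, yc)
  ss_tot <- sum(yc^2)
  ss_fit <- sum(fitted^2)
  r2 <- if (ss_tot > 0) ss_fit / ss_tot else 0
  m <- qx$rank
  sv <- svd(fitted)
  pos <- sv$d^2 > max(sv$d^2) * 1e-12
  eig <- (sv$d^2 / (n - 1))[pos]
  site_scores <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], sum(pos))
  species_scores <- sv$v[, pos, drop = FALSE]
  rownames(site_scores) <- rownames(y)
  rownames(species_scores) <- colnames(y)
  axis_names <- paste0("RDA", seq_len(sum(pos)))
  colnames(site_scores) <- colnames(species_scores) <- axis_names
  biplot_scores <- suppressWarnings(cor(xc, site_scores))
  structure(list(r2 = r2, r2_adj = adjusted_r2(r2, n, m), eig = eig,
                 site_scores = site_scores, species_scores = species_scores,
                 biplot_scores = biplot_scores, df_model = m,
                 df_resid = n - m - 1, n = n, rank = m),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("RDA: n %d, df_model %d, df_resid %d\n", x$n, x$df_model,
              x$df_resid))
  cat(sprintf("  R2 %.4f  R2_adj %.4f  axes %d\n", x$r2, x$r2_adj,
              length(x$eig)))
  invisible(x)
}

#' Partial redundancy analysis
#'
#' Residualizes both the response and the predictors on a conditioning set,
#' then runs [rda_fit()] on the residuals. The conditional adjusted fraction
#' is computed by fraction subtraction,
#' `adj(X | Z) = adjR2(X union Z) - adjR2(Z)`, the construction under which
#' the partition fractions add exactly. With an empty conditioning set this is
#' identical to [rda_fit()].
#'
#' @inheritParams rda_fit
#' @param z conditioning predictor set (data frame/matrix), or `NULL`.
#' @return an `rda_fit` object; for a non-empty `z`, `r2` is the proportion of
#'   the *total* variance of `y` captured after conditioning, and `r2_adj` is
#'   the subtraction-based conditional fraction.
#' @export
partial_rda <- function(y, x, z = NULL, scale_x = TRUE) {
  if (is.null(z) || NCOL(z) == 0) return(rda_fit(y, x, scale_x = scale_x))
  y <- as.matrix(y)
  x <- as.matrix(as.data.frame(x))
  z <- as.matrix(as.data.frame(z))
  stopifnot(nrow(y) == nrow(x), nrow(y) == nrow(z))
  n <- nrow(y)
  yc <- center_cols(y)
  xc <- center_cols(x, scale = scale_x)
  zc <- center_cols(z, scale = scale_x)
  qz <- qr_full_rank(zc, warn = FALSE)
  yr <- qr.resid(qz, yc)
  xr <- qr.resid(qz, xc)
  xr <- drop_null_columns(xr, xc)   # columns inside span(Z) carry no signal
  if (ncol(xr) == 0) {
    fitted <- matrix(0, n, ncol(yc))
    qx <- list(rank = 0L)
  } else {
    qx <- qr_full_rank(xr)
    fitted <- qr.fitted(qx, yr)
  }
  ss_tot <- sum(yc^2)
  r2 <- if (ss_tot > 0) sum(fitted^2) / ss_tot else 0

  both <- rda_fit(y, cbind(x, z), scale_x = scale_x)
  zonly <- rda_fit(y, z, scale_x = scale_x)
  r2_adj <- both$r2_adj - zonly$r2_adj

  m <- qx$rank
  sv <- svd(fitted)
  pos <- sv$d^2 > max(sv$d^2, 1e-300) * 1e-12
  eig <- (sv$d^2 / (n - 1))[pos]
  site_scores <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], sum(pos))
  species_scores <- sv$v[, pos, drop = FALSE]
  rownames(site_scores) <- rownames(y)
  rownames(species_scores) <- colnames(y)
  if (sum(pos) > 0) {
    colnames(site_scores) <- colnames(species_scores) <-
      paste0("RDA", seq_len(sum(pos)))
  }
  bip <- if (ncol(xr) > 0 && sum(pos) > 0) {
    suppressWarnings(cor(xr, site_scores))
  } else NULL
  structure(list(r2 = r2, r2_adj = r2_adj, eig = eig,
                 site_scores = site_scores, species_scores = species_scores,
                 biplot_scores = bip,
                 df_model = m, df_resid = n - qz$rank - m - 1, n = n,
                 rank = m),
            class = "rda_fit")
}

#' Permutation test of (partial) RDA significance
#'
#' Tests the constrained variance with the pseudo-F statistic
#' `F = (SS_fit / df_model) / (SS_resid / df_resid)`. For partial models the
#' reduced-model residual scheme is used: the response is residualized on the
#' conditioning set and those residual rows are permuted. The p-value is
#' `(1 + #(F* >= F_obs)) / (1 + n_perm)`; with `exhaustive = TRUE` all `n!`
#' row orders are enumerated instead and the p-value is the exact proportion
#' `#(F* >= F_obs) / n!` (the identity permutation included).
#'
#' @inheritParams partial_rda
#' @param n_perm number of random permutations (ignored when exhaustive).
#' @param seed integer seed for the permutations.
#' @param exhaustive enumerate all row permutations (requires `n <= 8`).
#' @return list with `statistic` (observed pseudo-F), `p`, `df_model`,
#'   `df_resid`, `n_perm`, `method`.
#' @export
permutation_test <- function(y, x, z = NULL, n_perm = 999, seed = NULL,
                             exhaustive = FALSE) {
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- as.matrix(y)
  x <- as.matrix(as.data.frame(x))
  n <- nrow(y)
  if (n < 5 && !exhaustive) {
    warning("fewer than 5 rows: permutation p-values are coarse",
            call. = FALSE)
  }
  yc <- center_cols(y)
  xc <- center_cols(x, scale = TRUE)
  rank_z <- 0
  if (!is.null(z) && NCOL(z) > 0) {
    zc <- center_cols(as.matrix(as.data.frame(z)), scale = TRUE)
    qz <- qr_full_rank(zc, warn = FALSE)
    yc <- qr.resid(qz, yc)          # reduced-model residuals
    xc0 <- xc
    xc <- drop_null_columns(qr.resid(qz, xc), xc0)
    rank_z <- qz$rank
  }
  if (ncol(xc) == 0) {
    stop("predictors lie entirely within the conditioning set", call. = FALSE)
  }
  qx <- qr_full_rank(xc, warn = FALSE)
  dfm <- qx$rank
  dfr <- n - rank_z - dfm - 1
  if (dfr <= 0) stop("no residual degrees of freedom", call. = FALSE)
  pseudo_f <- function(yp) {
    ssf <- sum(qr.fitted(qx, yp)^2)
    ssr <- sum(yp^2) - ssf
    (ssf / dfm) / (ssr / dfr)
  }
  f_obs <- pseudo_f(yc)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    f_all <- vapply(perms, function(p) pseudo_f(yc[p, , drop = FALSE]), 0)
    p <- mean(f_all >= f_obs - 1e-12)
    return(list(statistic = f_obs, p = p, df_model = dfm, df_resid = dfr,
                n_perm = length(perms), method = "exhaustive"))
  }
  hits <- 0L
  for (i in seq_len(n_perm)) {
    fp <- pseudo_f(yc[sample.int(n), , drop = FALSE])
    if (fp >= f_obs - 1e-12) hits <- hits + 1L
  }
  list(statistic = f_obs, p = (1 + hits) / (1 + n_perm), df_model = dfm,
       df_resid = dfr, n_perm = n_perm, method = "monte-carlo")
}

# All permutations of 1..n as a list, by inserting n into every position of
# each permutation of 1..(n-1). n is small (exhaustive tests only).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  unlist(lapply(sub, function(p) {
    lapply(seq_len(n), function(i) append(p, as.integer(n), after = i - 1L))
  }), recursive = FALSE)
}

#' Variance partitioning among three stressor sets
#'
#' Computes the adjusted R-squared explained by each stressor set alone, by
#' each pair and by all three together, with a marginal permutation test per
#' subset; derives the unique and shared Venn fractions by
#' inclusion-exclusion; and, for every combination, the additive expectation
#' (AD, the sum of the component individual fractions) and the interaction
#' type: `"A"` (antagonistic) when the combined fraction falls below AD,
#' `"S"` (synergistic) when it surpasses it. Negative adjusted fractions are
#' reported as computed so the additive-expectation arithmetic stays exact.
#'
#' @param y (transformed) site-by-family community matrix.
#' @param pt,ne,ha predictor sets for pesticide toxicity, nutrient enrichment
#'   and habitat alteration (vectors or data frames; `ha` typically holds the
#'   sedimentation index and temperature).
#' @param n_perm permutations for the significance tests (0 disables them).
#' @param seed integer seed for the permutation tests.
#' @return object of class `variance_partition`: list with `table` (data
#'   frame `variables`, `df_model`, `df_resid`, `r2adj`, `p`, `AD`, `type`),
#'   `fractions` (named Venn fractions: `unique_*`, `shared_*`, `all_three`,
#'   `residual`) and `adj` (named adjusted R-squared of the 7 subsets).
#' @export
variance_partition <- function(y, pt, ne, ha, n_perm = 999, seed = NULL) {
  as_m <- function(v, nm) {
    m <- as.matrix(as.data.frame(v))
    if (is.null(colnames(m)) || any(colnames(m) == "") ||
        any(grepl("^V\\d+$", colnames(m)))) {
      colnames(m) <- paste0(nm, seq_len(ncol(m)))
    }
    m
  }
  sets <- list(PT = as_m(pt, "pt"), NE = as_m(ne, "ne"), HA = as_m(ha, "ha"))
  y <- as.matrix(y)
  n <- nrow(y)
  stopifnot(all(vapply(sets, nrow, 0L) == n))

  subsets <- list(PT = "PT", NE = "NE", HA = "HA",
                  `PT+NE` = c("PT", "NE"), `PT+HA` = c("PT", "HA"),
                  `NE+HA` = c("NE", "HA"), `PT+NE+HA` = c("PT", "NE", "HA"))
  adj <- numeric(length(subsets))
  names(adj) <- names(subsets)
  dfm <- dfr <- integer(length(subsets))
  pval <- rep(NA_real_, length(subsets))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_along(subsets)) {
    xm <- do.call(cbind, sets[subsets[[i]]])
    fit <- rda_fit(y, xm)
    adj[i] <- fit$r2_adj
    dfm[i] <- fit$df_model
    dfr[i] <- fit$df_resid
    if (n_perm > 0) {
      pval[i] <- permutation_test(y, xm, n_perm = n_perm)$p
    }
  }

  combos <- c("PT+NE", "PT+HA", "NE+HA", "PT+NE+HA")
  ad <- c(`PT+NE` = adj[["PT"]] + adj[["NE"]],
          `PT+HA` = adj[["PT"]] + adj[["HA"]],
          `NE+HA` = adj[["NE"]] + adj[["HA"]],
          `PT+NE+HA` = adj[["PT"]] + adj[["NE"]] + adj[["HA"]])
  type <- ifelse(adj[combos] > ad[combos], "S", "A")

  tab <- data.frame(
    variables = c("PT", "NE", "HA", "PT x NE", "PT x HA", "NE x HA",
                  "PT x NE x HA"),
    df_model = dfm, df_resid = dfr, r2adj = as.numeric(adj), p = pval,
    AD = c(NA, NA, NA, as.numeric(ad)),
    type = c(NA, NA, NA, type), stringsAsFactors = FALSE)

  # Venn fractions by inclusion-exclusion (may be negative)
  g <- adj[["PT"]] + adj[["NE"]] + adj[["HA"]] - adj[["PT+NE"]] -
    adj[["PT+HA"]] - adj[["NE+HA"]] + adj[["PT+NE+HA"]]
  fractions <- c(
    unique_pt = adj[["PT+NE+HA"]] - adj[["NE+HA"]],
    unique_ne = adj[["PT+NE+HA"]] - adj[["PT+HA"]],
    unique_ha = adj[["PT+NE+HA"]] - adj[["PT+NE"]],
    shared_pt_ne = adj[["PT"]] + adj[["NE"]] - adj[["PT+NE"]] - g,
    shared_pt_ha = adj[["PT"]] + adj[["HA"]] - adj[["PT+HA"]] - g,
    shared_ne_ha = adj[["NE"]] + adj[["HA"]] - adj[["NE+HA"]] - g,
    all_three = g,
    residual = 1 - adj[["PT+NE+HA"]])

  structure(list(table = tab, fractions = fractions, adj = adj),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variance partitioning (adjusted R2)\n")
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Additive expectation of combined stressor fractions
#'
#' The additive expectation (AD) of a stressor combination is the sum of the
#' individual adjusted R-squared fractions of its components.
#'
#' @param ... individual adjusted R-squared values (two or more).
#' @return their sum.
#' @export
#' @examples
#' additive_expectation(0.13, 0.51)  # 0.64
additive_expectation <- function(...) {
  vals <- c(...)
  if (length(vals) < 2) stop("need at least two components", call. = FALSE)
  if (any(!is.finite(vals))) stop("components must be finite", call. = FALSE)
  sum(vals)
}

#' Interaction type of a combined fraction (variance-partitioning rule)
#'
#' `"A"` (antagonistic) when the combined adjusted fraction is lower than the
#' additive expectation, `"S"` (synergistic) when it surpasses it.
#'
#' @param combined adjusted R-squared of the combined stressor set.
#' @param ad additive expectation (sum of component individual fractions).
#' @return `"A"` or `"S"`.
#' @export
#' @examples
#' classify_fraction(0.55, 0.50)  # "S"
#' classify_fraction(0.50, 0.64)  # "A"
classify_fraction <- function(combined, ad) {
  stopifnot(is.finite(combined), is.finite(ad))
  if (combined > ad) "S" else "A"
}
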