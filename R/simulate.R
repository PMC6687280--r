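# Synthetic biomonitoring data with known ground truth.
#
# The generator emulates a repeated-measures catchment survey: a fixed set of
# stream sites sampled over many campaigns, a family-level community with a few
# dominant taxa, stressor gradients spanning realistic ranges, site-level
# random effects and AR(1) temporal autocorrelation on the latent log-mean.

#' Configuration for the synthetic biomonitoring design
#'
#' Defaults emulate the study design the pipeline targets: 13 sites sampled in
#' 20 campaigns (260 samples), 57 macroinvertebrate families of which four
#' dominate the community (roughly 33%, 26%, 19% and 5% of individuals), and
#' stressor gradients spanning the observed field ranges -- pesticide toxicity
#' as maximum toxic units (log10 scale, -4.46 to 0.24), soluble reactive
#' phosphorus (0.04--0.53 mg/L), a sedimentation index (0--20 habitat-protocol
#' scale, higher = less sediment) and water temperature (13.3--18.2 degrees C).
#'
#' @param n_sites number of stream sites (>= 2).
#' @param n_campaigns number of sampling campaigns per site (>= 2).
#' @param n_families number of macroinvertebrate families.
#' @param stressor_ranges named list of `c(min, max)` per stressor in natural
#'   units; names must be `pt`, `ne`, `se`, `temp`.
#' @param noise_frac campaign-level noise SD per stressor, as a fraction of the
#'   range width.
#' @param stressor_cor latent correlation between site-level stressor means
#'   (0 = mutually independent gradients, the default).
#' @param frac_at_risk fraction of families carrying the SPEAR at-risk trait.
#' @param mean_sample_abundance expected number of individuals per sample.
#' @param dominant_shares expected abundance shares of the leading families;
#'   remaining share is split evenly among the rest.
#' @param beta optional `n_families x 3` matrix of per-family responses to the
#'   standardized pt, ne and se gradients on the log-mean scale; by default it
#'   is built from the trait table (see [generate_community()]).
#' @param beta_pt_at_risk,beta_pt_other log-scale pesticide-toxicity slope for
#'   at-risk and not-at-risk families (at-risk more negative, so SPEAR responds
#'   to toxicity by construction).
#' @param beta_ne_sensitive,beta_ne_other nutrient-enrichment slope for
#'   nutrient-sensitive (BMWP score >= 6) and tolerant families.
#' @param beta_se sedimentation-index slope (positive: a higher index means
#'   less sediment, hence more individuals).
#' @param sigma_site SD of the shared site random intercept (log scale).
#' @param rho AR(1) correlation of the latent within-site process, in (-1, 1).
#' @param ar_sd stationary SD of the latent AR(1) process (log scale).
#' @param dispersion negative-binomial size parameter (> 0); `Inf` gives
#'   Poisson counts.
#' @param drop_fraction fraction of (site, campaign) samples dropped at random
#'   to mimic unbalanced sampling.
#' @param seed integer seed; all generator functions are deterministic given
#'   the configuration.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_stressors()], [generate_community()], [make_trait_table()]
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 4, n_campaigns = 6, n_families = 12)
#' str(generate_stressors(cfg))
sim_config <- function(n_sites = 13,
                       n_campaigns = 20,
                       n_families = 57,
                       stressor_ranges = list(pt = c(-4.46, 0.24),
                                              ne = c(0.04, 0.53),
                                              se = c(0, 20),
                                              temp = c(13.3, 18.2)),
                       noise_frac = 0.10,
                       stressor_cor = 0,
                       frac_at_risk = 0.3,
                       mean_sample_abundance = 166,
                       dominant_shares = c(0.333, 0.263, 0.186, 0.046),
                       beta = NULL,
                       beta_pt_at_risk = -0.6,
                       beta_pt_other = -0.1,
                       beta_ne_sensitive = -0.4,
                       beta_ne_other = -0.05,
                       beta_se = 0.3,
                       sigma_site = 0.3,
                       rho = 0.4,
                       ar_sd = 0.3,
                       dispersion = 2,
                       drop_fraction = 0,
                       seed = 1L) {
  stopifnot(is.numeric(n_sites), n_sites >= 2,
            is.numeric(n_campaigns), n_campaigns >= 2,
            is.numeric(n_families), n_families >= 1)
  if (!all(c("pt", "ne", "se", "temp") %in% names(stressor_ranges))) {
    stop("stressor_ranges must name pt, ne, se and temp", call. = FALSE)
  }
  for (nm in names(stressor_ranges)) {
    r <- stressor_ranges[[nm]]
    if (length(r) != 2 || !is.finite(r[1]) || !is.finite(r[2]) || r[1] >= r[2]) {
      stop("invalid range for stressor '", nm, "': min must be < max",
           call. = FALSE)
    }
  }
  if (!(rho > -1 && rho < 1)) stop("rho must lie in (-1, 1)", call. = FALSE)
  if (!(dispersion > 0)) stop("dispersion must be > 0", call. = FALSE)
  if (frac_at_risk < 0 || frac_at_risk > 1) {
    stop("frac_at_risk must lie in [0, 1]", call. = FALSE)
  }
  if (drop_fraction < 0 || drop_fraction >= 1) {
    stop("drop_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (sum(dominant_shares) >= 1) stop("dominant_shares must sum to < 1",
                                      call. = FALSE)
  if (length(dominant_shares) > n_families) {
    stop("more dominant shares than families", call. = FALSE)
  }
  cfg <- list(n_sites = as.integer(n_sites),
              n_campaigns = as.integer(n_campaigns),
              n_families = as.integer(n_families),
              stressor_ranges = stressor_ranges,
              noise_frac = noise_frac,
              stressor_cor = stressor_cor,
              frac_at_risk = frac_at_risk,
              mean_sample_abundance = mean_sample_abundance,
              dominant_shares = dominant_shares,
              beta = beta,
              beta_pt_at_risk = beta_pt_at_risk,
              beta_pt_other = beta_pt_other,
              beta_ne_sensitive = beta_ne_sensitive,
              beta_ne_other = beta_ne_other,
              beta_se = beta_se,
              sigma_site = sigma_site,
              rho = rho,
              ar_sd = ar_sd,
              dispersion = dispersion,
              drop_fraction = drop_fraction,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

site_labels <- function(n) sprintf("S%02d", seq_len(n))
family_labels <- function(n) sprintf("F%02d", seq_len(n))

#' Generate per-(site, campaign) stressor values
#'
#' Each stressor is drawn from a site-level mean (uniform over its configured
#' range) plus Gaussian campaign-level noise, clipped to the range. With
#' `stressor_cor > 0` the site-level means are coupled through a Gaussian
#' copula so collinear gradients can be produced on purpose (e.g. to exercise
#' the predictor screen).
#'
#' @param config a [sim_config()] object.
#' @return a data frame with columns `site`, `campaign`, `pt`, `ne`, `se`,
#'   `temp`; one row per (site, campaign).
#' @export
generate_stressors <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_sites
  nc <- config$n_campaigns
  vars <- c("pt", "ne", "se", "temp")
  k <- length(vars)

  # site means: latent exchangeable-correlation normals -> uniform in range
  r <- config$stressor_cor
  sigma <- matrix(r, k, k); diag(sigma) <- 1
  l <- chol(sigma)
  z <- matrix(rnorm(ns * k), ns, k) %*% l
  u <- pnorm(z)
  out <- expand.grid(campaign = seq_len(nc), site = site_labels(ns),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("site", "campaign")]
  for (j in seq_along(vars)) {
    rng <- config$stressor_ranges[[vars[j]]]
    mu_site <- rng[1] + u[, j] * (rng[2] - rng[1])
    noise_sd <- config$noise_frac * (rng[2] - rng[1])
    val <- rep(mu_site, each = nc) + rnorm(ns * nc, sd = noise_sd)
    out[[vars[j]]] <- pmin(pmax(val, rng[1]), rng[2])
  }
  rownames(out) <- NULL
  out
}

#' Generate a family trait table
#'
#' Assigns each family the SPEAR at-risk flag (exactly
#' `round(frac_at_risk * n_families)` families at risk) and an integer BMWP
#' tolerance score in 1--9, with at-risk families biased toward higher
#' (more sensitive) scores.
#'
#' @param n_families number of families.
#' @param frac_at_risk fraction of families flagged at risk.
#' @param seed integer seed.
#' @param score_bias exponent controlling how strongly at-risk families are
#'   pushed toward high BMWP scores (0 = no bias).
#' @return data frame with columns `family`, `at_risk` (0/1), `bmwp_score`.
#' @export
make_trait_table <- function(n_families, frac_at_risk = 0.3, seed = 1L,
                             score_bias = 2) {
  stopifnot(n_families >= 1, frac_at_risk >= 0, frac_at_risk <= 1)
  set.seed(seed)
  fam <- family_labels(n_families)
  n_risk <- round(frac_at_risk * n_families)
  at_risk <- integer(n_families)
  if (n_risk > 0) at_risk[sample.int(n_families, n_risk)] <- 1L
  w_hi <- (1:9)^score_bias        # favours sensitive (high) scores
  w_lo <- (9:1)^score_bias        # favours tolerant (low) scores
  score <- integer(n_families)
  for (i in seq_len(n_families)) {
    w <- if (at_risk[i] == 1L) w_hi else w_lo
    score[i] <- sample.int(9, 1, prob = w)
  }
  data.frame(family = fam, at_risk = at_risk, bmwp_score = score,
             stringsAsFactors = FALSE)
}

# Default per-family response matrix on the standardized-stressor scale.
default_beta <- function(traits, config) {
  cbind(pt = ifelse(traits$at_risk == 1L,
                    config$beta_pt_at_risk, config$beta_pt_other),
        ne = ifelse(traits$bmwp_score >= 6,
                    config$beta_ne_sensitive, config$beta_ne_other),
        se = rep(config$beta_se, nrow(traits)))
}

#' Generate a family-level community count table
#'
#' Counts are negative binomial with
#' `log mu = intercept_f + sum_k beta_fk * z_k + b_s + e_st`, where `z_k` are
#' the standardized stressor gradients, `b_s` is a site random intercept shared
#' by all families, and `e_st` is a stationary AR(1) process within site, also
#' shared across families so that community composition (and hence the biotic
#' indices) inherits temporal autocorrelation. Family intercepts are set from
#' the configured dominance shares with a lognormal-mean correction so realized
#' shares match their targets in expectation. At-risk families receive more
#' negative pesticide-toxicity slopes by default, so SPEAR responds to toxicity
#' by construction.
#'
#' @param stressors output of [generate_stressors()].
#' @param traits output of [make_trait_table()]; must have
#'   `config$n_families` rows.
#' @param config a [sim_config()] object.
#' @return long-format data frame `site`, `campaign`, `family`, `count`, with
#'   the realized ground truth attached as attribute `"ground_truth"` (see
#'   [ground_truth()]).
#' @export
generate_community <- function(stressors, traits, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(traits) != config$n_families) {
    stop("traits has ", nrow(traits), " rows but config expects ",
         config$n_families, " families", call. = FALSE)
  }
  need <- c("site", "campaign", "pt", "ne", "se")
  if (!all(need %in% names(stressors))) {
    stop("stressors must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  set.seed(config$seed + 1L)
  nf <- config$n_families

  beta <- if (is.null(config$beta)) default_beta(traits, config) else config$beta
  if (!is.matrix(beta) || nrow(beta) != nf || ncol(beta) != 3) {
    stop("beta must be an n_families x 3 matrix (pt, ne, se)", call. = FALSE)
  }

  # standardized gradients (z-scores over the realized table)
  zscore <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  z <- cbind(pt = zscore(stressors$pt), ne = zscore(stressors$ne),
             se = zscore(stressors$se))

  # intercepts from dominance shares, with Jensen correction for the
  # family-specific lognormal terms (shared site/AR terms cancel in shares)
  shares <- c(config$dominant_shares,
              rep((1 - sum(config$dominant_shares)) /
                    max(1, nf - length(config$dominant_shares)),
                  nf - length(config$dominant_shares)))
  intercept <- log(shares * config$mean_sample_abundance) -
    0.5 * rowSums(beta^2)

  sites <- unique(stressors$site)
  b_site <- setNames(rnorm(length(sites), sd = config$sigma_site), sites)

  # shared latent AR(1) per site, stationary SD = ar_sd
  rho <- config$rho
  ar <- numeric(nrow(stressors))
  for (s in sites) {
    idx <- which(stressors$site == s)
    idx <- idx[order(stressors$campaign[idx])]
    e <- numeric(length(idx))
    e[1] <- rnorm(1, sd = config$ar_sd)
    if (length(idx) > 1) {
      innov <- rnorm(length(idx) - 1, sd = config$ar_sd * sqrt(1 - rho^2))
      for (t in 2:length(idx)) e[t] <- rho * e[t - 1] + innov[t - 1]
    }
    ar[idx] <- e
  }

  eta_sample <- b_site[stressors$site] + ar          # length n_samples
  xb <- z %*% t(beta)                                # n_samples x n_families
  log_mu <- sweep(xb, 2, intercept, "+") + eta_sample

  n <- length(log_mu)
  counts <- if (is.finite(config$dispersion)) {
    rnbinom(n, size = config$dispersion, mu = exp(log_mu))
  } else {
    rpois(n, lambda = exp(log_mu))
  }
  out <- data.frame(site = rep(stressors$site, times = nf),
                    campaign = rep(stressors$campaign, times = nf),
                    family = rep(traits$family, each = nrow(stressors)),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)

  if (config$drop_fraction > 0) {
    keys <- unique(out[, c("site", "campaign")])
    n_drop <- floor(config$drop_fraction * nrow(keys))
    if (n_drop > 0) {
      drop <- keys[sample.int(nrow(keys), n_drop), ]
      dropped <- paste(out$site, out$campaign) %in%
        paste(drop$site, drop$campaign)
      out <- out[!dropped, ]
    }
  }
  rownames(out) <- NULL
  attr(out, "ground_truth") <- ground_truth(config, beta, intercept, b_site)
  out
}

#' Ground truth of a simulated dataset
#'
#' Collects the realized simulation parameters (response matrix, intercepts,
#' site random intercepts, variance and correlation parameters) so downstream
#' estimators can be checked against the values that generated the data. The
#' object serializes losslessly through [write_ground_truth()] /
#' [read_ground_truth()].
#'
#' @param config a [sim_config()] object.
#' @param beta realized family-by-stressor coefficient matrix.
#' @param intercept realized family intercepts.
#' @param b_site named vector of site random intercepts.
#' @return an object of class `ground_truth` (a list).
#' @export
ground_truth <- function(config, beta, intercept, b_site) {
  structure(list(beta = beta, intercept = intercept, b_site = b_site,
                 sigma_site = config$sigma_site, rho = config$rho,
                 ar_sd = config$ar_sd, dispersion = config$dispersion,
                 seed = config$seed),
            class = "ground_truth")
}

#' @rdname ground_truth
#' @param gt a `ground_truth` object.
#' @param path file path for the JSON sidecar.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  x <- list(beta = as.data.frame(gt$beta),
            intercept = gt$intercept,
            b_site = as.list(gt$b_site),
            sigma_site = gt$sigma_site, rho = gt$rho, ar_sd = gt$ar_sd,
            dispersion = gt$dispersion, seed = gt$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(beta = as.matrix(x$beta), intercept = x$intercept,
                 b_site = unlist(x$b_site), sigma_site = x$sigma_site,
                 rho = x$rho, ar_sd = x$ar_sd,
                 dispersion = if (is.null(x$dispersion)) Inf else x$dispersion,
                 seed = x$seed),
            class = "ground_truth")
}

#' Generate pesticide concentration tables with a known maximum toxic unit
#'
#' For each target, one carrier pesticide (the one with the largest LC50, so
#' even very low targets stay above the limit of quantification) is placed at
#' `C = LC50 * 10^target`, and decoy pesticides are placed strictly below their
#' own target-equivalent concentration. Applying [tu_max()] to the emitted
#' table therefore recovers each target exactly (to machine precision).
#'
#' @param targets data frame with columns `site`, `campaign`, `target_tu`
#'   (log10 toxic units), or a bare numeric vector of targets.
#' @param lc50_table data frame `pesticide`, `lc50_ugL` (48-h acute *D. magna*
#'   LC50, micrograms per litre, > 0).
#' @param seed integer seed for the decoys.
#' @param loq limit of quantification (micrograms per litre) written to every
#'   row.
#' @param n_decoys decoy pesticides attempted per sample (those that would fall
#'   below the LOQ are not emitted).
#' @return data frame `site`, `campaign`, `pesticide`, `concentration_ugL`,
#'   `loq_ugL`.
#' @export
generate_pesticides <- function(targets, lc50_table, seed = 1L, loq = 1e-3,
                                n_decoys = 2) {
  if (is.numeric(targets)) {
    targets <- data.frame(site = site_labels(length(targets)),
                          campaign = 1L, target_tu = targets)
  }
  stopifnot(all(c("site", "campaign", "target_tu") %in% names(targets)))
  if (!all(is.finite(targets$target_tu))) {
    stop("every target_tu must be finite", call. = FALSE)
  }
  if (is.null(lc50_table) || nrow(lc50_table) == 0) {
    stop("lc50_table must be non-empty", call. = FALSE)
  }
  stopifnot(all(lc50_table$lc50_ugL > 0))
  set.seed(seed)
  carrier <- which.max(lc50_table$lc50_ugL)
  rows <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tt <- targets$target_tu[i]
    c_main <- lc50_table$lc50_ugL[carrier] * 10^tt
    if (c_main < loq) {
      stop("target TU ", tt, " puts the carrier pesticide below the LOQ; ",
           "supply an LC50 table with a larger maximum LC50 or a lower loq",
           call. = FALSE)
    }
    pest <- lc50_table$pesticide[carrier]
    conc <- c_main
    others <- setdiff(seq_len(nrow(lc50_table)), carrier)
    if (n_decoys > 0 && length(others) > 0) {
      pick <- sample(others, min(n_decoys, length(others)))
      gap <- runif(length(pick), 0.5, 2)        # decoy TU strictly below target
      c_dec <- lc50_table$lc50_ugL[pick] * 10^(tt - gap)
      keep <- c_dec >= loq
      pest <- c(pest, lc50_table$pesticide[pick][keep])
      conc <- c(conc, c_dec[keep])
    }
    rows[[i]] <- data.frame(site = targets$site[i],
                            campaign = targets$campaign[i],
                            pesticide = pest, concentration_ugL = conc,
                            loq_ugL = loq, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a Gaussian response with the fitted model's own structure
#'
#' Draws `y = X beta + b_site + e` over an existing stressor table, where
#' `b_site` is a site random intercept and `e` a stationary AR(1) error within
#' site. Used for parameter-recovery checks of [fit_stressor_model()], whose
#' likelihood assumes exactly this structure.
#'
#' @param stressors data frame with `site`, `campaign`, `pt`, `ne`, `se`.
#' @param beta named numeric vector `c(intercept, pt, ne, se)` on the
#'   standardized-predictor scale.
#' @param sigma_site SD of the site random intercept.
#' @param rho AR(1) correlation in (-1, 1).
#' @param sigma stationary SD of the AR(1) error.
#' @param seed integer seed.
#' @return the `stressors` data frame with a `y` column appended.
#' @export
simulate_response <- function(stressors, beta = c(10, -1, -0.5, 1),
                              sigma_site = 1, rho = 0.4, sigma = 1,
                              seed = 1L) {
  stopifnot(length(beta) == 4, rho > -1, rho < 1, sigma > 0, sigma_site >= 0)
  set.seed(seed)
  zscore <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  x <- cbind(1, zscore(stressors$pt), zscore(stressors$ne),
             zscore(stressors$se))
  sites <- unique(stressors$site)
  b <- setNames(rnorm(length(sites), sd = sigma_site), sites)
  e <- numeric(nrow(stressors))
  for (s in sites) {
    idx <- which(stressors$site == s)
    idx <- idx[order(stressors$campaign[idx])]
    es <- numeric(length(idx))
    es[1] <- rnorm(1, sd = sigma)
    if (length(idx) > 1) {
      innov <- rnorm(length(idx) - 1, sd = sigma * sqrt(1 - rho^2))
      for (t in 2:length(idx)) es[t] <- rho * es[t - 1] + innov[t - 1]
    }
    e[idx] <- es
  }
  stressors$y <- drop(x %*% beta) + b[stressors$site] + e
  stressors
}

#' Write a simulated dataset bundle to CSV + JSON
#'
#' Writes the long-format abundance table, the stressor table, the trait table,
#' optionally a pesticide concentration table, and the ground-truth JSON
#' sidecar, using the package's standard file schemas.
#'
#' @param dir output directory (created if needed).
#' @param abundance,stressors,traits data frames as produced by the generators.
#' @param pesticides optional pesticide concentration table.
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(dir, abundance, stressors, traits,
                             pesticides = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(abundance = file.path(dir, "abundance.csv"),
             stressors = file.path(dir, "stressors.csv"),
             traits = file.path(dir, "traits.csv"))
  write.csv(abundance, files["abundance"], row.names = FALSE)
  write.csv(stressors, files["stressors"], row.names = FALSE)
  write.csv(traits, files["traits"], row.names = FALSE)
  if (!is.null(pesticides)) {
    files <- c(files, pesticides = file.path(dir, "pesticides.csv"))
    write.csv(pesticides, files["pesticides"], row.names = FALSE)
  }
  gt <- attr(abundance, "ground_truth")
  if (!is.null(gt)) {
    files <- c(files, ground_truth = file.path(dir, "ground_truth.json"))
    write_ground_truth(gt, files["ground_truth"])
  }
  invisible(files)
}
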