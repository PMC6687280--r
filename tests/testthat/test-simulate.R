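test_that("stressor generation respects configured ranges and determinism", {
  cfg <- small_config(seed = 5)
  st1 <- generate_stressors(cfg)
  st2 <- generate_stressors(cfg)
  expect_identical(st1, st2)

  expect_equal(nrow(st1), cfg$n_sites * cfg$n_campaigns)
  for (v in c("pt", "ne", "se", "temp")) {
    rng <- cfg$stressor_ranges[[v]]
    expect_true(all(st1[[v]] >= rng[1] & st1[[v]] <= rng[2]))
  }
})

test_that("zero campaign noise collapses each site to a constant stressor", {
  cfg <- small_config(seed = 5, noise_frac = 0)
  st <- generate_stressors(cfg)
  per_site_sd <- tapply(st$pt, st$site, sd)
  expect_true(all(per_site_sd == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_sites = 1), "n_sites")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(stressor_ranges = list(pt = c(1, -1),
                                                 ne = c(0, 1), se = c(0, 1),
                                                 temp = c(0, 1))),
               "min must be < max")
})

test_that("null community model yields iid NB counts at the right mean", {
  # beta = 0, no site effect, no AR noise: counts are iid negative binomial
  cfg <- sim_config(n_sites = 10, n_campaigns = 10, n_families = 3,
                    dominant_shares = c(0.4, 0.3),
                    beta = matrix(0, 3, 3), sigma_site = 0, ar_sd = 0,
                    rho = 0, mean_sample_abundance = 100, seed = 21)
  st <- generate_stressors(cfg)
  tr <- make_trait_table(3, 0.5, seed = 21)
  ab <- generate_community(st, tr, cfg)
  x <- ab$count[ab$family == "F01"]
  mu <- 0.4 * 100
  # MC standard error of the mean for NB(mu, size)
  mc_se <- sqrt((mu + mu^2 / cfg$dispersion) / length(x))
  expect_lt(abs(mean(x) - mu), 3 * mc_se)
})

test_that("dominant-family shares are realized at the study scale", {
  b <- study_bundle()
  tot <- tapply(b$abundance$count, b$abundance$family, sum)
  shares <- tot / sum(tot)
  target <- c(F01 = 0.333, F02 = 0.263, F03 = 0.186, F04 = 0.046)
  expect_true(all(abs(shares[names(target)] - target) < 0.03))
})

test_that("site-mean SPEAR declines along the pesticide-toxicity gradient", {
  # many sites, one campaign: at-risk families get strongly negative PT slopes
  cfg <- sim_config(n_sites = 200, n_campaigns = 2, n_families = 20,
                    dominant_shares = c(0.2, 0.15),
                    beta_pt_at_risk = -1, beta_pt_other = 0,
                    sigma_site = 0.1, ar_sd = 0.1, seed = 31)
  st <- generate_stressors(cfg)
  tr <- make_trait_table(20, 0.4, seed = 31)
  ab <- generate_community(st, tr, cfg)
  idx <- suppressWarnings(community_indices(ab, tr))
  m <- merge(idx, st, by = c("site", "campaign"))
  site_spear <- tapply(m$spear, m$site, mean)
  site_pt <- tapply(m$pt, m$site, mean)
  expect_lt(cor(site_spear, site_pt[names(site_spear)]), 0)
})

test_that("trait tables have valid scores, exact at-risk fraction, determinism", {
  tr <- make_trait_table(40, 0.25, seed = 3)
  expect_identical(tr, make_trait_table(40, 0.25, seed = 3))
  expect_true(all(tr$bmwp_score %in% 1:9))
  expect_equal(sum(tr$at_risk), round(0.25 * 40))
  expect_true(all(make_trait_table(10, 1, seed = 1)$at_risk == 1))
  # at-risk families are biased toward sensitive (high) scores
  tr2 <- make_trait_table(500, 0.5, seed = 9)
  expect_gt(mean(tr2$bmwp_score[tr2$at_risk == 1]),
            mean(tr2$bmwp_score[tr2$at_risk == 0]))
})

test_that("dropping campaigns removes whole samples and downstream tolerates it", {
  b <- small_bundle(seed = 12, drop_fraction = 0.2)
  keys <- unique(b$abundance[, c("site", "campaign")])
  n_total <- b$config$n_sites * b$config$n_campaigns
  expect_equal(nrow(keys), n_total - floor(0.2 * n_total))
  idx <- suppressWarnings(community_indices(b$abundance, b$traits))
  expect_equal(nrow(idx), nrow(keys))
})

test_that("ground truth round-trips through JSON", {
  b <- small_bundle(seed = 8)
  gt <- attr(b$abundance, "ground_truth")
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, path)
  gt2 <- read_ground_truth(path)
  expect_equal(unname(gt2$beta), unname(gt$beta))
  expect_equal(gt2$b_site, gt$b_site)
  expect_equal(gt2$rho, gt$rho)
  expect_equal(gt2$sigma_site, gt$sigma_site)
})

test_that("pesticide tables are exactly invertible and reject bad input", {
  lc50 <- lc50_fixture()
  expect_error(generate_pesticides(data.frame(site = "a", campaign = 1,
                                              target_tu = NaN), lc50),
               "finite")
  expect_error(generate_pesticides(0, lc50[0, ]), "non-empty")
  # target 0 puts the carrier exactly at its LC50
  p0 <- generate_pesticides(0, lc50, n_decoys = 0)
  expect_equal(p0$concentration_ugL[1],
               lc50$lc50_ugL[which.max(lc50$lc50_ugL)])
})
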