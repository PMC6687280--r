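test_that("predictor screen flags collinear pairs and constants", {
  set.seed(2)
  d <- data.frame(a = rnorm(50))
  d$b <- d$a                                  # |r| = 1
  d$c <- rnorm(50)
  d$k <- 1                                    # constant
  out <- screen_predictors(d, c("a", "b", "c", "k"), threshold = 0.7)
  expect_true(any(out$flagged$var1 == "a" & out$flagged$var2 == "b"))
  expect_equal(out$constant, "k")
  expect_equal(out$retained, c("a", "c"))
  # threshold 0 flags every well-defined pair
  out0 <- screen_predictors(d, c("a", "b", "c"), threshold = 0)
  expect_equal(nrow(out0$flagged), 3)
})

test_that("independently simulated stressor gradients pass the screen", {
  cfg <- sim_config(seed = 6)
  st <- generate_stressors(cfg)
  out <- screen_predictors(st, c("pt", "ne", "se", "temp"))
  expect_equal(nrow(out$flagged), 0)
  expect_equal(out$retained, c("pt", "ne", "se", "temp"))
})

test_that("aicc matches hand arithmetic and is monotone in K", {
  expect_equal(aicc(0, 1, 3), 6)              # 2K + 2K(K+1)/(n-K-1) = 2 + 4
  expect_error(aicc(0, 2, 3), "n > K")
  k <- 3
  ll <- -10
  expect_true(all(diff(sapply(1:5, function(K) aicc(ll, K, 100))) > 0))
  # AICc -> AIC monotonically as n grows
  gap <- sapply(c(10, 20, 50, 100, 1000), function(n) {
    aicc(ll, k, n) - (-2 * ll + 2 * k)
  })
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[length(gap)], 0.05)
})

test_that("akaike weights normalize, preserve order, and ignore shifts", {
  expect_equal(akaike_weights(0), 1)
  w <- akaike_weights(c(0, 2, 4))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(diff(w) < 0))
  # reordering deltas permutes weights
  d <- c(0, 1.3, 2.2, 5)
  o <- c(3, 1, 4, 2)
  expect_equal(akaike_weights(d)[o], akaike_weights(d[o]), tolerance = 1e-12)
  # AICc ranking is invariant to adding a constant to all log-likelihoods:
  # deltas (hence weights) are unchanged
  ll <- c(-100, -102, -104.5)
  a1 <- aicc(ll, 3, 50)
  a2 <- aicc(ll + 7, 3, 50)
  expect_equal(a1 - min(a1), a2 - min(a2), tolerance = 1e-10)
})

test_that("the five candidate structures are exactly the specified set", {
  fs <- candidate_formulas("y")
  expect_named(fs, c("M1", "M2", "M3", "M4", "M5"))
  tt <- lapply(fs, function(f) attr(terms(f), "term.labels"))
  expect_equal(tt$M1, c("pt", "ne", "se"))
  expect_setequal(tt$M2, c("pt", "ne", "se", "ne:se"))
  expect_setequal(tt$M3, c("pt", "ne", "se", "pt:se"))
  expect_setequal(tt$M4, c("pt", "ne", "se", "pt:ne"))
  expect_setequal(tt$M5, c("pt", "ne", "se", "pt:ne", "pt:se", "ne:se",
                           "pt:ne:se"))
})

test_that("without random terms the fit reduces to ordinary least squares", {
  b <- small_bundle(seed = 3)
  idx <- suppressWarnings(community_indices(b$abundance, b$traits))
  d <- merge(idx, b$stressors, by = c("site", "campaign"))
  f <- fit_stressor_model("spear", d, "M1", random_intercept = FALSE,
                          ar1 = FALSE, per_site_variance = FALSE,
                          standardize = FALSE)
  ols <- lm(spear ~ pt + ne + se, data = d)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
})

test_that("random-intercept model dominates its nested fixed-only model", {
  b <- study_bundle()
  d <- b$merged
  full <- fit_stressor_model("spear", d, "M1", per_site_variance = FALSE,
                             ar1 = FALSE)
  nested <- fit_stressor_model("spear", d, "M1", random_intercept = FALSE,
                               per_site_variance = FALSE, ar1 = FALSE)
  expect_true(full$converged && nested$converged)
  expect_gte(full$logLik, nested$logLik - 1e-6)
})

test_that("K counts fixed effects plus variance, correlation and residual", {
  b <- study_bundle()
  f <- fit_stressor_model("spear", b$merged, "M1")
  # 4 fixed + sigma_site + rho + (n_sites - 1) variance ratios + sigma
  expect_equal(f$K, 4 + 1 + 1 + (b$config$n_sites - 1) + 1)
  f5 <- fit_stressor_model("spear", b$merged, "M5")
  expect_equal(f5$K, f$K + 4)
})

test_that("doubling the response doubles estimates and leaves rho alone", {
  b <- study_bundle()
  d <- b$merged
  f1 <- fit_stressor_model("spear", d, "M1", per_site_variance = FALSE)
  d$spear2 <- 2 * d$spear
  f2 <- fit_stressor_model("spear2", d, "M1", per_site_variance = FALSE)
  expect_equal(f2$coefficients$estimate, 2 * f1$coefficients$estimate,
               tolerance = 1e-4)
  expect_equal(f2$rho, f1$rho, tolerance = 1e-4)
})

test_that("fitted AR(1) and variance parameters track the generator", {
  # variance components are noisy in any single realization (20 sites), so
  # calibration is checked on the replicate average
  cfg <- sim_config(n_sites = 20, n_campaigns = 20, seed = 17)
  st <- generate_stressors(cfg)
  est <- vapply(1:8, function(r) {
    d <- simulate_response(st, beta = c(5, -1, -0.5, 1), sigma_site = 1,
                           rho = 0.5, sigma = 1, seed = 300 + r)
    f <- fit_stressor_model("y", d, "M1", per_site_variance = FALSE)
    expect_true(f$converged)
    c(f$sigma_site, f$rho)
  }, c(0, 0))
  expect_lt(abs(mean(est[1, ]) - 1), 0.35)
  expect_lt(abs(mean(est[2, ]) - 0.5), 0.15)
})

test_that("selection table orders by AICc with coherent deltas and weights", {
  b <- study_bundle()
  fits <- fit_candidates("bmwp", b$merged, per_site_variance = FALSE)
  tab <- model_selection(fits)
  expect_equal(tab$delta[1], 0)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(tab$AICc))
})

test_that("model averaging degenerates correctly and bounds its SE", {
  b <- study_bundle()
  fits <- fit_candidates("spear", b$merged, per_site_variance = FALSE)
  tab <- model_selection(fits)
  # retain exactly one model: averaged estimates equal that model's own
  avg1 <- model_average(fits, top_k = 1)
  best <- fits[[tab$model[1]]]
  expect_equal(avg1$estimate[match(best$coefficients$term, avg1$term)],
               best$coefficients$estimate, tolerance = 1e-12)
  expect_equal(avg1$se[match(best$coefficients$term, avg1$term)],
               best$coefficients$se, tolerance = 1e-12)
  # unconditional SE never undercuts the smallest within-model SE
  avg <- model_average(fits, retention_delta = Inf)
  for (tm in c("pt", "ne", "se")) {
    ses <- vapply(fits, function(f) f$coefficients$se[f$coefficients$term == tm], 0)
    expect_gte(avg$se[avg$term == tm], min(ses))
  }
})

test_that("two equally weighted models average to the midpoint", {
  f_a <- structure(list(converged = TRUE, model = "M1", response = "y",
                        logLik = -10, K = 2L, n = 50,
                        aicc = aicc(-10, 2, 50),
                        coefficients = data.frame(term = "pt", estimate = 1,
                                                  se = 0.5, lo95 = 0.02,
                                                  hi95 = 1.98)),
                   class = "stressor_fit")
  f_b <- f_a
  f_b$model <- "M2"
  f_b$coefficients$estimate <- 3
  avg <- model_average(list(M1 = f_a, M2 = f_b), retention_delta = 2)
  expect_equal(avg$estimate[avg$term == "pt"], 2)
})

test_that("interaction classification follows the additive-expectation rule", {
  expect_equal(classify_interaction(-0.5, -0.9, -0.1, -2), "antagonistic")
  expect_equal(classify_interaction(-3, -3.8, -2.2, -1), "synergistic")
  expect_equal(classify_interaction(-2, -2.5, -1.5, -2), "additive")
  expect_equal(classify_interaction(0.1, -0.2, 0.4, 1), "no-effect")
  expect_error(classify_interaction(1, 0.5, 1.5, NA), "additive expectation")
})

test_that("a built-in antagonistic interaction is detected end to end", {
  # response with a PT x SE interaction weaker than the additive expectation
  # of its strong negative main effects; moderate noise, many sites
  cfg <- sim_config(n_sites = 30, n_campaigns = 20, seed = 23)
  st <- generate_stressors(cfg)
  hits <- 0
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    d <- simulate_response(st, beta = c(10, -2, -0.3, -2), sigma_site = 0.5,
                           rho = 0.3, sigma = 1, seed = 4000 + r)
    zs <- function(x) as.numeric(scale(x))
    d$y <- d$y + 1.0 * zs(d$pt) * zs(d$se)   # |1.0| < |(-2) + (-2)| = 4
    fits <- fit_candidates("y", d, per_site_variance = FALSE)
    eff <- averaged_effects(fits, retention_delta = 2)
    cls <- eff$classification[eff$term == "pt:se"]
    if (length(cls) == 1 && !is.na(cls) && cls == "antagonistic") {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 8)
})
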