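# Candidate mixed models of index responses on the stressor gradients,
# AICc-based selection, model averaging, and classification of interaction
# estimates against the additive expectation.

#' Screen predictors for collinearity
#'
#' Computes the pairwise Pearson correlation matrix of candidate predictors
#' and flags pairs at or above the threshold; one member of each flagged pair
#' (by default the later column) is suggested for removal. Constant columns
#' have undefined correlations and are flagged separately.
#'
#' @param data data frame containing the predictor columns.
#' @param predictors character vector of column names (default: all numeric
#'   columns except `site` and `campaign`).
#' @param threshold absolute correlation at which a pair is flagged.
#' @return list with `correlations` (matrix), `flagged` (data frame
#'   `var1`, `var2`, `r`), `constant` (names of constant columns) and
#'   `retained` (suggested predictor set).
#' @export
screen_predictors <- function(data, predictors = NULL, threshold = 0.70) {
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          c("campaign"))
  }
  if (length(predictors) < 2) stop("need at least 2 predictors", call. = FALSE)
  x <- data[, predictors, drop = FALSE]
  if (sum(complete.cases(x)) < 3) {
    stop("need at least 3 complete rows", call. = FALSE)
  }
  constant <- predictors[vapply(x, function(v) sd(v, na.rm = TRUE) == 0,
                                logical(1))]
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  flagged <- data.frame(var1 = character(0), var2 = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  drop <- character(0)
  for (i in seq_len(ncol(r) - 1)) {
    for (j in (i + 1):ncol(r)) {
      rij <- r[i, j]
      if (!is.na(rij) && abs(rij) >= threshold) {
        flagged <- rbind(flagged,
                         data.frame(var1 = predictors[i], var2 = predictors[j],
                                    r = rij, stringsAsFactors = FALSE))
        drop <- union(drop, predictors[j])
      }
    }
  }
  list(correlations = r, flagged = flagged, constant = constant,
       retained = setdiff(predictors, union(drop, constant)))
}

# The five candidate fixed-effect structures: all contain the three stressor
# main effects and differ only in their interaction set.
candidate_interactions <- list(
  M1 = character(0),
  M2 = "ne:se",
  M3 = "pt:se",
  M4 = "pt:ne",
  M5 = c("pt:ne", "pt:se", "ne:se", "pt:ne:se")
)

#' The candidate model set
#'
#' Returns the five candidate fixed-effect structures for a response: a null
#' (purely additive) model with the three stressor main effects, three models
#' each adding one pairwise interaction, and a full model with all pairwise
#' interactions plus the three-way interaction.
#'
#' @param response name of the response column.
#' @return named list of model formulas.
#' @export
candidate_formulas <- function(response) {
  lapply(candidate_interactions, function(ints) {
    rhs <- paste(c("pt", "ne", "se", ints), collapse = " + ")
    as.formula(paste(response, "~", rhs))
  })
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K + 1) / (n - K - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param K number of estimated parameters (fixed effects + variance,
#'   correlation and residual parameters).
#' @param n number of observations; must exceed `K + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, K, n) {
  if (any(n <= K + 1)) stop("AICc requires n > K + 1", call. = FALSE)
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from AICc differences
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`, interpretable as the
#' probability that model i is the best of the candidate set.
#'
#' @param delta vector of AICc differences from the best model (min must be 0).
#' @return weights summing to 1, in the input order.
#' @export
#' @examples
#' akaike_weights(c(0, 2.5, 4.66, 4.87, 6.01))
akaike_weights <- function(delta) {
  if (any(delta < 0) || abs(min(delta)) > 1e-8) {
    stop("delta values must be >= 0 with minimum 0", call. = FALSE)
  }
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Fit one candidate linear mixed model
#'
#' Fits `response ~ pt + ne + se` plus the requested interaction set by
#' maximum likelihood, with (optionally) a site random intercept, an AR(1)
#' correlation structure over campaigns within site, and per-site residual
#' variances. Models with a random intercept are fit with [nlme::lme()];
#' without one, with [nlme::gls()]. ML (not REML) is used because candidates
#' differ in their fixed effects. Predictors are z-standardized by default so
#' effects -- and the additive expectations built from them -- are comparable
#' across stressors. Non-convergence is captured and returned as a flagged
#' result, never silently dropped.
#'
#' @param response name of the response column in `data`.
#' @param data data frame with `site`, `campaign`, the response, and `pt`,
#'   `ne`, `se`.
#' @param model one of `"M1"` (additive null) ... `"M5"` (all interactions
#'   incl. three-way), or a character vector of extra interaction terms.
#' @param random_intercept include a site random intercept.
#' @param ar1 include the AR(1) within-site correlation structure.
#' @param per_site_variance allow a different residual variance per site.
#' @param standardize z-standardize the predictors before fitting.
#' @param method `"ML"` (default, required for AICc comparison of fixed
#'   effects) or `"REML"` for a final refit.
#' @return an object of class `stressor_fit`: a list with elements
#'   `converged`, `model` (label), `fit` (the nlme object or `NULL`),
#'   `logLik`, `K`, `n`, `aicc`, `coefficients` (data frame `term`,
#'   `estimate`, `se`, `lo95`, `hi95`), `sigma`, `sigma_site`, `rho`,
#'   `message`.
#' @export
fit_stressor_model <- function(response, data, model = "M1",
                               random_intercept = TRUE, ar1 = TRUE,
                               per_site_variance = TRUE,
                               standardize = TRUE, method = "ML") {
  need <- c("site", "campaign", response, "pt", "ne", "se")
  if (!all(need %in% names(data))) {
    stop("data must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ints <- if (length(model) == 1 && model %in% names(candidate_interactions)) {
    candidate_interactions[[model]]
  } else model
  label <- if (length(model) == 1 && model %in% names(candidate_interactions)) {
    model
  } else "custom"

  d <- data[complete.cases(data[, need]), need]
  d$site <- factor(d$site)
  if (standardize) {
    for (v in c("pt", "ne", "se")) d[[v]] <- as.numeric(scale(d[[v]]))
  }
  fixed <- as.formula(paste(response, "~",
                            paste(c("pt", "ne", "se", ints), collapse = " + ")))
  corr <- if (ar1) nlme::corAR1(form = ~ campaign | site) else NULL
  wts <- if (per_site_variance) nlme::varIdent(form = ~ 1 | site) else NULL

  fit <- tryCatch({
    if (random_intercept) {
      nlme::lme(fixed, data = d, random = ~ 1 | site, correlation = corr,
                weights = wts, method = method,
                control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                           returnObject = FALSE))
    } else {
      nlme::gls(fixed, data = d, correlation = corr, weights = wts,
                method = method,
                control = nlme::glsControl(maxIter = 200, msMaxIter = 200,
                                           returnObject = FALSE))
    }
  }, error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE, model = label, fit = NULL,
                          response = response, logLik = NA_real_,
                          K = NA_integer_, n = nrow(d), aicc = NA_real_,
                          coefficients = NULL, sigma = NA_real_,
                          sigma_site = NA_real_, rho = NA_real_,
                          message = conditionMessage(fit)),
                     class = "stressor_fit"))
  }

  ll <- logLik(fit)
  K <- as.integer(attr(ll, "df"))
  n <- nrow(d)
  est <- if (random_intercept) nlme::fixef(fit) else coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(0.975)
  coefs <- data.frame(term = names(est), estimate = as.numeric(est),
                      se = as.numeric(se),
                      lo95 = as.numeric(est) - z * as.numeric(se),
                      hi95 = as.numeric(est) + z * as.numeric(se),
                      stringsAsFactors = FALSE)
  rho <- NA_real_
  if (ar1) {
    cs <- fit$modelStruct$corStruct
    rho <- as.numeric(coef(cs, unconstrained = FALSE))
  }
  sigma_site <- NA_real_
  if (random_intercept) {
    vc <- nlme::VarCorr(fit)
    sigma_site <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  }
  structure(list(converged = TRUE, model = label, fit = fit,
                 response = response, logLik = as.numeric(ll), K = K, n = n,
                 aicc = aicc(as.numeric(ll), K, n), coefficients = coefs,
                 sigma = fit$sigma, sigma_site = sigma_site, rho = rho,
                 message = "converged"),
            class = "stressor_fit")
}

#' @export
print.stressor_fit <- function(x, ...) {
  cat("stressor_fit [", x$model, "] response:", x$response,
      if (x$converged) "" else "(NOT CONVERGED)", "\n")
  if (x$converged) {
    cat(sprintf("  logLik %.2f  K %d  n %d  AICc %.2f  rho %s\n",
                x$logLik, x$K, x$n, x$aicc,
                ifelse(is.na(x$rho), "-", sprintf("%.3f", x$rho))))
    print(x$coefficients, digits = 4)
  } else {
    cat("  ", x$message, "\n")
  }
  invisible(x)
}

#' Fit all five candidate models for one response
#'
#' @inheritParams fit_stressor_model
#' @param ... passed to [fit_stressor_model()].
#' @return named list of `stressor_fit` objects (`M1` ... `M5`).
#' @export
fit_candidates <- function(response, data, ...) {
  fits <- lapply(names(candidate_interactions), function(m) {
    fit_stressor_model(response, data, model = m, ...)
  })
  names(fits) <- names(candidate_interactions)
  fits
}

#' AICc model-selection table
#'
#' Ranks converged candidate fits by AICc and attaches AICc differences and
#' Akaike weights. Non-converged fits are excluded (and named in the
#' `"dropped"` attribute).
#'
#' @param fits list of `stressor_fit` objects.
#' @return data frame `model`, `K`, `AICc`, `delta`, `weight`, ordered best
#'   first.
#' @export
model_selection <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) stop("no converged candidate model", call. = FALSE)
  tab <- data.frame(model = vapply(conv, `[[`, "", "model"),
                    K = as.integer(vapply(conv, function(f) as.numeric(f$K), 0)),
                    AICc = vapply(conv, `[[`, 0, "aicc"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc), ]
  tab$delta <- tab$AICc - tab$AICc[1]
  tab$weight <- akaike_weights(tab$delta)
  rownames(tab) <- NULL
  attr(tab, "dropped") <- setdiff(vapply(fits, `[[`, "", "model"), tab$model)
  tab
}

#' Average fixed effects over the retained candidate models
#'
#' Retains candidates within `retention_delta` AICc units of the best (or the
#' `top_k` best), renormalizes their Akaike weights, and averages each term
#' over the retained models that contain it (weights renormalized again over
#' that subset). The unconditional standard error combines within-model
#' variance and between-model spread
#' (`SE = sum_i w_i * sqrt(se_i^2 + (b_i - b_bar)^2)`), and the 95% CI is
#' normal-based on that SE.
#'
#' @param fits list of `stressor_fit` objects for one response.
#' @param retention_delta retain models with `delta <= retention_delta`
#'   (default 2); ignored if `top_k` is given.
#' @param top_k alternatively, retain the k best models.
#' @return data frame `term`, `estimate`, `se`, `lo95`, `hi95`, `n_models`,
#'   with the selection table attached as attribute `"selection"` and the
#'   retained model labels as `"retained"`.
#' @export
model_average <- function(fits, retention_delta = 2, top_k = NULL) {
  tab <- model_selection(fits)
  retained <- if (!is.null(top_k)) {
    tab$model[seq_len(min(top_k, nrow(tab)))]
  } else {
    tab$model[tab$delta <= retention_delta]
  }
  sub <- tab[tab$model %in% retained, ]
  w <- setNames(sub$weight / sum(sub$weight), sub$model)
  keep <- fits[retained]

  terms <- unique(unlist(lapply(keep, function(f) f$coefficients$term)))
  z <- qnorm(0.975)
  rows <- lapply(terms, function(tm) {
    have <- Filter(function(f) tm %in% f$coefficients$term, keep)
    wi <- w[vapply(have, `[[`, "", "model")]
    wi <- wi / sum(wi)
    b <- vapply(have, function(f) {
      f$coefficients$estimate[f$coefficients$term == tm]
    }, 0)
    s <- vapply(have, function(f) {
      f$coefficients$se[f$coefficients$term == tm]
    }, 0)
    bbar <- sum(wi * b)
    se <- sum(wi * sqrt(s^2 + (b - bbar)^2))
    data.frame(term = tm, estimate = bbar, se = se,
               lo95 = bbar - z * se, hi95 = bbar + z * se,
               n_models = length(have), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "selection") <- tab
  attr(out, "retained") <- retained
  out
}

#' Classify an interaction estimate against its additive expectation
#'
#' The additive expectation (AE) of an interaction is the sum of its component
#' single-stressor effects. A confidence interval containing zero means no
#' interactive effect; one containing the AE means the stressors combine
#' additively; otherwise the interaction is antagonistic when its magnitude
#' falls short of the AE and synergistic when it surpasses it.
#'
#' @param estimate averaged interaction estimate.
#' @param lo95,hi95 its 95% confidence bounds.
#' @param additive_expectation sum of the component single-stressor estimates.
#' @return one of `"no-effect"`, `"additive"`, `"antagonistic"`,
#'   `"synergistic"`.
#' @export
classify_interaction <- function(estimate, lo95, hi95, additive_expectation) {
  stopifnot(is.finite(estimate), is.finite(lo95), is.finite(hi95),
            lo95 <= estimate, estimate <= hi95)
  if (!is.finite(additive_expectation)) {
    stop("additive expectation missing", call. = FALSE)
  }
  if (lo95 <= 0 && 0 <= hi95) return("no-effect")
  if (lo95 <= additive_expectation && additive_expectation <= hi95) {
    return("additive")
  }
  if (abs(estimate) < abs(additive_expectation)) "antagonistic" else "synergistic"
}

#' Averaged effects with interaction classification
#'
#' Runs [model_average()] and, for every interaction term, computes the
#' additive expectation (sum of the averaged estimates of its component main
#' effects) and the [classify_interaction()] label.
#'
#' @inheritParams model_average
#' @return the [model_average()] data frame with `additive_expectation` and
#'   `classification` columns (NA for non-interaction terms).
#' @export
averaged_effects <- function(fits, retention_delta = 2, top_k = NULL) {
  avg <- model_average(fits, retention_delta = retention_delta, top_k = top_k)
  avg$additive_expectation <- NA_real_
  avg$classification <- NA_character_
  for (i in seq_len(nrow(avg))) {
    tm <- avg$term[i]
    if (!grepl(":", tm, fixed = TRUE)) next
    comps <- strsplit(tm, ":", fixed = TRUE)[[1]]
    idx <- match(comps, avg$term)
    if (anyNA(idx)) {
      stop("component estimate missing for interaction ", tm, call. = FALSE)
    }
    ae <- sum(avg$estimate[idx])
    avg$additive_expectation[i] <- ae
    avg$classification[i] <- classify_interaction(avg$estimate[i],
                                                  avg$lo95[i], avg$hi95[i], ae)
  }
  avg
}
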