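# End-to-end orchestration: validate inputs, run every analysis stage in
# order, track record counts so no data is lost silently, and write outputs.

#' Validate an input dataset bundle
#'
#' Schema-checks the tables of one analysis run and resolves their
#' cross-references: families in the abundance table against the trait table,
#' pesticides against the LC50 table, and (site, campaign) samples against
#' the stressor table. Mismatches that the pipeline tolerates (unclassified
#' families, samples without stressor values) are reported as warnings in the
#' returned report; structural defects (missing columns, duplicate keys) are
#' errors.
#'
#' @param abundance long-format abundance data frame.
#' @param stressors per-(site, campaign) stressor data frame.
#' @param traits family trait data frame.
#' @param pesticides optional pesticide concentration data frame.
#' @param lc50 optional LC50 reference data frame.
#' @return list with `ok`, `warnings` (character), `counts` (records per
#'   table), `unmatched_families`, `unmatched_pesticides`,
#'   `samples_without_stressors`.
#' @export
validate_inputs <- function(abundance, stressors, traits, pesticides = NULL,
                            lc50 = NULL) {
  req <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(name, " is missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  req(abundance, c("site", "campaign", "family", "count"), "abundance")
  req(stressors, c("site", "campaign", "pt", "ne", "se"), "stressors")
  req(traits, c("family", "at_risk", "bmwp_score"), "traits")

  dup <- which(duplicated(stressors[, c("site", "campaign")]))
  if (length(dup) > 0) {
    stop("stressors has duplicate (site, campaign) keys at rows: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(traits$family))
  if (length(dup) > 0) {
    stop("traits has duplicate family keys at rows: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(traits$at_risk %in% c(0, 1))) {
    stop("traits$at_risk must be 0/1", call. = FALSE)
  }
  if (!all(traits$bmwp_score %in% 1:9)) {
    stop("traits$bmwp_score must be integers in 1..9", call. = FALSE)
  }

  warnings <- character(0)
  unmatched_fam <- setdiff(unique(abundance$family), traits$family)
  if (length(unmatched_fam) > 0) {
    warnings <- c(warnings,
                  paste0("families without traits (excluded from indices): ",
                         paste(unmatched_fam, collapse = ", ")))
  }
  ab_keys <- unique(paste(abundance$site, abundance$campaign, sep = "\r"))
  st_keys <- paste(stressors$site, stressors$campaign, sep = "\r")
  missing_samples <- setdiff(ab_keys, st_keys)
  if (length(missing_samples) > 0) {
    warnings <- c(warnings,
                  paste0(length(missing_samples),
                         " sample(s) lack stressor values and are excluded ",
                         "from modeling"))
  }
  unmatched_pest <- character(0)
  if (!is.null(pesticides)) {
    req(pesticides, c("site", "campaign", "pesticide", "concentration_ugL",
                      "loq_ugL"), "pesticides")
    if (!is.null(lc50)) {
      req(lc50, c("pesticide", "lc50_ugL"), "lc50")
      unmatched_pest <- setdiff(unique(pesticides$pesticide), lc50$pesticide)
      if (length(unmatched_pest) > 0) {
        warnings <- c(warnings,
                      paste0("pesticides without LC50 (excluded from TU): ",
                             paste(unmatched_pest, collapse = ", ")))
      }
    }
  }
  list(ok = TRUE, warnings = warnings,
       counts = c(abundance = nrow(abundance), stressors = nrow(stressors),
                  traits = nrow(traits),
                  pesticides = if (is.null(pesticides)) 0L else nrow(pesticides)),
       unmatched_families = unmatched_fam,
       unmatched_pesticides = unmatched_pest,
       samples_without_stressors = gsub("\r", "/", missing_samples))
}

#' Configuration of a full pipeline run
#'
#' @param sim a [sim_config()] describing the synthetic dataset (ignored when
#'   `data` is supplied to [run_pipeline()]).
#' @param responses responses to model; any of `"abundance"`, `"richness"`,
#'   `"spear"`, `"bmwp"`.
#' @param retention_delta AICc retention rule for model averaging.
#' @param n_perm permutations for the ordination significance tests.
#' @param per_site_variance allow per-site residual variances in the mixed
#'   models.
#' @param random_intercept named logical vector: include the site random
#'   intercept per response (the richness model conventionally drops it).
#' @param log_abundance model abundance on the `log(x + 1)` scale.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            responses = c("abundance", "richness", "spear",
                                          "bmwp"),
                            retention_delta = 2,
                            n_perm = 999,
                            per_site_variance = TRUE,
                            random_intercept = c(abundance = TRUE,
                                                 richness = FALSE,
                                                 spear = TRUE, bmwp = TRUE),
                            log_abundance = TRUE,
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  responses <- match.arg(responses, several.ok = TRUE)
  structure(list(sim = sim, responses = responses,
                 retention_delta = retention_delta, n_perm = n_perm,
                 per_site_variance = per_site_variance,
                 random_intercept = random_intercept,
                 log_abundance = log_abundance, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full multi-stressor analysis
#'
#' Executes the stages in analysis order: (1) simulate or ingest the dataset;
#' (2) recover per-sample pesticide toxicity (TU_max) from concentrations via
#' [tu_max()]; (3) compute community summaries and biotic indices; (4) screen
#' predictors for collinearity; (5) fit, select and average the candidate
#' mixed models per response and classify interactions; (6) partition
#' community-composition variance among stressor sets by Hellinger-RDA.
#' Rerunning with the same configuration reproduces every numeric output
#' exactly.
#'
#' @param config a [pipeline_config()].
#' @param data optional list with elements `abundance`, `stressors`, `traits`
#'   (and optionally `pesticides`, `lc50`) to analyse instead of simulating.
#' @return a `run_report` list: configuration echo, validation report, stage
#'   record counts, predictor screen, per-response selection tables and
#'   averaged effects, variance partition, and convergence notes.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = config, stages = character(0))

  if (is.null(data)) {
    sim <- config$sim
    stressors <- generate_stressors(sim)
    traits <- make_trait_table(sim$n_families, sim$frac_at_risk,
                               seed = sim$seed)
    abundance <- generate_community(stressors, traits, sim)
    lc50 <- read.csv(system.file("extdata", "lc50_daphnia_synthetic.csv",
                                 package = "streamstress"))
    targets <- data.frame(site = stressors$site, campaign = stressors$campaign,
                          target_tu = stressors$pt)
    pesticides <- generate_pesticides(targets, lc50, seed = sim$seed + 2L)
    data <- list(abundance = abundance, stressors = stressors,
                 traits = traits, pesticides = pesticides, lc50 = lc50)
    report$ground_truth <- attr(abundance, "ground_truth")
    report$stages <- c(report$stages, "simulate")
  }

  report$validation <- validate_inputs(data$abundance, data$stressors,
                                       data$traits, data$pesticides,
                                       data$lc50)
  report$stages <- c(report$stages, "validate")

  # toxic units: recompute pt from concentrations when they are available
  if (!is.null(data$pesticides) && !is.null(data$lc50)) {
    tu <- tu_max(data$pesticides, data$lc50)
    report$tu <- tu
    st <- data$stressors
    key_st <- paste(st$site, st$campaign, sep = "\r")
    key_tu <- paste(tu$site, tu$campaign, sep = "\r")
    recovered <- tu$tu_max[match(key_st, key_tu)]
    st$pt <- ifelse(is.na(recovered), st$pt, recovered)
    data$stressors <- st
    report$stages <- c(report$stages, "toxic_units")
  }

  indices <- suppressWarnings(community_indices(data$abundance, data$traits))
  report$indices_n <- nrow(indices)
  report$stages <- c(report$stages, "indices")

  merged <- merge(indices, data$stressors, by = c("site", "campaign"))
  report$modeled_samples <- nrow(merged)
  report$dropped_samples <- nrow(indices) - nrow(merged)
  if (config$log_abundance) merged$abundance <- log(merged$abundance + 1)

  report$screen <- screen_predictors(
    merged, predictors = intersect(c("pt", "ne", "se", "temp"), names(merged)))
  report$stages <- c(report$stages, "screen")

  report$models <- list()
  for (resp in config$responses) {
    ri <- isTRUE(config$random_intercept[[resp]])
    fits <- fit_candidates(resp, merged, random_intercept = ri,
                           per_site_variance = config$per_site_variance)
    conv <- vapply(fits, `[[`, TRUE, "converged")
    entry <- list(converged = conv)
    if (any(conv)) {
      entry$selection <- model_selection(fits)
      entry$effects <- averaged_effects(fits,
                                        retention_delta =
                                          config$retention_delta)
    }
    report$models[[resp]] <- entry
  }
  report$stages <- c(report$stages, "models")

  ycomm <- hellinger(site_community_matrix(data$abundance))
  num_cols <- intersect(c("pt", "ne", "se", "temp"), names(data$stressors))
  site_str <- aggregate(data$stressors[num_cols],
                        by = list(site = data$stressors$site), FUN = mean)
  site_str <- site_str[match(rownames(ycomm), site_str$site), ]
  ha <- site_str[, intersect(c("se", "temp"), num_cols), drop = FALSE]
  report$variance_partition <- variance_partition(
    ycomm, pt = site_str$pt, ne = site_str$ne, ha = ha,
    n_perm = config$n_perm, seed = config$seed + 10L)
  report$stages <- c(report$stages, "ordination")

  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("streamstress run:", paste(x$stages, collapse = " -> "), "\n")
  cat(sprintf("  samples modeled %d (dropped %d)\n",
              x$modeled_samples, x$dropped_samples))
  for (resp in names(x$models)) {
    m <- x$models[[resp]]
    if (!is.null(m$selection)) {
      cat(sprintf("  %s: best model %s (w = %.3f)\n", resp,
                  m$selection$model[1], m$selection$weight[1]))
    } else {
      cat(sprintf("  %s: no converged model\n", resp))
    }
  }
  cat("  variance partition:\n")
  print(x$variance_partition$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write the artifacts of a pipeline run
#'
#' Writes the model-selection tables, averaged effects, variance-partition
#' table and a JSON run summary (configuration echo, stage list, counts,
#' warnings) under `dir`.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (resp in names(report$models)) {
    m <- report$models[[resp]]
    if (is.null(m$selection)) next
    f1 <- file.path(dir, paste0("selection_", resp, ".csv"))
    write.csv(m$selection, f1, row.names = FALSE)
    f2 <- file.path(dir, paste0("effects_", resp, ".csv"))
    write.csv(m$effects, f2, row.names = FALSE)
    files <- c(files, f1, f2)
  }
  f3 <- file.path(dir, "variance_partition.csv")
  write.csv(report$variance_partition$table, f3, row.names = FALSE)
  files <- c(files, f3)
  summary <- list(
    stages = report$stages,
    seed = report$config$seed,
    n_perm = report$config$n_perm,
    retention_delta = report$config$retention_delta,
    responses = report$config$responses,
    modeled_samples = report$modeled_samples,
    dropped_samples = report$dropped_samples,
    warnings = report$validation$warnings,
    converged = lapply(report$models, `[[`, "converged"))
  f4 <- file.path(dir, "run_summary.json")
  jsonlite::write_json(summary, f4, auto_unbox = TRUE, digits = NA)
  files <- c(files, f4)
  invisible(files)
}
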