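# Pesticide toxic units relative to Daphnia magna acute LC50 values.

#' Toxic unit of a single pesticide concentration
#'
#' The toxic unit is `log10(C / LC50)`: 0 means the measured concentration
#' equals the 48-h acute median lethal concentration for *Daphnia magna*, each
#' decade below the LC50 subtracts one unit.
#'
#' @param concentration measured concentration (micrograms per litre, > 0).
#' @param lc50 reference LC50 (micrograms per litre, > 0).
#' @param base logarithm base; 10 is the toxic-unit convention.
#' @return numeric vector of toxic units (dimensionless, log scale).
#' @export
#' @examples
#' toxic_unit(1, 1)      # 0
#' toxic_unit(0.1, 1)    # -1
toxic_unit <- function(concentration, lc50, base = 10) {
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentration must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(lc50)) || any(lc50 <= 0)) {
    stop("lc50 must be finite and > 0", call. = FALSE)
  }
  log(concentration / lc50, base = base)
}

#' Maximum toxic unit per sample
#'
#' Joins measured concentrations to an LC50 reference table and returns, per
#' sample (or per site when `aggregate = "site"`), the maximum toxic unit over
#' all usable pesticides. Measurements below their limit of quantification are
#' excluded, as are pesticides with no LC50 entry (with a warning naming
#' them). Samples with no usable measurement are flagged `no_detect` and carry
#' an `NA` toxic unit rather than an error.
#'
#' @param measurements data frame with columns `site`, `campaign`,
#'   `pesticide`, `concentration_ugL`, `loq_ugL`; a missing concentration or
#'   one below `loq_ugL` marks a below-LOQ measurement.
#' @param lc50_table data frame `pesticide`, `lc50_ugL` with unique pesticide
#'   keys and strictly positive LC50 values.
#' @param aggregate `"campaign"` (default) computes TU_max per
#'   (site, campaign); `"site"` pools all campaigns of a site first.
#' @param base logarithm base passed to [toxic_unit()].
#' @return data frame with the grouping columns plus `tu_max`, `n_used`,
#'   `no_detect`.
#' @export
tu_max <- function(measurements, lc50_table, aggregate = c("campaign", "site"),
                   base = 10) {
  aggregate <- match.arg(aggregate)
  need <- c("site", "campaign", "pesticide", "concentration_ugL", "loq_ugL")
  if (!all(need %in% names(measurements))) {
    stop("measurements must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(lc50_table$pesticide)) {
    stop("lc50_table has duplicate pesticide keys", call. = FALSE)
  }
  if (any(lc50_table$lc50_ugL <= 0)) {
    stop("lc50_table values must be > 0", call. = FALSE)
  }
  m <- measurements
  quantified <- !is.na(m$concentration_ugL) &
    m$concentration_ugL >= m$loq_ugL
  m <- m[quantified, , drop = FALSE]

  unmatched <- setdiff(unique(m$pesticide), lc50_table$pesticide)
  if (length(unmatched) > 0) {
    warning("no LC50 value for: ", paste(unmatched, collapse = ", "),
            "; these measurements are excluded", call. = FALSE)
    m <- m[!(m$pesticide %in% unmatched), , drop = FALSE]
  }
  m$lc50 <- lc50_table$lc50_ugL[match(m$pesticide, lc50_table$pesticide)]
  m$tu <- if (nrow(m) > 0) {
    toxic_unit(m$concentration_ugL, m$lc50, base = base)
  } else numeric(0)

  keys <- if (aggregate == "campaign") c("site", "campaign") else "site"
  groups <- unique(measurements[, keys, drop = FALSE])
  groups <- groups[do.call(order, groups), , drop = FALSE]
  gk <- do.call(paste, c(groups, sep = "\r"))
  mk <- do.call(paste, c(m[, keys, drop = FALSE], sep = "\r"))
  out <- groups
  out$tu_max <- NA_real_
  out$n_used <- 0L
  for (i in seq_along(gk)) {
    tui <- m$tu[mk == gk[i]]
    out$n_used[i] <- length(tui)
    if (length(tui) > 0) out$tu_max[i] <- max(tui)
  }
  out$no_detect <- out$n_used == 0L
  rownames(out) <- NULL
  out
}
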