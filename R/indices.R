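# Biotic indices: SPEAR (pesticides) and BMWP family scores, plus the basic
# community summaries (total abundance, family richness).

#' SPEAR pesticides index of one sample
#'
#' The log-abundance-weighted fraction of taxa classified as at risk from
#' pesticides, as a percentage:
#' `100 * sum(log(x_i + 1) * y_i) / sum(log(x_i + 1))`, where the sums run
#' over taxa present in the sample (`x_i > 0`) and `y_i` is the binary
#' at-risk trait. The ratio is invariant to the logarithm base. An empty
#' sample returns 0 with a warning.
#'
#' @param x integer abundances (one value per taxon, >= 0).
#' @param at_risk binary at-risk classification, same length as `x`; `NA`
#'   entries (unclassified taxa) are excluded with a warning.
#' @param base logarithm base (does not affect the result; exposed so the
#'   invariance can be demonstrated).
#' @param weighting `"log"` uses the `log(x + 1)` abundance weight;
#'   `"log4x"` uses the `log(4 x + 1)` variant found in parts of the SPEAR
#'   literature.
#' @return SPEAR value in percent, within `[0, 100]`.
#' @export
#' @examples
#' spear(c(9, 99), c(1, 0))   # 100 * 1 / (1 + 2) = 33.33
spear <- function(x, at_risk, base = 10, weighting = c("log", "log4x")) {
  weighting <- match.arg(weighting)
  stopifnot(length(x) == length(at_risk))
  if (any(x < 0, na.rm = TRUE)) stop("abundances must be >= 0", call. = FALSE)
  keep <- !is.na(x) & x > 0
  if (any(keep & is.na(at_risk))) {
    warning("taxa without an at-risk classification excluded from SPEAR",
            call. = FALSE)
    keep <- keep & !is.na(at_risk)
  }
  if (!any(keep)) {
    warning("empty sample: SPEAR set to 0", call. = FALSE)
    return(0)
  }
  x <- x[keep]
  y <- at_risk[keep]
  w <- switch(weighting,
              log = log(x + 1, base = base),
              log4x = log(4 * x + 1, base = base))
  100 * sum(w * y) / sum(w)
}

#' BMWP score of one sample
#'
#' The sum of per-family tolerance scores (1 = most tolerant, 9 = most
#' sensitive in the Panama-adapted table) over the distinct families present
#' (`x_i > 0`). Families without a score are excluded with a warning.
#'
#' @param x integer abundances, one per family.
#' @param scores integer tolerance scores in 1--9, same length as `x`; `NA`
#'   marks an unscored family.
#' @return non-negative integer score (0 for an empty sample).
#' @export
#' @examples
#' bmwp(c(1, 5, 0, 2), c(3, 7, 9, 9))  # 3 + 7 + 9 = 19
bmwp <- function(x, scores) {
  stopifnot(length(x) == length(scores))
  if (any(x < 0, na.rm = TRUE)) stop("abundances must be >= 0", call. = FALSE)
  ok <- !is.na(scores)
  if (!all(ok | !(x > 0), na.rm = TRUE)) {
    warning("families without a BMWP score excluded", call. = FALSE)
  }
  present <- !is.na(x) & x > 0 & ok
  if (any(scores[present] < 1 | scores[present] > 9)) {
    stop("BMWP scores must lie in 1..9", call. = FALSE)
  }
  sum(scores[present])
}

#' Per-sample community summaries and biotic indices
#'
#' Aggregates a long-format abundance table to one record per (site, campaign):
#' total abundance, family richness, SPEAR and BMWP. Duplicate
#' (site, campaign, family) rows are summed before any computation. Families
#' missing from the trait table still count toward abundance and richness but
#' are excluded from both indices (reported via the `"unmatched_families"`
#' attribute and a warning).
#'
#' @param abundance long-format data frame `site`, `campaign`, `family`,
#'   `count`.
#' @param traits data frame `family`, `at_risk`, `bmwp_score`.
#' @param ... passed to [spear()] (e.g. `weighting`).
#' @return data frame `site`, `campaign`, `abundance`, `richness`, `spear`,
#'   `bmwp`.
#' @export
community_indices <- function(abundance, traits, ...) {
  need <- c("site", "campaign", "family", "count")
  if (!all(need %in% names(abundance))) {
    stop("abundance must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(abundance$count < 0, na.rm = TRUE)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  agg <- aggregate(count ~ site + campaign + family, data = abundance,
                   FUN = sum)
  unmatched <- setdiff(unique(agg$family[agg$count > 0]), traits$family)
  if (length(unmatched) > 0) {
    warning("families absent from the trait table (excluded from indices): ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  at_risk <- traits$at_risk[match(agg$family, traits$family)]
  score <- traits$bmwp_score[match(agg$family, traits$family)]

  keys <- unique(agg[, c("site", "campaign")])
  keys <- keys[order(keys$site, keys$campaign), , drop = FALSE]
  kk <- paste(agg$site, agg$campaign, sep = "\r")
  out <- keys
  out$abundance <- NA_integer_
  out$richness <- NA_integer_
  out$spear <- NA_real_
  out$bmwp <- NA_integer_
  gid <- paste(keys$site, keys$campaign, sep = "\r")
  for (i in seq_along(gid)) {
    sel <- kk == gid[i]
    x <- agg$count[sel]
    out$abundance[i] <- sum(x)
    out$richness[i] <- sum(x > 0)
    known <- !is.na(at_risk[sel])
    out$spear[i] <- if (any(x[known] > 0)) {
      spear(x[known], at_risk[sel][known], ...)
    } else 0
    out$bmwp[i] <- suppressWarnings(bmwp(x, score[sel]))
  }
  rownames(out) <- NULL
  attr(out, "unmatched_families") <- unmatched
  out
}
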