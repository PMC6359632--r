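#' Abundance tiers and tier ordering
#'
#' Proteins are binned by mean spectral count into abundance tiers that
#' decide which significance cutoffs apply: absent (SC = 0), very_low
#' (0 < SC < 8), low (8 <= SC < 20), medium (20 <= SC < 80), high
#' (SC >= 80). Boundaries are half-open; a mean SC of exactly 80 is high.
#'
#' @format NULL
#' @name abundance-tiers
NULL

tier_levels <- c("absent", "very_low", "low", "medium", "high")

#' Classify mean spectral counts into abundance tiers
#'
#' @param mean_sc Numeric vector of non-negative mean spectral counts.
#' @return An ordered factor with levels
#'   `absent < very_low < low < medium < high`.
#' @examples
#' classify_abundance(c(0, 1.7, 18, 34, 2486.7))
#' @export
classify_abundance <- function(mean_sc) {
  if (any(mean_sc < 0, na.rm = TRUE)) {
    abort_input("mean spectral counts must be non-negative")
  }
  f <- cut(mean_sc, breaks = c(-Inf, 0, 8, 20, 80, Inf),
           labels = tier_levels, right = FALSE,
           include.lowest = TRUE, ordered_result = TRUE)
  f[!is.na(mean_sc) & mean_sc == 0] <- "absent"
  f
}

#' Governing tier for a two-group comparison
#'
#' When the two groups fall in different abundance tiers the *higher* tier's
#' cutoffs govern the call. Any strongly differential protein necessarily
#' straddles tiers, and judging it by the lower (noisier) tier's stricter
#' fold cutoff would penalize exactly the largest effects.
#'
#' @param tier_ref,tier_cmp Tiers as returned by [classify_abundance()];
#'   neither may be `absent` (proteins absent from a group are resolved to
#'   unique/absent calls before thresholds apply).
#' @return The elementwise maximum tier, as an ordered factor.
#' @export
governing_tier <- function(tier_ref, tier_cmp) {
  tier_ref <- as_tier(tier_ref)
  tier_cmp <- as_tier(tier_cmp)
  if (any(tier_ref == "absent" | tier_cmp == "absent", na.rm = TRUE)) {
    abort_input("governing tier is undefined for absent proteins")
  }
  idx <- pmax(as.integer(tier_ref), as.integer(tier_cmp))
  factor(tier_levels[idx], levels = tier_levels, ordered = TRUE)
}

as_tier <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (!all(x %in% tier_levels, na.rm = TRUE)) {
    abort_input("unknown tier value")
  }
  factor(x, levels = tier_levels, ordered = TRUE)
}

#' Tier-specific significance thresholds
#'
#' Each abundance tier pairs a p-value ceiling with NSAF-ratio cutoffs:
#' sparse (very-low / low abundance) proteins must clear a stringent p and a
#' 2.5-fold change, while well-sampled proteins face p <= 0.05 with
#' progressively smaller fold cutoffs (2.0 for medium, 1.5 for high). The
#' underexpression cutoff is the reciprocal of the overexpression cutoff in
#' every tier — the high tier's is kept as exactly 2/3 rather than the
#' rounded 0.67 so that swapping reference and comparison groups maps every
#' overexpressed call to an underexpressed one and vice versa.
#'
#' @param p_max Named numeric vector of p-value ceilings per tier.
#' @param oe_ratio_min Named numeric vector of minimum NSAF ratios for an
#'   overexpressed call per tier. The underexpression ceiling is always
#'   `1 / oe_ratio_min`.
#' @return A tibble with columns `tier`, `p_max`, `oe_ratio_min`,
#'   `ue_ratio_max`.
#' @export
tier_thresholds <- function(p_max = c(very_low = 0.001, low = 0.01,
                                      medium = 0.05, high = 0.05),
                            oe_ratio_min = c(very_low = 2.5, low = 2.5,
                                             medium = 2.0, high = 1.5)) {
  tiers <- setdiff(tier_levels, "absent")
  if (!setequal(names(p_max), tiers) || !setequal(names(oe_ratio_min), tiers)) {
    abort_input("thresholds must name exactly the tiers ",
                paste(tiers, collapse = ", "))
  }
  if (any(p_max <= 0 | p_max > 1) || any(oe_ratio_min <= 1)) {
    abort_input("p_max must lie in (0, 1] and oe_ratio_min must exceed 1")
  }
  oe <- unname(oe_ratio_min[tiers])
  tibble::tibble(
    tier = factor(tiers, levels = tier_levels, ordered = TRUE),
    p_max = unname(p_max[tiers]),
    oe_ratio_min = oe,
    ue_ratio_max = 1 / oe
  )
}
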