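#' A-priori thresholds for the ascent decision matrix
#'
#' Collects every threshold the decision matrix compares against: the three
#' invasion-front trait means (a fish with above-front-mean traits is deemed
#' to "intend" to ascend), the flow limit Ucrit must exceed, the pool-gap
#' distance the traversable distance must exceed, and the compensation rule
#' (how many of the three traits must exceed their means; default 2 of 3).
#' All comparisons downstream are strict: a value exactly equal to its
#' threshold does not pass.
#'
#' @param boldness_mean,activity_mean,asociability_mean Trait thresholds
#'   (index units); defaults are the printed invasion-front means
#'   [front_trait_means()].
#' @param flow_limit_m_s Flow velocity Ucrit must exceed, m/s (> 0).
#' @param distance_limit_m Pool gap the traversable distance must exceed,
#'   m (> 0).
#' @param min_traits_above How many traits must strictly exceed their means
#'   (1, 2, or 3).
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(boldness_mean = 1.13,
                          activity_mean = 1.17,
                          asociability_mean = 0.95,
                          flow_limit_m_s = 0.5,
                          distance_limit_m = 4.54,
                          min_traits_above = 2L) {
  assert_scalar_number(flow_limit_m_s, "flow_limit_m_s", positive = TRUE)
  assert_scalar_number(distance_limit_m, "distance_limit_m", positive = TRUE)
  if (!min_traits_above %in% 1:3) {
    abort_input("`min_traits_above` must be 1, 2, or 3")
  }
  structure(
    list(boldness_mean = boldness_mean, activity_mean = activity_mean,
         asociability_mean = asociability_mean,
         flow_limit_m_s = flow_limit_m_s,
         distance_limit_m = distance_limit_m,
         min_traits_above = as.integer(min_traits_above)),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Ascent decision thresholds\n")
  cat(sprintf("  trait means: boldness %g, activity %g, asociability %g (%d of 3 must exceed)\n",
              x$boldness_mean, x$activity_mean, x$asociability_mean,
              x$min_traits_above))
  cat(sprintf("  flow limit %g m/s, pool-gap limit %g m\n",
              x$flow_limit_m_s, x$distance_limit_m))
  invisible(x)
}

#' Trait thresholds from an invasion-front cohort
#'
#' The personality thresholds are defined as the arithmetic trait means of
#' individuals sampled at newly colonized invasion-front sites — the trait
#' profile of a "good disperser". Non-trait thresholds (flow and distance
#' limits) are taken from `base`.
#'
#' @param front_cohort Data.frame with columns `boldness`, `activity`,
#'   `asociability` (nonempty; `NA`s removed per trait).
#' @param base A [threshold_set()] providing the non-trait fields.
#' @return A [threshold_set()] with trait means replaced by cohort means.
#' @export
compute_thresholds <- function(front_cohort, base = threshold_set()) {
  if (!is.data.frame(front_cohort) || nrow(front_cohort) == 0L) {
    abort_input("`front_cohort` must be a nonempty data.frame")
  }
  needed <- c("boldness", "activity", "asociability")
  if (!all(needed %in% names(front_cohort))) {
    abort_input("`front_cohort` must have columns boldness, activity, asociability")
  }
  threshold_set(
    boldness_mean = mean(front_cohort$boldness, na.rm = TRUE),
    activity_mean = mean(front_cohort$activity, na.rm = TRUE),
    asociability_mean = mean(front_cohort$asociability, na.rm = TRUE),
    flow_limit_m_s = base$flow_limit_m_s,
    distance_limit_m = base$distance_limit_m,
    min_traits_above = base$min_traits_above
  )
}

#' Compensatory personality decision
#'
#' Counts how many of the three traits strictly exceed their invasion-front
#' mean thresholds and returns 1 iff the count reaches `min_traits_above`
#' (default 2 of 3). The rule is compensatory and unweighted: any two
#' above-average traits compensate for a below-average third, and no trait
#' counts more than another.
#'
#' @param boldness,activity,asociability Trait values of one fish.
#' @param thresholds A [threshold_set()].
#' @return List with `decision` (0/1) and `traits_above` (0–3); `decision`
#'   is `NA` (with `exclusion_reason`) if any trait is missing.
#' @examples
#' decision_personality(1.71, 1.76, 0.47)  # 2 traits above -> decision 1
#' @export
decision_personality <- function(boldness, activity, asociability,
                                 thresholds = threshold_set()) {
  stopifnot(inherits(thresholds, "threshold_set"))
  vals <- c(boldness, activity, asociability)
  if (any(is.na(vals))) {
    return(structure(list(decision = NA_integer_, traits_above = NA_integer_),
                     exclusion_reason = "missing trait value"))
  }
  above <- sum(boldness > thresholds$boldness_mean,
               activity > thresholds$activity_mean,
               asociability > thresholds$asociability_mean)
  list(decision = as.integer(above >= thresholds$min_traits_above),
       traits_above = as.integer(above))
}

#' Run the ascent decision matrix over a cohort
#'
#' Applies the three a-priori criteria to every fish and records a full audit
#' trace:
#'
#' 1. swimming: `ucrit > flow limit`, where the flow limit is the profile's
#'    maximum velocity at `flow_position` (near-bottom by default — the
#'    realistic limit for a bottom-dwelling fish) unless `thresholds`
#'    overrides it via `use_threshold_flow_limit = TRUE`;
#' 2. endurance: traversable distance (Ucrit as ground speed for the
#'    endurance time at the limiting flow) `> ` maximum pool spacing;
#' 3. personality: the compensatory rule of [decision_personality()].
#'
#' The overall outcome is the conjunction of the three. Fish with missing
#' traits keep their row, flagged excluded with a reason; nothing is silently
#' dropped.
#'
#' @param cohort Data.frame with columns `fish_id`, `tl_cm`, `boldness`,
#'   `activity`, `asociability`.
#' @param profile A [flow_profile()].
#' @param swim A [swim_model()].
#' @param thresholds A [threshold_set()]. Trait means and `min_traits_above`
#'   are always taken from here.
#' @param flow_position Measuring position whose maximum defines the limiting
#'   flow velocity.
#' @param use_threshold_flow_limit If `TRUE`, compare against
#'   `thresholds$flow_limit_m_s` instead of the profile maximum. Default
#'   `FALSE`: the profile's own computed maximum is authoritative.
#' @param subtract_flow If `TRUE`, ground speed is `ucrit - flow` for the
#'   distance computation (sensitivity variant); default treats Ucrit as
#'   ground speed.
#' @return A data.frame of class `decision_traces`, one row per fish:
#'   `fish_id`, `tl_cm`, the three traits, `ucrit_m_s`, `flow_limit_m_s`,
#'   `endurance_min`, `distance_m`, `distance_limit_m`, `decision_swim`,
#'   `decision_endurance`, `traits_above`, `decision_personality`, `overall`,
#'   `excluded`, `exclusion_reason`.
#' @export
run_decision_matrix <- function(cohort, profile, swim = swim_model(),
                                thresholds = threshold_set(),
                                flow_position = "near_bottom",
                                use_threshold_flow_limit = FALSE,
                                subtract_flow = FALSE) {
  stopifnot(inherits(profile, "flow_profile"), inherits(swim, "swim_model"),
            inherits(thresholds, "threshold_set"))
  needed <- c("fish_id", "tl_cm", "boldness", "activity", "asociability")
  if (!all(needed %in% names(cohort))) {
    abort_input("cohort must have columns ", paste(needed, collapse = ", "))
  }
  if (any(!is.na(cohort$tl_cm) & cohort$tl_cm <= 0)) {
    abort_input("all `tl_cm` must be > 0")
  }
  flow_limit <- if (use_threshold_flow_limit) {
    thresholds$flow_limit_m_s
  } else {
    max_velocity(profile, flow_position)
  }
  distance_limit <- max_pool_spacing(profile)

  ucrit <- ucrit_from_length(cohort$tl_cm, swim)
  endur <- endurance_minutes(flow_limit * 100, cohort$tl_cm, swim)
  dist <- traversable_distance(
    ucrit, endur,
    subtract_flow_m_s = if (subtract_flow) flow_limit else NULL
  )

  pers <- lapply(seq_len(nrow(cohort)), function(i) {
    decision_personality(cohort$boldness[i], cohort$activity[i],
                         cohort$asociability[i], thresholds)
  })
  traits_above <- vapply(pers, function(p) p$traits_above, integer(1))
  dec_pers <- vapply(pers, function(p) p$decision, integer(1))
  excl_reason <- vapply(pers, function(p) {
    r <- attr(p, "exclusion_reason")
    if (is.null(r)) NA_character_ else r
  }, character(1))

  dec_swim <- as.integer(ucrit > flow_limit)
  dec_endur <- as.integer(dist > distance_limit)
  overall <- dec_swim * dec_endur * dec_pers

  out <- data.frame(
    fish_id = cohort$fish_id, tl_cm = cohort$tl_cm,
    boldness = cohort$boldness, activity = cohort$activity,
    asociability = cohort$asociability,
    ucrit_m_s = ucrit, flow_limit_m_s = flow_limit,
    endurance_min = endur, distance_m = dist,
    distance_limit_m = distance_limit,
    decision_swim = dec_swim, decision_endurance = dec_endur,
    traits_above = traits_above, decision_personality = dec_pers,
    overall = overall,
    excluded = !is.na(excl_reason),
    exclusion_reason = excl_reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("decision_traces", "data.frame")
  attr(out, "thresholds") <- thresholds
  out
}

#' @export
print.decision_traces <- function(x, ...) {
  n <- nrow(x)
  n_excl <- sum(x$excluded)
  ok <- !x$excluded
  cat(sprintf("Decision matrix traces: %d fish (%d excluded)\n", n, n_excl))
  if (any(ok)) {
    cat(sprintf("  ascents: %d of %d (%.1f%%)\n",
                sum(x$overall[ok]), sum(ok),
                100 * mean(x$overall[ok])))
    cat(sprintf("  gates passed: swim %d, endurance %d, personality %d\n",
                sum(x$decision_swim[ok]), sum(x$decision_endurance[ok]),
                sum(x$decision_personality[ok])))
  }
  invisible(x)
}

#' @export
summary.decision_traces <- function(object, ...) {
  ok <- !object$excluded
  out <- list(
    n = nrow(object),
    n_excluded = sum(object$excluded),
    n_success = sum(object$overall[ok]),
    fraction_success = if (any(ok)) mean(object$overall[ok]) else NA_real_,
    flow_limit_m_s = object$flow_limit_m_s[1],
    distance_limit_m = object$distance_limit_m[1]
  )
  class(out) <- "summary.decision_traces"
  out
}

#' @export
print.summary.decision_traces <- function(x, ...) {
  cat(sprintf("n = %d (excluded %d); successes %d (fraction %.3f)\n",
              x$n, x$n_excluded, x$n_success, x$fraction_success))
  cat(sprintf("flow limit %.3g m/s; pool-gap limit %.3g m\n",
              x$flow_limit_m_s, x$distance_limit_m))
  invisible(x)
}

#' Write decision traces to CSV and a JSON summary
#' @param traces A `decision_traces` data.frame.
#' @param path Trace CSV path.
#' @param summary_path Optional JSON path receiving `n`, `n_success`,
#'   `fraction`.
#' @return `path`, invisibly.
#' @export
write_decision_traces_csv <- function(traces, path, summary_path = NULL) {
  write.csv(as.data.frame(traces), path, row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- summary(traces)
    jsonlite::write_json(
      list(n = s$n, n_excluded = s$n_excluded, n_success = s$n_success,
           fraction = s$fraction_success),
      summary_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
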