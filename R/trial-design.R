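# Stepped-wedge evaluation-plan computations: analyzable sample size,
# Cohen's d with its large-sample precision, NNT from event rates, the
# centering transforms that prepare the multilevel analysis table, and a
# Monte-Carlo check of the design's effect-size precision.
#
# The analyzable-n arithmetic reconstructs the design's accounting: groups
# enter the rollout at a fixed lag, every group contributes one measurement
# and one group contributes both baseline and post measurement, so with
# g groups of size s, u dual-contribution groups and retention r the
# analyzable sample is floor(s * (g + u) * r) — 40 * (5 + 1) * 0.8 = 192 at
# the defaults.

#' Stepped-wedge design specification
#'
#' @param n_groups number of intervention groups (rollout waves).
#' @param group_size participants recruited per group.
#' @param lag_weeks time lag between successive group starts.
#' @param retention anticipated retention rate, in (0, 1].
#' @param dual_contribution_groups groups contributing data to both the
#'   baseline and the post-intervention measurement; fewer than `n_groups`.
#' @return a list of class `design_spec`.
#' @export
#' @examples
#' design_spec() # the default five-group rollout
design_spec <- function(n_groups = 5L, group_size = 40L, lag_weeks = 7L,
                        retention = 0.8, dual_contribution_groups = 1L) {
  stopifnot(
    n_groups >= 1L, group_size >= 1L, lag_weeks >= 1L,
    retention > 0, retention <= 1,
    dual_contribution_groups >= 0L, dual_contribution_groups < n_groups
  )
  structure(
    list(
      n_groups = as.integer(n_groups),
      group_size = as.integer(group_size),
      lag_weeks = as.integer(lag_weeks),
      retention = retention,
      dual_contribution_groups = as.integer(dual_contribution_groups)
    ),
    class = "design_spec"
  )
}

#' Analyzable sample size of the rollout
#'
#' Each group contributes one measurement occasion, plus one extra occasion
#' per dual-contribution group; attrition scales the total:
#' `floor(group_size * (n_groups + dual_contribution_groups) * retention)`.
#'
#' @param design a [design_spec()].
#' @return integer count of analyzable observations.
#' @export
#' @examples
#' analyzable_sample_size(design_spec()) # 192
analyzable_sample_size <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  as.integer(floor(
    design$group_size *
      (design$n_groups + design$dual_contribution_groups) *
      design$retention
  ))
}

#' Risk difference and number needed to treat
#'
#' Compares the control event rate (proportion meeting the program goal at
#' baseline) with an experimental event rate. NNT = 1 / (eer - cer) is the
#' number of people who must receive the intervention for one additional
#' person to meet the goal; it is undefined (flagged, `NA`) when the
#' experimental rate does not exceed the control rate.
#'
#' @param cer,eer event rates in \[0, 1\].
#' @return a one-row tibble: `cer`, `eer`, `risk_difference`, `nnt`,
#'   `nnt_defined`.
#' @export
#' @examples
#' nnt_from_rates(0.261, 0.561)
nnt_from_rates <- function(cer, eer) {
  if (!is.numeric(cer) || !is.numeric(eer) ||
    cer < 0 || cer > 1 || eer < 0 || eer > 1) {
    stop("event rates must lie in [0, 1]", call. = FALSE)
  }
  rd <- eer - cer
  tibble::tibble(
    cer = cer, eer = eer,
    risk_difference = rd,
    nnt = if (rd > 0) 1 / rd else NA_real_,
    nnt_defined = rd > 0
  )
}

#' Cohen's d with large-sample precision
#'
#' Standardized mean difference `(mean(b) - mean(a)) / s_p` with the pooled
#' standard deviation `s_p^2 = ((n1-1) s_a^2 + (n2-1) s_b^2) / (n1+n2-2)`.
#' The standard error uses the usual large-sample approximation
#' `se^2 = (n1+n2)/(n1 n2) + d^2 / (2 (n1+n2))` and the 95% interval is
#' `d +/- 1.96 se`.
#'
#' @param group_a,group_b numeric outcome vectors (each of length >= 2).
#' @return a one-row tibble: `cohens_d`, `se`, `ci_low`, `ci_high`,
#'   `ci_halfwidth`.
#' @export
cohens_d <- function(group_a, group_b) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  stopifnot(n1 >= 2L, n2 >= 2L)
  sp2 <- ((n1 - 1) * var(group_a) + (n2 - 1) * var(group_b)) / (n1 + n2 - 2)
  if (sp2 <= 0) {
    stop("zero pooled variance; Cohen's d is undefined", call. = FALSE)
  }
  d <- (mean(group_b) - mean(group_a)) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- qnorm(0.975)
  tibble::tibble(
    cohens_d = d, se = se,
    ci_low = d - z * se, ci_high = d + z * se,
    ci_halfwidth = z * se
  )
}

#' Center outcomes around baseline company means (between-subject analysis)
#'
#' Prepares the between-subject comparison table: each participant's outcome
#' minus their company's baseline mean, with the calendar week as the
#' nesting label. No model is fitted here.
#'
#' @param data a tibble with columns `participant_id`, `company`, `week_id`
#'   and `value`.
#' @param baseline_means a tibble with columns `company` and
#'   `baseline_mean`, one row per company.
#' @return `data` with added `value_centered` and `nesting` (= `week_id`).
#' @export
center_between <- function(data, baseline_means) {
  stopifnot(
    all(c("participant_id", "company", "week_id", "value") %in% names(data)),
    all(c("company", "baseline_mean") %in% names(baseline_means)),
    !anyDuplicated(baseline_means$company)
  )
  idx <- match(data$company, baseline_means$company)
  if (anyNA(idx)) {
    miss <- data$participant_id[which(is.na(idx))[1L]]
    stop("no baseline company mean for participant ", miss, call. = FALSE)
  }
  data$value_centered <- data$value - baseline_means$baseline_mean[idx]
  data$nesting <- data$week_id
  data
}

#' Center outcomes around calendar-week means (within-subject analysis)
#'
#' Prepares the within-subject comparison table: each observation minus its
#' calendar week's mean, with the participant as the nesting label. When
#' `week_means` is `NULL` the means are computed from `data` itself (so the
#' week means of the centered values are exactly zero).
#'
#' @param data a tibble with columns `participant_id`, `week_id`, `value`.
#' @param week_means optional tibble with columns `week_id` and `week_mean`.
#' @return `data` with added `value_centered` and `nesting`
#'   (= `participant_id`).
#' @export
center_within <- function(data, week_means = NULL) {
  stopifnot(all(c("participant_id", "week_id", "value") %in% names(data)))
  if (is.null(week_means)) {
    week_means <- dplyr::summarise(
      dplyr::group_by(data, week_id),
      week_mean = mean(value), .groups = "drop"
    )
  }
  stopifnot(
    all(c("week_id", "week_mean") %in% names(week_means)),
    !anyDuplicated(week_means$week_id)
  )
  idx <- match(data$week_id, week_means$week_id)
  if (anyNA(idx)) {
    miss <- data$week_id[which(is.na(idx))[1L]]
    stop("no calendar-week mean for week ", miss, call. = FALSE)
  }
  data$value_centered <- data$value - week_means$week_mean[idx]
  data$nesting <- data$participant_id
  data
}

#' Monte-Carlo precision of the design's effect-size estimate
#'
#' Simulates the stepped-wedge comparison under a normal outcome model with
#' a true standardized effect `true_d`. Each of the
#' `n_groups + dual_contribution_groups` group-measurement contributions
#' retains `floor(group_size * retention)` participants; contributions are
#' split between the baseline and post-intervention measurement (the dual
#' group supplying both sides). Two pairing schemes are available:
#' \describe{
#'   \item{`pooled`}{(default) all baseline contributions against all post
#'     contributions in one two-sample comparison;}
#'   \item{`pairwise`}{each adjacent pair of contributions (last week of
#'     one group against first week of the next) estimated separately, the
#'     pair estimates averaged and their standard errors combined.}
#' }
#'
#' @param design a [design_spec()].
#' @param true_d true standardized mean difference.
#' @param n_reps number of Monte-Carlo replications (>= 100).
#' @param seed integer seed.
#' @param pairing comparison scheme, see above.
#' @return a list of class `design_precision`: `estimates` (one
#'   [cohens_d()]-style row per replication), `mean_d`,
#'   `median_ci_halfwidth`, `n_baseline`, `n_post`.
#' @export
simulate_design_precision <- function(design, true_d = 0, n_reps = 1000L,
                                      seed = 1L,
                                      pairing = c("pooled", "pairwise")) {
  stopifnot(inherits(design, "design_spec"), n_reps >= 100L)
  pairing <- match.arg(pairing)
  per_contrib <- floor(design$group_size * design$retention)
  contribs <- design$n_groups + design$dual_contribution_groups
  k_base <- ceiling(contribs / 2)
  k_post <- contribs - k_base
  stopifnot(k_post >= 1L)
  n1 <- per_contrib * k_base
  n2 <- per_contrib * k_post

  est <- with_seed(seed, {
    purrr::map(seq_len(n_reps), function(r) {
      if (pairing == "pooled") {
        cohens_d(rnorm(n1), rnorm(n2, mean = true_d))
      } else {
        k <- min(k_base, k_post)
        pair_est <- purrr::map(seq_len(k), function(j) {
          cohens_d(rnorm(per_contrib), rnorm(per_contrib, mean = true_d))
        }) |> dplyr::bind_rows()
        d <- mean(pair_est$cohens_d)
        se <- sqrt(sum(pair_est$se^2)) / k
        z <- qnorm(0.975)
        tibble::tibble(
          cohens_d = d, se = se,
          ci_low = d - z * se, ci_high = d + z * se,
          ci_halfwidth = z * se
        )
      }
    }) |> dplyr::bind_rows()
  })
  structure(
    list(
      estimates = est,
      mean_d = mean(est$cohens_d),
      median_ci_halfwidth = stats::median(est$ci_halfwidth),
      n_baseline = n1, n_post = n2
    ),
    class = "design_precision"
  )
}
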