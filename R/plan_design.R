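#' Balanced sampling plan
#'
#' A replicate allocation for one treatment group: `n_subjects` biological
#' subjects, each sampled with `n_sampling` RNA extractions, each extraction
#' split into `n_rt` RT reactions, each RT run in `n_qpcr` qPCR replicates.
#'
#' @param n_subjects,n_sampling,n_rt,n_qpcr Integer counts, all >= 1.
#' @return A list of class `sampling_plan`.
#' @export
sampling_plan <- function(n_subjects, n_sampling, n_rt, n_qpcr) {
  counts <- c(n_subjects = n_subjects, n_sampling = n_sampling,
              n_rt = n_rt, n_qpcr = n_qpcr)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 1) ||
      any(counts != as.integer(counts))) {
    stop("all replicate counts must be integers >= 1", call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> %d subjects x %d extractions x %d RTs x %d qPCRs (%d reactions)\n",
              x$n_subjects, x$n_sampling, x$n_rt, x$n_qpcr,
              x$n_subjects * x$n_sampling * x$n_rt * x$n_qpcr))
  invisible(x)
}

#' Step-noise components for plan evaluation
#'
#' Holds the three step components on the variance scale, recording whether
#' the caller supplied them as SDs (squared on ingest) or as variance-scale
#' values (used directly). The scale must be declared explicitly because
#' published step-noise tables are sometimes used unsquared in plan
#' arithmetic; reproducing such tables requires `scale = "variance"`.
#'
#' @param sampling,rt,qpcr Step components, >= 0 (cycles if `scale = "sd"`,
#'   cycles^2 if `scale = "variance"`).
#' @param scale Either `"sd"` or `"variance"`; no default, by design.
#' @param subject Optional between-subject component on the same scale,
#'   default 0; used by [plan_variance()] as an additional `v/n_subjects`
#'   term.
#' @return A list of class `step_noise` with variance-scale fields
#'   `sampling`, `rt`, `qpcr`, `subject` and the marker `scale_declared`.
#' @export
#' @examples
#' step_noise(0.87, 0.59, 0.35, scale = "variance")
step_noise <- function(sampling, rt, qpcr, scale, subject = 0) {
  if (missing(scale)) {
    stop("scale must be declared explicitly: \"sd\" or \"variance\"",
         call. = FALSE)
  }
  scale <- match.arg(scale, c("sd", "variance"))
  v <- c(sampling = sampling, rt = rt, qpcr = qpcr, subject = subject)
  if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
    stop("noise components must be non-negative numbers", call. = FALSE)
  }
  if (scale == "sd") v <- v^2
  structure(list(sampling = v[["sampling"]], rt = v[["rt"]],
                 qpcr = v[["qpcr"]], subject = v[["subject"]],
                 scale_declared = scale), class = "step_noise")
}

#' @export
print.step_noise <- function(x, ...) {
  cat(sprintf("<step_noise> (variance scale; declared as %s)\n", x$scale_declared))
  cat(sprintf("  sampling %.4g, rt %.4g, qpcr %.4g, subject %.4g\n",
              x$sampling, x$rt, x$qpcr, x$subject))
  invisible(x)
}

#' Per-unit cost model
#'
#' Monetary cost of each unit of work: one biological subject, one RNA
#' extraction, one RT reaction, one qPCR reaction. Units are arbitrary but
#' must be consistent with the budget.
#'
#' @param subject,sampling,rt,qpcr Non-negative per-unit costs.
#' @return A list of class `cost_model`.
#' @export
cost_model <- function(subject, sampling, rt, qpcr) {
  v <- c(subject = subject, sampling = sampling, rt = rt, qpcr = qpcr)
  if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
    stop("costs must be non-negative numbers", call. = FALSE)
  }
  structure(as.list(v), class = "cost_model")
}

#' Expected variance of a group-mean Cq under a plan
#'
#' For a balanced plan, averaging over replicates shrinks each step's
#' variance by the number of independent draws of that step entering the
#' mean: per subject the expected variance of the mean Cq is
#' `v_sampling/n_i + v_rt/(n_i n_j) + v_qpcr/(n_i n_j n_k)`, and averaging
#' over `n_subjects` subjects divides the whole by the subject count (plus
#' an optional between-subject component `v_subject/n_subjects`).
#'
#' @param noise A [step_noise()] object.
#' @param plan A [sampling_plan()].
#' @return Expected variance of the group-mean Cq (cycles^2 when the
#'   components are true variances; on the same scale as the inputs
#'   otherwise).
#' @export
#' @examples
#' noise <- step_noise(0.87, 0.59, 0.35, scale = "variance")
#' plan_variance(noise, sampling_plan(2, 1, 2, 3))
plan_variance <- function(noise, plan) {
  stopifnot(inherits(noise, "step_noise"), inherits(plan, "sampling_plan"))
  ni <- plan$n_sampling; nj <- plan$n_rt; nk <- plan$n_qpcr
  per_subject <- noise$sampling / ni + noise$rt / (ni * nj) +
    noise$qpcr / (ni * nj * nk)
  per_subject / plan$n_subjects + noise$subject / plan$n_subjects
}

#' Total cost of a plan
#'
#' Per condition the cost telescopes down the hierarchy:
#' `n_subjects * (cost_subject + n_sampling * (cost_sampling + n_rt *
#' (cost_rt + n_qpcr * cost_qpcr)))`; the total multiplies by the number of
#' experimental conditions.
#'
#' @param plan A [sampling_plan()].
#' @param costs A [cost_model()].
#' @param n_conditions Number of treatment groups (default 1).
#' @return Total monetary cost.
#' @export
plan_cost <- function(plan, costs, n_conditions = 1) {
  stopifnot(inherits(plan, "sampling_plan"), inherits(costs, "cost_model"),
            n_conditions >= 1)
  per_condition <- plan$n_subjects *
    (costs$subject + plan$n_sampling *
       (costs$sampling + plan$n_rt *
          (costs$rt + plan$n_qpcr * costs$qpcr)))
  n_conditions * per_condition
}

plan_evaluation_row <- function(noise, plan, costs = NULL, n_conditions = 1) {
  tibble::tibble(
    total_replicates = plan$n_subjects * plan$n_sampling * plan$n_rt *
      plan$n_qpcr,
    n_subjects = plan$n_subjects,
    n_sampling = plan$n_sampling,
    n_rt = plan$n_rt,
    n_qpcr = plan$n_qpcr,
    group_variance = plan_variance(noise, plan),
    total_cost = if (is.null(costs)) NA_real_
                 else plan_cost(plan, costs, n_conditions)
  )
}

#' Evaluate and rank candidate plans
#'
#' Evaluates each candidate plan's expected group-mean variance (and cost,
#' when a cost model is given) and sorts ascending by variance, so the first
#' row is the most precise allocation. `total_replicates` counts the qPCR
#' reactions per condition, the conventional "total replicates" of a plan
#' listing.
#'
#' @param noise A [step_noise()] object.
#' @param plans A list of [sampling_plan()] objects.
#' @param costs Optional [cost_model()].
#' @param n_conditions Number of treatment groups for costing (default 1).
#' @return A tibble with columns `total_replicates`, `n_subjects`,
#'   `n_sampling`, `n_rt`, `n_qpcr`, `group_variance`, `total_cost`, sorted
#'   by `group_variance`.
#' @export
rank_plans <- function(noise, plans, costs = NULL, n_conditions = 1) {
  stopifnot(inherits(noise, "step_noise"), is.list(plans))
  if (inherits(plans, "sampling_plan")) plans <- list(plans)
  rows <- lapply(plans, function(p) {
    stopifnot(inherits(p, "sampling_plan"))
    plan_evaluation_row(noise, p, costs, n_conditions)
  })
  out <- do.call(rbind, rows)
  out[order(out$group_variance, out$total_cost, out$total_replicates), ,
      drop = FALSE]
}

#' Constraints for plan optimization
#'
#' @param budget Total monetary budget across all conditions (> 0).
#' @param n_conditions Number of treatment groups (>= 1, default 1).
#' @param min_subjects Minimum biological replicates per condition; defaults
#'   to 3, the conventional floor for drawing biological conclusions.
#' @param max_subjects,max_sampling,max_rt,max_qpcr Optional upper bounds per
#'   count; when omitted they are derived from the budget and unit costs.
#' @return A list of class `optimization_constraints`.
#' @export
optimization_constraints <- function(budget, n_conditions = 1,
                                     min_subjects = 3,
                                     max_subjects = NULL, max_sampling = NULL,
                                     max_rt = NULL, max_qpcr = NULL) {
  stopifnot(is.numeric(budget), budget > 0, n_conditions >= 1,
            min_subjects >= 1)
  structure(list(budget = budget, n_conditions = as.integer(n_conditions),
                 min_subjects = as.integer(min_subjects),
                 max_subjects = max_subjects, max_sampling = max_sampling,
                 max_rt = max_rt, max_qpcr = max_qpcr),
            class = "optimization_constraints")
}

# largest count of one level affordable when every other level is at its
# minimum; NULL marginal cost means the budget imposes no bound
derived_bound <- function(given, marginal, remaining) {
  if (marginal <= 0) return(NULL)
  max(1L, as.integer(floor(remaining / marginal)))
}

#' Optimal sampling plan under a budget
#'
#' Exhaustively enumerates balanced integer plans whose total cost across
#' all conditions fits the budget and whose subject count meets the
#' biological-replication floor, and returns the plan minimizing the
#' expected group-mean variance. The variance objective is compared at the
#' reporting precision (`tie_digits` decimals, default 2): step components
#' estimated from a small pilot carry far more uncertainty than differences
#' in the third decimal of a predicted variance, so plans whose predictions
#' agree to that precision are treated as practically equivalent, and the
#' tie is broken by lower cost, then fewer qPCR reactions per condition,
#' then lexicographic plan order. Set `tie_digits = NULL` to minimize the
#' exact variance. Enumeration is exact: the feasible region is finite
#' whenever every level has positive marginal cost (levels with zero
#' marginal cost require an explicit upper bound in the constraints,
#' because the variance strictly decreases in every count above a positive
#' component).
#'
#' @param noise A [step_noise()] object.
#' @param costs A [cost_model()].
#' @param constraints An [optimization_constraints()] object.
#' @param frontier Also return every feasible evaluated plan (default
#'   `FALSE`).
#' @param tie_digits Decimals at which predicted variances are compared
#'   (default 2); `NULL` compares exact values.
#' @return A list of class `plan_evaluation` with `plan` (the optimal
#'   [sampling_plan()]), `group_variance`, `total_cost`,
#'   `reactions_per_condition`, `n_conditions`, the applied `constraints`,
#'   and — when `frontier = TRUE` — `frontier`, a tibble of all feasible
#'   plans sorted by variance.
#' @export
#' @examples
#' noise <- step_noise(0.42, 0.31, 0.30, scale = "variance")
#' costs <- cost_model(subject = 50, sampling = 10, rt = 3, qpcr = 1)
#' optimize_plan(noise, costs,
#'               optimization_constraints(budget = 1000, n_conditions = 3))
optimize_plan <- function(noise, costs, constraints, frontier = FALSE,
                          tie_digits = 2) {
  stopifnot(inherits(noise, "step_noise"), inherits(costs, "cost_model"),
            inherits(constraints, "optimization_constraints"))
  if (costs$subject + costs$sampling + costs$rt + costs$qpcr <= 0) {
    stop("at least one unit cost must be positive", call. = FALSE)
  }
  budget <- constraints$budget
  ncond <- constraints$n_conditions
  per_cond_budget <- budget / ncond

  cheapest <- sampling_plan(constraints$min_subjects, 1, 1, 1)
  cheapest_cost <- plan_cost(cheapest, costs, ncond)
  if (cheapest_cost > budget) {
    stop(sprintf(
      "no feasible plan: cheapest admissible plan (%d subjects x 1 x 1 x 1) costs %g, budget is %g",
      constraints$min_subjects, cheapest_cost, budget), call. = FALSE)
  }

  unit_chain <- costs$subject + costs$sampling + costs$rt + costs$qpcr
  bound <- function(explicit, marginal, label) {
    if (!is.null(explicit)) return(as.integer(explicit))
    b <- derived_bound(NULL, marginal, per_cond_budget)
    if (is.null(b)) {
      stop("level '", label, "' has zero marginal cost; supply an explicit ",
           "upper bound in the constraints", call. = FALSE)
    }
    b
  }
  # marginal per-condition cost of raising each count with the others at 1
  s_max <- bound(constraints$max_subjects, unit_chain, "subjects")
  i_max <- bound(constraints$max_sampling,
                 constraints$min_subjects *
                   (costs$sampling + costs$rt + costs$qpcr), "sampling")
  j_max <- bound(constraints$max_rt,
                 constraints$min_subjects * (costs$rt + costs$qpcr), "rt")
  k_max <- bound(constraints$max_qpcr,
                 constraints$min_subjects * costs$qpcr, "qpcr")

  best <- NULL
  rows <- if (frontier) vector("list", 256) else NULL
  n_rows <- 0L
  for (s in constraints$min_subjects:s_max) {
    if (ncond * s * (costs$subject + costs$sampling + costs$rt + costs$qpcr) >
        budget) break
    for (ni in 1:i_max) {
      if (ncond * s * (costs$subject + ni * (costs$sampling + costs$rt +
                                             costs$qpcr)) > budget) break
      for (nj in 1:j_max) {
        if (ncond * s * (costs$subject + ni * (costs$sampling + nj *
                                               (costs$rt + costs$qpcr))) >
            budget) break
        for (nk in 1:k_max) {
          plan <- sampling_plan(s, ni, nj, nk)
          cost <- plan_cost(plan, costs, ncond)
          if (cost > budget) break
          v <- plan_variance(noise, plan)
          reactions <- s * ni * nj * nk
          cand <- list(plan = plan, v = v,
                       v_cmp = if (is.null(tie_digits)) v
                               else round(v, tie_digits),
                       cost = cost, reactions = reactions)
          if (is.null(best) || better_plan(cand, best)) best <- cand
          if (frontier) {
            n_rows <- n_rows + 1L
            if (n_rows > length(rows)) {
              rows <- c(rows, vector("list", length(rows)))
            }
            rows[[n_rows]] <- tibble::tibble(
              total_replicates = reactions, n_subjects = s, n_sampling = ni,
              n_rt = nj, n_qpcr = nk, group_variance = v, total_cost = cost)
          }
        }
      }
    }
  }

  out <- structure(list(
    plan = best$plan,
    group_variance = best$v,
    total_cost = best$cost,
    reactions_per_condition = best$reactions,
    n_conditions = ncond,
    constraints = constraints,
    tie_digits = tie_digits
  ), class = "plan_evaluation")
  if (frontier) {
    fr <- do.call(rbind, rows[seq_len(n_rows)])
    out$frontier <- fr[order(fr$group_variance, fr$total_cost,
                             fr$total_replicates), , drop = FALSE]
  }
  out
}

# strict ordering: variance (at comparison precision), then cost, then
# reactions per condition, then lexicographic plan order
better_plan <- function(a, b) {
  if (a$v_cmp != b$v_cmp) return(a$v_cmp < b$v_cmp)
  if (a$cost != b$cost) return(a$cost < b$cost)
  if (a$reactions != b$reactions) return(a$reactions < b$reactions)
  ka <- unlist(a$plan); kb <- unlist(b$plan)
  diff <- which(ka != kb)
  if (length(diff) == 0) return(FALSE)
  ka[diff[1]] < kb[diff[1]]
}

#' @export
print.plan_evaluation <- function(x, ...) {
  p <- x$plan
  cat(sprintf("Optimal plan: %d subjects x %d extractions x %d RTs x %d qPCRs per condition\n",
              p$n_subjects, p$n_sampling, p$n_rt, p$n_qpcr))
  cat(sprintf("  expected group-mean variance: %.2f (full precision %.6g)\n",
              round(x$group_variance, 2), x$group_variance))
  cat(sprintf("  total cost over %d condition(s): %g (budget %g)\n",
              x$n_conditions, x$total_cost, x$constraints$budget))
  cat(sprintf("  qPCR reactions per condition: %d\n",
              x$reactions_per_condition))
  invisible(x)
}
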