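#' Unbalanced nested ANOVA for one Cq stratum
#'
#' Computes the Type-I (sequential) nested analysis of variance for the fully
#' nested random-effects model of a single stratum (one subject, tissue, and
#' gene): Cq = mu + a_i + b_j(i) + c_k(ij), where a_i is the RNA
#' sampling/extraction effect, b_j(i) the RT effect within extraction i, and
#' c_k(ij) the qPCR effect within RT j. Sums of squares are formed from group
#' means; missing Cq records are excluded (complete-case) and the
#' expected-mean-square coefficients are recomputed from the realized group
#' sizes, so unbalanced and incomplete designs are handled exactly.
#'
#' With n_ij observations in RT j of extraction i, n_i. their per-extraction
#' totals and N the grand total, the expected mean squares of the random
#' model are
#' \deqn{E[MS_{qpcr}] = \sigma^2_k}
#' \deqn{E[MS_{rt}] = \sigma^2_k + c_1 \sigma^2_j}
#' \deqn{E[MS_{sampling}] = \sigma^2_k + c_2 \sigma^2_j + c_3 \sigma^2_i}
#' with \eqn{c_1 = (N - \sum_i (\sum_j n_{ij}^2)/n_{i.}) / (\sum_i b_i - a)},
#' \eqn{c_2 = (\sum_i (\sum_j n_{ij}^2)/n_{i.} - \sum_{ij} n_{ij}^2 / N) / (a-1)},
#' \eqn{c_3 = (N - \sum_i n_{i.}^2 / N) / (a-1)}. In a balanced design with
#' n_k qPCRs per RT and n_j RTs per extraction these reduce to the familiar
#' n_k, n_k and n_j n_k.
#'
#' @param stratum A [cq_dataset()] restricted to a single (subject, tissue,
#'   gene) combination.
#' @return An object of class `nested_anova`: a list with `table` (tibble of
#'   level, df, ss, ms), `coefficients` (c1, c2, c3), `n` (observations
#'   used), `mu` (mean of the non-missing Cq values), and `estimable`
#'   (logical per level, `FALSE` where df = 0).
#' @seealso [estimate_components()] to solve the EMS system for the variance
#'   components.
#' @export
nested_anova <- function(stratum) {
  stopifnot(inherits(stratum, "cq_dataset"))
  df <- as.data.frame(stratum)
  key <- unique(df[c("subject", "tissue", "gene")])
  if (nrow(key) != 1) {
    stop("stratum spans more than one (subject, tissue, gene) combination; ",
         "use estimate_by_group()", call. = FALSE)
  }
  df <- df[!is.na(df$cq), , drop = FALSE]
  if (nrow(df) == 0) stop("no non-missing Cq values in stratum", call. = FALSE)

  y <- df$cq
  N <- length(y)
  i <- factor(df$rna_rep)
  ij <- interaction(df$rna_rep, df$rt_rep, drop = TRUE)

  ybar <- mean(y)
  mi <- tapply(y, i, mean)
  ni <- tapply(y, i, length)
  mij <- tapply(y, ij, mean)
  nij <- tapply(y, ij, length)
  parent <- tapply(as.character(i), ij, `[`, 1)

  a <- nlevels(i)
  bi <- table(factor(parent, levels = levels(i)))

  mi_obs <- mi[as.character(i)]
  mij_obs <- mij[as.character(ij)]
  ss <- c(
    sampling = sum(ni * (mi - ybar)^2),
    rt = sum((mij_obs - mi_obs)^2),
    qpcr = sum((y - mij_obs)^2)
  )
  # guard against spurious tiny negatives from floating-point cancellation
  ss[ss < 1e-12] <- 0

  dfree <- c(
    sampling = a - 1L,
    rt = sum(bi) - a,
    qpcr = N - sum(bi)
  )
  ms <- ifelse(dfree > 0, ss / dfree, NA_real_)

  # EMS coefficients for the unbalanced fully nested random model
  s_nij2_by_i <- tapply(nij^2, parent, sum)[names(ni)]
  s_nij2_over_ni <- sum(s_nij2_by_i / ni)
  coef <- c(
    c1 = if (dfree[["rt"]] > 0) (N - s_nij2_over_ni) / dfree[["rt"]] else NA_real_,
    c2 = if (dfree[["sampling"]] > 0)
      (s_nij2_over_ni - sum(nij^2) / N) / dfree[["sampling"]] else NA_real_,
    c3 = if (dfree[["sampling"]] > 0)
      (N - sum(ni^2) / N) / dfree[["sampling"]] else NA_real_
  )

  structure(list(
    table = tibble::tibble(
      level = c("sampling", "rt", "qpcr"),
      df = as.integer(dfree),
      ss = unname(ss),
      ms = unname(ms)
    ),
    coefficients = coef,
    n = N,
    mu = ybar,
    estimable = dfree > 0,
    stratum = key
  ), class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  cat(sprintf("Nested ANOVA, stratum %s/%s/%s (N = %d, mean Cq = %.2f)\n",
              x$stratum$subject, x$stratum$tissue, x$stratum$gene,
              x$n, x$mu))
  print(x$table)
  cat(sprintf("EMS coefficients: c1 = %.4g, c2 = %.4g, c3 = %.4g\n",
              x$coefficients[["c1"]], x$coefficients[["c2"]],
              x$coefficients[["c3"]]))
  invisible(x)
}

#' Method-of-moments variance components for one stratum
#'
#' Solves the triangular expected-mean-square system of [nested_anova()]
#' bottom-up: sigma2_qpcr = MS_qpcr, sigma2_rt = (MS_rt - MS_qpcr)/c1,
#' sigma2_sampling = (MS_sampling - MS_qpcr - c2 * sigma2_rt)/c3, where the
#' raw (possibly negative) RT solution is carried into the sampling equation.
#' Negative raw solutions are truncated to zero by default and recorded in
#' the `truncated` field; set `truncate = FALSE` to keep the raw
#' method-of-moments values for diagnostics.
#'
#' @param stratum A [cq_dataset()] restricted to one (subject, tissue, gene).
#' @param truncate Truncate negative raw solutions to zero (default `TRUE`).
#' @return An object of class `variance_components`: list with `mu` (grand
#'   mean Cq, cycles), `var_sampling`, `var_rt`, `var_qpcr` (cycles^2),
#'   `sd_sampling`, `sd_rt`, `sd_qpcr` (cycles, exact square roots of the
#'   variance fields; `NaN` when an untruncated variance is negative),
#'   `truncated` (character subset of sampling/rt/qpcr), `estimable`,
#'   and the `nested_anova` fit in `anova`.
#' @export
#' @examples
#' spec <- simulation_spec(mu = 24, sd_sampling = 0.45, sd_rt = 0.73,
#'                         sd_qpcr = 0.32, seed = 7)
#' estimate_components(simulate_stratum(spec))
estimate_components <- function(stratum, truncate = TRUE) {
  an <- nested_anova(stratum)
  ms <- stats::setNames(an$table$ms, an$table$level)
  cf <- an$coefficients

  v <- c(sampling = NA_real_, rt = NA_real_, qpcr = NA_real_)
  if (an$estimable[["qpcr"]]) v[["qpcr"]] <- ms[["qpcr"]]
  if (an$estimable[["rt"]] && !is.na(v[["qpcr"]])) {
    v[["rt"]] <- (ms[["rt"]] - ms[["qpcr"]]) / cf[["c1"]]
  }
  if (an$estimable[["sampling"]] && !is.na(v[["rt"]])) {
    v[["sampling"]] <-
      (ms[["sampling"]] - ms[["qpcr"]] - cf[["c2"]] * v[["rt"]]) / cf[["c3"]]
  }

  truncated <- character()
  if (truncate) {
    neg <- !is.na(v) & v < 0
    truncated <- names(v)[neg]
    v[neg] <- 0
  }

  structure(list(
    mu = an$mu,
    var_sampling = v[["sampling"]],
    var_rt = v[["rt"]],
    var_qpcr = v[["qpcr"]],
    # raw (untruncated) negatives have no real square root: NaN, silently
    sd_sampling = suppressWarnings(sqrt(v[["sampling"]])),
    sd_rt = suppressWarnings(sqrt(v[["rt"]])),
    sd_qpcr = suppressWarnings(sqrt(v[["qpcr"]])),
    truncated = truncated,
    estimable = an$estimable,
    stratum = an$stratum,
    anova = an
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components, stratum %s/%s/%s\n",
              x$stratum$subject, x$stratum$tissue, x$stratum$gene))
  cat(sprintf("  mean Cq: %.2f cycles\n", x$mu))
  cat(sprintf("  sampling: var %.4f, sd %.3f\n", x$var_sampling, x$sd_sampling))
  cat(sprintf("  rt:       var %.4f, sd %.3f\n", x$var_rt, x$sd_rt))
  cat(sprintf("  qpcr:     var %.4f, sd %.3f\n", x$var_qpcr, x$sd_qpcr))
  if (length(x$truncated) > 0) {
    cat("  truncated to zero:", paste(x$truncated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Variance components for every group of a dataset
#'
#' Splits a dataset on the requested coordinates (by default subject, tissue
#' and gene — one stratum per combination, the model's single-treatment-group
#' assumption) and estimates components for each group. Groups whose realized
#' design leaves a level with zero degrees of freedom are kept in the output
#' with `NA` estimates and a diagnostic note rather than dropped.
#'
#' @param ds A [cq_dataset()].
#' @param grouping Coordinate names to split on; subset of
#'   `c("subject", "tissue", "gene")`.
#' @param truncate Passed to [estimate_components()].
#' @return A tibble with one row per group: the grouping coordinates,
#'   `n_obs`, `mu`, `var_*`, `sd_*` columns, `truncated` (comma-separated),
#'   and `note` (empty when estimation succeeded). The list of underlying
#'   `variance_components` objects is attached as attribute `fits`.
#' @export
estimate_by_group <- function(ds, grouping = c("subject", "tissue", "gene"),
                              truncate = TRUE) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (!all(grouping %in% c("subject", "tissue", "gene"))) {
    stop("grouping must be a subset of subject/tissue/gene", call. = FALSE)
  }
  df <- as.data.frame(ds)
  # strata are always subject x tissue x gene; grouping coarser than that
  # would pool across strata, which the single-group model does not allow
  split_key <- do.call(paste, c(df[c("subject", "tissue", "gene")], sep = "\r"))
  pieces <- split(df, split_key)
  rows <- lapply(pieces, function(piece) {
    key <- piece[1, c("subject", "tissue", "gene")]
    sub <- cq_dataset(piece, provenance = attr(ds, "provenance"))
    fit <- NULL
    note <- ""
    res <- tryCatch(estimate_components(sub, truncate = truncate),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "variance_components")) {
      fit <- res
      not_est <- names(res$estimable)[!res$estimable]
      if (length(not_est) > 0) {
        note <- paste0("not estimable: ", paste(not_est, collapse = ", "))
      }
      row <- tibble::tibble(
        subject = key$subject, tissue = key$tissue, gene = key$gene,
        n_obs = res$anova$n, mu = res$mu,
        var_sampling = res$var_sampling, var_rt = res$var_rt,
        var_qpcr = res$var_qpcr,
        sd_sampling = res$sd_sampling, sd_rt = res$sd_rt,
        sd_qpcr = res$sd_qpcr,
        truncated = paste(res$truncated, collapse = ","),
        note = note
      )
    } else {
      row <- tibble::tibble(
        subject = key$subject, tissue = key$tissue, gene = key$gene,
        n_obs = sum(!is.na(piece$cq)), mu = NA_real_,
        var_sampling = NA_real_, var_rt = NA_real_, var_qpcr = NA_real_,
        sd_sampling = NA_real_, sd_rt = NA_real_, sd_qpcr = NA_real_,
        truncated = "", note = res
      )
    }
    list(row = row, fit = fit)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  keep <- intersect(grouping, names(out))
  out <- out[do.call(order, out[keep]), , drop = FALSE]
  attr(out, "fits") <- lapply(rows, `[[`, "fit")
  out
}

#' Average step-SD estimates across subjects
#'
#' The per-stratum estimator is fit to each subject separately (the nested
#' model has no subject level); averaging the resulting SD estimates across
#' subjects for the same tissue and gene reduces their sampling error.
#'
#' @param by_group Output of [estimate_by_group()].
#' @return A tibble keyed by tissue and gene with `n_subjects` and the
#'   across-subject means `mu`, `sd_sampling`, `sd_rt`, `sd_qpcr`.
#' @export
average_components <- function(by_group) {
  need <- c("tissue", "gene", "mu", "sd_sampling", "sd_rt", "sd_qpcr")
  stopifnot(all(need %in% names(by_group)))
  key <- paste(by_group$tissue, by_group$gene, sep = "\r")
  agg <- function(col) as.numeric(tapply(by_group[[col]], key,
                                         mean, na.rm = TRUE))
  keys <- do.call(rbind, strsplit(sort(unique(key)), "\r", fixed = TRUE))
  tibble::tibble(
    tissue = keys[, 1], gene = keys[, 2],
    n_subjects = as.integer(tapply(by_group$subject, key,
                                   function(s) length(unique(s)))),
    mu = agg("mu"),
    sd_sampling = agg("sd_sampling"),
    sd_rt = agg("sd_rt"),
    sd_qpcr = agg("sd_qpcr")
  )
}
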