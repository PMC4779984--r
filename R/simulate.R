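#' Specification of a simulated Cq stratum
#'
#' Describes one stratum (subject x tissue x gene) of the hierarchical
#' Gaussian measurement model: each Cq is the stratum mean plus independent
#' zero-mean Gaussian effects drawn once per RNA extraction, once per RT
#' reaction within an extraction, and once per qPCR reaction. Defaults use
#' the 4 extractions x 4 RTs x 3 qPCRs pilot layout (48 reactions per
#' stratum). Records can be knocked out completely at random with
#' `missing_rate` to emulate failed reactions.
#'
#' @param mu Grand mean Cq, cycles.
#' @param sd_sampling,sd_rt,sd_qpcr Step SDs, cycles (>= 0).
#' @param sd_subject Between-subject SD, cycles (default 0: the
#'   single-group measurement model has no subject term; a positive value
#'   supports testing the optional subject-variance term of
#'   [plan_variance()]).
#' @param n_subjects,n_sampling,n_rt,n_qpcr Design dimensions (>= 1).
#' @param missing_rate Probability each record is missing, in `[0, 1)`.
#' @param seed Optional RNG seed for reproducible draws.
#' @param subject,tissue,gene Labels; with `n_subjects > 1` the subject
#'   label is suffixed per subject.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(mu, sd_sampling, sd_rt, sd_qpcr,
                            sd_subject = 0,
                            n_subjects = 1, n_sampling = 4, n_rt = 4,
                            n_qpcr = 3, missing_rate = 0, seed = NULL,
                            subject = "S1", tissue = "tissue1",
                            gene = "gene1") {
  sds <- c(sd_subject, sd_sampling, sd_rt, sd_qpcr)
  dims <- c(n_subjects, n_sampling, n_rt, n_qpcr)
  stopifnot(is.numeric(mu), length(mu) == 1, is.finite(mu))
  if (!is.numeric(sds) || anyNA(sds) || any(sds < 0)) {
    stop("all SDs must be non-negative", call. = FALSE)
  }
  if (!is.numeric(dims) || any(dims < 1) || any(dims != as.integer(dims))) {
    stop("design dimensions must be integers >= 1", call. = FALSE)
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(mu = mu, sd_subject = sd_subject,
                 sd_sampling = sd_sampling, sd_rt = sd_rt, sd_qpcr = sd_qpcr,
                 n_subjects = as.integer(n_subjects),
                 n_sampling = as.integer(n_sampling),
                 n_rt = as.integer(n_rt), n_qpcr = as.integer(n_qpcr),
                 missing_rate = missing_rate, seed = seed,
                 subject = subject, tissue = tissue, gene = gene),
            class = "simulation_spec")
}

# one subject's records; assumes RNG state is already set by the caller
simulate_one_subject <- function(spec, subject_label) {
  ni <- spec$n_sampling; nj <- spec$n_rt; nk <- spec$n_qpcr
  a <- stats::rnorm(ni, 0, spec$sd_sampling)
  b <- matrix(stats::rnorm(ni * nj, 0, spec$sd_rt), nrow = ni)
  subj_eff <- stats::rnorm(1, 0, spec$sd_subject)
  grid <- expand.grid(qpcr_rep = seq_len(nk), rt_rep = seq_len(nj),
                      rna_rep = seq_len(ni))
  grid <- grid[order(grid$rna_rep, grid$rt_rep, grid$qpcr_rep), , drop = FALSE]
  cq <- spec$mu + subj_eff + a[grid$rna_rep] +
    b[cbind(grid$rna_rep, grid$rt_rep)] +
    stats::rnorm(nrow(grid), 0, spec$sd_qpcr)
  rec <- data.frame(subject = subject_label, tissue = spec$tissue,
                    gene = spec$gene, rna_rep = grid$rna_rep,
                    rt_rep = grid$rt_rep, qpcr_rep = grid$qpcr_rep,
                    cq = cq, stringsAsFactors = FALSE)
  if (spec$missing_rate > 0) {
    # redraw the knockout pattern if it would empty the stratum, so every
    # generated dataset satisfies the >= 1 observed record invariant
    for (try in 1:100) {
      miss <- stats::runif(nrow(rec)) < spec$missing_rate
      if (!all(miss)) break
    }
    rec$cq[miss] <- NA_real_
  }
  rec
}

subject_labels <- function(spec) {
  if (spec$n_subjects == 1) return(spec$subject)
  paste0(spec$subject, "_", seq_len(spec$n_subjects))
}

#' Simulate one or more strata from a single specification
#'
#' Draws the hierarchical Gaussian effects of the measurement model — one
#' sampling effect per RNA extraction, one RT effect per RT reaction nested
#' in its extraction, one qPCR effect per reaction — sums them with the
#' stratum mean, applies missing-completely-at-random knockouts, and returns
#' a validated [cq_dataset()]. The same spec and seed always produce an
#' identical dataset.
#'
#' @param spec A [simulation_spec()].
#' @return A [cq_dataset()] with
#'   `n_subjects * n_sampling * n_rt * n_qpcr` records.
#' @export
#' @examples
#' spec <- simulation_spec(mu = 23.69, sd_sampling = 0.87, sd_rt = 0.59,
#'                         sd_qpcr = 0.35, seed = 1)
#' simulate_stratum(spec)
simulate_stratum <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  gen <- function() {
    recs <- lapply(subject_labels(spec),
                   function(lbl) simulate_one_subject(spec, lbl))
    do.call(rbind, recs)
  }
  recs <- if (is.null(spec$seed)) gen() else withr::with_seed(spec$seed, gen())
  cq_dataset(recs, provenance = sprintf(
    "simulated (seed %s): mu=%g, sds=(%g,%g,%g), dims=%dx%dx%dx%d, missing_rate=%g",
    if (is.null(spec$seed)) "none" else spec$seed, spec$mu,
    spec$sd_sampling, spec$sd_rt, spec$sd_qpcr,
    spec$n_subjects, spec$n_sampling, spec$n_rt, spec$n_qpcr,
    spec$missing_rate))
}

#' Simulate a multi-stratum study
#'
#' Concatenates simulated strata over a collection of per-(tissue, gene)
#' specifications, e.g. the bundled pilot presets of [pilot_presets()]. All
#' strata are drawn from one seeded RNG stream in spec order, so the full
#' study is reproducible from a single seed.
#'
#' @param specs A list of [simulation_spec()] objects with distinct
#'   (tissue, gene) keys.
#' @param seed Optional seed for the whole study; overrides per-spec seeds.
#' @return A [cq_dataset()] concatenating all strata.
#' @export
simulate_study <- function(specs, seed = NULL) {
  if (inherits(specs, "simulation_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "simulation_spec")))
  keys <- vapply(specs, function(s) paste(s$tissue, s$gene, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (tissue, gene) keys in study specs", call. = FALSE)
  }
  gen <- function() {
    do.call(rbind, lapply(specs, function(spec) {
      do.call(rbind, lapply(subject_labels(spec),
                            function(lbl) simulate_one_subject(spec, lbl)))
    }))
  }
  recs <- if (is.null(seed)) {
    if (length(specs) == 1 && !is.null(specs[[1]]$seed)) {
      return(simulate_stratum(specs[[1]]))
    }
    gen()
  } else {
    withr::with_seed(seed, gen())
  }
  cq_dataset(recs, provenance = sprintf(
    "simulated study (%d strata, seed %s)", length(specs),
    if (is.null(seed)) "none" else seed))
}

#' Blueberry pilot-study noise presets
#'
#' Per-(tissue, gene) mean Cq and step-SD estimates from a nested RT-qPCR
#' pilot in blueberry (three tissues by three assays, 4 extractions x 4 RTs
#' x 3 qPCRs per plant), bundled so simulated studies can emulate realistic
#' noise magnitudes. `sd_total` is the published cumulative noise of a
#' single Cq measurement for that stratum (pooled over plants), which also
#' reflects between-plant spread and therefore exceeds the combination of
#' the three step SDs alone.
#'
#' @return A tibble with columns `tissue`, `gene`, `mean_cq`, `sd_sampling`,
#'   `sd_rt`, `sd_qpcr`, `sd_total`.
#' @export
pilot_presets <- function() {
  tibble::tibble(
    tissue = rep(c("leaves", "stems", "fruits"), each = 3),
    gene = rep(c("VRN", "KAT", "F35H"), times = 3),
    mean_cq = c(25.19, 22.78, 30.82,
                23.69, 22.29, 30.76,
                25.12, 20.77, 18.29),
    sd_sampling = c(0.45, 0.02, 0.64,
                    0.87, 0.53, 0.19,
                    0.41, 0.42, 0.43),
    sd_rt = c(0.73, 0.28, 0.53,
              0.59, 0.32, 0.50,
              0.34, 0.31, 0.29),
    sd_qpcr = c(0.32, 0.18, 0.49,
                0.35, 0.21, 0.44,
                0.30, 0.27, 0.35),
    sd_total = c(0.91, 0.55, 0.97,
                 1.15, 0.67, 0.74,
                 0.65, 0.60, 0.64)
  )
}

#' Simulate a full pilot-style study from the bundled presets
#'
#' Builds one [simulation_spec()] per preset stratum (optionally restricted)
#' and simulates `n_subjects` plants for each, reproducing the pilot layout:
#' with 2 subjects, 3 tissues, 3 genes and the 4 x 4 x 3 design this yields
#' 864 qPCR reactions.
#'
#' @param n_subjects Plants per stratum (default 2).
#' @param n_sampling,n_rt,n_qpcr Design dimensions (defaults 4, 4, 3).
#' @param missing_rate Missing-record probability (default 0).
#' @param seed RNG seed.
#' @param tissues,genes Optional preset filters.
#' @return A [cq_dataset()].
#' @export
simulate_pilot_study <- function(n_subjects = 2, n_sampling = 4, n_rt = 4,
                                 n_qpcr = 3, missing_rate = 0, seed = NULL,
                                 tissues = NULL, genes = NULL) {
  presets <- pilot_presets()
  if (!is.null(tissues)) presets <- presets[presets$tissue %in% tissues, ]
  if (!is.null(genes)) presets <- presets[presets$gene %in% genes, ]
  if (nrow(presets) == 0) stop("no presets match the filters", call. = FALSE)
  specs <- lapply(seq_len(nrow(presets)), function(r) {
    p <- presets[r, ]
    simulation_spec(mu = p$mean_cq, sd_sampling = p$sd_sampling,
                    sd_rt = p$sd_rt, sd_qpcr = p$sd_qpcr,
                    n_subjects = n_subjects, n_sampling = n_sampling,
                    n_rt = n_rt, n_qpcr = n_qpcr,
                    missing_rate = missing_rate,
                    subject = "plant", tissue = p$tissue, gene = p$gene)
  })
  simulate_study(specs, seed = seed)
}
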