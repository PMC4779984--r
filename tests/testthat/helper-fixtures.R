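# Fixture builders and independent oracles used across the test files.

# One stratum from explicit vectors of coordinates and Cq values.
make_stratum <- function(rna, rt, qpcr, cq, subject = "P1",
                         tissue = "stems", gene = "VRN") {
  cq_dataset(data.frame(subject = subject, tissue = tissue, gene = gene,
                        rna_rep = as.integer(rna), rt_rep = as.integer(rt),
                        qpcr_rep = as.integer(qpcr), cq = cq,
                        stringsAsFactors = FALSE))
}

# A fully balanced stratum laid out row-major over (rna, rt, qpcr).
make_balanced_stratum <- function(cq, ni, nj, nk, ...) {
  grid <- expand.grid(qpcr = seq_len(nk), rt = seq_len(nj),
                      rna = seq_len(ni))
  grid <- grid[order(grid$rna, grid$rt, grid$qpcr), ]
  make_stratum(grid$rna, grid$rt, grid$qpcr, cq, ...)
}

# Independent method-of-moments oracle: explicit loops over group means,
# no shared code with the package's vectorized estimator.
oracle_components <- function(ds) {
  df <- as.data.frame(ds)
  df <- df[!is.na(df$cq), ]
  extractions <- sort(unique(df$rna_rep))
  a <- length(extractions)
  N <- nrow(df)
  grand <- mean(df$cq)

  ss_sampling <- 0
  ss_rt <- 0
  ss_qpcr <- 0
  sum_bi <- 0
  s_nij2_over_ni <- 0
  s_nij2 <- 0
  s_ni2 <- 0
  for (i in extractions) {
    di <- df[df$rna_rep == i, ]
    ni <- nrow(di)
    mi <- mean(di$cq)
    ss_sampling <- ss_sampling + ni * (mi - grand)^2
    s_ni2 <- s_ni2 + ni^2
    rts <- sort(unique(di$rt_rep))
    sum_bi <- sum_bi + length(rts)
    nij2 <- 0
    for (j in rts) {
      dij <- di[di$rt_rep == j, ]
      nij <- nrow(dij)
      mij <- mean(dij$cq)
      ss_rt <- ss_rt + nij * (mij - mi)^2
      ss_qpcr <- ss_qpcr + sum((dij$cq - mij)^2)
      nij2 <- nij2 + nij^2
      s_nij2 <- s_nij2 + nij^2
    }
    s_nij2_over_ni <- s_nij2_over_ni + nij2 / ni
  }
  ms_s <- ss_sampling / (a - 1)
  ms_r <- ss_rt / (sum_bi - a)
  ms_q <- ss_qpcr / (N - sum_bi)
  c1 <- (N - s_nij2_over_ni) / (sum_bi - a)
  c2 <- (s_nij2_over_ni - s_nij2 / N) / (a - 1)
  c3 <- (N - s_ni2 / N) / (a - 1)
  vq <- ms_q
  vr <- (ms_r - ms_q) / c1
  vs <- (ms_s - ms_q - c2 * vr) / c3
  list(mu = grand, var_sampling = vs, var_rt = vr, var_qpcr = vq,
       c1 = c1, c2 = c2, c3 = c3)
}

# Independent brute-force plan optimizer: enumerate a grid, evaluate cost
# and variance from first principles, minimize (variance at 2 dp, cost,
# reactions, lexicographic).
oracle_optimize <- function(v, costs, budget, n_conditions, min_subjects,
                            grid_max = 30) {
  g <- expand.grid(s = min_subjects:grid_max, ni = 1:grid_max,
                   nj = 1:grid_max, nk = 1:grid_max)
  g$cost <- n_conditions * g$s *
    (costs[1] + g$ni * (costs[2] + g$nj * (costs[3] + g$nk * costs[4])))
  g <- g[g$cost <= budget, ]
  if (nrow(g) == 0) return(NULL)
  g$variance <- (v[1] / g$ni + v[2] / (g$ni * g$nj) +
                   v[3] / (g$ni * g$nj * g$nk)) / g$s
  g$reactions <- g$s * g$ni * g$nj * g$nk
  g <- g[order(round(g$variance, 2), g$cost, g$reactions,
               g$s, g$ni, g$nj, g$nk), ]
  g[1, ]
}
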