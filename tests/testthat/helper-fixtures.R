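# shared fixtures and independent oracles, all built in code

small_design <- function(...) {
  args <- list(n_subclones = 2, concentrations = c(300, 1000),
               n_compounds = 20, wt_vehicle_wells_per_plate = 8,
               ko_vehicle_wells_per_plate = 6,
               ko_untreated_wells_per_plate = 2, fields_per_well = 4)
  do.call(screen_design, utils::modifyList(args, list(...)))
}

small_params <- function(...) {
  args <- list(n_features = 60, n_reverters = 3, n_latent = 6, seed = 11)
  do.call(sim_params, utils::modifyList(args, list(...)))
}

small_screen <- function(seed = 11, ...) {
  simulate_screen(small_design(), small_params(seed = seed, ...))
}

# brute-force Benjamini-Hochberg step-up adjustment (independent of p.adjust)
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj_sorted[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# align columns of a loading matrix to a reference up to sign and permutation;
# returns the aligned matrix or NULL if no 1:1 column matching exists
align_loadings <- function(L, ref) {
  co <- suppressWarnings(abs(stats::cor(L, ref)))
  perm <- apply(co, 2, which.max)
  if (anyDuplicated(perm)) return(NULL)
  out <- L[, perm, drop = FALSE]
  for (j in seq_len(ncol(ref)))
    if (sum(out[, j] * ref[, j]) < 0) out[, j] <- -out[, j]
  out
}

# planted simple-structure loading matrix: k factors, vars_per_factor each
simple_structure <- function(k, vars_per_factor, lo = 0.6, hi = 0.9) {
  p <- k * vars_per_factor
  L <- matrix(0, p, k)
  L[cbind(seq_len(p), rep(seq_len(k), each = vars_per_factor))] <-
    runif(p, lo, hi)
  L
}

# exact permutation p-value for the separation ratio by full enumeration of
# class-A index subsets (small n only)
exact_separation_p <- function(profiles, labels, metric) {
  n <- length(labels)
  cls <- unique(labels)
  na <- sum(labels == cls[1])
  obs <- separation_score(profiles, labels, metric)
  combos <- utils::combn(n, na)
  stats <- apply(combos, 2, function(idx) {
    lab <- rep(cls[2], n)
    lab[idx] <- cls[1]
    separation_score(profiles, lab, metric)
  })
  mean(stats >= obs - 1e-12)
}
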