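# Independent oracles used across tests.

# Exhaustive enumeration of all 2^N site-occupancy configurations.
enumerate_bound_distribution <- function(n_sites, p) {
  counts <- numeric(n_sites + 1L)
  for (m in 0:(2^n_sites - 1L)) {
    occ <- sum(bitwAnd(m, bitwShiftL(1L, 0:(n_sites - 1L))) != 0L)
    counts[occ + 1L] <- counts[occ + 1L] +
      p^occ * (1 - p)^(n_sites - occ)
  }
  counts
}

# Brute-force all-pairs boundary classification (minimum image, plain loops).
brute_force_boundary_ids <- function(frame, cutoff = 6) {
  tmd <- frame$protein[frame$protein$tmd, c("x", "y", "z")]
  box <- frame$box
  ids <- unique(frame$lipids$lipid_id)
  out <- character(0)
  for (id in ids) {
    beads <- frame$lipids[frame$lipids$lipid_id == id, c("x", "y", "z")]
    hit <- FALSE
    for (i in seq_len(nrow(beads))) {
      for (j in seq_len(nrow(tmd))) {
        d <- unlist(beads[i, ]) - unlist(tmd[j, ])
        for (k in seq_along(box)) d[k] <- d[k] - box[k] * round(d[k] / box[k])
        if (sqrt(sum(d^2)) <= cutoff) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) out <- c(out, id)
  }
  out
}

# Clean stretched-exponential quench trace.
make_quench_trace <- function(tau, beta, f0 = 1, f_inf = 0.2,
                              times = exp(seq(log(5e-4), log(1),
                                              length.out = 150L))) {
  list(time = times, fluorescence = f_inf + (f0 - f_inf) *
         exp(-(times / tau)^beta))
}
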