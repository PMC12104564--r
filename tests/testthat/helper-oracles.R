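# Independent naive reimplementations used as oracles; deliberately written
# the dumb way so they share no code with the package internals.

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  # step-up: enforce monotonicity from the largest p downwards
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

oracle_raw_mad <- function(x) median(abs(x - median(x)))

oracle_robust_z <- function(b, a) {
  (median(a) - median(b)) /
    sqrt((oracle_raw_mad(b)^2 + oracle_raw_mad(a)^2) / 2)
}

oracle_cohen_d <- function(b, a) {
  sp <- sqrt(((length(b) - 1) * var(b) + (length(a) - 1) * var(a)) /
             (length(b) + length(a) - 2))
  (mean(a) - mean(b)) / sp
}

# Exact two-sided signed-rank p by full enumeration of all 2^n sign
# assignments (feasible for n <= 14).
oracle_signed_rank_p <- function(b, a) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Small fixture builders -----------------------------------------------------

tiny_plate <- function(seed = 42, n_wells = 2, n_electrodes = 4,
                       duration = 20, conc = c(10, 0),
                       ic50 = 1, hill_n = 2, active_fraction = 1) {
  spec <- plate_spec(n_wells = n_wells, n_electrodes = n_electrodes,
                     duration = duration, seed = seed,
                     active_fraction = active_fraction)
  truths <- list(CMP1 = compound_truth("CMP1", ic50_true = ic50,
                                       hill_n_true = hill_n))
  expo <- data.frame(well = seq_len(n_wells), compound_id = "CMP1",
                     concentration = rep_len(conc, n_wells))
  simulate_plate(spec, expo, truths)
}

# A 20-compound library: 4 planted strong suppressors, 16 inert compounds.
planted_library <- function() {
  truths <- list()
  for (i in 1:4)
    truths[[sprintf("HIT%02d", i)]] <-
      compound_truth(sprintf("HIT%02d", i), ic50_true = 2, hill_n_true = 3)
  for (i in 1:16)
    truths[[sprintf("NULL%02d", i)]] <-
      compound_truth(sprintf("NULL%02d", i), ic50_true = 1e6,
                     hill_n_true = 1)
  truths
}

planted_exposures <- function(truths) {
  data.frame(well = sprintf("W%02d", seq_along(truths)),
             compound_id = names(truths), concentration = 10)
}

screen_from_rates <- function(rates_df, thresholds = hit_thresholds()) {
  # run the per-compound metric + hit-call chain on a rate-level table
  metrics <- lapply(split(rates_df, rates_df$compound_id), function(sub) {
    screen_metrics(sub$compound_id[1], sub$rate_before, sub$rate_after)
  })
  praw <- vapply(metrics, function(m) m$p_raw, numeric(1))
  padj <- fdr_adjust(praw)
  calls <- mapply(function(m, p) {
    m$p_fdr <- p
    call_hit(m)
  }, metrics, padj, SIMPLIFY = FALSE)
  calls
}
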