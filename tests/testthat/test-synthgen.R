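test_that("identical spec and seed give bit-identical plates", {
  p1 <- tiny_plate(seed = 7, duration = 5)
  p2 <- tiny_plate(seed = 7, duration = 5)
  expect_identical(p1$channels, p2$channels)
  p3 <- tiny_plate(seed = 8, duration = 5)
  expect_false(identical(p1$channels[[1]]$traces$baseline$samples,
                         p3$channels[[1]]$traces$baseline$samples))
})

test_that("adding wells does not perturb existing channels", {
  small <- tiny_plate(seed = 5, n_wells = 2, duration = 5)
  big <- tiny_plate(seed = 5, n_wells = 3, duration = 5,
                    conc = c(10, 0, 0))
  for (id in names(small$channels))
    expect_identical(small$channels[[id]], big$channels[[id]])
})

test_that("spike times respect the recording window and the dead time", {
  pl <- tiny_plate(seed = 3, duration = 10)
  for (ch in pl$channels) {
    for (ph in names(ch$true_spikes)) {
      st <- ch$true_spikes[[ph]]
      expect_true(all(st >= 0 & st <= pl$spec$duration))
      if (length(st) > 1) expect_gte(min(diff(st)), 0.003)
    }
  }
})

test_that("washout rate lies between post and baseline rates", {
  for (rf in c(0, 0.3, 1)) {
    truths <- list(C = compound_truth("C", 1, 2, recovery_fraction = rf))
    spec <- plate_spec(n_wells = 1, n_electrodes = 2, duration = 2,
                       seed = 1, active_fraction = 1)
    pl <- simulate_plate(spec, data.frame(well = 1, compound_id = "C",
                                          concentration = 5), truths)
    for (ch in pl$channels) {
      r <- ch$true_rates
      expect_gte(r[["washout"]], r[["post"]] - 1e-12)
      expect_lte(r[["washout"]], r[["baseline"]] + 1e-12)
    }
  }
})

test_that("rendered template insertions equal the true spike count", {
  # noiseless trace: every insertion is the only signal present
  spec <- plate_spec(n_wells = 1, n_electrodes = 2, duration = 10,
                     noise_sd = 0, seed = 12, active_fraction = 1)
  pl <- simulate_plate(spec, data.frame(well = 1, compound_id = "C",
                                        concentration = 0),
                       list(C = compound_truth("C", 1)))
  for (ch in pl$channels) {
    v <- ch$traces$baseline$samples
    # count entries into the negative template lobe (< 90% of peak)
    deep <- v < -0.9 * spec$spike_amplitude
    entries <- sum(deep & !c(FALSE, deep[-length(deep)]))
    expect_equal(entries, length(ch$true_spikes$baseline))
  }
})

test_that("the realised Poisson rate is calibrated to its target", {
  set.seed(31)
  for (rate in c(0.5, 2, 8)) {
    counts <- replicate(40, length(meascreen:::.sim_spike_times(rate, 300)))
    se <- sqrt(rate * 300) / 300
    expect_lt(abs(mean(counts) / 300 - rate), 3 * se / sqrt(40))
  }
})

test_that("a null compound leaves post rates statistically at baseline", {
  truths <- list(V = compound_truth("V", 1))
  expo <- data.frame(well = "W01", compound_id = "V", concentration = 0)
  nonsig <- logical(50)
  for (s in 1:50) {
    r <- simulate_screen_rates(expo, truths, seed = s)
    nonsig[s] <- paired_wilcoxon(r$rate_before, r$rate_after) > 0.01
  }
  expect_gte(mean(nonsig), 0.95)
})

test_that("dosing at the true IC50 halves the firing rate", {
  truths <- list(C = compound_truth("C", ic50_true = 4, hill_n_true = 3))
  expo <- data.frame(well = sprintf("W%02d", 1:20), compound_id = "C",
                     concentration = 4)
  r <- simulate_screen_rates(expo, truths, seed = 77, n_channels = 12)
  ratio <- mean(r$rate_after) / mean(r$rate_before)
  # Poisson sampling error on the pooled counts
  tot <- sum(r$rate_before) * 300
  se <- 0.5 * sqrt(1 / (0.5 * tot) + 1 / tot)
  expect_lt(abs(ratio - 0.5), 4 * se)
})

test_that("simulator rejects invalid exposures", {
  spec <- plate_spec(n_wells = 1, n_electrodes = 1, duration = 1)
  truths <- list(C = compound_truth("C", 1))
  expect_error(simulate_plate(spec,
    data.frame(well = 1, compound_id = "MYSTERY", concentration = 1),
    truths), "unknown compound")
  expect_error(simulate_plate(spec,
    data.frame(well = 1, compound_id = "C", concentration = -1),
    truths), "non-negative")
})

test_that("noiseless LDH readings sit exactly at their design fractions", {
  truths <- list(TOX = compound_truth("TOX", 1, toxic = TRUE),
                 SAFE = compound_truth("SAFE", 1, toxic = FALSE))
  ldh <- simulate_ldh(truths, seed = 1, noise_sd = 0)
  at <- function(role, id = NA) {
    sel <- ldh$role == role & ldh$timepoint_h == 1
    if (!is.na(id)) sel <- sel & ldh$compound_id == id
    ldh[which(sel)[1], ]
  }
  veh <- at("vehicle"); pos <- at("positive_control")
  expect_equal(ldh_activity(at("sample", "TOX"), veh, pos), 20)
  expect_equal(ldh_activity(at("sample", "SAFE"), veh, pos), 1)
})

test_that("AP sweep kinds honour their voltage-class contracts", {
  q <- simulate_ap_sweep("quiet", seed = 2)
  expect_true(all(q$value < -40))
  expect_equal(nrow(attr(q, "truth")), 0)
  a <- simulate_ap_sweep("attempting", seed = 2)
  expect_true(all(attr(a, "truth")$peak_mV > -40 &
                  attr(a, "truth")$peak_mV < 0))
  s <- simulate_ap_sweep("spontaneous", seed = 2)
  expect_true(any(attr(s, "truth")$peak_mV >= 0))
})

test_that("voltage-step families honour their contracts at c = 0 and TTX", {
  # steep block (ic50 >> h) so the linear-Boltzmann residual at c = 0 is
  # negligible and the vehicle family coincides with control
  fam <- simulate_voltage_step_family(10, 1.25, concentrations = c(0, 10))
  iv0 <- extract_iv(fam$conditions$c_0)
  ivc <- extract_iv(fam$conditions$control)
  expect_equal(iv0$nav_activation, ivc$nav_activation, tolerance = 1e-3)
  ivt <- extract_iv(fam$conditions$ttx)
  expect_true(all(abs(ivt$nav_activation) < 1e-9))
  ivh <- extract_iv(fam$conditions$c_10)
  expect_equal(ttx_normalised_inhibition(ivc, ivh, ivt), 0.5,
               tolerance = 1e-9)
})
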