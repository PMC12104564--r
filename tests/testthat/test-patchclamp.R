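test_that("resting Vm is the spike-masked mean over the first 30 s", {
  fs <- 10000
  tt <- (0:(35 * fs - 1)) / fs
  flat <- patch_sweep(tt, rep(-60, length(tt)), "gapfree")
  expect_equal(resting_vm(flat), -60)

  sw <- simulate_ap_sweep("spontaneous", seed = 4)
  expect_lt(abs(resting_vm(sw) - (-60)), 0.5)

  q <- simulate_ap_sweep("quiet", seed = 4)
  expect_lt(abs(resting_vm(q) - (-60)), 0.1)

  short <- patch_sweep((0:9999) / fs, rep(-55, 10000), "gapfree")
  expect_warning(v <- resting_vm(short), "full length")
  expect_equal(v, -55)
})

test_that("gap-free classes follow the 0 mV overshoot rule", {
  expect_equal(classify_gapfree(simulate_ap_sweep("quiet", seed = 1)),
               "quiet")
  att <- simulate_ap_sweep("attempting", seed = 1)
  expect_equal(classify_gapfree(att), "attempting_sap")
  pk <- detect_patch_events(att)$peak_mV
  expect_true(all(pk > -40 & pk < 0))
  spo <- simulate_ap_sweep("spontaneous", seed = 1)
  expect_equal(classify_gapfree(spo), "spontaneous")
  expect_true(any(detect_patch_events(spo)$peak_mV >= 0))
})

test_that("classification is stable under 1 mV added noise", {
  for (s in 1:5) {
    expect_equal(classify_gapfree(
      simulate_ap_sweep("quiet", seed = s, noise_sd = 1)), "quiet")
    expect_equal(classify_gapfree(
      simulate_ap_sweep("spontaneous", seed = s, noise_sd = 1)),
      "spontaneous")
    expect_equal(classify_gapfree(
      simulate_ap_sweep("attempting", seed = s, noise_sd = 1)),
      "attempting_sap")
  }
})

test_that("current-step families map to the five induced-activity classes", {
  fam <- function(kinds, seeds = seq_along(kinds))
    mapply(simulate_ap_sweep, kinds, seeds, SIMPLIFY = FALSE)
  expect_equal(classify_current_step(fam(c("quiet", "iap_single", "quiet"))),
               "single_iap")
  expect_equal(classify_current_step(fam(c("quiet", "iap_train"))), "train")
  expect_equal(classify_current_step(fam(c("quiet", "iap_attempting"))),
               "attempting_single")
  expect_equal(classify_current_step(fam(rep("quiet", 3))), "quiet")
  expect_error(classify_current_step(list()), "empty")
})

test_that("AP parameters recover the analytic shape of a Gaussian spike", {
  sw <- simulate_ap_sweep("spontaneous", seed = 6, noise_sd = 0.2)
  tru <- attr(sw, "truth")
  ap <- spike_parameters(sw, 1)
  expect_false(ap$incomplete)
  # peak / overshoot
  expect_lt(abs(ap$overshoot - tru$peak_mV[1]), 1)
  # half-height width within 5% of 2*sigma*sqrt(2 log 2)
  expect_lt(abs(ap$half_height_width - tru$fwhm_ms[1]) / tru$fwhm_ms[1],
            0.05)
  # max depolarising slope within 5% of height * exp(-1/2) / sigma
  expect_lt(abs(ap$depolarising_rate - tru$max_dvdt[1]) / tru$max_dvdt[1],
            0.05)
  # symmetric spike: repolarising rate mirrors the depolarising rate
  expect_lt(abs(ap$repolarising_rate + ap$depolarising_rate) /
              ap$depolarising_rate, 0.1)
  expect_gt(ap$spike_height, 0)
  expect_lt(ap$after_hyperpolarisation, 0)
  expect_lt(ap$threshold, tru$peak_mV[1])
})

test_that("AP parameter recovery holds across the synthetic sweep bank", {
  for (s in 1:4) {
    sw <- simulate_ap_sweep("spontaneous", seed = 10 + s, noise_sd = 0.3)
    tru <- attr(sw, "truth")
    for (k in seq_len(min(2, nrow(tru)))) {
      ap <- spike_parameters(sw, k)
      # compare against the closed-form width for the threshold-referenced
      # half-height definition (tighter than the FWHM bound below)
      expect_lt(abs(ap$half_height_width - tru$hhw_ms[k]) / tru$hhw_ms[k],
                0.05)
      expect_lt(abs(ap$depolarising_rate - tru$max_dvdt[k]) /
                  tru$max_dvdt[k], 0.05)
    }
  }
})

test_that("I-V extraction reads activation, trough and Kv windows", {
  fam <- simulate_voltage_step_family(4, 3.2, concentrations = 4)
  ivc <- extract_iv(fam$conditions$control)
  expect_equal(ivc$test_potentials, seq(-120, 80, 5))
  # inward peak at the -35 mV step, close to the generator amplitude
  i35 <- which(ivc$test_potentials == -35)
  expect_equal(which.min(ivc$nav_activation), i35)
  expect_lt(abs(ivc$nav_activation[i35] + 500) / 500, 0.02)
  # Kv plateau at +80 mV: 2 pA/mV * (80+80), fully activated
  i80 <- which(ivc$test_potentials == 80)
  expect_lt(abs(ivc$kv_steady[i80] - 320) / 320, 0.01)
  # inactivation trough is inward where availability is high
  im100 <- which(ivc$test_potentials == -100)
  expect_lt(ivc$nav_inactivation[im100], -300)
  expect_gt(ivc$nav_inactivation[i80], -10) # fully inactivated

  # TTX abolishes the inward component everywhere
  ivt <- extract_iv(fam$conditions$ttx)
  expect_true(all(ivt$nav_activation > -1e-6))
  # and leaves Kv untouched
  expect_equal(ivt$kv_steady[i80], ivc$kv_steady[i80], tolerance = 1e-9)
})

test_that("TTX-normalised inhibition hits its anchor points", {
  fam <- simulate_voltage_step_family(4, 3.2, concentrations = 4)
  ivc <- extract_iv(fam$conditions$control)
  ivt <- extract_iv(fam$conditions$ttx)
  ivx <- extract_iv(fam$conditions$c_4)
  expect_equal(ttx_normalised_inhibition(ivc, ivc, ivt), 0)
  expect_equal(ttx_normalised_inhibition(ivc, ivt, ivt), 1)
  expect_equal(ttx_normalised_inhibition(ivc, ivx, ivt), 0.5,
               tolerance = 1e-9)
  expect_error(ttx_normalised_inhibition(ivc, ivx, ivc), "assay error")
})

test_that("inhibition is monotone in the true block fraction and refit
           recovers the generating Boltzmann parameters", {
  concs <- c(0.5, 1, 2, 4, 8, 16, 32)
  fam <- simulate_voltage_step_family(4, 3.2, concentrations = concs)
  ivc <- extract_iv(fam$conditions$control)
  ivt <- extract_iv(fam$conditions$ttx)
  frac <- vapply(concs, function(cc)
    ttx_normalised_inhibition(
      ivc, extract_iv(fam$conditions[[sprintf("c_%g", cc)]]), ivt),
    numeric(1))
  expect_true(all(diff(frac) > 0))
  fit <- fit_dose_response(
    data.frame(concentration = concs, response = frac), "boltzmann_linear")
  expect_equal(fit$ic50, 4, tolerance = 1e-4)
  expect_equal(fit$slope, 3.2, tolerance = 1e-4)
})

test_that("degenerate sweep construction is rejected", {
  expect_error(patch_sweep(c(0, 1e-4, 3e-4), c(1, 2, 3)), "uniform")
  expect_error(simulate_voltage_step_family(4, 3.2, numeric(0)),
               "non-empty")
  expect_error(simulate_ap_sweep("warbling"))
})
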