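test_that("AIC ranking reproduces published difference arithmetic", {
  # competing survival models: (8749.19, 51) vs (8745.79, 53)
  ms <- rank_models(data.frame(deviance = c(8749.19, 8745.79), npar = c(51, 53)))
  expect_equal(ms$dAIC[ms$npar == 53], 0.60, tolerance = 1e-9)
  expect_equal(ms$dAIC[ms$npar == 51], 0, tolerance = 1e-9)
  # cockchafer adult-survival models: (8747.12, 52) best, (8749.19, 51) at 0.07
  ms2 <- rank_models(data.frame(deviance = c(8747.12, 8749.19), npar = c(52, 51)))
  expect_equal(ms2$dAIC[ms2$npar == 51], 0.07, tolerance = 1e-9)
})

test_that("a single model gets dAIC 0 and weight 1", {
  ms <- rank_models(data.frame(deviance = 100, npar = 3))
  expect_equal(ms$dAIC, 0)
  expect_equal(ms$weight, 1)
})

test_that("weights sum to one and are invariant to a deviance offset", {
  dev <- c(500.2, 498.7, 505.1, 501.4)
  k <- c(10, 12, 9, 11)
  a <- rank_models(data.frame(deviance = dev, npar = k))
  b <- rank_models(data.frame(deviance = dev + 1234.5, npar = k))
  expect_equal(sum(a$weight), 1, tolerance = 1e-12)
  expect_equal(a$weight, b$weight, tolerance = 1e-12)
  expect_equal(a$dAIC, b$dAIC, tolerance = 1e-10)
  expect_equal(a$dAIC[1], 0)
  expect_true(!is.unsorted(a$dAIC))
})

test_that("AIC ties are broken in favour of fewer parameters", {
  ms <- rank_models(data.frame(deviance = c(100, 104), npar = c(5, 3),
                               model = c("big", "small")))
  expect_equal(ms$model, c("small", "big"))
})

test_that("model averaging returns conditional values in the degenerate cases", {
  # one model: its own estimate and SE
  expect_equal(akaike_average(0.8, 0.02, 1), c(estimate = 0.8, se = 0.02))
  # equal estimates: between-model variance vanishes whatever the weights
  expect_equal(akaike_average(c(0.7, 0.7), c(0.03, 0.03), c(0.9, 0.1)),
               c(estimate = 0.7, se = 0.03))
  # hand-evaluated unconditional SE
  out <- akaike_average(c(0.8, 0.9), c(0.02, 0.02), c(0.5, 0.5))
  expect_equal(unname(out["estimate"]), 0.85)
  expect_equal(unname(out["se"]), sqrt(0.02^2 + 0.05^2), tolerance = 1e-12)
  # weights are renormalised internally
  out2 <- akaike_average(c(0.8, 0.9), c(0.02, 0.02), c(2, 2))
  expect_equal(out, out2)
})

test_that("the unconditional SE never falls below agreement cases and grows with spread", {
  base <- akaike_average(c(0.8, 0.8), c(0.05, 0.02), c(0.6, 0.4))
  spread <- akaike_average(c(0.75, 0.85), c(0.05, 0.02), c(0.6, 0.4))
  expect_gte(spread["se"], base["se"])
})

test_that("averaging across fitted models honours the weight threshold", {
  cfg <- myotis_config()
  des <- subset_releases(cfg$design, 100L)
  sim <- simulate_dataset(des, cfg$rates, seed = 41)
  m1 <- ms_model(phi_juv = ".", phi_ad = ".", alpha = "a3",
                 move_juv = ".", move_ad = ".", p = ".", fix = list(alpha1 = 0))
  m2 <- ms_model(phi_juv = ".", phi_ad = "species", alpha = "a3",
                 move_juv = ".", move_ad = ".", p = ".", fix = list(alpha1 = 0))
  f1 <- ms_fit(m1, sim, starts = 1)
  f2 <- ms_fit(m2, sim, starts = 1)
  ms <- rank_models(list(f1, f2), labels = c("constant", "species"))
  expect_equal(sum(ms$weight), 1, tolerance = 1e-12)
  avg <- model_average(ms, "phi_ad",
                       which = list(species = "blythii", colony = "N", interval = 1))
  expect_true(avg["estimate"] > 0 && avg["estimate"] < 1)
  expect_true(avg["se"] >= 0)
  # with a threshold above every weight the call must fail, not fabricate
  expect_error(model_average(ms, "phi_ad", threshold = 1.5), "threshold")
  # table-built sets carry no fits to average over
  tab <- rank_models(data.frame(deviance = c(10, 12), npar = c(1, 1)))
  expect_error(model_average(tab, "phi_ad"), "table")

  # ranked-table TSV writer round-trips the layout
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_table(ms, path)
  back <- read.delim(path)
  expect_equal(names(back), c("model", "deviance", "parameters", "dAIC", "weight"))
  expect_equal(back$dAIC[1], 0)
})

test_that("models fitted to different datasets refuse to be ranked together", {
  cfg <- myotis_config()
  des <- subset_releases(cfg$design, 60L)
  m <- ms_model(phi_juv = ".", phi_ad = ".", alpha = "a3",
                move_juv = ".", move_ad = ".", p = ".", fix = list(alpha1 = 0))
  f1 <- ms_fit(m, simulate_dataset(des, cfg$rates, seed = 1), starts = 1)
  f2 <- ms_fit(m, simulate_dataset(des, cfg$rates, seed = 2), starts = 1)
  expect_error(rank_models(list(f1, f2)), "different datasets")
})
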