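test_that("degenerate histories have the documented likelihoods", {
  des <- toy_design(T = 2L, species = "A")
  # release at the final occasion: empty product, probability 1
  des3 <- toy_design(T = 3L, species = "A")
  r3 <- random_rates(des3, 1)
  expect_equal(history_nll(r3, c(0L, 0L, 3L), "A", "adult"), 0)

  # adult breeder, one later occasion, p = 1, no dispersal, phi_ad = 0.8,
  # never reseen: the only unseen outcome is death
  r <- rate_set(des, phi_juv = 0.5, phi_ad = 0.8, alpha = c(0, 0, 0, 1), p = 1)
  expect_equal(history_nll(r, c(3L, 0L), "A", "adult"), -log(0.2), tolerance = 1e-12)
  # ... and being reseen has probability phi_ad
  expect_equal(history_nll(r, c(3L, 3L), "A", "adult"), -log(0.8), tolerance = 1e-12)
})

test_that("forward recursion equals path enumeration on random histories", {
  des <- toy_design(T = 5L, skipped = 2002L, cockchafer = 2001L)
  des$releases <- msrecap:::validate_releases(
    expand.grid(year = c(2000L, 2001L), colony = des$colonies,
                species = des$species, age = c("juvenile", "adult"), n = 4L,
                stringsAsFactors = FALSE), des)
  for (seed in 1:3) {
    gen <- random_rates(des, seed)
    sim <- simulate_dataset(des, gen, seed = seed)
    eval_rates <- random_rates(des, seed + 100)   # evaluate under different rates
    for (i in seq_len(nrow(sim$obs))) {
      expect_equal(
        history_nll(eval_rates, sim$obs[i, ], sim$info$species[i],
                    sim$info$age_at_marking[i]),
        oracle_history_nll(eval_rates, sim$obs[i, ], sim$info$species[i],
                           sim$info$age_at_marking[i]),
        tolerance = 1e-10)
    }
  }
})

test_that("dataset deviance is additive and matches the per-history sum", {
  des <- toy_design(T = 4L)
  r <- random_rates(des, 5)
  two <- hand_data(des, list(
    list(id = "a", species = "A", age = "juvenile", codes = c(1, 0, 3, 0)),
    list(id = "b", species = "A", age = "juvenile", codes = c(1, 0, 3, 0))))
  one <- hand_data(des, list(
    list(id = "a", species = "A", age = "juvenile", codes = c(1, 0, 3, 0))))
  expect_equal(dataset_deviance(two, r), 2 * dataset_deviance(one, r))

  empty <- ms_data(des, data.frame(id = character(0), species = character(0),
                                   age_at_marking = character(0)),
                   matrix(integer(0), 0, 4))
  expect_equal(dataset_deviance(empty, r), 0)

  cfg <- myotis_config()
  sdes <- subset_releases(cfg$design, 100L)
  sim <- simulate_dataset(sdes, cfg$rates, seed = 11)
  per_hist <- sum(vapply(seq_len(nrow(sim$obs)), function(i)
    history_nll(cfg$rates, sim$obs[i, ], sim$info$species[i],
                sim$info$age_at_marking[i]), numeric(1)))
  expect_equal(dataset_deviance(sim, cfg$rates), 2 * per_hist, tolerance = 1e-8)
})

test_that("probabilities of all observation tails after release sum to one", {
  des <- toy_design(T = 4L, species = "A", cockchafer = 2001L)
  r <- random_rates(des, 9)
  for (case in list(list(age = "juvenile", init = 1L),
                    list(age = "juvenile", init = 2L),
                    list(age = "adult", init = 3L))) {
    H <- enumerate_histories(des, case$age, case$init)
    tot <- sum(vapply(seq_len(nrow(H)), function(i)
      exp(-history_nll(r, H[i, ], "A", case$age)), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("a fixed zero recapture makes any later sighting impossible", {
  des <- toy_design(T = 4L, species = "A")
  r <- rate_set(des, phi_juv = 0.5, phi_ad = 0.8, alpha = c(0, 0.3, 0.6, 1),
                p = 0)
  expect_equal(history_nll(r, c(3L, 0L, 3L, 0L), "A", "adult"), Inf)
  # and the fit aborts with a data-model diagnostic instead of dropping rows
  d <- hand_data(des, list(
    list(id = "a", species = "A", age = "adult", codes = c(3, 0, 3, 0))))
  m <- ms_model(phi_juv = ".", phi_ad = ".", alpha = "a3",
                move_juv = ".", move_ad = ".", p = ".", fix = list(p = 0))
  expect_error(ms_fit(m, d, starts = 1), "impossible")
})

test_that("likelihood is invariant to history order", {
  cfg <- myotis_config()
  des <- subset_releases(cfg$design, 60L)
  sim <- simulate_dataset(des, cfg$rates, seed = 21)
  perm <- sample(nrow(sim$obs))
  shuffled <- ms_data(des, sim$info[perm, ], sim$obs[perm, ])
  expect_equal(dataset_deviance(shuffled, cfg$rates),
               dataset_deviance(sim, cfg$rates), tolerance = 1e-10)
})
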