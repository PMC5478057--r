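test_that("CSV capture histories parse, validate, and report bad rows by line", {
  des <- toy_design(T = 5L, species = c("blythii", "myotis"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,species,age_at_marking,y2000,y2001,y2002,y2003,y2004",
    "b001,blythii,juvenile,1,0,1,0,3",      # released occ 1, breeder at occ 5
    "b002,blythii,adult,0,3,0,4,0",
    "b003,myotis,juvenile,2,2,0,4,4",
    "b004,blythii,juvenile,1,3,0,0,1",      # reversal 3 -> 1
    "b005,myotis,adult,0,0,3,3,3",
    "b006,myotis,juvenile,1,1,1,0,0"), path)
  expect_warning(d <- read_histories(path, des), "malformed")
  expect_equal(nrow(d$obs), 5L)
  prob <- attr(d, "problems")
  expect_equal(nrow(prob), 1L)
  expect_equal(prob$line, 5L)               # header is line 1
  expect_match(prob$message, "reversal")
  expect_equal(unname(d$obs["b001", ]), c(1L, 0L, 1L, 0L, 3L))
  rel <- which(d$obs["b001", ] != 0)[1]
  expect_equal(unname(rel), 1L)
})

test_that("history validation rejects each documented violation", {
  des <- toy_design(T = 4L, skipped = 2002L)
  bad <- list(
    list(codes = c(1, 0, 0, 5), age = "juvenile", why = "codes"),
    list(codes = c(0, 1, 0, 3), age = "adult", why = "young-state"),
    list(codes = c(3, 0, 0, 1), age = "juvenile", why = "state 1 or 2"),
    list(codes = c(1, 3, 0, 2), age = "juvenile", why = "reversal"),
    list(codes = c(1, 0, 2, 0), age = "juvenile", why = "skipped"),
    list(codes = c(0, 0, 0, 0), age = "juvenile", why = "no capture"))
  for (b in bad) {
    msg <- msrecap:::history_problem(as.integer(b$codes), "A", b$age, des)
    expect_false(is.null(msg), label = b$why)
  }
  expect_null(msrecap:::history_problem(c(1L, 3L, 0L, 4L), "A", "juvenile", des))
})

test_that("summaries are additive, exhaustive, and exact on an empty dataset", {
  des <- toy_design(T = 4L)
  empty <- ms_data(des, data.frame(id = character(0), species = character(0),
                                   age_at_marking = character(0)),
                   matrix(integer(0), 0, 4))
  s <- summary(empty)
  expect_equal(sum(s$marked), 0L)
  expect_equal(sum(s$by_colony), 0L)

  d <- hand_data(des, list(
    list(id = "x1", species = "A", age = "juvenile", codes = c(1, 0, 0, 3)),
    list(id = "x2", species = "A", age = "adult", codes = c(0, 4, 4, 0)),
    list(id = "x3", species = "B", age = "juvenile", codes = c(2, 2, 0, 0))))
  s <- summary(d)
  expect_equal(unname(s$marked), c(2L, 1L))
  expect_equal(unname(s$known_age), c(1L, 1L))
  expect_equal(sum(s$marked), s$n)
  expect_equal(sum(s$by_colony), s$n)
})

test_that("simulated datasets round-trip through CSV and .inp unchanged", {
  cfg <- myotis_config()
  des <- subset_releases(cfg$design, 50L)
  sim <- simulate_dataset(des, cfg$rates, seed = 7)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_histories(sim, csv)
  back <- read_histories(csv, des)
  expect_equal(back$info, sim$info)
  expect_equal(back$obs, sim$obs)

  inp <- withr::local_tempfile(fileext = ".inp")
  write_inp(sim, inp)
  lines <- readLines(inp)
  expect_true(all(grepl(";$", lines)))
  back2 <- read_inp(inp, des)
  expect_equal(back2$info, sim$info)
  expect_equal(back2$obs, sim$obs)
  # the skipped 1994 occasion survives as an all-zero column
  expect_true(all(back2$obs[, "1994"] == 0L))
})

test_that("round-trip holds over randomly generated valid datasets", {
  for (seed in 1:3) {
    des <- toy_design(T = 5L, skipped = if (seed == 2) 2002L else integer(0))
    des$releases <- msrecap:::validate_releases(
      expand.grid(year = setdiff(des$years[1:3], des$skipped),
                  colony = des$colonies, species = des$species,
                  age = c("juvenile", "adult"), n = 2L,
                  stringsAsFactors = FALSE), des)
    sim <- simulate_dataset(des, random_rates(des, seed), seed = seed)
    f <- withr::local_tempfile(fileext = ".csv")
    write_histories(sim, f)
    back <- read_histories(f, des)
    expect_equal(back$obs, sim$obs)
    expect_equal(back$info, sim$info)
  }
})

test_that("study designs round-trip through the YAML configuration format", {
  cfg <- myotis_config()
  path <- withr::local_tempfile(fileext = ".yml")
  write_design(cfg$design, path)
  back <- read_design(path)
  expect_equal(back$years, cfg$design$years)
  expect_equal(back$skipped, cfg$design$skipped)
  expect_equal(back$cockchafer_years, cfg$design$cockchafer_years)
  expect_equal(sum(back$releases$n), sum(cfg$design$releases$n))
})
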