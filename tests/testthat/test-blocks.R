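# Rate sets with hand-chosen values for checking printed matrix entries.
block_rates <- function(des, phi_juv, phi_ad, alpha, n_NR = 0, n_RN = 0,
                        b_NR = 0, b_RN = 0, p = 1) {
  rate_set(des, phi_juv = phi_juv, phi_ad = phi_ad, alpha = alpha,
           natal_NR = n_NR, natal_RN = n_RN,
           breeding_NR = b_NR, breeding_RN = b_RN, p = p)
}

test_that("juvenile block reproduces the printed first-year structure", {
  des <- toy_design(T = 3L, species = "A")
  # no survival: everything dies
  r0 <- block_rates(des, 0, 0.8, c(0.2, 0.5, 0.5, 1))
  M <- juvenile_block(r0, 1, 1)$matrix
  expect_equal(unname(M[1, ]), c(0, 0, 0, 0, 1))
  expect_equal(unname(M[2, ]), c(0, 0, 0, 0, 1))

  # phi_juv = 0.5, natal NR = 0.1, alpha1 = 0.2 -> (1,3) = 0.5 * 0.9 * 0.2
  r <- block_rates(des, 0.5, 0.8, c(0.2, 0.5, 0.5, 1), n_NR = 0.1, n_RN = 0.3)
  M <- juvenile_block(r, 1, 1)$matrix
  expect_equal(unname(M[1, 3]), 0.09)
  expect_equal(unname(M[1, 1]), 0.5 * 0.9 * 0.8)
  expect_equal(unname(M[1, 2]), 0.5 * 0.1 * 0.8)
  expect_equal(unname(M[1, 4]), 0.5 * 0.1 * 0.2)
  # live mass of a row equals that colony's first-year survival
  expect_equal(sum(M[1, 1:4]), 0.5)
  expect_equal(sum(M[2, 1:4]), 0.5)
  # no breeders exist at age 0
  expect_equal(unname(M[3, ]), c(0, 0, 0, 0, 1))
})

test_that("immature blocks use attained-age first breeding, forced at age 4", {
  des <- toy_design(T = 3L, species = "A")
  r <- block_rates(des, 0.5, 0.8, c(0.2, 0.5, 0.7, 1))
  # attained age 4: alpha = 1 leaves no mass in the not-yet-bred states
  M4 <- immature_block(r, age = 4, 1, 1)$matrix
  expect_equal(unname(M4[1, 1:2]), c(0, 0))
  expect_equal(unname(M4[2, 1:2]), c(0, 0))
  # phi_ad = 0.8, b_NR = 0, alpha2 = 0.5 -> row 1 = (.4, 0, .4, 0, .2)
  M2 <- immature_block(r, age = 2, 1, 1)$matrix
  expect_equal(unname(M2[1, ]), c(0.4, 0, 0.4, 0, 0.2))
  # breeder rows equal the experienced block rows at the same rates
  E <- experienced_block(r, 1, 1)$matrix
  expect_equal(M2[3:4, ], E[3:4, ])
})

test_that("experienced block reproduces the printed adult structure", {
  des <- toy_design(T = 3L, species = "A")
  # no dispersal: diagonal survival on the breeder states
  r0 <- block_rates(des, 0.5, 0.8, c(0, 0, 0, 1))
  E <- experienced_block(r0, 1, 1)$matrix
  expect_equal(unname(E[3:4, 3:4]), diag(c(0.8, 0.8)))
  # phi_ad(R) = 0.84, b_RN = 0.142 -> (4,3) = 0.11928, (4,4) = 0.72072
  r <- block_rates(des, 0.5, 0.84, c(0, 0, 0, 1), b_RN = 0.142)
  E <- experienced_block(r, 1, 1)$matrix
  expect_equal(unname(E[4, 3]), 0.84 * 0.142)
  expect_equal(unname(E[4, 4]), 0.84 * (1 - 0.142))
  expect_equal(sum(E[4, 3:4]), 0.84)
  # not-yet-bred states cannot exist from age 5 onward
  expect_equal(unname(E[1, ]), c(0, 0, 0, 0, 1))
})

test_that("block_for dispatches on age at marking and attained age", {
  des <- toy_design(T = 8L, species = "A")
  r <- random_rates(des, 3)
  juv <- block_for(r, "juvenile", release = 3L, interval = 3L)
  expect_equal(juv$matrix, juvenile_block(r, 1, 3)$matrix)
  imm <- block_for(r, "juvenile", release = 1L, interval = 2L)
  expect_equal(imm$matrix, immature_block(r, 2, 1, 2)$matrix)
  exp5 <- block_for(r, "juvenile", release = 1L, interval = 5L)
  expect_equal(exp5$matrix, experienced_block(r, 1, 5)$matrix)
  for (i in 1:7)
    expect_equal(block_for(r, "adult", 1L, i)$matrix,
                 experienced_block(r, 1, i)$matrix)
  expect_error(block_for(r, "juvenile", release = 4L, interval = 2L), "release")
})

test_that("every block is row-stochastic with an absorbing dead state", {
  des <- toy_design(T = 6L, skipped = 2003L, cockchafer = c(2001L, 2004L))
  for (seed in 1:5) {
    r <- random_rates(des, seed)
    for (sp in 1:2) for (i in 1:5) for (co in 1:2) {
      blocks <- list(juvenile_block(r, sp, i, co)$matrix,
                     immature_block(r, 2, sp, i, co)$matrix,
                     immature_block(r, 3, sp, i, co)$matrix,
                     immature_block(r, 4, sp, i, co)$matrix,
                     experienced_block(r, sp, i)$matrix)
      for (M in blocks) {
        expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
        expect_equal(unname(M[5, ]), c(0, 0, 0, 0, 1))
        expect_true(all(M[3:4, 1:2] == 0))   # having bred is absorbing
        expect_true(all(M >= 0 & M <= 1))
      }
      # the internal fast constructor agrees with the documented blocks
      for (ty in 1:5) {
        ref <- switch(ty, juvenile_block(r, sp, i, co)$matrix,
                      immature_block(r, 2, sp, i, co)$matrix,
                      immature_block(r, 3, sp, i, co)$matrix,
                      immature_block(r, 4, sp, i, co)$matrix,
                      experienced_block(r, sp, i)$matrix)
        expect_equal(msrecap:::block_matrix(r, ty, sp, i, co), unname(ref))
      }
    }
  }
})

test_that("survival increases every live entry of its rows", {
  des <- toy_design(T = 3L, species = "A")
  lo <- block_rates(des, 0.4, 0.6, c(0.2, 0.5, 0.7, 1), n_NR = 0.1, n_RN = 0.2,
                    b_NR = 0.05, b_RN = 0.1)
  hi <- block_rates(des, 0.6, 0.8, c(0.2, 0.5, 0.7, 1), n_NR = 0.1, n_RN = 0.2,
                    b_NR = 0.05, b_RN = 0.1)
  for (get in list(function(r) juvenile_block(r, 1, 1)$matrix,
                   function(r) immature_block(r, 3, 1, 1)$matrix,
                   function(r) experienced_block(r, 1, 1)$matrix)) {
    expect_true(all(get(hi)[, 1:4] >= get(lo)[, 1:4]))
  }
})

test_that("with no early breeding, breeder states are reached only by the forced age-4 step", {
  des <- toy_design(T = 6L, species = "A")
  r <- block_rates(des, 0.9, 0.9, c(0, 0, 0, 1), n_NR = 0.1, n_RN = 0.1,
                   b_NR = 0.1, b_RN = 0.1)
  f <- c(1, 0, 0, 0, 0)                     # juvenile released in colony 1
  f <- f %*% juvenile_block(r, 1, 1)$matrix
  f <- f %*% immature_block(r, 2, 1, 2)$matrix
  f <- f %*% immature_block(r, 3, 1, 3)$matrix
  expect_equal(sum(f[3:4]), 0)              # no breeders through age 3
  f <- f %*% immature_block(r, 4, 1, 4)$matrix
  expect_equal(sum(f[1:2]), 0)              # all survivors forced to breed
  expect_gt(sum(f[3:4]), 0)
})
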