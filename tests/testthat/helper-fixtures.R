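# Small designs, random rate sets and hand-built datasets used across tests.

toy_design <- function(T = 4L, species = c("A", "B"), skipped = integer(0),
                       cockchafer = integer(0)) {
  ms_design(2000L + seq_len(T) - 1L, colonies = c("N", "R"), species = species,
            skipped = skipped, cockchafer_years = cockchafer)
}

random_rates <- function(design, seed = 1L) {
  set.seed(seed)
  T <- length(design$years)
  S <- length(design$species)
  arr <- function(d) array(runif(prod(d), 0.05, 0.95), dim = d)
  alpha <- arr(c(4L, 2L, S, T - 1L, 2L))
  alpha[4L, , , , ] <- 1
  rate_set(design,
           phi_juv = arr(c(2L, S, T - 1L)),
           phi_ad = arr(c(2L, S, T - 1L)),
           alpha = alpha,
           natal_NR = runif(S, 0, 0.3), natal_RN = runif(S, 0, 0.3),
           breeding_NR = runif(S, 0, 0.3), breeding_RN = runif(S, 0, 0.3),
           p = arr(c(2L, S, 2L, T - 1L)))
}

# every valid observation sequence starting in `init_state` at `release`
enumerate_histories <- function(design, age, init_state, release = 1L) {
  T <- length(design$years)
  tails <- as.matrix(expand.grid(rep(list(0:4), T - release)))
  obs <- cbind(matrix(0L, nrow(tails), release - 1L), init_state, tails)
  colnames(obs) <- NULL
  sp <- design$species[1L]
  keep <- apply(obs, 1L, function(y)
    is.null(msrecap:::history_problem(as.integer(y), sp, age, design)))
  obs[keep, , drop = FALSE]
}

# dataset from explicit rows: list of list(id, species, age, codes)
hand_data <- function(design, rows) {
  info <- data.frame(id = vapply(rows, `[[`, character(1), "id"),
                     species = vapply(rows, `[[`, character(1), "species"),
                     age_at_marking = vapply(rows, `[[`, character(1), "age"),
                     stringsAsFactors = FALSE)
  obs <- do.call(rbind, lapply(rows, function(r) as.integer(r$codes)))
  ms_data(design, info, obs)
}
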