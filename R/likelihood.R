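#' Negative log-likelihood of one capture history
#'
#' The probability of the observation sequence after the release occasion,
#' conditional on release in the observed state, evaluated by the forward
#' (hidden-Markov) recursion: the state distribution starts as a point mass
#' on the state at first capture; each interval propagates it through the
#' age-appropriate transition block; each subsequent occasion weights the
#' live states by the detection outcome (the observed state's recapture
#' probability when seen, one minus it per live state when not; the dead
#' state is never detected).
#'
#' @param rates An `ms_rates` object.
#' @param observations Integer vector of codes 0-4, one per occasion.
#' @param species Species label or index.
#' @param age_at_marking `"juvenile"` or `"adult"`.
#' @return The negative log-probability (0 for a history with no occasion
#'   after release; `Inf` for a history that is impossible under the model).
#' @export
history_nll <- function(rates, observations, species, age_at_marking = "juvenile") {
  stopifnot(inherits(rates, "ms_rates"))
  d <- rates$design
  T <- n_occasions(d)
  y <- as.integer(observations)
  if (length(y) != T) stop("history length must equal the number of occasions")
  msg <- history_problem(y, if (is.character(species)) species else d$species[species],
                         age_at_marking, d)
  if (!is.null(msg)) stop("invalid history: ", msg)
  s <- resolve_species(rates, species)
  release <- which(y != 0L)[1L]
  cohort <- birth_cohort(d, release, age_at_marking)
  f <- numeric(5L)
  f[y[release]] <- 1
  if (release == T) return(0)
  for (t in seq.int(release + 1L, T)) {
    blk <- block_for(rates, age_at_marking, release, t - 1L, s, cohort)
    f <- drop(f %*% blk$matrix)
    pv <- blk$recapture
    if (y[t] == 0L) {
      f <- f * c(1 - pv, 1)
    } else {
      f <- replace(numeric(5L), y[t], f[y[t]] * pv[y[t]])
    }
  }
  ll <- sum(f)
  if (ll <= 0) Inf else -log(ll)
}

# cockchafer cohort class of a history (2 = born in a cockchafer year);
# adult-marked females have an unknown birth year and never use alpha,
# so class 1 is an arbitrary placeholder.
birth_cohort <- function(design, release, age_at_marking) {
  if (age_at_marking == "adult") return(1L)
  if (design$years[release] %in% cc_years(design)) 2L else 1L
}

#' Deviance of a dataset under fixed rates
#'
#' Minus twice the summed log-likelihood over independent individuals (no
#' saturated-model constant).  Identical histories contribute additively.
#'
#' @param data An `ms_data` object.
#' @param rates An `ms_rates` object on the same design.
#' @return `2 * sum(history_nll(...))` over all histories.
#' @export
dataset_deviance <- function(data, rates) {
  stopifnot(inherits(data, "ms_data"), inherits(rates, "ms_rates"))
  2 * grouped_nll(group_histories(data), rates)
}

# ---------------------------------------------------------------------------
# Grouped, vectorised likelihood used by the optimizer.  Histories sharing
# (species, age at marking, release occasion) march through the same block
# sequence, so the forward recursion runs on an n x 5 matrix per group.
# Duplicate observation rows within a group are collapsed with counts, the
# block needed at every step is resolved to an id in a descriptor table at
# grouping time, and the observation weights are pre-indexed, so that one
# likelihood evaluation only builds each distinct 5 x 5 matrix once.

group_histories <- function(data) {
  d <- data$design
  T <- n_occasions(d)
  obs <- data$obs
  rel <- release_occasion(obs)
  spi <- match(data$info$species, d$species)
  adult <- data$info$age_at_marking == "adult"

  desc <- matrix(integer(0), 0L, 4L,
                 dimnames = list(NULL, c("type", "species", "interval", "cohort")))
  desc_key <- character(0)
  get_desc <- function(type, sp, i, co) {
    k <- paste(type, sp, i, co)
    j <- match(k, desc_key)
    if (is.na(j)) {
      desc_key <<- c(desc_key, k)
      desc <<- rbind(desc, c(type, sp, i, co))
      j <- length(desc_key)
    }
    j
  }

  key <- paste(spi, adult, rel)
  groups <- lapply(split(seq_len(nrow(obs)), key), function(idx) {
    r <- rel[idx[1L]]
    sp <- spi[idx[1L]]
    ad <- adult[idx[1L]]
    cohort <- birth_cohort(d, r, if (ad) "adult" else "juvenile")
    pat <- apply(obs[idx, , drop = FALSE], 1L, paste, collapse = ",")
    tab <- table(pat)
    Y <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
    steps <- if (r < T) lapply(seq.int(r + 1L, T), function(t) {
      attained <- t - r   # age reached at occasion t (juvenile-marked)
      type <- if (ad || attained >= 5L) 5L else attained
      y <- Y[, t]
      seen <- which(y != 0L)
      list(block = get_desc(type, sp, t - 1L, cohort), occ = t - 1L,
           miss = which(y == 0L), seen = seen, state = y[seen])
    }) else list()
    list(species = sp, adult = ad, release = r, cohort = cohort,
         Y = Y, count = as.numeric(tab), members = idx, steps = steps)
  })
  structure(list(groups = unname(groups), desc = desc, T = T, n = nrow(obs),
                 n_species = length(d$species)),
            class = "ms_groups")
}

# bare 5x5 transition matrix for a block descriptor (type 1 = juvenile
# interval, 2-4 = immature interval to that attained age, 5 = experienced)
block_matrix <- function(rates, type, sp, i, cohort) {
  M <- matrix(0, 5L, 5L)
  M[5L, 5L] <- 1
  if (type == 1L) {
    phi <- rates$phi_juv[, sp, i]
    mv <- rates$move_juv[, sp]
    a <- rates$alpha[1L, , sp, i, cohort]
    M[1L, 1:4] <- phi[1L] * c((1 - mv[1L]) * (1 - a[1L]), mv[1L] * (1 - a[2L]),
                              (1 - mv[1L]) * a[1L], mv[1L] * a[2L])
    M[2L, 1:4] <- phi[2L] * c(mv[2L] * (1 - a[1L]), (1 - mv[2L]) * (1 - a[2L]),
                              mv[2L] * a[1L], (1 - mv[2L]) * a[2L])
  } else {
    phi <- rates$phi_ad[, sp, i]
    mv <- rates$move_ad[, sp]
    if (type < 5L) {
      a <- rates$alpha[type, , sp, i, cohort]
      M[1L, 1:4] <- phi[1L] * c((1 - mv[1L]) * (1 - a[1L]), mv[1L] * (1 - a[2L]),
                                (1 - mv[1L]) * a[1L], mv[1L] * a[2L])
      M[2L, 1:4] <- phi[2L] * c(mv[2L] * (1 - a[1L]), (1 - mv[2L]) * (1 - a[2L]),
                                mv[2L] * a[1L], (1 - mv[2L]) * a[2L])
    }
    M[3L, 3:4] <- phi[1L] * c(1 - mv[1L], mv[1L])
    M[4L, 3:4] <- phi[2L] * c(mv[2L], 1 - mv[2L])
  }
  # clamp: the live entries can sum to 1 + eps in floating point, and a
  # negative dead-state mass would leak sign into the path probabilities
  M[1:4, 5L] <- pmax(0, 1 - rowSums(M[1:4, 1:4, drop = FALSE]))
  M
}

# total NLL; attr "per_group" holds group NLL vectors when detail = TRUE
grouped_nll <- function(gr, rates, detail = FALSE) {
  blocks <- lapply(seq_len(nrow(gr$desc)), function(j)
    block_matrix(rates, gr$desc[j, 1L], gr$desc[j, 2L], gr$desc[j, 3L], gr$desc[j, 4L]))
  # recapture vectors (nb1, nb2, br1, br2) per species x interval
  pv_tab <- lapply(seq_len(gr$n_species), function(s)
    rbind(rates$p[1L, s, 1L, ], rates$p[2L, s, 1L, ],
          rates$p[1L, s, 2L, ], rates$p[2L, s, 2L, ]))
  total <- 0
  per <- if (detail) vector("list", length(gr$groups))
  for (k in seq_along(gr$groups)) {
    g <- gr$groups[[k]]
    n <- nrow(g$Y)
    F <- matrix(0, n, 5L)
    F[cbind(seq_len(n), g$Y[, g$release])] <- 1
    pvs <- pv_tab[[g$species]]
    for (st in g$steps) {
      F <- F %*% blocks[[st$block]]
      pv <- pvs[, st$occ]
      if (length(st$miss)) {
        F[st$miss, ] <- F[st$miss, , drop = FALSE] *
          rep(c(1 - pv, 1), each = length(st$miss))
      }
      if (length(st$seen)) {
        vals <- F[cbind(st$seen, st$state)] * pv[st$state]
        F[st$seen, ] <- 0
        F[cbind(st$seen, st$state)] <- vals
      }
    }
    lik <- rowSums(F)
    nll <- rep(Inf, length(lik))
    ok <- is.finite(lik) & lik > 0
    nll[ok] <- -log(lik[ok])
    if (detail) per[[k]] <- nll
    total <- total + sum(g$count * nll)
  }
  if (detail) attr(total, "per_group") <- per
  total
}

# ids of histories that are impossible under the given rates (used for the
# structural data-model diagnostic before fitting)
impossible_histories <- function(data, rates) {
  gr <- group_histories(data)
  nll <- grouped_nll(gr, rates, detail = TRUE)
  bad <- integer(0)
  for (k in seq_along(gr$groups)) {
    g <- gr$groups[[k]]
    inf_pat <- which(!is.finite(attr(nll, "per_group")[[k]]))
    if (length(inf_pat)) {
      pat_of <- match(apply(data$obs[g$members, , drop = FALSE], 1L, paste, collapse = ","),
                      apply(g$Y, 1L, paste, collapse = ","))
      bad <- c(bad, g$members[pat_of %in% inf_pat])
    }
  }
  sort(bad)
}
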