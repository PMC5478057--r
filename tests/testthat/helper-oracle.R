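# Independent likelihood oracle: enumerates every latent state path and sums
# path probabilities built directly from the four printed matrix structures.
# Shares nothing with the package's forward recursion or block constructors.

oracle_matrix <- function(rates, sp, interval, attained, adult, cohort = 1L) {
  phiJ <- rates$phi_juv[, sp, interval]
  phiA <- rates$phi_ad[, sp, interval]
  nv <- rates$move_juv[, sp]
  bv <- rates$move_ad[, sp]
  live <- matrix(0, 4L, 4L)
  if (!adult && attained == 1L) {
    a <- rates$alpha[1L, , sp, interval, cohort]
    live[1L, ] <- phiJ[1L] * c((1 - nv[1L]) * (1 - a[1L]), nv[1L] * (1 - a[2L]),
                               (1 - nv[1L]) * a[1L], nv[1L] * a[2L])
    live[2L, ] <- phiJ[2L] * c(nv[2L] * (1 - a[1L]), (1 - nv[2L]) * (1 - a[2L]),
                               nv[2L] * a[1L], (1 - nv[2L]) * a[2L])
  } else if (!adult && attained <= 4L) {
    a <- rates$alpha[attained, , sp, interval, cohort]
    live[1L, ] <- phiA[1L] * c((1 - bv[1L]) * (1 - a[1L]), bv[1L] * (1 - a[2L]),
                               (1 - bv[1L]) * a[1L], bv[1L] * a[2L])
    live[2L, ] <- phiA[2L] * c(bv[2L] * (1 - a[1L]), (1 - bv[2L]) * (1 - a[2L]),
                               bv[2L] * a[1L], (1 - bv[2L]) * a[2L])
    live[3L, 3:4] <- phiA[1L] * c(1 - bv[1L], bv[1L])
    live[4L, 3:4] <- phiA[2L] * c(bv[2L], 1 - bv[2L])
  } else {
    live[3L, 3:4] <- phiA[1L] * c(1 - bv[1L], bv[1L])
    live[4L, 3:4] <- phiA[2L] * c(bv[2L], 1 - bv[2L])
  }
  rbind(cbind(live, 1 - rowSums(live)), c(0, 0, 0, 0, 1))
}

oracle_history_nll <- function(rates, obs, species, age_at_marking) {
  d <- rates$design
  T <- length(d$years)
  sp <- match(species, d$species)
  adult <- age_at_marking == "adult"
  r <- which(obs != 0L)[1L]
  cc <- if (is.list(d$cockchafer_years)) sort(unique(unlist(d$cockchafer_years)))
        else d$cockchafer_years
  cohort <- if (!adult && d$years[r] %in% cc) 2L else 1L
  if (r == T) return(0)
  k <- T - r
  paths <- as.matrix(expand.grid(rep(list(1:5), k)))
  prob <- rep(1, nrow(paths))
  prev <- rep(obs[r], nrow(paths))
  for (j in seq_len(k)) {
    t <- r + j
    M <- oracle_matrix(rates, sp, t - 1L, j, adult, cohort)
    cur <- paths[, j]
    prob <- prob * M[cbind(prev, cur)]
    pv <- c(rates$p[1L, sp, 1L, t - 1L], rates$p[2L, sp, 1L, t - 1L],
            rates$p[1L, sp, 2L, t - 1L], rates$p[2L, sp, 2L, t - 1L])
    y <- obs[t]
    w <- if (y == 0L) ifelse(cur == 5L, 1, 1 - pv[pmin(cur, 4L)])
         else ifelse(cur == y, pv[y], 0)
    prob <- prob * w
    prev <- cur
  }
  tot <- sum(prob)
  if (tot <= 0) Inf else -log(tot)
}
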