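#' Construct a full set of demographic rates
#'
#' Assembles the probability-scale rates that drive the transition engine and
#' the simulator.  Inputs are broadcast to the canonical array layout: a
#' scalar applies everywhere, a vector of length `length(design$species)`
#' is per-species, and a full array (see Details) is taken as is.
#'
#' @details Canonical layouts (`C` colonies, `S` species, `T` occasions):
#' `phi_juv`/`phi_ad` are `[C, S, T-1]`; `alpha` is `[4, C, S, T-1, 2]`
#' (attained age, destination colony, species, interval, birth-cohort
#' cockchafer class) and may also be given as a length-4 vector or a `4 x S`
#' matrix; dispersal arguments are scalars or per-species vectors; `p` is a
#' scalar, a per-occasion vector (length `T-1`, occasions 2..T), or a full
#' `[C, S, 2, T-1]` array (status `nb`/`br`).  Recapture at skipped
#' occasions is forced to 0 and `alpha` at attained age 4 must be 1.
#'
#' @param design An [ms_design()].
#' @param phi_juv,phi_ad First-year and adult apparent survival.
#' @param alpha Age-specific probabilities of first reproduction.
#' @param natal_NR,natal_RN Natal dispersal (first year) between colonies,
#'   in the direction colony 1 to colony 2 and back.
#' @param breeding_NR,breeding_RN Breeding dispersal of adults.
#' @param p Recapture probability.
#' @return An object of class `ms_rates`.
#' @export
#' @examples
#' d <- ms_design(2000:2004, species = "blythii")
#' rate_set(d, phi_juv = 0.5, phi_ad = 0.84, alpha = c(0, 0.33, 0.63, 1),
#'          natal_NR = 0.02, natal_RN = 0.11, breeding_NR = 0.06,
#'          breeding_RN = 0.14, p = 0.7)
rate_set <- function(design, phi_juv, phi_ad, alpha,
                     natal_NR = 0, natal_RN = 0,
                     breeding_NR = 0, breeding_RN = 0, p = 1) {
  stopifnot(inherits(design, "ms_design"))
  T <- n_occasions(design)
  S <- length(design$species)

  bc_phi <- function(x, what) {
    if (is.array(x) && length(dim(x)) == 3L) {
      if (!all(dim(x) == c(2L, S, T - 1L))) stop(what, ": array must be [2, S, T-1]")
      return(x)
    }
    if (length(x) == 1L) x <- rep(x, S)
    if (length(x) != S) stop(what, ": give a scalar, one value per species, or a full array")
    array(rep(x, each = 2L), dim = c(2L, S, T - 1L))
  }
  bc_alpha <- function(x) {
    if (is.array(x) && length(dim(x)) == 5L) {
      if (!all(dim(x) == c(4L, 2L, S, T - 1L, 2L))) stop("alpha: array must be [4, 2, S, T-1, 2]")
      return(x)
    }
    x <- as.matrix(x)
    if (nrow(x) != 4L) stop("alpha needs one probability per attained age 1-4")
    if (ncol(x) == 1L) x <- x[, rep(1L, S), drop = FALSE]
    if (ncol(x) != S) stop("alpha: give 4 values or a 4 x S matrix")
    a <- array(NA_real_, dim = c(4L, 2L, S, T - 1L, 2L))
    for (s in seq_len(S)) a[, , s, , ] <- x[, s]
    a
  }
  bc_move <- function(nr, rn, what) {
    if (length(nr) == 1L) nr <- rep(nr, S)
    if (length(rn) == 1L) rn <- rep(rn, S)
    if (length(nr) != S || length(rn) != S) stop(what, ": scalar or per-species values")
    matrix(c(nr, rn), nrow = 2L, byrow = TRUE,
           dimnames = list(direction = c("NR", "RN"), species = design$species))
  }
  bc_p <- function(x) {
    if (is.array(x) && length(dim(x)) == 4L) {
      if (!all(dim(x) == c(2L, S, 2L, T - 1L))) stop("p: array must be [2, S, 2, T-1]")
      out <- x
    } else {
      if (length(x) == 1L) x <- rep(x, T - 1L)
      if (length(x) != T - 1L) stop("p: scalar, per-occasion vector (occasions 2..T), or full array")
      out <- array(rep(x, each = 4L * S), dim = c(2L, S, 2L, T - 1L))
    }
    out[, , , design$years[-1L] %in% design$skipped] <- 0
    out
  }

  r <- list(phi_juv = bc_phi(phi_juv, "phi_juv"),
            phi_ad = bc_phi(phi_ad, "phi_ad"),
            alpha = bc_alpha(alpha),
            move_juv = bc_move(natal_NR, natal_RN, "natal dispersal"),
            move_ad = bc_move(breeding_NR, breeding_RN, "breeding dispersal"),
            p = bc_p(p),
            design = design)
  class(r) <- "ms_rates"
  r <- set_rate_dimnames(r)
  validate_rates(r)
  r
}

validate_rates <- function(r) {
  for (f in c("phi_juv", "phi_ad", "alpha", "move_juv", "move_ad", "p")) {
    v <- r[[f]]
    if (anyNA(v) || any(v < 0 | v > 1)) stop(f, ": all rates must lie in [0, 1]")
  }
  if (any(r$alpha[4L, , , , ] != 1))
    stop("alpha at attained age 4 must be 1 (all survivors have started to breed)")
  skip <- r$design$years[-1L] %in% r$design$skipped
  if (any(r$p[, , , skip] != 0))
    stop("recapture at skipped occasions must be 0")
  invisible(r)
}

#' @export
print.ms_rates <- function(x, ...) {
  d <- x$design
  cat("Demographic rate set over", n_occasions(d), "occasions,",
      length(d$species), "species\n")
  cat("  mean phi_juv:", round(mean(x$phi_juv), 3),
      " mean phi_ad:", round(mean(x$phi_ad), 3), "\n")
  cat("  alpha (first species, first interval):",
      paste(round(x$alpha[, 1, 1, 1, 1], 3), collapse = ", "), "\n")
  invisible(x)
}
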