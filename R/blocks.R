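#' Age-specific transition blocks
#'
#' The process model moves a female among five states between consecutive
#' occasions: 1 not-yet-breeder in colony 1, 2 not-yet-breeder in colony 2,
#' 3 experienced breeder in colony 1, 4 experienced breeder in colony 2, and
#' 5 dead (explicit and absorbing, so every row sums to one).  Three blocks
#' cover the age structure:
#'
#' * `juvenile_block()` -- age 0 to 1: first-year survival, natal dispersal,
#'   and the attained-age-1 probability of first breeding;
#' * `immature_block()` -- attained age `a` in 2..4 for females that have not
#'   yet bred: adult survival, breeding dispersal, and the attained-age
#'   probability of first breeding (fixed to 1 at age 4, which forces every
#'   survivor into a breeder state); rows 3-4 are the experienced-breeder
#'   rows;
#' * `experienced_block()` -- attained age 5 onwards, and every interval of a
#'   female marked as an adult: only the breeder states are live.
#'
#' First-breeding probabilities are indexed by the *attained* age (the age at
#' the end of the interval) and by the destination colony.
#'
#' @param rates An `ms_rates` object (from [rate_set()] or a fitted model).
#' @param species Species label or index.
#' @param interval Interval index `i` (occasion `i` to `i + 1`) or the
#'   calendar year of the interval's start occasion.
#' @param cohort `"no"`/`"yes"` (or 1/2): whether the female was born in a
#'   cockchafer year (used when first breeding has a cohort effect).
#' @param age Attained age, 2 to 4 (`immature_block()` only).
#' @return An object of class `ms_block`: list with the 5 x 5 row-stochastic
#'   `matrix` and the length-4 `recapture` vector of detection probabilities
#'   for the live states at the destination occasion.
#' @export
juvenile_block <- function(rates, species = 1L, interval = 1L, cohort = 1L) {
  i <- resolve_interval(rates, interval); s <- resolve_species(rates, species)
  co <- resolve_cohort(cohort)
  phi <- rates$phi_juv[, s, i]
  n <- rates$move_juv[, s]                       # n[1] = NR, n[2] = RN
  a1 <- rates$alpha[1L, , s, i, co]              # by destination colony
  M <- empty_block()
  M[1L, 1:4] <- phi[1L] * c((1 - n[1L]) * (1 - a1[1L]), n[1L] * (1 - a1[2L]),
                            (1 - n[1L]) * a1[1L], n[1L] * a1[2L])
  M[2L, 1:4] <- phi[2L] * c(n[2L] * (1 - a1[1L]), (1 - n[2L]) * (1 - a1[2L]),
                            n[2L] * a1[1L], (1 - n[2L]) * a1[2L])
  M[, 5L] <- pmax(0, 1 - rowSums(M[, 1:4, drop = FALSE]))
  new_block(M, recapture_vector(rates, s, i))
}

#' @rdname juvenile_block
#' @export
immature_block <- function(rates, age, species = 1L, interval = 1L, cohort = 1L) {
  if (!age %in% 2:4) stop("'age' must be an attained age between 2 and 4")
  i <- resolve_interval(rates, interval); s <- resolve_species(rates, species)
  co <- resolve_cohort(cohort)
  phi <- rates$phi_ad[, s, i]
  b <- rates$move_ad[, s]
  aa <- rates$alpha[age, , s, i, co]
  M <- empty_block()
  M[1L, 1:4] <- phi[1L] * c((1 - b[1L]) * (1 - aa[1L]), b[1L] * (1 - aa[2L]),
                            (1 - b[1L]) * aa[1L], b[1L] * aa[2L])
  M[2L, 1:4] <- phi[2L] * c(b[2L] * (1 - aa[1L]), (1 - b[2L]) * (1 - aa[2L]),
                            b[2L] * aa[1L], (1 - b[2L]) * aa[2L])
  M[3:4, 3:4] <- breeder_rows(phi, b)
  M[, 5L] <- pmax(0, 1 - rowSums(M[, 1:4, drop = FALSE]))
  new_block(M, recapture_vector(rates, s, i))
}

#' @rdname juvenile_block
#' @export
experienced_block <- function(rates, species = 1L, interval = 1L) {
  i <- resolve_interval(rates, interval); s <- resolve_species(rates, species)
  phi <- rates$phi_ad[, s, i]
  b <- rates$move_ad[, s]
  M <- empty_block()
  M[3:4, 3:4] <- breeder_rows(phi, b)
  M[, 5L] <- pmax(0, 1 - rowSums(M[, 1:4, drop = FALSE]))
  new_block(M, recapture_vector(rates, s, i))
}

#' Select the transition block for one interval of a capture history
#'
#' Juvenile-marked females climb the age ladder from their release occasion:
#' the first interval is the juvenile block, attained ages 2-4 the immature
#' blocks (age 4 forcing first breeding), and age 5 onwards the experienced
#' block.  Adult-marked females are experienced in every interval.
#'
#' @inheritParams juvenile_block
#' @param age_at_marking `"juvenile"` or `"adult"`.
#' @param release Release occasion index (first non-zero code).
#' @export
block_for <- function(rates, age_at_marking, release, interval,
                      species = 1L, cohort = 1L) {
  i <- resolve_interval(rates, interval)
  if (i < release) stop("interval precedes the release occasion")
  if (age_at_marking == "adult") return(experienced_block(rates, species, i))
  attained <- i - release + 1L
  if (attained == 1L) juvenile_block(rates, species, i, cohort)
  else if (attained <= 4L) immature_block(rates, attained, species, i, cohort)
  else experienced_block(rates, species, i)
}

# rows 3-4 x cols 3-4 of every adult-age block
breeder_rows <- function(phi, b) {
  matrix(c(phi[1L] * (1 - b[1L]), phi[1L] * b[1L],
           phi[2L] * b[2L], phi[2L] * (1 - b[2L])),
         nrow = 2L, byrow = TRUE)
}

empty_block <- function() {
  M <- matrix(0, 5L, 5L)
  M[5L, 5L] <- 1
  M
}

# detection probabilities (nb-1, nb-2, br-1, br-2) at the destination
# occasion of interval i
recapture_vector <- function(rates, s, i) {
  c(rates$p[1L, s, 1L, i], rates$p[2L, s, 1L, i],
    rates$p[1L, s, 2L, i], rates$p[2L, s, 2L, i])
}

new_block <- function(M, recapture) {
  dimnames(M) <- list(from = state_labels(), to = state_labels())
  structure(list(matrix = M, recapture = recapture), class = "ms_block")
}

state_labels <- function() c("nb1", "nb2", "br1", "br2", "dead")

#' @export
print.ms_block <- function(x, digits = 4, ...) {
  cat("Transition block (rows = state at t, columns = state at t + 1):\n")
  print(round(x$matrix, digits))
  cat("recapture:", paste(round(x$recapture, digits), collapse = ", "), "\n")
  invisible(x)
}

resolve_species <- function(rates, species) {
  if (is.character(species)) {
    s <- match(species, rates$design$species)
    if (is.na(s)) stop("unknown species '", species, "'")
    s
  } else as.integer(species)
}

resolve_interval <- function(rates, interval) {
  interval <- as.integer(interval)
  T <- n_occasions(rates$design)
  if (interval >= rates$design$years[1L]) interval <- occ_index(rates$design, interval)
  if (interval < 1L || interval >= T) stop("interval index out of range")
  interval
}

resolve_cohort <- function(cohort) {
  if (is.character(cohort)) match(match.arg(cohort, c("no", "yes")), c("no", "yes"))
  else as.integer(cohort)
}
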