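#' Simulate capture histories under the four-state model
#'
#' For every scheduled release the latent state path is drawn through the
#' age-appropriate transition blocks (juveniles enter in state 1/2, adults
#' in 3/4) and the observation at each later occasion is drawn with the
#' recapture vector (structurally 0 at skipped occasions).  Each individual
#' consumes its own pseudo-random stream derived from `(seed, index)`, so a
#' dataset is reproducible even under partial regeneration of the schedule.
#'
#' @param design An [ms_design()] carrying a release schedule.
#' @param rates An `ms_rates` object on the same design.
#' @param seed Integer seed.
#' @return An `ms_data` with one history per released female.
#' @export
simulate_dataset <- function(design, rates, seed = 1L) {
  stopifnot(inherits(design, "ms_design"), inherits(rates, "ms_rates"))
  if (is.null(design$releases) || !nrow(design$releases))
    stop("the design has no release schedule")
  validate_rates(rates)
  T <- n_occasions(design)
  rel <- design$releases[design$releases$n > 0L, , drop = FALSE]
  if (any(rel$year == design$years[T]))
    warning("releases at the final occasion produce histories with no recapture information")
  total <- sum(rel$n)
  obs <- matrix(0L, total, T)
  info <- data.frame(id = character(total), species = character(total),
                     age_at_marking = character(total), stringsAsFactors = FALSE)
  row <- 0L
  for (k in seq_len(nrow(rel))) {
    r <- occ_index(design, rel$year[k])
    coli <- match(rel$colony[k], design$colonies)
    spi <- match(rel$species[k], design$species)
    age <- rel$age[k]
    state0 <- if (age == "juvenile") coli else coli + 2L
    cohort <- birth_cohort(design, r, age)
    for (j in seq_len(rel$n[k])) {
      row <- row + 1L
      set.seed(individual_seed(seed, row))
      codes <- integer(T)
      codes[r] <- state0
      s <- state0
      if (r < T) {
        for (t in seq.int(r + 1L, T)) {
          blk <- block_for(rates, age, r, t - 1L, spi, cohort)
          s <- sample.int(5L, 1L, prob = blk$matrix[s, ])
          if (s == 5L) break
          if (!design$years[t] %in% design$skipped &&
              runif(1L) < blk$recapture[s]) codes[t] <- s
        }
      }
      obs[row, ] <- codes
      info$id[row] <- sprintf("%s_%s_%d_%04d", substr(rel$species[k], 1L, 3L),
                              substr(age, 1L, 3L), rel$year[k], j)
      info$species[row] <- rel$species[k]
      info$age_at_marking[row] <- age
    }
  }
  ms_data(design, info, obs)
}

# one reproducible stream per (dataset seed, individual index)
individual_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647
}

#' Study configuration of the Valais mouse-eared bat monitoring programme
#'
#' Returns the design and the generating rates that emulate the long-term
#' two-colony study: 13 annual occasions 1989-2001 with no capture in 1994,
#' colonies Naters (`"N"`) and Raron (`"R"`), two species, per-colony
#' pulse-resource (cockchafer) calendars (Naters 1990/1994/1998, Raron
#' 1989/1992/1995/1998/2001), and a release schedule totalling 430 lesser
#' (`blythii`; 227 known-age juveniles) and 849 greater (`myotis`; 461
#' juveniles) mouse-eared bat females, spread uniformly over the marking
#' years 1989-2000 (1994 excluded) with the observed colony proportions
#' (57% of `blythii` at Naters, 79% of `myotis` at Raron).
#'
#' Default rates: adult survival 0.84/0.80 (blythii/myotis), first-year
#' survival 0.52, first-breeding probabilities (0, 0.33, 0.63, 1) and
#' (0, 0.93, 0.98, 1), species-specific natal and breeding dispersal, and
#' constant recapture 0.7 (0 in 1994).
#'
#' @return List with elements `design` (an `ms_design`) and `rates` (an
#'   `ms_rates`).
#' @export
myotis_config <- function() {
  design <- ms_design(
    years = 1989:2001,
    colonies = c("N", "R"),
    species = c("blythii", "myotis"),
    skipped = 1994L,
    cockchafer_years = list(N = c(1990L, 1994L, 1998L),
                            R = c(1989L, 1992L, 1995L, 1998L, 2001L)))
  design$releases <- validate_releases(
    default_release_schedule(design,
                             totals = c(blythii = 430L, myotis = 849L),
                             juveniles = c(blythii = 227L, myotis = 461L),
                             prop_first_colony = c(blythii = 0.57, myotis = 0.21)),
    design)
  rates <- rate_set(
    design,
    phi_juv = 0.52,
    phi_ad = c(blythii = 0.84, myotis = 0.80),
    alpha = cbind(blythii = c(0, 0.33, 0.63, 1), myotis = c(0, 0.93, 0.98, 1)),
    natal_NR = c(blythii = 0.019, myotis = 0.060),
    natal_RN = c(blythii = 0.108, myotis = 0.098),
    breeding_NR = c(blythii = 0.063, myotis = 0.172),
    breeding_RN = c(blythii = 0.142, myotis = 0.053),
    p = 0.7)
  list(design = design, rates = rates)
}

# Spread species totals uniformly over the marking years (all but the final
# occasion and any skipped year), split by age class and colony.  Remainders
# go to the earliest years so the totals are met exactly.
default_release_schedule <- function(design, totals, juveniles, prop_first_colony) {
  mark_years <- setdiff(design$years[-n_occasions(design)], design$skipped)
  out <- list()
  for (sp in design$species) {
    n_juv <- juveniles[[sp]]
    n_ad <- totals[[sp]] - n_juv
    for (age in c("juvenile", "adult")) {
      n_age <- if (age == "juvenile") n_juv else n_ad
      n_col <- c(round(n_age * prop_first_colony[[sp]]))
      n_col <- c(n_col, n_age - n_col)
      for (ci in 1:2) {
        n <- n_col[ci]
        base <- n %/% length(mark_years)
        extra <- n %% length(mark_years)
        counts <- rep(base, length(mark_years)) + (seq_along(mark_years) <= extra)
        out[[length(out) + 1L]] <- data.frame(
          year = mark_years, colony = design$colonies[ci], species = sp,
          age = age, n = counts, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Scale a release schedule down to a smaller total
#'
#' Keeps the structure of the schedule (years, colonies, species, age
#' classes) while shrinking every count proportionally; useful for quick
#' examples and tests.
#'
#' @param design An `ms_design` with a release schedule.
#' @param total Target total number of releases.
#' @return The design with the scaled schedule.
#' @export
subset_releases <- function(design, total) {
  stopifnot(inherits(design, "ms_design"), !is.null(design$releases))
  rel <- design$releases
  f <- total / sum(rel$n)
  rel$n <- floor(rel$n * f)
  deficit <- total - sum(rel$n)
  if (deficit > 0L) {
    i <- order(rel$n, decreasing = TRUE)[seq_len(deficit)]
    rel$n[i] <- rel$n[i] + 1L
  }
  design$releases <- rel
  design
}

#' Parameter-recovery study for one species
#'
#' Simulates replicate datasets for a single species under the study
#' configuration of [myotis_config()] and refits the generating model
#' (constant first-year and adult survival, attained-age first-breeding
#' probabilities with the first-year probability fixed at its generating
#' value 0, direction-specific dispersal, constant recapture) to each
#' replicate by maximum likelihood.
#'
#' @param species `"blythii"` or `"myotis"`.
#' @param n_rep Number of replicate datasets.
#' @param seed Base seed; replicate `i` is simulated with seed `seed + i -
#'   1`.
#' @param starts,control Passed to [ms_fit()].
#' @param config Study configuration (defaults to [myotis_config()]).
#' @return Data frame with one row per replicate: seed, estimates of
#'   `phi_juv`, `phi_ad`, `alpha2`, `alpha3`, recapture `p`, deviance and
#'   the convergence flag.
#' @export
parameter_recovery <- function(species = c("blythii", "myotis"), n_rep = 20L,
                               seed = 1L, starts = 2L, control = list(),
                               config = myotis_config()) {
  species <- match.arg(species)
  design <- subset_species(config$design, species)
  rates <- subset_rates(config$rates, design)
  model <- ms_model(phi_juv = ".", phi_ad = ".", alpha = "a3",
                    move_juv = ".", move_ad = ".", p = ".",
                    fix = list(alpha1 = 0))
  out <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    sim <- simulate_dataset(design, rates, seed = seed + i - 1L)
    fit <- ms_fit(model, sim, starts = starts, seed = seed + i - 1L,
                  control = control)
    est <- fitted_rates(fit)
    out[[i]] <- data.frame(
      replicate = i, seed = seed + i - 1L,
      phi_juv = est$phi_juv[1L, 1L, 1L],
      phi_ad = est$phi_ad[1L, 1L, 1L],
      alpha2 = est$alpha[2L, 1L, 1L, 1L, 1L],
      alpha3 = est$alpha[3L, 1L, 1L, 1L, 1L],
      p = est$p[1L, 1L, 1L, 1L],
      deviance = fit$deviance, converged = fit$converged)
  }
  do.call(rbind, out)
}

# restrict canonical rate arrays to the species of a (sub)design
subset_rates <- function(rates, design) {
  keep <- match(design$species, rates$design$species)
  if (anyNA(keep)) stop("design species not present in the rate set")
  rate_set(design,
           phi_juv = rates$phi_juv[, keep, , drop = FALSE],
           phi_ad = rates$phi_ad[, keep, , drop = FALSE],
           alpha = rates$alpha[, , keep, , , drop = FALSE],
           natal_NR = rates$move_juv[1L, keep], natal_RN = rates$move_juv[2L, keep],
           breeding_NR = rates$move_ad[1L, keep], breeding_RN = rates$move_ad[2L, keep],
           p = rates$p[, keep, , , drop = FALSE])
}
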