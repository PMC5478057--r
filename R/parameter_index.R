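#' Build the parameter index of a model on a design
#'
#' Every model cell (parameter family x age class x colony x species x
#' interval/occasion x status x direction) is resolved to either a fixed
#' constant (attained-age-4 first breeding = 1, recapture at skipped
#' occasions = 0, plus any user-requested constants) or a linear combination
#' of free parameters on the logit scale.  Additive terms share a reference
#' cell (corner-point coding); interactive terms produce one free parameter
#' per factor-level combination.  The coding is deterministic.
#'
#' @param model An [ms_model()].
#' @param design An [ms_design()].
#' @return An object of class `ms_index`: per-family cell grids, design
#'   matrices, fixed-value masks and global parameter coordinates, with the
#'   total free-parameter count in `$n_par`.
#' @export
parameter_index <- function(model, design) {
  stopifnot(inherits(model, "ms_model"), inherits(design, "ms_design"))
  T <- n_occasions(design)
  yrs <- design$years
  cc <- cc_years(design)
  ccf <- function(years) factor(ifelse(years %in% cc, "yes", "no"), levels = c("no", "yes"))

  # Interval covariates refer to the destination year: interval i spans the
  # period from the capture season of year i to that of year i + 1, which
  # contains the spring cockchafer flight of year i + 1.
  grid_phi <- function() {
    g <- expand.grid(colony = factor(design$colonies, levels = design$colonies),
                     species = factor(design$species, levels = design$species),
                     interval = seq_len(T - 1L), KEEP.OUT.ATTRS = FALSE)
    g$year <- factor(yrs[g$interval], levels = yrs[-T])
    g$cc_time <- ccf(yrs[g$interval + 1L])
    g
  }
  grid_alpha <- function() {
    g <- expand.grid(age = 1:4,
                     colony = factor(design$colonies, levels = design$colonies),
                     species = factor(design$species, levels = design$species),
                     interval = seq_len(T - 1L),
                     cohort = factor(c("no", "yes"), levels = c("no", "yes")),
                     KEEP.OUT.ATTRS = FALSE)
    lab <- if (model$alpha_classes == 2L) c("1", "2+", "2+", "2+") else c("1", "2", "3+", "3+")
    g$age_class <- factor(lab[g$age], levels = unique(lab))
    g$cc_time <- ccf(yrs[g$interval + 1L])
    g$cc_cohort <- g$cohort
    g
  }
  grid_move <- function() {
    expand.grid(direction = factor(c("NR", "RN"), levels = c("NR", "RN")),
                species = factor(design$species, levels = design$species),
                KEEP.OUT.ATTRS = FALSE)
  }
  grid_p <- function() {
    g <- expand.grid(colony = factor(design$colonies, levels = design$colonies),
                     species = factor(design$species, levels = design$species),
                     status = factor(c("nb", "br"), levels = c("nb", "br")),
                     occasion = 2:T, KEEP.OUT.ATTRS = FALSE)
    g$year <- factor(yrs[g$occasion], levels = yrs[-1L])
    g$cc_time <- ccf(yrs[g$occasion])
    g
  }

  fams <- list(
    phi_juv = list(cells = grid_phi(), terms = model$phi_juv, dim = c(2L, length(design$species), T - 1L)),
    phi_ad = list(cells = grid_phi(), terms = model$phi_ad, dim = c(2L, length(design$species), T - 1L)),
    alpha = list(cells = grid_alpha(), terms = model$alpha,
                 dim = c(4L, 2L, length(design$species), T - 1L, 2L)),
    move_juv = list(cells = grid_move(), terms = model$move_juv, dim = c(2L, length(design$species))),
    move_ad = list(cells = grid_move(), terms = model$move_ad, dim = c(2L, length(design$species))),
    p = list(cells = grid_p(), terms = model$p, dim = c(2L, length(design$species), 2L, T - 1L)))

  # structural and user-requested fixed cells
  for (f in names(fams)) {
    n <- nrow(fams[[f]]$cells)
    fams[[f]]$fixed <- rep(FALSE, n)
    fams[[f]]$value <- rep(NA_real_, n)
  }
  fams$alpha$fixed <- fams$alpha$cells$age == 4L
  fams$alpha$value[fams$alpha$fixed] <- 1
  if (!is.null(model$fix$alpha1)) {
    i <- fams$alpha$cells$age == 1L
    fams$alpha$fixed[i] <- TRUE
    fams$alpha$value[i] <- model$fix$alpha1
  }
  skip <- yrs[fams$p$cells$occasion] %in% design$skipped
  fams$p$fixed[skip] <- TRUE
  fams$p$value[skip] <- 0
  if (!is.null(model$fix$p)) {
    fams$p$fixed[!skip] <- TRUE
    fams$p$value[!skip] <- model$fix$p
  }
  for (f in c("move_juv", "move_ad")) {
    if (!is.null(model$fix[[f]])) {
      fams[[f]]$fixed[] <- TRUE
      fams[[f]]$value[] <- model$fix[[f]]
    }
  }

  offset <- 0L
  for (f in names(fams)) {
    free <- !fams[[f]]$fixed
    X <- if (any(free))
      coding_matrix(fams[[f]]$terms, fams[[f]]$cells[free, , drop = FALSE],
                    movement = f %in% c("move_juv", "move_ad"))
    else matrix(0, 0L, 0L)
    fams[[f]]$X <- X
    fams[[f]]$cols <- if (ncol(X)) offset + seq_len(ncol(X)) else integer(0)
    if (ncol(X)) colnames(fams[[f]]$X) <- paste0(f, ":", colnames(X))
    offset <- offset + ncol(X)
  }
  structure(list(families = fams, n_par = offset, design = design, model = model),
            class = "ms_index")
}

# Deterministic corner-point coding.  The first interactive group is coded as
# cell means (one column per level combination); every further group and
# every additive single factor contributes treatment-style dummies that drop
# the reference (first) level.  Factors that do not vary over the free cells
# are silently dropped from their group.  Movement families always carry the
# direction factor: "." is direction-specific constants, any term group is
# crossed with direction.
coding_matrix <- function(terms, cells, movement = FALSE) {
  groups <- lapply(terms$groups, function(g) {
    g <- replace(g, g == "age", "age_class")   # the model factor is the age-class coding
    g[vapply(g, function(f) nlevels(droplevels(cells[[f]])) >= 2L, logical(1))]
  })
  groups <- groups[lengths(groups) > 0L]
  if (movement) {
    groups <- if (length(groups)) lapply(groups, function(g) c("direction", g))
              else list("direction")
    interactive <- rep(TRUE, length(groups))
  } else {
    interactive <- lengths(groups) > 1L
  }
  if (!length(groups))
    return(matrix(1, nrow(cells), 1L, dimnames = list(NULL, "(const)")))

  cell_means <- function(g, drop_ref = FALSE) {
    f <- droplevels(interaction(cells[g], drop = FALSE, sep = ":"))
    M <- vapply(levels(f), function(l) as.numeric(f == l), numeric(length(f)))
    M <- matrix(M, nrow = length(f),
                dimnames = list(NULL, paste(paste(g, collapse = ":"), levels(f), sep = "=")))
    if (drop_ref) M[, -1L, drop = FALSE] else M
  }
  X <- NULL
  ord <- if (any(interactive)) c(which(interactive), which(!interactive))
         else seq_along(groups)
  lead <- any(interactive)
  for (k in seq_along(ord)) {
    g <- groups[[ord[k]]]
    if (k == 1L && lead) {
      X <- cell_means(g)
    } else if (k == 1L) {
      X <- cbind(`(const)` = rep(1, nrow(cells)), cell_means(g, drop_ref = TRUE))
    } else {
      X <- cbind(X, cell_means(g, drop_ref = TRUE))
    }
  }
  X
}

#' Count the free parameters of a model on a design
#'
#' @inheritParams parameter_index
#' @return Integer count of free parameters (fixed cells excluded).
#' @export
n_parameters <- function(model, design) parameter_index(model, design)$n_par

#' @export
print.ms_index <- function(x, ...) {
  cat("Parameter index:", x$n_par, "free parameters\n")
  for (f in names(x$families)) {
    fam <- x$families[[f]]
    cat(sprintf("  %-8s %3d free, %4d fixed of %4d cells\n", f,
                length(fam$cols), sum(fam$fixed), nrow(fam$cells)))
  }
  invisible(x)
}

# Map a free-parameter vector (logit scale) to the canonical probability
# arrays consumed by the transition engine:
#   phi_juv, phi_ad [colony, species, interval]
#   alpha           [age 1-4, colony, species, interval, cohort(no/yes)]
#   move_juv/ad     [direction (NR, RN), species]
#   p               [colony, species, status (nb, br), occasion 2..T]
resolve_rates <- function(index, beta) {
  stopifnot(length(beta) == index$n_par)
  d <- index$design
  out <- lapply(index$families, function(fam) {
    pr <- fam$value
    if (any(!fam$fixed))
      pr[!fam$fixed] <- plogis(drop(fam$X %*% beta[fam$cols]))
    array(pr, dim = fam$dim)
  })
  set_rate_dimnames(structure(c(out, list(design = d)), class = "ms_rates"))
}

set_rate_dimnames <- function(r) {
  d <- r$design
  dn_phi <- list(colony = d$colonies, species = d$species,
                 interval = d$years[-length(d$years)])
  dimnames(r$phi_juv) <- dn_phi
  dimnames(r$phi_ad) <- dn_phi
  dimnames(r$alpha) <- c(list(age = 1:4), dn_phi[1:2],
                         list(interval = dn_phi$interval, cohort = c("no", "yes")))
  dimnames(r$move_juv) <- dimnames(r$move_ad) <-
    list(direction = c("NR", "RN"), species = d$species)
  dimnames(r$p) <- list(colony = d$colonies, species = d$species,
                        status = c("nb", "br"), occasion = d$years[-1L])
  r
}
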