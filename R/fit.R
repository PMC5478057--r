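#' Fit a multistate capture-recapture model by maximum likelihood
#'
#' Maximises the product-multinomial likelihood of the capture histories on
#' the logit scale with quasi-Newton (PORT, [stats::nlminb()]) optimisation
#' from several dispersed starting points.  The reported optimum is the best start;
#' the fit is flagged as converged when the optimizer reports success, the
#' numeric gradient is small at the optimum, and the two best starts agree
#' in deviance.  Standard errors come from the inverse of a
#' finite-difference Hessian, mapped to the probability scale by the delta
#' method; estimates at the logit boundary (|logit| > 10) have their SE
#' suppressed.
#'
#' @param model An [ms_model()].
#' @param data An [ms_data()].
#' @param starts Number of starting points (the first is logit 0.5 for every
#'   parameter, the rest are dispersed uniformly on (-2, 2)).
#' @param seed Seed for the dispersed starts (one fixed stream per fit, so
#'   refits are reproducible).
#' @param control List of numerical settings: `maxit` (default 500),
#'   `reltol` (optimizer relative tolerance, 1e-10), `grad_tol` (numeric
#'   gradient of the NLL accepted as converged, relative to the NLL
#'   magnitude, 1e-3), `agree_tol` (deviance agreement of the two best
#'   starts, 1e-4).
#' @return An object of class `ms_fit`.
#' @export
#' @examples
#' cfg <- myotis_config()
#' des <- subset_releases(cfg$design, total = 60)
#' sim <- simulate_dataset(des, cfg$rates, seed = 1)
#' m <- ms_model(phi_juv = ".", phi_ad = "species", alpha = "a3",
#'               move_juv = ".", move_ad = ".", p = ".",
#'               fix = list(alpha1 = 0))
#' \donttest{
#' fit <- ms_fit(m, sim, starts = 2)
#' fit
#' }
ms_fit <- function(model, data, starts = 5L, seed = 1L, control = list()) {
  stopifnot(inherits(model, "ms_model"), inherits(data, "ms_data"))
  ctrl <- modifyList(list(maxit = 500L, reltol = 1e-10,
                          grad_tol = 1e-3, agree_tol = 1e-4), control)
  index <- parameter_index(model, data$design)
  np <- index$n_par
  gr <- group_histories(data)

  nll <- function(beta) {
    v <- grouped_nll(gr, resolve_rates(index, beta))
    if (!is.finite(v)) return(1e10)
    v
  }

  # structural data-model check: histories that are impossible whatever the
  # free parameters are (e.g. a capture at a skipped occasion slipped past
  # validation, or a fixed rate contradicting the data) abort the fit
  bad <- impossible_histories(data, resolve_rates(index, rep(0, np)))
  if (length(bad))
    stop("histories impossible under the model (ids: ",
         paste(utils::head(data$info$id[bad], 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "",
         "); check fixed parameters and state codes")

  set.seed(seed)
  start_list <- c(list(rep(0, np)),
                  replicate(max(0L, starts - 1L), runif(np, -2, 2), simplify = FALSE))
  runs <- lapply(start_list, function(b0) {
    if (np == 0L)
      return(list(par = numeric(0), value = nll(numeric(0)), convergence = 0L))
    res <- stats::nlminb(b0, nll,
                         control = list(rel.tol = ctrl$reltol,
                                        iter.max = ctrl$maxit,
                                        eval.max = 10L * ctrl$maxit))
    list(par = res$par, value = res$objective, convergence = res$convergence)
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- which.min(values)
  fit <- runs[[best]]
  beta <- fit$par

  grad <- if (np) num_gradient(nll, beta) else numeric(0)
  agree <- length(values) == 1L ||
    2 * (sort(values)[2L] - values[best]) <= ctrl$agree_tol
  converged <- fit$convergence == 0L &&
    (np == 0L || max(abs(grad)) < ctrl$grad_tol * max(1, abs(fit$value))) && agree

  H <- if (np) optimHess(beta, nll) else matrix(0, 0L, 0L)
  eig <- if (np) eigen(H, symmetric = TRUE, only.values = TRUE)$values else numeric(0)
  hrank <- sum(eig > max(eig, 0) * 1e-8)
  V <- if (np) {
    out <- try(solve(H), silent = TRUE)
    if (inherits(out, "try-error")) {
      # pseudo-inverse on the estimable subspace
      e <- eigen(H, symmetric = TRUE)
      keep <- e$values > max(e$values, 0) * 1e-8
      e$vectors[, keep, drop = FALSE] %*%
        diag(1 / e$values[keep], sum(keep)) %*% t(e$vectors[, keep, drop = FALSE])
    } else out
  } else matrix(0, 0L, 0L)

  structure(list(
    model = model, index = index, beta = beta, vcov = V,
    deviance = 2 * fit$value, n_par = np,
    converged = converged, hessian_rank = hrank,
    boundary = abs(beta) > 10,
    gradient = grad, nll_trace = values,
    data_signature = data_signature(data),
    design = data$design, n = nrow(data$obs),
    call = match.call()), class = "ms_fit")
}

num_gradient <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h)
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

data_signature <- function(data) {
  c(n = nrow(data$obs), T = ncol(data$obs), sum = sum(data$obs),
    captures = sum(data$obs != 0L))
}

#' @export
print.ms_fit <- function(x, ...) {
  cat("Multistate capture-recapture fit\n")
  cat("  model    : "); print(x$model)
  cat(sprintf("  histories: %d   free parameters: %d\n", x$n, x$n_par))
  cat(sprintf("  deviance : %.4f   AIC: %.4f\n", x$deviance, x$deviance + 2 * x$n_par))
  cat(sprintf("  converged: %s (Hessian rank %d/%d)\n",
              x$converged, x$hessian_rank, x$n_par))
  if (any(x$boundary))
    cat("  note     :", sum(x$boundary), "parameter(s) at the logit boundary\n")
  invisible(x)
}

#' @export
logLik.ms_fit <- function(object, ...) {
  structure(-object$deviance / 2, df = object$n_par, nobs = object$n,
            class = "logLik")
}

#' @export
coef.ms_fit <- function(object, type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (type == "link") {
    b <- object$beta
    names(b) <- unlist(lapply(object$index$families, function(f) colnames(f$X)))
    b
  } else {
    fitted_rates(object)
  }
}

#' @export
vcov.ms_fit <- function(object, ...) object$vcov

#' Probability-scale rate arrays of a fitted model
#'
#' @param object An `ms_fit`.
#' @return An `ms_rates` object holding the ML estimates.
#' @export
fitted_rates <- function(object) {
  stopifnot(inherits(object, "ms_fit"))
  resolve_rates(object$index, object$beta)
}

#' Estimates and standard errors for one parameter family
#'
#' Returns the model cells of a family with the ML estimate and a
#' delta-method standard error on the probability scale.  Fixed cells carry
#' their constant and `NA` SE; boundary estimates have their SE suppressed.
#'
#' @param object An `ms_fit`.
#' @param family One of `"phi_juv"`, `"phi_ad"`, `"alpha"`, `"move_juv"`,
#'   `"move_ad"`, `"p"`.
#' @param ... Unused.
#' @return A data frame of cells with columns `estimate` and `se`.
#' @export
predict.ms_fit <- function(object, family = "phi_ad", ...) {
  fam <- object$index$families[[match.arg(family, names(object$index$families))]]
  cells <- fam$cells
  est <- fam$value
  se <- rep(NA_real_, nrow(cells))
  if (length(fam$cols)) {
    eta <- drop(fam$X %*% object$beta[fam$cols])
    Vb <- object$vcov[fam$cols, fam$cols, drop = FALSE]
    var_eta <- rowSums((fam$X %*% Vb) * fam$X)
    p <- plogis(eta)
    est[!fam$fixed] <- p
    se_free <- abs(p * (1 - p)) * sqrt(pmax(var_eta, 0))
    se_free[abs(eta) > 10] <- NA_real_   # boundary
    se[!fam$fixed] <- se_free
  }
  cbind(cells, estimate = est, se = se)
}

#' @export
summary.ms_fit <- function(object, ...) {
  fams <- names(object$index$families)
  tables <- lapply(fams, function(f) unique_cells(predict(object, f)))
  names(tables) <- fams
  out <- list(model = object$model, deviance = object$deviance,
              n_par = object$n_par, n = object$n, converged = object$converged,
              hessian_rank = object$hessian_rank, tables = tables)
  class(out) <- "summary.ms_fit"
  out
}

# collapse cells that share the same estimate profile (drop replicated
# physical indices so the printed table shows the distinct parameters)
unique_cells <- function(tab) {
  keep <- !names(tab) %in% c("interval", "occasion", "cohort", "age")
  key <- interaction(tab[setdiff(names(tab)[keep], c("estimate", "se"))], drop = TRUE)
  agg <- !duplicated(data.frame(key, tab$estimate))
  tab[agg, , drop = FALSE]
}

#' @export
print.summary.ms_fit <- function(x, digits = 4, ...) {
  cat("Model: "); print(x$model)
  cat(sprintf("Deviance %.4f on %d free parameters (%d histories); converged: %s\n\n",
              x$deviance, x$n_par, x$n, x$converged))
  for (f in names(x$tables)) {
    tab <- x$tables[[f]]
    cat(f, ":\n", sep = "")
    print(utils::head(data.frame(lapply(tab, function(col)
      if (is.numeric(col)) round(col, digits) else col)), 24L), row.names = FALSE)
    if (nrow(tab) > 24L) cat("  ... (", nrow(tab) - 24L, " more cells)\n", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Simulate datasets from a fitted model
#'
#' Draws new capture-history datasets from the fitted rates under the
#' design (and release schedule) of the data the model was fitted to.
#'
#' @param object An `ms_fit` whose design carries a release schedule.
#' @param nsim Number of datasets.
#' @param seed Base seed; replicate `i` uses `seed + i - 1`.
#' @param ... Unused.
#' @return A list of `ms_data` objects (a single `ms_data` if `nsim = 1`).
#' @export
simulate.ms_fit <- function(object, nsim = 1, seed = 1L, ...) {
  if (is.null(object$design$releases))
    stop("the fitted design has no release schedule; supply one via ms_design()")
  sims <- lapply(seq_len(nsim), function(i)
    simulate_dataset(object$design, fitted_rates(object), seed = seed + i - 1L))
  if (nsim == 1L) sims[[1L]] else sims
}
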