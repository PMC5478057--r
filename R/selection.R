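#' Rank candidate models by AIC
#'
#' Computes `AIC = deviance + 2 * parameters`, the difference to the best
#' model, and Akaike weights `exp(-dAIC/2) / sum(exp(-dAIC/2))` over the
#' full candidate set.  Entries are sorted by dAIC, ties broken by fewer
#' parameters.  Accepts either fitted models (which must all refer to the
#' same dataset) or a plain table of deviances and parameter counts, so a
#' published model-selection table can be re-ranked without refitting.
#'
#' @param models Either a list of [ms_fit()] objects, or a data frame with
#'   columns `deviance` and `npar` (optionally `model` labels).
#' @param labels Optional model labels (defaults to the model notation of
#'   each fit, or the `model` column).
#' @return An object of class `ms_modelset`: a data frame with columns
#'   `model`, `deviance`, `npar`, `AIC`, `dAIC`, `weight`; fitted models,
#'   when supplied, are attached for [model_average()].
#' @export
rank_models <- function(models, labels = NULL) {
  fits <- NULL
  if (is.data.frame(models)) {
    if (!all(c("deviance", "npar") %in% names(models)))
      stop("table input needs columns 'deviance' and 'npar'")
    dev <- models$deviance
    k <- models$npar
    if (is.null(labels)) labels <- models$model %||% paste0("model", seq_along(dev))
  } else {
    if (inherits(models, "ms_fit")) models <- list(models)
    if (!length(models) || !all(vapply(models, inherits, logical(1), "ms_fit")))
      stop("supply ms_fit objects or a deviance/npar table")
    sigs <- vapply(models, function(f) paste(f$data_signature, collapse = "/"), character(1))
    if (length(unique(sigs)) > 1L)
      stop("models were fitted to different datasets and cannot be ranked together")
    dev <- vapply(models, `[[`, numeric(1), "deviance")
    k <- vapply(models, `[[`, numeric(1), "n_par")
    if (is.null(labels))
      labels <- vapply(models, function(f) paste(utils::capture.output(print(f$model))[1L]),
                       character(1))
    fits <- models
  }
  aic <- dev + 2 * k
  daic <- aic - min(aic)
  w <- exp(-daic / 2)
  w <- w / sum(w)
  ord <- order(daic, k)
  out <- data.frame(model = labels, deviance = dev, npar = k, AIC = aic,
                    dAIC = daic, weight = w, stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  attr(out, "fits") <- if (!is.null(fits)) fits[ord]
  class(out) <- c("ms_modelset", "data.frame")
  out
}

#' @export
print.ms_modelset <- function(x, digits = 3, ...) {
  cat("Model selection (", nrow(x), " models):\n", sep = "")
  df <- data.frame(model = x$model, deviance = round(x$deviance, 2),
                   npar = x$npar, dAIC = round(x$dAIC, 2),
                   weight = round(x$weight, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a ranked model table as TSV
#'
#' Columns: model notation, deviance, parameter count, dAIC, Akaike weight.
#'
#' @param modelset An `ms_modelset`.
#' @param path Output file.
#' @export
write_model_table <- function(modelset, path) {
  stopifnot(inherits(modelset, "ms_modelset"))
  df <- data.frame(model = modelset$model,
                   deviance = sprintf("%.2f", modelset$deviance),
                   parameters = modelset$npar,
                   dAIC = sprintf("%.2f", modelset$dAIC),
                   weight = sprintf("%.3f", modelset$weight))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Akaike model averaging with unconditional standard errors
#'
#' `akaike_average()` is the core arithmetic: weights are renormalised over
#' the supplied models, the average is the weighted mean of the estimates on
#' the probability scale, and the unconditional SE is the Burnham-Anderson
#' sum `sum(w_i * sqrt(se_i^2 + (est_i - avg)^2))`, which collapses to the
#' conditional SE when all estimates agree.
#'
#' `model_average()` applies it to one parameter cell across the fitted
#' models of a ranked set, keeping only models whose Akaike weight exceeds
#' `threshold` (the ranked set's weights are renormalised over the retained
#' models).
#'
#' @param estimates,se,weights Numeric vectors of per-model estimates,
#'   conditional SEs and (possibly unnormalised) weights.
#' @return A named vector with `estimate` and `se`.
#' @export
akaike_average <- function(estimates, se, weights) {
  stopifnot(length(estimates) == length(se), length(estimates) == length(weights),
            length(estimates) >= 1L, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  avg <- sum(w * estimates)
  unc <- sum(w * sqrt(se^2 + (estimates - avg)^2))
  c(estimate = avg, se = unc)
}

#' @rdname akaike_average
#' @param modelset An `ms_modelset` built from fitted models.
#' @param family Parameter family, as in [predict.ms_fit()].
#' @param which Named list of cell coordinates (e.g. `list(species =
#'   "blythii", colony = "N", interval = 1)`); must select exactly one cell
#'   in every retained model.
#' @param threshold Akaike-weight cutoff for retaining a model (default
#'   0.02).
#' @export
model_average <- function(modelset, family, which = list(), threshold = 0.02) {
  stopifnot(inherits(modelset, "ms_modelset"))
  fits <- attr(modelset, "fits")
  if (is.null(fits)) stop("this model set was built from a table; no fitted models to average")
  keep <- modelset$weight > threshold
  if (!any(keep)) stop("no model exceeds the averaging threshold")
  ests <- ses <- numeric(sum(keep))
  kk <- which(keep)
  for (j in seq_along(kk)) {
    tab <- predict(fits[[kk[j]]], family)
    for (nm in names(which)) {
      if (!nm %in% names(tab)) stop("unknown cell coordinate '", nm, "'")
      tab <- tab[tab[[nm]] == which[[nm]], , drop = FALSE]
    }
    if (!nrow(tab)) stop("parameter cell absent from a retained model")
    if (length(unique(tab$estimate)) > 1L)
      stop("cell selector matches ", nrow(tab), " distinct cells; add coordinates")
    ests[j] <- tab$estimate[1L]
    ses[j] <- if (all(is.na(tab$se))) NA_real_ else max(tab$se, na.rm = TRUE)
  }
  akaike_average(ests, ses, modelset$weight[keep])
}
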