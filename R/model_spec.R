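#' Declare a multistate model structure
#'
#' A model is described by one effect structure per parameter family:
#'
#' * `phi_juv`, `phi_ad` -- first-year and adult apparent survival;
#' * `move_juv`, `move_ad` -- natal and breeding dispersal between the two
#'   colonies (always direction-specific);
#' * `alpha` -- age-specific probability that a not-yet-breeding female starts
#'   to reproduce at the attained age (the probability at attained age 4 is
#'   always fixed to 1: no female starts later);
#' * `p` -- recapture probability (fixed to 0 at skipped occasions).
#'
#' Each structure is a string over the factors `year`, `species` (`spec`),
#' `colony` (`col`), `status` (`rep`; has-bred vs not-yet-bred, recapture
#' only), `cockchafer` / `cockchafer(time)` (pulse-resource year of the
#' interval), `cockchafer(coh)` (born in a pulse-resource year; `alpha`
#' only), and for `alpha` the age coding `a2` or `a3`.  `"."` (or `"1"`)
#' means constant.  `+` combines terms additively on the logit scale
#' (corner-point coding); `*` makes a cell-means interaction.
#'
#' Alternatively the whole model can be given in field notation, e.g.
#' `"phi(juv: year; ad: spec) psi(juv: .; ad: spec) p(Col*year+rep+spec)
#' alpha(a3+spec)"`.  In `phi(...)`/`psi(...)` blocks without a `juv:`/`ad:`
#' split, `a2` stands for the juvenile/adult age split itself, so
#' `phi(a2*spec)` is species-specific survival in both age classes.
#'
#' @param notation Optional full model string (overrides the per-family
#'   arguments).
#' @param phi_juv,phi_ad,alpha,move_juv,move_ad,p Per-family structure
#'   strings.
#' @param fix Named list of structural constants: `alpha1` (fixes the
#'   first-year probability of first breeding, e.g. to 0), `move_juv`,
#'   `move_ad`, `p` (fix a whole family to a constant; skipped occasions
#'   stay at 0).  The attained-age-4 probability and skipped-occasion
#'   recapture are always fixed and need not be listed.
#' @return An object of class `ms_model`.
#' @export
#' @examples
#' ms_model("phi(juv: year; ad: spec) psi(juv: .; ad: spec)
#'           p(Col*year+rep+spec) alpha(a3+spec)")
#' ms_model(phi_juv = ".", phi_ad = "species", alpha = "a3",
#'          move_juv = ".", move_ad = ".", p = ".", fix = list(alpha1 = 0))
ms_model <- function(notation = NULL,
                     phi_juv = ".", phi_ad = ".", alpha = "a3",
                     move_juv = ".", move_ad = ".", p = "colony*year",
                     fix = list()) {
  if (!is.null(notation)) {
    parsed <- parse_notation(notation)
    phi_juv <- parsed$phi_juv; phi_ad <- parsed$phi_ad
    move_juv <- parsed$move_juv; move_ad <- parsed$move_ad
    alpha <- parsed$alpha; p <- parsed$p
  }
  bad_fix <- setdiff(names(fix), c("alpha1", "move_juv", "move_ad", "p"))
  if (length(bad_fix)) stop("unknown fix entries: ", paste(bad_fix, collapse = ", "))
  al <- parse_terms(alpha, allow_age = TRUE)
  structure(list(
    phi_juv = parse_terms(phi_juv),
    phi_ad = parse_terms(phi_ad),
    alpha = al,
    move_juv = parse_terms(move_juv),
    move_ad = parse_terms(move_ad),
    p = parse_terms(p, allow_status = TRUE),
    alpha_classes = al$age_classes %||% 3L,
    fix = fix), class = "ms_model")
}

# --- term-structure parser -------------------------------------------------

# One family structure -> list(groups = list of character vectors of factor
# names, constant = flag, age_classes = 2/3 for alpha codings).
parse_terms <- function(str, allow_age = FALSE, allow_status = FALSE) {
  stopifnot(is.character(str), length(str) == 1L)
  s <- tolower(gsub("\\s+", "", str))
  s <- gsub("cockchafer\\(time\\)", "cc_time", s)
  s <- gsub("cockchafer\\(coh\\)", "cc_cohort", s)
  age_classes <- NULL
  if (s %in% c(".", "", "1", "const", "constant"))
    return(list(groups = list(), constant = TRUE, age_classes = NULL))
  groups <- strsplit(strsplit(s, "+", fixed = TRUE)[[1L]], "*", fixed = TRUE)
  map <- c(year = "year", time = "year", t = "year",
           spec = "species", species = "species",
           col = "colony", colony = "colony",
           rep = "status", status = "status",
           cockchafer = "cc_time", cc_time = "cc_time", cc_cohort = "cc_cohort",
           a2 = "age", a3 = "age")
  groups <- lapply(groups, function(g) {
    g <- g[!g %in% c(".", "1")]
    unknown <- setdiff(g, names(map))
    if (length(unknown)) stop("unknown model factor(s): ", paste(unknown, collapse = ", "))
    if (any(g %in% c("a2", "a3"))) {
      if (!allow_age) stop("age-class factors a2/a3 are only valid for alpha here")
      age_classes <<- if ("a2" %in% g) 2L else 3L
    }
    if ("rep" %in% g || "status" %in% g) {
      if (!allow_status) stop("the reproductive-status factor is only valid for recapture")
    }
    unname(map[g])
  })
  groups <- groups[lengths(groups) > 0L]
  list(groups = groups, constant = length(groups) == 0L, age_classes = age_classes)
}

# render a term structure back to a compact string (for printing)
deparse_terms <- function(ts, alpha_classes = NULL) {
  if (ts$constant) return(".")
  back <- c(year = "year", species = "spec", colony = "Col", status = "rep",
            cc_time = "cockchafer(time)", cc_cohort = "cockchafer(coh)",
            age = if (identical(alpha_classes, 2L)) "a2" else "a3")
  paste(vapply(ts$groups, function(g) paste(back[g], collapse = "*"), character(1)),
        collapse = "+")
}

# --- field-notation parser -------------------------------------------------

parse_notation <- function(notation) {
  s <- gsub("cockchafer\\(time\\)", "cc_time", notation, ignore.case = TRUE)
  s <- gsub("cockchafer\\(coh\\)", "cc_cohort", s, ignore.case = TRUE)
  m <- gregexpr("(phi|psi|p|alpha)\\s*\\(([^()]*)\\)", s, ignore.case = TRUE)[[1L]]
  if (m[1L] == -1L) stop("no phi()/psi()/p()/alpha() blocks found in notation")
  pieces <- regmatches(s, gregexpr("(phi|psi|p|alpha)\\s*\\(([^()]*)\\)", s,
                                   ignore.case = TRUE))[[1L]]
  fam <- tolower(sub("\\s*\\(.*$", "", pieces))
  body <- sub("^[^(]*\\(", "", sub("\\)$", "", pieces))
  if (anyDuplicated(fam)) stop("duplicated family block in notation")
  out <- list(phi_juv = ".", phi_ad = ".", move_juv = ".", move_ad = ".",
              alpha = "a3", p = "colony*year")
  for (i in seq_along(fam)) {
    b <- body[i]
    if (fam[i] %in% c("phi", "psi")) {
      sub2 <- split_juv_ad(b)
      pre <- if (fam[i] == "phi") c("phi_juv", "phi_ad") else c("move_juv", "move_ad")
      out[[pre[1L]]] <- sub2$juv
      out[[pre[2L]]] <- sub2$ad
    } else if (fam[i] == "alpha") {
      out$alpha <- b
    } else {
      out$p <- b
    }
  }
  out
}

# "juv: X; ad: Y" -> list(juv = X, ad = Y); "a2*Z" -> Z for both families;
# "a2" alone -> constant in both.
split_juv_ad <- function(b) {
  if (grepl("juv\\s*:", b, ignore.case = TRUE)) {
    parts <- strsplit(b, ";")[[1L]]
    get <- function(tag) {
      hit <- grep(paste0("^\\s*", tag, "\\s*:"), parts, ignore.case = TRUE, value = TRUE)
      if (length(hit) != 1L) stop("expected exactly one '", tag, ":' part in '", b, "'")
      sub(paste0("^\\s*", tag, "\\s*:"), "", hit)
    }
    list(juv = get("juv"), ad = get("ad"))
  } else {
    s <- tolower(gsub("\\s+", "", b))
    toks <- strsplit(unlist(strsplit(s, "+", fixed = TRUE)), "*", fixed = TRUE)
    toks <- lapply(toks, setdiff, y = c("a2", "."))
    toks <- toks[lengths(toks) > 0L]
    rest <- if (length(toks)) paste(vapply(toks, paste, character(1), collapse = "*"),
                                    collapse = "+") else "."
    list(juv = rest, ad = rest)
  }
}

#' @export
print.ms_model <- function(x, ...) {
  cat(sprintf("phi(juv: %s; ad: %s) psi(juv: %s; ad: %s) p(%s) alpha(%s)\n",
              deparse_terms(x$phi_juv), deparse_terms(x$phi_ad),
              deparse_terms(x$move_juv), deparse_terms(x$move_ad),
              deparse_terms(x$p), deparse_terms(x$alpha, x$alpha_classes)))
  if (length(x$fix))
    cat("fixed:", paste(sprintf("%s=%s", names(x$fix), unlist(x$fix)), collapse = ", "), "\n")
  invisible(x)
}

#' Logit link and inverse
#'
#' All probability parameters are estimated on the logit scale so the
#' optimisation is unconstrained.  `logit()` signals an error at the
#' boundaries 0 and 1.
#'
#' @param p Probability in (0, 1).
#' @param x Real number.
#' @return `logit()` the log-odds; `inv_logit()` a probability in (0, 1).
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("logit is undefined at the boundary: p must lie in (0, 1)")
  qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) plogis(x)
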