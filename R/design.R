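#' Define a multistate capture-recapture study design
#'
#' A study design records everything about the sampling scheme that is needed
#' to interpret a capture history: the ordered annual capture occasions, the
#' occasions at which no capture took place (detection is structurally zero
#' there), the two nursery colonies, the species under study, the calendar of
#' pulse-resource ("cockchafer") years, and optionally an explicit release
#' schedule used by the simulator.
#'
#' @param years Integer vector of occasion labels (calendar years), strictly
#'   increasing.  Occasions are assumed annual and consecutive entries one
#'   year apart; a year with no field work is still an occasion and is listed
#'   in `skipped`.
#' @param colonies Character vector of exactly two colony labels.  The first
#'   label is the reference colony for corner-point codings.
#' @param species Character vector of one or two species labels.
#' @param skipped Years (subset of `years`, excluding the first) at which no
#'   capture took place; recapture probability is fixed to zero there.
#' @param cockchafer_years Either an integer vector of years with mass
#'   cockchafer occurrence, or a named list with one vector per colony.  The
#'   covariate coding always uses the union across colonies.
#' @param releases Optional release schedule: a data frame with columns
#'   `year`, `colony`, `species`, `age` (`"juvenile"` or `"adult"`) and `n`.
#'
#' @return An object of class `ms_design`.
#' @seealso [myotis_config()] for the design of the Valais mouse-eared bat
#'   study, [simulate_dataset()] for generating data under a design.
#' @export
#' @examples
#' ms_design(1989:2001, skipped = 1994,
#'           cockchafer_years = list(N = c(1990, 1994, 1998),
#'                                   R = c(1989, 1992, 1995, 1998, 2001)))
ms_design <- function(years,
                      colonies = c("N", "R"),
                      species = c("blythii", "myotis"),
                      skipped = integer(0),
                      cockchafer_years = integer(0),
                      releases = NULL) {
  years <- as.integer(years)
  if (length(years) < 2L) stop("a design needs at least two occasions")
  if (is.unsorted(years, strictly = TRUE)) stop("'years' must be strictly increasing")
  colonies <- as.character(colonies)
  if (length(colonies) != 2L || anyDuplicated(colonies))
    stop("exactly two distinct colony labels are required")
  species <- as.character(species)
  if (!length(species) %in% 1:2 || anyDuplicated(species))
    stop("one or two distinct species labels are required")
  skipped <- as.integer(skipped)
  if (!all(skipped %in% years)) stop("'skipped' must be a subset of 'years'")
  if (years[1L] %in% skipped) stop("the first occasion cannot be a skipped occasion")
  if (is.list(cockchafer_years)) {
    if (!all(names(cockchafer_years) %in% colonies))
      stop("per-colony cockchafer years must be named after the colonies")
    cockchafer_years <- lapply(cockchafer_years, as.integer)
    if (!all(unlist(cockchafer_years) %in% years))
      stop("cockchafer years must be a subset of the occasion years")
  } else {
    cockchafer_years <- as.integer(cockchafer_years)
    if (!all(cockchafer_years %in% years))
      stop("cockchafer years must be a subset of the occasion years")
  }
  design <- structure(
    list(years = years, colonies = colonies, species = species,
         skipped = skipped, cockchafer_years = cockchafer_years,
         releases = NULL),
    class = "ms_design")
  if (!is.null(releases)) design$releases <- validate_releases(releases, design)
  design
}

validate_releases <- function(releases, design) {
  releases <- as.data.frame(releases)
  need <- c("year", "colony", "species", "age", "n")
  if (!all(need %in% names(releases)))
    stop("'releases' needs columns ", paste(need, collapse = ", "))
  releases$year <- as.integer(releases$year)
  releases$n <- as.integer(releases$n)
  if (!all(releases$year %in% design$years)) stop("release year outside the design")
  if (any(releases$year %in% design$skipped))
    stop("releases cannot occur at a skipped occasion")
  if (!all(releases$colony %in% design$colonies)) stop("unknown release colony")
  if (!all(releases$species %in% design$species)) stop("unknown release species")
  if (!all(releases$age %in% c("juvenile", "adult"))) stop("release age must be 'juvenile' or 'adult'")
  if (any(releases$n < 0L)) stop("negative release count")
  if (any(releases$year == max(design$years) & releases$n > 0L))
    warning("releases at the final occasion carry no recapture information")
  releases[c("year", "colony", "species", "age", "n")]
}

# Union of the per-colony cockchafer calendars (the covariate coding
# always uses common cockchafer years across the study area).
cc_years <- function(design) {
  cc <- design$cockchafer_years
  if (is.list(cc)) sort(unique(unlist(cc))) else cc
}

n_occasions <- function(design) length(design$years)

occ_index <- function(design, year) {
  i <- match(year, design$years)
  if (anyNA(i)) stop("year not an occasion of the design: ", paste(year[is.na(i)], collapse = ", "))
  i
}

# logical index of skipped occasions
skipped_idx <- function(design) design$years %in% design$skipped

#' @export
print.ms_design <- function(x, ...) {
  cat("Multistate capture-recapture study design\n")
  cat("  occasions :", length(x$years), sprintf("(%d-%d)", x$years[1], x$years[length(x$years)]), "\n")
  if (length(x$skipped)) cat("  skipped   :", paste(x$skipped, collapse = ", "), "\n")
  cat("  colonies  :", paste(x$colonies, collapse = ", "), "\n")
  cat("  species   :", paste(x$species, collapse = ", "), "\n")
  cc <- cc_years(x)
  if (length(cc)) cat("  cockchafer:", paste(cc, collapse = ", "), "\n")
  if (!is.null(x$releases))
    cat("  releases  :", sum(x$releases$n), "individuals scheduled\n")
  invisible(x)
}

#' Read or write a study design as a YAML configuration block
#'
#' The on-disk format mirrors the fields of [ms_design()]: `years`, `colonies`,
#' `species`, `skipped`, `cockchafer_years` (vector or per-colony mapping) and
#' an optional `releases` table (list of records).
#'
#' @param path File path.
#' @return `read_design()` returns an `ms_design`; `write_design()` returns
#'   `path` invisibly.
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  rel <- cfg$releases
  if (!is.null(rel)) rel <- do.call(rbind, lapply(rel, as.data.frame))
  ms_design(years = cfg$years,
            colonies = cfg$colonies %||% c("N", "R"),
            species = cfg$species %||% c("blythii", "myotis"),
            skipped = cfg$skipped %||% integer(0),
            cockchafer_years = cfg$cockchafer_years %||% integer(0),
            releases = rel)
}

#' @param design An `ms_design` object.
#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "ms_design"))
  cfg <- list(years = design$years, colonies = design$colonies,
              species = design$species, skipped = design$skipped,
              cockchafer_years = design$cockchafer_years)
  if (!is.null(design$releases)) {
    cfg$releases <- lapply(seq_len(nrow(design$releases)), function(i)
      as.list(design$releases[i, ]))
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# restrict a design (and its release schedule) to one species
subset_species <- function(design, sp) {
  stopifnot(sp %in% design$species)
  design$species <- sp
  if (!is.null(design$releases))
    design$releases <- design$releases[design$releases$species == sp, , drop = FALSE]
  design
}
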