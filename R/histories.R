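#' Assemble a capture-history dataset
#'
#' Observation codes per occasion are 0 (not captured), 1-2 (captured as a
#' not-yet-breeding female in colony 1 or 2) and 3-4 (captured as an
#' experienced breeder in colony 1 or 2).  A history's release occasion is its
#' first non-zero code.  Structural rules enforced here:
#'
#' * adult-marked females never carry codes 1 or 2 (they are assigned to the
#'   breeder states from marking on, whatever their current reproduction);
#' * juvenile-marked females are released in state 1 or 2 and once observed
#'   in 3/4 never revert to 1/2 (having bred is absorbing);
#' * codes at skipped occasions are 0;
#' * every history has one code per occasion.
#'
#' @param design An [ms_design()].
#' @param info Data frame with columns `id`, `species`, `age_at_marking`
#'   (`"juvenile"` or `"adult"`), one row per individual.
#' @param obs Integer matrix of observation codes, rows matching `info`,
#'   columns matching `design$years`.
#' @return An object of class `ms_data`.
#' @export
ms_data <- function(design, info, obs) {
  stopifnot(inherits(design, "ms_design"))
  info <- as.data.frame(info)
  obs <- as.matrix(obs)
  storage.mode(obs) <- "integer"
  if (nrow(info) != nrow(obs)) stop("'info' and 'obs' disagree on the number of histories")
  if (ncol(obs) != n_occasions(design))
    stop("histories must have one observation per occasion (", n_occasions(design), ")")
  if (!all(c("id", "species", "age_at_marking") %in% names(info)))
    stop("'info' needs columns id, species, age_at_marking")
  bad <- vapply(seq_len(nrow(obs)), function(i)
    history_problem(obs[i, ], info$species[i], info$age_at_marking[i], design) %||% "",
    character(1))
  if (any(nzchar(bad)))
    stop("invalid capture histories:\n", paste0("  row ", which(nzchar(bad)), ": ",
                                                bad[nzchar(bad)], collapse = "\n"))
  rownames(obs) <- info$id
  colnames(obs) <- design$years
  structure(list(design = design, info = info[c("id", "species", "age_at_marking")],
                 obs = obs),
            class = "ms_data")
}

# NULL if valid, otherwise a message.  Works on a single history.
history_problem <- function(codes, species, age, design) {
  if (!age %in% c("juvenile", "adult")) return("age_at_marking must be 'juvenile' or 'adult'")
  if (!species %in% design$species) return(paste0("unknown species '", species, "'"))
  if (anyNA(codes) || !all(codes %in% 0:4)) return("observation codes must be integers 0-4")
  if (all(codes == 0L)) return("history has no capture at all")
  if (any(codes[skipped_idx(design)] != 0L)) return("non-zero code at a skipped occasion")
  first <- which(codes != 0L)[1L]
  if (age == "adult") {
    if (any(codes %in% 1:2)) return("adult-marked female carries a young-state code (1/2)")
  } else {
    if (!codes[first] %in% 1:2) return("juvenile-marked female must be released in state 1 or 2")
    seen <- codes[codes != 0L]
    if (any(diff(seen >= 3L) < 0L)) return("breeding-state reversal (3/4 followed by 1/2)")
  }
  NULL
}

release_occasion <- function(obs) apply(obs != 0L, 1L, which.max)

#' @export
print.ms_data <- function(x, ...) {
  cat("Capture-history dataset:", nrow(x$obs), "females,",
      n_occasions(x$design), "occasions",
      sprintf("(%d-%d)\n", x$design$years[1], max(x$design$years)))
  s <- summary(x)
  cat("  marked per species   :",
      paste(sprintf("%s=%d", names(s$marked), s$marked), collapse = ", "), "\n")
  cat("  known-age (juvenile) :",
      paste(sprintf("%s=%d", names(s$known_age), s$known_age), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a capture-history dataset
#'
#' Counts of marked females per species, the known-age (juvenile-marked)
#' subset per species, and totals by colony of first capture.  The partitions
#' are disjoint and exhaustive: each table sums to the number of histories.
#'
#' @param object An `ms_data` object.
#' @param ... Unused.
#' @return A list with components `marked`, `known_age`, `by_colony`
#'   (species x colony table of first-capture colonies) and `n`.
#' @export
summary.ms_data <- function(object, ...) {
  d <- object$design
  sp <- factor(object$info$species, levels = d$species)
  marked <- table(sp)
  known <- table(sp[object$info$age_at_marking == "juvenile"])
  if (nrow(object$obs)) {
    rel <- release_occasion(object$obs)
    first_code <- object$obs[cbind(seq_len(nrow(object$obs)), rel)]
    col1 <- factor(d$colonies[ifelse(first_code %in% c(1L, 3L), 1L, 2L)],
                   levels = d$colonies)
  } else {
    col1 <- factor(character(0), levels = d$colonies)
  }
  out <- list(marked = c(marked), known_age = c(known),
              by_colony = table(species = sp, colony = col1),
              n = nrow(object$obs))
  class(out) <- "summary.ms_data"
  out
}

#' @export
print.summary.ms_data <- function(x, ...) {
  cat("Marked females       :", paste(sprintf("%s=%d", names(x$marked), x$marked),
                                      collapse = ", "), "(total", x$n, ")\n")
  cat("Known age at marking :", paste(sprintf("%s=%d", names(x$known_age), x$known_age),
                                      collapse = ", "), "\n")
  cat("Colony of first capture:\n")
  print(x$by_colony)
  invisible(x)
}

#' Read and write capture histories as CSV
#'
#' The CSV dialect has a header row and columns `id`, `species`,
#' `age_at_marking`, then one column per occasion year (named `y<year>`),
#' holding the codes 0-4.  `read_histories()` validates every row; malformed
#' rows are dropped with a warning citing their file line numbers, and the
#' full problem list is attached as `attr(x, "problems")`.
#'
#' @param path CSV file path.
#' @param design The [ms_design()] the file refers to.
#' @return `read_histories()` returns an `ms_data` with a `problems`
#'   attribute (data frame of `line`, `id`, `message`); `write_histories()`
#'   returns `path` invisibly.
#' @export
read_histories <- function(path, design) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  ycols <- paste0("y", design$years)
  if (!all(c("id", "species", "age_at_marking") %in% names(raw)) ||
      !all(ycols %in% names(raw)))
    stop("CSV header must contain id, species, age_at_marking and columns ",
         ycols[1], " ... ", ycols[length(ycols)])
  obs <- suppressWarnings(vapply(ycols, function(cn) as.integer(raw[[cn]]),
                                 integer(nrow(raw))))
  obs <- matrix(obs, nrow = nrow(raw))
  msgs <- vapply(seq_len(nrow(raw)), function(i) {
    if (anyNA(obs[i, ])) "non-integer observation code" else
      history_problem(obs[i, ], raw$species[i], raw$age_at_marking[i], design) %||% ""
  }, character(1))
  keep <- !nzchar(msgs)
  problems <- data.frame(line = which(!keep) + 1L,  # +1 for the header line
                         id = raw$id[!keep], message = msgs[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(problems))
    warning(sprintf("dropped %d malformed row(s): %s", nrow(problems),
                    paste(sprintf("line %d (%s)", problems$line, problems$message),
                          collapse = "; ")))
  out <- ms_data(design,
                 info = data.frame(id = raw$id[keep], species = raw$species[keep],
                                   age_at_marking = raw$age_at_marking[keep],
                                   stringsAsFactors = FALSE),
                 obs = obs[keep, , drop = FALSE])
  attr(out, "problems") <- problems
  out
}

#' @param data An `ms_data` object.
#' @rdname read_histories
#' @export
write_histories <- function(data, path) {
  stopifnot(inherits(data, "ms_data"))
  df <- cbind(data$info, as.data.frame(data$obs))
  names(df) <- c("id", "species", "age_at_marking", paste0("y", data$design$years))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export and import MARK-style .inp capture-history records
#'
#' One record per individual: a comment holding the id, the digit string of
#' observation codes, one frequency column per species (group coding), and a
#' terminating `";"`.  Age at marking is implicit in the record: a first code
#' of 1/2 marks a known-age (juvenile) release, 3/4 an adult release, so
#' `read_inp(write_inp(d)) == d` on this format's supported subset.
#'
#' @param data An `ms_data` object.
#' @param path Output file.
#' @return `write_inp()` returns `path` invisibly; `read_inp()` an `ms_data`.
#' @export
write_inp <- function(data, path) {
  stopifnot(inherits(data, "ms_data"))
  sp <- match(data$info$species, data$design$species)
  groups <- vapply(seq_len(nrow(data$obs)), function(i)
    paste(as.integer(seq_along(data$design$species) == sp[i]), collapse = " "),
    character(1))
  lines <- sprintf("/* %s */ %s %s ;", data$info$id,
                   apply(data$obs, 1L, paste, collapse = ""), groups)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_inp
#' @param design The [ms_design()] the file refers to.
#' @export
read_inp <- function(path, design) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^/\\*\\s*(\\S+)\\s*\\*/\\s*([0-9]+)\\s+([01[:space:]]+);$", lines))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("unparseable .inp record at line ", which(bad)[1])
  ids <- vapply(m, `[`, character(1), 2L)
  codes <- vapply(m, `[`, character(1), 3L)
  if (any(nchar(codes) != n_occasions(design)))
    stop("record length does not match the number of occasions")
  obs <- t(vapply(strsplit(codes, ""), as.integer, integer(n_occasions(design))))
  grp <- lapply(strsplit(vapply(m, `[`, character(1), 4L), "\\s+"), as.integer)
  spi <- vapply(grp, function(g) which(g == 1L)[1L], integer(1))
  first <- apply(obs != 0L, 1L, which.max)
  age <- ifelse(obs[cbind(seq_len(nrow(obs)), first)] %in% 1:2, "juvenile", "adult")
  ms_data(design,
          info = data.frame(id = ids, species = design$species[spi],
                            age_at_marking = age, stringsAsFactors = FALSE),
          obs = obs)
}
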