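# Two-level IVF cohort container: one table of treatment cycles, one table of
# gradable embryos.  Stage-wise dropout is encoded by explicit missingness:
# a field that is undefined because the stage was never reached is NA (an
# empty CSV cell), never 0.  An observed zero count is 0.

CYCLE_COLUMNS <- c("cycle_id", "age", "partner_age", "attempt", "n_oocytes",
                   "mixed", "n_embryos", "transferred", "det", "lbe")
EMBRYO_COLUMNS <- c("cycle_id", "evenness", "fragmentation", "icsi")
ATTEMPT_LEVELS <- c("1", "2", "3", "4-5")

#' Construct an IVF cohort
#'
#' Bundles a cycle-level table (one row per treatment cycle) and an
#' embryo-level table (one row per gradable embryo) into a validated
#' `ivf_cohort` object.
#'
#' @param cycles data frame with columns `cycle_id`, `age`, `partner_age`,
#'   `attempt` (one of `"1"`, `"2"`, `"3"`, `"4-5"`; higher attempt numbers
#'   are pooled into `"4-5"`), `n_oocytes`, `mixed`, `n_embryos`,
#'   `transferred`, `det`, `lbe`.  Binary fields are 0/1; fields downstream
#'   of a failed stage are `NA`.
#' @param embryos data frame with columns `cycle_id`, `evenness`,
#'   `fragmentation` (integer grades 1--4) and `icsi` (0/1).
#' @param scaling optional named list of `c(center, scale)` pairs recording
#'   the covariate standardisation in force (filled in by [fit_ivf()]).
#' @param validate if `TRUE` (default) run [validate_cohort()].
#' @return an object of class `ivf_cohort`.
#' @seealso [read_cohort()], [simulate_cohort()], [validate_cohort()]
#' @export
ivf_cohort <- function(cycles, embryos, scaling = NULL, validate = TRUE) {
  cycles <- as.data.frame(cycles, stringsAsFactors = FALSE)
  embryos <- as.data.frame(embryos, stringsAsFactors = FALSE)
  missing_cy <- setdiff(CYCLE_COLUMNS, names(cycles))
  if (length(missing_cy))
    stop("cycle table is missing column(s): ", paste(missing_cy, collapse = ", "))
  missing_em <- setdiff(EMBRYO_COLUMNS, names(embryos))
  if (length(missing_em))
    stop("embryo table is missing column(s): ", paste(missing_em, collapse = ", "))
  cycles <- cycles[CYCLE_COLUMNS]
  embryos <- embryos[EMBRYO_COLUMNS]
  cycles$cycle_id <- as.character(cycles$cycle_id)
  embryos$cycle_id <- as.character(embryos$cycle_id)
  cycles$attempt <- pool_attempts(cycles$attempt)
  for (v in c("n_oocytes", "mixed", "n_embryos", "transferred", "det", "lbe"))
    cycles[[v]] <- as.integer(cycles[[v]])
  for (v in c("evenness", "fragmentation", "icsi"))
    embryos[[v]] <- as.integer(embryos[[v]])
  rownames(cycles) <- NULL
  rownames(embryos) <- NULL
  obj <- structure(list(cycles = cycles, embryos = embryos, scaling = scaling),
                   class = "ivf_cohort")
  if (validate) validate_cohort(obj)
  obj
}

# Attempt numbers of 4 or more are pooled into one "4-5" category at intake;
# the categories beyond the third are too sparse to support separate levels.
pool_attempts <- function(x) {
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(x))
  x[!is.na(num) & num >= 4] <- "4-5"
  bad <- !(x %in% ATTEMPT_LEVELS)
  if (any(bad))
    stop("invalid attempt value(s): ", paste(unique(x[bad]), collapse = ", "),
         " (row ", which(bad)[1], ")")
  x
}

#' Validate an IVF cohort
#'
#' Checks the schema, referential integrity between the two tables and the
#' stage-funnel invariants: a cycle without mixing has no downstream fields;
#' `n_embryos <= n_oocytes`; a transfer requires at least one embryo; double
#' embryo transfer requires at least two; the live-birth indicator is defined
#' exactly for transferred cycles; and the embryo table holds exactly
#' `n_embryos` rows per mixed cycle.
#'
#' @param cohort an [ivf_cohort] object.
#' @return invisibly `TRUE`; otherwise an error naming the offending row.
#' @export
validate_cohort <- function(cohort) {
  cy <- cohort$cycles
  em <- cohort$embryos

  fail <- function(rows, what, table = "cycle") {
    id <- if (table == "cycle") cy$cycle_id[rows[1]] else em$cycle_id[rows[1]]
    stop(sprintf("%s (%s row %d, cycle_id %s; %d row(s) affected)",
                 what, table, rows[1], id, length(rows)), call. = FALSE)
  }

  if (anyDuplicated(cy$cycle_id))
    fail(which(duplicated(cy$cycle_id)), "duplicated cycle_id")
  if (any(is.na(cy$age)) || any(is.na(cy$partner_age)))
    fail(which(is.na(cy$age) | is.na(cy$partner_age)), "missing age")
  if (any(is.na(cy$n_oocytes) | cy$n_oocytes < 0))
    fail(which(is.na(cy$n_oocytes) | cy$n_oocytes < 0),
         "n_oocytes must be a non-negative count")
  if (any(is.na(cy$mixed) | !cy$mixed %in% 0:1))
    fail(which(is.na(cy$mixed) | !cy$mixed %in% 0:1), "mixed must be 0 or 1")

  for (v in c("transferred", "det", "lbe")) {
    bad <- !is.na(cy[[v]]) & !cy[[v]] %in% 0:1
    if (any(bad)) fail(which(bad), sprintf("%s must be 0, 1 or missing", v))
  }

  nm <- cy$mixed == 0
  down <- c("n_embryos", "transferred", "det", "lbe")
  for (v in down) {
    bad <- nm & !is.na(cy[[v]])
    if (any(bad))
      fail(which(bad), sprintf("%s defined although oocytes were never mixed", v))
  }
  bad <- !nm & is.na(cy$n_embryos)
  if (any(bad)) fail(which(bad), "n_embryos missing for a mixed cycle")
  bad <- !nm & cy$n_embryos > cy$n_oocytes
  if (any(bad)) fail(which(bad), "n_embryos exceeds n_oocytes")

  tr <- !is.na(cy$transferred) & cy$transferred == 1
  bad <- tr & cy$n_embryos < 1
  if (any(bad)) fail(which(bad), "transfer recorded without any embryo")
  bad <- tr != !is.na(cy$lbe)
  if (any(bad)) fail(which(bad), "lbe must be defined exactly for transferred cycles")
  bad <- !tr & !is.na(cy$det)
  if (any(bad)) fail(which(bad), "det defined for a non-transferred cycle")
  bad <- tr & is.na(cy$det)
  if (any(bad)) fail(which(bad), "det missing for a transferred cycle")
  bad <- !is.na(cy$det) & cy$det == 1 & cy$n_embryos < 2
  if (any(bad)) fail(which(bad), "double embryo transfer with fewer than 2 embryos")

  # embryo table
  for (v in c("evenness", "fragmentation")) {
    bad <- is.na(em[[v]]) | !em[[v]] %in% 1:4
    if (any(bad)) fail(which(bad), sprintf("%s grade outside 1..4", v), "embryo")
  }
  bad <- is.na(em$icsi) | !em$icsi %in% 0:1
  if (any(bad)) fail(which(bad), "icsi must be 0 or 1", "embryo")
  orphan <- !em$cycle_id %in% cy$cycle_id
  if (any(orphan)) fail(which(orphan), "embryo refers to unknown cycle_id", "embryo")

  counts <- table(factor(em$cycle_id, levels = cy$cycle_id))
  expected <- ifelse(nm, 0L, cy$n_embryos)
  bad <- as.integer(counts) != expected
  if (any(bad))
    fail(which(bad), "embryo row count does not match n_embryos")

  # stage funnel monotonicity
  n_lbe <- sum(cy$lbe == 1, na.rm = TRUE)
  n_tr <- sum(tr)
  n_emb <- sum(!nm & cy$n_embryos >= 1)
  n_mix <- sum(!nm)
  if (!(n_lbe <= n_tr && n_tr <= n_emb && n_emb <= n_mix && n_mix <= nrow(cy)))
    stop("stage funnel violated: counts (lbe, transfer, embryos, mixed, cycles) = ",
         paste(c(n_lbe, n_tr, n_emb, n_mix, nrow(cy)), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Read an IVF cohort from CSV files
#'
#' Empty cells encode "undefined because the stage was not reached"; `"."` is
#' rejected as a missing marker.  Attempt numbers of 4 or more are pooled
#' into the `"4-5"` category at read time.
#'
#' @param cycle_path path to the cycle-level CSV
#'   (columns `cycle_id,age,partner_age,attempt,n_oocytes,mixed,n_embryos,transferred,det,lbe`).
#' @param embryo_path path to the embryo-level CSV
#'   (columns `cycle_id,evenness,fragmentation,icsi`).
#' @return a validated [ivf_cohort].
#' @export
read_cohort <- function(cycle_path, embryo_path) {
  for (p in c(cycle_path, embryo_path))
    if (!file.exists(p)) stop("file not found: ", p)
  cycles <- utils::read.csv(cycle_path, colClasses = "character",
                            na.strings = "", fileEncoding = "UTF-8")
  embryos <- utils::read.csv(embryo_path, colClasses = "character",
                             na.strings = "", fileEncoding = "UTF-8")
  for (tab in list(cycles, embryos)) {
    dots <- vapply(tab, function(col) any(!is.na(col) & trimws(col) == "."), logical(1))
    if (any(dots))
      stop("'.' is not an accepted missing-value marker (column ",
           names(tab)[dots][1], "); leave the field empty instead")
  }
  num <- function(tab, cols, table_name) {
    for (v in cols) {
      if (is.null(tab[[v]])) next
      x <- suppressWarnings(as.numeric(tab[[v]]))
      bad <- which(!is.na(tab[[v]]) & is.na(x))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in column %s (%s row %d)",
                     tab[[v]][bad[1]], v, table_name, bad[1]))
      tab[[v]] <- x
    }
    tab
  }
  cycles <- num(cycles, setdiff(CYCLE_COLUMNS, c("cycle_id", "attempt")), "cycle")
  embryos <- num(embryos, setdiff(EMBRYO_COLUMNS, "cycle_id"), "embryo")
  ivf_cohort(cycles, embryos)
}

#' Write an IVF cohort to CSV files
#'
#' Inverse of [read_cohort()]: `read_cohort()` on the written files
#' reproduces the cohort exactly, including the distinction between an
#' observed zero (`"0"`) and a stage never reached (empty field).
#'
#' @param cohort an [ivf_cohort].
#' @param cycle_path,embryo_path output paths.
#' @return invisibly `cohort`.
#' @export
write_cohort <- function(cohort, cycle_path, embryo_path) {
  stopifnot(inherits(cohort, "ivf_cohort"))
  utils::write.csv(cohort$cycles, cycle_path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(cohort$embryos, embryo_path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(cohort)
}

#' @export
print.ivf_cohort <- function(x, ...) {
  cy <- x$cycles
  cat(sprintf("IVF cohort: %d cycles, %d gradable embryos\n",
              nrow(cy), nrow(x$embryos)))
  cat(sprintf("  funnel: %d started -> %d mixed -> %d with embryos -> %d transferred -> %d live births\n",
              nrow(cy), sum(cy$mixed == 1),
              sum(cy$mixed == 1 & cy$n_embryos >= 1, na.rm = TRUE),
              sum(cy$transferred == 1, na.rm = TRUE),
              sum(cy$lbe == 1, na.rm = TRUE)))
  invisible(x)
}

med_iqr_range <- function(x) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3], min = min(x), max = max(x))
}

#' Summarise an IVF cohort
#'
#' Cohort characteristics in the layout of a clinical baseline table:
#' stage-funnel counts, median/IQR/range of ages and counts per cycle
#' started, attempt-number breakdown, and the distribution of the number of
#' embryos transferred and of live birth events per transfer procedure.
#'
#' @param object an [ivf_cohort].
#' @param ... unused.
#' @return a `summary.ivf_cohort` list with components `counts`,
#'   `continuous`, `attempt`, `det`, `lbe`.
#' @export
summary.ivf_cohort <- function(object, ...) {
  cy <- object$cycles
  if (nrow(cy) == 0L) stop("cannot summarise an empty cohort")
  counts <- c(cycles_started = nrow(cy),
              cycles_mixed = sum(cy$mixed == 1),
              gradable_embryos = nrow(object$embryos),
              transfer_procedures = sum(cy$transferred == 1, na.rm = TRUE))
  oo_started <- cy$n_oocytes
  emb_started <- ifelse(cy$mixed == 1, cy$n_embryos, 0L)
  continuous <- rbind(
    age = med_iqr_range(cy$age),
    partner_age = med_iqr_range(cy$partner_age),
    n_oocytes_per_cycle_started = med_iqr_range(oo_started),
    n_embryos_per_cycle_started = med_iqr_range(emb_started))
  continuous <- data.frame(variable = rownames(continuous), continuous,
                           row.names = NULL)
  att <- table(factor(cy$attempt, levels = ATTEMPT_LEVELS))
  tr <- !is.na(cy$transferred) & cy$transferred == 1
  det_tab <- table(factor(cy$det[tr], levels = 0:1))
  names(det_tab) <- c("single", "double")
  lbe_tab <- table(factor(cy$lbe[tr], levels = 0:1))
  names(lbe_tab) <- c("no", "yes")
  structure(list(counts = counts, continuous = continuous,
                 attempt = att, det = det_tab, lbe = lbe_tab),
            class = "summary.ivf_cohort")
}

#' @export
print.summary.ivf_cohort <- function(x, ...) {
  cat("Cohort characteristics\n")
  for (i in seq_along(x$counts))
    cat(sprintf("  %-28s %d\n", names(x$counts)[i], x$counts[i]))
  cat("  median [IQR] (range):\n")
  cc <- x$continuous
  for (i in seq_len(nrow(cc)))
    cat(sprintf("  %-28s %g [%g to %g] (%g to %g)\n", cc$variable[i],
                cc$median[i], cc$q1[i], cc$q3[i], cc$min[i], cc$max[i]))
  pct <- function(tab) {
    tot <- sum(tab)
    for (i in seq_along(tab))
      cat(sprintf("    %-10s %d (%.0f%%)\n", names(tab)[i], tab[i],
                  if (tot > 0) 100 * tab[i] / tot else 0))
  }
  cat("  attempt number:\n"); pct(x$attempt)
  cat("  embryos transferred per transfer:\n"); pct(x$det)
  cat("  live birth event per transfer:\n"); pct(x$lbe)
  invisible(x)
}
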