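## Examination records and the cleaning rules that turn repeated clinical
## examinations into a one-row-per-animal analysis set.

GRADE_LEVELS <- c("none", "mild", "moderate", "severe")

#' Read examination records
#'
#' @param path CSV file with columns `animal`, `examdate` (ISO-8601, may be
#'   empty), `diagnosis` (`affected`/`unaffected`) and optionally `grade`
#'   (`mild`/`moderate`/`severe`, empty when not graded).
#' @param sep field separator.
#' @param ... passed to [utils::read.table()].
#' @return A data frame of validated examination records (see
#'   [exam_records()]).
#' @export
read_exam_records <- function(path, sep = ",", ...) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, ...)
  need <- c("animal", "examdate", "diagnosis")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in records file: ", paste(miss, collapse = ", "))
  exam_records(animal = df$animal,
               exam_date = ifelse(df$examdate == "", NA, df$examdate),
               diagnosis = df$diagnosis,
               grade = if ("grade" %in% names(df)) df$grade else NULL)
}

#' Validate raw examination records
#'
#' Records with a grade but an `unaffected` diagnosis are internally
#' inconsistent and are rejected with a warning (their count is kept in the
#' `"n_rejected"` attribute).
#'
#' @param animal animal ids.
#' @param exam_date examination dates (`Date` or parseable); `NA` allowed.
#' @param diagnosis `"affected"` or `"unaffected"` (abbreviations `"a"`,
#'   `"u"`, and `0`/`1` accepted).
#' @param grade `"mild"`, `"moderate"`, `"severe"`, or `""`/`NA`/`"none"`
#'   when not graded.
#' @return data frame of class `"exam_records"` with columns `animal`,
#'   `exam_date`, `diagnosis`, `grade`.
#' @export
exam_records <- function(animal, exam_date, diagnosis, grade = NULL) {
  animal <- as.character(animal)
  n <- length(animal)
  exam_date <- as.Date(exam_date)
  diagnosis <- normalize_diagnosis(diagnosis)
  if (is.null(grade)) grade <- rep("none", n)
  grade <- as.character(grade)
  grade[is.na(grade) | grade == ""] <- "none"
  grade <- tolower(grade)
  bad_grade <- !(grade %in% GRADE_LEVELS)
  if (any(bad_grade))
    stop("unknown grade value(s): ",
         paste(unique(grade[bad_grade]), collapse = ", "))
  if (length(exam_date) != n || length(diagnosis) != n || length(grade) != n)
    stop("record fields must have equal length")

  inconsistent <- grade != "none" & diagnosis == "unaffected"
  if (any(inconsistent)) {
    warning(sum(inconsistent),
            " record(s) graded but diagnosed unaffected; rejected")
  }
  out <- data.frame(animal = animal, exam_date = exam_date,
                    diagnosis = diagnosis, grade = grade,
                    stringsAsFactors = FALSE)[!inconsistent, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(inconsistent)
  class(out) <- c("exam_records", "data.frame")
  out
}

normalize_diagnosis <- function(x) {
  x <- tolower(as.character(x))
  x[x %in% c("a", "affected", "1", "true")] <- "affected"
  x[x %in% c("u", "unaffected", "0", "false")] <- "unaffected"
  bad <- !(x %in% c("affected", "unaffected"))
  if (any(bad))
    stop("diagnosis must be affected/unaffected; got: ",
         paste(unique(x[bad]), collapse = ", "))
  x
}

#' Age at examination
#'
#' @param birth,exam dates (`Date` or parseable). `exam >= birth` required.
#' @return A list with `age_years` (completed years, integer) and
#'   `age_continuous` (days / 365.25).
#' @export
compute_age <- function(birth, exam) {
  birth <- as.Date(birth)
  exam <- as.Date(exam)
  days <- as.numeric(exam - birth)
  if (any(days < 0, na.rm = TRUE))
    stop("examination date precedes birth date")
  cont <- days / 365.25
  list(age_years = as.integer(floor(cont)), age_continuous = cont)
}

#' Clean examination records into a one-animal-one-row dataset
#'
#' Applies the cleaning rules used for screening registries:
#' \itemize{
#'   \item records without an examination date cannot be ordered and are
#'     dropped first; an animal is removed only if no dated record remains;
#'   \item duplicates are collapsed keeping the "worst" diagnosis: an animal
#'     is `affected` if any examination found it affected
#'     ("once affected = affected");
#'   \item the final grade is the worst grade ever recorded
#'     (mild < moderate < severe; affected but never graded ranks below
#'     mild);
#'   \item the retained examination date is the date of the first affected
#'     examination for affected animals (age at diagnosis), otherwise the
#'     first examination date;
#'   \item animals whose birth date is missing (or absent from the pedigree)
#'     are removed and counted.
#' }
#'
#' @param records an [exam_records()] data frame (a plain data frame with the
#'   same columns is accepted).
#' @param ped a [pedigree()] supplying `sex` and `birth` per animal.
#' @return An object of class `"clean_data"`: a data frame with one row per
#'   animal (`animal`, `y` (0/1), `diagnosis`, `grade`, `sex`, `birth`,
#'   `exam_date`, `age_years`, `age_continuous`, `diagnosis_year`) and a
#'   [print()]-able `"report"` attribute of class `"cleaning_report"` with
#'   the removal and transition counts.
#' @export
clean_records <- function(records, ped) {
  stopifnot(inherits(ped, "pedigree"))
  if (!all(c("animal", "exam_date", "diagnosis", "grade") %in%
           names(records)))
    stop("'records' must have columns animal, exam_date, diagnosis, grade")
  n_raw <- nrow(records)
  if (n_raw == 0L) stop("no examination records")

  trans <- transition_counts(records)

  dated <- records[!is.na(records$exam_date), , drop = FALSE]
  animals_all <- unique(records$animal)
  animals_dated <- unique(dated$animal)
  n_removed_exam <- length(setdiff(animals_all, animals_dated))

  dated <- dated[order(dated$animal, dated$exam_date), , drop = FALSE]
  sp <- split(seq_len(nrow(dated)), dated$animal)

  rows <- lapply(sp, function(idx) {
    di <- dated[idx, , drop = FALSE]
    affected <- any(di$diagnosis == "affected")
    if (affected) {
      grade_rank <- max(match(di$grade[di$diagnosis == "affected"],
                              GRADE_LEVELS))
      grade <- GRADE_LEVELS[grade_rank]
      date <- di$exam_date[which(di$diagnosis == "affected")[1L]]
    } else {
      grade <- "none"
      date <- di$exam_date[1L]
    }
    data.frame(animal = di$animal[1L],
               diagnosis = if (affected) "affected" else "unaffected",
               grade = grade, exam_date = date, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_unique <- length(animals_all)

  m <- match(out$animal, ped$id)
  if (anyNA(m))
    stop("animal(s) with records missing from pedigree: ",
         paste(utils::head(out$animal[is.na(m)], 5L), collapse = ", "))
  out$sex <- ped$sex[m]
  out$birth <- ped$birth[m]

  no_birth <- is.na(out$birth)
  n_removed_birth <- sum(no_birth)
  out <- out[!no_birth, , drop = FALSE]
  if (!nrow(out)) stop("no animals left after cleaning")

  age <- compute_age(out$birth, out$exam_date)
  out$y <- as.integer(out$diagnosis == "affected")
  out$age_years <- age$age_years
  out$age_continuous <- age$age_continuous
  out$diagnosis_year <- as.integer(format(out$exam_date, "%Y"))
  rownames(out) <- NULL

  report <- structure(list(
    n_raw = n_raw,
    n_unique = n_unique,
    n_removed_missing_exam_date = n_removed_exam,
    n_removed_missing_birth_date = n_removed_birth,
    n_final = nrow(out),
    n_unaffected_to_affected = trans[["unaffected_to_affected"]],
    n_affected_to_unaffected = trans[["affected_to_unaffected"]]
  ), class = "cleaning_report")

  attr(out, "report") <- report
  class(out) <- c("clean_data", "data.frame")
  out
}

#' First-vs-last examination transition counts
#'
#' Over animals with at least two dated examinations, counts how many went
#' from unaffected at the first examination to affected at the last, and
#' vice versa.
#'
#' @param records a data frame with columns `animal`, `exam_date`,
#'   `diagnosis`.
#' @return Named integer vector `c(unaffected_to_affected, affected_to_unaffected)`.
#' @export
transition_counts <- function(records) {
  dated <- records[!is.na(records$exam_date), , drop = FALSE]
  dated <- dated[order(dated$animal, dated$exam_date), , drop = FALSE]
  sp <- split(dated$diagnosis, dated$animal)
  up <- 0L; down <- 0L
  for (dg in sp) {
    if (length(dg) < 2L) next
    first <- dg[1L]; last <- dg[length(dg)]
    if (first == "unaffected" && last == "affected") up <- up + 1L
    if (first == "affected" && last == "unaffected") down <- down + 1L
  }
  c(unaffected_to_affected = up, affected_to_unaffected = down)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Examination cleaning report\n")
  cat("  raw records:                 ", x$n_raw, "\n")
  cat("  unique animals:              ", x$n_unique, "\n")
  cat("  removed, missing exam date:  ", x$n_removed_missing_exam_date, "\n")
  cat("  removed, missing birth date: ", x$n_removed_missing_birth_date, "\n")
  cat("  animals in analysis set:     ", x$n_final, "\n")
  cat("  first->last unaffected->affected:", x$n_unaffected_to_affected, "\n")
  cat("  first->last affected->unaffected:", x$n_affected_to_unaffected, "\n")
  invisible(x)
}

#' @export
print.clean_data <- function(x, ...) {
  cat("Clean analysis set:", nrow(x), "animals,",
      sum(x$y), "affected (prevalence",
      sprintf("%.3f", mean(x$y)), ")\n")
  print(attr(x, "report"))
  invisible(x)
}
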