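#' Construct and validate a pedigree
#'
#' Builds a validated, topologically ordered pedigree from per-animal parent
#' information. Animals referenced only as parents are added as founders with
#' unknown parents. Each animal receives a consecutive integer code
#' (1..N) such that both parents of an animal always carry smaller codes than
#' the animal itself; ties in the ordering are broken by birth date (earliest
#' first, missing dates last) and then by input order.
#'
#' @param id character vector of unique animal identifiers.
#' @param sire,dam character vectors of parent identifiers; `NA`, `""` and
#'   `"0"` denote an unknown parent.
#' @param sex optional vector with values `"male"`, `"female"` or
#'   `"unknown"` (`NA` is mapped to `"unknown"`).
#' @param birth optional vector of birth dates (`Date` or something
#'   `as.Date()` understands); missing dates are allowed.
#'
#' @return An object of class `"pedigree"`: a data frame with one row per
#'   animal in code order and columns `id`, `sire`, `dam` (codes, 0 =
#'   unknown), `sire_id`, `dam_id`, `sex`, `birth` and `code`.
#'
#' @details A cycle in the parent relation (an animal that is its own
#'   ancestor, including the degenerate self-parent case) is a hard error
#'   naming one animal on the cycle, as is a duplicated animal id.
#'
#' @examples
#' ped <- pedigree(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
#'                 dam = c(NA, NA, "B"))
#' ped$code
#' @export
pedigree <- function(id, sire, dam, sex = NULL, birth = NULL) {
  id   <- as.character(id)
  sire <- normalize_parent(sire)
  dam  <- normalize_parent(dam)
  if (length(sire) != length(id) || length(dam) != length(id))
    stop("'id', 'sire' and 'dam' must have the same length")
  if (anyNA(id) || any(id == ""))
    stop("animal ids must be non-missing and non-empty")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1L]
    stop("duplicate animal id: ", dup)
  }

  sex <- if (is.null(sex)) rep("unknown", length(id)) else normalize_sex(sex)
  birth <- if (is.null(birth)) as.Date(rep(NA, length(id))) else as.Date(birth)

  ## closure: parents that never appear as an animal row become founders
  extra <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), id)
  if (length(extra)) {
    id    <- c(id, extra)
    sire  <- c(sire, rep(NA_character_, length(extra)))
    dam   <- c(dam, rep(NA_character_, length(extra)))
    sex   <- c(sex, rep("unknown", length(extra)))
    birth <- c(birth, as.Date(rep(NA, length(extra))))
  }
  n <- length(id)

  sire_i <- match(sire, id)          # NA = unknown
  dam_i  <- match(dam, id)
  self <- which(sire_i == seq_len(n) | dam_i == seq_len(n))
  if (length(self))
    stop("pedigree cycle detected involving animal '", id[self[1L]],
         "' (animal is its own parent)")

  ## Kahn-style topological ordering; among ready animals, earliest birth
  ## first (missing last), then input order.
  code <- integer(n)
  placed <- logical(n)
  bkey <- as.numeric(birth)
  bkey[is.na(bkey)] <- Inf
  remaining <- seq_len(n)
  next_code <- 1L
  while (length(remaining)) {
    ok_s <- is.na(sire_i[remaining]) | placed[ifelse(is.na(sire_i[remaining]),
                                                     1L, sire_i[remaining])]
    ok_d <- is.na(dam_i[remaining]) | placed[ifelse(is.na(dam_i[remaining]),
                                                    1L, dam_i[remaining])]
    ready <- remaining[ok_s & ok_d]
    if (!length(ready))
      stop("pedigree cycle detected involving animal '",
           id[remaining[1L]], "'")
    ready <- ready[order(bkey[ready], ready)]
    code[ready] <- seq.int(next_code, length.out = length(ready))
    next_code <- next_code + length(ready)
    placed[ready] <- TRUE
    remaining <- remaining[!(ok_s & ok_d)]
  }

  ord <- order(code)
  new_code <- integer(n)
  new_code[ord] <- seq_len(n)
  ped <- data.frame(
    id      = id[ord],
    sire    = ifelse(is.na(sire_i[ord]), 0L, new_code[sire_i[ord]]),
    dam     = ifelse(is.na(dam_i[ord]), 0L, new_code[dam_i[ord]]),
    sire_id = sire[ord],
    dam_id  = dam[ord],
    sex     = sex[ord],
    birth   = birth[ord],
    code    = seq_len(n),
    stringsAsFactors = FALSE
  )
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  stopifnot(all(ped$sire < ped$code), all(ped$dam < ped$code))
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("", "0", "NA") | is.na(x)] <- NA_character_
  x
}

normalize_sex <- function(x) {
  x <- tolower(as.character(x))
  x[x %in% c("m", "male", "1")] <- "male"
  x[x %in% c("f", "female", "2")] <- "female"
  x[is.na(x) | !(x %in% c("male", "female"))] <- "unknown"
  x
}

#' Read a pedigree file
#'
#' Reads a delimited text file with one row per animal and builds a validated
#' [pedigree()]. Missing parents may be encoded as an empty field, `"0"` or
#' `NA`.
#'
#' @param path path to the file.
#' @param columns named character vector mapping the roles `animal`, `sire`,
#'   `dam` and optionally `sex`, `birth` to column names in the file.
#' @param sep field separator (default `","`).
#' @param ... further arguments passed to [utils::read.table()].
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path,
                          columns = c(animal = "animal", sire = "sire",
                                      dam = "dam", sex = "sex",
                                      birth = "birthdate"),
                          sep = ",", ...) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, ...)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(columns)))
    stop("'columns' must name at least animal, sire and dam")
  miss <- setdiff(columns[need], names(df))
  if (length(miss))
    stop("missing column(s) in pedigree file: ", paste(miss, collapse = ", "))
  sex <- if ("sex" %in% names(columns) && columns[["sex"]] %in% names(df))
    df[[columns[["sex"]]]] else NULL
  birth <- if ("birth" %in% names(columns) && columns[["birth"]] %in% names(df))
    df[[columns[["birth"]]]] else NULL
  if (!is.null(birth)) birth[birth == ""] <- NA
  pedigree(df[[columns[["animal"]]]], df[[columns[["sire"]]]],
           df[[columns[["dam"]]]], sex = sex, birth = birth)
}

#' Restrict a pedigree to focal animals and their ancestors
#'
#' @param ped a [pedigree()].
#' @param focal_ids character vector of animal ids to keep (with all their
#'   ancestors).
#' @return A new, re-coded [pedigree()] containing the focal animals and
#'   every ancestor.
#' @export
trace_ancestors <- function(ped, focal_ids) {
  stopifnot(inherits(ped, "pedigree"))
  focal_ids <- unique(as.character(focal_ids))
  bad <- setdiff(focal_ids, ped$id)
  if (length(bad))
    stop("unknown focal id(s): ", paste(bad, collapse = ", "))
  keep <- logical(nrow(ped))
  keep[match(focal_ids, ped$id)] <- TRUE
  ## parents precede offspring in code order, so one reverse sweep suffices
  for (j in rev(seq_len(nrow(ped)))) {
    if (keep[j]) {
      if (ped$sire[j] > 0L) keep[ped$sire[j]] <- TRUE
      if (ped$dam[j] > 0L) keep[ped$dam[j]] <- TRUE
    }
  }
  sub <- ped[keep, , drop = FALSE]
  pedigree(sub$id, sub$sire_id, sub$dam_id, sex = sub$sex, birth = sub$birth)
}

#' Animals with recorded offspring
#'
#' Returns the ids of the animals that appear as sire or dam of at least one
#' animal in the pedigree. This "parental subset" drives the genetic-variance
#' update of the threshold-model Gibbs sampler when each animal carries a
#' single binary record.
#'
#' @param ped a [pedigree()].
#' @return Character vector of animal ids (possibly empty), in code order.
#' @export
parent_subset <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  codes <- sort(unique(c(ped$sire, ped$dam)))
  codes <- codes[codes > 0L]
  ped$id[codes]
}

#' @export
print.pedigree <- function(x, ...) {
  n_founder <- sum(x$sire == 0L & x$dam == 0L)
  cat("Pedigree with", nrow(x), "animals (", n_founder, "founders )\n")
  cat("Sexes:", paste(names(table(x$sex)), table(x$sex), collapse = ", "),
      "\n")
  if (nrow(x) > 0) {
    cat("First rows:\n")
    print.data.frame(utils::head(as.data.frame(x)[,
      c("id", "sire_id", "dam_id", "sex", "birth", "code")], 5L))
  }
  invisible(x)
}
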