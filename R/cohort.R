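#' Individual-level cohort containers
#'
#' A `cohort_table` holds one insect cohort followed from oviposition to the
#' death of the last individual: one row per individual with its completed
#' stage durations, sex, fate and death day, plus a long-format table of
#' daily egg counts for females. Ages are whole days with day 0 = the day of
#' oviposition; an individual's stage on day x is the stage occupied at the
#' daily census (end-of-day convention), so a record with stage durations
#' (3, 5, 4) occupies the egg on days 0-2, the larva on days 3-7 and the
#' pupa on days 8-11.
#'
#' @param individuals data.frame with columns `id`, `sex`
#'   (`"female"`/`"male"`/`"unknown"`), `fate` (`"died_preadult"`/
#'   `"died_adult"`), `death_stage`, `emergence_day` (NA for preadult
#'   deaths), `death_day`, and one `dur_<stage>` column per preadult stage
#'   holding the completed duration in days (NA when the stage was not
#'   completed).
#' @param fecundity data.frame with columns `id`, `age_day`, `eggs`
#'   (one row per female per day with at least one egg; may have zero rows).
#' @param stage_order character vector of stage names, the last two being
#'   the female and male adult stages. Default `c("egg", "larva", "pupa",
#'   "female", "male")`, matching pooled larval instars.
#' @param strain_label character label for the strain/treatment.
#'
#' @return A validated object of class `cohort_table` with elements
#'   `strain_label`, `n0`, `stage_order`, `individuals`, `fecundity`.
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()],
#'   [life_table()]
#' @export
#' @examples
#' ind <- data.frame(
#'   id = "f1", sex = "female", fate = "died_adult", death_stage = "female",
#'   emergence_day = 12, death_day = 14, dur_egg = 3, dur_larva = 5,
#'   dur_pupa = 4
#' )
#' fec <- data.frame(id = "f1", age_day = 12, eggs = 30)
#' cohort_table(ind, fec)
cohort_table <- function(individuals, fecundity = NULL,
                         stage_order = c("egg", "larva", "pupa",
                                         "female", "male"),
                         strain_label = "unspecified") {
  if (is.null(fecundity)) {
    fecundity <- data.frame(id = character(), age_day = integer(),
                            eggs = integer())
  }
  obj <- structure(
    list(strain_label = as.character(strain_label)[1],
         n0 = nrow(individuals),
         stage_order = as.character(stage_order),
         individuals = as.data.frame(individuals),
         fecundity = as.data.frame(fecundity)),
    class = "cohort_table"
  )
  validate_cohort(obj)
  obj
}

#' Preadult stage names of a cohort
#' @param cohort a `cohort_table` or a stage-order character vector.
#' @return character vector of preadult stage names (all but the last two).
#' @keywords internal
preadult_stages <- function(cohort) {
  so <- if (inherits(cohort, "cohort_table")) cohort$stage_order else cohort
  so[seq_len(length(so) - 2L)]
}

adult_stages <- function(cohort) {
  so <- if (inherits(cohort, "cohort_table")) cohort$stage_order else cohort
  so[c(length(so) - 1L, length(so))]
}

#' Validate a cohort table
#'
#' Checks every stated invariant of the individual-record data model:
#' consistency of `death_day` with stage durations, sexing rules (unsexed
#' individuals must have died before pupation), and that egg records belong
#' to adult females and fall between emergence and death. Called by
#' [cohort_table()] and [read_cohort()]; errors name the offending record.
#'
#' @param cohort a `cohort_table`.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  ind <- cohort$individuals
  fec <- cohort$fecundity
  so <- cohort$stage_order
  pre <- preadult_stages(so)
  ad <- adult_stages(so)

  need <- c("id", "sex", "fate", "death_stage", "emergence_day", "death_day",
            paste0("dur_", pre))
  miss <- setdiff(need, names(ind))
  if (length(miss) > 0) {
    stop("cohort schema error: missing individual columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(c("id", "age_day", "eggs") %in% names(fec))) {
    stop("cohort schema error: fecundity table needs id, age_day, eggs",
         call. = FALSE)
  }
  if (cohort$n0 != nrow(ind)) {
    stop("validation error: n0 != number of records", call. = FALSE)
  }
  if (anyDuplicated(ind$id)) {
    stop("validation error: duplicated individual ids", call. = FALSE)
  }
  bad_sex <- !(ind$sex %in% c("female", "male", "unknown"))
  if (any(bad_sex)) {
    stop("validation error: invalid sex for record ",
         ind$id[which(bad_sex)[1]], call. = FALSE)
  }
  bad_fate <- !(ind$fate %in% c("died_preadult", "died_adult"))
  if (any(bad_fate)) {
    stop("validation error: invalid fate for record ",
         ind$id[which(bad_fate)[1]], call. = FALSE)
  }
  bad_stage <- !(ind$death_stage %in% so)
  if (any(bad_stage)) {
    stop("validation error: death_stage not in stage_order for record ",
         ind$id[which(bad_stage)[1]], call. = FALSE)
  }

  for (k in seq_len(nrow(ind))) {
    r <- ind[k, ]
    id <- r$id
    durs <- unlist(r[paste0("dur_", pre)])
    if (r$fate == "died_adult") {
      if (!(r$death_stage %in% ad)) {
        stop("validation error: record ", id,
             ": died_adult but death_stage is preadult", call. = FALSE)
      }
      if (is.na(r$emergence_day) || any(is.na(durs))) {
        stop("validation error: record ", id,
             ": adult death requires all preadult durations and ",
             "emergence_day", call. = FALSE)
      }
      if (any(durs < 1)) {
        stop("validation error: record ", id,
             ": completed stage durations must be >= 1 day", call. = FALSE)
      }
      if (sum(durs) != r$emergence_day) {
        stop("validation error: record ", id,
             ": emergence_day != sum of preadult durations", call. = FALSE)
      }
      if (r$death_day - r$emergence_day < 1) {
        stop("validation error: record ", id,
             ": adult must survive >= 1 day past emergence", call. = FALSE)
      }
      expected <- if (r$sex == "female") ad[1] else ad[2]
      if (r$sex == "unknown" || r$death_stage != expected) {
        stop("validation error: record ", id,
             ": adult sex/death_stage mismatch", call. = FALSE)
      }
    } else {
      if (!(r$death_stage %in% pre)) {
        stop("validation error: record ", id,
             ": died_preadult but death_stage is an adult stage",
             call. = FALSE)
      }
      j <- match(r$death_stage, pre)
      done <- if (j > 1) durs[seq_len(j - 1)] else numeric(0)
      if (any(is.na(done)) || any(done < 1)) {
        stop("validation error: record ", id,
             ": stages before death_stage must have durations >= 1",
             call. = FALSE)
      }
      if (!all(is.na(durs[seq(j, length(pre))]))) {
        stop("validation error: record ", id,
             ": durations recorded at or after the death stage",
             call. = FALSE)
      }
      if (!is.na(r$emergence_day)) {
        stop("validation error: record ", id,
             ": preadult death cannot have emergence_day", call. = FALSE)
      }
      partial <- r$death_day - sum(done)
      if (partial < 0) {
        stop("validation error: record ", id,
             ": death_day inconsistent with completed durations",
             call. = FALSE)
      }
    }
    if (r$death_day < 1) {
      stop("validation error: record ", id,
           ": death_day must be >= 1 (alive at the age-0 census)",
           call. = FALSE)
    }
    # unsexed individuals can only be preadult deaths (sexing happens at
    # pupation); the converse (sexed preadult deaths, e.g. in the pupa)
    # is allowed
    if (r$sex == "unknown" && r$fate != "died_preadult") {
      stop("validation error: record ", id,
           ": unknown sex requires fate died_preadult", call. = FALSE)
    }
  }

  if (nrow(fec) > 0) {
    if (any(fec$eggs < 0)) {
      stop("validation error: negative egg counts", call. = FALSE)
    }
    unknown_id <- setdiff(fec$id, ind$id)
    if (length(unknown_id) > 0) {
      stop("validation error: fecundity rows for unknown id ",
           unknown_id[1], call. = FALSE)
    }
    idx <- match(fec$id, ind$id)
    if (any(ind$sex[idx] != "female" | ind$fate[idx] != "died_adult")) {
      bad <- fec$id[which(ind$sex[idx] != "female" |
                            ind$fate[idx] != "died_adult")[1]]
      stop("validation error: record ", bad,
           ": egg records require an adult female", call. = FALSE)
    }
    before <- fec$age_day < ind$emergence_day[idx]
    if (any(before)) {
      stop("validation error: record ", fec$id[which(before)[1]],
           ": eggs recorded before emergence_day", call. = FALSE)
    }
    after <- fec$age_day >= ind$death_day[idx]
    if (any(after)) {
      stop("validation error: record ", fec$id[which(after)[1]],
           ": eggs recorded on or after death_day", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.cohort_table <- function(x, ...) {
  ad <- adult_stages(x)
  ind <- x$individuals
  cat("<cohort_table> strain ", x$strain_label, ": n0 = ", x$n0, "\n",
      sep = "")
  cat("  stages: ", paste(x$stage_order, collapse = " -> "), "\n", sep = "")
  cat("  adults reached: ", sum(ind$fate == "died_adult"),
      " (F ", sum(ind$sex == "female" & ind$fate == "died_adult"),
      ", M ", sum(ind$sex == "male" & ind$fate == "died_adult"), ")\n",
      sep = "")
  cat("  total eggs recorded: ", sum(x$fecundity$eggs), "\n", sep = "")
  invisible(x)
}

# ---- I/O --------------------------------------------------------------

fecundity_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", "_fecundity\\1", path)
}

#' Write a cohort to CSV
#'
#' Writes the individual table to `path` and the long-format daily egg
#' table to a companion file (`<path base>_fecundity.<ext>`). Metadata
#' (strain label, stage order, n0 and any `meta` entries) is kept in
#' leading `#` comment lines so the round trip through [read_cohort()] is
#' lossless.
#'
#' @param cohort a valid `cohort_table`.
#' @param path output CSV path for the individual table.
#' @param meta optional named character vector of extra header metadata
#'   (e.g. seed and package version for simulated cohorts).
#' @return Invisibly, the two paths written.
#' @export
write_cohort <- function(cohort, path, meta = NULL) {
  validate_cohort(cohort)
  fpath <- fecundity_path(path)
  hdr <- c(paste0("# agestagelt ",
                  as.character(utils::packageVersion("agestagelt"))),
           paste0("# strain_label=", cohort$strain_label),
           paste0("# stage_order=", paste(cohort$stage_order,
                                          collapse = "|")),
           paste0("# n0=", cohort$n0))
  if (!is.null(meta)) {
    hdr <- c(hdr, paste0("# ", names(meta), "=", unname(meta)))
  }
  con <- file(path, open = "wt")
  writeLines(hdr, con)
  utils::write.csv(cohort$individuals, con, row.names = FALSE, quote = FALSE)
  close(con)
  con <- file(fpath, open = "wt")
  writeLines(hdr[1], con)
  utils::write.csv(cohort$fecundity, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(c(path, fpath))
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort()]. The companion fecundity file is optional;
#' if absent the cohort has no egg records. `schema` renames non-standard
#' column headers, e.g. `c(id = "insect", death_day = "dday")` maps the
#' file's `insect` column onto `id`.
#'
#' @param path CSV path of the individual table.
#' @param schema optional named character vector: names are the standard
#'   column names, values the column names used in the file.
#' @return A validated `cohort_table`.
#' @export
read_cohort <- function(path, schema = NULL) {
  top <- readLines(path, n = 100)
  hdr <- top[cumprod(startsWith(top, "#")) == 1]

  meta <- list(strain_label = "unspecified",
               stage_order = c("egg", "larva", "pupa", "female", "male"))
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      if (key == "strain_label") meta$strain_label <- val
      if (key == "stage_order") {
        meta$stage_order <- strsplit(val, "|", fixed = TRUE)[[1]]
      }
    }
  }

  ind <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    pos <- match(unname(schema), names(ind))
    if (anyNA(pos)) {
      stop("cohort schema error: file lacks mapped column(s): ",
           paste(schema[is.na(pos)], collapse = ", "), call. = FALSE)
    }
    names(ind)[pos] <- names(schema)
  }
  fpath <- fecundity_path(path)
  fec <- if (file.exists(fpath)) {
    utils::read.csv(fpath, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    NULL
  }
  if (!is.null(fec) && !is.null(fec$id)) fec$id <- as.character(fec$id)
  if (!is.null(ind$id)) ind$id <- as.character(ind$id)
  cohort_table(ind, fec, stage_order = meta$stage_order,
               strain_label = meta$strain_label)
}
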