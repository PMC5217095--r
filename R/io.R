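#' Read a rigid-body realignment parameter file
#'
#' Reads the six-column text files emitted by volume realignment: three
#' translations (mm) and three rotations (radians) per retained frame. Two
#' column orders occur in the wild and are handled as named dialects:
#' `"spm_order"` (`tx ty tz rx ry rz`, as in SPM `rp_*.txt`) and
#' `"mcflirt_order"` (`rx ry rz tx ty tz`, as in MCFLIRT `*.par`). There is no
#' reliable way to tell them apart from the numbers alone, so the dialect must
#' be declared.
#'
#' Participant and run identity are supplied by the caller (normally from a
#' manifest table); filenames are never parsed implicitly — see
#' [parse_run_filename()] for an explicit helper.
#'
#' @param path Path to a whitespace-, comma- or tab-delimited file with
#'   exactly 6 numeric columns.
#' @param dialect `"spm_order"` or `"mcflirt_order"`.
#' @param participant_id,run_id Identity of the series.
#' @param drop_frames Integer: discard this many leading frames (dummy-frame
#'   handling). Default 0 — upstream tools usually emit parameters for
#'   retained frames only.
#' @return A tibble with columns `participant_id`, `run_id`, `frame`,
#'   `trans_x`, `trans_y`, `trans_z` (mm), `rot_x`, `rot_y`, `rot_z` (rad).
#' @export
read_realignment <- function(path, dialect = c("spm_order", "mcflirt_order"),
                             participant_id = "p", run_id = "r",
                             drop_frames = 0L) {
  dialect <- match.arg(dialect)
  mat <- read_numeric_table(path, n_cols = 6L)
  if (drop_frames > 0L) {
    if (drop_frames >= nrow(mat))
      abort(sprintf("drop_frames (%d) leaves no frames in '%s'", drop_frames, path))
    mat <- mat[-seq_len(drop_frames), , drop = FALSE]
  }
  realignment_from_matrix(mat, dialect, participant_id, run_id)
}

realignment_from_matrix <- function(mat, dialect, participant_id, run_id) {
  cols <- if (dialect == "spm_order") c(1:3, 4:6) else c(4:6, 1:3)
  tibble(
    participant_id = participant_id,
    run_id = run_id,
    frame = seq_len(nrow(mat)),
    trans_x = mat[, cols[1]], trans_y = mat[, cols[2]], trans_z = mat[, cols[3]],
    rot_x = mat[, cols[4]], rot_y = mat[, cols[5]], rot_z = mat[, cols[6]]
  )
}

#' Write a realignment series back to a parameter file
#'
#' Inverse of [read_realignment()]; values are written in the requested
#' dialect with full double precision.
#'
#' @param series Tibble as returned by [read_realignment()] (one run).
#' @param path Output path.
#' @param dialect Column order to write.
#' @export
write_realignment <- function(series, path,
                              dialect = c("spm_order", "mcflirt_order")) {
  dialect <- match.arg(dialect)
  stopifnot(length(unique(series$run_id)) == 1)
  m <- as.matrix(series[, c("trans_x", "trans_y", "trans_z",
                            "rot_x", "rot_y", "rot_z")])
  if (dialect == "mcflirt_order") m <- m[, c(4:6, 1:3), drop = FALSE]
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = " ")
  invisible(path)
}

# Strict numeric table reader with delimiter auto-detection among
# whitespace / comma / tab. Mixed delimiters and ragged rows are rejected
# with the offending line number.
read_numeric_table <- function(path, n_cols) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty file: '%s'", path))
  has_comma <- any(grepl(",", lines, fixed = TRUE))
  has_tab <- any(grepl("\t", lines, fixed = TRUE))
  if (has_comma && has_tab)
    abort(sprintf("mixed delimiters (comma and tab) in '%s'", path))
  split_re <- if (has_comma) "\\s*,\\s*" else "[ \t]+"
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[[i]]), split_re)[[1]]
    if (length(parts) != n_cols)
      abort(sprintf("line %d of '%s': expected %d columns, found %d",
                    i, path, n_cols, length(parts)))
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals))
      abort(sprintf("line %d of '%s': non-numeric value '%s'",
                    i, path, parts[which(is.na(vals))[1]]))
    vals
  })
  do.call(rbind, rows)
}

#' Extract participant and run identity from a filename
#'
#' A convenience for the common `rp_<participant>_<run>.txt` /
#' `<participant>_<run>.par` layouts. Never applied implicitly by any reader.
#'
#' @param path File path.
#' @param pattern Regex with two capture groups (participant, run).
#' @return A list with `participant_id` and `run_id`.
#' @export
parse_run_filename <- function(path,
                               pattern = "^(?:rp_)?([^_]+)_([^_.]+)\\.(?:txt|par)$") {
  base <- basename(path)
  m <- regmatches(base, regexec(pattern, base))[[1]]
  if (length(m) != 3)
    abort(sprintf("filename '%s' does not match pattern '%s'", base, pattern))
  list(participant_id = m[2], run_id = m[3])
}

#' Quality-rating levels
#'
#' The ordinal three-level scale used for visual T1w quality control, ordered
#' worst-first so that the composite ("most stringent") rating is the minimum.
#' @export
rating_levels <- function() c("fail", "warn", "pass")

as_rating <- function(x) {
  lv <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(lv), rating_levels())
  if (length(bad) > 0)
    abort(sprintf("unknown rating level(s): %s (allowed: %s)",
                  paste(sQuote(bad), collapse = ", "),
                  paste(rating_levels(), collapse = ", ")))
  factor(lv, levels = rating_levels(), ordered = TRUE)
}

#' Read a two-rater quality rating table
#'
#' @param path CSV/TSV with header columns `participant_id`, `rater_id`,
#'   `rating`. Rating strings are case-insensitive `pass`/`warn`/`fail`.
#' @return Tibble with `participant_id`, `rater_id` and `rating` (ordered
#'   factor, `fail < warn < pass`).
#' @export
read_ratings <- function(path) {
  df <- read_delim_auto(path)
  need <- c("participant_id", "rater_id", "rating")
  if (!all(need %in% names(df)))
    abort(sprintf("ratings file must have columns %s",
                  paste(need, collapse = ", ")))
  dup <- df %>% count(.data$participant_id, .data$rater_id) %>% filter(n > 1)
  if (nrow(dup) > 0)
    abort(sprintf("duplicate (participant, rater) pairs: %s",
                  paste(dup$participant_id, dup$rater_id,
                        sep = "/", collapse = ", ")))
  df %>%
    mutate(participant_id = as.character(.data$participant_id),
           rater_id = as.character(.data$rater_id),
           rating = as_rating(.data$rating)) %>%
    select(all_of(need))
}

#' Read a participant covariate table
#'
#' @param path CSV/TSV with header columns `participant_id`, `age`, `gender`
#'   and optionally `icv`.
#' @return Tibble with validated covariates; `gender` is a factor.
#' @export
read_covariates <- function(path) {
  df <- read_delim_auto(path)
  need <- c("participant_id", "age", "gender")
  if (!all(need %in% names(df)))
    abort(sprintf("covariate file must have columns %s",
                  paste(need, collapse = ", ")))
  df <- df %>% mutate(participant_id = as.character(.data$participant_id),
                      age = as.numeric(.data$age),
                      gender = factor(.data$gender))
  if (anyDuplicated(df$participant_id))
    abort("duplicate participant IDs in covariate table")
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    abort("age must be positive and finite for every participant")
  if (anyNA(df$gender)) abort("gender must be non-missing")
  if (nlevels(df$gender) != 2)
    warn("gender does not have exactly 2 levels")
  as_tibble(df)
}

#' Read a run manifest
#'
#' The manifest assigns each realignment file to a participant, task and run;
#' it is the single source of identity for motion aggregation.
#'
#' @param path CSV/TSV with header columns `participant_id`, `task`, `run_id`
#'   and optionally `file`.
#' @return Tibble.
#' @export
read_manifest <- function(path) {
  df <- read_delim_auto(path)
  need <- c("participant_id", "task", "run_id")
  if (!all(need %in% names(df)))
    abort(sprintf("manifest must have columns %s", paste(need, collapse = ", ")))
  df %>% mutate(participant_id = as.character(.data$participant_id),
                task = as.character(.data$task),
                run_id = as.character(.data$run_id))
}

#' Read a participants-by-vertices thickness matrix
#'
#' @param path_matrix Delimited text; first column `participant_id`, remaining
#'   columns one per vertex (mm).
#' @param path_parcels Optional text file with one integer parcel label per
#'   vertex (one per line).
#' @param cohort Optional covariate tibble; when given, rows are re-ordered to
#'   match (and restricted to) its participants.
#' @return A list of class `mf_thickness` with elements `thickness` (numeric
#'   matrix, rownames = participant IDs), `parcel_map` (integer vector or
#'   NULL) and `hemisphere` (character vector, first half `"lh"`, second
#'   `"rh"`).
#' @export
read_thickness <- function(path_matrix, path_parcels = NULL, cohort = NULL) {
  df <- read_delim_auto(path_matrix)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  bad <- which(!is.finite(mat) | mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort(sprintf("non-positive or non-finite thickness at row %d, vertex %d",
                  bad[1, 1], bad[1, 2]))
  parcels <- NULL
  if (!is.null(path_parcels)) {
    parcels <- as.integer(readLines(path_parcels, warn = FALSE))
    if (length(parcels) != ncol(mat))
      abort(sprintf("parcel file has %d labels but matrix has %d vertices",
                    length(parcels), ncol(mat)))
  }
  if (!is.null(cohort)) {
    missing <- setdiff(cohort$participant_id, ids)
    if (length(missing) > 0)
      abort(sprintf("thickness matrix lacks participants: %s",
                    paste(head(missing, 5), collapse = ", ")))
    mat <- mat[cohort$participant_id, , drop = FALSE]
  }
  new_thickness(mat, parcels)
}

new_thickness <- function(mat, parcel_map = NULL, hemisphere = NULL) {
  if (is.null(hemisphere)) {
    half <- ceiling(ncol(mat) / 2)
    hemisphere <- rep(c("lh", "rh"), c(half, ncol(mat) - half))
  }
  structure(list(thickness = mat, parcel_map = parcel_map,
                 hemisphere = hemisphere),
            class = "mf_thickness")
}

#' @export
print.mf_thickness <- function(x, ...) {
  cat(sprintf("<mf_thickness> %d participants x %d vertices%s\n",
              nrow(x$thickness), ncol(x$thickness),
              if (is.null(x$parcel_map)) "" else
                sprintf(", %d parcels", length(unique(x$parcel_map)))))
  invisible(x)
}

#' Write a thickness dataset to delimited text
#'
#' @param dataset `mf_thickness` object.
#' @param path_matrix,path_parcels Output paths (parcels written only when a
#'   parcel map is present and a path is given).
#' @export
write_thickness <- function(dataset, path_matrix, path_parcels = NULL) {
  df <- data.frame(participant_id = rownames(dataset$thickness),
                   format(dataset$thickness, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("participant_id",
                 sprintf("v%04d", seq_len(ncol(dataset$thickness))))
  utils::write.table(df, path_matrix, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(path_parcels) && !is.null(dataset$parcel_map))
    writeLines(as.character(dataset$parcel_map), path_parcels)
  invisible(path_matrix)
}

# Header-row CSV/TSV reader (delimiter sniffed from the header line).
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) abort(sprintf("empty file: '%s'", path))
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}
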