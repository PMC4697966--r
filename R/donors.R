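#' Allocate donors to WHO T-score groups
#'
#' Applies the WHO densitometric classification to a distal-radius DXA
#' T-score: osteoporotic if T <= -2.5, normal if T >= -1.0, osteopenia in
#' between. Both boundaries are inclusive toward their band by the usual WHO
#' convention ("<= -2.5" osteoporotic, ">= -1.0" normal).
#'
#' @param t_score Numeric vector of finite T-scores.
#' @return Factor with levels `normal`, `osteopenia`, `osteoporotic`.
#' @examples
#' allocate_group(c(1.6, -0.9, -1.8, -2.5, -6.5))
#' @export
allocate_group <- function(t_score) {
  if (!is.numeric(t_score) || any(!is.finite(t_score))) {
    stop("t_score must be finite numeric", call. = FALSE)
  }
  out <- ifelse(t_score <= -2.5, "osteoporotic",
                ifelse(t_score >= -1.0, "normal", "osteopenia"))
  factor(out, levels = c("normal", "osteopenia", "osteoporotic"))
}

#' Read a donor table
#'
#' Reads a CSV with header `id,age,sex,t_score` and returns one record per
#' donor with the WHO group filled in by [allocate_group()].
#'
#' @param path CSV file path.
#' @return Tibble with columns `donor_id`, `age`, `sex`, `t_score`, `group`.
#' @export
read_donor_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  required <- c("id", "age", "sex", "t_score")
  missing <- setdiff(required, trimws(header))
  if (length(missing) > 0L) {
    stop(sprintf("donor table is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    t_score = readr::col_character()   # parsed manually for row-level errors
  ))
  # tolerate unicode minus signs from spreadsheet exports
  ts <- suppressWarnings(as.numeric(gsub("−", "-", df$t_score)))
  bad <- which(!is.finite(ts))
  if (length(bad) > 0L) {
    stop(sprintf("unparsable t_score in row(s) %s (id %s)",
                 paste(bad, collapse = ", "),
                 paste(df$id[bad], collapse = ", ")), call. = FALSE)
  }
  if (!all(df$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  tibble::tibble(
    donor_id = df$id,
    age = df$age,
    sex = factor(df$sex, levels = c("M", "F")),
    t_score = ts,
    group = allocate_group(ts)
  )
}

#' Write and re-read morphometry result tables
#'
#' `write_results()` serializes a [measure_section()] result (or a bound
#' tibble of several donors' results) into three CSV files with stable column
#' order: `bvtv.csv` (one row per donor x region), `plate_thickness.csv`
#' (donor x angle), and `cortical_thickness.csv` (donor x side x level).
#' `read_results()` reads them back; the round trip reproduces values
#' bit-exactly. Missing plate thickness (ray without cartilage) is written as
#' an empty field, never as 0.
#'
#' @param result A `morphometry_result` or a list with tibbles `bvtv`,
#'   `plate`, `cortical` (as produced by binding several results).
#' @param dir Output directory (created if needed).
#' @param header Optional comment line (e.g. a config hash) written at the
#'   top of every file; must start with `#`.
#' @return Invisibly, the three file paths.
#' @export
write_results <- function(result, dir, header = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    bvtv = file.path(dir, "bvtv.csv"),
    plate = file.path(dir, "plate_thickness.csv"),
    cortical = file.path(dir, "cortical_thickness.csv")
  )
  emit <- function(df, path) {
    if (is.null(header)) {
      readr::write_csv(df, path, na = "")
    } else {
      stopifnot(startsWith(header, "#"))
      writeLines(header, path)
      readr::write_csv(df, path, na = "", append = TRUE, col_names = TRUE)
    }
  }
  emit(result$bvtv[c("donor_id", "region", "bvtv")], paths[["bvtv"]])
  emit(result$plate[c("donor_id", "angle", "thickness_mm")], paths[["plate"]])
  emit(result$cortical[c("donor_id", "side", "level", "thickness_mm")], paths[["cortical"]])
  invisible(paths)
}

#' @rdname write_results
#' @export
read_results <- function(dir) {
  # base read.csv parses doubles with strtod, which inverts the shortest
  # round-trip representation bit-exactly
  rd <- function(file, classes) {
    tibble::as_tibble(utils::read.csv(file.path(dir, file), comment.char = "#",
                                      colClasses = classes))
  }
  list(
    bvtv = rd("bvtv.csv",
              c(donor_id = "character", region = "character", bvtv = "numeric")),
    plate = rd("plate_thickness.csv",
               c(donor_id = "character", angle = "numeric", thickness_mm = "numeric")),
    cortical = rd("cortical_thickness.csv",
                  c(donor_id = "character", side = "character",
                    level = "integer", thickness_mm = "numeric"))
  )
}
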