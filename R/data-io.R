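#' Packaged lifetime datasets
#'
#' Three classic datasets used throughout the package examples, shipped
#' as plain-text fixtures:
#'
#' * `covid_moldova` — 28 daily COVID-19 mortality rates (per 10,000)
#'   for the Republic of Moldova, 25 Oct - 21 Nov 2020.
#' * `jute_gauge10`, `jute_gauge20` — breaking strengths of jute fibre
#'   at 10 mm and 20 mm gauge lengths (30 each); a standard
#'   strength/stress pair.
#' * `bank_a`, `bank_b` — customer waiting times (minutes) before
#'   service at two bank counters (100 and 60); another standard
#'   strength/stress pair.
#'
#' @param name one of `"covid_moldova"`, `"jute_gauge10"`,
#'   `"jute_gauge20"`, `"bank_a"`, `"bank_b"`.
#' @return A numeric vector of strictly positive values.
#' @examples
#' length(pml_data("covid_moldova"))  # 28
#' @export
pml_data <- function(name) {
  sizes <- c(covid_moldova = 28L, jute_gauge10 = 30L, jute_gauge20 = 30L,
             bank_a = 100L, bank_b = 60L)
  if (!is.character(name) || length(name) != 1L || !name %in% names(sizes))
    stop("unknown dataset; available: ",
         paste(names(sizes), collapse = ", "), call. = FALSE)
  path <- system.file("extdata", paste0(name, ".txt"),
                      package = "pmlindley", mustWork = TRUE)
  x <- read_sample(path)
  if (length(x) != sizes[[name]])
    stop("packaged dataset ", name, " is corrupted", call. = FALSE)
  x
}

#' Read a univariate positive sample from disk
#'
#' Accepts plain text (one value per line) or single-column CSV with an
#' optional header (auto-detected).  Every entry must parse to a finite,
#' strictly positive number; violations are reported with their line
#' number.
#'
#' @param path file to read.
#' @param column column name or index for multi-column CSV input.
#' @return A numeric vector.
#' @export
read_sample <- function(path, column = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  has_comma <- any(grepl(",", lines))
  offset <- 0L
  if (has_comma || suppressWarnings(is.na(as.numeric(
        strsplit(trimws(lines[1]), ",")[[1]][1])))) {
    df <- utils::read.csv(path, header = suppressWarnings(
      is.na(as.numeric(strsplit(trimws(lines[1]), ",")[[1]][1]))),
      stringsAsFactors = FALSE)
    offset <- nrow(df) < length(lines)  # header consumed a line
    vals <- df[[column]]
    raw <- as.character(vals)
  } else {
    raw <- trimws(lines)
    vals <- suppressWarnings(as.numeric(raw))
  }
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.finite(num) | num <= 0)
  if (length(bad) > 0)
    stop("non-positive or non-numeric entries at line(s) ",
         paste(bad + offset, collapse = ", "), " of ", path, call. = FALSE)
  num
}

#' Write an analysis report to JSON or CSV
#'
#' Deterministic serialisation (stable key ordering, no scientific
#' notation surprises) of a list or data frame.
#'
#' @param report a named list (JSON) or data frame (either format).
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    if (!is.data.frame(report)) report <- as.data.frame(report)
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
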