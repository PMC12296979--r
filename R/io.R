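#' Read an ordinal response matrix from delimited text
#'
#' Wide format is canonical: one row per person, one column per item, a
#' header of item ids, and optionally a first column `person` of person ids.
#' Long format has columns `person,item,response`. Categories are stored
#' 1-based externally.
#'
#' @param path file path.
#' @param format `"wide"` (default) or `"long"`.
#' @param missing_code string coding a missing response (default `"NA"`).
#' @param n_cat number of categories (default 4).
#' @return An `ers_responses` object.
#' @export
read_responses <- function(path, format = c("wide", "long"),
                           missing_code = "NA", n_cat = 4L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty input file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = missing_code, colClasses = NA)
  if (nrow(df) == 0L) stop("empty input file: ", path)
  if (format == "wide") {
    person_ids <- NULL
    if (tolower(names(df)[1]) == "person") {
      person_ids <- as.character(df[[1]])
      df <- df[, -1, drop = FALSE]
    }
    m <- as.matrix(df)
    bad_len <- apply(m, 1, function(r) all(is.na(r)) && any(r == ""))
    suppressWarnings(storage.mode(m) <- "integer")
    response_matrix(m, n_cat = n_cat, person_ids = person_ids,
                    item_ids = names(df))
  } else {
    need <- c("person", "item", "response")
    if (!all(need %in% tolower(names(df))))
      stop("long format needs columns person,item,response")
    names(df) <- tolower(names(df))
    persons <- unique(as.character(df$person))
    items <- unique(as.character(df$item))
    m <- matrix(NA_integer_, length(persons), length(items),
                dimnames = list(persons, items))
    m[cbind(match(as.character(df$person), persons),
            match(as.character(df$item), items))] <-
      as.integer(df$response)
    response_matrix(m, n_cat = n_cat, person_ids = persons, item_ids = items)
  }
}

#' Write a response matrix as wide CSV
#'
#' @param x an `ers_responses` object.
#' @param path output file.
#' @param missing_code string to write for missing cells (default `"NA"`).
#' @export
write_responses <- function(x, path, missing_code = "NA") {
  df <- as.data.frame(x$responses)
  df <- cbind(person = x$person_ids, df)
  utils::write.csv(df, path, row.names = FALSE, na = missing_code)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Known MCMC keys are passed through to [mcmc_config()]; PPC cutoffs and
#' paths are returned alongside. Round-trips losslessly with
#' [write_run_config()].
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config named list to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
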