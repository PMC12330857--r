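#' Read a sectioned key/value configuration file
#'
#' The configuration format is INI-style plain text: `[section]` headers
#' followed by `key = value` lines; `#` starts a comment. Values are
#' coerced to numeric or logical where unambiguous, and comma-separated
#' values become vectors. The format round-trips through
#' [write_config()].
#'
#' @param path file path.
#' @return nested named list (sections of key/value entries).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "default"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      cfg[[section]][[key]] <- parse_config_value(val)
    } else {
      vf_stop(sprintf("malformed config line: %s", ln),
              "vigifc_config_error")
    }
  }
  cfg
}

parse_config_value <- function(val) {
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  coerce1 <- function(v) {
    if (v %in% c("TRUE", "true")) return(TRUE)
    if (v %in% c("FALSE", "false")) return(FALSE)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  out <- lapply(parts, coerce1)
  if (length(unique(vapply(out, class, character(1)))) == 1) {
    unlist(out)
  } else {
    vapply(parts, identity, character(1), USE.NAMES = FALSE)
  }
}

#' Write a configuration list back to sectioned key/value text
#'
#' @param cfg nested named list as returned by [read_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (section in names(cfg)) {
    writeLines(sprintf("[%s]", section), con)
    for (key in names(cfg[[section]])) {
      val <- cfg[[section]][[key]]
      writeLines(sprintf("%s = %s", key,
                         paste(format(val, scientific = FALSE,
                                      trim = TRUE), collapse = ", ")),
                 con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# build a study spec from the [study] section of a config
spec_from_config <- function(cfg, seed_override = NULL) {
  s <- cfg$study %||% list()
  args <- list()
  known <- names(formals(study_spec))
  for (k in intersect(names(s), known)) args[[k]] <- s[[k]]
  if (!is.null(seed_override)) args$rng_seed <- seed_override
  do.call(study_spec, args)
}
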