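LOG_SCHEMA_VERSION <- 1L

#' Write / read a simulation log
#'
#' Logs are stored as tab-separated text with a metadata header of
#' `#`-prefixed lines carrying the schema version, seed, a parameter hash
#' and the full parameter YAML, so that a log round-trips losslessly and a
#' run can be reproduced from the file alone.
#'
#' @param log A `sim_log` tibble.
#' @param path Output file.
#' @return `write_sim_log()`: the path, invisibly. `read_sim_log()`: the
#'   `sim_log` tibble.
#' @export
write_sim_log <- function(log, path) {
  params <- attr(log, "params")
  obst <- attr(log, "obstacles")
  p2 <- params
  if (!is.null(obst) && nrow(obst) > 0) attr(p2, "obstacles") <- obst
  meta <- c(
    sprintf("# vibrisim_log_version: %d", LOG_SCHEMA_VERSION),
    sprintf("# seed: %s", format(attr(log, "seed"))),
    sprintf("# params_hash: %s", rlang::hash(unclass(params))),
    paste0("# ", strsplit(write_params(p2), "\n")[[1]])
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  df <- as.data.frame(log)
  df$tick <- as.integer(df$tick)
  df$clamped <- as.integer(df$clamped)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sim_log
#' @export
read_sim_log <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines)
  header <- lines[meta]
  ver_line <- grep("vibrisim_log_version", header, value = TRUE)
  if (length(ver_line) == 0) {
    abort("not a vibrisim log: missing version header",
          class = "vibrisim_io_error")
  }
  ver <- as.integer(sub(".*: *", "", ver_line[1]))
  if (ver != LOG_SCHEMA_VERSION) {
    abort(sprintf("log schema version %d not supported (expected %d)",
                  ver, LOG_SCHEMA_VERSION),
          class = "vibrisim_io_error")
  }
  body <- lines[-meta]
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (length(unique(nfield)) != 1) {
    bad <- which(nfield != nfield[1])[1]
    abort(sprintf("parse error at data row %d: %d fields, expected %d",
                  bad, nfield[bad], nfield[1]),
          class = "vibrisim_io_error")
  }
  df <- utils::read.delim(text = body, sep = "\t", check.names = FALSE)
  out <- as_tibble(df)
  # all-NA contact columns parse as logical; restore their numeric type
  for (nm in grep("^contact_", names(out), value = TRUE)) {
    out[[nm]] <- as.double(out[[nm]])
  }
  out$tick <- out$tick > 0
  out$clamped <- out$clamped > 0
  yaml_lines <- sub("^# ?", "", header[-seq_len(3)])
  params <- load_params(paste(yaml_lines, collapse = "\n"))
  seed_line <- grep("# seed:", header, value = TRUE)
  attr(out, "seed") <- as.integer(sub(".*: *", "", seed_line[1]))
  attr(out, "obstacles") <- attr(params, "obstacles")
  attr(params, "obstacles") <- NULL
  attr(params, "experiment") <- NULL
  attr(out, "params") <- params
  class(out) <- c("sim_log", class(out))
  out
}

#' Write an experiment result as structured text
#'
#' Serialises an `hta_result`, `cia_result` or `sr_result` (scalars, and
#' grids as records) to YAML.
#'
#' @param x A result object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_result <- function(x, path) {
  drop <- c("params", "data", "whisks", "samples")
  lst <- unclass(x)[setdiff(names(unclass(x)), drop)]
  lst <- lapply(lst, function(v) {
    if (inherits(v, "tbl_df")) as.list(as.data.frame(v)) else v
  })
  lst$type <- class(x)[1]
  yaml::write_yaml(lst, path)
  invisible(path)
}
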