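# Long-format CSV interfaces: UTF-8, comma separated, "." decimal, header row.

#' Write / read the package's long-format CSV tables
#'
#' Plain-CSV persistence for reaction, sharing, rating and score tables.
#' `read_table_csv` restores the table class from the column signature.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `write_table` returns `path` invisibly; `read_table_csv` the
#'   data frame.
#' @export
write_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  sig <- names(out)
  cls <- if (all(c("like", "distrust", "skipped") %in% sig)) "reaction_table"
  else if (all(c("choice", "rt") %in% sig)) "sharing_table"
  else if ("rating" %in% sig) "rating_table"
  else NULL
  if (!is.null(cls)) class(out) <- c(cls, "data.frame")
  out
}

#' Serialize posterior draws to CSV
#'
#' One row per retained draw and group-level parameter: `chain`,
#' `iteration`, `parameter`, `value`.
#'
#' @param fit a `ddm_posterior`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(fit, path) {
  dims <- dim(fit$group)
  df <- data.frame(
    chain = rep(seq_len(dims[2]), each = dims[1], times = dims[3]),
    iteration = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
    parameter = rep(GROUP_PARS, each = dims[1] * dims[2]),
    value = as.numeric(fit$group))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Optional loader for the published study CSVs
#'
#' Convenience reader for externally downloaded experiment CSVs (long
#' format with participant/post/choice columns); nothing in the package
#' depends on it, and it simply normalizes column names it recognizes.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_external_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(out))
  nm[nm %in% c("subject", "subj", "participant")] <- "participant_id"
  nm[nm %in% c("stimulus", "item", "post")] <- "post_id"
  names(out) <- nm
  out
}
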