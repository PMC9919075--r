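# Delimited-text readers and writers for the pipeline's interchange formats.
# All files are tab-separated with a header line and "." as decimal point.

#' Read per-sample peak tables from a delimited file
#'
#' Long format: columns `sample_id`, `rt_min`, `area`; one row per detected
#' peak. Returns one data frame per sample, in first-appearance order.
#'
#' @param path file path.
#' @return named list of peak-list data frames.
#' @export
read_peak_tables <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "rt_min", "area")
  if (!all(need %in% names(d))) {
    stop(sprintf("peak table needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(d$rt_min)) || any(d$area < 0)) {
    stop("retention times must be finite and areas nonnegative", call. = FALSE)
  }
  ids <- unique(d$sample_id)
  out <- lapply(ids, function(id) {
    s <- d[d$sample_id == id, need, drop = FALSE]
    s[order(s$rt_min), , drop = FALSE]
  })
  names(out) <- ids
  out
}

#' Write per-sample peak tables to a delimited file
#'
#' @param tables list of peak-list data frames (`sample_id`, `rt_min`,
#'   `area`).
#' @param path file path.
#' @export
write_peak_tables <- function(tables, path) {
  d <- do.call(rbind, tables)
  utils::write.table(d[, c("sample_id", "rt_min", "area")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a peak matrix as a wide delimited table
#'
#' One row per sample, one column per reference retention time (named
#' `rt_<minutes>`), preceded by `sample_id`.
#'
#' @param matrix a `peak_matrix`.
#' @param path file path.
#' @export
write_peak_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "peak_matrix"))
  d <- as.data.frame(matrix$areas)
  names(d) <- sprintf("rt_%.3f", matrix$reference_rts)
  d <- cbind(sample_id = rownames(matrix$areas), d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an activity table
#'
#' Wide layout mirroring the published endpoint tables: `sample_id`, one
#' column per endpoint, plus a trailing comment-style header line encoding
#' endpoint directions.
#'
#' @param activity an `activity_table`.
#' @param path file path.
#' @export
write_activity_table <- function(activity, path) {
  stopifnot(inherits(activity, "activity_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# direction: %s",
                     paste(sprintf("%s=%s", names(activity$direction),
                                   activity$direction), collapse = " ")),
             con)
  d <- cbind(sample_id = rownames(activity$values),
             as.data.frame(activity$values))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an activity table written by [write_activity_table()]
#'
#' @param path file path.
#' @return an `activity_table`.
#' @export
read_activity_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# direction:", lines, value = TRUE)
  if (length(hdr) != 1) {
    stop("activity table lacks the '# direction:' header line", call. = FALSE)
  }
  pairs <- strsplit(sub("^# direction:\\s*", "", hdr), "\\s+")[[1]]
  kv <- strsplit(pairs, "=")
  dir <- stats::setNames(vapply(kv, `[`, character(1), 2),
                         vapply(kv, `[`, character(1), 1))
  d <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                         stringsAsFactors = FALSE)
  vals <- as.matrix(d[, setdiff(names(d), "sample_id"), drop = FALSE])
  rownames(vals) <- d$sample_id
  endpoints <- lapply(colnames(vals), function(e) {
    list(values = stats::setNames(vals[, e], rownames(vals)),
         direction = unname(dir[[e]]))
  })
  names(endpoints) <- colnames(vals)
  build_activity_table(endpoints)
}

#' Read a target set (one identifier per line)
#'
#' @param path file path; blank lines and `#` comments are ignored.
#' @return character vector of identifiers.
#' @export
read_target_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a two-column interaction edge list
#'
#' Tab-delimited, header required, first two columns are the interacting
#' node identifiers.
#'
#' @param path file path.
#' @return two-column character data frame.
#' @export
read_edge_list <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("edge list needs two columns", call. = FALSE)
  d[, 1:2]
}

#' Read a term-membership map
#'
#' Tab-delimited with columns `term` and `member` (one pair per line).
#'
#' @param path file path.
#' @return named list: term id -> character vector of members.
#' @export
read_term_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term", "member") %in% names(d))) {
    stop("term map needs columns 'term' and 'member'", call. = FALSE)
  }
  split(d$member, d$term)
}

#' Write a screening report and enrichment-style tables
#'
#' @param x a data frame (e.g. `screening_report`, [rank_table()] output or
#'   [hypergeom_enrich()] records).
#' @param path file path.
#' @export
write_report <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network edge list in SIF format
#'
#' One line per edge: `from <TAB> type <TAB> to`.
#'
#' @param network list with an `edges` data frame (`from`, `to`, `type`),
#'   as returned by [build_ctpd_network()].
#' @param path file path.
#' @export
write_sif <- function(network, path) {
  e <- network$edges
  writeLines(sprintf("%s\t%s\t%s", e$from, e$type, e$to), path)
  invisible(path)
}
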