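#' Read a score table into a weighted sample
#'
#' Reads a tab-separated table with one row per data point.  In weighted
#' mode the columns are `score`, `w_fg`, `w_bg`; in unweighted mode they
#' are `score`, `label` with labels in \{fg, bg, 1, 0\}.  Lines starting
#' with `#` are comments.  Validation (finite scores, non-negative weights,
#' removal of zero-total-weight points) is as in [weighted_sample()].
#'
#' @param path path to a TSV file.
#' @param mode `"weighted"` or `"unweighted"`.
#' @return A `wpr_sample`.
#' @examples
#' tsv <- system.file("extdata", "table2_weighted.tsv", package = "wpr")
#' read_sample(tsv, "weighted")
#' @export
read_sample <- function(path, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_input("input file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) stop_input("cannot parse ", path, ": ",
                                   conditionMessage(e)))
  if (mode == "weighted") {
    need <- c("score", "w_fg", "w_bg")
    if (!all(need %in% names(df)))
      stop_input("weighted input needs columns score, w_fg, w_bg")
    weighted_sample(df$score, df$w_fg, df$w_bg)
  } else {
    need <- c("score", "label")
    if (!all(need %in% names(df)))
      stop_input("unweighted input needs columns score, label")
    unweighted_sample(df$score, df$label)
  }
}

fmt17 <- function(x) {
  # 17 significant digits round-trip IEEE doubles exactly
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

#' Write a curve result to a TSV file
#'
#' Serializes the curve points of a `wpr_curve_result` with header comment
#' lines recording kind, interpolation method, AUC, segment count, tool
#' version and (if given) the seed.  Numbers are written with 17
#' significant digits so the file round-trips through [read_curve()] at
#' full double precision.
#'
#' @param curve a `wpr_curve_result`.
#' @param path output file path.
#' @param seed optional integer recorded in the header.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, seed = NULL) {
  stopifnot(inherits(curve, "wpr_curve_result"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_input("cannot write ", path))
  on.exit(close(con))
  version <- as.character(utils::packageVersion("wpr"))
  writeLines(c(
    sprintf("# kind=%s method=%s", curve$kind, curve$method),
    sprintf("# auc=%s n_segments=%d version=%s%s",
            fmt17(curve$auc), curve$n_segments, version,
            if (is.null(seed)) "" else sprintf(" seed=%d", seed))
  ), con)
  pts <- curve$points
  cols <- names(pts)
  writeLines(paste(cols, collapse = "\t"), con)
  body <- do.call(paste, c(lapply(pts, fmt17), sep = "\t"))
  if (length(body)) writeLines(body, con)
  invisible(path)
}

#' Read a curve TSV written by [write_curve()]
#'
#' @param path path to a curve TSV file.
#' @return A `data.frame` of curve points with attributes `kind`,
#'   `method`, `auc`, `n_segments` recovered from the header comments.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  lines <- readLines(path)
  headers <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in headers) {
    kv <- regmatches(h, gregexpr("[a-z_]+=[^ ]+", h))[[1L]]
    for (pair in kv) {
      p <- strsplit(pair, "=", fixed = TRUE)[[1L]]
      meta[[p[1L]]] <- p[2L]
    }
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "kind") <- meta$kind
  attr(df, "method") <- meta$method
  attr(df, "auc") <- as.numeric(meta$auc)
  attr(df, "n_segments") <- as.integer(meta$n_segments)
  df
}
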