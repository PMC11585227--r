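#' Incomplete factorial repeated-measures data
#'
#' Container for observations from `a` independent groups of subjects, each
#' measured at `d` time points, where individual measurements may be missing.
#' Values are stored per group as an `n_i x d` numeric matrix with `NA` marking
#' a missing measurement; the observation indicator \eqn{\lambda_{ijk}} is 1
#' exactly where the value is non-missing. Everything downstream (ranks,
#' effects, covariances, tests) ignores the content of unobserved cells.
#'
#' @param values a single `n x d` matrix (one group) or a list of `n_i x d`
#'   matrices, one per group. `NA` entries are missing observations.
#' @param group_labels,time_labels optional character labels; defaults are
#'   `"G1"..., "T1"...`.
#' @param subject_ids optional list of per-group subject identifier vectors.
#' @param warn_empty_subjects warn when a subject has no observation at any
#'   time point (such subjects are kept but contribute nothing; the
#'   missingness simulators disable the warning since they produce them by
#'   design).
#' @return an object of class `"ifd"` with fields `a`, `d`, `n` (group sizes),
#'   `values` (list of matrices), `observed` (list of 0/1 matrices),
#'   `group_labels`, `time_labels`, `subject_ids`.
#' @examples
#' x <- ifd(matrix(c(1, 2, 4, 3, 3, NA, 2, 5), ncol = 2))
#' design_meta(x)$N
#' @export
ifd <- function(values, group_labels = NULL, time_labels = NULL,
                subject_ids = NULL, warn_empty_subjects = TRUE) {
  if (is.matrix(values)) values <- list(values)
  if (!is.list(values) || length(values) == 0L)
    stop("'values' must be a matrix or a non-empty list of matrices")
  values <- lapply(values, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  d <- unique(vapply(values, ncol, 0L))
  if (length(d) != 1L)
    stop("all groups must have the same number of time points")
  n <- vapply(values, nrow, 0L)
  if (any(n < 1L)) stop("every group needs at least one subject (n_i >= 1)")
  a <- length(values)
  observed <- lapply(values, function(m) {
    o <- matrix(1L, nrow(m), ncol(m))
    o[is.na(m)] <- 0L
    o
  })
  if (is.null(group_labels)) group_labels <- paste0("G", seq_len(a))
  if (is.null(time_labels)) time_labels <- paste0("T", seq_len(d))
  if (length(group_labels) != a || length(time_labels) != d)
    stop("label lengths do not match the design")
  if (is.null(subject_ids))
    subject_ids <- lapply(seq_len(a), function(i) {
      paste0(group_labels[i], ".", seq_len(n[i]))
    })
  no_obs <- vapply(seq_len(a), function(i) sum(rowSums(observed[[i]]) == 0), 0)
  if (warn_empty_subjects && any(no_obs > 0))
    warning(sprintf("%d subject(s) have no observation at any time point; %s",
                    sum(no_obs),
                    "they are kept but contribute nothing to any statistic"))
  structure(
    list(a = a, d = d, n = n, values = values, observed = observed,
         group_labels = as.character(group_labels),
         time_labels = as.character(time_labels),
         subject_ids = subject_ids),
    class = "ifd"
  )
}

#' @export
print.ifd <- function(x, ...) {
  cat(sprintf("Incomplete factorial repeated-measures data: %d group(s), %d time point(s)\n",
              x$a, x$d))
  cat("  group sizes:", paste(x$n, collapse = ", "), "\n")
  ld <- lambda_dot(x)
  cat("  observed per cell (lambda_ij.):\n")
  dimnames(ld) <- list(x$group_labels, x$time_labels)
  print(ld)
  invisible(x)
}

# a x d table of per-cell observed counts
lambda_dot <- function(x) {
  t(vapply(x$observed, colSums, numeric(x$d)))
}

#' Validate an incomplete design before testing
#'
#' Checks that every (group, time) cell has enough observed subjects:
#' \eqn{\lambda_{ij\cdot} \ge 1} for rank/effect computation and
#' \eqn{\lambda_{ij\cdot} \ge 2} wherever a covariance estimate is needed.
#' Cells that fail are named in the error message.
#'
#' @param x an [ifd] object.
#' @param min_per_cell minimum observed subjects per cell (2 for testing).
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_ifd <- function(x, min_per_cell = 2L) {
  stopifnot(inherits(x, "ifd"))
  ld <- lambda_dot(x)
  bad <- which(ld < min_per_cell, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(bad, 1L, function(ij) {
      sprintf("(%s, %s): %d observed", x$group_labels[ij[1]],
              x$time_labels[ij[2]], ld[ij[1], ij[2]])
    })
    stop(sprintf("cell(s) with fewer than %d observed subjects: %s",
                 min_per_cell, paste(cells, collapse = "; ")))
  }
  invisible(x)
}

#' Design metadata: observed counts and pairwise-complete counts
#'
#' Computes the total observed count \eqn{N = \sum_{ijk} \lambda_{ijk}}, the
#' per-cell counts \eqn{\lambda_{ij\cdot}}, and for each group the pairwise
#' complete counts \eqn{\Delta_{i,jj'} = \sum_k \lambda_{ijk}\lambda_{ij'k}}
#' that enter the off-diagonal covariance denominators.
#'
#' @param x an [ifd] object.
#' @return a list of class `"ifd_meta"` with fields `N`, `n_total`,
#'   `lambda_dot` (a x d matrix) and `delta` (list of d x d matrices).
#' @export
design_meta <- function(x) {
  stopifnot(inherits(x, "ifd"))
  ld <- lambda_dot(x)
  delta <- lapply(x$observed, function(o) crossprod(o))
  structure(
    list(N = sum(ld), n_total = sum(x$n), lambda_dot = ld, delta = delta,
         a = x$a, d = x$d, n = x$n),
    class = "ifd_meta"
  )
}

#' @export
print.ifd_meta <- function(x, ...) {
  cat(sprintf("Design meta: N = %d observations, %d subjects\n",
              x$N, x$n_total))
  print(x$lambda_dot)
  invisible(x)
}

#' Serialize design metadata as JSON
#'
#' @param meta an `"ifd_meta"` object from [design_meta()].
#' @return a JSON string.
#' @export
meta_json <- function(meta) {
  jsonlite::toJSON(
    list(N = meta$N, n_total = meta$n_total, n = meta$n,
         lambda_dot = meta$lambda_dot, delta = meta$delta),
    auto_unbox = TRUE, digits = NA
  )
}

#' Read long-format repeated-measures data
#'
#' Reads a CSV or TSV file with columns `subject`, `group`, `time`, `value`
#' (header required). Missing observations may be encoded either as empty/`NA`
#' values or by the complete absence of the (subject, time) row; the two
#' encodings are equivalent. Groups and times are ordered by first appearance
#' unless `sort_labels = TRUE`.
#'
#' @param path file path; tab-separated if the extension is `.tsv`, otherwise
#'   comma-separated.
#' @param sort_labels sort group and time labels instead of keeping
#'   first-appearance order.
#' @return an [ifd] object.
#' @examples
#' read_long_format(system.file("extdata", "demo.csv", package = "wildrank"))
#' @export
read_long_format <- function(path, sort_labels = FALSE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  long_to_ifd(df, sort_labels = sort_labels)
}

# build an ifd from a long data.frame (subject, group, time, value)
long_to_ifd <- function(df, sort_labels = FALSE) {
  need <- c("subject", "group", "time", "value")
  if (!all(need %in% names(df)))
    stop("long format requires columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("no records")
  df$subject <- as.character(df$subject)
  df$group <- as.character(df$group)
  df$time <- as.character(df$time)
  key <- paste(df$subject, df$group, df$time, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, group, time) records: ",
         paste(utils::head(unique(gsub("\r", "/", key[duplicated(key)])), 3),
               collapse = "; "))
  sg <- unique(df[, c("subject", "group")])
  if (anyDuplicated(sg$subject))
    stop("subject(s) appearing in more than one group: ",
         paste(unique(sg$subject[duplicated(sg$subject)]), collapse = ", "))
  groups <- unique(df$group)
  times <- unique(df$time)
  if (sort_labels) { groups <- sort(groups); times <- sort(times) }
  values <- vector("list", length(groups))
  ids <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sub <- df[df$group == groups[i], , drop = FALSE]
    subs <- unique(sub$subject)
    if (sort_labels) subs <- sort(subs)
    m <- matrix(NA_real_, length(subs), length(times),
                dimnames = list(subs, times))
    m[cbind(match(sub$subject, subs), match(sub$time, times))] <-
      as.numeric(sub$value)
    dimnames(m) <- NULL
    values[[i]] <- m
    ids[[i]] <- subs
  }
  ifd(values, group_labels = groups, time_labels = times, subject_ids = ids)
}

#' Write long-format repeated-measures data
#'
#' Inverse of [read_long_format()]: one row per observed (subject, time) pair;
#' unobserved pairs are written as empty values so the round trip preserves
#' the observation mask exactly.
#'
#' @param x an [ifd] object.
#' @param path output file; `.tsv` extension selects tab separation.
#' @param keep_missing write rows with empty `value` for unobserved entries
#'   (default `TRUE`; `FALSE` drops them, the equivalent absent-row dialect).
#' @return `path`, invisibly.
#' @export
write_long_format <- function(x, path, keep_missing = TRUE) {
  stopifnot(inherits(x, "ifd"))
  rows <- do.call(rbind, lapply(seq_len(x$a), function(i) {
    data.frame(
      subject = rep(x$subject_ids[[i]], times = x$d),
      group = x$group_labels[i],
      time = rep(x$time_labels, each = x$n[i]),
      value = as.vector(x$values[[i]]),
      stringsAsFactors = FALSE
    )
  }))
  if (!keep_missing) rows <- rows[!is.na(rows$value), , drop = FALSE]
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(rows, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

#' Worked demonstration dataset
#'
#' A tiny one-group, two-time design (4 subjects, one missing value) whose
#' mid-ranks, relative effects and covariance entries are simple fractions;
#' used throughout the documentation and tests.
#'
#' @return an [ifd] object with `a = 1`, `d = 2`, `n = 4`.
#' @examples
#' relative_effects(midranks(demo_fixture()), design_meta(demo_fixture()))
#' @export
demo_fixture <- function() {
  ifd(matrix(c(1, 2, 4, 3,
               3, NA, 2, 5), ncol = 2))
}
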