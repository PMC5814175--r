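## Data containers and on-disk formats.
##
## Expression matrices are log2 values, genes as rows, samples as columns
## (column-oriented files are rejected, never guessed). Missing values are
## the literal token "NA" only and are excluded from medians and tests,
## never imputed. Gene identifiers are matched case-sensitively with no
## alias resolution.

#' Construct a validated expression dataset
#'
#' @param values numeric matrix of log2 expression, genes as rows (unique
#'   non-empty rownames), samples as columns (unique non-empty colnames).
#'   Entries must be finite or \code{NA}.
#' @param cohort optional character vector naming the cohort of each
#'   sample; either named by sample id or in column order. \code{NULL}
#'   assigns every sample to cohort \code{"default"}.
#' @return an object of class \code{"ExpressionDataset"}: a list with
#'   \code{values} (the matrix) and \code{cohort} (named character
#'   vector, one label per sample).
#' @export
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' ds <- expression_dataset(m)
#' dim(ds$values)
expression_dataset <- function(values, cohort = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || any(!nzchar(gid)))
    stop("gene ids (rownames) must be present and non-empty")
  if (is.null(sid) || any(!nzchar(sid)))
    stop("sample ids (colnames) must be present and non-empty")
  if (anyDuplicated(gid))
    stop("duplicate gene id: ", gid[duplicated(gid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  bad <- is.infinite(values) | is.nan(values)
  if (any(bad))
    stop("non-finite expression value at gene ", gid[row(values)[bad][1L]],
         ", sample ", sid[col(values)[bad][1L]])
  if (is.null(cohort)) {
    cohort <- setNames(rep("default", ncol(values)), sid)
  } else {
    nm <- names(cohort)
    cohort <- as.character(cohort)
    if (length(cohort) != length(sid))
      stop("cohort labels must cover every sample exactly once")
    names(cohort) <- if (is.null(nm)) sid else nm
    if (!setequal(names(cohort), sid))
      stop("cohort labels must cover every sample exactly once")
    cohort <- cohort[sid]
    if (anyNA(cohort) || any(!nzchar(cohort)))
      stop("every sample needs one non-empty cohort label")
  }
  structure(list(values = values, cohort = cohort),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples;", length(unique(x$cohort)), "cohort(s)\n")
  invisible(x)
}

#' Construct a gene set
#'
#' @param name non-empty set label.
#' @param members character vector of gene identifiers; duplicates are
#'   removed, first-occurrence order preserved.
#' @param description free text.
#' @return an object of class \code{"GeneSet"}.
#' @export
gene_set <- function(name, members, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set name must be a non-empty string")
  members <- unique(as.character(members))
  structure(list(name = name, description = description,
                 members = members), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet", x$name, "-", length(x$members), "genes\n")
  invisible(x)
}

#' Construct a validated survival table
#'
#' @param sample_id unique sample identifiers.
#' @param time follow-up time (days), all \eqn{\ge 0}.
#' @param event logical or 0/1; \code{TRUE} = death observed.
#' @param covariate optional numeric per-sample covariate (log2
#'   expression of one gene).
#' @return a \code{data.frame} of class \code{"survival_table"} with
#'   columns \code{sample_id}, \code{time}, \code{event} (logical) and
#'   optionally \code{covariate}.
#' @export
survival_table <- function(sample_id, time, event, covariate = NULL) {
  sample_id <- as.character(sample_id)
  if (length(sample_id) == 0L) stop("survival table needs at least one record")
  if (anyDuplicated(sample_id))
    stop("duplicate sample id: ", sample_id[duplicated(sample_id)][1L])
  time <- as.numeric(time)
  if (anyNA(time) || any(time < 0)) stop("time must be >= 0 for every record")
  if (is.numeric(event)) {
    if (!all(event %in% c(0, 1))) stop("event must be 0/1 or logical")
    event <- event == 1
  }
  if (!is.logical(event) || anyNA(event)) stop("event must be 0/1 or logical")
  out <- data.frame(sample_id = sample_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  if (!is.null(covariate)) out$covariate <- as.numeric(covariate)
  class(out) <- c("survival_table", "data.frame")
  out
}

version_header <- function(seed = NULL) {
  paste0("# cyclederg ", as.character(packageVersion("cyclederg")),
         if (!is.null(seed)) paste0(" seed=", seed) else "")
}

#' Read a genes-by-samples expression TSV
#'
#' The file is tab-separated, UTF-8, first header cell \code{gene_id},
#' remaining header cells sample ids; each following row is a gene id
#' plus numeric (or literal \code{NA}) cells. Lines starting with
#' \code{#} are comments. An optional two-column cohort map
#' (\code{sample_id}, \code{cohort}) assigns cohorts; without it every
#' sample is cohort \code{"default"}. Every sample in the map must be in
#' the matrix and vice versa.
#'
#' @param path expression TSV.
#' @param cohort_map_path optional cohort map TSV.
#' @return an \code{\link{expression_dataset}}.
#' @export
read_expression_matrix <- function(path, cohort_map_path = NULL) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", comment.char = "#",
                    quote = "", na.strings = NULL)
  if (ncol(raw) < 2L) stop("expression file needs a gene_id column plus samples: ", path)
  if (names(raw)[1L] != "gene_id")
    stop("first header cell must be 'gene_id', found '", names(raw)[1L], "' in ", path)
  gid <- raw[[1L]]
  if (anyDuplicated(gid))
    stop("duplicate gene id: ", gid[duplicated(gid)][1L], " in ", path)
  sid <- names(raw)[-1L]
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L], " in ", path)
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- is.na(num) & vals != "NA"
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell '", vals[bad][1L], "' at gene ", gid[i[1L]],
         " (row ", i[1L], "), sample ", sid[i[2L]], " in ", path)
  }
  dimnames(num) <- list(gid, sid)
  cohort <- NULL
  if (!is.null(cohort_map_path)) {
    cm <- read.delim(cohort_map_path, header = TRUE, sep = "\t",
                     check.names = FALSE, colClasses = "character",
                     comment.char = "#", quote = "")
    if (!all(c("sample_id", "cohort") %in% names(cm)))
      stop("cohort map needs columns sample_id, cohort: ", cohort_map_path)
    missing <- setdiff(cm$sample_id, sid)
    if (length(missing))
      stop("cohort map sample absent from matrix: ", missing[1L])
    unmapped <- setdiff(sid, cm$sample_id)
    if (length(unmapped))
      stop("matrix sample missing from cohort map: ", unmapped[1L])
    cohort <- setNames(cm$cohort, cm$sample_id)
  }
  expression_dataset(num, cohort)
}

#' Write an expression dataset as TSV
#'
#' Emits a comment header line with tool version (and seed if supplied),
#' then a \code{gene_id}-headed genes-by-samples table readable by
#' \code{\link{read_expression_matrix}}.
#'
#' @param dataset an \code{ExpressionDataset}.
#' @param path output file.
#' @param cohort_map_path optional path for the cohort map TSV.
#' @param seed optional seed to record in the header comment.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(dataset, path, cohort_map_path = NULL,
                                    seed = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(version_header(seed), con)
  df <- data.frame(gene_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort_map_path)) {
    cm <- data.frame(sample_id = names(dataset$cohort),
                     cohort = unname(dataset$cohort))
    con2 <- file(cohort_map_path, "w", encoding = "UTF-8")
    writeLines(version_header(seed), con2)
    write.table(cm, con2, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con2)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: each line is \code{name TAB description TAB
#' member TAB member ...}. Members are deduplicated, line order is
#' preserved. A line with fewer than three fields is a hard error.
#'
#' @param path GMT file.
#' @return a list of \code{\link{gene_set}} objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields in ", path)
    out[[i]] <- gene_set(f[1L], f[-(1:2)], description = f[2L])
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets a \code{GeneSet} or list of them.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, if (nzchar(s$description)) s$description else ".",
            s$members), collapse = "\t"), character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a clinical survival TSV
#'
#' Columns \code{sample_id}, \code{time_days}, \code{event} (0/1) and
#' optionally \code{covariate}. Negative times and events outside
#' \{0, 1\} are hard errors.
#'
#' @param path TSV file.
#' @return a \code{\link{survival_table}}.
#' @export
read_survival_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "#", quote = "")
  need <- c("sample_id", "time_days", "event")
  if (!all(need %in% names(df)))
    stop("survival table needs columns sample_id, time_days, event: ", path)
  survival_table(df$sample_id, df$time_days, df$event,
                 covariate = if ("covariate" %in% names(df)) df$covariate)
}

#' Write a survival table as TSV
#'
#' @param table a \code{survival_table}.
#' @param path output file.
#' @param seed optional seed recorded in the header comment.
#' @return \code{path}, invisibly.
#' @export
write_survival_table <- function(table, path, seed = NULL) {
  stopifnot(inherits(table, "survival_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(version_header(seed), con)
  out <- data.frame(sample_id = table$sample_id,
                    time_days = table$time,
                    event = as.integer(table$event))
  if (!is.null(table$covariate)) out$covariate <- table$covariate
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
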