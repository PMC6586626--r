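# Tabular outputs carry a single '#' header line with tool version, config
# hash and seed so every file is traceable to the run that produced it.
provenanceHeader <- function(configHash = "none", seed = NA) {
  sprintf("# rtkmet %s\tconfig=%s\tseed=%s",
          as.character(packageVersion("rtkmet")), configHash,
          as.character(seed))
}

#' Write a data.frame as provenance-stamped TSV
#'
#' Tab-separated values preceded by one `#` comment line carrying the
#' package version, a config hash and the seed of the producing run.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param configHash short configuration hash (any string).
#' @param seed integer seed of the producing run.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path, configHash = "none", seed = NA) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenanceHeader(configHash, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-stamped TSV
#'
#' @param path file path; `#`-prefixed lines are skipped.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a matrix as TSV with a leading id column
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @param idColumn name of the leading identifier column.
#' @inheritParams writeTsv
#' @return `path`, invisibly.
#' @export
writeMatrixTsv <- function(m, path, idColumn = "feature",
                           configHash = "none", seed = NA) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  writeTsv(df, path, configHash, seed)
}

#' Read a matrix written by [writeMatrixTsv()]
#'
#' @param path file path.
#' @return numeric matrix with row names from the first column.
#' @export
readMatrixTsv <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a GMT gene-set file
#'
#' Standard GMT layout: one set per line, tab-separated
#' `name <tab> description <tab> member1 <tab> member2 ...`.
#'
#' @param path file path.
#' @param toUpper upper-case member ids (default TRUE, to make downstream
#'   set operations case-robust).
#' @return named list set name -> character vector of members; descriptions
#'   kept in attribute `descriptions`.
#' @export
readGmt <- function(path, toUpper = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) (need name, description, >=1 member): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    if (toUpper) members <- toupper(members)
    unique(members[nzchar(members)])
  })
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "descriptions") <-
    setNames(vapply(parts, `[`, character(1), 2L), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list set name -> member ids.
#' @param path output path.
#' @param descriptions optional named character vector of descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
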