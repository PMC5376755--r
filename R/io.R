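.pkgVersion <- function()
  as.character(utils::packageVersion("MycStratify"))

.stampLine <- function(configHash = NULL)
  paste0("# MycStratify ", .pkgVersion(),
         if (!is.null(configHash)) paste0(" config_hash=", configHash))

#' Hash a configuration object
#'
#' MD5 of the canonical JSON serialization; stamped into every pipeline
#' output so runs are traceable to their configuration.
#'
#' @param config any jsonlite-serializable object
#' @return character md5 digest
#' @export
configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Read a genes-by-samples expression matrix
#'
#' TSV/CSV: first column gene ids, header row sample ids; leading `#`
#' comment lines are skipped. GCT v1.2: `#1.2` line, dimension line,
#' `Name`/`Description` columns. Gene and sample ids must be unique.
#'
#' @param path file path
#' @param format "tsv", "csv" or "gct"; default guessed from the extension
#' @param scale declared scale of the values, "linear" or "log2"
#' @return \linkS4class{SummarizedExperiment} with assay `exprs` and
#'   `metadata(x)$scale` set
#' @export
readExpressionMatrix <- function(path, format = NULL,
                                 scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     gct = "gct", csv = "csv", "tsv")
  format <- match.arg(format, c("tsv", "csv", "gct"))
  if (format == "gct") {
    mat <- .readGct(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- as.character(df[[1]])
  }
  if (!is.numeric(mat)) stop("non-numeric expression cell(s) in ", path)
  dup <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]),
               collapse = ", "))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat), metadata = list(scale = scale))
}

.readGct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#1.2"))
    stop("not a GCT v1.2 file: ", path)
  dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
  body <- utils::read.table(text = lines[-(1:2)], header = TRUE,
                            sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(body) != dims[1] || ncol(body) - 2L != dims[2])
    stop(sprintf("GCT dimension line says %d x %d but body is %d x %d",
                 dims[1], dims[2], nrow(body), ncol(body) - 2L))
  mat <- as.matrix(body[, -(1:2), drop = FALSE])
  rownames(mat) <- as.character(body[[1]])
  mat
}

#' Write an expression matrix as TSV or GCT v1.2
#'
#' @param x matrix or SummarizedExperiment (assay 1)
#' @param path destination
#' @param format "tsv" or "gct"
#' @param configHash optional hash stamped into the TSV header comment
#' @export
writeExpressionMatrix <- function(x, path, format = c("tsv", "gct"),
                                  configHash = NULL) {
  format <- match.arg(format)
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, 1L)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
    body <- data.frame(Name = rownames(x), Description = rownames(x),
                       x, check.names = FALSE)
    utils::write.table(body, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.stampLine(configHash), con)
    utils::write.table(data.frame(gene = rownames(x), x,
                                  check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, member ids. Duplicate
#' member ids within a set are deduplicated with a warning; duplicate set
#' names and lines with fewer than 3 fields are errors.
#'
#' @param path GMT file
#' @return named list of character gene-id vectors
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(stats::setNames(list(), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate gene-set name(s): ", paste(dup, collapse = ", "))
  sets <- lapply(seq_along(fields), function(i) {
    members <- fields[[i]][-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate member id(s) in set '", nm[i], "'; deduplicated")
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  empty <- lengths(sets) == 0
  if (any(empty))
    stop("empty gene set(s): ", paste(nm[empty], collapse = ", "))
  sets
}

#' Write a GMT gene-set collection
#'
#' @param collection named list of character vectors
#' @param path destination
#' @param descriptions optional per-set description (defaults to the name)
#' @export
writeGmt <- function(collection, path, descriptions = names(collection)) {
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' CSV with a `sample_id` column; `#` comment lines skipped.
#'
#' @param path CSV file
#' @return data.frame
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("metadata must contain a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s) in metadata")
  df
}

.writeStampedCsv <- function(df, path, configHash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.stampLine(configHash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits the expression TSV (genes as rows), the sample metadata CSV
#' (sample_id, group, time_months, event, ki67, diff), the chemogram CSV
#' and the qPCR Ct CSV, each stamped with the tool version and config
#' hash.
#'
#' @param cohort a \linkS4class{MycCohort}
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of written paths
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- configHash(cohort@simConfig)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    chemograms = file.path(dir, "chemograms.csv"),
    qpcr = file.path(dir, "qpcr.csv"))
  writeExpressionMatrix(cohort, paths["expression"], configHash = h)
  cd <- SummarizedExperiment::colData(cohort)
  meta <- data.frame(sample_id = colnames(cohort),
                     group = as.character(cd$group),
                     time_months = cd$time_months, event = cd$event,
                     ki67 = cd$ki67, diff = cd$diff)
  .writeStampedCsv(meta, paths["metadata"], h)
  .writeStampedCsv(chemograms(cohort), paths["chemograms"], h)
  .writeStampedCsv(qpcrData(cohort), paths["qpcr"], h)
  invisible(paths)
}
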