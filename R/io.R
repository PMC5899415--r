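# Plain-text file formats. All indices written to files are 1-based and all
# numbers use %.12g with locale-independent decimal points.

#' Read a pedigree file
#'
#' Three whitespace- or tab-separated columns: id, sire, dam, with the
#' sentinel (default `"0"`) for unknown parents. Malformed rows are reported
#' with their 1-based line number. Input that is not in parents-first order
#' is re-sorted with a warning.
#'
#' @param path file path.
#' @param header does the file carry a header line? Default `FALSE`.
#' @param sentinel unknown-parent code.
#' @return A validated pedigree tibble (see [validate_pedigree()]).
#' @export
read_pedigree <- function(path, header = FALSE, sentinel = "0") {
  lines <- readLines(path)
  if (header) lines <- lines[-1]
  keep <- nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 3)) {
    bad <- which(keep)[which(nf != 3)[1]] + as.integer(header)
    ss_abort(sprintf("line %d: expected 3 fields, found %d",
                     bad, nf[which(nf != 3)[1]]), "parse")
  }
  m <- do.call(rbind, fields)
  validate_pedigree(
    tibble::tibble(id = m[, 1], sire = m[, 2], dam = m[, 3]),
    sentinel = sentinel
  )
}

#' @rdname read_pedigree
#' @param ped pedigree tibble.
#' @export
write_pedigree <- function(ped, path, sentinel = "0") {
  out <- ped
  out$sire[is.na(out$sire)] <- sentinel
  out$dam[is.na(out$dam)] <- sentinel
  utils::write.table(out[, c("id", "sire", "dam")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write marker matrices
#'
#' TSV with a header line; first column `id`, remaining columns markers.
#' Values are validated against the declared coding; missing values are
#' rejected.
#'
#' @param path file path.
#' @param coding `"presence01"` or `"dosage012"`.
#' @return A numeric matrix with id rownames.
#' @export
read_markers <- function(path, coding = c("presence01", "dosage012")) {
  coding <- match.arg(coding)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) ss_abort("marker file needs id plus >= 1 marker column", "parse")
  ids <- df[[1]]
  Z <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(Z) <- "numeric")
  if (anyNA(Z)) ss_abort("missing or non-numeric marker values", "parse")
  rownames(Z) <- ids
  allowed <- if (coding == "presence01") c(0, 1) else c(0, 1, 2)
  if (!all(Z %in% allowed)) {
    ss_abort(sprintf("marker values outside {%s}", paste(allowed, collapse = ",")),
             "parse")
  }
  Z
}

#' @rdname read_markers
#' @param Z marker matrix with id rownames.
#' @export
write_markers <- function(Z, path) {
  df <- data.frame(id = rownames(Z), Z, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Two tab-separated columns `id`, `y` with a header; `NA` allowed.
#'
#' @param path file path.
#' @return A tibble with columns `id`, `y`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "numeric"))
  names(df)[1:2] <- c("id", "y")
  tibble::as_tibble(df[, 1:2])
}

#' @rdname read_phenotypes
#' @param pheno data frame with columns `id`, `y`.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- pheno[, c("id", "y")]
  out$y <- ifelse(is.na(out$y), "NA", fmt_num(out$y))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write fold-assignment tables
#'
#' Two tab-separated columns `id`, `fold` with a header.
#'
#' @param path file path.
#' @return A tibble with columns `id`, `fold`.
#' @export
read_folds <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "integer"))
  names(df)[1:2] <- c("id", "fold")
  tibble::as_tibble(df[, 1:2])
}

#' @rdname read_folds
#' @param folds data frame with columns `id`, `fold`.
#' @export
write_folds <- function(folds, path) {
  utils::write.table(folds[, c("id", "fold")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a relationship matrix
#'
#' Two dialects: `"dense"` is a TSV with an id header row and an id first
#' column; `"triplet"` is the breeding-software interchange format — one line
#' `"row col value"` per non-zero lower-triangle entry (1-based indices)
#' plus a separate id-map file (`<path>.ids` by default, lines
#' `"index<TAB>id"`). Values are printed with `%.12g`, so a write/read
#' round-trip reproduces them to full printed precision.
#'
#' @param M symmetric matrix with id dimnames.
#' @param path output path.
#' @param dialect `"dense"` or `"triplet"`.
#' @param idmap_path id-map sidecar path for the triplet dialect.
#' @return `path`, invisibly.
#' @export
write_relmat <- function(M, path, dialect = c("dense", "triplet"),
                         idmap_path = paste0(path, ".ids")) {
  dialect <- match.arg(dialect)
  ids <- rownames(M)
  if (is.null(ids)) ss_abort("matrix must carry id dimnames", "ids")
  if (dialect == "dense") {
    txt <- apply(M, 1, function(r) paste(fmt_num(r), collapse = "\t"))
    writeLines(c(paste(c("id", ids), collapse = "\t"),
                 paste(ids, txt, sep = "\t")), path)
  } else {
    n <- nrow(M)
    idx <- which(lower.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
    writeLines(sprintf("%d %d %s", idx[, 1], idx[, 2],
                       fmt_num(M[idx])), path)
    writeLines(paste(seq_len(n), ids, sep = "\t"), idmap_path)
  }
  invisible(path)
}

#' @rdname write_relmat
#' @param tol symmetry tolerance on dense read.
#' @export
read_relmat <- function(path, dialect = c("dense", "triplet"),
                        idmap_path = paste0(path, ".ids"), tol = 1e-8) {
  dialect <- match.arg(dialect)
  if (dialect == "dense") {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    ids <- df[[1]]
    M <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(M) <- "numeric"
    if (!identical(colnames(M), ids)) {
      ss_abort("dense matrix header ids do not match row ids", "ids")
    }
    dimnames(M) <- list(ids, ids)
    check_symmetric(M, tol = tol, what = "matrix on file")
  } else {
    map <- utils::read.delim(idmap_path, header = FALSE,
                             colClasses = "character")
    ids <- map[[2]][order(as.integer(map[[1]]))]
    n <- length(ids)
    trip <- utils::read.table(path, col.names = c("row", "col", "value"),
                              colClasses = c("integer", "integer", "numeric"))
    if (any(trip$row < 1 | trip$row > n | trip$col < 1 | trip$col > n)) {
      ss_abort("triplet index out of range", "parse")
    }
    M <- matrix(0, n, n, dimnames = list(ids, ids))
    M[cbind(trip$row, trip$col)] <- trip$value
    M[cbind(trip$col, trip$row)] <- trip$value
    M
  }
}

#' Run manifest
#'
#' JSON sidecar recording everything needed to reproduce a run: the command
#' and its parameters, seeds, tolerances, package version, and md5 checksums
#' of the input files.
#'
#' @param command name of the operation.
#' @param params named list of parameter values.
#' @param inputs character vector of input file paths (checksummed).
#' @param path output path for the JSON, or `NULL` to return the list.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(command, params = list(), inputs = character(),
                         path = NULL) {
  manifest <- list(
    command = command,
    package = "ssblend",
    version = as.character(packageVersion("ssblend")),
    r_version = as.character(getRversion()),
    params = params,
    inputs = if (length(inputs)) {
      as.list(setNames(unname(tools::md5sum(inputs)), inputs))
    } else list()
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
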