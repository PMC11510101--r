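#' Read a pedigree CSV
#'
#' Expects columns `id,sire,dam`; `0`, empty or `NA` denote unknown
#' parents.  The result is validated and topologically sorted (a warning is
#' issued if records had to be reordered).
#'
#' @param path CSV file path.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (!nrow(ped)) stop("empty pedigree file: ", path)
  out <- validate_pedigree(ped)
  orig <- ped$id
  if (!identical(out$id[out$id %in% orig], orig[orig %in% out$id]))
    warning("pedigree records reordered so parents precede offspring")
  out
}

#' Write a pedigree CSV
#'
#' @param ped pedigree data frame.
#' @param path output path; unknown parents are written as `0`.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped[, c("id", "sire", "dam")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype dosage table
#'
#' `tsv` dialect: tab-separated, first column animal id, remaining columns
#' integer dosages with a marker-id header.  `plink_raw` dialect: the PLINK
#' `.raw` layout (`FID IID PAT MAT SEX PHENOTYPE` then one column per
#' marker); the IID column provides animal ids and the other metadata
#' columns are ignored.  Dosages must be 0/1/2 with no missing values
#' (inputs are assumed imputed).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @return dosage matrix, animals in rows.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(df)))
      stop("not a plink .raw file: missing ",
           paste(setdiff(meta, names(df)), collapse = ", "))
    ids <- as.character(df$IID)
    mat <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  }
  storage.mode(mat) <- "numeric"
  bad <- which(is.na(mat) | !(mat %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid or missing dosage at row ", bad[1, 1], " (animal ",
         ids[bad[1, 1]], "), column ", colnames(mat)[bad[1, 2]])
  rownames(mat) <- ids
  mat
}

#' Write a genotype dosage table (tsv dialect)
#'
#' @param geno dosage matrix with animal rownames.
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(id = rownames(geno), geno, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASV count table (animals x ASVs, TSV)
#'
#' @param path file path; first column animal id, header of ASV ids.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  if (any(is.na(mat) | mat < 0)) stop("counts must be nonnegative integers")
  rownames(mat) <- as.character(df[[1]])
  mat
}

#' Write an ASV count table
#'
#' @param counts count matrix with animal rownames.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype CSV
#'
#' Requires an `id` column; a `dam` column, if present, is checked against
#' an optional pedigree (`ped`): unknown dam ids get their own maternal
#' level with a warning.
#'
#' @param path CSV path.
#' @param ped optional pedigree for dam-id validation.
#' @export
read_phenotypes <- function(path, ped = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty phenotype file: ", path)
  if (!"id" %in% names(df)) stop("phenotype file needs an 'id' column")
  df$id <- as.character(df$id)
  if (!is.null(ped) && "dam" %in% names(df)) {
    unknown <- setdiff(stats::na.omit(unique(df$dam)), ped$id)
    if (length(unknown))
      warning("dam id(s) not in pedigree (kept as own maternal levels): ",
              paste(utils::head(unknown, 5L), collapse = ", "))
  }
  df
}

#' Write / read a relationship matrix as TSV
#'
#' Square layout with the animal ids as header row and first column.
#' Values are written with full precision, so a write/read round trip is
#' exact to below 1e-12.
#'
#' @param M symmetric matrix with id dimnames.
#' @param path file path.
#' @export
write_matrix <- function(M, path) {
  M <- (M + t(M)) / 2
  df <- data.frame(id = rownames(M),
                   format(M, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "numeric"
  rownames(mat) <- as.character(df[[1]])
  mat
}

#' Write a workflow report
#'
#' Writes the per-trait model-comparison table as TSV and the full report
#' (including warnings collected by the caller) as JSON.
#'
#' @param report list with at least a `table` data frame.
#' @param dir output directory (created if needed).
#' @param name file stem (default "report").
#' @export
write_report <- function(report, dir, name = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(report$table, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  json <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(report[setdiff(names(report), "fits")], json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(c(tsv = tsv, json = json))
}
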