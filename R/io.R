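#' Read and write gene-level count matrices
#'
#' Counts travel as a plain TSV (genes in rows, a header row of sample
#' ids, first column of gene ids) or as a MatrixMarket triple
#' (`matrix.mtx`, `genes.tsv`, `samples.tsv`).
#'
#' @param path for TSV, the file; for MTX, the directory holding the
#'   triple.
#' @return an integer matrix, genes x samples, with dimnames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  check_counts(m)
  m
}

#' @rdname read_counts_tsv
#' @param counts gene x sample integer matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  check_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_counts_tsv
#' @export
read_counts_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
  storage.mode(m) <- "integer"
  rownames(m) <- readLines(file.path(path, "genes.tsv"))
  colnames(m) <- readLines(file.path(path, "samples.tsv"))
  check_counts(m)
  m
}

#' @rdname read_counts_tsv
#' @export
write_counts_mtx <- function(counts, path) {
  check_counts(counts)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(path, "matrix.mtx"))
  writeLines(rownames(counts), file.path(path, "genes.tsv"))
  writeLines(colnames(counts), file.path(path, "samples.tsv"))
  invisible(path)
}

#' Gene-set collections (GMT + family map)
#'
#' A gene-set collection couples named member-gene sets (blood
#' transcription modules, BTMs) with a family label per set
#' (e.g. "IFN type I", "B cells"); sets without a family default to
#' "others".
#'
#' @param sets named list of character vectors of member gene ids.
#' @param families named character vector mapping set id to family
#'   label; ids absent from it get "others".
#' @param descriptions optional named character vector of set
#'   descriptions (second GMT field).
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, families = NULL, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("sets must be a uniquely named list")
  if (any(lengths(sets) == 0L)) stopf("empty gene sets are not allowed")
  fam <- setNames(rep("others", length(sets)), names(sets))
  if (!is.null(families)) {
    keep <- intersect(names(families), names(sets))
    fam[keep] <- families[keep]
  }
  structure(list(sets = lapply(sets, as.character),
                 families = fam,
                 descriptions = descriptions %||%
                   setNames(rep("", length(sets)), names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d families\n",
              length(x$sets), length(unique(x$families))))
  invisible(x)
}

#' @rdname gene_set_collection
#' @param gmt_path GMT file (tab-separated: id, description, members).
#' @param family_path optional CSV with columns `set_id`, `family`.
#' @export
read_gene_sets <- function(gmt_path, family_path = NULL) {
  sets <- fgsea::gmtPathways(gmt_path)
  lines <- strsplit(readLines(gmt_path), "\t", fixed = TRUE)
  desc <- setNames(vapply(lines, function(x) x[2], ""),
                   vapply(lines, function(x) x[1], ""))
  fam <- NULL
  if (!is.null(family_path)) {
    fdf <- read.csv(family_path, stringsAsFactors = FALSE)
    fam <- setNames(fdf$family, fdf$set_id)
  }
  gene_set_collection(sets, fam, desc[names(sets)])
}

#' @rdname gene_set_collection
#' @param collection a `gene_set_collection`.
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]] %||% "",
            collection$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gene_set_collection
#' @export
write_family_map <- function(collection, path) {
  write.csv(data.frame(set_id = names(collection$families),
                       family = unname(collection$families)),
            path, row.names = FALSE)
  invisible(path)
}
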