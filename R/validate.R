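#' Validate a bundle of pipeline input files
#'
#' Report-only schema checks: the counts file parses with unique gene
#' and sample ids; the metadata CSV has the required columns; every
#' counts column is described in the metadata (and vice versa); GMT
#' lines have at least three tab-separated fields (violations carry
#' the line number); plate/lab CSVs have their documented columns.
#'
#' @param paths named list of paths: any of `counts`, `metadata`,
#'   `gene_sets`, `family_map`, `titers`, `labs`, `elisa`,
#'   `neutralization`, `titration`.
#' @return data.frame with columns `input`, `violation`; zero rows
#'   for a fully consistent bundle.
#' @export
validate_inputs <- function(paths) {
  v <- list()
  note <- function(input, msg)
    v[[length(v) + 1]] <<- data.frame(input = input, violation = msg,
                                      stringsAsFactors = FALSE)
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]) &&
        !dir.exists(paths[[nm]]))
      note(nm, sprintf("file not found: %s", paths[[nm]]))
  }
  counts <- NULL
  if (!is.null(paths$counts) && file.exists(paths$counts)) {
    counts <- tryCatch(read_counts_tsv(paths$counts), error = function(e) {
      note("counts", conditionMessage(e)); NULL })
  }
  meta <- NULL
  if (!is.null(paths$metadata) && file.exists(paths$metadata)) {
    meta <- read.csv(paths$metadata, stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "subject_id", "timepoint")
    miss <- setdiff(need, names(meta))
    if (length(miss))
      note("metadata", sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  }
  if (!is.null(counts) && !is.null(meta) && "sample_id" %in% names(meta)) {
    extra <- setdiff(colnames(counts), meta$sample_id)
    for (s in extra)
      note("counts", sprintf("sample '%s' absent from metadata", s))
    orphan <- setdiff(meta$sample_id, colnames(counts))
    for (s in orphan)
      note("metadata", sprintf("sample '%s' absent from counts", s))
  }
  if (!is.null(paths$gene_sets) && file.exists(paths$gene_sets)) {
    lines <- readLines(paths$gene_sets)
    nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
    for (i in which(nf < 3))
      note("gene_sets", sprintf("line %d has %d field(s), need >= 3", i, nf[i]))
  }
  if (!is.null(paths$family_map) && file.exists(paths$family_map)) {
    fm <- read.csv(paths$family_map, stringsAsFactors = FALSE)
    miss <- setdiff(c("set_id", "family"), names(fm))
    if (length(miss))
      note("family_map", sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  }
  schema <- list(
    titers = c("subject_id", "group"),
    labs = c("subject_id", "analyte", "phase", "value"),
    elisa = c("type", "sample_id", "dilution_stage", "od450"),
    neutralization = c("type", "sample_id", "reciprocal_dilution", "rlu"),
    titration = c("infected", "total"))
  for (nm in names(schema)) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) next
    df <- read.csv(paths[[nm]], stringsAsFactors = FALSE)
    miss <- setdiff(schema[[nm]], names(df))
    if (length(miss))
      note(nm, sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  }
  if (!length(v))
    return(data.frame(input = character(0), violation = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}
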