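#' Read a Matrix Market UMI count matrix with feature/barcode sidecars
#'
#' Reads the standard 10x-style triplet layout: a Matrix Market `.mtx` file
#' (1-based indices on disk) plus `features.tsv` and `barcodes.tsv` sidecars,
#' any of which may be gzip-compressed. Returns a sparse features x cells
#' integer matrix with feature ids as rownames and barcodes as colnames, the
#' container the rest of the package consumes.
#'
#' @param mtx_path path to the `.mtx` (or `.mtx.gz`) triplet file.
#' @param features_path path to the feature-id sidecar (one id per line,
#'   first column used).
#' @param barcodes_path path to the barcode sidecar (one barcode per line).
#' @return a [Matrix::dgCMatrix-class] of nonnegative integer counts.
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 1, cells_per_animal = 50))
#' d <- tempfile(); paths <- write_counts(co$counts, d)
#' m <- read_counts(paths$mtx, paths$features, paths$barcodes)
#' identical(as.matrix(m), as.matrix(co$counts))
#' @seealso [write_counts()], [aggregate_pseudobulk()]
#' @export
read_counts <- function(mtx_path, features_path, barcodes_path) {
  for (p in c(mtx_path, features_path, barcodes_path))
    if (!file.exists(p)) stop_bad("file not found: ", p)
  m <- as(Matrix::readMM(open_maybe_gz(mtx_path)), "TsparseMatrix")
  features <- read_sidecar(features_path)
  barcodes <- read_sidecar(barcodes_path)
  if (nrow(m) != length(features))
    stop_bad("dimension mismatch: matrix has ", nrow(m), " rows but ",
             length(features), " feature ids")
  if (ncol(m) != length(barcodes))
    stop_bad("dimension mismatch: matrix has ", ncol(m), " columns but ",
             length(barcodes), " barcodes")
  if (anyDuplicated(paste(m@i, m@j)))
    stop_bad("duplicate (row, col) triplet in ", mtx_path)
  vals <- if (.hasSlot(m, "x")) m@x else rep(1, length(m@i))
  if (any(vals < 0)) stop_bad("negative count entry in ", mtx_path)
  if (any(vals != round(vals))) stop_bad("non-integer count entry in ", mtx_path)
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(features, barcodes)
  validate_count_matrix(m)
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

read_sidecar <- function(path) {
  x <- read.delim(open_maybe_gz(path), header = FALSE,
                  stringsAsFactors = FALSE)
  as.character(x[[1L]])
}

validate_count_matrix <- function(m) {
  if (!is(m, "sparseMatrix")) m <- as(as(Matrix::Matrix(m, sparse = TRUE),
                                         "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_bad("count matrix needs feature ids (rownames) and barcodes (colnames)")
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop_bad("count matrix entries must be nonnegative integers")
  m
}

#' Write a count matrix as Matrix Market triplet plus sidecars
#'
#' Writes `matrix.mtx` (1-based triplet indices), `features.tsv` and
#' `barcodes.tsv` under `dir_path`, the layout [read_counts()] reads back.
#'
#' @param m sparse features x cells count matrix with dimnames.
#' @param dir_path output directory, created if absent.
#' @return invisibly, a named list of the three file paths.
#' @export
write_counts <- function(m, dir_path) {
  m <- validate_count_matrix(m)
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  paths <- list(mtx      = file.path(dir_path, "matrix.mtx"),
                features = file.path(dir_path, "features.tsv"),
                barcodes = file.path(dir_path, "barcodes.tsv"))
  if (length(m@x)) {
    Matrix::writeMM(m, paths$mtx)
  } else {
    # writeMM declares an entry-less matrix "pattern symmetric"; write the
    # general-coordinate header explicitly instead
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 paste(nrow(m), ncol(m), 0)), paths$mtx)
  }
  writeLines(rownames(m), paths$features)
  writeLines(colnames(m), paths$barcodes)
  invisible(paths)
}

#' Read or write a cell annotation table
#'
#' The annotation table maps every barcode to its animal, treatment arm,
#' cell type, brain region and weeks post dose. Stored as plain TSV.
#'
#' @param path TSV path (optionally gzipped on read).
#' @return a data.frame with columns `barcode`, `animal`, `treatment`,
#'   `cell_type`, `region`, `weeks_post_dose`.
#' @export
read_annotations <- function(path) {
  ann <- read.delim(open_maybe_gz(path), stringsAsFactors = FALSE)
  validate_annotations(ann)
}

#' @param ann annotation data.frame as returned by [read_annotations()].
#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  ann <- validate_annotations(ann)
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_annotations <- function(ann) {
  need <- c("barcode", "animal", "treatment", "cell_type", "region",
            "weeks_post_dose")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop_bad("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$barcode)) stop_bad("duplicate barcodes in annotation")
  ann
}

#' Collapse single cells to per-animal, per-cell-type pseudobulk sums
#'
#' For every (animal, cell type) group, sums the target-gene UMIs and the
#' total UMIs over that group's cells. These pseudobulk sums, with total UMIs
#' as exposure, are the input to the negative binomial knockdown model
#' ([fit_nb_offset_model()]). Cells with zero total UMIs carry no exposure
#' and are dropped with a warning.
#'
#' @param m count matrix (features x cells) with dimnames.
#' @param ann annotation data.frame covering every barcode of `m`.
#' @param target_feature feature id of the target gene.
#' @return a `pseudobulk` data.frame with one row per (animal, cell type):
#'   columns `animal`, `cell_type`, `treatment`, `target_umi`, `total_umi`,
#'   `n_cells`.
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 1, cells_per_animal = 100))
#' pb <- aggregate_pseudobulk(co$counts, co$annotations, "TARGET")
#' head(pb)
#' @export
aggregate_pseudobulk <- function(m, ann, target_feature) {
  m <- validate_count_matrix(m)
  ann <- validate_annotations(ann)
  if (!target_feature %in% rownames(m))
    stop_bad("target feature '", target_feature, "' not in matrix")
  missing_bc <- setdiff(colnames(m), ann$barcode)
  if (length(missing_bc))
    stop_bad("unannotated barcode(s): ", paste(utils::head(missing_bc, 3),
                                               collapse = ", "))
  ann <- ann[match(colnames(m), ann$barcode), , drop = FALSE]

  totals <- Matrix::colSums(m)
  target <- as.numeric(m[target_feature, ])
  keep <- totals > 0
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) with zero total UMIs dropped before ",
            "pseudobulk aggregation", call. = FALSE)
    ann <- ann[keep, , drop = FALSE]
    totals <- totals[keep]
    target <- target[keep]
  }
  grp <- interaction(ann$animal, ann$cell_type, drop = TRUE, sep = "\r")
  tab <- data.frame(
    animal     = sub("\r.*", "", levels(grp)),
    cell_type  = sub(".*\r", "", levels(grp)),
    target_umi = as.integer(rowsum(target, grp)[, 1L]),
    total_umi  = as.integer(rowsum(totals, grp)[, 1L]),
    n_cells    = as.integer(tabulate(grp)),
    stringsAsFactors = FALSE
  )
  tab$treatment <- ann$treatment[match(tab$animal, ann$animal)]
  tab <- tab[order(tab$cell_type, tab$animal),
             c("animal", "cell_type", "treatment", "target_umi",
               "total_umi", "n_cells")]
  rownames(tab) <- NULL
  class(tab) <- c("pseudobulk", "data.frame")
  tab
}

validate_pseudobulk <- function(tab) {
  need <- c("animal", "cell_type", "treatment", "target_umi", "total_umi",
            "n_cells")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_bad("pseudobulk table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(tab$target_umi > tab$total_umi))
    stop_bad("target_umi exceeds total_umi in pseudobulk table")
  if (any(tab$n_cells < 1L)) stop_bad("pseudobulk rows need n_cells >= 1")
  tab
}

#' Per-cell (target, total) UMI pairs for one cell type
#'
#' Extracts, for each cell of the requested type, its target-gene UMI count
#' and its total UMI count -- the raw material for per-cell histograms and
#' the single-cell knockdown-architecture comparison ([compare_modes()]).
#' Rows are ordered by barcode so the output is stable under permutation of
#' matrix columns.
#'
#' @inheritParams aggregate_pseudobulk
#' @param cell_type cell-type label to extract.
#' @param treatment optional treatment label to additionally filter on.
#' @return data.frame with columns `barcode`, `target_umi`, `total_umi`.
#' @export
per_cell_target_counts <- function(m, ann, target_feature, cell_type,
                                   treatment = NULL) {
  m <- validate_count_matrix(m)
  ann <- validate_annotations(ann)
  if (!target_feature %in% rownames(m))
    stop_bad("target feature '", target_feature, "' not in matrix")
  if (!cell_type %in% ann$cell_type)
    stop_bad("unknown cell type '", cell_type, "'")
  keep <- ann$cell_type == cell_type
  if (!is.null(treatment)) keep <- keep & ann$treatment == treatment
  bcs <- sort(intersect(ann$barcode[keep], colnames(m)))
  sub <- m[, bcs, drop = FALSE]
  data.frame(barcode    = bcs,
             target_umi = as.integer(sub[target_feature, ]),
             total_umi  = as.integer(Matrix::colSums(sub)),
             stringsAsFactors = FALSE)
}

#' Read or write a pseudobulk table as TSV
#'
#' @param tab pseudobulk data.frame ([aggregate_pseudobulk()] schema).
#' @param path TSV path. Lines starting with `#` (run metadata headers) are
#'   skipped on read.
#' @export
write_pseudobulk <- function(tab, path, meta = NULL) {
  tab <- validate_pseudobulk(tab)
  con <- file(path, "w")
  on.exit(close(con))
  write_meta_header(con, meta)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pseudobulk
#' @param meta optional named list written as `# key=value` header lines.
#' @export
read_pseudobulk <- function(path) {
  tab <- read.delim(open_maybe_gz(path), comment.char = "#",
                    stringsAsFactors = FALSE)
  tab <- validate_pseudobulk(tab)
  class(tab) <- c("pseudobulk", "data.frame")
  tab
}

write_meta_header <- function(con, meta) {
  if (is.null(meta)) return(invisible())
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, as.character(meta[[k]])), con)
}
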