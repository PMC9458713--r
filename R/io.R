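# TSV readers/writers for the pipeline's on-disk formats. All files are
# plain tab-separated text with parcel ids as headers so runs are
# inspectable and diffable.

#' Read and write parcel BOLD timeseries TSV
#'
#' Rows are timepoints, columns are parcels (header row of parcel ids).
#'
#' @param bold a `bold_ts` or T x N matrix.
#' @param path file path.
#' @param tr_seconds repetition time recorded when reading a bare matrix.
#' @return `read_bold_tsv` returns a `bold_ts` (without hidden labels).
#' @export
write_bold_tsv <- function(bold, path) {
  values <- if (inherits(bold, "bold_ts")) bold$values else as.matrix(bold)
  write.table(values, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bold_tsv
#' @export
read_bold_tsv <- function(path, tr_seconds = NA_real_) {
  values <- as.matrix(read.delim(path, check.names = FALSE))
  if (any(!is.finite(values)))
    stop_invalid("non-finite values in BOLD file ", path)
  structure(list(values = values, tr_seconds = tr_seconds,
                 parcel_id = colnames(values), labels = NULL),
            class = "bold_ts")
}

#' Read and write a dense connectome matrix TSV
#'
#' N x N matrix with a parcel-id header row and first column.
#'
#' @param W square matrix with parcel dimnames.
#' @param path file path.
#' @export
write_connectome_tsv <- function(W, path) {
  assert_square(W)
  df <- data.frame(parcel_id = rownames(W), W, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome_tsv
#' @export
read_connectome_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df[[1]]
  assert_square(W)
  W
}

#' Read and write nodal map tables
#'
#' First column `parcel_id`, one named column per map.
#'
#' @param maps named list of nodal vectors or N x M matrix.
#' @param parcel_id parcel ids (atlas order).
#' @param path file path.
#' @export
write_maps_tsv <- function(maps, parcel_id, path) {
  if (is.list(maps)) maps <- do.call(cbind, maps)
  df <- data.frame(parcel_id = parcel_id, maps, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_maps_tsv
#' @export
read_maps_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a synthetic cohort to disk
#'
#' Writes the atlas, per-subject BOLD and connectome TSVs, a cohort manifest
#' (`subject_id`, `group`, `bold_path`, `sc_path`) and a JSON sidecar
#' recording all generator parameters and seeds, so the directory fully
#' determines the cohort.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  rows <- lapply(cohort$subjects, function(s) {
    bp <- file.path(dir, paste0(s$subject_id, "_bold.tsv"))
    sp <- file.path(dir, paste0(s$subject_id, "_sc.tsv"))
    write_bold_tsv(s$bold, bp)
    write_connectome_tsv(s$sc, sp)
    data.frame(subject_id = s$subject_id, group = s$group,
               bold_path = basename(bp), sc_path = basename(sp))
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.tsv")
  write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$planted, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
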