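# Tabular I/O. All tabular data travel as TSV (participants x features
# with a header row and an id column); models and statistics as JSON.
# Floats are written at 15 significant digits, so TSV round trips are
# faithful well below 1e-12.

fmtNum <- function(x) signif(x, 15)

#' Write a participants x features matrix as TSV
#'
#' @param matrix numeric matrix with participant row names.
#' @param path output file.
#' @export
writeModalityMatrix <- function(matrix, path) {
  df <- data.frame(participant_id = rownames(matrix),
                   fmtNum(matrix), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a participants x features TSV written by [writeModalityMatrix()]
#'
#' @param path TSV file.
#' @return numeric matrix with participant row names.
#' @export
readModalityMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "participant_id")
    stop("malformed header in ", path, ": first column must be participant_id")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate participant id(s) in ", path, ": ",
         paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M))
    stop("non-numeric cell(s) in ", path)
  rownames(M) <- ids
  M
}

#' Write a covariate table as TSV
#' @param cohort data.frame with participant row names.
#' @param path output file.
#' @export
writeCohortTable <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a covariate table written by [writeCohortTable()]
#' @param path TSV file.
#' @export
readCohortTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = TRUE)
  if (!"participant_id" %in% colnames(df))
    stop("cohort table lacks a participant_id column")
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant id(s) in ", path)
  rownames(df) <- df$participant_id
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Write a parcellation as TSV (id, hemisphere, x, y, z, network)
#' @param parc a [Parcellation-class].
#' @param path output file.
#' @export
writeParcellation <- function(parc, path) {
  df <- data.frame(parcel_id = parcelIds(parc),
                   hemisphere = hemispheres(parc),
                   x = fmtNum(centroids(parc)[, 1]),
                   y = fmtNum(centroids(parc)[, 2]),
                   z = fmtNum(centroids(parc)[, 3]),
                   network = networks(parc))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a parcellation TSV written by [writeParcellation()]
#' @param path TSV file.
#' @param nNetworks total network count (default: max label present).
#' @export
readParcellation <- function(path, nNetworks = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  new("Parcellation",
      parcelId = as.character(df$parcel_id),
      hemisphere = df$hemisphere,
      centroid = as.matrix(df[, c("x", "y", "z")]),
      network = as.integer(df$network),
      nNetworks = as.integer(nNetworks %||% max(df$network)))
}

#' Read a dense symmetric FC matrix TSV
#'
#' Expects a square numeric table with parcel-id header and row ids;
#' asymmetric input is rejected with the maximal asymmetry reported.
#'
#' @param path TSV file.
#' @param tol symmetry tolerance (default 1e-8).
#' @export
readFCMatrix <- function(path, tol = 1e-8) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M))
    stop("FC matrix in ", path, " is not square")
  asym <- max(abs(M - t(M)))
  if (asym > tol)
    stop("FC matrix in ", path, " is asymmetric (max |M - t(M)| = ",
         format(asym), ")")
  M
}

#' Write a synthetic cohort to a directory
#'
#' Emits the covariates, behavior, each modality and held-out matrix, the
#' parcellation, and the ground truth (JSON), in the package's TSV/JSON
#' conventions.
#'
#' @param synth a [SynthCohort-class].
#' @param dir output directory (created if needed).
#' @export
writeSynthCohort <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCohortTable(synth@cohort, file.path(dir, "cohort.tsv"))
  writeModalityMatrix(synth@behavior, file.path(dir, "behavior.tsv"))
  for (m in names(synth@modalities))
    writeModalityMatrix(synth@modalities[[m]],
                        file.path(dir, paste0("modality_", m, ".tsv")))
  for (m in names(synth@heldout))
    writeModalityMatrix(synth@heldout[[m]],
                        file.path(dir, paste0("heldout_", m, ".tsv")))
  writeParcellation(synth@parcellation, file.path(dir, "parcellation.tsv"))
  gt <- synth@groundTruth
  jsonlite::write_json(
    list(itemLoadings = unname(apply(gt@itemLoadings, 2, as.numeric,
                                     simplify = FALSE)),
         structuralLoadings = lapply(gt@structuralLoadings, function(C)
           unname(apply(C, 2, as.numeric, simplify = FALSE))),
         factorScores = unname(apply(gt@factorScores, 2, as.numeric,
                                     simplify = FALSE)),
         seed = gt@seed),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
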