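# Plain-text exchange formats: dense labeled CSV matrices for distances and
# weights, tidy edge lists, and JSON manifests. No binary formats.

#' Read a distance matrix from CSV
#'
#' Expects a dense numeric matrix with area labels in the first row and first
#' column. Symmetry is checked to a relative tolerance of 1e-6 (on the scale
#' of the largest entry); passing matrices are then symmetrized exactly by
#' averaging with the transpose.
#'
#' @param path CSV file path.
#' @param units `"mm"` or `"adimensional"`.
#' @return a [distance_matrix()].
#' @export
read_distance_csv <- function(path, units = "mm") {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  if (max(abs(m - t(m))) > 1e-6 * max(abs(m)))
    stop("distance matrix in ", path, " is not symmetric (tolerance 1e-6 relative)")
  m <- (m + t(m)) / 2
  distance_matrix(m, labels = rownames(m), units = units)
}

#' Write a distance matrix to CSV
#' @param D distance matrix.
#' @param path output path.
#' @export
write_distance_csv <- function(D, path) {
  attr(D, "units") <- NULL
  utils::write.csv(as.data.frame(D), path)
  invisible(path)
}

#' Read a connectome from a dense weight-matrix CSV
#' @param path CSV file path (labels in first row/column, source rows, target
#'   columns).
#' @return a [connectome()].
#' @export
read_connectome_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  connectome(m, labels = rownames(m))
}

#' Write a connectome's weight matrix to CSV
#' @param G connectome.
#' @param path output path.
#' @export
write_connectome_csv <- function(G, path) {
  utils::write.csv(as.data.frame(G$W), path)
  invisible(path)
}

#' Write a connectome as a tidy edge list
#' @param G connectome.
#' @param path output path; columns `source`, `target`, `weight`.
#' @export
write_edgelist_csv <- function(G, path) {
  sel <- which(G$W > 0, arr.ind = TRUE)
  df <- data.frame(source = G$labels[sel[, 1]], target = G$labels[sel[, 2]],
                   weight = G$W[sel])
  df <- df[order(df$source, df$target), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a connectome from a tidy edge list
#' @param path CSV with columns `source`, `target`, `weight`.
#' @param labels optional full area set (to retain isolated areas).
#' @return a [connectome()].
#' @export
read_edgelist_csv <- function(path, labels = NULL) {
  df <- utils::read.csv(path)
  if (is.null(labels)) labels <- sort(unique(c(df$source, df$target)))
  W <- matrix(0, length(labels), length(labels), dimnames = list(labels, labels))
  W[cbind(match(df$source, labels), match(df$target, labels))] <- df$weight
  connectome(W, labels)
}

#' Write a run manifest as JSON
#'
#' Records parameters, seeds and package version so a run can be reproduced
#' exactly.
#'
#' @param params named list of parameters (must include any seeds used).
#' @param path output path.
#' @export
write_manifest <- function(params, path) {
  params$package <- "edrconnectome"
  params$version <- as.character(utils::packageVersion("edrconnectome"))
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize a synthetic species fixture to a directory
#'
#' Writes `coordinates.csv`, `distance.csv`, `connectome.csv`, `lengths.csv`
#' and a `manifest.json` holding the ground truth (all plain text).
#'
#' @param species a `synthetic_species`.
#' @param dir output directory (created if needed).
#' @export
write_species <- function(species, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(area = rownames(species$coords),
                              x = species$coords[, 1], y = species$coords[, 2]),
                   file.path(dir, "coordinates.csv"), row.names = FALSE)
  write_distance_csv(species$D, file.path(dir, "distance.csv"))
  write_connectome_csv(species$connectome, file.path(dir, "connectome.csv"))
  utils::write.csv(data.frame(length = species$axon_lengths),
                   file.path(dir, "lengths.csv"), row.names = FALSE)
  write_manifest(list(name = species$name, lambda = species$lambda,
                      gamma = species$gamma, density = species$density,
                      n_areas = nrow(species$coords), seed = species$seed,
                      synthetic = TRUE),
                 file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a synthetic species fixture back from a directory
#' @param dir directory written by [write_species()].
#' @return a `synthetic_species` (without regenerating randomness).
#' @export
read_species <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  co <- utils::read.csv(file.path(dir, "coordinates.csv"))
  pts <- as.matrix(co[, c("x", "y")])
  rownames(pts) <- co$area
  D <- read_distance_csv(file.path(dir, "distance.csv"))
  structure(list(
    name = man$name, coords = pts, D = D, lambda = man$lambda,
    gamma = man$gamma, density = man$density,
    connectome = read_connectome_csv(file.path(dir, "connectome.csv")),
    axon_lengths = utils::read.csv(file.path(dir, "lengths.csv"))$length,
    seed = man$seed
  ), class = "synthetic_species")
}
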