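## Plain-text file formats: activity matrices and hidden traces as CSV
## with a JSON sidecar of attributes, annotations and morphology as TSV,
## connectivity as CSV + JSON sidecar, run manifests as JSON. Every
## format carries a format_version key.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a binary spike matrix (CSV + JSON sidecar)
#'
#' The matrix is stored neuron-major (one row per neuron, one column per
#' frame) as headerless CSV; frame rate, dimensions and optional region
#' labels go into a JSON sidecar next to it.
#'
#' @param data a [crbm_data] object.
#' @param path CSV file path (sidecar written at the same path with
#'   extension `.json`).
#' @return `read_spike_matrix` returns a [crbm_data];
#'   `write_spike_matrix` returns `path` invisibly.
#' @export
write_spike_matrix <- function(data, path) {
  stopifnot(inherits(data, "crbm_data"))
  data.table::fwrite(data.table::as.data.table(data$v), path,
                     col.names = FALSE)
  jsonlite::write_json(list(format_version = 1L, frame_rate = data$frame_rate,
                            n_neurons = data$n_neurons, n_frames = data$n_frames,
                            regions = data$regions),
                       sidecar_path(path), digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_spike_matrix
#' @export
read_spike_matrix <- function(path) {
  v <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(v) <- NULL
  meta <- list(frame_rate = NULL, regions = NULL)
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$frame_rate)) {
    warning("no frame_rate recorded; defaulting to 1 Hz")
    meta$frame_rate <- 1
  }
  bad <- which(!(v %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(v))
    stop_dims("file %s is not binary: entry at row %d, column %d is %s",
              path, rc[1], rc[2], format(v[bad[1]]))
  }
  regions <- meta$regions
  if (!is.null(regions) && length(regions) == 0) regions <- NULL
  crbm_data(v, frame_rate = meta$frame_rate, regions = regions)
}

#' Write / read a region annotation (TSV)
#'
#' Long format: one row per (neuron, region) membership, columns
#' `neuron_id`, `region`.
#'
#' @param ann a [region_annotation()].
#' @param path TSV file path.
#' @param n_neurons total neuron count (needed on read because neurons
#'   without any region do not appear in the file); defaults to the
#'   largest mentioned id.
#' @return `read_region_annotation` returns a [region_annotation()].
#' @export
write_region_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "crbm_regions"))
  idx <- which(ann$membership == 1, arr.ind = TRUE)
  df <- data.frame(neuron_id = idx[, 2], region = ann$region_names[idx[, 1]])
  df <- df[order(df$neuron_id), ]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_region_annotation
#' @export
read_region_annotation <- function(path, n_neurons = NULL) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  n_neurons <- n_neurons %||% max(df$neuron_id)
  regions <- sort(unique(df$region))
  L <- matrix(0L, length(regions), n_neurons, dimnames = list(regions, NULL))
  L[cbind(match(df$region, regions), df$neuron_id)] <- 1L
  region_annotation(L, regions)
}

#' Write / read a morphology set (TSV pair)
#'
#' Neurite lengths in long format (`neuron_id`, `soma_region`, `region`,
#' `length`; zero-length entries omitted, soma region repeated per row)
#' plus a second TSV of region volumes (`region`, `volume`).
#'
#' @param m a [morphology_set()].
#' @param path neurite TSV path.
#' @param volumes_path volumes TSV path (default: `path` with
#'   `_volumes.tsv` suffix).
#' @return `read_morphology` returns a [morphology_set()].
#' @export
write_morphology <- function(m, path,
                             volumes_path = sub("\\.tsv$", "_volumes.tsv", path)) {
  stopifnot(inherits(m, "crbm_morphology"))
  idx <- which(m$neurite_length > 0, arr.ind = TRUE)
  df <- data.frame(neuron_id = idx[, 1],
                   soma_region = m$soma_region[idx[, 1]],
                   region = m$region_names[idx[, 2]],
                   length = m$neurite_length[idx])
  ## neurons with no neurites at all still need their soma on record
  missing <- setdiff(seq_along(m$soma_region), unique(df$neuron_id))
  if (length(missing))
    df <- rbind(df, data.frame(neuron_id = missing,
                               soma_region = m$soma_region[missing],
                               region = m$soma_region[missing], length = 0))
  df <- df[order(df$neuron_id), ]
  data.table::fwrite(df, path, sep = "\t")
  data.table::fwrite(data.frame(region = m$region_names,
                                volume = unname(m$volumes)),
                     volumes_path, sep = "\t")
  invisible(path)
}

#' @rdname write_morphology
#' @export
read_morphology <- function(path,
                            volumes_path = sub("\\.tsv$", "_volumes.tsv", path)) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  vol <- data.table::fread(volumes_path, sep = "\t", data.table = FALSE)
  regions <- vol$region
  n <- max(df$neuron_id)
  soma <- character(n)
  soma[df$neuron_id] <- df$soma_region
  L <- matrix(0, n, length(regions), dimnames = list(NULL, regions))
  nz <- df$length > 0
  L[cbind(df$neuron_id[nz], match(df$region[nz], regions))] <- df$length[nz]
  morphology_set(soma, L, vol$volume, regions)
}

#' Write / read a connectivity matrix (CSV + JSON sidecar)
#'
#' Values as CSV with label header row and first column; provenance,
#' level and mask count in a JSON sidecar.
#'
#' @param cm a [connectivity_matrix()].
#' @param path CSV path.
#' @return `read_connectivity` returns a [connectivity_matrix()].
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "crbm_connectivity"))
  df <- data.frame(label = cm$labels, cm$values, check.names = FALSE)
  data.table::fwrite(df, path)
  jsonlite::write_json(list(format_version = 1L, level = cm$level,
                            provenance = cm$provenance,
                            n_masked = sum(is.na(cm$values))),
                       sidecar_path(path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  labels <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- list(labels, labels)
  meta <- list(level = "region", provenance = "crbm_fast")
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  connectivity_matrix(vals, meta$level, labels, meta$provenance)
}

#' Write a run manifest
#'
#' JSON record of a pipeline invocation: inputs, configuration, seed and
#' package version; every CLI subcommand drops one next to its outputs so
#' artifacts are reproducible.
#'
#' @param dir output directory.
#' @param subcommand CLI subcommand name.
#' @param inputs named list/character of input paths.
#' @param config named list of settings.
#' @param seed the seed used.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, subcommand, inputs, config, seed) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(format_version = 1L, subcommand = subcommand,
                            inputs = inputs, config = config, seed = seed,
                            package_version = as.character(utils::packageVersion("crbm")),
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                       path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
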