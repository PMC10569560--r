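# Core containers: per-neuron spike/stimulus records, datasets, GLM
# parameter vectors, and the model shape (filter dimensions).

#' Filter dimensions of the single-cell GLM
#'
#' The single-cell model has a stimulus filter of length `T_stim` applied to a
#' box-prefiltered, downsampled stimulus (downsampling factor `d_stim`), a
#' spike-history (self-interaction) filter of length `T_self`, and an offset.
#' Defaults correspond to filtering 100 ms of stimulus and 40 ms of spiking
#' history at a 2 ms bin width.
#'
#' @param T_stim length of the stimulus filter (number of coefficients).
#' @param T_self length of the self-interaction filter.
#' @param d_stim stimulus downsampling factor: stimulus-filter taps are spaced
#'   `d_stim` bins apart and each tap sees the sum of `d_stim` raw bins.
#' @return an object of class `model_shape`.
#' @export
model_shape <- function(T_stim = 10L, T_self = 20L, d_stim = 5L) {
  T_stim <- as.integer(T_stim); T_self <- as.integer(T_self)
  d_stim <- as.integer(d_stim)
  stopifnot(T_stim >= 1L, T_self >= 1L, d_stim >= 1L)
  structure(list(T_stim = T_stim, T_self = T_self, d_stim = d_stim),
            class = "model_shape")
}

#' Number of GLM parameters for a model shape
#' @param shape a [model_shape()].
#' @return integer, `T_stim + T_self + 1`.
#' @export
n_params <- function(shape) shape$T_stim + shape$T_self + 1L

#' Single-cell GLM parameter vector
#'
#' Bundles the stimulus filter, self-interaction filter, and offset of one
#' neuron's Poisson GLM. The concatenation order used everywhere downstream is
#' `c(beta_stim, beta_self, beta0)`.
#'
#' @param beta_stim numeric stimulus filter.
#' @param beta_self numeric self-interaction filter.
#' @param beta0 scalar offset (log baseline rate per bin).
#' @return an object of class `glm_params`.
#' @export
glm_params <- function(beta_stim, beta_self, beta0) {
  beta_stim <- as.numeric(beta_stim); beta_self <- as.numeric(beta_self)
  beta0 <- as.numeric(beta0)
  stopifnot(length(beta0) == 1L)
  if (!all(is.finite(c(beta_stim, beta_self, beta0))))
    stop("glm_params: all entries must be finite")
  structure(list(beta_stim = beta_stim, beta_self = beta_self, beta0 = beta0),
            class = "glm_params")
}

#' @export
as.vector.glm_params <- function(x, mode = "any") {
  c(x$beta_stim, x$beta_self, x$beta0)
}

# Rebuild a glm_params from a flat vector laid out per a model_shape.
params_from_vector <- function(v, shape) {
  stopifnot(length(v) == n_params(shape))
  glm_params(v[seq_len(shape$T_stim)],
             v[shape$T_stim + seq_len(shape$T_self)],
             v[length(v)])
}

# Canonicalize partitions to an integer matrix with columns start, end
# (1-based, inclusive).
canon_partitions <- function(partitions, T_i) {
  if (is.null(partitions)) partitions <- list(c(1L, T_i))
  if (is.matrix(partitions)) {
    partitions <- lapply(seq_len(nrow(partitions)), function(r) partitions[r, ])
  }
  m <- do.call(rbind, lapply(partitions, function(p) as.integer(p[1:2])))
  colnames(m) <- c("start", "end")
  m
}

#' One neuron's recording
#'
#' @param neuron_id character id.
#' @param stimulus numeric vector of injected current per time bin.
#' @param spikes integer vector of spike counts per bin (same length).
#' @param partitions trial/CV boundaries: a list of `c(start, end)` 1-based
#'   inclusive index ranges, or a 2-column matrix. Must be ordered, disjoint,
#'   contiguous, and cover `1..T_i`. Default: one partition covering all bins.
#' @param metadata named character vector of categorical attributes (e.g.
#'   `c(cre_line = "Pvalb")`); may be empty.
#' @return an object of class `neuron_record`.
#' @export
neuron_record <- function(neuron_id, stimulus, spikes, partitions = NULL,
                          metadata = character()) {
  rec <- structure(
    list(neuron_id = as.character(neuron_id),
         stimulus = as.numeric(stimulus),
         spikes = as.numeric(spikes),
         partitions = canon_partitions(partitions, length(stimulus)),
         metadata = metadata),
    class = "neuron_record")
  validate_neuron(rec)
  rec
}

validate_neuron <- function(rec) {
  id <- rec$neuron_id
  T_i <- length(rec$stimulus)
  if (T_i < 1L)
    stop(sprintf("neuron '%s': empty stimulus", id))
  if (length(rec$spikes) != T_i)
    stop(sprintf("neuron '%s': stimulus (%d) and spikes (%d) lengths differ",
                 id, T_i, length(rec$spikes)))
  if (anyNA(rec$stimulus) || anyNA(rec$spikes))
    stop(sprintf("neuron '%s': missing values", id))
  if (any(rec$spikes < 0))
    stop(sprintf("neuron '%s': negative spike counts", id))
  if (any(rec$spikes != round(rec$spikes)))
    stop(sprintf("neuron '%s': non-integer spike counts", id))
  p <- rec$partitions
  if (nrow(p) < 1L)
    stop(sprintf("neuron '%s': needs at least one partition", id))
  if (p[1L, "start"] != 1L || p[nrow(p), "end"] != T_i ||
      any(p[, "end"] < p[, "start"]) ||
      (nrow(p) > 1L && any(p[-1L, "start"] != p[-nrow(p), "end"] + 1L)))
    stop(sprintf(
      "neuron '%s': partitions must be ordered, disjoint, contiguous and cover 1..%d",
      id, T_i))
  invisible(rec)
}

#' A dataset of spike-train recordings
#'
#' @param neurons list of [neuron_record()] objects with unique ids.
#' @param bin_width bin width in seconds (default 0.002, i.e. 2 ms bins).
#' @param name dataset label.
#' @return an object of class `spike_dataset`.
#' @export
spike_dataset <- function(neurons, bin_width = 0.002, name = "dataset") {
  ds <- structure(list(neurons = neurons, bin_width = as.numeric(bin_width),
                       name = as.character(name)),
                  class = "spike_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a spike dataset
#' @param ds a [spike_dataset()].
#' @return the dataset, invisibly; errors name the offending neuron.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "spike_dataset"), length(ds$neurons) >= 1L,
            ds$bin_width > 0)
  for (rec in ds$neurons) validate_neuron(rec)
  ids <- vapply(ds$neurons, function(r) r$neuron_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate neuron ids")
  invisible(ds)
}

#' @export
print.spike_dataset <- function(x, ...) {
  Ts <- vapply(x$neurons, function(r) length(r$spikes), numeric(1))
  cat(sprintf("<spike_dataset '%s'> %d neurons, bin width %g s, T = %s bins\n",
              x$name, length(x$neurons), x$bin_width,
              if (length(unique(Ts)) == 1L) format(Ts[1]) else
                paste0(min(Ts), "-", max(Ts))))
  invisible(x)
}

neuron_ids <- function(ds) vapply(ds$neurons, function(r) r$neuron_id,
                                  character(1))

# Subset a dataset by neuron index, preserving bin width and name.
subset_dataset <- function(ds, idx, name = ds$name) {
  spike_dataset(ds$neurons[idx], bin_width = ds$bin_width, name = name)
}

#' Write a dataset to a plain-text directory container
#'
#' Layout: `manifest.json` (name, bin width, neuron ordering), one
#' `arrays/<id>.tsv` per neuron with `stimulus` and `spikes` columns,
#' `partitions.tsv` (neuron_id, start, end), and long-format `metadata.tsv`
#' with header `neuron_id  attribute  value`. Reals are written with 17
#' significant digits so the round trip is lossless.
#'
#' @param ds a [spike_dataset()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  dir.create(file.path(path, "arrays"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("write_dataset: cannot create ", path)
  ids <- neuron_ids(ds)
  jsonlite::write_json(
    list(name = ds$name, bin_width = ds$bin_width, neuron_ids = ids),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  part_rows <- list(); meta_rows <- list()
  for (rec in ds$neurons) {
    con <- file(file.path(path, "arrays", paste0(rec$neuron_id, ".tsv")), "w")
    writeLines("stimulus\tspikes", con)
    writeLines(paste(sprintf("%.17g", rec$stimulus),
                     format(as.integer(rec$spikes)), sep = "\t"), con)
    close(con)
    part_rows[[rec$neuron_id]] <- data.frame(
      neuron_id = rec$neuron_id,
      start = rec$partitions[, "start"], end = rec$partitions[, "end"])
    if (length(rec$metadata))
      meta_rows[[rec$neuron_id]] <- data.frame(
        neuron_id = rec$neuron_id, attribute = names(rec$metadata),
        value = unname(rec$metadata))
  }
  utils::write.table(do.call(rbind, part_rows),
                     file.path(path, "partitions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- if (length(meta_rows)) do.call(rbind, meta_rows) else
    data.frame(neuron_id = character(), attribute = character(),
               value = character())
  utils::write.table(meta, file.path(path, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#' @param path directory containing the container.
#' @return a validated [spike_dataset()].
#' @export
read_dataset <- function(path) {
  man_path <- file.path(path, "manifest.json")
  if (!file.exists(man_path)) stop("read_dataset: no manifest.json in ", path)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  parts <- utils::read.table(file.path(path, "partitions.tsv"), sep = "\t",
                             header = TRUE, colClasses = c("character",
                                                           "integer",
                                                           "integer"))
  meta <- utils::read.table(file.path(path, "metadata.tsv"), sep = "\t",
                            header = TRUE,
                            colClasses = rep("character", 3L))
  neurons <- lapply(man$neuron_ids, function(id) {
    f <- file.path(path, "arrays", paste0(id, ".tsv"))
    if (!file.exists(f)) stop("read_dataset: missing array file for neuron '",
                              id, "'")
    arr <- utils::read.table(f, sep = "\t", header = TRUE,
                             colClasses = c("numeric", "numeric"))
    p <- parts[parts$neuron_id == id, , drop = FALSE]
    md <- meta[meta$neuron_id == id, , drop = FALSE]
    metadata <- stats::setNames(md$value, md$attribute)
    if (!length(metadata)) metadata <- character()
    neuron_record(id, arr$stimulus, arr$spikes,
                  partitions = cbind(p$start, p$end), metadata = metadata)
  })
  spike_dataset(neurons, bin_width = man$bin_width, name = man$name)
}

#' Split neurons into cross-validation folds
#'
#' Partitions the neurons into `n_folds` disjoint held-out sets of nearly
#' equal size (sizes differ by at most one), returning for each fold the
#' training and held-out datasets. Used to assess generalization to held-out
#' neurons.
#'
#' @param ds a [spike_dataset()].
#' @param n_folds number of folds (>= 2, <= number of neurons).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return list of `n_folds` elements, each `list(train =, heldout =)`.
#' @export
split_neuron_folds <- function(ds, n_folds, seed = 1L) {
  N <- length(ds$neurons)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n_folds > N) stop("n_folds exceeds the number of neurons")
  ord <- withr::with_seed(seed, sample.int(N))
  fold_of <- integer(N)
  fold_of[ord] <- rep_len(seq_len(n_folds), N)
  lapply(seq_len(n_folds), function(f) {
    list(train = subset_dataset(ds, which(fold_of != f),
                                name = paste0(ds$name, "/train", f)),
         heldout = subset_dataset(ds, which(fold_of == f),
                                  name = paste0(ds$name, "/heldout", f)))
  })
}
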