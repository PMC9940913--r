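## Binary spike matrix container.

#' Construct a binary spike matrix
#'
#' Wraps a neurons x frames binary activity matrix with its frame rate and
#' optional per-neuron anatomical region labels.
#'
#' @param v N x T matrix with entries in \{0, 1\} (neurons are rows,
#'   frames are columns).
#' @param frame_rate acquisition rate in Hz (frames per second).
#' @param regions optional character/factor vector of length N with one
#'   region label per neuron.
#' @return object of class `crbm_data`.
#' @export
crbm_data <- function(v, frame_rate = 1, regions = NULL) {
  v <- as.matrix(v)
  bad <- which(!(v %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(v))
    stop_dims("activity matrix must be binary; first offending entry at neuron %d, frame %d (value %s)",
              rc[1], rc[2], format(v[bad[1]]))
  }
  if (any(!is.finite(v))) stop_dims("activity matrix must be finite")
  if (!is.null(regions) && length(regions) != nrow(v))
    stop_dims("regions has length %d, expected one label per neuron (%d)",
              length(regions), nrow(v))
  structure(list(v = v, frame_rate = as.numeric(frame_rate),
                 regions = if (is.null(regions)) NULL else as.character(regions),
                 n_neurons = nrow(v), n_frames = ncol(v)),
            class = "crbm_data")
}

#' @export
print.crbm_data <- function(x, ...) {
  cat(sprintf("binary spike matrix: %d neurons x %d frames at %g Hz (mean activity %.4f)\n",
              x$n_neurons, x$n_frames, x$frame_rate, mean(x$v)))
  if (!is.null(x$regions))
    cat(sprintf("  %d region labels (%d distinct)\n",
                length(x$regions), length(unique(x$regions))))
  invisible(x)
}
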