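#' Construct a ConcentrationTrajectory
#'
#' @param times sample times (strictly increasing, length T+1).
#' @param counts (T+1) x m matrix of non-negative integer species counts,
#'   columns named by species label.
#' @return a [ConcentrationTrajectory-class] object.
#' @export
ConcentrationTrajectory <- function(times, counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("ConcentrationTrajectory", times = as.numeric(times), counts = counts)
}

#' @rdname accessors
#' @export
setMethod("countsMatrix", "ConcentrationTrajectory",
          function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("sampleTimes", "ConcentrationTrajectory",
          function(object) object@times)

#' @rdname accessors
#' @export
setMethod("speciesLabels", "ConcentrationTrajectory",
          function(object) colnames(object@counts))

#' @describeIn ConcentrationTrajectory-class compact summary
#' @param object a ConcentrationTrajectory
#' @export
setMethod("show", "ConcentrationTrajectory", function(object) {
  cat("ConcentrationTrajectory:", nrow(object@counts), "frames x",
      ncol(object@counts), "species, t in [",
      min(object@times), ",", max(object@times), "]\n")
  invisible(object)
})

#' Construct a ReactionCountSeries
#'
#' @param counts T x r matrix of non-negative integer firing counts;
#'   row t holds n_j(t, t+dt) for every reaction j.
#' @return a [ReactionCountSeries-class] object.
#' @export
ReactionCountSeries <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("ReactionCountSeries", counts = counts)
}

#' @rdname accessors
#' @export
setMethod("countsMatrix", "ReactionCountSeries",
          function(object) object@counts)

#' @describeIn ReactionCountSeries-class compact summary
#' @param object a ReactionCountSeries
#' @export
setMethod("show", "ReactionCountSeries", function(object) {
  cat("ReactionCountSeries:", nrow(object@counts), "intervals x",
      ncol(object@counts), "reactions,", sum(object@counts),
      "events total\n")
  invisible(object)
})

#' Construct a BondTrajectory
#'
#' @param elements per-atom element symbols.
#' @param frames list of edge matrices (k x 2 integer, 1-based atom
#'   indices) or of zero-row matrices for bond-free frames.
#' @param frameDt time between frames.
#' @return a [BondTrajectory-class] object.
#' @export
BondTrajectory <- function(elements, frames, frameDt = 1) {
  frames <- lapply(frames, function(f) {
    f <- if (length(f) == 0L) matrix(integer(), ncol = 2L) else as.matrix(f)
    storage.mode(f) <- "integer"
    # canonical edge order: smaller index first, rows sorted
    if (nrow(f)) {
      swap <- f[, 1L] > f[, 2L]
      f[swap, ] <- f[swap, c(2L, 1L)]
      f <- f[order(f[, 1L], f[, 2L]), , drop = FALSE]
    }
    dimnames(f) <- NULL
    f
  })
  new("BondTrajectory", nAtoms = length(elements),
      elements = as.character(elements), frames = frames,
      frameDt = as.numeric(frameDt))
}

#' @describeIn BondTrajectory-class compact summary
#' @param object a BondTrajectory
#' @export
setMethod("show", "BondTrajectory", function(object) {
  cat("BondTrajectory:", object@nAtoms, "atoms (",
      paste(names(table(object@elements)), table(object@elements),
            collapse = " "),
      "),", length(object@frames), "frames, frameDt =", object@frameDt,
      "\n")
  invisible(object)
})
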