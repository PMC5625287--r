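namedList <- function(x) {
  if (length(x) == 0L) return(structure(list(), names = character()))
  as.list(x)
}

networkToList <- function(network) {
  list(
    species = lapply(network@species, function(s) list(
      label = s@label,
      element_counts = namedList(s@elementCounts),
      bond_counts = namedList(s@bondCounts))),
    reactions = lapply(network@reactions, function(rx) list(
      reactants = namedList(rx@reactants),
      products = namedList(rx@products),
      rate_k = rx@rateK,
      observed_count_total = rx@observedCountTotal)),
    dt = network@dt)
}

networkFromList <- function(x) {
  sp <- lapply(x$species, function(s)
    Species(unlist(s$element_counts), unlist(s$bond_counts)))
  rx <- lapply(x$reactions, function(r) {
    Reaction(unlist(r$reactants), unlist(r$products),
             rateK = r$rate_k, observedCountTotal = r$observed_count_total)
  })
  ReactionNetwork(sp, rx, dt = x$dt)
}

#' Read and write reaction networks as JSON
#'
#' The on-disk document has fields `species` (list of label /
#' element_counts / bond_counts records), `reactions` (reactant and
#' product multisets keyed by species label, `rate_k`,
#' `observed_count_total`) and `dt`. The writer is deterministic, so
#' write -> read -> write round-trips are byte-identical.
#'
#' @param network a [ReactionNetwork-class] object.
#' @param path file path.
#' @return `readNetworkJSON` returns a [ReactionNetwork-class];
#'   `writeNetworkJSON` returns `path` invisibly.
#' @export
writeNetworkJSON <- function(network, path) {
  jsonlite::write_json(networkToList(network), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNetworkJSON
#' @export
readNetworkJSON <- function(path) {
  networkFromList(jsonlite::read_json(path))
}

#' Flat CSV export of a network's reactions
#'
#' One reaction per row: textual equation, order, rate coefficient and
#' total observed count.
#'
#' @param network a [ReactionNetwork-class] object.
#' @param path file path.
#' @return the exported data.frame, invisibly.
#' @export
exportNetworkCSV <- function(network, path) {
  df <- data.frame(
    reaction = reactionLabels(network),
    order = vapply(network@reactions, reactionOrder, numeric(1)),
    rate_k = rates(network),
    observed_count_total = observedCounts(network),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Rate-table CSV export
#'
#' Per reaction: equation, order, estimated rate, total observed count and
#' the number of informative intervals (frames at which the reaction was
#' combinatorially possible), the confidence proxy for the estimate.
#'
#' @param network a [ReactionNetwork-class] carrying estimated rates.
#' @param informative integer vector of informative-interval counts, as
#'   returned by [estimateRates()].
#' @param path file path.
#' @return the exported data.frame, invisibly.
#' @export
exportRateTableCSV <- function(network, informative, path) {
  df <- data.frame(
    reaction = reactionLabels(network),
    order = vapply(network@reactions, reactionOrder, numeric(1)),
    k_est = rates(network),
    total_count = observedCounts(network),
    informative_intervals = informative,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read and write concentration trajectories as CSV
#'
#' A `time` column followed by one column per species label.
#'
#' @param traj a [ConcentrationTrajectory-class] object.
#' @param path file path.
#' @return `readTrajectoryCSV` returns a [ConcentrationTrajectory-class];
#'   the writer returns `path` invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  df <- data.frame(time = traj@times, check.names = FALSE)
  df <- cbind(df, as.data.frame(traj@counts, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ConcentrationTrajectory(df$time,
                          as.matrix(df[, -1L, drop = FALSE]))
}

#' Write per-interval reaction counts as CSV
#'
#' An `interval` column (0-based interval index) plus one column per
#' reaction index.
#'
#' @param counts a [ReactionCountSeries-class] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeCountsCSV <- function(counts, path) {
  M <- counts@counts
  colnames(M) <- paste0("reaction_", seq_len(ncol(M)))
  df <- cbind(data.frame(interval = seq_len(nrow(M)) - 1L), M)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-frame XYZ coordinate trajectory
#'
#' Plain or extended XYZ: repeated blocks of an atom count line, a comment
#' line, and one `element x y z ...` line per atom. Extra per-atom columns
#' are ignored. All frames must contain the same atoms in the same order.
#'
#' @param path file path.
#' @return list with `elements` (per-atom symbols) and `frames` (list of
#'   n x 3 coordinate matrices).
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  # trailing blanks are padding; interior blank lines can be XYZ comments
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  i <- 1L
  frames <- list()
  elements <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    if (i + 1L + n > length(lines))
      stop("malformed XYZ: truncated frame starting at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    els <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (is.null(elements)) elements <- els
    else if (!identical(elements, els))
      stop("inconsistent atoms across XYZ frames (frame ",
           length(frames) + 1L, ")")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  list(elements = elements, frames = frames)
}

#' Read and write bond-list trajectory files
#'
#' Text format: an optional comment header `# elements: C H H ...`
#' followed by one line per frame, `frame_index i j [i j ...]` with
#' 0-based atom indices.
#'
#' @param bondTraj a [BondTrajectory-class] object.
#' @param path file path.
#' @param elements per-atom element symbols; if NULL the reader requires
#'   the `# elements:` header.
#' @param frameDt time between frames for the returned object.
#' @return `readBondList` returns a [BondTrajectory-class]; the writer
#'   returns `path` invisibly.
#' @export
writeBondList <- function(bondTraj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# elements:",
                   paste(bondTraj@elements, collapse = " ")), con)
  for (f in seq_along(bondTraj@frames)) {
    e <- bondTraj@frames[[f]]
    line <- paste(c(f - 1L, as.integer(t(e - 1L))), collapse = " ")
    writeLines(line, con)
  }
  invisible(path)
}

#' @rdname writeBondList
#' @export
readBondList <- function(path, elements = NULL, frameDt = 1) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^#\\s*elements:\\s*(.+)$", h))[[1]]
    if (length(m) == 2L) elements <- strsplit(trimws(m[2]), "\\s+")[[1]]
  }
  if (is.null(elements))
    stop("per-atom elements required (argument or '# elements:' header)")
  lines <- lines[!hdr & nzchar(trimws(lines))]
  frames <- lapply(lines, function(ln) {
    v <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])[-1L]
    if (length(v) %% 2L != 0L)
      stop("malformed bond-list line (odd number of atom indices)")
    matrix(v + 1L, ncol = 2L, byrow = TRUE)
  })
  idx <- vapply(lines, function(ln)
    as.integer(strsplit(trimws(ln), "\\s+")[[1]][1]), integer(1))
  frames <- frames[order(idx)]
  BondTrajectory(elements, frames, frameDt = frameDt)
}

PIPELINE_KEYS <- list(
  cutoffs = "list", tau_frames = "numeric", frame_dt = "numeric",
  method = "character", lambda = "numeric", min_count = "numeric",
  epsilon = "numeric", replicates = "numeric", seed = "numeric",
  burn_in = "numeric", output_dir = "character")

#' Read and validate a pipeline configuration file
#'
#' YAML document holding the user-facing parameters of the pipeline:
#' `cutoffs` (map of element-pair keys like `C-H` to bond-length cutoffs,
#' length units of the coordinates), `tau_frames` (bond duration criterion
#' in frames), `frame_dt` (time between frames), `method`
#' (`count`/`iqp`/`lasso` or `none`), `lambda`, `min_count`, `epsilon`,
#' `replicates`, `seed`, `burn_in`, `output_dir`. Unknown keys are
#' rejected; missing optional keys take package defaults.
#'
#' @param path YAML file path.
#' @return a named list of validated configuration values.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(PIPELINE_KEYS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(method = "none", lambda = NA_real_, min_count = 1,
                   epsilon = 0.01, replicates = 20, seed = 1, burn_in = 0,
                   output_dir = ".")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (req in c("tau_frames", "frame_dt"))
    if (is.null(cfg[[req]]))
      stop("missing required configuration key: ", req)
  for (k in names(cfg)) {
    want <- PIPELINE_KEYS[[k]]
    ok <- switch(want, numeric = is.numeric(cfg[[k]]) || all(is.na(cfg[[k]])),
                 character = is.character(cfg[[k]]),
                 list = is.list(cfg[[k]]))
    if (!isTRUE(ok))
      stop("configuration key '", k, "' must be of type ", want)
  }
  if (cfg$tau_frames < 1) stop("tau_frames must be >= 1")
  if (cfg$frame_dt <= 0) stop("frame_dt must be positive")
  cfg
}
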