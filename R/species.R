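# Element priority used everywhere labels are rendered or pairs ordered:
# carbon first, hydrogen second, all other elements alphabetical after.
elementRank <- function(els) {
  base <- c(C = 1L, H = 2L)
  r <- base[els]
  other <- is.na(r)
  if (any(other)) {
    ord <- sort(unique(els[other]))
    r[other] <- 2L + match(els[other], ord)
  }
  unname(r)
}

# en dash as printed between bonded elements in species labels
BOND_DASH <- "\u2013"

#' Canonical pair key for an unordered element pair
#'
#' Machine-facing key: elements in ascending priority order joined by an
#' ASCII hyphen ("C-H", "H-H"). Used for `bondCounts` names and cutoff
#' table keys; the display form inside species labels is the reverse
#' order with an en dash ("H{endash}C").
#'
#' @param a,b element symbols (vectorized).
#' @return character vector of canonical pair keys.
#' @export
bondPairKey <- function(a, b) {
  swap <- elementRank(a) > elementRank(b)
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste0(lo, "-", hi)
}

#' Canonical species label from element and bond-type counts
#'
#' Renders the text identity of a species: elements in fixed priority
#' order (C, H, then others alphabetically) as `<El><count>`, followed by
#' one term per nonzero bond type, `<n>(<El2>{endash}<El1>)`, with bond
#' types ordered by their ascending pair key and the two elements printed
#' in descending priority order (so a C/H bond renders as `H{endash}C`).
#' Single atoms have no bond part.
#'
#' @param elementCounts named vector, element symbol -> positive count.
#' @param bondCounts named vector keyed by canonical pair key
#'   (see [bondPairKey()]) -> non-negative count; zero entries are dropped.
#' @return a single character label, e.g. `"C1 H4 4(H–C)"`.
#' @examples
#' canonicalLabel(c(C = 1, H = 4), c("C-H" = 4))
#' canonicalLabel(c(H = 1), integer())
#' @export
canonicalLabel <- function(elementCounts, bondCounts = integer()) {
  if (any(elementCounts < 0) || (length(bondCounts) && any(bondCounts < 0)))
    stop("counts must be non-negative")
  if (length(elementCounts) == 0L || sum(elementCounts) < 1L)
    stop("empty molecule: at least one atom is required")
  elementCounts <- elementCounts[elementCounts > 0]
  els <- names(elementCounts)
  ord <- order(elementRank(els))
  atomPart <- paste0(els[ord], elementCounts[ord], collapse = " ")
  if (length(bondCounts)) bondCounts <- bondCounts[bondCounts > 0]
  if (length(bondCounts) == 0L) return(atomPart)
  pairs <- strsplit(names(bondCounts), "-", fixed = TRUE)
  lo <- vapply(pairs, `[`, character(1), 1L)
  hi <- vapply(pairs, `[`, character(1), 2L)
  ord <- order(elementRank(lo), elementRank(hi), lo, hi)
  bondPart <- paste0(bondCounts[ord], "(", hi[ord], BOND_DASH, lo[ord], ")",
                     collapse = " ")
  paste(atomPart, bondPart)
}

#' Construct a Species
#'
#' @param elementCounts named vector of positive atom counts per element.
#' @param bondCounts named vector of bond counts keyed by canonical pair
#'   key (`"C-H"` style); defaults to no bonds.
#' @return a [Species-class] object.
#' @examples
#' Species(c(C = 1, H = 4), c("C-H" = 4))
#' @export
Species <- function(elementCounts, bondCounts = integer()) {
  ec <- as.integer(elementCounts)
  names(ec) <- names(elementCounts)
  ec <- ec[ec > 0L]
  bc <- as.integer(bondCounts)
  names(bc) <- names(bondCounts)
  if (length(bc)) bc <- bc[bc > 0L]
  ec <- ec[order(elementRank(names(ec)))]
  if (length(bc)) {
    pr <- strsplit(names(bc), "-", fixed = TRUE)
    lo <- vapply(pr, `[`, character(1), 1L)
    hi <- vapply(pr, `[`, character(1), 2L)
    bc <- bc[order(elementRank(lo), elementRank(hi), lo, hi)]
  }
  new("Species", elementCounts = ec, bondCounts = bc,
      label = canonicalLabel(ec, bc))
}

#' @describeIn Species-class display the canonical label
#' @param object a Species
#' @export
setMethod("show", "Species", function(object) {
  cat("Species:", object@label, "\n")
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("speciesLabels", "Species", function(object) object@label)
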