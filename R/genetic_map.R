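#' Construct a genetic map
#'
#' A genetic map holds the genome model: each locus is assigned to a
#' chromosome (linkage group) and has a genetic position in Morgan. The map
#' is the single source of the pairwise recombination-frequency matrix used
#' by all variance predictors and by the forward simulator.
#'
#' @param locus_id Character vector of unique locus identifiers.
#' @param chrom Vector of chromosome (linkage group) labels, one per locus.
#' @param pos Numeric vector of genetic positions, non-negative and finite.
#' @param unit Unit of `pos`: `"M"` (Morgan, default) or `"cM"`
#'   (centiMorgan, converted to Morgan internally).
#'
#' @return An object of class `genetic_map`: a data.frame with columns
#'   `locus_id`, `chrom` and `pos` (Morgan), sorted by (chromosome,
#'   position).
#' @export
genetic_map <- function(locus_id, chrom, pos, unit = c("M", "cM")) {
  unit <- match.arg(unit)
  locus_id <- as.character(locus_id)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(locus_id) == 0L)
    stop("genetic map must contain at least one locus")
  if (length(chrom) != length(locus_id) || length(pos) != length(locus_id))
    stop("locus_id, chrom and pos must have equal length")
  if (anyDuplicated(locus_id))
    stop("locus_ids must be unique")
  if (any(!is.finite(pos)) || any(pos < 0))
    stop("map positions must be finite and non-negative")
  if (unit == "cM") pos <- pos / 100
  map <- data.frame(locus_id = locus_id, chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$pos, map$locus_id), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d loci on %d chromosome(s), %.3f M total\n",
              nrow(x), length(unique(x$chrom)),
              sum(tapply(x$pos, x$chrom, function(p) diff(range(p))))))
  invisible(x)
}

#' Haldane's mapping function
#'
#' Converts a genetic distance in Morgan to a recombination frequency under
#' the assumption of no crossover interference (Poisson-distributed
#' crossovers): c = (1 - exp(-2 d)) / 2.
#'
#' @param d Numeric vector of map distances in Morgan, non-negative.
#' @return Recombination frequencies in `[0, 0.5)`, approaching 0.5 for
#'   unlinked loci.
#' @export
haldane_c <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("map distance must be finite and non-negative")
  (1 - exp(-2 * d)) / 2
}

#' Kosambi's mapping function
#'
#' Alternative mapping function accounting for positive interference:
#' c = tanh(2 d) / 2. Provided as a pluggable alternative; all published
#' checks in this package use Haldane's function.
#'
#' @inheritParams haldane_c
#' @return Recombination frequencies in `[0, 0.5)`.
#' @export
kosambi_c <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("map distance must be finite and non-negative")
  tanh(2 * d) / 2
}

#' Pairwise recombination-frequency matrix
#'
#' Builds the p x p symmetric matrix of recombination frequencies c_jl
#' between all pairs of loci of a map: entries are
#' `mapping_function(|pos_j - pos_l|)` for loci on the same chromosome and
#' exactly 0.5 for loci on different chromosomes (unlinked). The diagonal
#' is 0.
#'
#' @param map A [genetic_map].
#' @param mapping_function Function converting Morgan distance to
#'   recombination frequency; default [haldane_c].
#' @return A p x p numeric matrix with dimnames set to the locus ids.
#' @export
recombination_matrix <- function(map, mapping_function = haldane_c) {
  stopifnot(inherits(map, "genetic_map"))
  p <- nrow(map)
  cmat <- matrix(0.5, p, p, dimnames = list(map$locus_id, map$locus_id))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    d <- abs(outer(map$pos[idx], map$pos[idx], "-"))
    cmat[idx, idx] <- mapping_function(d)
  }
  diag(cmat) <- 0
  cmat
}
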