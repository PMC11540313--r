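#' Gametic Mendelian sampling variance from DH and F1 variances
#'
#' The average gametic MSV of individuals of a group is recovered from the
#' variance of DH lines the group would produce and the genetic variance
#' among the group's F1 members: MSV = (dh_var - f1_var) / 4.
#'
#' @param dh_var Variance of DH lines from the group's founders.
#' @param f1_var Genetic variance among the group's F1 individuals.
#' @param tol Relative tolerance before a negative result is treated as an
#'   inconsistency between the two inputs.
#' @return The average gametic MSV, non-negative.
#' @export
msv_from_dh <- function(dh_var, f1_var, tol = 1e-9) {
  if (any(dh_var < -tol) || any(f1_var < -tol))
    stop("variances must be non-negative")
  msv <- (dh_var - f1_var) / 4
  if (any(msv < -tol * pmax(1, abs(dh_var))))
    stop("inconsistent inputs: DH variance smaller than F1 variance")
  pmax(msv, 0)
}

#' Per-generation variance cascade of a balanced crossing plan
#'
#' Walks the balanced binary bracket of an N-way cross (N = 2^L founder
#' haplotypes) and computes, for every group at every generation and every
#' trait: the variance of DH lines derivable from the group's founders
#' (haplotype-based predictor), the genetic variance among the group's F1
#' individuals, and the average gametic MSV of a group member.
#'
#' Generation-1 groups cross two fully inbred haplotypes, so all their F1s
#' share one genotype and the F1 variance is 0. For every later group the
#' F1 variance follows the transmission recursion
#' `f1 = f1_left/4 + f1_right/4 + msv_left + msv_right`,
#' and the gametic MSV is `(dh - f1)/4`. The terminal DH family variance
#' equals `f1 + 4 * msv` of the top group, which is also its directly
#' predicted DH variance.
#'
#' @param panel A [founder_panel] with N = 2^L slots.
#' @param cmat Optional recombination matrix (defaults to the Haldane
#'   matrix of the panel's map).
#' @param beta Numeric p-vector of effects, or a p x T matrix with one
#'   column per trait (column names become trait ids).
#' @return A data.frame of class `variance_cascade` with columns
#'   `generation`, `group`, `trait`, `dh_variance`, `f1_variance`,
#'   `gametic_msv`, one row per (group, trait).
#' @export
build_cascade <- function(panel, cmat = NULL, beta) {
  stopifnot(inherits(panel, "founder_panel"))
  if (is.null(cmat)) {
    if (is.null(panel$map))
      stop("no recombination matrix supplied and the panel carries no map")
    cmat <- recombination_matrix(panel$map)
  }
  beta <- as.matrix(beta)
  if (nrow(beta) != nrow(panel$haplotypes))
    stop("effects length does not match the panel's loci")
  if (is.null(colnames(beta)))
    colnames(beta) <- if (ncol(beta) == 1) "trait1" else
      paste0("trait", seq_len(ncol(beta)))
  N <- ncol(panel$haplotypes)
  labels <- colnames(panel$haplotypes)
  rows <- list()

  walk <- function(slots) {
    n <- length(slots)
    gen <- log2(n)
    sub <- founder_panel(panel$haplotypes[, slots, drop = FALSE])
    sig <- sigma_dh(sub, cmat)
    dh <- apply(beta, 2, function(b) dh_variance(sig, b))
    if (n == 2) {
      f1 <- rep(0, ncol(beta))
    } else {
      half <- n / 2
      left <- walk(slots[seq_len(half)])
      right <- walk(slots[half + seq_len(half)])
      f1 <- left$f1 / 4 + right$f1 / 4 + left$msv + right$msv
    }
    msv <- msv_from_dh(dh, f1)
    lab <- paste(paste(labels[slots[seq_len(n / 2)]], collapse = ""),
                 paste(labels[slots[n / 2 + seq_len(n / 2)]], collapse = ""),
                 sep = "x")
    rows[[length(rows) + 1L]] <<- data.frame(
      generation = gen, group = lab, trait = colnames(beta),
      dh_variance = unname(dh), f1_variance = unname(f1),
      gametic_msv = unname(msv), stringsAsFactors = FALSE)
    list(f1 = f1, msv = msv)
  }
  walk(seq_len(N))
  out <- do.call(rbind, rows)
  out <- out[order(out$generation, out$group, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variance_cascade", "data.frame")
  out
}

#' Terminal DH-family variance of a cascade
#'
#' Variance among DH lines produced from gametes of the top (X-way F1)
#' group: `f1_variance + 4 * gametic_msv` of the highest generation, per
#' trait. Identical to the top group's `dh_variance`.
#'
#' @param cascade A cascade from [build_cascade].
#' @return Named numeric vector, one entry per trait.
#' @export
terminal_dh_variance <- function(cascade) {
  stopifnot(inherits(cascade, "variance_cascade"))
  top <- cascade[cascade$generation == max(cascade$generation), , drop = FALSE]
  stats::setNames(top$f1_variance + 4 * top$gametic_msv, top$trait)
}
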