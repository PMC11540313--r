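#' Construct a founder panel
#'
#' A founder panel is an ordered set of N phased, fully inbred founder
#' haplotypes over the loci of a genetic map, with N a power of two. The
#' slot order defines the balanced crossing bracket: slots 1 and 2 are
#' crossed in generation 1, slots 3 and 4 likewise, the resulting groups
#' are crossed in generation 2, and so on. Duplicate haplotypes are
#' permitted (a duplicated slot acts like a backcross to that line).
#'
#' @param haplotypes A p x N matrix of 0/1 allele indicators, one column
#'   per founder haplotype, rows in the locus order of `map`.
#' @param map A [genetic_map] with p loci, or `NULL` when the panel is used
#'   only with a pre-built recombination matrix.
#' @return An object of class `founder_panel`.
#' @export
founder_panel <- function(haplotypes, map = NULL) {
  haplotypes <- as.matrix(haplotypes)
  N <- ncol(haplotypes)
  if (N < 2 || bitwAnd(N, N - 1L) != 0)
    stop("number of founder haplotypes must be a power of 2 (>= 2)")
  if (!all(haplotypes %in% c(0, 1)))
    stop("haplotypes must be coded 0/1")
  if (!is.null(map)) {
    stopifnot(inherits(map, "genetic_map"))
    if (nrow(haplotypes) != nrow(map))
      stop("haplotype length does not match the map's locus count")
    rownames(haplotypes) <- map$locus_id
  }
  if (is.null(colnames(haplotypes)))
    colnames(haplotypes) <- slot_labels(N)
  structure(list(haplotypes = haplotypes, map = map),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("founder_panel: %d haplotypes x %d loci (%d-way cross, %d generations)\n",
              ncol(x$haplotypes), nrow(x$haplotypes),
              ncol(x$haplotypes), log2(ncol(x$haplotypes))))
  invisible(x)
}

slot_labels <- function(N) {
  if (N <= 26) LETTERS[seq_len(N)] else sprintf("H%02d", seq_len(N))
}

#' Expand individuals into a power-of-two founder panel
#'
#' Fills the 2^ceiling(log2(n)) bracket slots from a smaller set of
#' founders by duplication: a fully inbred line occupies two sibling slots
#' (crossing it with itself reproduces the line), and an outbred individual
#' contributes its paternal and maternal haplotypes to sibling slots.
#'
#' @param haplotypes p x n matrix of candidate haplotypes (columns).
#' @param inbred Logical vector of length n (or scalar): `TRUE` marks a
#'   column as a fully inbred line to be duplicated into both slots of its
#'   pair; consecutive `FALSE` columns are taken as the paternal/maternal
#'   haplotypes of one outbred individual and placed in sibling slots.
#' @param map Optional [genetic_map] passed to [founder_panel].
#' @return A [founder_panel] whose slot count is the next power of two.
#' @export
expand_to_panel <- function(haplotypes, inbred = TRUE, map = NULL) {
  haplotypes <- as.matrix(haplotypes)
  n <- ncol(haplotypes)
  inbred <- rep_len(inbred, n)
  cols <- list()
  i <- 1L
  while (i <= n) {
    if (inbred[i]) {
      cols <- c(cols, list(haplotypes[, i], haplotypes[, i]))
      i <- i + 1L
    } else {
      if (i + 1L > n || inbred[i + 1L])
        stop("outbred individuals must contribute two consecutive haplotype columns")
      cols <- c(cols, list(haplotypes[, i], haplotypes[, i + 1L]))
      i <- i + 2L
    }
  }
  H <- do.call(cbind, cols)
  N <- 2^ceiling(log2(ncol(H)))
  while (ncol(H) < N) # pad by re-using the last pair (backcross semantics)
    H <- cbind(H, H[, ncol(H) - 1L], H[, ncol(H)])
  founder_panel(H, map)
}

#' Meiosis count between two founder slots
#'
#' Number of meiotic events between the generation in which alleles from
#' founder slots i and k can first be combined in one genome and the
#' gametes that found the DH lines of an N-way cross. With 0-based slot
#' indices this is `log2(N) - floor(log2(xor(i, k)))`; slots are passed
#' 1-based here (R convention).
#'
#' @param i,k Integer slot indices (1-based), `i < k`, vectorised.
#' @param N Panel size, a power of two.
#' @return Integer vector of meiosis counts, between 1 and log2(N).
#' @export
meiosis_count <- function(i, k, N) {
  if (N < 2 || bitwAnd(as.integer(N), as.integer(N) - 1L) != 0)
    stop("N must be a power of 2")
  if (any(i < 1) || any(k > N) || any(i >= k))
    stop("slot indices must satisfy 1 <= i < k <= N")
  x <- bitwXor(as.integer(i) - 1L, as.integer(k) - 1L)
  as.integer(log2(N)) - floor(log2(x))
}

#' Progeny genotypic covariance matrix of an N-way DH family
#'
#' Builds the p x p matrix Sigma whose quadratic form with the
#' allele-substitution effects gives the additive genetic variance among DH
#' lines descending from the panel's balanced bracket:
#' Sigma = (4/N)^2 * sum over slot pairs i<k of
#' (1 - 2c)^(m_ik) (elementwise) Hadamard D^(ik),
#' where c is the recombination-frequency matrix, m_ik the meiosis count of
#' the pair, and D^(ik) the disequilibrium matrix of the two haplotypes.
#' Pairs sharing the same meiosis count are accumulated before the
#' elementwise decay multiplication; the result is identical to the naive
#' pair-by-pair sum.
#'
#' @param panel A [founder_panel].
#' @param cmat Recombination matrix from [recombination_matrix] over the
#'   same loci (defaults to the Haldane matrix of the panel's map).
#' @return A p x p symmetric positive semidefinite matrix.
#' @export
sigma_dh <- function(panel, cmat = NULL) {
  stopifnot(inherits(panel, "founder_panel"))
  if (is.null(cmat)) {
    if (is.null(panel$map))
      stop("no recombination matrix supplied and the panel carries no map")
    cmat <- recombination_matrix(panel$map)
  }
  H <- panel$haplotypes
  p <- nrow(H)
  N <- ncol(H)
  if (!is.matrix(cmat) || nrow(cmat) != p || ncol(cmat) != p)
    stop("recombination matrix dimensions do not match the panel's loci")
  pair <- which(upper.tri(diag(N)), arr.ind = TRUE)
  m <- meiosis_count(pair[, 1], pair[, 2], N)
  decay <- 1 - 2 * cmat
  Sigma <- matrix(0, p, p)
  for (mm in sort(unique(m))) {
    sel <- m == mm
    Delta <- H[, pair[sel, 1], drop = FALSE] - H[, pair[sel, 2], drop = FALSE]
    # sum of outer(delta, delta) = 4 * sum of D matrices for this m
    Sigma <- Sigma + decay^mm * tcrossprod(Delta)
  }
  Sigma <- Sigma * (4 / N)^2 / 4
  dimnames(Sigma) <- dimnames(cmat)
  Sigma
}

#' Variance, covariance and correlation of traits among DH progeny
#'
#' `dh_variance` evaluates the quadratic form beta' Sigma beta, the
#' additive genetic variance of one trait among the DH lines;
#' `dh_covariance` evaluates beta1' Sigma beta2, the genetic covariance of
#' two traits among the DH lines; `dh_correlation` standardises the
#' covariance by the two variances.
#'
#' @param sigma Progeny covariance matrix from [sigma_dh].
#' @param beta,beta1,beta2 Numeric p-vectors of additive
#'   allele-substitution effects (allele 1 is the effect allele).
#' @return A scalar variance (trait units squared), covariance, or
#'   correlation in `[-1, 1]`.
#' @export
dh_variance <- function(sigma, beta) {
  dh_covariance(sigma, beta, beta)
}

#' @rdname dh_variance
#' @export
dh_covariance <- function(sigma, beta1, beta2) {
  beta1 <- as.numeric(beta1)
  beta2 <- as.numeric(beta2)
  if (!all(is.finite(beta1)) || !all(is.finite(beta2)))
    stop("effects must be finite")
  if (length(beta1) != nrow(sigma) || length(beta2) != nrow(sigma))
    stop("effect vector length does not match sigma")
  drop(crossprod(beta1, sigma %*% beta2))
}

#' @rdname dh_variance
#' @export
dh_correlation <- function(sigma, beta1, beta2) {
  v1 <- dh_variance(sigma, beta1)
  v2 <- dh_variance(sigma, beta2)
  if (v1 <= 0 || v2 <= 0)
    stop("correlation undefined: a trait has zero progeny variance")
  r <- dh_covariance(sigma, beta1, beta2) / sqrt(v1 * v2)
  max(-1, min(1, r))
}

#' Gametic variance from a DH variance
#'
#' A DH line doubles a single gamete, so the DH breeding value is twice the
#' gametic one and the DH variance is ploidy-squared (4) times the gametic
#' variance.
#'
#' @param dh_var Non-negative DH variance.
#' @param tol Tolerance for small negative numerical noise.
#' @return `dh_var / 4`.
#' @export
gamete_variance_from_dh <- function(dh_var, tol = 1e-9) {
  if (any(dh_var < -tol * max(1, abs(dh_var))))
    stop("DH variance must be non-negative")
  pmax(dh_var, 0) / 4
}
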