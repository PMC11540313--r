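#' Per-locus strand-switch probabilities for gamete simulation
#'
#' Under a no-interference (Poisson crossover) model, the parental strand
#' transmitted along a chromosome is a Markov chain over the map's loci:
#' between adjacent loci the strand switches with probability equal to
#' their recombination frequency, and at the start of every chromosome the
#' strand is drawn fresh (switch probability 0.5, independent
#' chromosomes). Restricted to the marker loci this reproduces exactly the
#' distribution of gametes generated by Poisson crossover counts with
#' uniform positions.
#'
#' @param map A [genetic_map].
#' @param mapping_function Distance-to-recombination function (default
#'   [haldane_c]).
#' @return Numeric vector of length p of switch probabilities.
#' @keywords internal
gamete_switch_prob <- function(map, mapping_function = haldane_c) {
  p <- nrow(map)
  new_chr <- c(TRUE, map$chrom[-1] != map$chrom[-p])
  d <- c(0, diff(map$pos))
  s <- mapping_function(pmax(d, 0))
  s[new_chr] <- 0.5
  s
}

# simulate one gamete per row of (pat, mat); sprob from gamete_switch_prob
sim_gametes <- function(pat, mat, sprob) {
  n <- nrow(pat)
  p <- ncol(pat)
  S <- matrix(stats::runif(n * p), n, p) < rep(sprob, each = n)
  strand <- matrix(FALSE, n, p)
  acc <- rep(FALSE, n)
  for (j in seq_len(p)) {
    acc <- xor(acc, S[, j])
    strand[, j] <- acc
  }
  g <- pat
  g[strand] <- mat[strand]
  g
}

#' Simulate one meiosis
#'
#' Draws a single gamete from an individual's two phased haplotypes under
#' the map's no-interference recombination model (Haldane by default).
#'
#' @param pat,mat Paternal and maternal haplotypes (0/1 vectors in map
#'   locus order).
#' @param map A [genetic_map].
#' @param mapping_function Distance-to-recombination function.
#' @return A 0/1 gamete haplotype of length p.
#' @export
meiosis <- function(pat, mat, map, mapping_function = haldane_c) {
  if (length(pat) != nrow(map) || length(mat) != nrow(map))
    stop("haplotype length does not match the map")
  drop(sim_gametes(matrix(pat, 1), matrix(mat, 1),
                   gamete_switch_prob(map, mapping_function)))
}

#' Exact gametic MSV of one individual
#'
#' Variance of breeding values among the gametes an individual can
#' produce, from its own two haplotypes: beta' [(11' - 2c) .x. D] beta / 4
#' with D the pairwise disequilibrium matrix of the two haplotypes (the
#' 2-way formula on the gametic scale). With `beta2` supplied the gametic
#' Mendelian sampling covariance of two traits is returned instead.
#'
#' @param pat,mat The individual's phased haplotypes (0/1 vectors).
#' @param cmat Recombination matrix over the same loci.
#' @param beta Effect vector of the trait.
#' @param beta2 Optional effect vector of a second trait.
#' @return Scalar gametic MSV (or MS covariance).
#' @export
individual_gametic_msv <- function(pat, mat, cmat, beta, beta2 = beta) {
  d <- haplotype_diff(pat, mat)
  u1 <- d * as.numeric(beta)
  u2 <- d * as.numeric(beta2)
  drop(crossprod(u1, (1 - 2 * cmat) %*% u2)) / 4
}

# group-level mean gametic MSVs / covariance, vectorised over members
group_gametic_msv <- function(pat, mat, cmat, beta, beta2 = beta) {
  D <- pat - mat                     # n x p
  U1 <- D * rep(as.numeric(beta), each = nrow(D))
  U2 <- if (identical(beta, beta2)) U1 else
    D * rep(as.numeric(beta2), each = nrow(D))
  R <- 1 - 2 * cmat
  mean(rowSums((U1 %*% R) * U2)) / 4
}

new_group <- function(label, pat, mat, beta) {
  storage.mode(pat) <- "integer"
  storage.mode(mat) <- "integer"
  list(label = label, pat = pat, mat = mat,
       bv = (pat + mat) %*% as.matrix(beta))
}

select_rows <- function(group, fraction, trait) {
  n <- nrow(group$pat)
  if (is.null(fraction) || fraction >= 1) return(seq_len(n))
  k <- floor(fraction * n)
  if (k < 1) stop("selected fraction leaves no parents")
  order(group$bv[, trait], decreasing = TRUE)[seq_len(k)]
}

#' Simulate a balanced crossing plan forward in time
#'
#' Runs the N-way crossing bracket of a founder panel: generation 1
#' crosses slot pairs of fully inbred founders; every later group mates
#' members of its two parent groups at random in a one-to-one pairing
#' (each parent contributes one offspring, limiting drift); the final step
#' doubles one gamete of each top-group member into a DH line. Optional
#' truncation selection on the true BV of one trait is applied within
#' every group before its members are used as parents; selected parents
#' are then re-used round-robin so group sizes stay constant.
#'
#' @param panel A [founder_panel] (its map is required).
#' @param beta p-vector or p x T matrix of allele-substitution effects.
#' @param n_per_group Individuals simulated per group (>= 2).
#' @param select_fraction Fraction selected within each group before
#'   mating (`NULL` or 1 disables selection).
#' @param trait Column of `beta` used for selection (default 1).
#' @param mapping_function Distance-to-recombination function for
#'   meiosis.
#' @return An object of class `xway_population`: list with `generations`
#'   (list of lists of groups, each group holding `label`, `pat`, `mat`
#'   haplotype matrices and a `bv` matrix), `dh` (the DH group), `map`,
#'   `beta`.
#' @export
run_plan <- function(panel, beta, n_per_group,
                     select_fraction = NULL, trait = 1,
                     mapping_function = haldane_c) {
  stopifnot(inherits(panel, "founder_panel"))
  if (is.null(panel$map)) stop("the panel must carry a genetic map")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (!is.null(select_fraction) &&
      (select_fraction <= 0 || select_fraction > 1))
    stop("select_fraction must be in (0, 1]")
  beta <- as.matrix(beta)
  H <- panel$haplotypes
  N <- ncol(H)
  L <- log2(N)
  labels <- colnames(H)
  sprob <- gamete_switch_prob(panel$map, mapping_function)
  n <- as.integer(n_per_group)

  gens <- vector("list", L)
  gens[[1]] <- lapply(seq_len(N / 2), function(t) {
    new_group(paste(labels[2 * t - 1], labels[2 * t], sep = "x"),
              matrix(H[, 2 * t - 1], n, nrow(H), byrow = TRUE),
              matrix(H[, 2 * t], n, nrow(H), byrow = TRUE), beta)
  })
  blocks <- lapply(seq_len(N / 2), function(t)   # bracket labels per group
    paste0(labels[2 * t - 1], labels[2 * t]))

  for (g in seq_len(L)[-1]) {
    prev <- gens[[g - 1]]
    ng <- length(prev) / 2
    gens[[g]] <- lapply(seq_len(ng), function(t) {
      sire <- prev[[2 * t - 1]]
      dam <- prev[[2 * t]]
      si <- select_rows(sire, select_fraction, trait)
      di <- select_rows(dam, select_fraction, trait)
      si <- sample(rep_len(sample(si), n))   # one offspring per parent when
      di <- sample(rep_len(sample(di), n))   # no selection (k = n)
      pat <- sim_gametes(sire$pat[si, , drop = FALSE],
                         sire$mat[si, , drop = FALSE], sprob)
      mat <- sim_gametes(dam$pat[di, , drop = FALSE],
                         dam$mat[di, , drop = FALSE], sprob)
      new_group(paste(blocks[[2 * t - 1]], blocks[[2 * t]], sep = "x"),
                pat, mat, beta)
    })
    blocks <- lapply(seq_len(ng), function(t)
      paste0(blocks[[2 * t - 1]], blocks[[2 * t]]))
  }

  top <- gens[[L]][[1]]
  ti <- select_rows(top, select_fraction, trait)
  ti <- sample(rep_len(sample(ti), n))
  gam <- sim_gametes(top$pat[ti, , drop = FALSE],
                     top$mat[ti, , drop = FALSE], sprob)
  dh <- new_group(paste0("DHs ", gsub("x", "", top$label)), gam, gam, beta)

  structure(list(generations = gens, dh = dh, map = panel$map, beta = beta),
            class = "xway_population")
}

#' @export
print.xway_population <- function(x, ...) {
  n <- nrow(x$generations[[1]][[1]]$pat)
  cat(sprintf("xway_population: %d generations + DH group, %d individuals/group\n",
              length(x$generations), n))
  invisible(x)
}

#' Mean within-chromosome Falconer disequilibrium of a haplotype pool
#'
#' For every pair of loci on the same chromosome computes
#' D = fAB fab - fAb faB (equivalently pAB - pA pB) over the pooled
#' haplotypes and returns the mean over pairs.
#'
#' @param haplotypes n x p matrix of 0/1 haplotypes (rows are haplotypes),
#'   already oriented so allele 1 is the allele of interest.
#' @param chrom Length-p vector of chromosome labels.
#' @return Mean pairwise within-chromosome D (scalar).
#' @export
falconer_d <- function(haplotypes, chrom) {
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != length(chrom))
    stop("chrom must have one entry per locus")
  af <- colMeans(haplotypes)
  Dm <- crossprod(haplotypes) / nrow(haplotypes) - tcrossprod(af)
  same_chr <- outer(chrom, chrom, "==")
  diag(same_chr) <- FALSE
  if (!any(same_chr)) return(NA_real_)
  mean(Dm[same_chr])
}

#' Population diagnostics of a simulated crossing plan
#'
#' For each F1 generation's pooled individuals (and the DH group),
#' computes, over the loci segregating among the founder slots:
#' the mean change of the beneficial-allele frequency relative to the
#' founders (percentage points), the mean percentage of homozygous loci
#' per individual, and the mean within-chromosome Falconer disequilibrium
#' D = fAB fab - fAb faB between beneficial alleles. The beneficial allele
#' at a locus is the one increasing the designated trait.
#'
#' @param pop An [run_plan] result.
#' @param panel The founder panel the plan was run from.
#' @param trait Trait column used to orient beneficial alleles.
#' @return data.frame with one row per generation (plus the DH group):
#'   `generation`, `af_change_pct`, `homozygosity_pct`, `mean_D`.
#' @export
population_diagnostics <- function(pop, panel, trait = 1) {
  stopifnot(inherits(pop, "xway_population"))
  H <- panel$haplotypes
  beta <- pop$beta[, trait]
  seg <- rowMeans(H) > 0 & rowMeans(H) < 1
  if (!any(seg)) stop("no locus segregates among the founders")
  flip <- beta < 0                  # beneficial allele is 0 there
  orient <- function(X) {           # haplotypes in rows
    X[, flip] <- 1L - X[, flip, drop = FALSE]
    X[, seg, drop = FALSE]
  }
  founder_af <- colMeans(orient(t(H)))
  chrom <- pop$map$chrom[seg]

  one <- function(label, gen, group) {
    hap <- orient(rbind(group$pat, group$mat))
    af <- colMeans(hap)
    hom <- mean(group$pat[, seg, drop = FALSE] ==
                  group$mat[, seg, drop = FALSE]) * 100
    data.frame(generation = label,
               af_change_pct = mean(af - founder_af) * 100,
               homozygosity_pct = hom,
               mean_D = falconer_d(hap, chrom),
               stringsAsFactors = FALSE)
  }
  out <- lapply(seq_along(pop$generations), function(g) {
    groups <- pop$generations[[g]]
    hapstats <- lapply(groups, function(gr) one(as.character(g), g, gr))
    agg <- do.call(rbind, hapstats)
    data.frame(generation = as.character(g),
               af_change_pct = mean(agg$af_change_pct),
               homozygosity_pct = mean(agg$homozygosity_pct),
               mean_D = mean(agg$mean_D), stringsAsFactors = FALSE)
  })
  rbind(do.call(rbind, out), one("DH", NA, pop$dh))
}

#' Validate analytical predictions against replicate simulated crosses
#'
#' The package's validation experiment: repeatedly samples `n_founders`
#' haplotypes from a pool of inbred lines, predicts the DH variance, the
#' top-group mean gametic MSV and (with two traits) the gametic MS
#' covariance and correlation analytically, then simulates the crossing
#' plan and measures the realized counterparts — the variance of BVs of
#' simulated DH lines and the mean of the exact per-individual gametic
#' MSVs of the top F1 group.
#'
#' @param pool p x n matrix of candidate inbred haplotypes.
#' @param map [genetic_map] of the pool.
#' @param effects p-vector or p x T matrix of effects (first two traits
#'   are used for covariance/correlation when T >= 2).
#' @param n_crosses Number of replicate crosses.
#' @param n_per_group Individuals per simulated group.
#' @param n_founders Founder haplotypes per cross (power of 2, default
#'   16).
#' @param select_fraction Optional within-group selected fraction passed
#'   to [run_plan].
#' @return data.frame with one row per cross: analytic and realized DH
#'   variance, mean gametic MSV, and (two traits) MS covariance and
#'   correlation.
#' @export
validate_predictions <- function(pool, map, effects, n_crosses = 50,
                                 n_per_group = 3000, n_founders = 16,
                                 select_fraction = NULL) {
  effects <- as.matrix(effects)
  two_traits <- ncol(effects) >= 2
  cmat <- recombination_matrix(map)
  b1 <- effects[, 1]
  rows <- vector("list", n_crosses)
  for (r in seq_len(n_crosses)) {
    idx <- sample(ncol(pool), n_founders)
    panel <- founder_panel(pool[, idx, drop = FALSE], map)
    colnames(panel$haplotypes) <- slot_labels(n_founders)

    if (two_traits) {
      b2 <- effects[, 2]
      casc <- build_cascade(panel, cmat,
                            cbind(t1 = b1, t2 = b2,
                                  s = b1 + b2, d = b1 - b2))
      top <- casc[casc$generation == max(casc$generation), ]
      msv1 <- top$gametic_msv[top$trait == "t1"]
      msv2 <- top$gametic_msv[top$trait == "t2"]
      # polarization: cov = (msv(b1+b2) - msv(b1-b2)) / 4
      mscov <- (top$gametic_msv[top$trait == "s"] -
                  top$gametic_msv[top$trait == "d"]) / 4
      an <- c(dh = top$dh_variance[top$trait == "t1"], msv = msv1,
              ms_cov = mscov, ms_cor = mscov / sqrt(msv1 * msv2))
    } else {
      casc <- build_cascade(panel, cmat, b1)
      top <- casc[casc$generation == max(casc$generation), ]
      an <- c(dh = top$dh_variance, msv = top$gametic_msv)
    }

    pop <- run_plan(panel, effects, n_per_group,
                    select_fraction = select_fraction)
    topg <- pop$generations[[length(pop$generations)]][[1]]
    re <- c(dh = stats::var(pop$dh$bv[, 1]),
            msv = group_gametic_msv(topg$pat, topg$mat, cmat, b1))
    if (two_traits) {
      v2 <- group_gametic_msv(topg$pat, topg$mat, cmat, effects[, 2])
      cv <- group_gametic_msv(topg$pat, topg$mat, cmat, b1, effects[, 2])
      re <- c(re, ms_cov = cv, ms_cor = cv / sqrt(re[["msv"]] * v2))
    }
    rows[[r]] <- data.frame(cross = r, t(c(analytic = an, realized = re)))
  }
  out <- do.call(rbind, rows)
  names(out) <- sub("\\.", "_", names(out))
  out
}
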