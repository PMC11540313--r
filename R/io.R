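#' Read and write genetic-map TSV files
#'
#' Map files are tab-separated with a header line and columns
#' `locus_id  chrom  pos_cM` (positions in centiMorgan; converted to
#' Morgan internally).
#'
#' @param path File path.
#' @return [read_genetic_map()] returns a [genetic_map].
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("locus_id", "chrom", "pos_cM")
  if (!all(need %in% names(df)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  genetic_map(df$locus_id, df$chrom, df$pos_cM, unit = "cM")
}

#' @rdname read_genetic_map
#' @param map A [genetic_map] to write.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  df <- data.frame(locus_id = map$locus_id, chrom = map$chrom,
                   pos_cM = map$pos * 100)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phased haplotypes
#'
#' TSV format: header, first column `locus_id`, then one 0/1 column per
#' haplotype. Allele 1 is the effect allele (the allele whose substitution
#' effect is recorded in the effects file). VCF input must be phased
#' (`|` separator); each sample contributes two haplotypes named
#' `<sample>_1` and `<sample>_2` (requires the vcfR package).
#' Haplotypes are aligned to the map's locus order; loci missing from the
#' map (or vice versa) are an error.
#'
#' @param path File path.
#' @param map [genetic_map] the haplotypes must cover.
#' @param format `"tsv"` or `"vcf"`.
#' @return p x n 0/1 matrix of haplotypes in map locus order.
#' @export
read_haplotypes <- function(path, map, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(map, "genetic_map"))
  if (format == "tsv") {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (names(df)[1] != "locus_id")
      stop("haplotype TSV must start with a locus_id column")
    H <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!(H %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("non-binary haplotype entry at data line %d",
                   ((bad[1] - 1) %% nrow(H)) + 1))
    rownames(H) <- df$locus_id
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("VCF input requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (any(grepl("/", gt, fixed = TRUE)))
      stop("unphased genotypes in VCF: phased '|' separator required")
    ids <- rownames(gt)
    if (is.null(ids) || anyNA(ids))
      stop("VCF records must carry locus IDs")
    split1 <- sub("\\|.*", "", gt)
    split2 <- sub(".*\\|", "", gt)
    H <- cbind(matrix(as.integer(split1), nrow(gt)),
               matrix(as.integer(split2), nrow(gt)))
    colnames(H) <- c(paste0(colnames(gt), "_1"), paste0(colnames(gt), "_2"))
    # interleave so the two phases of a sample sit in sibling columns
    H <- H[, as.vector(rbind(seq_len(ncol(gt)), ncol(gt) + seq_len(ncol(gt))))]
    rownames(H) <- ids
    if (!all(H %in% c(0, 1)))
      stop("only biallelic 0/1 genotypes are supported")
  }
  miss <- setdiff(map$locus_id, rownames(H))
  if (length(miss))
    stop("haplotypes missing mapped loci: ", paste(utils::head(miss, 3),
                                                   collapse = ", "))
  extra <- setdiff(rownames(H), map$locus_id)
  if (length(extra))
    stop("haplotypes contain loci absent from the map: ",
         paste(utils::head(extra, 3), collapse = ", "))
  storage.mode(H) <- "integer"
  H[map$locus_id, , drop = FALSE]
}

#' @rdname read_haplotypes
#' @param haplotypes p x n 0/1 matrix (rows named by locus).
#' @export
write_haplotypes <- function(haplotypes, path) {
  df <- data.frame(locus_id = rownames(haplotypes), haplotypes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write trait-effect TSV files
#'
#' Long format with header and columns `locus_id  trait  beta`; allele 1
#' is the effect allele. [read_effects()] returns a p x T matrix aligned
#' to the map's locus order.
#'
#' @param path File path.
#' @param map [genetic_map] to align to.
#' @return p x T numeric matrix, columns named by trait.
#' @export
read_effects <- function(path, map) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("locus_id", "trait", "beta")
  if (!all(need %in% names(df)))
    stop("effects file must have columns: ", paste(need, collapse = ", "))
  traits <- unique(df$trait)
  E <- matrix(NA_real_, nrow(map), length(traits),
              dimnames = list(map$locus_id, traits))
  for (tr in traits) {
    sub <- df[df$trait == tr, ]
    idx <- match(sub$locus_id, map$locus_id)
    if (anyNA(idx))
      stop("effects refer to loci absent from the map")
    E[idx, tr] <- sub$beta
  }
  if (anyNA(E))
    stop("effects missing for some mapped loci")
  E
}

#' @rdname read_effects
#' @param effects p x T matrix (rows named by locus).
#' @export
write_effects <- function(effects, path) {
  effects <- as.matrix(effects)
  if (is.null(colnames(effects)))
    colnames(effects) <- paste0("trait", seq_len(ncol(effects)))
  df <- data.frame(
    locus_id = rep(rownames(effects), ncol(effects)),
    trait = rep(colnames(effects), each = nrow(effects)),
    beta = as.vector(effects))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
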