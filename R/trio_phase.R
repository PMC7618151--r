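#' Read biallelic SNP genotypes for one sample from a VCF
#'
#' Thin wrapper around \pkg{vcfR} extracting the genotype call of a single
#' sample at biallelic SNPs. Indels, multi-allelic records and missing
#' genotypes are dropped.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample Sample name; defaults to the first sample in the file.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `gt`
#'   where `gt` is the unphased diploid call (e.g. `"0/1"`).
#' @export
read_genotypes <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_mat <- vcfR::extract.gt(v, element = "GT")
  if (is.null(sample)) sample <- colnames(gt_mat)[1]
  if (!sample %in% colnames(gt_mat))
    stop("sample '", sample, "' not found in ", path)
  gt <- gsub("|", "/", gt_mat[, sample], fixed = TRUE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & !is.na(gt) & !grepl("\\.", gt)
  data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
             ref = fix$REF[keep], alt = fix$ALT[keep], gt = gt[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

gt_alleles <- function(gt, ref, alt) {
  # "0/1" -> c("A","G"); assumes biallelic
  codes <- strsplit(gt, "/", fixed = TRUE)
  lapply(seq_along(gt), function(i)
    ifelse(codes[[i]] == "0", ref[i], alt[i]))
}

#' Phase donor heterozygous sites by Mendelian trio logic
#'
#' For each biallelic SNP where the child (the gamete donor) is heterozygous,
#' checks that both child alleles are present among the parental genotypes at
#' the same site. If both parents are heterozygous the site is uninformative
#' and omitted. Otherwise the allele inherited from `parent1` is assigned to
#' haplotype 1 and the allele from `parent2` to haplotype 2. Sites where the
#' transmission is impossible (a child allele absent from both parents, or no
#' consistent assignment) are counted as Mendelian violations and skipped.
#'
#' Phased sites are emitted as one haplotype block per chromosome with
#' `phase_err = 0`: the Mendelian assignment is deterministic given correct
#' genotypes, so no phasing-algorithm uncertainty applies.
#'
#' @param child,parent1,parent2 Genotype `data.frame`s as returned by
#'   [read_genotypes()] (columns `chrom`, `pos`, `ref`, `alt`, `gt`).
#' @return A list of `haplotype_block` objects (one per chromosome) with
#'   attributes `n_phased`, `n_unphaseable` (both parents heterozygous or a
#'   parent genotype missing) and `n_mendelian_violations`.
#' @export
trio_phase <- function(child, parent1, parent2) {
  key <- function(df) paste(df$chrom, df$pos, sep = ":")
  p1 <- parent1[!duplicated(key(parent1)), , drop = FALSE]
  p2 <- parent2[!duplicated(key(parent2)), , drop = FALSE]
  rownames(p1) <- key(p1); rownames(p2) <- key(p2)

  het <- child[vapply(strsplit(child$gt, "/", fixed = TRUE),
                      function(a) length(unique(a)) == 2L, logical(1)), ,
               drop = FALSE]
  n_unph <- 0L; n_viol <- 0L
  res <- vector("list", nrow(het))
  for (i in seq_len(nrow(het))) {
    k <- paste(het$chrom[i], het$pos[i], sep = ":")
    ca <- c(het$ref[i], het$alt[i])
    if (!k %in% rownames(p1) || !k %in% rownames(p2)) { n_unph <- n_unph + 1L; next }
    a1 <- gt_alleles(p1[k, "gt"], p1[k, "ref"], p1[k, "alt"])[[1]]
    a2 <- gt_alleles(p2[k, "gt"], p2[k, "ref"], p2[k, "alt"])[[1]]
    # both child alleles must be present somewhere in the parents
    if (!all(ca %in% c(a1, a2))) { n_viol <- n_viol + 1L; next }
    het1 <- length(unique(a1)) == 2L
    het2 <- length(unique(a2)) == 2L
    if (het1 && het2) { n_unph <- n_unph + 1L; next }
    if (!het1) {            # parent1 homozygous: transmitted allele is forced
      h1 <- a1[1]
      h2 <- setdiff(ca, h1)
      if (length(h2) != 1L || !h2 %in% a2) { n_viol <- n_viol + 1L; next }
    } else {                # parent2 homozygous
      h2 <- a2[1]
      h1 <- setdiff(ca, h2)
      if (length(h1) != 1L || !h1 %in% a1) { n_viol <- n_viol + 1L; next }
    }
    res[[i]] <- data.frame(chrom = het$chrom[i], pos = het$pos[i],
                           allele_h1 = h1, allele_h2 = h2,
                           ref = het$ref[i], alt = het$alt[i],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  blocks <- list()
  if (!is.null(res) && nrow(res)) {
    for (ch in unique(res$chrom)) {
      s <- res[res$chrom == ch, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <-
        haplotype_block(ch, s$pos, s$allele_h1, s$allele_h2, phase_err = 0,
                        ref = s$ref, alt = s$alt,
                        block_id = paste0("trio_", ch))
    }
  }
  attr(blocks, "n_phased") <- if (is.null(res)) 0L else nrow(res)
  attr(blocks, "n_unphaseable") <- n_unph
  attr(blocks, "n_mendelian_violations") <- n_viol
  blocks
}
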