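#' Read HapCUT2 phased haplotype blocks
#'
#' Parses the HapCUT2 block output format (v1.1+ column layout) into a list
#' of haplotype blocks. Each block is a `data.frame` of phased heterozygous
#' sites with one row per SNP and columns `pos`, `allele_h1`, `allele_h2`,
#' `phase_err`, `ref`, `alt`, plus attributes `chrom` and `block_id`.
#'
#' Per-site lines carry, in order: variant index, haplotype-1 call (0/1/-),
#' haplotype-2 call, chromosome, 1-based position, reference allele,
#' alternate allele, genotype, and (when present) pruned status, switch
#' quality and mismatch quality (both phred-scaled). The per-site mismatch
#' quality Q is converted to a phase-flip probability `10^(-Q/10)`, capped
#' into `[0, 0.5]` (a phase call cannot be worse than random). Pruned sites
#' (haplotype-1 call `-`) are skipped, as are non-biallelic records (with a
#' warning). Trailing extra columns are tolerated.
#'
#' @param path Path to a HapCUT2 block file.
#' @return A list of haplotype blocks (class `haplotype_block`), one per
#'   `BLOCK:` section in the file.
#' @seealso [write_hapcut2()], [trio_phase()]
#' @export
read_hapcut2 <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  cur_id <- NULL
  n_block <- 0L
  flush <- function() {
    if (is.null(cur) || length(cur) == 0L) return(invisible(NULL))
    df <- do.call(rbind, cur)
    df <- df[order(df$pos), , drop = FALSE]
    rownames(df) <- NULL
    blocks[[length(blocks) + 1L]] <<- new_haplotype_block(df, attr(df, "chrom_tmp"), cur_id)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "BLOCK:")) {
      flush()
      n_block <- n_block + 1L
      cur <- list()
      cur_id <- paste0("block_", n_block)
      next
    }
    if (startsWith(ln, "********")) {
      flush()
      cur <- NULL
      next
    }
    f <- strsplit(trimws(ln), "\t|[ ]+")[[1]]
    if (length(f) < 7L)
      stop("malformed HapCUT2 line ", i, " in '", path, "': expected >= 7 fields, got ",
           length(f))
    h1_call <- f[2]
    if (h1_call == "-") next  # pruned site
    ref <- f[6]; alt <- f[7]
    if (nchar(ref) != 1L || nchar(alt) != 1L || grepl(",", alt, fixed = TRUE)) {
      warning("skipping non-biallelic-SNP record at line ", i, " (", f[4], ":", f[5], ")")
      next
    }
    if (!h1_call %in% c("0", "1"))
      stop("malformed HapCUT2 line ", i, ": haplotype call '", h1_call, "'")
    # mismatch quality is column 11 in the modern layout; fall back to the
    # last numeric trailing column if the file carries fewer fields
    q <- NA_real_
    if (length(f) >= 11L) q <- suppressWarnings(as.numeric(f[11]))
    if (is.na(q) && length(f) >= 9L)
      q <- suppressWarnings(as.numeric(f[length(f)]))
    perr <- if (is.na(q)) 0 else 10^(-q / 10)
    perr <- min(max(perr, 0), 0.5)
    a_h1 <- if (h1_call == "0") ref else alt
    a_h2 <- if (h1_call == "0") alt else ref
    if (is.null(cur)) {  # site line outside any BLOCK header: single implicit block
      n_block <- n_block + 1L
      cur <- list()
      cur_id <- paste0("block_", n_block)
    }
    row <- data.frame(pos = as.integer(f[5]), allele_h1 = a_h1, allele_h2 = a_h2,
                      phase_err = perr, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
    attr(row, "chrom_tmp") <- f[4]
    if (length(cur) > 0L) attr(row, "chrom_tmp") <- attr(cur[[1L]], "chrom_tmp")
    cur[[length(cur) + 1L]] <- row
  }
  flush()
  blocks
}

new_haplotype_block <- function(sites, chrom, block_id) {
  stopifnot(all(sites$allele_h1 != sites$allele_h2),
            all(sites$phase_err >= 0 & sites$phase_err <= 1),
            !is.unsorted(sites$pos, strictly = TRUE))
  attr(sites, "chrom_tmp") <- NULL
  attr(sites, "chrom") <- chrom
  attr(sites, "block_id") <- block_id
  class(sites) <- c("haplotype_block", "data.frame")
  sites
}

#' Construct a haplotype block from phased sites
#'
#' @param chrom Chromosome name.
#' @param pos Integer vector of 1-based SNP positions (strictly increasing).
#' @param allele_h1,allele_h2 Single-base alleles on haplotypes 1 and 2.
#' @param phase_err Per-site probability that the h1/h2 assignment is flipped
#'   relative to its block; in `[0, 1]`.
#' @param ref,alt Optional reference/alternate alleles (default: h1/h2).
#' @param block_id Block identifier.
#' @return A `haplotype_block`.
#' @export
haplotype_block <- function(chrom, pos, allele_h1, allele_h2, phase_err = 0,
                            ref = allele_h1, alt = allele_h2,
                            block_id = "block_1") {
  df <- data.frame(pos = as.integer(pos), allele_h1 = allele_h1,
                   allele_h2 = allele_h2,
                   phase_err = rep_len(phase_err, length(pos)),
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  df <- df[order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  new_haplotype_block(df, chrom, block_id)
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat("<haplotype_block> ", attr(x, "block_id"), " on ", attr(x, "chrom"),
      ": ", nrow(x), " phased sites [",
      if (nrow(x)) paste0(min(x$pos), "-", max(x$pos)) else "", "]\n", sep = "")
  invisible(x)
}

#' Write haplotype blocks in HapCUT2 format
#'
#' Writes one `BLOCK:` section per block, terminated by `********`, using the
#' standard column layout so that the output is re-readable by
#' [read_hapcut2()] with all fields preserved. The per-site phase-error
#' probability is encoded as a phred-scaled mismatch quality
#' (`-10*log10(phase_err)`, capped at 100 for error-free sites).
#'
#' @param blocks List of `haplotype_block` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hapcut2 <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(blocks) == 0L) {
    warning("no blocks to write; producing empty file")
    return(invisible(path))
  }
  idx <- 0L
  for (b in blocks) {
    chrom <- attr(b, "chrom")
    n <- nrow(b)
    span <- if (n) max(b$pos) - min(b$pos) else 0L
    writeLines(sprintf("BLOCK: offset: %d len: %d phased: %d SPAN: %d fragments %d",
                       idx + 1L, n, n, span, 0L), con)
    for (k in seq_len(n)) {
      idx <- idx + 1L
      h1_call <- if (b$allele_h1[k] == b$ref[k]) "0" else "1"
      h2_call <- if (h1_call == "0") "1" else "0"
      q <- if (b$phase_err[k] <= 1e-10) 100 else -10 * log10(b$phase_err[k])
      writeLines(paste(idx, h1_call, h2_call, chrom, b$pos[k], b$ref[k], b$alt[k],
                       paste0(h1_call, "|", h2_call), 0,
                       sprintf("%.6f", 100), sprintf("%.6f", q),
                       sep = "\t"), con)
    }
    writeLines("********", con)
  }
  invisible(path)
}

#' Index haplotype blocks by chromosome
#'
#' Collapses a block list into one lookup table per chromosome, used by
#' [find_informative_pairs()]. Sites from multiple blocks on the same
#' chromosome are concatenated; the per-site `phase_err` continues to refer
#' to flips relative to the site's own block.
#'
#' @param blocks List of `haplotype_block` objects.
#' @return Named list (by chromosome) of site data frames sorted by position.
#' @keywords internal
index_blocks <- function(blocks) {
  if (length(blocks) == 0L) return(list())
  chroms <- vapply(blocks, function(b) attr(b, "chrom"), character(1))
  out <- list()
  for (ch in unique(chroms)) {
    df <- do.call(rbind, lapply(blocks[chroms == ch], as.data.frame))
    df <- df[order(df$pos), , drop = FALSE]
    df <- df[!duplicated(df$pos), , drop = FALSE]
    rownames(df) <- NULL
    out[[ch]] <- df
  }
  out
}
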