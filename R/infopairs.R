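#' Per-end haplotype flip-error probability
#'
#' Composes the base-calling error probability `b` and the phase error
#' probability `p` of a SNP observation into the probability that the
#' observed haplotype assignment of that read end is wrong, treating the two
#' error sources as independent: a flip occurs when exactly one of the two
#' errors occurs, `e = b(1-p) + p(1-b)`.
#'
#' This composition is isolated here so that the likelihood model can be
#' swapped without touching the pair-classification machinery.
#'
#' @param b Base-calling error probability in `[0, 1]`.
#' @param p Phase error probability in `[0, 1]`.
#' @return Flip probability, same length as the inputs.
#' @export
flip_error <- function(b, p) b * (1 - p) + p * (1 - b)

#' Crossover and non-crossover likelihoods for informative pairs
#'
#' For a pair observed as crossover (status `C`), the crossover likelihood
#' `lc = P(X=C | crossover)` is the probability that neither or both read
#' ends are flipped, `lc = (1-e1)(1-e2) + e1*e2`, and the non-crossover
#' likelihood `ln = P(X=C | no crossover)` is the probability of exactly one
#' flip, `ln = e1(1-e2) + e2(1-e1)`, with per-end flip probabilities from
#' [flip_error()]. For pairs observed as non-crossover (status `N`) the
#' conservative convention `lc = 0`, `ln = 1` is applied: an N call is never
#' allowed to generate crossover evidence, at the cost of a small,
#' position-independent false-negative rate.
#'
#' @param pairs Informative-pairs `data.frame` with columns `status`, `b1`,
#'   `p1`, `b2`, `p2` (per-end base and phase error probabilities of the two
#'   outermost SNPs).
#' @return `pairs` with columns `lc` and `ln` added (and `d` computed from
#'   `left_pos`/`right_pos` if absent).
#' @export
pair_likelihoods <- function(pairs) {
  e1 <- flip_error(pairs$b1, pairs$p1)
  e2 <- flip_error(pairs$b2, pairs$p2)
  is_c <- pairs$status == "C"
  pairs$lc <- ifelse(is_c, (1 - e1) * (1 - e2) + e1 * e2, 0)
  pairs$ln <- ifelse(is_c, e1 * (1 - e2) + e2 * (1 - e1), 1)
  if (is.null(pairs$d)) pairs$d <- pairs$right_pos - pairs$left_pos
  pairs
}

# Map reference positions to query (read) offsets through a CIGAR string.
# Returns NA for reference positions consumed by deletions/skips or outside
# the aligned span. Handles M/=/X, I, D, N, S, H.
cigar_query_offsets <- function(cigar, read_start, ref_pos) {
  ops <- strsplit(gsub("([MIDNSHP=X])", "\\1;", cigar), ";")[[1]]
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  qoff <- 0L; rpos <- read_start
  out <- rep(NA_integer_, length(ref_pos))
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "=", "X")) {
      hit <- ref_pos >= rpos & ref_pos < rpos + n[k]
      out[hit] <- qoff + (ref_pos[hit] - rpos) + 1L
      rpos <- rpos + n[k]; qoff <- qoff + n[k]
    } else if (op[k] %in% c("I", "S")) {
      qoff <- qoff + n[k]
    } else if (op[k] %in% c("D", "N")) {
      rpos <- rpos + n[k]
    }                                   # H, P consume nothing relevant
  }
  out
}

snp_observations <- function(pos, cigar, seq, qual, sites) {
  # sites: data.frame(pos, allele_h1, allele_h2, phase_err), sorted
  end <- pos + sum(with(cig_tab(cigar), n[op %in% c("M", "=", "X", "D", "N")])) - 1L
  cand <- sites[sites$pos >= pos & sites$pos <= end, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  q_at <- cigar_query_offsets(cigar, pos, cand$pos)
  ok <- !is.na(q_at)
  cand <- cand[ok, , drop = FALSE]; q_at <- q_at[ok]
  if (!nrow(cand)) return(NULL)
  bases <- substring(seq, q_at, q_at)
  quals <- 10^(-(utf8ToInt(qual)[q_at] - 33L) / 10)
  hap <- ifelse(bases == cand$allele_h1, 1L,
                ifelse(bases == cand$allele_h2, 2L, NA_integer_))
  keep <- !is.na(hap)                    # base matches neither allele: discard
  if (!any(keep)) return(NULL)
  data.frame(pos = cand$pos[keep], read_base = bases[keep],
             base_err = quals[keep], phase_err = cand$phase_err[keep],
             hap_match = hap[keep], stringsAsFactors = FALSE)
}

cig_tab <- function(cigar) {
  ops <- strsplit(gsub("([MIDNSHP=X])", "\\1;", cigar), ";")[[1]]
  data.frame(n = as.integer(sub("[MIDNSHP=X]$", "", ops)),
             op = sub("^[0-9]+", "", ops), stringsAsFactors = FALSE)
}

#' Extract crossover-informative read pairs from gamete Hi-C alignments
#'
#' Scans paired-end Hi-C alignments and emits one informative pair per read
#' pair in which (i) both mates are primary alignments mapped to the same
#' chromosome with mapping quality at or above `min_mapq`, (ii) each mate
#' overlaps at least one phased heterozygous site whose read base matches
#' one of the two donor alleles, and (iii) all matched SNPs within each mate
#' agree on the mate's haplotype, so the pair status is unambiguous. Pairs
#' whose mates carry internally inconsistent haplotype matches are dropped
#' and counted. The pair is classified `C` (crossover) when the two mates
#' match different donor haplotypes and `N` otherwise, and is represented by
#' its two outermost SNPs: the reported `left_pos`/`right_pos`, error
#' probabilities and insert size `d = right_pos - left_pos` all refer to the
#' outermost SNP of each mate; interior SNPs only serve the consistency
#' check.
#'
#' @param file SAM or BAM file of coordinate-sorted, duplicate-removed Hi-C
#'   alignments. A `.sam` file is converted on the fly via
#'   [Rsamtools::asBam()].
#' @param blocks List of `haplotype_block` objects (phased donor
#'   heterozygous sites).
#' @param min_mapq Minimum mapping quality for both mates (default 30).
#' @return A `data.frame` of informative pairs with columns `chrom`,
#'   `left_pos`, `right_pos`, `status`, `b1`, `p1`, `b2`, `p2`, `d`, and an
#'   attribute `counts` with summary tallies (pairs seen, emitted,
#'   inconsistent, uninformative, filtered).
#' @export
find_informative_pairs <- function(file, blocks, min_mapq = 30) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- suppressMessages(Rsamtools::asBam(file, destination = dest,
                                              overwrite = TRUE,
                                              indexDestination = FALSE))
  }
  site_idx <- index_blocks(blocks)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  res <- Rsamtools::scanBam(file, param = Rsamtools::ScanBamParam(what = what))[[1]]
  flag <- res$flag
  primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L &
    bitwAnd(flag, 4L) == 0L & !is.na(res$pos)
  counts <- c(pairs_seen = 0L, emitted = 0L, inconsistent = 0L,
              uninformative = 0L, filtered = 0L, unpaired = 0L)
  df <- data.frame(qname = res$qname, rname = as.character(res$rname),
                   pos = res$pos, mapq = res$mapq, cigar = res$cigar,
                   seq = as.character(res$seq), qual = as.character(res$qual),
                   stringsAsFactors = FALSE)[primary, , drop = FALSE]
  sp <- split(seq_len(nrow(df)), df$qname)
  out <- vector("list", length(sp))
  oi <- 0L
  for (ii in sp) {
    if (length(ii) != 2L) { counts["unpaired"] <- counts["unpaired"] + 1L; next }
    counts["pairs_seen"] <- counts["pairs_seen"] + 1L
    a <- df[ii[1], ]; b <- df[ii[2], ]
    if (a$rname != b$rname || min(a$mapq, b$mapq) < min_mapq) {
      counts["filtered"] <- counts["filtered"] + 1L; next
    }
    sites <- site_idx[[a$rname]]
    if (is.null(sites)) { counts["uninformative"] <- counts["uninformative"] + 1L; next }
    oa <- snp_observations(a$pos, a$cigar, a$seq, a$qual, sites)
    ob <- snp_observations(b$pos, b$cigar, b$seq, b$qual, sites)
    if (is.null(oa) || is.null(ob)) {
      counts["uninformative"] <- counts["uninformative"] + 1L; next
    }
    if (length(unique(oa$hap_match)) > 1L || length(unique(ob$hap_match)) > 1L) {
      counts["inconsistent"] <- counts["inconsistent"] + 1L; next
    }
    if (min(oa$pos) > min(ob$pos)) { tmp <- oa; oa <- ob; ob <- tmp }
    left <- oa[which.min(oa$pos), ]    # outermost SNP of the left mate
    right <- ob[which.max(ob$pos), ]   # outermost SNP of the right mate
    if (right$pos <= left$pos) { counts["inconsistent"] <- counts["inconsistent"] + 1L; next }
    oi <- oi + 1L
    out[[oi]] <- data.frame(
      chrom = a$rname, left_pos = left$pos, right_pos = right$pos,
      status = if (oa$hap_match[1] != ob$hap_match[1]) "C" else "N",
      b1 = left$base_err, p1 = left$phase_err,
      b2 = right$base_err, p2 = right$phase_err, stringsAsFactors = FALSE)
  }
  counts["emitted"] <- oi
  pairs <- if (oi) do.call(rbind, out[seq_len(oi)]) else
    data.frame(chrom = character(), left_pos = integer(), right_pos = integer(),
               status = character(), b1 = numeric(), p1 = numeric(),
               b2 = numeric(), p2 = numeric(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$chrom, pairs$left_pos, pairs$right_pos), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$d <- pairs$right_pos - pairs$left_pos
  attr(pairs, "counts") <- counts
  pairs
}

#' Write / read the tab-delimited informative-pairs format
#'
#' Columns: `chrom`, `left_pos`, `right_pos`, `status`, `b1`, `p1`, `b2`,
#' `p2`. Positions are 1-based coordinates of the two outermost SNPs.
#'
#' @param pairs Informative-pairs `data.frame`.
#' @param path File path.
#' @return `write_pairs` returns `path` invisibly; `read_pairs` returns the
#'   pairs `data.frame` with `d` recomputed.
#' @export
write_pairs <- function(pairs, path) {
  cols <- c("chrom", "left_pos", "right_pos", "status", "b1", "p1", "b2", "p2")
  data.table::fwrite(as.data.frame(pairs)[, cols], path, sep = "\t")
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  pairs <- as.data.frame(data.table::fread(path, sep = "\t"))
  pairs$d <- pairs$right_pos - pairs$left_pos
  pairs
}
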