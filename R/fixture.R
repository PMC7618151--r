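#' Generate a miniature aligned gamete Hi-C dataset with known crossovers
#'
#' Writes a small SAM file of paired reads, a matching HapCUT2 phased-block
#' file, and a truth table, for end-to-end testing of
#' [find_informative_pairs()]. A random reference sequence carries `n_hets`
#' phased heterozygous sites; each simulated gamete starts on a random
#' parental haplotype and switches haplotype at every planted breakpoint.
#' Each read pair places one 100 bp read over a left SNP and one over a
#' right SNP (reads are shifted so they never straddle a breakpoint
#' internally) and its bases at het positions follow the gamete haplotype,
#' so a pair is a true crossover exactly when its two reads sit on opposite
#' sides of an odd number of breakpoints.
#'
#' @param chrom_len Chromosome length in bp (default 50000).
#' @param n_hets Number of phased heterozygous sites (>= 2).
#' @param n_pairs Number of read pairs.
#' @param breakpoints Integer vector of planted crossover positions
#'   (possibly empty); must lie inside the chromosome.
#' @param seed Integer seed; fixed seeds give byte-identical files.
#' @param dir Output directory (default `tempdir()`).
#' @param read_len Read length (default 100).
#' @param base_qual Phred base quality written for all bases (default 40).
#' @return List with `sam`, `hapcut2` (file paths), `truth` (`data.frame`
#'   with per-pair true status and read placements) and `sites`.
#' @export
make_fixture <- function(chrom_len = 50000, n_hets = 100, n_pairs = 60,
                         breakpoints = integer(0), seed = 1,
                         dir = tempdir(), read_len = 100, base_qual = 40) {
  stopifnot(n_hets >= 2)
  if (length(breakpoints) &&
      (min(breakpoints) <= read_len || max(breakpoints) >= chrom_len - read_len))
    stop("breakpoints must lie inside the chromosome (margin one read length)")
  set.seed(seed)
  chrom <- "chrFix"
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, chrom_len, replace = TRUE)
  het_pos <- sort(sample(seq(read_len, chrom_len - read_len), n_hets))
  alt <- vapply(het_pos, function(p) sample(setdiff(bases, ref[p]), 1), "")
  sites <- data.frame(pos = het_pos, ref = ref[het_pos], alt = alt,
                      stringsAsFactors = FALSE)
  bp <- sort(breakpoints)
  hap_at <- function(x, start_hap) {
    # haplotype of a gamete at position x: switches at each breakpoint
    1L + (start_hap - 1L + findInterval(x, bp)) %% 2L
  }
  shift_off_breakpoints <- function(start) {
    # move a read window so it contains no breakpoint
    for (cut in bp) {
      if (start < cut && start + read_len - 1L >= cut)
        start <- if (cut - read_len >= 1L) cut - read_len else cut + 1L
    }
    start
  }
  read_seq <- function(start, hap_fun) {
    s <- ref[start:(start + read_len - 1L)]
    in_read <- sites$pos >= start & sites$pos <= start + read_len - 1L
    for (j in which(in_read)) {
      h <- hap_fun(sites$pos[j])
      s[sites$pos[j] - start + 1L] <- if (h == 1L) sites$ref[j] else sites$alt[j]
    }
    paste(s, collapse = "")
  }
  qual_str <- paste(rep(intToUtf8(base_qual + 33L), read_len), collapse = "")
  sam_lines <- c("@HD\tVN:1.6\tSO:coordinate",
                 paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len))
  truth <- vector("list", n_pairs)
  recs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    # keep the two reads well separated so the pair orientation is unambiguous
    repeat {
      li <- sample(seq_len(n_hets - 1L), 1)
      cand <- which(sites$pos > sites$pos[li] + 3L * read_len)
      if (length(cand)) break
    }
    ri <- if (length(cand) == 1L) cand else sample(cand, 1)
    s1 <- shift_off_breakpoints(max(1L, sites$pos[li] - sample.int(read_len - 1L, 1) + 1L))
    if (sites$pos[li] < s1 || sites$pos[li] > s1 + read_len - 1L)
      s1 <- shift_off_breakpoints(sites$pos[li])
    s2 <- shift_off_breakpoints(max(1L, sites$pos[ri] - sample.int(read_len - 1L, 1) + 1L))
    if (sites$pos[ri] < s2 || sites$pos[ri] > s2 + read_len - 1L)
      s2 <- shift_off_breakpoints(sites$pos[ri])
    start_hap <- sample(1:2, 1)
    hf <- function(x) hap_at(x, start_hap)
    seq1 <- read_seq(s1, hf); seq2 <- read_seq(s2, hf)
    h1 <- hf(s1); h2 <- hf(s2)     # constant within a read by construction
    qn <- sprintf("pair%04d", i)
    recs[[i]] <- c(
      paste(qn, 99, chrom, s1, 60, paste0(read_len, "M"), "=", s2,
            s2 - s1 + read_len, seq1, qual_str, sep = "\t"),
      paste(qn, 147, chrom, s2, 60, paste0(read_len, "M"), "=", s1,
            -(s2 - s1 + read_len), seq2, qual_str, sep = "\t"))
    in1 <- sites$pos[sites$pos >= s1 & sites$pos <= s1 + read_len - 1L]
    in2 <- sites$pos[sites$pos >= s2 & sites$pos <= s2 + read_len - 1L]
    truth[[i]] <- data.frame(qname = qn, read1_start = s1, read2_start = s2,
                             left_snp = min(in1), right_snp = max(in2),
                             true_status = if (h1 != h2) "C" else "N",
                             start_hap = start_hap, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  # SAM must be coordinate-sorted: interleave records by leftmost position
  flat <- unlist(recs)
  pos_of <- as.integer(vapply(strsplit(flat, "\t"), `[`, "", 4))
  sam_lines <- c(sam_lines, flat[order(pos_of)])
  sam_path <- file.path(dir, sprintf("fixture_seed%d.sam", seed))
  writeLines(sam_lines, sam_path)
  hap_path <- file.path(dir, sprintf("fixture_seed%d.hapcut2", seed))
  blk <- haplotype_block(chrom, sites$pos, allele_h1 = sites$ref,
                         allele_h2 = sites$alt, phase_err = 1e-6,
                         ref = sites$ref, alt = sites$alt)
  write_hapcut2(list(blk), hap_path)
  list(sam = sam_path, hapcut2 = hap_path, truth = truth, sites = sites,
       breakpoints = bp, chrom = chrom, chrom_len = chrom_len)
}
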