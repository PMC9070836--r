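## IUPAC nucleotide ambiguity sets used by the motif scanner.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' @noRd
norm_call <- function(call) {
  vapply(strsplit(call, "/", fixed = TRUE), function(a) {
    paste(sort(unique(a)), collapse = "/")
  }, character(1))
}

#' Filter resistance-specific SNPs by genotype set logic
#'
#' Keeps biallelic SNP records whose calls in the two resistant
#' cultivars are identical to each other (heterozygous calls compared as
#' unordered allele sets) and different from the susceptible cultivar's
#' call -- "common in the resistant pair but different from the
#' susceptible comparator". Records with a missing call in any of the
#' three genotypes, or that are not simple biallelic SNPs, are skipped
#' and counted. The filter is idempotent: reapplying it returns the same
#' records.
#'
#' @param variants variant data frame (chrom, pos, ref, alt, one call
#'   column per genotype; see [simulate_variants()] / [read_variant_vcf()]).
#' @param resistant names of the two resistant-genotype call columns.
#' @param susceptible name of the susceptible-genotype call column.
#' @return The filtered data frame, with attributes `n_skipped_missing`
#'   and `n_skipped_nonsnp`.
#' @export
resistance_specific_snps <- function(variants,
                                     resistant = c("H9553", "H9492"),
                                     susceptible = "H9775") {
  cols <- c(resistant, susceptible)
  missing_cols <- setdiff(cols, names(variants))
  if (length(missing_cols)) {
    stopf("call column(s) missing from variant table: %s",
          paste(missing_cols, collapse = ", "))
  }
  bases <- c("A", "C", "G", "T")
  is_snp <- variants$ref %in% bases & variants$alt %in% bases
  calls <- lapply(cols, function(g) variants[[g]])
  has_missing <- Reduce(`|`, lapply(calls, function(x) {
    is.na(x) | x == "." | x == ""
  }))
  usable <- is_snp & !has_missing
  r1 <- norm_call(ifelse(usable, variants[[resistant[1]]], "A"))
  r2 <- norm_call(ifelse(usable, variants[[resistant[2]]], "A"))
  su <- norm_call(ifelse(usable, variants[[susceptible]], "A"))
  keep <- usable & r1 == r2 & r1 != su
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_missing") <- sum(has_missing & is_snp)
  attr(out, "n_skipped_nonsnp") <- sum(!is_snp)
  out
}

#' Strand-aware promoter windows upstream of gene starts
#'
#' For a plus-strand gene starting at S the promoter is
#' `[max(1, S - window), S - 1]`; for a minus-strand gene ending at E it
#' is `[E + 1, min(chromosome length, E + window)]`. All coordinates are
#' 1-based inclusive; windows are clipped at chromosome ends, and genes
#' whose window would be empty (gene start at position 1) are dropped.
#' The transcription start is taken as the gene feature's 5' end.
#'
#' @param genes data frame with columns `gene`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param window promoter length in bp (default 5000).
#' @param chrom_lengths optional named vector of chromosome lengths used
#'   to clip minus-strand windows.
#' @return Data frame: gene, chrom, start, end, strand.
#' @export
promoter_windows <- function(genes, window = 5000L, chrom_lengths = NULL) {
  check_scalar(window, "window", 1)
  if (!all(genes$strand %in% c("+", "-"))) {
    stopf("unknown strand value; must be '+' or '-'")
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(1, genes$start - window), genes$end + 1)
  end <- ifelse(plus, genes$start - 1, genes$end + window)
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[genes$chrom]
    if (any(is.na(len))) stopf("chromosome length missing for some genes")
    end <- pmin(end, len)
  }
  out <- data.frame(gene = genes$gene, chrom = genes$chrom,
                    start = as.integer(start), end = as.integer(end),
                    strand = genes$strand, stringsAsFactors = FALSE)
  out <- out[out$end >= out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a sequence for an IUPAC motif on one or both strands
#'
#' Reports every position where the pattern (default the W-box core
#' TTGACY, Y = C/T) matches the forward strand, plus -- when
#' `both_strands` -- positions whose reverse complement matches,
#' reported in forward coordinates with strand `"-"` and the matched
#' word given in pattern orientation. `N` bases in the sequence never
#' match.
#'
#' @param seq a DNA sequence: character string, `DNAString`, or named
#'   character of length 1.
#' @param pattern IUPAC pattern (default `"TTGACY"`).
#' @param both_strands scan the reverse strand too? (default TRUE)
#' @param chrom chromosome name attached to the hits (defaults to the
#'   sequence's name if any).
#' @return Data frame: chrom, start, end (1-based inclusive), strand,
#'   match.
#' @export
scan_motif <- function(seq, pattern = "TTGACY", both_strands = TRUE,
                       chrom = NULL) {
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1]], names(IUPAC_SETS))
  if (length(bad)) stopf("invalid IUPAC code(s) in pattern: %s", paste(bad, collapse = ", "))
  if (is.null(chrom)) chrom <- names(seq) %||% "seq"
  subj <- Biostrings::DNAString(as.character(seq))
  fixed <- c(pattern = FALSE, subject = TRUE)  # N in subject never matches
  fwd <- Biostrings::matchPattern(pattern, subj, fixed = fixed)
  out <- data.frame(
    chrom = rep(chrom, length(fwd)),
    start = Biostrings::start(fwd), end = Biostrings::end(fwd),
    strand = rep("+", length(fwd)),
    match = as.character(fwd),
    stringsAsFactors = FALSE
  )
  if (both_strands) {
    rc_pat <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
    rev <- Biostrings::matchPattern(rc_pat, subj, fixed = fixed)
    if (length(rev)) {
      out <- rbind(out, data.frame(
        chrom = rep(chrom, length(rev)),
        start = Biostrings::start(rev), end = Biostrings::end(rev),
        strand = rep("-", length(rev)),
        match = as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(rev)
        )),
        stringsAsFactors = FALSE
      ))
    }
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Overlap resistance-specific SNPs with promoter motif hits
#'
#' For every SNP that falls inside a promoter interval, reports each
#' motif hit whose span contains the SNP position, and notes whether the
#' alternate allele breaks the motif match (the alt base, read in the
#' hit's pattern orientation, no longer satisfies the IUPAC code at that
#' motif position).
#'
#' @param snps filtered variant data frame (see
#'   [resistance_specific_snps()]).
#' @param hits motif hit data frame (see [scan_motif()]).
#' @param promoters promoter interval data frame (see
#'   [promoter_windows()]).
#' @param pattern the IUPAC pattern that produced `hits`.
#' @return Data frame: gene, chrom, pos, ref, alt, motif_start,
#'   motif_end, motif_strand, match, breaks_motif.
#' @export
snp_motif_overlap <- function(snps, hits, promoters, pattern = "TTGACY") {
  pat <- strsplit(toupper(pattern), "")[[1]]
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    pos <- snps$pos[i]; chrom <- snps$chrom[i]
    pr <- promoters[promoters$chrom == chrom &
                      promoters$start <= pos & promoters$end >= pos, ,
                    drop = FALSE]
    if (!nrow(pr)) next
    hh <- hits[hits$chrom == chrom & hits$start <= pos & hits$end >= pos, ,
               drop = FALSE]
    if (!nrow(hh)) next
    for (g in pr$gene) for (j in seq_len(nrow(hh))) {
      if (hh$strand[j] == "+") {
        off <- pos - hh$start[j] + 1L
        base <- snps$alt[i]
      } else {
        off <- hh$end[j] - pos + 1L
        base <- complement_base(snps$alt[i])
      }
      breaks <- !(base %in% IUPAC_SETS[[pat[off]]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, chrom = chrom, pos = pos,
        ref = snps$ref[i], alt = snps$alt[i],
        motif_start = hh$start[j], motif_end = hh$end[j],
        motif_strand = hh$strand[j], match = hh$match[j],
        breaks_motif = breaks, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), motif_start = integer(0),
                      motif_end = integer(0), motif_strand = character(0),
                      match = character(0), breaks_motif = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export promoter intervals as BED
#'
#' BED uses 0-based half-open coordinates; the conversion from the
#' package's 1-based inclusive intervals happens here only.
#'
#' @param promoters a [promoter_windows()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_promoter_bed <- function(promoters, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   promoters$chrom, promoters$start - 1L, promoters$end,
                   promoters$gene, promoters$strand)
  writeLines(lines, path)
  invisible(path)
}
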