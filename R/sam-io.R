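## Minimal SAM emission for simulator truth alignments, and alignment
## ingestion through Rsamtools/GenomicAlignments. The simulators know read
## placement exactly, so truth SAM records are ungapped (<len>M) primary
## alignments; real data enter through the same readers.

sam_header <- function(reference) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
            Biostrings::width(reference)))
}

## records: data.frame with qname, flag, scaffold, pos (0-based), seq
write_sam <- function(records, reference, path) {
  lines <- sam_header(reference)
  if (nrow(records) > 0L) {
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                              records$qname, records$flag, records$scaffold,
                              records$pos + 1L, nchar(records$seq),
                              records$seq))
  }
  writeLines(lines, path)
  invisible(path)
}

## paired records: one row per fragment; emits two mates with proper-pair flags
write_sam_pairs <- function(frags, reference, read_len, path) {
  lines <- sam_header(reference)
  if (nrow(frags) > 0L) {
    r1_len <- pmin(read_len, frags$length)
    r2_len <- pmin(read_len, frags$length)
    p1 <- frags$start + 1L                      # 1-based leftmost
    p2 <- frags$end - r2_len + 1L
    seq1 <- strrep("N", r1_len)
    seq2 <- strrep("N", r2_len)
    l1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                  frags$qname, frags$scaffold, p1, r1_len, p2, frags$length,
                  seq1)
    l2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                  frags$qname, frags$scaffold, p2, r2_len, p1, -frags$length,
                  seq2)
    lines <- c(lines, as.vector(rbind(l1, l2)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read single-end alignments from a SAM/BAM file
#'
#' Secondary, supplementary and unmapped records are dropped; the number of
#' unmapped records skipped is attached as attribute `n_unmapped`.
#'
#' @param path SAM or BAM file.
#' @return a named [GenomicAlignments::GAlignments] object.
#' @export
read_alignments <- function(path) {
  bam <- as_bam(path)
  flag0 <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  n_all <- length(Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(flag = flag0, what = "flag"))[[1]]$flag)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, use.names = TRUE, param = Rsamtools::ScanBamParam(flag = flag))
  attr(ga, "n_unmapped") <- n_all - length(ga)
  ga
}

#' Read paired-end fragments from a SAM/BAM file
#'
#' Keeps proper pairs only and returns one interval per fragment (outer span
#' of the two mates).
#'
#' @param path SAM or BAM file of paired alignments.
#' @param library label stored in the `library` column.
#' @return data.frame with columns `scaffold, start, end, length, library`
#'   (0-based half-open).
#' @export
read_fragments <- function(path, library = "library") {
  bam <- as_bam(path)
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  gp <- GenomicAlignments::readGAlignmentPairs(
    bam, param = Rsamtools::ScanBamParam(flag = flag))
  gr <- GenomicRanges::granges(gp)
  data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             length = GenomicRanges::width(gr),
             library = library,
             stringsAsFactors = FALSE)
}

as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
}
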