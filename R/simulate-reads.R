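## Read simulators with known ground truth. Placement is exact, so truth
## alignments are emitted directly as SAM; no external aligner is involved.

#' Simulate genomic DNA reads with per-IES retention fractions
#'
#' Single-end reads are drawn uniformly along the germline-inclusive (MIC)
#' reference. A read overlapping IES *i* comes from the IES-retained
#' haplotype with probability `retention[i]`, otherwise from the excised
#' form; per-read sampling reflects the high ploidy of the *Paramecium*
#' somatic nucleus, where each read is effectively an independent genome
#' copy. Reads whose start falls inside an IES on an excised copy are
#' dropped, which reproduces uniform sampling on the shorter haplotype.
#'
#' @param genome result of [build_toy_genome()].
#' @param retention numeric vector of per-IES retention fractions in
#'   \[0, 1\], named by or ordered as `genome$annotation$ies_id`.
#' @param depth target fold-coverage of the MIC reference.
#' @param read_length read length in bp; must not exceed the smallest
#'   inter-IES gap so that no read spans two IESs.
#' @param seed integer RNG seed.
#' @param error_rate optional uniform substitution rate (default 0).
#' @return a list of class `genomic_read_sim` with
#'   \describe{
#'     \item{reads}{data.frame `read_id, scaffold, mic_pos, mac_pos, length,
#'       seq, ies_id, form` — the truth table; `form` is one of
#'       `"retained"`, `"excised"`, `"none"`; positions are 0-based, `NA`
#'       when the read has no placement on that reference.}
#'     \item{retention}{the truth retention fractions, named by ies_id.}
#'     \item{annotation}{the IES annotation used.}
#'   }
#' @export
simulate_genomic_reads <- function(genome, retention, depth = 50,
                                   read_length = 100L, seed = 1L,
                                   error_rate = 0) {
  ann <- genome$annotation
  if (nrow(ann) == 0L && length(retention) > 0L)
    stop("retention truth supplied but annotation is empty")
  if (nrow(ann) > 0L) {
    if (is.null(names(retention))) {
      stopifnot(length(retention) == nrow(ann))
      names(retention) <- ann$ies_id
    }
    stopifnot(all(ann$ies_id %in% names(retention)),
              all(retention >= 0), all(retention <= 1))
    gaps <- min_inter_ies_gap(genome$mic, ann)
    if (read_length > gaps)
      stop("read_length ", read_length, " exceeds the smallest inter-IES ",
           "gap (", gaps, "); reads would span two IESs")
  }
  stopifnot(depth > 0, read_length >= 2L)
  mic_chr <- as.character(genome$mic)
  mac_chr <- as.character(genome$mac)
  mic_len <- nchar(mic_chr)
  scafs <- names(mic_chr)
  with_seed(seed, {
    n_reads <- ceiling(depth * sum(mic_len) / read_length)
    sc_idx <- sample.int(length(scafs), n_reads, replace = TRUE,
                         prob = mic_len)
    start <- as.integer(floor(runif(n_reads) * (mic_len[sc_idx] - read_length + 1)))
    reads <- data.frame(read_id = sprintf("read_%07d", seq_len(n_reads)),
                        scaffold = scafs[sc_idx],
                        mic_pos = start,
                        mac_pos = NA_integer_,
                        length = read_length,
                        ies_id = NA_character_,
                        form = "none",
                        stringsAsFactors = FALSE)
    if (nrow(ann) > 0L) {
      read_gr <- GenomicRanges::GRanges(reads$scaffold,
        IRanges::IRanges(start = reads$mic_pos + 1L, width = read_length))
      hits <- GenomicRanges::findOverlaps(read_gr, annotation_granges(ann),
                                          select = "first")
      ov <- !is.na(hits)
      r_i <- retention[ann$ies_id[hits[ov]]]
      keep_ies <- runif(sum(ov)) < r_i
      reads$ies_id[ov] <- ann$ies_id[hits[ov]]
      reads$form[ov] <- ifelse(keep_ies, "retained", "excised")
    }
    ## MAC placement: shift by cumulative excised length upstream of the read
    offset <- mic_to_mac_offset(reads$scaffold, reads$mic_pos, ann)
    is_none <- reads$form == "none"
    reads$mac_pos[is_none] <- reads$mic_pos[is_none] - offset[is_none]
    is_exc <- reads$form == "excised"
    in_flank <- is_exc &
      reads$mic_pos < ann$start_mic[match(reads$ies_id, ann$ies_id)]
    reads$mac_pos[in_flank] <- reads$mic_pos[in_flank] - offset[in_flank]
    ## excised-copy reads starting inside the IES have no source: drop
    drop <- is_exc & !in_flank
    ## retained reads keep their MIC placement only
    reads$mic_pos[is_exc] <- NA_integer_
    reads <- reads[!drop, , drop = FALSE]
    ## sequences from the emitting reference
    from_mic <- !is.na(reads$mic_pos)
    reads$seq <- NA_character_
    reads$seq[from_mic] <- substring(mic_chr[reads$scaffold[from_mic]],
                                     reads$mic_pos[from_mic] + 1L,
                                     reads$mic_pos[from_mic] + read_length)
    from_mac <- !from_mic
    reads$seq[from_mac] <- substring(mac_chr[reads$scaffold[from_mac]],
                                     reads$mac_pos[from_mac] + 1L,
                                     reads$mac_pos[from_mac] + read_length)
    if (error_rate > 0) reads$seq <- add_substitutions(reads$seq, error_rate)
    rownames(reads) <- NULL
    structure(list(reads = reads,
                   retention = if (nrow(ann)) retention[ann$ies_id] else
                     setNames(numeric(0), character(0)),
                   annotation = ann,
                   genome = genome),
              class = "genomic_read_sim")
  })
}

min_inter_ies_gap <- function(mic, ann) {
  gaps <- unlist(lapply(split(ann, ann$scaffold), function(a) {
    a <- a[order(a$start_mic), , drop = FALSE]
    len <- Biostrings::width(mic)[match(a$scaffold[1], names(mic))]
    c(a$start_mic[1], len - a$end_mic[nrow(a)],
      if (nrow(a) > 1) a$start_mic[-1] - a$end_mic[-nrow(a)])
  }), use.names = FALSE)
  min(gaps)
}

mic_to_mac_offset <- function(scaffold, pos, ann) {
  if (nrow(ann) == 0L) return(integer(length(pos)))
  off <- integer(length(pos))
  for (sc in unique(ann$scaffold)) {
    a <- ann[ann$scaffold == sc, , drop = FALSE]
    a <- a[order(a$start_mic), , drop = FALSE]
    sel <- scaffold == sc
    ## offset accrued by IESs whose end lies at or before the position;
    ## for positions inside an IES this is the offset of its left flank
    cum <- cumsum(a$length - 2L)
    idx <- findInterval(pos[sel], a$end_mic)
    off[sel] <- c(0L, cum)[idx + 1L]
  }
  off
}

add_substitutions <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit)) {
      ch <- strsplit(s, "")[[1]]
      ch[hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
      s <- paste(ch, collapse = "")
    }
    s
  }, "", USE.NAMES = FALSE)
}

#' Write simulated genomic reads as FASTQ and truth SAM
#'
#' Emits one FASTQ of all reads plus one truth SAM per reference (reads are
#' recorded only against the reference consistent with their haplotype of
#' origin; flank reads appear in both).
#'
#' @param sim a `genomic_read_sim`.
#' @param dir output directory (created if needed).
#' @return named list of file paths (`fastq`, `mac_sam`, `mic_sam`).
#' @export
write_genomic_read_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- sim$reads
  fastq <- file.path(dir, "reads.fastq")
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+",
                             strrep("I", reads$length))), fastq)
  mic <- reads[!is.na(reads$mic_pos), , drop = FALSE]
  mac <- reads[!is.na(reads$mac_pos), , drop = FALSE]
  mic_sam <- file.path(dir, "reads_mic.sam")
  mac_sam <- file.path(dir, "reads_mac.sam")
  write_sam(data.frame(qname = mic$read_id, flag = 0L, scaffold = mic$scaffold,
                       pos = mic$mic_pos, seq = mic$seq), sim$genome$mic, mic_sam)
  write_sam(data.frame(qname = mac$read_id, flag = 0L, scaffold = mac$scaffold,
                       pos = mac$mac_pos, seq = mac$seq), sim$genome$mac, mac_sam)
  list(fastq = fastq, mac_sam = mac_sam, mic_sam = mic_sam)
}

#' Simulate MNase-protected fragments over weighted intervals
#'
#' Fragment midpoints land in interval *i* with per-bp rate proportional to
#' `weights[i]`; fragment lengths come from `frag_length_sampler`, whose
#' support is expected to include, and extend beyond, the 125–175 bp
#' mononucleosome band so that size filtering is exercised.
#'
#' @param reference `DNAStringSet` the fragments live on (MAC+IES).
#' @param annotation IES annotation data.frame (intervals).
#' @param weights strictly positive per-interval density weights, named by or
#'   ordered as `annotation$ies_id`.
#' @param n_fragments number of fragments to draw (> 0).
#' @param frag_length_sampler function `n -> integer lengths`; default is
#'   `round(rnorm(n, 150, 20))` truncated to \[80, 220\].
#' @param seed integer RNG seed.
#' @param library label for the emitted fragments.
#' @return data.frame `qname, scaffold, start, end, length, ies_id, library`
#'   (0-based half-open), class `mnase_frag_sim`.
#' @export
simulate_mnase_fragments <- function(reference, annotation, weights,
                                     n_fragments,
                                     frag_length_sampler = default_frag_length_sampler,
                                     seed = 1L, library = "mnase") {
  if (n_fragments <= 0) stop("n_fragments must be > 0")
  if (is.null(names(weights))) {
    stopifnot(length(weights) == nrow(annotation))
    names(weights) <- annotation$ies_id
  }
  w <- weights[annotation$ies_id]
  if (any(is.na(w)) || any(w <= 0)) stop("weights must be strictly positive")
  with_seed(seed, {
    lens <- annotation$end_mic - annotation$start_mic
    pick <- sample.int(nrow(annotation), n_fragments, replace = TRUE,
                       prob = w * lens)
    mid <- annotation$start_mic[pick] +
      as.integer(floor(runif(n_fragments) * lens[pick]))
    fl <- as.integer(frag_length_sampler(n_fragments))
    start <- mid - fl %/% 2L
    ref_len <- setNames(Biostrings::width(reference), names(reference))
    start <- pmax(0L, pmin(start, ref_len[annotation$scaffold[pick]] - fl))
    out <- data.frame(qname = sprintf("frag_%07d", seq_len(n_fragments)),
                      scaffold = annotation$scaffold[pick],
                      start = start,
                      end = start + fl,
                      length = fl,
                      ies_id = annotation$ies_id[pick],
                      library = library,
                      stringsAsFactors = FALSE)
    class(out) <- c("mnase_frag_sim", class(out))
    out
  })
}

#' @rdname simulate_mnase_fragments
#' @param n number of lengths to draw.
#' @export
default_frag_length_sampler <- function(n) {
  pmin(pmax(as.integer(round(stats::rnorm(n, 150, 20))), 80L), 220L)
}

#' Write simulated MNase fragments as a paired-end SAM
#'
#' @param frags result of [simulate_mnase_fragments()].
#' @param reference the `DNAStringSet` used for simulation.
#' @param path output SAM path.
#' @param read_len per-mate read length (bp).
#' @return `path`, invisibly.
#' @export
write_mnase_sam <- function(frags, reference, path, read_len = 50L) {
  write_sam_pairs(frags, reference, read_len, path)
}

#' Simulate small-RNA reads from length/class mixtures
#'
#' Draws reads from the three development-specific small-RNA classes of
#' *Paramecium*: 23 nt endo-siRNAs, 25 nt scnRNAs and 26–31 nt iesRNAs
#' (iesRNAs match exclusively to IES sequences). Each read is a substring of
#' a sequence from its class's source reference, reverse-complemented with
#' probability 1/2.
#'
#' @param class_mix named numeric vector of proportions over
#'   `c("siRNA", "scnRNA", "iesRNA")`; must sum to 1 within 1e-9.
#' @param sources named list of `DNAStringSet` source references, one per
#'   class (the iesRNA source must be the IES sequences).
#' @param n_reads number of reads.
#' @param seed integer RNG seed.
#' @return data.frame `read_id, class, length, source_seq, seq` with truth
#'   labels; `source_seq` is the name of the originating reference sequence.
#' @export
simulate_srna_reads <- function(class_mix, sources, n_reads, seed = 1L) {
  classes <- c("siRNA", "scnRNA", "iesRNA")
  stopifnot(setequal(names(class_mix), classes),
            abs(sum(class_mix) - 1) < 1e-9)
  lens_by_class <- list(siRNA = 23L, scnRNA = 25L, iesRNA = 26:31)
  for (cl in classes[class_mix[classes] > 0]) {
    src <- sources[[cl]]
    if (is.null(src) || length(src) == 0L || any(Biostrings::width(src) == 0))
      stop("class ", cl, " has an empty or zero-length source reference")
    if (min(Biostrings::width(src)) < max(lens_by_class[[cl]]))
      stop("class ", cl, " source sequences shorter than the read length")
  }
  with_seed(seed, {
    cls <- sample(classes, n_reads, replace = TRUE, prob = class_mix[classes])
    out <- lapply(classes, function(cl) {
      n <- sum(cls == cl)
      if (n == 0L) return(NULL)
      src <- sources[[cl]]
      src_chr <- as.character(src)
      nm <- names(src_chr) %||% as.character(seq_along(src_chr))
      rl <- sample(rep(lens_by_class[[cl]], 2L), n, replace = TRUE)
      pick <- sample.int(length(src_chr), n, replace = TRUE)
      maxs <- nchar(src_chr)[pick] - rl
      pos <- as.integer(floor(runif(n) * (maxs + 1)))
      s <- substring(src_chr[pick], pos + 1L, pos + rl)
      flip <- runif(n) < 0.5
      s[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s[flip])))
      data.frame(class = cl, length = rl, source_seq = nm[pick], seq = s,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out <- out[sample.int(nrow(out)), , drop = FALSE]  # shuffle class blocks
    out <- cbind(read_id = sprintf("srna_%06d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}
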