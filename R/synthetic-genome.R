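## Toy genome construction: paired somatic (MAC) and germline-inclusive
## (MAC+IES, "MIC") references with TA-bounded IESs at known positions.
##
## Coordinate convention: all internal coordinates are 0-based half-open.
## The stored IES sequence includes both terminal TAs; the excised (MAC) form
## keeps exactly one TA at the junction, so
##   mac = mic[0, start_mic) + mic[end_mic, ...)   with  mic[start_mic, start_mic+2) == "TA"
## and `junction_mac` is the 0-based start of the retained TA on the MAC scaffold.

#' Specification for a synthetic toy genome
#'
#' Bundles the parameters of [build_toy_genome()]. The IES length sampler must
#' never return lengths below 26 bp, the minimum IES length observed in
#' *Paramecium*; the default sampler draws `26 + rexp(mean = 45)` rounded,
#' which puts about 93% of lengths under 150 bp, matching the short-biased
#' length profile of the system.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length length of each MAC scaffold in bp.
#' @param n_ies total number of IESs across all scaffolds.
#' @param ies_length_sampler function `n -> integer vector` of IES lengths
#'   (bp, all >= 26).
#' @param gc_content GC fraction of the background sequence, in \[0, 1\].
#' @param min_flank minimum distance (bp) between IES junctions and from a
#'   junction to a scaffold end; keeps IESs non-adjacent so short reads span
#'   at most one IES.
#' @param seed integer RNG seed; all outputs are byte-identical under a fixed
#'   seed.
#' @return a list of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(n_scaffolds = 5L, scaffold_length = 25000L,
                            n_ies = 200L,
                            ies_length_sampler = default_ies_length_sampler,
                            gc_content = 0.28, min_flank = 300L, seed = 1L) {
  stopifnot(n_scaffolds >= 1L, scaffold_length >= 1L, n_ies >= 0L,
            is.function(ies_length_sampler),
            gc_content >= 0, gc_content <= 1, min_flank >= 1L)
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length = as.integer(scaffold_length),
                 n_ies = as.integer(n_ies),
                 ies_length_sampler = ies_length_sampler,
                 gc_content = gc_content,
                 min_flank = as.integer(min_flank),
                 seed = as.integer(seed)),
            class = "toy_genome_spec")
}

#' Default IES length sampler
#'
#' Lengths are `26 + round(rexp(n, rate = 1/45))`, capped at `max_len`.
#' The exponential tail reproduces the strongly short-biased IES length
#' profile (roughly 93% below 150 bp) without asserting a particular
#' biological distribution shape.
#'
#' @param n number of lengths to draw.
#' @param max_len upper cap in bp.
#' @return integer vector of lengths, all >= 26.
#' @export
default_ies_length_sampler <- function(n, max_len = 400L) {
  pmin(26L + as.integer(round(rexp(n, rate = 1 / 45))), as.integer(max_len))
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Build a toy MAC / MAC+IES reference pair with known IES annotation
#'
#' Generates `n_scaffolds` i.i.d.-background MAC scaffolds, plants `n_ies`
#' TA junctions, and inserts a TA-bounded IES at each junction to produce the
#' germline-inclusive (MIC, "MAC+IES") reference. Excising every annotated
#' IES and retaining a single TA per junction reproduces the MAC reference
#' byte-for-byte.
#'
#' @param spec a [toy_genome_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{mac}{[Biostrings::DNAStringSet] somatic reference.}
#'     \item{mic}{[Biostrings::DNAStringSet] germline-inclusive reference.}
#'     \item{annotation}{data.frame with columns `ies_id, scaffold,
#'       start_mic, end_mic, junction_mac, length, sequence` (0-based
#'       half-open coordinates).}
#'   }
#' @export
build_toy_genome <- function(spec) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  with_seed(spec$seed, {
    n_per <- diff(floor(seq(0, spec$n_ies, length.out = spec$n_scaffolds + 1)))
    lo <- spec$min_flank
    hi <- spec$scaffold_length - spec$min_flank - 2L
    n_slots <- if (hi < lo) 0L else (hi - lo) %/% spec$min_flank + 1L
    if (any(n_per > n_slots))
      stop("requested IESs do not fit: scaffold_length ", spec$scaffold_length,
           " holds at most ", n_slots, " IESs at min_flank ", spec$min_flank)
    scafs <- sprintf("scaffold_%02d", seq_len(spec$n_scaffolds))
    mac <- character(spec$n_scaffolds)
    mic <- character(spec$n_scaffolds)
    ann <- vector("list", spec$n_scaffolds)
    for (k in seq_len(spec$n_scaffolds)) {
      seq_mac <- random_dna(spec$scaffold_length, spec$gc_content)
      nk <- n_per[k]
      if (nk > 0L) {
        ## junction slots on a min_flank grid, jittered by < min_flank/4 so
        ## consecutive junctions stay >= 3/4 min_flank apart
        slots <- sort(sample.int(n_slots, nk) - 1L) * spec$min_flank + lo
        jit <- as.integer(floor(runif(nk, 0, spec$min_flank %/% 4)))
        junctions <- slots + jit
        for (j in junctions)  # plant the shared TA on the MAC scaffold
          substr(seq_mac, j + 1L, j + 2L) <- "TA"
        lens <- spec$ies_length_sampler(nk)
        if (any(lens < 26L)) stop("ies_length_sampler returned a length < 26 bp")
        cores <- vapply(lens - 4L, random_dna, "", gc = spec$gc_content)
        ies_seq <- paste0("TA", cores, "TA")
        ## assemble MIC: insert IES in place of the retained TA
        pieces <- character(2L * nk + 1L)
        prev <- 0L
        for (i in seq_len(nk)) {
          pieces[2L * i - 1L] <- substr(seq_mac, prev + 1L, junctions[i])
          pieces[2L * i] <- ies_seq[i]
          prev <- junctions[i] + 2L
        }
        pieces[2L * nk + 1L] <- substr(seq_mac, prev + 1L, spec$scaffold_length)
        seq_mic <- paste(pieces, collapse = "")
        offset <- c(0L, cumsum(lens - 2L))[seq_len(nk)]
        start_mic <- junctions + offset
        ann[[k]] <- data.frame(
          ies_id = sprintf("ies_%s_%03d", sub("scaffold_", "", scafs[k]),
                           seq_len(nk)),
          scaffold = scafs[k],
          start_mic = start_mic,
          end_mic = start_mic + lens,
          junction_mac = junctions,
          length = lens,
          sequence = ies_seq,
          stringsAsFactors = FALSE)
      } else {
        seq_mic <- seq_mac
        ann[[k]] <- NULL
      }
      mac[k] <- seq_mac
      mic[k] <- seq_mic
    }
    annotation <- if (all(vapply(ann, is.null, TRUE)))
      empty_annotation() else do.call(rbind, ann)
    rownames(annotation) <- NULL
    mac <- Biostrings::DNAStringSet(setNames(mac, scafs))
    mic <- Biostrings::DNAStringSet(setNames(mic, scafs))
    list(mac = mac, mic = mic, annotation = annotation)
  })
}

empty_annotation <- function() {
  data.frame(ies_id = character(), scaffold = character(),
             start_mic = integer(), end_mic = integer(),
             junction_mac = integer(), length = integer(),
             sequence = character(), stringsAsFactors = FALSE)
}

#' Excise annotated IESs from a germline-inclusive reference
#'
#' String-surgery inverse of [build_toy_genome()]: removes every annotated
#' interval `[start_mic, end_mic)` and retains a single TA per junction.
#' Used as the round-trip check that the annotation is exact.
#'
#' @param mic `DNAStringSet` germline-inclusive reference.
#' @param annotation IES annotation data.frame (see [build_toy_genome()]).
#' @return `DNAStringSet` of excised (MAC-form) scaffolds.
#' @export
excise_ies <- function(mic, annotation) {
  seqs <- as.character(mic)
  out <- vapply(names(seqs), function(sc) {
    s <- seqs[[sc]]
    a <- annotation[annotation$scaffold == sc, , drop = FALSE]
    if (nrow(a) == 0L) return(s)
    a <- a[order(a$start_mic), , drop = FALSE]
    pieces <- character(nrow(a) + 1L)
    prev <- 0L
    for (i in seq_len(nrow(a))) {
      ## keep the left flank plus one TA of the IES
      pieces[i] <- substr(s, prev + 1L, a$start_mic[i] + 2L)
      prev <- a$end_mic[i]
    }
    pieces[nrow(a) + 1L] <- substr(s, prev + 1L, nchar(s))
    paste(pieces, collapse = "")
  }, "")
  Biostrings::DNAStringSet(setNames(out, names(seqs)))
}

#' Write an IES annotation as GFF3
#'
#' Features use type `internal_eliminated_sequence` on the MAC+IES reference
#' with 1-based inclusive coordinates and an `ID` attribute equal to
#' `ies_id`.
#'
#' @param annotation IES annotation data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ies_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$scaffold,
    ranges = IRanges::IRanges(start = annotation$start_mic + 1L,
                              end = annotation$end_mic),
    type = "internal_eliminated_sequence",
    ID = annotation$ies_id,
    junction_mac = annotation$junction_mac)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an IES annotation from GFF3 or BED
#'
#' Accepts GFF3 written by [write_ies_gff3()] (or any GFF3/BED whose records
#' are IES intervals on the MAC+IES reference). Returns 0-based half-open
#' coordinates. `junction_mac` is taken from a `junction_mac` attribute when
#' present, otherwise reconstructed from the cumulative excised length of the
#' preceding IESs on each scaffold.
#'
#' @param path GFF3 or BED file.
#' @return IES annotation data.frame (without sequences).
#' @export
read_ies_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID)
         else if ("name" %in% names(md)) as.character(md$name)
         else sprintf("ies_%05d", seq_along(gr))
  ann <- data.frame(
    ies_id = ids,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start_mic = GenomicRanges::start(gr) - 1L,
    end_mic = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  ann$length <- ann$end_mic - ann$start_mic
  ann <- ann[order(ann$scaffold, ann$start_mic), , drop = FALSE]
  if ("junction_mac" %in% names(md)) {
    ann$junction_mac <- as.integer(md$junction_mac[match(ann$ies_id, ids)])
  } else {
    ## ann is sorted by (scaffold, start), so split() concatenates in row order
    ann$junction_mac <- unlist(lapply(split(ann, ann$scaffold), function(a) {
      a$start_mic - c(0L, cumsum(a$length - 2L))[seq_len(nrow(a))]
    }), use.names = FALSE)
  }
  rownames(ann) <- NULL
  ann[, c("ies_id", "scaffold", "start_mic", "end_mic", "junction_mac",
          "length")]
}

## Annotation as GRanges on the MAC+IES reference (1-based, for overlap work).
annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$scaffold,
    ranges = IRanges::IRanges(start = annotation$start_mic + 1L,
                              end = annotation$end_mic),
    ies_id = annotation$ies_id)
}
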