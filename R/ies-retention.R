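## IES retention scoring from dual-reference alignments.
##
## A read supports the IES+ (retained) form when its alignment on the
## MAC+IES reference crosses an IES boundary with at least `anchor` aligned
## bases on each side; it supports the excised form when its MAC alignment
## crosses the collapsed junction with at least `anchor` aligned bases on
## each side of the retained TA. The retained TA itself matches both forms
## and is therefore excluded from the MAC-side anchors.

#' Count junction-supporting reads for each IES
#'
#' @param mic_alignments SAM/BAM path or `GAlignments` against the MAC+IES
#'   reference.
#' @param mac_alignments SAM/BAM path or `GAlignments` against the MAC
#'   reference.
#' @param annotation IES annotation data.frame (see [build_toy_genome()] /
#'   [read_ies_annotation()]).
#' @param anchor minimum aligned bases required on each side of a boundary
#'   or junction (bp, >= 1).
#' @return data.frame `ies_id, left_plus, right_plus, mac_minus, anchor` —
#'   one row per annotated IES.
#' @export
count_junction_reads <- function(mic_alignments, mac_alignments, annotation,
                                 anchor = 5L) {
  stopifnot(anchor >= 1L)
  mic_ga <- if (is.character(mic_alignments)) read_alignments(mic_alignments)
            else mic_alignments
  mac_ga <- if (is.character(mac_alignments)) read_alignments(mac_alignments)
            else mac_alignments
  miss_mic <- setdiff(annotation$scaffold, GenomeInfoDb::seqlevels(mic_ga))
  miss_mac <- setdiff(annotation$scaffold, GenomeInfoDb::seqlevels(mac_ga))
  if (length(miss_mic) || length(miss_mac))
    stop("annotation scaffolds absent from alignment header: ",
         paste(unique(c(miss_mic, miss_mac)), collapse = ", "))

  ## windows that must be entirely covered by a read's aligned span
  ## (coordinates 1-based inclusive below)
  left_w <- GenomicRanges::GRanges(annotation$scaffold,
    IRanges::IRanges(start = annotation$start_mic - anchor + 1L,
                     end = annotation$start_mic + anchor))
  right_w <- GenomicRanges::GRanges(annotation$scaffold,
    IRanges::IRanges(start = annotation$end_mic - anchor + 1L,
                     end = annotation$end_mic + anchor))
  mac_w <- GenomicRanges::GRanges(annotation$scaffold,
    IRanges::IRanges(start = annotation$junction_mac - anchor + 1L,
                     end = annotation$junction_mac + 2L + anchor))

  mic_gr <- GenomicRanges::granges(mic_ga)
  mac_gr <- GenomicRanges::granges(mac_ga)
  hits_l <- GenomicRanges::findOverlaps(left_w, mic_gr, type = "within")
  hits_r <- GenomicRanges::findOverlaps(right_w, mic_gr, type = "within")
  hits_m <- GenomicRanges::findOverlaps(mac_w, mac_gr, type = "within")

  ## a read never supports both + and - of the same IES: drop its excised
  ## support when it already supports a boundary of that IES
  plus_keys <- c(paste(S4Vectors::queryHits(hits_l),
                       names(mic_ga)[S4Vectors::subjectHits(hits_l)]),
                 paste(S4Vectors::queryHits(hits_r),
                       names(mic_ga)[S4Vectors::subjectHits(hits_r)]))
  minus_keys <- paste(S4Vectors::queryHits(hits_m),
                      names(mac_ga)[S4Vectors::subjectHits(hits_m)])
  keep_m <- !(minus_keys %in% plus_keys)

  data.frame(
    ies_id = annotation$ies_id,
    left_plus = tabulate(S4Vectors::queryHits(hits_l), nrow(annotation)),
    right_plus = tabulate(S4Vectors::queryHits(hits_r), nrow(annotation)),
    mac_minus = tabulate(S4Vectors::queryHits(hits_m)[keep_m],
                         nrow(annotation)),
    anchor = anchor,
    stringsAsFactors = FALSE)
}

#' Compute IES retention scores from junction counts
#'
#' The global score pools both boundaries:
#' `irs = (left_plus + right_plus) / (left_plus + right_plus + 2 * mac_minus)`,
#' the boundary-symmetric convention (each retained read supports one of two
#' boundaries while each excised read supports the single junction, hence the
#' factor 2). Per-boundary scores `left_plus / (left_plus + mac_minus)` and
#' `right_plus / (right_plus + mac_minus)` are also emitted. A score is
#' undefined (`NA`, `coverage_ok = FALSE`) when no junction-informative read
#' exists.
#'
#' @param counts data.frame from [count_junction_reads()].
#' @param condition label stored as the `condition` attribute of the result.
#' @return data.frame (an IRS table) with columns `ies_id, left_plus,
#'   right_plus, mac_minus, irs_left, irs_right, irs, coverage_ok`.
#' @export
compute_irs <- function(counts, condition = "condition") {
  lp <- counts$left_plus; rp <- counts$right_plus; mm <- counts$mac_minus
  stopifnot(all(lp >= 0), all(rp >= 0), all(mm >= 0))
  denom <- lp + rp + 2 * mm
  out <- data.frame(
    ies_id = counts$ies_id,
    left_plus = lp, right_plus = rp, mac_minus = mm,
    irs_left = ifelse(lp + mm > 0, lp / (lp + mm), NA_real_),
    irs_right = ifelse(rp + mm > 0, rp / (rp + mm), NA_real_),
    irs = ifelse(denom > 0, (lp + rp) / denom, NA_real_),
    coverage_ok = denom > 0,
    stringsAsFactors = FALSE)
  attr(out, "condition") <- condition
  out
}

#' Classify IESs as retained by an IRS cutoff
#'
#' An IES is retained when its score is defined and **strictly** greater
#' than `threshold` (retention is called with `IRS > 0.1` by default; a
#' score of exactly 0.1 is not retained). Undefined scores are never
#' retained and are reported separately.
#'
#' @param irs_table IRS table (data.frame with `ies_id` and `irs`).
#' @param threshold retention cutoff in \[0, 1).
#' @return list with `retained` (character ids), `undefined` (ids with no
#'   defined score) and `n_undefined`.
#' @export
classify_retention <- function(irs_table, threshold = 0.1) {
  stopifnot(threshold >= 0, threshold < 1)
  undef <- irs_table$ies_id[is.na(irs_table$irs)]
  retained <- irs_table$ies_id[!is.na(irs_table$irs) &
                                 irs_table$irs > threshold]
  list(retained = retained, undefined = undef, n_undefined = length(undef))
}

#' Write / read an IRS table as TSV
#'
#' `read_irs_table()` also accepts a multi-condition table (one `ies_id`
#' column plus one numeric column per silencing condition, the layout of
#' published per-IES retention supplements); in that case a named list of
#' IRS tables is returned.
#'
#' @param irs_table an IRS table.
#' @param path TSV file path.
#' @return `write_irs_table()`: `path` invisibly. `read_irs_table()`: an IRS
#'   table data.frame, or a named list of minimal tables (`ies_id`, `irs`)
#'   for multi-condition input.
#' @export
write_irs_table <- function(irs_table, path) {
  write.table(irs_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_irs_table
#' @export
read_irs_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot("ies_id" %in% names(x))
  if ("irs" %in% names(x)) return(x)
  conds <- setdiff(names(x), "ies_id")
  setNames(lapply(conds, function(cn) {
    out <- data.frame(ies_id = x$ies_id, irs = as.numeric(x[[cn]]),
                      stringsAsFactors = FALSE)
    attr(out, "condition") <- cn
    out
  }), conds)
}
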