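## Priority-ordered small-RNA classification by iterative matching with
## read subtraction: each read is assigned the first reference in the
## hierarchy that it matches full-length (either strand by default), and is
## removed from consideration before the next reference; reads matching
## nothing are `unclassified`. This mirrors iterative alignment with read
## subtraction while keeping the matcher pluggable at desk scale.

#' Construct an ordered reference hierarchy for sRNA classification
#'
#' The default compartment order puts contaminant sources first and the most
#' specific genomic class (IES) before the genome-wide class (MDS):
#' vector, host bacterium, TE, OES, IES, MDS.
#'
#' @param references named list of `DNAStringSet`s, in priority order.
#' @param max_mismatch maximum mismatches for a full-length match.
#' @param both_strands also match the reverse complement of each read.
#' @return list of class `srna_hierarchy`.
#' @export
srna_hierarchy <- function(references, max_mismatch = 0L,
                           both_strands = TRUE) {
  stopifnot(length(references) >= 1L, !is.null(names(references)),
            !anyDuplicated(names(references)))
  for (nm in names(references)) {
    r <- references[[nm]]
    if (length(r) == 0L || any(Biostrings::width(r) == 0L))
      stop("empty reference sequence under label ", nm)
  }
  structure(list(references = references,
                 labels = names(references),
                 max_mismatch = as.integer(max_mismatch),
                 both_strands = isTRUE(both_strands)),
            class = "srna_hierarchy")
}

#' Classify small-RNA reads against a reference hierarchy
#'
#' @param reads a `DNAStringSet` (named), a character vector of sequences,
#'   or the data.frame returned by [simulate_srna_reads()].
#' @param hierarchy an [srna_hierarchy()].
#' @return data.frame `read_id, length, label, matched_feature`; the label
#'   is one of the hierarchy labels or `"unclassified"`, and
#'   `matched_feature` names the first matching sequence within the
#'   assigned reference (used downstream as the source IES of IES-matching
#'   reads).
#' @export
classify_reads <- function(reads, hierarchy) {
  stopifnot(inherits(hierarchy, "srna_hierarchy"))
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    seqs <- reads$seq
  } else if (methods::is(reads, "DNAStringSet")) {
    ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
    seqs <- as.character(reads)
  } else {
    ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
    seqs <- as.character(reads)
  }
  lens <- nchar(seqs)
  if (any(lens < 15L) || any(lens > 45L))
    stop("read lengths outside the 15-45 nt sanity bounds")
  label <- rep("unclassified", length(seqs))
  feature <- rep(NA_character_, length(seqs))
  remaining <- seq_along(seqs)
  for (lab in hierarchy$labels) {
    if (!length(remaining)) break
    hit <- match_reads(seqs[remaining], hierarchy$references[[lab]],
                       hierarchy$max_mismatch, hierarchy$both_strands)
    got <- !is.na(hit)
    label[remaining[got]] <- lab
    feature[remaining[got]] <-
      (names(hierarchy$references[[lab]]) %||%
         as.character(seq_along(hierarchy$references[[lab]])))[hit[got]]
    remaining <- remaining[!got]   # subtraction: matched reads leave the pool
  }
  data.frame(read_id = ids, length = lens, label = label,
             matched_feature = feature, stringsAsFactors = FALSE)
}

## For each read sequence, the index of the first reference sequence it
## matches full-length (<= max_mismatch, optionally either strand), or NA.
## 0-mismatch matching uses a PDict per read-length group; the k-mismatch
## path scans reads individually.
match_reads <- function(seqs, ref, max_mismatch, both_strands) {
  hit <- rep(NA_integer_, length(seqs))
  queries <- list(Biostrings::DNAStringSet(seqs))
  if (both_strands)
    queries <- c(queries, list(Biostrings::reverseComplement(queries[[1]])))
  for (q in queries) {
    todo <- which(is.na(hit))
    if (!length(todo)) break
    if (max_mismatch == 0L) {
      by_len <- split(todo, Biostrings::width(q)[todo])
      for (grp in by_len) {
        pd <- Biostrings::PDict(q[grp])
        for (j in seq_along(ref)) {
          idx <- grp[is.na(hit[grp])]
          if (!length(idx)) break
          found <- Biostrings::whichPDict(pd, ref[[j]])
          found <- grp[found]
          found <- found[is.na(hit[found])]
          hit[found] <- j
        }
      }
    } else {
      for (i in todo) {
        cnt <- Biostrings::vcountPattern(as.character(q[[i]]), ref,
                                         max.mismatch = max_mismatch)
        j <- which(cnt > 0)
        if (length(j)) hit[i] <- j[1]
      }
    }
  }
  hit
}

#' Length-by-compartment composition of a classified read set
#'
#' @param classified data.frame from [classify_reads()].
#' @return list of class `srna_composition`: `proportions` (matrix
#'   length x label, summing to 1 over all cells), `counts` (same shape),
#'   `total`.
#' @export
composition_profile <- function(classified) {
  if (nrow(classified) == 0L) stop("no reads to profile")
  counts <- table(factor(classified$length,
                         levels = sort(unique(classified$length))),
                  classified$label)
  counts <- unclass(counts)
  structure(list(proportions = counts / sum(counts), counts = counts,
                 total = nrow(classified)),
            class = "srna_composition")
}

#' scnRNA scanning ratio (IES-matching over MAC-matching at 25 nt)
#'
#' By late development the scanning process has degraded MAC-matching
#' scnRNAs, so a ratio well above its early-stage value indicates that
#' scanning occurred.
#'
#' @param classified data.frame from [classify_reads()].
#' @param scn_length scnRNA length in nt.
#' @param ies_label,mds_label hierarchy labels of the IES and MAC (MDS)
#'   compartments.
#' @return list `ratio` (numeric or NA), `n_ies`, `n_mds`, `defined`.
#' @export
scnrna_scanning_ratio <- function(classified, scn_length = 25L,
                                  ies_label = "IES", mds_label = "MDS") {
  at_len <- classified[classified$length == scn_length, , drop = FALSE]
  n_ies <- sum(at_len$label == ies_label)
  n_mds <- sum(at_len$label == mds_label)
  list(ratio = if (n_mds > 0) n_ies / n_mds else NA_real_,
       n_ies = n_ies, n_mds = n_mds, defined = n_mds > 0)
}

#' Contribution of retained IESs to the iesRNA pool
#'
#' iesRNAs are IES-matching reads of 26–31 nt. For each retention threshold
#' `t`, the contribution is the fraction of feature-assigned iesRNA reads
#' whose source IES has `IRS > t`. Larger thresholds select smaller
#' retained sets, so the fraction is monotone non-increasing in `t`.
#'
#' @param classified data.frame from [classify_reads()].
#' @param irs_table IRS table for the silencing condition.
#' @param thresholds retention cutoffs to evaluate.
#' @param ies_lengths optional named vector `ies_id -> bp` for per-bp
#'   normalised counts.
#' @param ies_label hierarchy label of the IES compartment.
#' @return list: `fractions` (named by threshold), `n_iesrna`,
#'   `n_unassigned` (iesRNA reads without a matched feature, excluded from
#'   the denominator), `per_ies` (data.frame `ies_id, count, count_per_bp`).
#' @export
iesrna_contribution <- function(classified, irs_table,
                                thresholds = c(0.1, 0.01),
                                ies_lengths = NULL, ies_label = "IES") {
  ies_reads <- classified[classified$label == ies_label &
                            classified$length >= 26L &
                            classified$length <= 31L, , drop = FALSE]
  unassigned <- is.na(ies_reads$matched_feature)
  assigned <- ies_reads[!unassigned, , drop = FALSE]
  irs <- setNames(irs_table$irs, irs_table$ies_id)[assigned$matched_feature]
  fractions <- vapply(thresholds, function(t) {
    if (nrow(assigned) == 0L) return(NA_real_)
    sum(!is.na(irs) & irs > t) / nrow(assigned)
  }, numeric(1))
  names(fractions) <- as.character(thresholds)
  per_ies <- as.data.frame(table(assigned$matched_feature),
                           stringsAsFactors = FALSE)
  names(per_ies) <- c("ies_id", "count")
  per_ies$count_per_bp <- if (!is.null(ies_lengths))
    per_ies$count / unname(ies_lengths[per_ies$ies_id]) else NA_real_
  list(fractions = fractions, n_iesrna = nrow(ies_reads),
       n_unassigned = sum(unassigned), per_ies = per_ies)
}
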