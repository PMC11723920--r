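## Per-IES nucleosome density from MNase and input fragment libraries:
## mononucleosome size filtering, library downsampling, interval counting,
## density = (MNase count / MNase total) / (input count / input total),
## and Mann-Whitney U tests under Holm-Bonferroni correction.

#' Filter fragments to the mononucleosome size band
#'
#' Keeps fragments with `min_len <= length <= max_len`, inclusive at both
#' ends (125 and 175 bp are kept by default; 124 and 176 bp are not).
#'
#' @param fragments data.frame with a `length` column (see
#'   [read_fragments()] / [simulate_mnase_fragments()]).
#' @param min_len,max_len inclusive bounds in bp.
#' @return the kept fragments, with attribute `n_discarded`.
#' @export
filter_fragments <- function(fragments, min_len = 125L, max_len = 175L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  keep <- fragments$length >= min_len & fragments$length <= max_len
  out <- fragments[keep, , drop = FALSE]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Downsample libraries in a group to a common size
#'
#' All libraries are reduced to the smallest library's fragment count by
#' sampling without replacement; deterministic under `seed`.
#'
#' @param libraries named list of fragment data.frames.
#' @param seed integer RNG seed.
#' @return named list of equal-sized fragment data.frames.
#' @export
downsample_libraries <- function(libraries, seed = 1L) {
  stopifnot(length(libraries) >= 2L)
  sizes <- vapply(libraries, nrow, integer(1))
  if (any(sizes == 0L)) stop("empty library: ",
                             paste(names(libraries)[sizes == 0L], collapse = ", "))
  target <- min(sizes)
  with_seed(seed, lapply(libraries, function(lib) {
    lib[sample.int(nrow(lib), target), , drop = FALSE]
  }))
}

#' Count fragments over IES intervals
#'
#' `any-overlap` counts a fragment for every IES it overlaps by at least
#' 1 bp; `midpoint` counts it for the unique IES containing its midpoint
#' (the lower of the two central bases for even-length fragments).
#'
#' @param fragments fragment data.frame (0-based half-open `start`, `end`).
#' @param annotation IES annotation data.frame.
#' @param mode `"any-overlap"` or `"midpoint"`.
#' @param scaffolds optional character vector of reference scaffold names
#'   (e.g. from the SAM header); when given, annotation scaffolds outside
#'   it are a reference-mismatch error.
#' @return named integer vector `ies_id -> count`.
#' @export
count_over_intervals <- function(fragments, annotation,
                                 mode = c("any-overlap", "midpoint"),
                                 scaffolds = NULL) {
  mode <- match.arg(mode)
  if (!is.null(scaffolds)) {
    bad <- setdiff(annotation$scaffold, scaffolds)
    if (length(bad))
      stop("annotation scaffolds absent from the reference: ",
           paste(bad, collapse = ", "))
  }
  ies_gr <- annotation_granges(annotation)
  if (mode == "any-overlap") {
    frag_gr <- GenomicRanges::GRanges(fragments$scaffold,
      IRanges::IRanges(start = fragments$start + 1L, end = fragments$end))
  } else {
    mid <- fragments$start + (fragments$length - 1L) %/% 2L
    frag_gr <- GenomicRanges::GRanges(fragments$scaffold,
      IRanges::IRanges(start = mid + 1L, width = 1L))
  }
  counts <- GenomicRanges::countOverlaps(ies_gr, frag_gr)
  setNames(as.integer(counts), annotation$ies_id)
}

#' Dimensionless per-IES nucleosome density
#'
#' `density = (mnase_count / mnase_total) / (input_count / input_total)`;
#' undefined (`NA`) when the input count is zero. Totals are the
#' post-downsampling mapped-fragment totals of each library, so the density
#' is invariant under rescaling both libraries by a common factor.
#'
#' @param mnase_counts,input_counts named integer vectors `ies_id -> count`.
#' @param mnase_total,input_total library totals (> 0).
#' @return data.frame `ies_id, mnase_count, input_count, density` with
#'   attribute `n_undefined`.
#' @export
compute_density <- function(mnase_counts, input_counts, mnase_total,
                            input_total) {
  stopifnot(mnase_total > 0, input_total > 0)
  if (any(mnase_counts < 0) || any(input_counts < 0))
    stop("negative counts")
  ids <- names(mnase_counts)
  stopifnot(identical(ids, names(input_counts)))
  dens <- ifelse(input_counts > 0,
                 (mnase_counts / mnase_total) / (input_counts / input_total),
                 NA_real_)
  out <- data.frame(ies_id = ids,
                    mnase_count = as.integer(mnase_counts),
                    input_count = as.integer(input_counts),
                    density = unname(dens),
                    stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- sum(input_counts == 0)
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed with midranks for ties. The p-value is exact (enumeration
#' over rank assignments) when `n_x + n_y <= 12` and there are no ties,
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @return list `U, p, n_x, n_y, method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_x = length(x), n_y = length(y),
       method = if (exact) "exact" else "normal approximation")
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, in the input order, elementwise >= raw and
#'   capped at 1.
#' @export
holm_bonferroni <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must be in [0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Run a family of two-group density comparisons
#'
#' Each comparison is a pair of density vectors (undefined densities already
#' excluded); the Holm family is all comparisons in one invocation.
#'
#' @param comparisons named list of `list(x =, y =)` numeric pairs.
#' @return data.frame `comparison, U, p_raw, p_adj, n_x, n_y`.
#' @export
density_tests <- function(comparisons) {
  res <- lapply(comparisons, function(cmp) mann_whitney_u(cmp$x, cmp$y))
  out <- data.frame(comparison = names(comparisons),
                    U = vapply(res, `[[`, numeric(1), "U"),
                    p_raw = vapply(res, `[[`, numeric(1), "p"),
                    n_x = vapply(res, `[[`, integer(1), "n_x"),
                    n_y = vapply(res, `[[`, integer(1), "n_y"),
                    stringsAsFactors = FALSE)
  out$p_adj <- holm_bonferroni(out$p_raw)
  rownames(out) <- NULL
  out[, c("comparison", "U", "p_raw", "p_adj", "n_x", "n_y")]
}

#' Five-number boxplot summary with 1.5 IQR whiskers
#'
#' Quartiles by linear interpolation between order statistics; whiskers at
#' the most extreme data points within `[q1 - 1.5 IQR, q3 + 1.5 IQR]`;
#' points beyond the whiskers are outliers.
#'
#' @param values non-empty numeric vector.
#' @return list `median, q1, q3, whisker_lo, whisker_hi, outliers`.
#' @export
box_summary <- function(values) {
  if (!length(values)) stop("empty input")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(values[inside]),
       whisker_hi = max(values[inside]),
       outliers = values[!inside])
}
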