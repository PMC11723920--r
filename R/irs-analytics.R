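## Ensemble analyses of IRS tables: retention histograms, size
## stratification, subset overlaps (Venn partitions), and cross-condition
## correlation with OLS, LOWESS and orthogonal-distance (total least
## squares) trends.

#' Histogram of retention scores above a cutoff
#'
#' Bins the defined scores strictly greater than `min_irs` into
#' `[min_irs, 1]` with bins of width `bin_width`; the last bin is closed on
#' the right. Total histogram mass equals the number of records passing the
#' filter.
#'
#' @param irs_table IRS table.
#' @param bin_width bin width in (0, 1].
#' @param min_irs lower cutoff (strict, matching retention calling).
#' @return data.frame `bin_lo, bin_hi, count`.
#' @export
retention_histogram <- function(irs_table, bin_width = 0.05, min_irs = 0.1) {
  stopifnot(bin_width > 0, bin_width <= 1)
  v <- irs_table$irs[!is.na(irs_table$irs) & irs_table$irs > min_irs]
  breaks <- seq(min_irs, 1, by = bin_width)
  if (tail(breaks, 1) < 1) breaks <- c(breaks, 1)
  idx <- pmin(findInterval(v, breaks, rightmost.closed = TRUE),
              length(breaks) - 1L)
  data.frame(bin_lo = breaks[-length(breaks)],
             bin_hi = breaks[-1],
             count = tabulate(idx, length(breaks) - 1L))
}

#' Stratify an IES subset by length
#'
#' Splits the subset at the given length cutoffs and reports the fraction of
#' the subset in each stratum; when `reference_ids` is supplied (e.g. the
#' all-IES set retained after excisase knockdown) the per-stratum fraction
#' of the reference subset captured by `ids` is reported as well.
#'
#' @param ids character vector of IES ids (the subset).
#' @param lengths named numeric vector `ies_id -> length` (bp).
#' @param cutoffs increasing length cutoffs in bp; strata are
#'   `(-Inf, c1), [c1, c2), ..., [ck, Inf)`.
#' @param reference_ids optional reference subset for relative fractions.
#' @return data.frame `stratum, n, fraction` (+ `n_reference,
#'   fraction_of_reference` when a reference is given); zero rows and an
#'   `empty` attribute for an empty subset.
#' @export
size_stratify <- function(ids, lengths, cutoffs, reference_ids = NULL) {
  missing <- setdiff(ids, names(lengths))
  if (length(missing))
    stop("no length for ids: ", paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  cutoffs <- sort(cutoffs)
  labs <- c(sprintf("<%g", cutoffs[1]),
            if (length(cutoffs) > 1)
              sprintf("[%g,%g)", cutoffs[-length(cutoffs)], cutoffs[-1]),
            sprintf(">=%g", cutoffs[length(cutoffs)]))
  strat <- function(v) tabulate(findInterval(v, cutoffs) + 1L,
                                length(cutoffs) + 1L)
  if (length(ids) == 0L) {
    out <- data.frame(stratum = labs, n = 0L, fraction = NA_real_)
    attr(out, "empty") <- TRUE
    return(out)
  }
  n <- strat(lengths[ids])
  out <- data.frame(stratum = labs, n = n, fraction = n / sum(n))
  if (!is.null(reference_ids)) {
    missing_ref <- setdiff(reference_ids, names(lengths))
    if (length(missing_ref))
      stop("no length for reference ids: ",
           paste(head(missing_ref, 5), collapse = ", "))
    nr <- strat(lengths[reference_ids])
    out$n_reference <- nr
    out$fraction_of_reference <- ifelse(nr > 0, n / nr, NA_real_)
  }
  out
}

#' Venn partition of two or three IES subsets
#'
#' @param subsets named list of 2 or 3 character vectors of ids.
#' @return data.frame `region, count`; regions are exclusive, and counts sum
#'   to the size of the union.
#' @export
subset_overlap <- function(subsets) {
  k <- length(subsets)
  if (k < 2L || k > 3L) stop("subset_overlap takes 2 or 3 subsets")
  nms <- names(subsets) %||% LETTERS[seq_len(k)]
  subsets <- lapply(subsets, unique)
  all_ids <- unique(unlist(subsets))
  member <- vapply(subsets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(m) paste(nms[m], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(m)
    apply(utils::combn(nms, m), 2, paste, collapse = "&")))
  data.frame(region = combos,
             count = as.integer(table(factor(key, levels = combos))),
             stringsAsFactors = FALSE)
}

#' Correlate retention scores between two conditions
#'
#' Computed on the intersection of ids with a defined score in both tables
#' (pairwise deletion, never imputation). Fits three trends: ordinary least
#' squares, LOWESS (tricube local linear smoother, 3 robustness iterations),
#' and orthogonal distance regression — the total-least-squares line
#' minimising perpendicular distances, obtained from the second-moment
#' principal axis. Hexagonal-bin counts (pointy-top hexagons) are attached
#' for plotting; they conserve the number of points.
#'
#' @param x_table,y_table IRS tables for the two conditions.
#' @param lowess_fraction LOWESS smoother span in (0, 1].
#' @param nbins number of hexagon columns across the x range.
#' @return list of class `irs_correlation`: `pearson_r`, `ols`
#'   (intercept/slope), `odr` (intercept/slope), `lowess` (x, y),
#'   `hexbin` (data.frame `hx, hy, count`), `n_points`.
#' @export
correlate_irs <- function(x_table, y_table, lowess_fraction = 0.3,
                          nbins = 40L) {
  m <- merge(x_table[, c("ies_id", "irs")], y_table[, c("ies_id", "irs")],
             by = "ies_id", suffixes = c("_x", "_y"))
  m <- m[complete.cases(m$irs_x, m$irs_y), , drop = FALSE]
  if (nrow(m) < 3L) stop("fewer than 3 shared defined scores")
  x <- m$irs_x; y <- m$irs_y
  fit <- lm(y ~ x)
  lw <- lowess(x, y, f = lowess_fraction, iter = 3)
  structure(list(
    pearson_r = cor(x, y),
    ols = c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2])),
    odr = odr_line(x, y),
    lowess = lw,
    lowess_fraction = lowess_fraction,
    hexbin = hexbin_counts(x, y, nbins = nbins),
    n_points = nrow(m)),
    class = "irs_correlation")
}

## Total least squares line through the centroid: the first principal axis
## of the centered second-moment matrix minimises summed squared
## perpendicular distances.
odr_line <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  slope <- if (sxy == 0 && sxx >= syy) 0 else
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

## Pointy-top hexagonal binning on a lattice of `nbins` columns across the
## x range. Returns centres and counts; counts conserve length(x).
hexbin_counts <- function(x, y, nbins = 40L) {
  rx <- range(x); ry <- range(y)
  w <- max(diff(rx), .Machine$double.eps) / nbins   # hex width
  h <- w * sqrt(3) / 2                              # row height
  row <- round((y - ry[1]) / h)
  colshift <- ifelse(row %% 2 == 1, 0.5, 0)
  col <- round((x - rx[1]) / w - colshift)
  hx <- rx[1] + (col + colshift) * w
  hy <- ry[1] + row * h
  key <- paste(col, row)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  first <- !duplicated(key)
  map <- match(agg$key, key[first])
  data.frame(hx = hx[first][map], hy = hy[first][map], count = agg$Freq)
}
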