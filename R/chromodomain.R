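## Chromodomain reader-preference classification. A candidate CD is
## classified from three features: integrity of the three-residue aromatic
## cage that sandwiches the methylated lysine (all of F/Y/W), the polarity
## of the two clasp residues outside the cage, and the predicted
## isoelectric point of the domain. HP1-family H3K9me readers carry a
## polar clasp on an acidic domain; Pc-family H3K27me readers carry a
## hydrophobic clasp on a basic domain; a broken cage implies no
## methyl-lysine binding at all.

AROMATIC <- c("F", "Y", "W")
POLAR_AA <- c("S", "T", "N", "Q", "C", "Y", "D", "E", "K", "R", "H")
NONPOLAR_AA <- c("G", "A", "V", "L", "I", "P", "M", "F", "W")

## EMBOSS pKa values; `sidechain` marks whether the residue is acidic (-1)
## or basic (+1) at low/high pH.
PKA_SETS <- list(
  EMBOSS = list(nterm = 8.6, cterm = 3.6,
                acidic = c(C = 8.5, D = 3.9, E = 4.1, Y = 10.1),
                basic = c(H = 6.5, K = 10.8, R = 12.5)))

#' Bundled synthetic reference chromodomains
#'
#' Loads the two exemplar reference CDs shipped with the package, with their
#' annotated cage (3) and clasp (2) alignment columns. The sequences are
#' *synthetic* exemplars engineered to carry the canonical feature sets of
#' the HP1 (H3K9me-reading) and Pc (H3K27me-reading) chromodomain families:
#' an intact aromatic cage in both, with polar clasp + acidic domain in the
#' HP1-type and nonpolar clasp + basic domain in the Pc-type.
#'
#' @return list of class `cd_reference`: per reference a list with
#'   `sequence`, `cage` (3 positions), `clasp` (2 positions).
#' @export
cd_reference <- function() {
  fa <- Biostrings::readAAStringSet(system.file(
    "extdata", "reference_cds_synthetic.fasta", package = "iesflow"))
  names(fa) <- sub(" .*", "", names(fa))
  cols <- read.delim(system.file(
    "extdata", "reference_cds_synthetic_columns.tsv", package = "iesflow"))
  refs <- lapply(seq_len(nrow(cols)), function(i) {
    id <- cols$cd_id[i]
    s <- as.character(fa[[id]])
    cage <- unlist(cols[i, c("cage1", "cage2", "cage3")], use.names = FALSE)
    clasp <- unlist(cols[i, c("clasp1", "clasp2")], use.names = FALSE)
    stopifnot(max(cage, clasp) <= nchar(s),
              all(strsplit(s, "")[[1]][cage] %in% AROMATIC))
    list(cd_id = id, sequence = s, cage = cage, clasp = clasp)
  })
  names(refs) <- cols$cd_id
  class(refs) <- "cd_reference"
  refs
}

#' Read residues at the annotated cage/clasp columns of a candidate CD
#'
#' Globally aligns the candidate to a reference CD (affine gaps, exchangeable
#' substitution matrix) and reads off the candidate residues aligned to the
#' reference's three cage and two clasp columns; a deletion spanning a
#' column is reported as `"-"`.
#'
#' @param cd_sequence candidate amino-acid sequence (30–80 aa).
#' @param reference one element of [cd_reference()] (a list with `sequence`,
#'   `cage`, `clasp`).
#' @param substitution_matrix name of the substitution matrix.
#' @param gap_opening,gap_extension affine gap penalties.
#' @param min_score alignment score floor; below it the sequence is rejected
#'   as not CD-like.
#' @return list `cage` (3 residues or `"-"`), `clasp` (2 residues),
#'   `score`.
#' @export
locate_cage_and_clasp <- function(cd_sequence, reference,
                                  substitution_matrix = "BLOSUM62",
                                  gap_opening = 10, gap_extension = 0.5,
                                  min_score = 40) {
  n <- nchar(cd_sequence)
  if (n < 30L || n > 80L)
    stop("candidate length ", n, " aa outside the 30-80 aa chromodomain range")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(cd_sequence), Biostrings::AAString(reference$sequence),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  if (Biostrings::score(aln) < min_score)
    stop("alignment score ", round(Biostrings::score(aln), 1), " below floor ",
         min_score, ": sequence does not look chromodomain-like")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ## reference position of each alignment column
  ref_pos <- cumsum(sub != "-")
  col_of <- function(p) which(ref_pos == p & sub != "-")[1]
  residues <- vapply(c(reference$cage, reference$clasp),
                     function(p) pat[col_of(p)], "")
  list(cage = unname(residues[1:3]), clasp = unname(residues[4:5]),
       score = Biostrings::score(aln))
}

#' Predicted isoelectric point of a peptide
#'
#' The pI is the pH at which the Henderson-Hasselbalch net charge over the
#' termini and the ionisable side chains (D, E, C, Y, H, K, R) crosses
#' zero, found by bisection until the residual charge magnitude is below
#' `tol`. `X` residues are ignored (with a count attached); other unknown
#' letters are an error.
#'
#' @param sequence amino-acid sequence over the 20-letter alphabet.
#' @param pka_set name of the pKa set (currently `"EMBOSS"`).
#' @param tol bisection tolerance on the net charge.
#' @return pI (numeric, in (0, 14)) with attributes `charge_residual` and
#'   `n_ignored`.
#' @export
compute_pi <- function(sequence, pka_set = "EMBOSS", tol = 1e-4) {
  stopifnot(nchar(sequence) > 0)
  pk <- PKA_SETS[[match.arg(pka_set, names(PKA_SETS))]]
  aa <- strsplit(toupper(sequence), "")[[1]]
  n_x <- sum(aa == "X")
  aa <- aa[aa != "X"]
  known <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V")
  if (length(bad <- setdiff(unique(aa), known)))
    stop("unknown residue letters: ", paste(bad, collapse = ", "))
  counts <- table(factor(aa, levels = known))
  net_charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - pk$nterm)) +
      sum(counts[names(pk$basic)] / (1 + 10^(ph - pk$basic)))
    neg <- 1 / (1 + 10^(pk$cterm - ph)) +
      sum(counts[names(pk$acidic)] / (1 + 10^(pk$acidic - ph)))
    pos - neg
  }
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    ch <- net_charge(mid)
    if (abs(ch) < tol || (hi - lo) < 1e-12) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  structure(mid, charge_residual = ch, n_ignored = n_x)
}

#' Classify a chromodomain from cage, clasp and pI
#'
#' Rules: a cage that is not fully aromatic (all of F/Y/W) means the domain
#' cannot bind methylated lysines (`non-binder`); an intact cage with both
#' clasp residues polar and an acidic domain (pI < 7) is `H3K9me-type`
#' (HP1-like); an intact cage with both clasp residues nonpolar and a basic
#' domain (pI > 7) is `H3K27me-type` (Pc-like); anything else is
#' `indeterminate`. An optional dead zone around pH 7 widens the
#' indeterminate band.
#'
#' @param cage character vector of 3 residues (or `"-"`).
#' @param clasp character vector of 2 residues.
#' @param pi predicted isoelectric point.
#' @param pi_dead_zone half-width of an indeterminate band around pH 7
#'   (default 0, disabled).
#' @return one of `"H3K9me-type"`, `"H3K27me-type"`, `"non-binder"`,
#'   `"indeterminate"`.
#' @export
classify_cd <- function(cage, clasp, pi, pi_dead_zone = 0) {
  cage_intact <- length(cage) == 3L && all(cage %in% AROMATIC)
  if (!cage_intact) return("non-binder")
  if (abs(pi - 7) <= pi_dead_zone) return("indeterminate")
  if (all(clasp %in% POLAR_AA) && pi < 7) return("H3K9me-type")
  if (all(clasp %in% NONPOLAR_AA) && pi > 7) return("H3K27me-type")
  "indeterminate"
}

clasp_polarity <- function(clasp) {
  if (all(clasp %in% POLAR_AA)) "polar"
  else if (all(clasp %in% NONPOLAR_AA)) "nonpolar"
  else "mixed"
}

#' Classify candidate chromodomains end to end
#'
#' For each candidate: align to each bundled reference, keep the
#' better-scoring alignment, read off cage and clasp residues, compute the
#' pI of the whole candidate, and apply [classify_cd()].
#'
#' @param cds named character vector, `AAStringSet`, or FASTA path of
#'   candidate CD sequences.
#' @param reference a [cd_reference()] (default: the bundled one).
#' @param ... passed to [locate_cage_and_clasp()].
#' @return data.frame `cd_id, cage, cage_intact, clasp, clasp_polarity, pi,
#'   call`.
#' @export
classify_chromodomains <- function(cds, reference = cd_reference(), ...) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds))
    cds <- Biostrings::readAAStringSet(cds)
  if (methods::is(cds, "AAStringSet")) {
    seqs <- as.character(cds)
  } else seqs <- cds
  ids <- names(seqs) %||% sprintf("cd_%03d", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    locs <- lapply(reference, function(r)
      locate_cage_and_clasp(seqs[[i]], r, ...))
    loc <- locs[[which.max(vapply(locs, `[[`, numeric(1), "score"))]]
    pi <- as.numeric(compute_pi(seqs[[i]]))
    data.frame(cd_id = ids[i],
               cage = paste(loc$cage, collapse = ""),
               cage_intact = all(loc$cage %in% AROMATIC),
               clasp = paste(loc$clasp, collapse = ""),
               clasp_polarity = clasp_polarity(loc$clasp),
               pi = pi,
               call = classify_cd(loc$cage, loc$clasp, pi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
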