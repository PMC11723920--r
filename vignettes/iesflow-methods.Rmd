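---
title: "Methods: scoring programmed DNA elimination phenotypes with iesflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring programmed DNA elimination phenotypes with iesflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iesflow)
```

## The problem

During sexual development of *Paramecium tetraurelia*, a new somatic
macronucleus (MAC) is built from the germline genome by eliminating tens of
thousands of short, TA-bounded Internal Eliminated Sequences (IESs), the
shortest of which are only 26 bp and most of which are shorter than a
nucleosome footprint. When a factor required for elimination is silenced,
IESs are retained in the sequenced somatic DNA in a graded, per-copy
fashion (the MAC is highly polyploid, ~800n). `iesflow` implements the
computational phenotyping used to study such silencings: per-IES retention
scores from sequencing alignments, ensemble retention analytics, small-RNA
class profiling, nucleosome-density scoring over IESs, and chromodomain
reader-preference classification — plus a synthetic-data module that
generates all inputs with known ground truth so the entire pipeline is
testable at desk scale.

## IES representation and coordinates

All internal coordinates are 0-based half-open; GFF3 output is 1-based
inclusive with feature type `internal_eliminated_sequence`. The stored IES
sequence includes both terminal TAs. The excised (MAC) form keeps exactly
one TA at the junction:

```
MIC:  ...flank | TA ... core ... TA | flank...
MAC:  ...flank | TA | flank...
```

so excision is exactly reversible, and `junction_mac` is the start of the
retained TA on the MAC scaffold. The toy genome builder plants junctions on
a jittered grid with a minimum inter-junction flank (default 300 bp), which
guarantees that reads of the default length span at most one IES;
`simulate_genomic_reads()` checks this precondition and refuses to run
otherwise rather than generating mosaic reads that would align cleanly to
neither reference.

## Retention scoring

A read supports the IES+ form when its alignment on the MAC+IES reference
covers an IES boundary with at least `anchor` aligned bases on each side
(default 5 bp; the choice is exposed because smaller anchors inflate
spurious junction support, and it is recorded in the output). It supports
the excised form when its MAC alignment covers the collapsed junction with
at least `anchor` bases on each side of the retained TA. The TA itself is
excluded from the MAC-side anchors: those two bases are shared between the
IES+ and excised forms, so they carry no evidence about which form the read
came from; "anchor bases on both sides of a 2-bp-wide junction" is
otherwise ill-defined. Secondary, supplementary and unmapped records are
dropped (unmapped records are counted and reported), and a read is never
allowed to support both the + and − form of the same IES.

The global retention score pools both boundaries:

$$\mathrm{IRS} = \frac{L^+ + R^+}{L^+ + R^+ + 2M^-}$$

where $L^+$ and $R^+$ count boundary-supporting reads and $M^-$ counts
junction-spanning MAC reads. The factor 2 compensates for the asymmetry
between two observable boundaries on the retained form and one junction on
the excised form; with it, the expected score equals the true retention
fraction (up to an edge effect of order $2/(L_\mathrm{read}-2a)$ from the
TA exclusion, well below the binomial sampling error at the depths used).
Because the convention used by the established retention-score tooling is
not fully specified in the literature we target, both per-boundary scores
$L^+/(L^+{+}M^-)$ and $R^+/(R^+{+}M^-)$ are emitted alongside the global
score, so either view can be compared externally. The score is undefined
(not zero) when no junction-informative read exists.

Retention calling uses a **strict** inequality, `IRS > threshold`, with a
default threshold of 0.1 chosen to exclude stochastic, weakly retained
copies; a score of exactly 0.1 is not retained. The alternative weak
cutoff 0.01 is exposed as a parameter rather than hard-coded, since both
are in common use.

## The genomic read simulator

Reads are single-end and drawn uniformly along the MIC reference. Whenever
a read overlaps an IES, its haplotype is drawn per read: IES-retained with
probability $r_i$, excised otherwise. Per-read (rather than per-genome)
sampling is the natural model here because the sequenced nucleus is ~800n,
so successive fragments are effectively independent genome copies. On an
excised copy, a read whose start falls inside the IES has no equivalent
sequence; dropping it reproduces uniform sampling on the shorter excised
haplotype (the only loss is the 2-position start window inside the retained
TA, which is negligible). Truth alignments are emitted directly as SAM —
placement is known exactly, so no aligner is involved at desk scale; real
data enter the pipeline as user-supplied SAM against the two references.
Sequencing errors are off by default (an optional uniform substitution rate
exists); error modelling contributes nothing to the statistics under test.

The IES length sampler defaults to $26 + \mathrm{round}(\mathrm{Exp}(
\mathrm{mean}=45))$ capped at 400 bp. This respects the 26 bp minimum and
puts ~93% of lengths below 150 bp, matching the short-biased length profile
of the system; the distribution's shape beyond those two constraints is a
modelling choice, not a biological claim, and the sampler is configurable.
Background sequence is i.i.d. at a configurable GC content (default 0.28,
AT-rich as in this organism), deliberately repeat-free so that toy-scale
matching is unambiguous.

## Retention analytics

Histograms bin scores strictly above the cutoff into `[min_irs, 1]`, with
mass equal to the number of filtered records. Size stratification reports
fractions within a subset and, optionally, relative to a reference subset —
the all-IES denominator used when an excisase knockdown defines the
complete IES complement. Subset overlaps are exact Venn partitions of two
or three id sets. Cross-condition correlation is computed on the
intersection of ids with defined scores in both tables; undefined scores
are dropped pairwise and never imputed, since imputation would manufacture
correlation. Three trends are fitted: ordinary least squares; LOWESS
(tricube locally weighted linear regression, default span 0.3, 3
robustness iterations — parameters recorded in the result because the
convention is otherwise unstated); and orthogonal distance regression,
implemented in closed form as total least squares via the principal axis of
the centred second-moment matrix, which is the exact minimiser of summed
squared perpendicular distances for a line. Hexagonal binning (pointy-top,
default 40 columns) is provided for plotting only; the tested property is
that bin counts conserve the number of points.

## Small-RNA classification

Reads are classified by priority-ordered iterative matching with
subtraction: each read is assigned the first reference in the hierarchy
that contains it full-length (either strand by default, `max_mismatch`
configurable, default 0), and assigned reads are removed before the next
reference is considered. This preserves the semantics of iterative
alignment with read subtraction while replacing the aligner with an exact
substring matcher at desk scale (0-mismatch matching uses a `PDict` per
read-length group; the k-mismatch path scans reads individually). The
default hierarchy order — vector, host bacterium, TE, OES, IES, MDS — puts
contaminant sources first and the most specific genomic class before the
genome-wide class; the order is a configuration with a documented default,
recorded in the output, not a claim about any particular published run.
Classification is order-dependent by design: only reads matching multiple
references are affected by permuting the hierarchy, a property covered by
the tests.

Class definitions follow the three development-specific classes: 23 nt
siRNAs, 25 nt scnRNAs, and 26–31 nt iesRNAs (drawn exclusively from IES
sequences in the simulator, matching the defining property of the class).
The scanning ratio is IES-matching over MAC(MDS)-matching reads at 25 nt,
undefined when the denominator is zero. The iesRNA contribution of a
retained set is the fraction of feature-assigned iesRNA reads whose source
IES exceeds the retention threshold; reads without a matched feature are
tallied separately and excluded from the denominator, and the fraction is
monotone non-increasing in the threshold.

## Nucleosome density

MNase-protected fragments are reconstructed from proper pairs, filtered to
the mononucleosome band 125–175 bp (inclusive at both ends), and libraries
within a group are downsampled without replacement to the smallest
library's size. Counting over IESs defaults to any-overlap (a fragment
counts for every IES it overlaps by ≥ 1 bp, the semantics of the standard
interval-counting tools); a midpoint mode (unique IES containing the lower
central base) is provided for sensitivity analysis. The density is the
dimensionless ratio

$$d_i = \frac{m_i / M}{g_i / G}$$

of normalised MNase to normalised input counts, undefined when the input
count is zero (undefined densities are excluded from tests, with the
exclusion count logged, rather than producing infinities). Density is
invariant under rescaling both libraries by a common factor. Any
presentation-only truncation of the density axis in plots is never applied
to statistics.

Two-group differences use the Mann–Whitney U test (midranks for ties;
exact enumeration when $n_x+n_y \le 12$ with no ties, otherwise the normal
approximation with tie and continuity correction — the standard
`wilcox.test` machinery, cross-checked in the tests against an independent
exhaustive enumeration oracle). The Holm–Bonferroni family is all
comparisons passed in one invocation, made explicit because the grouping
of comparisons is otherwise ambiguous; the adjustment is the standard
step-down, dominated below by the raw p-values and capped at 1. Boxplot
summaries use linear-interpolation quartiles (type 7, the most common
convention) with whiskers at the most extreme points within 1.5 IQR of the
quartiles.

## Chromodomain classification

Candidates (30–80 aa) are globally aligned (BLOSUM62, affine gaps, open 10
/ extend 0.5 — chromodomains are short and conserved, so global alignment
avoids fragment ambiguity) to each bundled reference; the better-scoring
reference supplies the annotated columns, and an alignment score below a
floor (default 40) rejects sequences that are not chromodomain-like.
Three features drive the call: the three aromatic-cage residues must all
be F, Y or W for the domain to bind methylated lysines at all (H is
deliberately excluded from the aromatic set — including it would silently
change non-binder calls); the two clasp residues are classified by the
standard side-chain polarity partition (polar: S T N Q C Y D E K R H;
nonpolar: G A V L I P M F W); and the predicted isoelectric point is
computed by bisection on the Henderson–Hasselbalch net charge with EMBOSS
pKa values (termini plus D, E, C, Y, H, K, R), to a residual charge below
1e-4. An intact cage with a polar clasp on an acidic domain (pI < 7) is
called H3K9me-type (HP1-like); an intact cage with a nonpolar clasp on a
basic domain (pI > 7) is H3K27me-type (Pc-like); a broken cage is a
non-binder regardless of the other features; everything else — including
mixed clasps, which are not given a weak call — is indeterminate. Because
the pKa set shifts pI by up to ~0.5 units, an optional dead zone around
pH 7 (disabled by default) can widen the indeterminate band.

The two bundled reference CDs are **synthetic** exemplars (so labelled in
their file and identifiers), engineered to carry the canonical feature sets
of the HP1 and Polycomb chromodomain families; they are reference points
for alignment and sanity checks, not curated natural sequences, and
published figure pI values are never used as test oracles.

## Problem sizes and what the tests show

The test and acceptance workloads use a 5-scaffold toy genome of 25 kb
scaffolds with 200 IESs at 100× coverage for retention recovery; 10,000
small-RNA reads for classification; and 50,000 MNase fragments over 120
IESs with a planted 2:1 density weight for the nucleosome analyses — sizes
at which every binomial oracle has comfortable resolution while the whole
suite runs in about a minute. Passing these tests demonstrates that the
implementations compute their definitions exactly and recover planted
truth under the simulator's assumptions: i.i.d. background sequence,
error-free reads, exact placement, and per-read haplotype independence.
They do not demonstrate robustness to mapping ambiguity in repetitive real
genomes, alignment errors around indels, PCR duplicates, or biased MNase
digestion — real-data runs enter via user-supplied SAM and inherit the
upstream aligner's handling of those effects.

## Known limitations

* The junction counter assumes coordinate-correct alignments; it does not
  re-examine sequence, so misalignments near junctions propagate.
* The substring matcher for small RNAs is exact (or k-mismatch) and
  full-length; it has no concept of splicing, soft-clipping or quality.
* Paired-end genomic reads are not merged into fragment intervals for
  retention counting; each alignment record counts independently.
* ODR is the linear total-least-squares case only.
* pI prediction ignores structural context (buried residues, disulfides),
  as all sequence-based pI methods do.
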