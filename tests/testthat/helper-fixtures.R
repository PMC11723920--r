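# Shared in-code fixtures: a small deterministic toy genome, a hand-placed
# junction-read fixture, and brute-force oracles used across tests.

tiny_genome <- function(n_scaffolds = 2, scaffold_length = 8000, n_ies = 16,
                        seed = 7) {
  build_toy_genome(toy_genome_spec(n_scaffolds = n_scaffolds,
                                   scaffold_length = scaffold_length,
                                   n_ies = n_ies, seed = seed))
}

# One IES (start_mic 100, end_mic 150, junction_mac 100) on a single
# scaffold pair, plus hand-placed 30 bp reads. Expected counts at anchor 5
# were enumerated by hand against the anchored crossing rules:
# left_plus = 3 (r01, r02, r08), right_plus = 2 (r05, r06),
# mac_minus = 4 (r09, r10, r11, r12).
junction_fixture <- function(dir = tempfile("jfix")) {
  dir.create(dir, showWarnings = FALSE)
  mac <- Biostrings::DNAStringSet(c(s1 = paste(rep("ACGT", 100), collapse = "")))
  mic <- Biostrings::DNAStringSet(c(s1 = paste(rep("ACGT", 112), collapse = "")))
  ann <- data.frame(ies_id = "ies1", scaffold = "s1", start_mic = 100L,
                    end_mic = 150L, junction_mac = 100L, length = 50L,
                    sequence = NA_character_, stringsAsFactors = FALSE)
  mic_reads <- data.frame(
    qname = sprintf("r%02d", 1:8), flag = 0L, scaffold = "s1",
    pos = c(80L, 95L, 96L, 110L, 130L, 145L, 70L, 90L),
    seq = strrep("A", 30L), stringsAsFactors = FALSE)
  mac_reads <- data.frame(
    qname = sprintf("r%02d", 9:12), flag = 0L, scaffold = "s1",
    pos = c(80L, 95L, 77L, 85L),
    seq = strrep("A", 30L), stringsAsFactors = FALSE)
  mic_sam <- file.path(dir, "mic.sam")
  mac_sam <- file.path(dir, "mac.sam")
  iesflow:::write_sam(mic_reads, mic, mic_sam)
  iesflow:::write_sam(mac_reads, mac, mac_sam)
  list(annotation = ann, mic_sam = mic_sam, mac_sam = mac_sam,
       mic_reads = mic_reads, mac_reads = mac_reads)
}

# Exhaustive per-read interval-arithmetic oracle for junction counting.
# reads: data.frame(pos, len) 0-based; independent of the package's
# GRanges-based implementation.
oracle_junction_counts <- function(mic_reads, mac_reads, ann, anchor) {
  covers <- function(s, e, lo, hi) s <= lo & e >= hi   # [lo,hi) within [s,e)
  lp <- rp <- mm <- 0L
  for (i in seq_len(nrow(mic_reads))) {
    s <- mic_reads$pos[i]; e <- s + nchar(mic_reads$seq[i])
    if (covers(s, e, ann$start_mic - anchor, ann$start_mic + anchor))
      lp <- lp + 1L
    if (covers(s, e, ann$end_mic - anchor, ann$end_mic + anchor))
      rp <- rp + 1L
  }
  for (i in seq_len(nrow(mac_reads))) {
    s <- mac_reads$pos[i]; e <- s + nchar(mac_reads$seq[i])
    if (covers(s, e, ann$junction_mac - anchor, ann$junction_mac + 2 + anchor))
      mm <- mm + 1L
  }
  c(left_plus = lp, right_plus = rp, mac_minus = mm)
}

# Quadratic all-pairs interval intersection oracle for fragment counting.
oracle_overlap_counts <- function(frags, ann, mode) {
  counts <- setNames(integer(nrow(ann)), ann$ies_id)
  for (i in seq_len(nrow(frags))) {
    for (j in seq_len(nrow(ann))) {
      if (frags$scaffold[i] != ann$scaffold[j]) next
      if (mode == "any-overlap") {
        if (frags$start[i] < ann$end_mic[j] && frags$end[i] > ann$start_mic[j])
          counts[j] <- counts[j] + 1L
      } else {
        mid <- frags$start[i] + (frags$length[i] - 1L) %/% 2L
        if (mid >= ann$start_mic[j] && mid < ann$end_mic[j])
          counts[j] <- counts[j] + 1L
      }
    }
  }
  counts
}

# Exhaustive two-sided Mann-Whitney p by enumeration of all rank
# assignments (no ties).
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  obs <- u_of(seq_len(nx))
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, u_of)
  mu <- nx * (n - nx) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}
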