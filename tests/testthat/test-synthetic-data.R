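test_that("toy genome round-trips: excising all IESs reproduces the MAC", {
  for (seed in c(1, 7, 23)) {
    g <- build_toy_genome(toy_genome_spec(n_scaffolds = 2,
                                          scaffold_length = 6000,
                                          n_ies = 10, seed = seed))
    expect_identical(as.character(excise_ies(g$mic, g$annotation)),
                     as.character(g$mac))
    ## per-IES re-excision by string surgery
    for (i in seq_len(nrow(g$annotation))) {
      a <- g$annotation[i, ]
      s <- as.character(g$mic[[a$scaffold]])
      expect_identical(substr(s, a$start_mic + 1, a$end_mic), a$sequence)
    }
  }
})

test_that("IES sequences are TA-bounded and at least 26 bp", {
  g <- tiny_genome()
  expect_true(all(g$annotation$length >= 26))
  expect_true(all(startsWith(g$annotation$sequence, "TA")))
  expect_true(all(endsWith(g$annotation$sequence, "TA")))
  expect_equal(g$annotation$length,
               g$annotation$end_mic - g$annotation$start_mic)
  ## non-overlapping and sorted within scaffold
  for (a in split(g$annotation, g$annotation$scaffold))
    expect_true(all(diff(a$start_mic) > 0) &&
                  all(a$start_mic[-1] >= a$end_mic[-nrow(a)]))
})

test_that("genome build is deterministic under a seed, and n_ies = 0 gives identical references", {
  spec <- toy_genome_spec(n_scaffolds = 2, scaffold_length = 5000,
                          n_ies = 8, seed = 99)
  g1 <- build_toy_genome(spec)
  g2 <- build_toy_genome(spec)
  expect_identical(as.character(g1$mic), as.character(g2$mic))
  expect_identical(g1$annotation, g2$annotation)
  ## byte-identical FASTA output
  f1 <- tempfile(); f2 <- tempfile()
  Biostrings::writeXStringSet(g1$mic, f1)
  Biostrings::writeXStringSet(g2$mic, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  g0 <- build_toy_genome(toy_genome_spec(n_scaffolds = 1,
                                         scaffold_length = 2000, n_ies = 0))
  expect_identical(as.character(g0$mac), as.character(g0$mic))
  expect_equal(nrow(g0$annotation), 0L)
})

test_that("over-full genomes are rejected with a capacity error", {
  expect_error(build_toy_genome(toy_genome_spec(n_scaffolds = 1,
                                                scaffold_length = 1000,
                                                n_ies = 50)),
               "do not fit")
})

test_that("GFF3 annotation round-trips through rtracklayer", {
  g <- tiny_genome()
  path <- tempfile(fileext = ".gff3")
  write_ies_gff3(g$annotation, path)
  back <- read_ies_annotation(path)
  back <- back[match(g$annotation$ies_id, back$ies_id), ]
  expect_equal(back$start_mic, g$annotation$start_mic)
  expect_equal(back$end_mic, g$annotation$end_mic)
  expect_equal(back$junction_mac, g$annotation$junction_mac)
})

test_that("full retention leaves no MAC junction reads; full excision leaves no boundary reads", {
  g <- tiny_genome()
  r1 <- setNames(rep(1, nrow(g$annotation)), g$annotation$ies_id)
  sim1 <- simulate_genomic_reads(g, r1, depth = 20, read_length = 100,
                                 seed = 2)
  d <- write_genomic_read_sim(sim1, tempfile())
  cnt <- compute_irs(count_junction_reads(d$mic_sam, d$mac_sam,
                                          g$annotation, anchor = 5))
  expect_true(all(cnt$mac_minus == 0))
  r0 <- setNames(rep(0, nrow(g$annotation)), g$annotation$ies_id)
  sim0 <- simulate_genomic_reads(g, r0, depth = 20, read_length = 100,
                                 seed = 2)
  d0 <- write_genomic_read_sim(sim0, tempfile())
  cnt0 <- compute_irs(count_junction_reads(d0$mic_sam, d0$mac_sam,
                                           g$annotation, anchor = 5))
  expect_true(all(cnt0$left_plus == 0 & cnt0$right_plus == 0))
})

test_that("junction-informative truth fractions follow the binomial law at r = 0.5", {
  g <- tiny_genome(n_ies = 8)
  r <- setNames(rep(0.5, 8), g$annotation$ies_id)
  sim <- simulate_genomic_reads(g, r, depth = 100, read_length = 100,
                                seed = 4)
  ## condition on fragments whose start lies in the left flank: there the
  ## per-fragment haplotype draw is observed regardless of outcome (interior
  ## starts on excised copies are dropped, so they would bias the tally)
  tr <- sim$reads[!is.na(sim$reads$ies_id), ]
  ann <- g$annotation
  start_mic_of <- setNames(ann$start_mic, ann$ies_id)
  off <- start_mic_of[tr$ies_id] - setNames(ann$junction_mac, ann$ies_id)[tr$ies_id]
  mic_start <- ifelse(tr$form == "retained", tr$mic_pos, tr$mac_pos + off)
  flank <- mic_start < start_mic_of[tr$ies_id]
  tr <- tr[flank, ]
  for (id in ann$ies_id) {
    n <- sum(tr$ies_id == id)
    p_hat <- mean(tr$form[tr$ies_id == id] == "retained")
    expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n))
  }
  ## mismatch between truth and annotation is rejected
  g0 <- build_toy_genome(toy_genome_spec(n_scaffolds = 1,
                                         scaffold_length = 2000, n_ies = 0))
  expect_error(simulate_genomic_reads(g0, c(a = 0.5), depth = 1),
               "annotation is empty")
})

test_that("MNase midpoint density tracks interval weights (binomial oracle)", {
  ## two equal-length intervals, equal weights: counts within 4 SE
  ann <- data.frame(ies_id = c("a", "b"), scaffold = "s1",
                    start_mic = c(1000L, 5000L), end_mic = c(1200L, 5200L),
                    junction_mac = NA_integer_, length = 200L,
                    sequence = NA_character_)
  ref <- Biostrings::DNAStringSet(c(s1 = strrep("A", 10000)))
  fr <- simulate_mnase_fragments(ref, ann, c(a = 1, b = 1), 8000, seed = 3)
  n <- table(fr$ies_id)
  se <- sqrt(8000 * 0.5 * 0.5)
  expect_lt(abs(n[["a"]] - n[["b"]]), 4 * 2 * se)
  ## 2:1 weights: ratio near 2
  fr2 <- simulate_mnase_fragments(ref, ann, c(a = 2, b = 1), 9000, seed = 5)
  n2 <- table(fr2$ies_id)
  p_hat <- n2[["a"]] / 9000
  expect_lt(abs(p_hat - 2 / 3), 4 * sqrt(2 / 9 / 9000))
  ## zero or negative weights rejected; n_fragments <= 0 rejected
  expect_error(simulate_mnase_fragments(ref, ann, c(a = 0, b = 1), 100),
               "strictly positive")
  expect_error(simulate_mnase_fragments(ref, ann, c(a = 1, b = 1), 0),
               "n_fragments")
  ## determinism
  fr3 <- simulate_mnase_fragments(ref, ann, c(a = 2, b = 1), 9000, seed = 5)
  expect_identical(fr2, fr3)
})

test_that("sRNA simulator honours class length definitions and mixtures", {
  g <- tiny_genome()
  ies <- Biostrings::DNAStringSet(setNames(g$annotation$sequence,
                                           g$annotation$ies_id))
  ies <- ies[Biostrings::width(ies) >= 40]
  src <- list(siRNA = g$mac, scnRNA = g$mac, iesRNA = ies)
  only_si <- simulate_srna_reads(c(siRNA = 1, scnRNA = 0, iesRNA = 0), src,
                                 500, seed = 1)
  expect_true(all(only_si$length == 23))
  only_ies <- simulate_srna_reads(c(siRNA = 0, scnRNA = 0, iesRNA = 1), src,
                                  200, seed = 2)
  expect_true(all(only_ies$length %in% 26:31))
  ## every iesRNA read is a substring of some IES sequence (either strand)
  ies_chr <- as.character(ies)
  hit <- vapply(seq_len(nrow(only_ies)), function(i) {
    s <- only_ies$seq[i]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    any(grepl(s, ies_chr, fixed = TRUE)) || any(grepl(rc, ies_chr, fixed = TRUE))
  }, logical(1))
  expect_true(all(hit))
  ## multinomial mixture recovery within 3 SE
  mix <- c(siRNA = 0.2, scnRNA = 0.5, iesRNA = 0.3)
  rs <- simulate_srna_reads(mix, src, 10000, seed = 3)
  for (cl in names(mix)) {
    p_hat <- mean(rs$class == cl)
    expect_lt(abs(p_hat - mix[[cl]]),
              3 * sqrt(mix[[cl]] * (1 - mix[[cl]]) / 10000))
  }
  ## zero-length source rejected
  bad <- src; bad$iesRNA <- Biostrings::DNAStringSet("")
  expect_error(simulate_srna_reads(mix, bad, 10, seed = 1), "zero-length|empty")
})
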