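test_that("fragment size filter is inclusive at 125 and 175 bp", {
  fr <- data.frame(scaffold = "s1", start = 0L,
                   end = c(124L, 125L, 150L, 175L, 176L),
                   length = c(124L, 125L, 150L, 175L, 176L),
                   library = "mnase")
  kept <- filter_fragments(fr)
  expect_equal(kept$length, c(125L, 150L, 175L))
  expect_equal(attr(kept, "n_discarded"), 2L)
  expect_equal(nrow(kept) + attr(kept, "n_discarded"), nrow(fr))
  expect_error(filter_fragments(fr, 200, 100), "min_len")
  ## mixed fixture: partition matches hand enumeration
  set.seed(2)
  fr2 <- data.frame(scaffold = "s1", start = 0L, length = sample(100:200, 10))
  fr2$end <- fr2$length
  kept2 <- filter_fragments(fr2)
  expect_equal(sort(kept2$length),
               sort(fr2$length[fr2$length >= 125 & fr2$length <= 175]))
})

test_that("downsampling equalises library sizes deterministically", {
  libs <- list(a = data.frame(i = 1:100), b = data.frame(i = 1:80))
  ds <- downsample_libraries(libs, seed = 4)
  expect_equal(vapply(ds, nrow, integer(1)), c(a = 80L, b = 80L))
  expect_true(!anyDuplicated(ds$a$i))        # without replacement
  ds2 <- downsample_libraries(libs, seed = 4)
  expect_identical(ds, ds2)
  ## equal sizes keep membership count
  eq <- downsample_libraries(list(a = data.frame(i = 1:50),
                                  b = data.frame(i = 51:100)), seed = 1)
  expect_equal(sort(eq$a$i), 1:50)
  expect_error(downsample_libraries(list(a = data.frame(), b = data.frame(i = 1))),
               "empty library")
})

test_that("interval counting agrees with the quadratic all-pairs oracle", {
  ann <- data.frame(ies_id = c("a", "b"), scaffold = "s1",
                    start_mic = c(100L, 300L), end_mic = c(200L, 460L),
                    junction_mac = NA_integer_, length = c(100L, 160L),
                    sequence = NA_character_)
  set.seed(6)
  start <- sample(0:500, 20)
  len <- sample(80:200, 20, replace = TRUE)
  fr <- data.frame(scaffold = "s1", start = start, end = start + len,
                   length = len, library = "mnase")
  for (mode in c("any-overlap", "midpoint")) {
    expect_equal(count_over_intervals(fr, ann, mode),
                 oracle_overlap_counts(fr, ann, mode), info = mode)
  }
  ## a fragment fully inside an IES counts in both modes; one straddling
  ## two adjacent IESs counts twice under any-overlap, once under midpoint
  ann2 <- data.frame(ies_id = c("a", "b"), scaffold = "s1",
                     start_mic = c(100L, 200L), end_mic = c(200L, 300L),
                     junction_mac = NA_integer_, length = 100L,
                     sequence = NA_character_)
  inside <- data.frame(scaffold = "s1", start = 120L, end = 180L,
                       length = 60L, library = "x")
  strad <- data.frame(scaffold = "s1", start = 150L, end = 280L,
                      length = 130L, library = "x")
  expect_equal(sum(count_over_intervals(inside, ann2, "any-overlap")), 1L)
  expect_equal(sum(count_over_intervals(inside, ann2, "midpoint")), 1L)
  expect_equal(sum(count_over_intervals(strad, ann2, "any-overlap")), 2L)
  expect_equal(sum(count_over_intervals(strad, ann2, "midpoint")), 1L)
  expect_error(count_over_intervals(fr, ann, "midpoint", scaffolds = "s2"),
               "absent from the reference")
})

test_that("density is the normalised MNase/input ratio and scale-invariant", {
  m <- c(a = 10L, b = 20L, c = 0L, d = 5L)
  g <- c(a = 10L, b = 10L, c = 10L, d = 0L)
  dens <- compute_density(m, g, mnase_total = 100, input_total = 100)
  expect_equal(dens$density[1], 1)
  expect_equal(dens$density[2], 2)
  expect_equal(dens$density[3], 0)
  expect_true(is.na(dens$density[4]))       # zero input: undefined
  expect_equal(attr(dens, "n_undefined"), 1L)
  ## multiplying both libraries by a constant leaves densities unchanged
  dens10 <- compute_density(m * 10L, g * 10L, 1000, 1000)
  expect_equal(dens10$density, dens$density)
  expect_error(compute_density(c(a = -1L), c(a = 1L), 1, 1), "negative")
})

test_that("Mann-Whitney p matches exhaustive enumeration and handles identical samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$p, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  ## a second configuration against the enumeration oracle
  x <- c(1.2, 3.4, 5.1, 2.2); y <- c(4.4, 6.3, 0.7)
  expect_equal(mann_whitney_u(x, y)$p, oracle_mw_exact_p(x, y))
  ## identical multisets separate nothing
  expect_gte(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  expect_error(mann_whitney_u(numeric(), 1), "empty")
})

test_that("Mann-Whitney type-I error is calibrated under the null", {
  set.seed(31)
  rej <- mean(replicate(1000, {
    mann_whitney_u(rnorm(30), rnorm(30))$p < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("Holm adjustment reproduces the hand step-down and dominates raw p", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    adj <- holm_bonferroni(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("box summaries follow the 1.5 IQR whisker convention", {
  const <- box_summary(rep(3.3, 10))
  expect_equal(const$median, 3.3)
  expect_equal(const$q1, 3.3)
  expect_equal(const$q3, 3.3)
  expect_equal(length(const$outliers), 0L)
  v <- c(1:100, 1000)
  bs <- box_summary(v)
  q <- unname(quantile(v, c(0.25, 0.75), type = 7))
  expect_equal(bs$q1, q[1]); expect_equal(bs$q3, q[2])
  expect_true(1000 %in% bs$outliers)
  expect_lte(bs$whisker_hi, q[2] + 1.5 * (q[2] - q[1]))
  ## conservation: outliers plus in-whisker points recover the input
  inside <- v[v >= bs$whisker_lo & v <= bs$whisker_hi]
  expect_equal(sort(c(inside, bs$outliers)), sort(v))
  expect_error(box_summary(numeric()), "empty")
})

test_that("planted density differences are detected and the pipeline conserves fragments", {
  g <- tiny_genome(n_scaffolds = 2, scaffold_length = 20000, n_ies = 40,
                   seed = 7)
  ann <- g$annotation
  grp <- rep(c("hi", "lo"), length.out = nrow(ann))
  w <- setNames(ifelse(grp == "hi", 2, 1), ann$ies_id)
  mn <- simulate_mnase_fragments(g$mic, ann, w, 20000, seed = 11)
  inp <- simulate_mnase_fragments(g$mic, ann,
                                  setNames(rep(1, nrow(ann)), ann$ies_id),
                                  20000, seed = 12)
  mnf <- filter_fragments(mn); inf <- filter_fragments(inp)
  expect_equal(nrow(mnf) + attr(mnf, "n_discarded"), 20000L)
  mc <- count_over_intervals(mnf, ann)
  ic <- count_over_intervals(inf, ann)
  dens <- compute_density(mc, ic, nrow(mnf), nrow(inf))
  tst <- density_tests(list(
    hi_vs_lo = list(x = dens$density[grp == "hi"],
                    y = dens$density[grp == "lo"])))
  expect_lt(tst$p_adj, 0.01)
  med_ratio <- median(dens$density[grp == "hi"], na.rm = TRUE) /
    median(dens$density[grp == "lo"], na.rm = TRUE)
  expect_lt(abs(med_ratio - 2), 0.3)
})
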