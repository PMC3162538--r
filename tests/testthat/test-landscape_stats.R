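test_that("density arithmetic reproduces the published magnitudes", {
  expect_equal(round(ssr_density(234, 1.74), 1), 134.5)
  expect_equal(round(ssr_density(821, 3.82), 1), 214.9)
  expect_error(ssr_density(10, 0), "positive")
})

test_that("repeat_type_table aggregates a single locus correctly", {
  perfect <- data.frame(seq_id = "s", start = 0L, end = 12L, unit_len = 2L,
                        motif_observed = "AC", motif_class = "AC",
                        n_units = 6, total_len = 12L, kind = "perfect",
                        stringsAsFactors = FALSE)
  summ <- data.frame(dataset = "toy", n_records = 1L, total_bp = 1000000L,
                     total_mbp = 1, gc_fraction = 0.4,
                     p_a = 0.3, p_c = 0.2, p_g = 0.2, p_t = 0.3)
  tab <- repeat_type_table(perfect, NULL, summ)
  di <- tab[tab$repeat_type == "2", ]
  expect_equal(di$count, 1)
  expect_equal(di$percent, 100)
  expect_equal(di$density, 1)
  expect_equal(di$mean_n_units, 6)
  tot <- tab[tab$repeat_type == "total_perfect", ]
  expect_equal(tot$count, 1)
  expect_equal(tab[tab$repeat_type == "compound", "count"], 0)
})

test_that("repeat_type_table equals an independent brute-force regrouping", {
  set.seed(19)
  n <- 400
  ks <- sample(2:8, n, replace = TRUE)
  units <- vapply(ks, function(k) max(3, ceiling(12 / k)) + rpois(1, 2),
                  numeric(1))
  perfect <- data.frame(
    seq_id = "s", start = 0L, end = as.integer(ks * units),
    unit_len = ks,
    motif_observed = vapply(ks, function(k) motif_classes(k)[1],
                            character(1)),
    motif_class = vapply(ks, function(k) motif_classes(k)[1], character(1)),
    n_units = units, total_len = as.integer(ks * units), kind = "perfect",
    stringsAsFactors = FALSE)
  summ <- data.frame(dataset = "x", n_records = 10L, total_bp = 2.5e6,
                     total_mbp = 2.5, gc_fraction = 0.4,
                     p_a = 0.3, p_c = 0.2, p_g = 0.2, p_t = 0.3)
  tab <- repeat_type_table(perfect, NULL, summ)
  for (k in 2:8) {
    sel <- ks == k
    row <- tab[tab$repeat_type == as.character(k), ]
    expect_equal(row$count, sum(sel))
    expect_equal(row$percent, 100 * sum(sel) / n)
    expect_equal(row$density, sum(sel) / 2.5)
    if (any(sel)) {
      expect_equal(row$mean_n_units, mean(units[sel]))
      expect_equal(row$mean_total_len, mean(ks[sel] * units[sel]))
    }
  }
})

test_that("expected motif probabilities follow the composition model", {
  uni <- expected_motif_probs(c(A = .25, C = .25, G = .25, T = .25), 2)
  expect_length(uni, 6)
  expect_equal(unname(uni), rep(1 / 6, 6))
  expect_length(expected_motif_probs(c(A = .25, C = .25, G = .25, T = .25),
                                     3), 20)

  ## skewed composition, hand-computed dinucleotide classes:
  ## class weight = sum over its two rotations of the base-product
  p <- c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)
  probs <- expected_motif_probs(p, 2)
  w <- c(AC = 2 * .4 * .1, AG = 2 * .4 * .1, AT = 2 * .4 * .4,
         CG = 2 * .1 * .1, CT = 2 * .1 * .4, GT = 2 * .1 * .4)
  expect_equal(probs[names(w)], w / sum(w))

  ## normalization holds for arbitrary compositions
  set.seed(8)
  for (i in 1:20) {
    f <- runif(4, 0.05, 1)
    pr <- expected_motif_probs(setNames(f / sum(f), c("A", "C", "G", "T")),
                               sample(2:3, 1))
    expect_equal(sum(pr), 1)
    expect_true(all(pr > 0))
  }
})

test_that("chisq_gof matches hand arithmetic and the null case", {
  null <- chisq_gof(c(30, 30, 40), c(0.3, 0.3, 0.4))
  expect_equal(null$chi2, 0)
  expect_equal(null$p, 1)
  expect_equal(null$df, 2)

  g <- chisq_gof(c(10, 20), c(0.5, 0.5))
  expect_equal(g$chi2, 10 / 3, tolerance = 1e-12)
  expect_equal(g$df, 1)

  expect_error(chisq_gof(c(10, 20), c(1, 0)), "pool")
  expect_error(chisq_gof(c(0, 0), c(0.5, 0.5)), "positive")
  ## named alignment: classes absent from observed count as zero
  probs <- expected_motif_probs(c(A = .3, C = .2, G = .2, T = .3), 2)
  g2 <- chisq_gof(c(AC = 5, AT = 15), probs)
  expect_equal(g2$df, 5)
  expect_equal(sum(g2$expected), 20)
})

test_that("chisq_gof agrees with independent recomputation to 1e-9", {
  set.seed(23)
  d_chi2 <- d_p <- d_df <- numeric(1000)
  for (i in 1:1000) {
    nclass <- sample(2:12, 1)
    probs <- runif(nclass, 0.05, 1)
    probs <- probs / sum(probs)
    obs <- rmultinom(1, sample(20:500, 1), probs)[, 1]
    g <- chisq_gof(obs, probs)
    o <- oracle_chisq(obs, probs)
    d_chi2[i] <- abs(g$chi2 - o$chi2) / max(1, abs(o$chi2))
    d_p[i] <- abs(g$p - o$p)
    d_df[i] <- abs(g$df - o$df)
  }
  expect_lt(max(d_chi2), 1e-9)
  expect_lt(max(d_p), 1e-9)
  expect_equal(max(d_df), 0)
})

test_that("placement_gof reproduces the two-class hand computation", {
  mk <- function(n_in, n_out, n_br = 0) data.frame(
    seq_id = "s", start = 0L, end = 10L, unit_len = 4L,
    motif_observed = "AAAT", motif_class = "AAAT", n_units = 3,
    total_len = 12L, kind = "perfect",
    status = c(rep("inside", n_in), rep("outside", n_out),
               rep("bridging", n_br)),
    stringsAsFactors = FALSE)
  ## split exactly at the ORF fraction -> chi2 = 0
  null <- placement_gof(mk(30, 70), orf_fraction = 0.3)
  expect_equal(null[null$repeat_type == "4", "chi2"], 0)
  ## n = 100, fraction 0.3, 50 inside: (50-30)^2/30 + (50-70)^2/70
  g <- placement_gof(mk(50, 50), orf_fraction = 0.3)
  row <- g[g$repeat_type == "total", ]
  expect_equal(row$chi2, 400 / 30 + 400 / 70, tolerance = 1e-12)
  expect_equal(row$df, 1)
  ## bridging placements are excluded but counted
  gb <- placement_gof(mk(50, 50, 7), orf_fraction = 0.3)
  rowb <- gb[gb$repeat_type == "total", ]
  expect_equal(rowb$n_bridging, 7)
  expect_equal(rowb$n_inside + rowb$n_outside, 107 - 7)
  expect_equal(rowb$chi2, row$chi2)
  ## types with no usable placements are NA rows
  expect_true(is.na(g[g$repeat_type == "2", "chi2"]))
  expect_error(placement_gof(mk(1, 1), orf_fraction = 0), "strictly")
})

test_that("placement test rejects planted inside-enrichment at stated power", {
  set.seed(41)
  f <- 0.3
  n <- 150
  reps <- 1000
  rej <- 0L
  for (i in seq_len(reps)) {
    n_in <- rbinom(1, n, 2 * f)  # two-fold enrichment
    g <- chisq_gof(c(n_in, n - n_in), c(f, 1 - f))
    if (g$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / reps, 0.8)
  ## and holds its size under the null
  rej0 <- 0L
  for (i in seq_len(reps)) {
    n_in <- rbinom(1, n, f)
    g <- chisq_gof(c(n_in, n - n_in), c(f, 1 - f))
    if (g$p < 0.05) rej0 <- rej0 + 1L
  }
  expect_lt(rej0 / reps, 0.08)
})

test_that("compare_datasets is a Welch t-test with degenerate conventions", {
  a <- c(4.4, 5.1, 3.9, 4.8, 4.2)
  expect_equal(compare_datasets(a, a)$p, 1)

  set.seed(15)
  dmax <- 0
  for (i in 1:50) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, 3, 9))
    y <- rnorm(sample(5:40, 1), mean = runif(1, 3, 9), sd = 2)
    got <- compare_datasets(x, y)
    ora <- oracle_welch(x, y)
    dmax <- max(dmax, abs(got$t - ora$t), abs(got$df - ora$df),
                abs(got$p - ora$p))
  }
  expect_lt(dmax, 1e-9)
  ## zero variance in both groups
  expect_equal(compare_datasets(c(3, 3), c(3, 3))$p, 1)
  expect_equal(compare_datasets(c(3, 3), c(4, 4))$p, 0)
})

test_that("compare_datasets detects the unit-number shift in simulation", {
  set.seed(29)
  rej <- 0L
  for (i in 1:200) {
    gssr <- 2 + rpois(60, 5.9)  # longer, more repetitive
    bssr <- 2 + rpois(60, 2.4)
    if (compare_datasets(gssr, bssr)$p < 0.001) rej <- rej + 1L
  }
  expect_gt(rej / 200, 0.95)
})

test_that("p-values print with the conventional floor", {
  expect_equal(format_pvalue(c(0.2341, 0.00004, NA)),
               c("0.2341", "<0.0001", NA))
})
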