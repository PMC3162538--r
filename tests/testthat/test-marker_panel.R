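toy_calls <- function(C = 0, D = 0, M = 0, A = 0, N = 0, miss = 0) {
  c(rep("codominant", C), rep("dominant", D), rep("monomorphic", M),
    rep("ambiguous", A), rep("no_amplification", N), rep("missing", miss))
}

test_that("compute_pi reproduces the worked values and bounds", {
  expect_equal(compute_pi(toy_calls(C = 7)), 100)
  expect_equal(compute_pi(toy_calls(M = 7)), 0)
  expect_equal(compute_pi(toy_calls(C = 1, D = 2, M = 2, miss = 2)), 40)
  expect_true(is.na(compute_pi(toy_calls(miss = 7))))
  ## all-dominant gives 50
  expect_equal(compute_pi(toy_calls(D = 7)), 50)
  ## ambiguous and failed amplification are scored but not polymorphic
  expect_equal(compute_pi(toy_calls(C = 2, A = 3, N = 2)), 100 * 4 / 14)
  expect_error(compute_pi(c("codominant", "weird")), "unknown")
})

test_that("PI is bounded and monotone in codominant count", {
  set.seed(37)
  for (i in 1:200) {
    calls <- sample(unname(ssrmine:::SCREEN_CALLS), 7, replace = TRUE)
    pi <- compute_pi(calls)
    if (!is.na(pi)) expect_true(pi >= 0 && pi <= 100)
  }
  ## monotone non-decreasing in C for fixed D, nd
  pis <- vapply(0:5, function(C)
    compute_pi(toy_calls(C = C, D = 1, M = 5 - C, miss = 1)), numeric(1))
  expect_true(all(diff(pis) >= 0))
  ## PI = 100 iff codominant in all scored populations
  expect_lt(compute_pi(toy_calls(C = 6, D = 1)), 100)
  expect_equal(compute_pi(toy_calls(C = 3, miss = 4)), 100)
})

test_that("polymorphism_summary counts by hand on a toy matrix", {
  calls <- rbind(
    mk1 = toy_calls(C = 2, M = 5),
    mk2 = toy_calls(D = 1, M = 6),
    mk3 = toy_calls(M = 7))
  colnames(calls) <- paste0("pop", 1:7)
  sm <- ssrmine:::new_screening_matrix(
    markers = data.frame(marker = rownames(calls),
                         source = c("GSSR", "BSSR", "BSSR"),
                         total_units = c(12, 5, 4),
                         stringsAsFactors = FALSE),
    calls = calls)
  ps <- polymorphism_summary(sm)
  expect_equal(ps$n_poly_ge1, 2)
  expect_equal(ps$n_poly_ge2, 1)
  expect_equal(ps$pct_poly_ge1, 100 * 2 / 3)
  expect_equal(ps$by_source$n_poly_ge1[ps$by_source$source == "GSSR"], 1)
  expect_equal(unname(ps$pi), c(100 * 4 / 14, 100 * 1 / 14, 0))
  ## all-monomorphic matrix -> zero counts
  calls0 <- matrix("monomorphic", 3, 7,
                   dimnames = list(rownames(calls), colnames(calls)))
  sm0 <- ssrmine:::new_screening_matrix(sm$markers, calls0)
  expect_equal(polymorphism_summary(sm0)$n_poly_ge1, 0)
})

test_that("summary is invariant to marker and population ordering", {
  spec <- panel_sim_spec(n_markers = 60, n_gssr = 30, seed = 4)
  sm <- gen_screening_matrix(spec)
  ps <- polymorphism_summary(sm)
  perm <- sample(nrow(sm$calls))
  pperm <- sample(ncol(sm$calls))
  sm2 <- ssrmine:::new_screening_matrix(sm$markers[perm, ],
                                        sm$calls[perm, pperm])
  ps2 <- polymorphism_summary(sm2)
  expect_equal(ps2$n_poly_ge1, ps$n_poly_ge1)
  expect_equal(ps2$n_poly_ge2, ps$n_poly_ge2)
  expect_equal(unname(sort(ps2$pi)), unname(sort(ps$pi)))
  expect_equal(ps2$pi[names(ps$pi)], ps$pi)
})

test_that("screening matrices survive a TSV round trip", {
  spec <- panel_sim_spec(n_markers = 40, n_gssr = 20, seed = 12)
  sm <- gen_screening_matrix(spec)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_screening_matrix(sm, tsv)
  back <- read_screening_matrix(tsv)
  expect_equal(back$markers, sm$markers)
  expect_equal(back$calls, sm$calls)
})

test_that("repeat classes bin at the documented boundaries", {
  expect_equal(as.character(bin_repeat_class(c(0, 5, 6, 10, 11, 15, 16))),
               c("<6", "<6", "6-10", "6-10", "11-15", "11-15", ">15"))
  ## multi-SSR amplicons use summed units: (AT)6 + (CTT)5 = 11
  expect_equal(as.character(bin_repeat_class(6 + 5)), "11-15")
  expect_error(bin_repeat_class(-1), ">= 0")
})

test_that("pi_vs_repeats recovers a perfect linear relationship", {
  ## markers where PI is exactly linear in units: use constructed calls
  calls <- rbind(
    a = toy_calls(C = 0, M = 7), b = toy_calls(C = 1, M = 6),
    c = toy_calls(C = 2, M = 5), d = toy_calls(C = 3, M = 4))
  colnames(calls) <- paste0("pop", 1:7)
  sm <- ssrmine:::new_screening_matrix(
    data.frame(marker = rownames(calls), source = "GSSR",
               total_units = c(2, 4, 6, 8), stringsAsFactors = FALSE),
    calls)
  fit <- pi_vs_repeats(sm)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, (100 / 7) / 2, tolerance = 1e-9)

  ## constant PI -> undefined correlation
  calls2 <- calls; calls2[] <- "monomorphic"
  sm2 <- ssrmine:::new_screening_matrix(sm$markers, calls2)
  expect_true(is.na(pi_vs_repeats(sm2)$r))

  ## zero-variance predictor is an error
  sm3 <- sm; sm3$markers$total_units <- 5
  expect_error(pi_vs_repeats(sm3), "zero variance")
})

test_that("simulated class-graded polymorphism yields a positive PI trend", {
  spec <- panel_sim_spec(n_markers = 300, n_gssr = 156, seed = 21)
  sm <- gen_screening_matrix(spec)
  fit <- pi_vs_repeats(sm)
  expect_gt(fit$r, 0)
  expect_lt(fit$p, 0.05)
  expect_gt(fit$slope, 0)
})

test_that("segregation chi-square matches the 1:2:1 and 3:1 expectations", {
  expect_equal(segregation_chisq(c(25, 50, 25), "codominant")$chi2, 0)
  expect_false(segregation_chisq(c(25, 50, 25), "codominant")$distorted)
  expect_equal(segregation_chisq(c(75, 25), "dominant")$chi2, 0)
  g <- segregation_chisq(c(10, 50, 40), "codominant")
  expect_equal(g$chi2, 18)
  expect_equal(g$df, 2)
  expect_true(g$distorted)
  expect_error(segregation_chisq(c(1, 2), "codominant"), "3 counts")
})

test_that("amplicon outcomes classify against the size window", {
  expect_equal(classify_amplicon(c(250), 200, 100), "expected_size")
  expect_equal(classify_amplicon(c(301), 200, 100), "off_size")
  expect_equal(classify_amplicon(c(301, 250), 200, 100), "expected_size")
  expect_equal(classify_amplicon(numeric(), 200), "none")
  expect_equal(classify_amplicon(NA_real_, 200), "none")
})

test_that("transfer_summary totals, groups and the high-rate set", {
  spec <- panel_sim_spec(n_markers = 40, seed = 3,
                         group_sizes = c(carota = 3,
                                         daucus_non_carota = 3,
                                         non_daucus = 2))
  tm <- gen_transfer_matrix(spec)
  ts <- transfer_summary(tm)
  expect_equal(ts$n_cells, 40 * 8)
  expect_equal(sum(ts$per_group$n_success_total), ts$n_success)
  expect_equal(sum(ts$per_accession$n_success), ts$n_success)

  ## all-success matrix -> 100% everywhere
  tm2 <- tm
  tm2$outcome[] <- "expected_size"
  ts2 <- transfer_summary(tm2)
  expect_equal(ts2$pct_success, 100)
  expect_true(all(ts2$per_accession$pct_success == 100))
  expect_equal(unname(ts2$n_all_members),
               rep(40L, 3))

  ## a marker succeeding in exactly 12 of 15 non-carrot accessions counts
  ## as broadly transferable (12/15 = 0.8)
  outcome <- matrix("none", 1, 23)
  groups <- rep(c("carota", "daucus_non_carota", "non_daucus"), c(8, 8, 7))
  outcome[1, c(rep(TRUE, 8), rep(c(TRUE, FALSE), c(12, 3)))] <-
    "expected_size"
  acc <- data.frame(accession = sprintf("a%02d", 1:23), group = groups,
                    stringsAsFactors = FALSE)
  colnames(outcome) <- acc$accession
  rownames(outcome) <- "mk1"
  tm3 <- ssrmine:::new_transfer_matrix(
    data.frame(marker = "mk1", expected_size = 200,
               stringsAsFactors = FALSE),
    acc, outcome,
    matrix(vector("list", 23), 1, 23, dimnames = dimnames(outcome)))
  expect_equal(transfer_summary(tm3)$n_high_noncarrot, 1)
  ## 11 of 15 falls below the threshold
  outcome[1, 20:23] <- "none"
  tm4 <- tm3; tm4$outcome <- outcome
  expect_equal(transfer_summary(tm4)$n_high_noncarrot, 0)
})

test_that("transfer matrices survive a TSV round trip", {
  spec <- panel_sim_spec(n_markers = 25, seed = 8)
  tm <- gen_transfer_matrix(spec)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_transfer_matrix(tm, tsv)
  back <- read_transfer_matrix(tsv, size_window = spec$size_window)
  expect_setequal(back$markers$marker, tm$markers$marker)
  m <- match(tm$markers$marker, back$markers$marker)
  expect_equal(back$markers$expected_size[m], tm$markers$expected_size)
  expect_equal(back$outcome[tm$markers$marker, tm$accessions$accession],
               tm$outcome)
})

test_that("allele counting clusters at gel resolution", {
  expect_equal(interspecific_allele_count(c(200, 200, 200)), 1)
  expect_equal(interspecific_allele_count(c(200, 201, 210)), 2)
  expect_equal(interspecific_allele_count(numeric()), 0)
  expect_equal(interspecific_allele_count(c(100, 102, 104, 120),
                                          resolution = 3), 2)
  expect_equal(interspecific_allele_count(c(100, 103, 106), resolution = 3),
               3)
})
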