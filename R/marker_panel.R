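SCREEN_CALLS <- c(C = "codominant", D = "dominant", M = "monomorphic",
                  A = "ambiguous", N = "no_amplification", `-` = "missing")

#' Read an F2 screening matrix from TSV
#'
#' Expected layout: one header row; columns `marker`, `source`
#' (`GSSR`/`BSSR`), `total_units` (summed repeat units of all perfect SSRs
#' in the amplicon), then one column per population with single-letter
#' calls: `C` codominant, `D` dominant, `M` monomorphic, `A` ambiguous,
#' `N` no amplification, `-` missing.
#'
#' @param path TSV path.
#' @return A `screening_matrix`: list with `markers` (data.frame: `marker`,
#'   `source`, `total_units`) and `calls` (character matrix markers x
#'   populations with full call words).
#' @export
read_screening_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c("marker", "source", "total_units")
  if (!all(need %in% names(df)))
    stop("screening TSV must have columns: ", paste(need, collapse = ", "))
  pop_cols <- setdiff(names(df), need)
  if (length(pop_cols) == 0L) stop("no population columns found")
  calls <- as.matrix(df[, pop_cols, drop = FALSE])
  bad <- !(calls %in% names(SCREEN_CALLS))
  if (any(bad))
    stop("unknown call code(s): ", paste(unique(calls[bad]), collapse = ", "))
  calls[] <- SCREEN_CALLS[calls]
  rownames(calls) <- df$marker
  new_screening_matrix(
    markers = data.frame(marker = df$marker, source = df$source,
                         total_units = as.numeric(df$total_units),
                         stringsAsFactors = FALSE),
    calls = calls)
}

new_screening_matrix <- function(markers, calls) {
  stopifnot(nrow(markers) == nrow(calls),
            all(calls %in% SCREEN_CALLS))
  structure(list(markers = markers, calls = calls),
            class = "screening_matrix")
}

#' Write a screening matrix to TSV
#'
#' @param sm A `screening_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screening_matrix <- function(sm, path) {
  codes <- stats::setNames(names(SCREEN_CALLS), SCREEN_CALLS)
  calls <- sm$calls
  calls[] <- codes[calls]
  out <- cbind(sm$markers, as.data.frame(calls, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Polymorphism index of one marker
#'
#' `PI = 100 * (2C + D) / (2 * (n - nd))`, where `C` and `D` are the
#' numbers of populations in which the marker segregated codominantly and
#' dominantly, `n` is the number of populations screened and `nd` the
#' number with no information (call `missing`). Ambiguous and
#' failed-amplification calls count as not polymorphic but are still
#' scored populations. PI is bounded on \[0, 100\]; 100 means codominant in
#' every scored population.
#'
#' @param calls Character vector of per-population calls (full words as in
#'   a `screening_matrix` row).
#' @return PI in percent, or `NA` when no population was scored.
#' @examples
#' compute_pi(rep("codominant", 7))                       # 100
#' compute_pi(c("codominant", "dominant", "dominant",
#'              "monomorphic", "monomorphic", "missing", "missing"))  # 40
#' @export
compute_pi <- function(calls) {
  bad <- setdiff(calls, SCREEN_CALLS)
  if (length(bad)) stop("unknown call(s): ", paste(bad, collapse = ", "))
  n <- length(calls)
  nd <- sum(calls == "missing")
  if (nd == n) return(NA_real_)
  C <- sum(calls == "codominant")
  D <- sum(calls == "dominant")
  100 * (2 * C + D) / (2 * (n - nd))
}

#' Marker polymorphism summary
#'
#' Counts markers polymorphic (codominant or dominant) in at least one and
#' at least two populations, overall and by source tag, plus per-population
#' polymorphic percentages and mean PI by source.
#'
#' @param sm A `screening_matrix`.
#' @return A list: `n_markers`, `n_poly_ge1`, `pct_poly_ge1`, `n_poly_ge2`,
#'   `by_source` (data.frame), `per_population` (data.frame), `pi`
#'   (per-marker PI vector), `mean_pi_by_source`.
#' @export
polymorphism_summary <- function(sm) {
  poly <- sm$calls %in% c("codominant", "dominant")
  dim(poly) <- dim(sm$calls)
  n_poly_pops <- rowSums(poly)
  pi <- apply(sm$calls, 1L, compute_pi)
  src <- sm$markers$source
  by_source <- do.call(rbind, lapply(unique(src), function(s) {
    sel <- src == s
    data.frame(source = s,
               n_markers = sum(sel),
               n_poly_ge1 = sum(n_poly_pops[sel] >= 1L),
               pct_poly_ge1 = 100 * mean(n_poly_pops[sel] >= 1L),
               n_poly_ge2 = sum(n_poly_pops[sel] >= 2L),
               mean_pi = mean(pi[sel], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  per_pop <- data.frame(
    population = colnames(sm$calls),
    n_polymorphic = colSums(poly),
    pct_polymorphic = 100 * colMeans(poly),
    stringsAsFactors = FALSE
  )
  rownames(per_pop) <- NULL
  list(n_markers = nrow(sm$markers),
       n_poly_ge1 = sum(n_poly_pops >= 1L),
       pct_poly_ge1 = 100 * mean(n_poly_pops >= 1L),
       n_poly_ge2 = sum(n_poly_pops >= 2L),
       by_source = by_source,
       per_population = per_pop,
       pi = stats::setNames(pi, sm$markers$marker),
       mean_pi_by_source = stats::setNames(by_source$mean_pi,
                                           by_source$source))
}

#' Repeat-number class of a marker
#'
#' Markers are binned by the summed repeat units of all perfect SSRs in
#' their amplicon into the four classes used for polymorphism-by-repeat
#' analyses.
#'
#' @param total_units Numeric vector of summed repeat units.
#' @return Factor with levels `"<6"`, `"6-10"`, `"11-15"`, `">15"`.
#' @examples
#' bin_repeat_class(c(5, 6, 11, 16))
#' @export
bin_repeat_class <- function(total_units) {
  if (any(total_units < 0)) stop("total_units must be >= 0")
  cut(total_units, breaks = c(-Inf, 5, 10, 15, Inf),
      labels = c("<6", "6-10", "11-15", ">15"))
}

#' Relationship between polymorphism and repeat number
#'
#' Pearson correlation and simple linear regression of the polymorphism
#' index on the summed repeat units, plus per-repeat-class mean PI and
#' percent-polymorphic.
#'
#' @param sm A `screening_matrix`.
#' @return A list: `r`, `p`, `slope`, `intercept`, `n`, and `by_class`
#'   (data.frame with `class`, `n`, `mean_pi`, `pct_polymorphic`). `r` and
#'   `p` are `NA` when PI has zero variance.
#' @export
pi_vs_repeats <- function(sm) {
  pi <- apply(sm$calls, 1L, compute_pi)
  units <- sm$markers$total_units
  ok <- !is.na(pi)
  if (sum(ok) < 3L) stop("need at least 3 markers with defined PI")
  x <- units[ok]; y <- pi[ok]
  if (stats::var(x) == 0) stop("repeat-unit predictor has zero variance")
  if (stats::var(y) == 0) {
    r <- NA_real_; pv <- NA_real_
    fit <- c(intercept = mean(y), slope = 0)
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); pv <- ct$p.value
    co <- stats::coef(stats::lm(y ~ x))
    fit <- c(intercept = unname(co[1L]), slope = unname(co[2L]))
  }
  cls <- bin_repeat_class(units)
  poly1 <- rowSums(matrix(sm$calls %in% c("codominant", "dominant"),
                          nrow = nrow(sm$calls))) >= 1L
  by_class <- do.call(rbind, lapply(levels(cls), function(cl) {
    sel <- cls == cl
    data.frame(class = cl, n = sum(sel),
               mean_pi = if (any(sel)) mean(pi[sel], na.rm = TRUE)
                         else NA_real_,
               pct_polymorphic = if (any(sel)) 100 * mean(poly1[sel])
                                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(r = r, p = pv, slope = unname(fit["slope"]),
       intercept = unname(fit["intercept"]), n = sum(ok),
       by_class = by_class)
}

#' F2 segregation distortion test
#'
#' Chi-square test of observed F2 genotype counts against 1:2:1 (A:H:B,
#' codominant; df = 2) or 3:1 (dominant; df = 1). Distortion is declared at
#' `p < alpha` (default 0.01).
#'
#' @param counts Numeric vector of genotype counts: length 3 (A, H, B) for
#'   codominant, length 2 (dominant class, recessive class) for dominant.
#' @param mode `"codominant"` or `"dominant"`.
#' @param alpha Significance level for the distortion flag.
#' @return A list with `chi2`, `df`, `p`, `distorted`.
#' @examples
#' segregation_chisq(c(10, 50, 40), "codominant")$chi2  # 18
#' @export
segregation_chisq <- function(counts, mode = c("codominant", "dominant"),
                              alpha = 0.01) {
  mode <- match.arg(mode)
  probs <- if (mode == "codominant") c(1, 2, 1) / 4 else c(3, 1) / 4
  if (length(counts) != length(probs))
    stop("expected ", length(probs), " counts for mode '", mode, "'")
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with positive total")
  gof <- chisq_gof(counts, probs, label = mode)
  list(chi2 = gof$chi2, df = gof$df, p = gof$p,
       distorted = gof$p < alpha)
}

#' Classify an amplification outcome from fragment sizes
#'
#' @param sizes Numeric vector of observed fragment sizes in bp (may be
#'   empty / all `NA`).
#' @param expected_size Expected amplicon size in the source species.
#' @param size_window Maximum deviation in bp still considered the expected
#'   size (default 100).
#' @return `"expected_size"`, `"off_size"` (all fragments deviate more than
#'   the window) or `"none"`.
#' @export
classify_amplicon <- function(sizes, expected_size, size_window = 100) {
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) == 0L) return("none")
  if (any(abs(sizes - expected_size) <= size_window)) "expected_size"
  else "off_size"
}

#' Read a transferability matrix from long-format TSV
#'
#' Expected columns: `marker`, `expected_size`, `accession`, `group` (one
#' of `carota`, `daucus_non_carota`, `non_daucus`), `size` (observed
#' fragment size in bp, `NA`/empty when no product; multiple fragments
#' separated by `;`). The outcome of each cell is derived with
#' [classify_amplicon()].
#'
#' @param path TSV path.
#' @param size_window Expected-size window in bp (default 100).
#' @return A `transfer_matrix`: list with `markers` (data.frame `marker`,
#'   `expected_size`), `accessions` (data.frame `accession`, `group`),
#'   `outcome` (character matrix markers x accessions) and `sizes` (list
#'   matrix of fragment-size vectors).
#' @export
read_transfer_matrix <- function(path, size_window = 100) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("marker", "expected_size", "accession", "group", "size")
  if (!all(need %in% names(df)))
    stop("transfer TSV must have columns: ", paste(need, collapse = ", "))
  markers <- unique(df[, c("marker", "expected_size")])
  accessions <- unique(df[, c("accession", "group")])
  bad <- setdiff(accessions$group,
                 c("carota", "daucus_non_carota", "non_daucus"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  outcome <- matrix("none", nrow(markers), nrow(accessions),
                    dimnames = list(markers$marker, accessions$accession))
  sizes <- matrix(vector("list", length(outcome)), nrow(markers),
                  nrow(accessions),
                  dimnames = dimnames(outcome))
  for (i in seq_len(nrow(df))) {
    mk <- df$marker[i]; ac <- df$accession[i]
    sz <- suppressWarnings(as.numeric(strsplit(as.character(df$size[i]),
                                               ";")[[1L]]))
    sz <- sz[!is.na(sz)]
    sizes[[mk, ac]] <- sz
    outcome[mk, ac] <- classify_amplicon(
      sz, markers$expected_size[markers$marker == mk][1L], size_window)
  }
  new_transfer_matrix(markers, accessions, outcome, sizes)
}

new_transfer_matrix <- function(markers, accessions, outcome, sizes) {
  stopifnot(all(outcome %in% c("expected_size", "off_size", "none")))
  structure(list(markers = markers, accessions = accessions,
                 outcome = outcome, sizes = sizes),
            class = "transfer_matrix")
}

#' Write a transferability matrix to long-format TSV
#'
#' @param tm A `transfer_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transfer_matrix <- function(tm, path) {
  rows <- expand.grid(mi = seq_len(nrow(tm$markers)),
                      ai = seq_len(nrow(tm$accessions)))
  out <- data.frame(
    marker = tm$markers$marker[rows$mi],
    expected_size = tm$markers$expected_size[rows$mi],
    accession = tm$accessions$accession[rows$ai],
    group = tm$accessions$group[rows$ai],
    size = vapply(seq_len(nrow(rows)), function(i) {
      sz <- tm$sizes[[rows$mi[i], rows$ai[i]]]
      if (length(sz) == 0L) "" else paste(sz, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$marker, out$accession), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-taxa transferability summary
#'
#' Summarizes heterologous amplification success: per-accession counts and
#' percents, per-group totals and means, the number of markers succeeding
#' in every member of each group, and the number succeeding in at least
#' `high_rate` of the non-source-species accessions (groups other than
#' `carota`).
#'
#' @param tm A `transfer_matrix`.
#' @param high_rate Success fraction defining broadly transferable markers
#'   (default 0.8, i.e. at least 12 of 15 non-carrot accessions in the
#'   canonical 8/8/7 panel).
#' @return A list: `n_cells`, `n_success`, `pct_success`, `per_accession`,
#'   `per_group` (with `n_success_total` summing to `n_success`),
#'   `n_all_members` (named by group), `n_high_noncarrot`,
#'   `high_noncarrot_markers`.
#' @export
transfer_summary <- function(tm, high_rate = 0.8) {
  succ <- tm$outcome == "expected_size"
  per_acc <- data.frame(
    accession = tm$accessions$accession,
    group = tm$accessions$group,
    n_success = colSums(succ),
    pct_success = 100 * colMeans(succ),
    stringsAsFactors = FALSE
  )
  rownames(per_acc) <- NULL
  groups <- unique(tm$accessions$group)
  per_group <- do.call(rbind, lapply(groups, function(g) {
    sel <- tm$accessions$group == g
    data.frame(group = g,
               n_accessions = sum(sel),
               n_success_total = sum(succ[, sel, drop = FALSE]),
               mean_n_success = mean(colSums(succ[, sel, drop = FALSE])),
               mean_pct_success = 100 * mean(colMeans(succ[, sel,
                                                           drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  n_all <- vapply(groups, function(g) {
    sel <- tm$accessions$group == g
    sum(rowSums(succ[, sel, drop = FALSE]) == sum(sel))
  }, integer(1))
  non_carrot <- tm$accessions$group != "carota"
  frac_nc <- rowMeans(succ[, non_carrot, drop = FALSE])
  high <- frac_nc >= high_rate - 1e-9
  list(n_cells = length(succ),
       n_success = sum(succ),
       pct_success = 100 * mean(succ),
       per_accession = per_acc,
       per_group = per_group,
       n_all_members = stats::setNames(n_all, groups),
       n_high_noncarrot = sum(high),
       high_noncarrot_markers = tm$markers$marker[high])
}

#' Count distinct alleles from fragment sizes at gel resolution
#'
#' Single-linkage clustering of fragment sizes: sizes closer than
#' `resolution` bp are merged into one allele (a gel cannot separate them);
#' the number of clusters is the allele count.
#'
#' @param sizes Numeric vector of fragment sizes in bp across accessions.
#' @param resolution Minimum resolvable size difference in bp (default 3).
#' @return Integer allele count (0 for empty input).
#' @examples
#' interspecific_allele_count(c(200, 201, 210))  # 2
#' @export
interspecific_allele_count <- function(sizes, resolution = 3) {
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) == 0L) return(0L)
  s <- sort(sizes)
  ## in one dimension, single linkage = splitting at gaps >= resolution
  sum(diff(s) >= resolution) + 1L
}
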