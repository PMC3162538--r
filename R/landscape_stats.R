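#' SSR density per megabase
#'
#' @param n_loci Number of loci.
#' @param total_mbp Dataset size in Mbp.
#' @return Loci per Mbp.
#' @examples
#' round(ssr_density(234, 1.74), 1)  # 134.5
#' @export
ssr_density <- function(n_loci, total_mbp) {
  if (any(total_mbp <= 0)) stop("total_mbp must be positive")
  n_loci / total_mbp
}

#' Repeat-type distribution table
#'
#' Aggregates perfect loci by unit length (counts, percent of total perfect,
#' mean unit number, mean length, density per Mbp, most frequent motif
#' classes), with summary rows for all perfect loci and for compound loci.
#' Densities use the dataset Mbp from `summary`; pass `density = FALSE` for
#' datasets that are not a random sample of the genome (e.g. an
#' enrichment-library set), where a density would be misleading.
#'
#' @param perfect Perfect-SSR `data.frame` (after compound partitioning, or
#'   not -- the caller decides what "perfect" means for the table).
#' @param compound Compound-SSR `data.frame` (may be `NULL`).
#' @param summary One-row dataset summary from [summarize_dataset()].
#' @param unit_len_range Unit lengths to tabulate (default `2:8`).
#' @param density Report densities? (default `TRUE`).
#' @param n_top Number of most-frequent motif classes listed per row.
#' @return A `data.frame` with one row per unit length plus rows
#'   `total_perfect` and `compound`.
#' @export
repeat_type_table <- function(perfect, compound = NULL, summary,
                              unit_len_range = 2:8, density = TRUE,
                              n_top = 3L) {
  total <- nrow(perfect)
  mbp <- summary$total_mbp
  row_for <- function(sub, label) {
    cnt <- nrow(sub)
    top <- ""
    if (cnt > 0L && !all(is.na(sub$motif_class))) {
      tb <- sort(table(sub$motif_class), decreasing = TRUE)
      tb <- tb[seq_len(min(n_top, length(tb)))]
      top <- paste(sprintf("%s(%d)", names(tb), as.integer(tb)),
                   collapse = ", ")
    }
    data.frame(
      repeat_type = label,
      count = cnt,
      percent = if (total > 0L) 100 * cnt / total else 0,
      mean_n_units = if (cnt > 0L) mean(sub$n_units) else NA_real_,
      mean_total_len = if (cnt > 0L) mean(sub$total_len) else NA_real_,
      density = if (density) ssr_density(cnt, mbp) else NA_real_,
      top_motifs = top,
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(unit_len_range, function(k)
    row_for(perfect[perfect$unit_len == k, , drop = FALSE], as.character(k)))
  rows <- c(rows, list(row_for(perfect, "total_perfect")))
  comp <- if (is.null(compound)) empty_compound_frame() else compound
  comp_row <- row_for(comp[, setdiff(names(comp), c("members", "n_members")),
                           drop = FALSE], "compound")
  comp_row$top_motifs <- ""
  rows <- c(rows, list(comp_row))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected motif-class probabilities from base composition
#'
#' Under a zero-order (mononucleotide) composition model, the probability of
#' a repeat unit is the product of its base frequencies; the probability of
#' a canonical class is the normalized sum over the class's cyclic
#' rotations. Homopolymeric and other non-primitive units are excluded.
#'
#' @param base_freqs Named numeric vector with elements `A`, `C`, `G`, `T`
#'   (need not sum exactly to 1; it is normalized), or a one-row summary
#'   from [summarize_dataset()].
#' @param k Unit length (2 or 3 in the motif tables; any k in 2..8 works).
#' @return Named probability vector over canonical classes, summing to 1.
#' @examples
#' expected_motif_probs(c(A = .25, C = .25, G = .25, T = .25), 2)  # all 1/6
#' @export
expected_motif_probs <- function(base_freqs, k) {
  if (is.data.frame(base_freqs))
    base_freqs <- c(A = base_freqs$p_a, C = base_freqs$p_c,
                    G = base_freqs$p_g, T = base_freqs$p_t)
  if (!all(c("A", "C", "G", "T") %in% names(base_freqs)))
    stop("base_freqs must be named A, C, G, T")
  p <- base_freqs[c("A", "C", "G", "T")] / sum(base_freqs)
  k <- as.integer(k)
  if (k < 2L || k > 8L) stop("k must be in 2..8")
  units <- primitive_units(k)
  w <- vapply(strsplit(units, ""), function(ch) prod(p[ch]), numeric(1))
  cls <- canonical_motif(units)
  probs <- tapply(w, cls, sum)
  tot <- sum(probs)
  if (tot <= 0) stop("degenerate base composition: all class weights are 0")
  out <- as.numeric(probs) / tot
  names(out) <- names(probs)
  out[order(names(out))]
}

#' Chi-square goodness-of-fit test
#'
#' Tests observed per-class counts against expected class probabilities,
#' with `df = classes - 1` and an upper-tail p-value.
#'
#' @param observed Named (or plain) numeric vector of counts.
#' @param expected_probs Probability vector; if both are named, classes are
#'   aligned by name and classes absent from `observed` count as 0.
#' @param label Optional label carried into the result.
#' @return A list with `label`, `chi2`, `df`, `p`, `observed`, `expected`.
#' @export
chisq_gof <- function(observed, expected_probs, label = "") {
  if (!is.null(names(observed)) && !is.null(names(expected_probs))) {
    full <- stats::setNames(numeric(length(expected_probs)),
                            names(expected_probs))
    unknown <- setdiff(names(observed), names(full))
    if (length(unknown))
      stop("observed class(es) not in expected set: ",
           paste(unknown, collapse = ", "))
    full[names(observed)] <- observed
    observed <- full
  }
  if (length(observed) != length(expected_probs))
    stop("observed and expected_probs must have the same number of classes")
  if (length(observed) < 2L) stop("at least 2 classes are required")
  total <- sum(observed)
  if (total <= 0) stop("total observed count must be positive")
  expected_probs <- expected_probs / sum(expected_probs)
  expected <- total * expected_probs
  if (any(expected == 0))
    stop("an expected count is 0; pool classes before testing")
  ht <- suppressWarnings(stats::chisq.test(x = observed, p = expected_probs))
  list(label = label,
       chi2 = unname(ht$statistic),
       df = unname(ht$parameter),
       p = unname(ht$p.value),
       observed = observed,
       expected = expected)
}

#' Inside/outside-ORF placement goodness-of-fit
#'
#' For each repeat type (unit length) and overall, tests whether the number
#' of SSRs inside ORFs matches the expectation from the fraction of dataset
#' bases inside ORFs (two classes, df = 1). Bridging SSRs are excluded.
#'
#' @param placements SSR `data.frame` with `status` column from
#'   [classify_placement()].
#' @param orf_fraction Proportion of dataset bases inside retained ORFs
#'   (strictly between 0 and 1).
#' @param unit_len_range Unit lengths reported (default `2:8`).
#' @return A `data.frame` with one row per repeat type plus `total`:
#'   `n_inside`, `n_outside`, `n_bridging`, `chi2`, `df`, `p` (`NA` rows
#'   when no usable placements exist for a type).
#' @export
placement_gof <- function(placements, orf_fraction, unit_len_range = 2:8) {
  if (orf_fraction <= 0 || orf_fraction >= 1)
    stop("orf_fraction must be strictly between 0 and 1")
  one <- function(sub, label) {
    n_in <- sum(sub$status == "inside")
    n_out <- sum(sub$status == "outside")
    n_br <- sum(sub$status == "bridging")
    if (n_in + n_out == 0L)
      return(data.frame(repeat_type = label, n_inside = n_in,
                        n_outside = n_out, n_bridging = n_br,
                        chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                        stringsAsFactors = FALSE))
    gof <- chisq_gof(c(inside = n_in, outside = n_out),
                     c(inside = orf_fraction, outside = 1 - orf_fraction),
                     label = label)
    data.frame(repeat_type = label, n_inside = n_in, n_outside = n_out,
               n_bridging = n_br, chi2 = gof$chi2, df = gof$df, p = gof$p,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(unit_len_range, function(k)
    one(placements[placements$unit_len == k, , drop = FALSE],
        as.character(k)))
  rows <- c(rows, list(one(placements, "total")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a repeat statistic between two datasets
#'
#' Welch two-sample t-test on a per-locus metric (`n_units` or `total_len`),
#' as used to contrast enrichment-library SSRs with sequence-mined SSRs.
#'
#' @param a,b Either SSR `data.frame`s (the `metric` column is extracted) or
#'   numeric vectors.
#' @param metric `"n_units"` or `"total_len"`; ignored for numeric input.
#' @return A list with `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
compare_datasets <- function(a, b, metric = c("n_units", "total_len")) {
  metric <- match.arg(metric)
  va <- if (is.data.frame(a)) a[[metric]] else as.numeric(a)
  vb <- if (is.data.frame(b)) b[[metric]] else as.numeric(b)
  if (length(va) < 2L || length(vb) < 2L)
    stop("both samples need n >= 2")
  if (stats::var(va) == 0 && stats::var(vb) == 0) {
    ## degenerate: no within-group variability
    if (mean(va) == mean(vb))
      return(list(mean_a = mean(va), mean_b = mean(vb), t = 0,
                  df = NA_real_, p = 1))
    return(list(mean_a = mean(va), mean_b = mean(vb), t = Inf,
                df = NA_real_, p = 0))
  }
  ht <- stats::t.test(va, vb, var.equal = FALSE)
  list(mean_a = mean(va), mean_b = mean(vb),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Format a p-value the way motif tables print them
#'
#' @param p P-value(s).
#' @param digits Decimal places (default 4).
#' @return Character vector; values below 10^-digits print as `"<0.0001"`.
#' @export
format_pvalue <- function(p, digits = 4L) {
  floorv <- 10^(-digits)
  ifelse(is.na(p), NA_character_,
         ifelse(p < floorv, paste0("<", format(floorv, scientific = FALSE)),
                formatC(p, format = "f", digits = digits)))
}
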