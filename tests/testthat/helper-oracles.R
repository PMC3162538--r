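# Independent oracles used to cross-check the implementation. These are
# deliberately written as plain character/arithmetic code paths, separate
# from the regex- and chisq.test-based implementations in the package.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_primitive <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        unit == strrep(substr(unit, 1L, d), k %/% d)) return(FALSE)
  }
  TRUE
}

# Leftmost-greedy scan for perfect repeats of one unit length, complete
# units only, no regular expressions.
oracle_detect_k <- function(s, k, min_units, min_total) {
  ch <- strsplit(s, "")[[1L]]
  n <- length(ch)
  m <- max(min_units, ceiling(min_total / k))
  out <- list()
  p <- 1L
  while (p + k * m - 1L <= n) {
    unit <- ch[p:(p + k - 1L)]
    if (any(!unit %in% ORACLE_BASES)) { p <- p + 1L; next }
    u <- 1L
    while (p + (u + 1L) * k - 1L <= n &&
           all(ch[(p + u * k):(p + (u + 1L) * k - 1L)] == unit)) u <- u + 1L
    if (u >= m) {
      if (oracle_primitive(paste(unit, collapse = "")))
        out[[length(out) + 1L]] <- data.frame(
          start = p - 1L, end = p - 1L + u * k, unit_len = k, n_units = u)
      p <- p + u * k
    } else p <- p + 1L
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), unit_len = integer(),
               n_units = integer())
}

oracle_detect_ssrs <- function(s, cfg = ssr_search_config()) {
  ks <- seq(cfg$unit_len_range[1L], cfg$unit_len_range[2L])
  out <- do.call(rbind, lapply(ks, function(k)
    oracle_detect_k(s, k, cfg$min_units, cfg$min_total_len)))
  out[order(out$start, out$unit_len), , drop = FALSE]
}

# Plain-arithmetic chi-square goodness of fit.
oracle_chisq <- function(obs, probs) {
  probs <- probs / sum(probs)
  e <- sum(obs) * probs
  chi2 <- sum((obs - e)^2 / e)
  list(chi2 = chi2, df = length(obs) - 1L,
       p = stats::pchisq(chi2, length(obs) - 1L, lower.tail = FALSE))
}

# Closed-form Welch t-test.
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

random_seq <- function(n, gc = 0.4) {
  paste(sample(ORACLE_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

ssr_key <- function(df) paste(df$seq_id, df$start, df$end, df$unit_len)
orf_key <- function(df) paste(df$seq_id, df$start, df$end, df$strand)

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}
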