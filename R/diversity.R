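#' Read a diploid genotype table from long-format TSV
#'
#' Expected columns: `individual`, `locus`, `allele1`, `allele2` (allele
#' sizes in bp; empty, `NA` or `-` marks a missing genotype; homozygotes
#' repeat the size).
#'
#' @param path TSV path.
#' @return A `genotype_table`: list with `individuals`, `loci` and `calls`
#'   (data.frame `individual`, `locus`, `allele1`, `allele2`).
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "", "-"))
  need <- c("individual", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("genotype TSV must have columns: ", paste(need, collapse = ", "))
  df$allele1 <- as.numeric(df$allele1)
  df$allele2 <- as.numeric(df$allele2)
  half <- xor(is.na(df$allele1), is.na(df$allele2))
  if (any(half))
    stop("half-missing genotype for individual '",
         df$individual[which(half)[1L]], "' at locus '",
         df$locus[which(half)[1L]], "'")
  if (any(df$allele1 <= 0 | df$allele2 <= 0, na.rm = TRUE))
    stop("allele sizes must be positive")
  if (anyDuplicated(df[, c("individual", "locus")]))
    stop("duplicate (individual, locus) entries")
  new_genotype_table(df)
}

new_genotype_table <- function(calls) {
  structure(list(individuals = unique(calls$individual),
                 loci = unique(calls$locus),
                 calls = calls),
            class = "genotype_table")
}

#' Write a genotype table to TSV
#'
#' @param gt A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path) {
  utils::write.table(gt$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "-")
  invisible(path)
}

#' Per-locus diversity statistics
#'
#' Computes the number of distinct alleles, allele size range, and expected
#' heterozygosity at one locus from diploid genotypes. Missing genotypes
#' drop out of the gene-copy count. By default the unbiased gene-diversity
#' estimator is used: `He = n/(n-1) * (1 - sum(p_i^2))` with `n` the number
#' of non-missing gene copies.
#'
#' @param gt A `genotype_table`.
#' @param locus Locus id.
#' @param unbiased Apply the `n/(n-1)` small-sample correction (default
#'   `TRUE`); `FALSE` gives the plain `1 - sum(p^2)`.
#' @return A one-row `data.frame`: `locus`, `n_copies`, `n_alleles`,
#'   `size_min`, `size_max`, `he`.
#' @export
locus_diversity <- function(gt, locus, unbiased = TRUE) {
  if (!locus %in% gt$loci) stop("locus '", locus, "' not in table")
  sub <- gt$calls[gt$calls$locus == locus, , drop = FALSE]
  alleles <- c(sub$allele1, sub$allele2)
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  if (n < 2L) stop("locus '", locus, "' has fewer than 2 gene copies")
  p <- as.numeric(table(alleles)) / n
  he <- 1 - sum(p^2)
  if (unbiased) he <- he * n / (n - 1)
  data.frame(locus = locus,
             n_copies = n,
             n_alleles = length(p),
             size_min = min(alleles),
             size_max = max(alleles),
             he = he,
             stringsAsFactors = FALSE)
}

#' Diversity statistics for every locus in a table
#'
#' @param gt A `genotype_table`.
#' @param unbiased Passed to [locus_diversity()].
#' @return A `data.frame` with one row per locus.
#' @export
diversity_table <- function(gt, unbiased = TRUE) {
  out <- do.call(rbind, lapply(gt$loci, function(l)
    locus_diversity(gt, l, unbiased = unbiased)))
  rownames(out) <- NULL
  out
}

#' Panel-level diversity summary
#'
#' Totals and moments over per-locus diversity rows: summed distinct
#' alleles, global allele size range, and mean/standard deviation of the
#' allele count and expected heterozygosity.
#'
#' @param stats A `data.frame` of per-locus rows (from [diversity_table()]
#'   or [locus_diversity()]), requiring columns `n_alleles`, `size_min`,
#'   `size_max`, `he`.
#' @return A list: `n_loci`, `total_alleles`, `size_min`, `size_max`,
#'   `mean_n_alleles`, `sd_n_alleles`, `mean_he`, `sd_he`.
#' @export
panel_summary <- function(stats) {
  if (nrow(stats) == 0L) stop("at least one locus is required")
  list(n_loci = nrow(stats),
       total_alleles = sum(stats$n_alleles),
       size_min = min(stats$size_min),
       size_max = max(stats$size_max),
       mean_n_alleles = mean(stats$n_alleles),
       sd_n_alleles = stats::sd(stats$n_alleles),
       mean_he = mean(stats$he),
       sd_he = stats::sd(stats$he))
}
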