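#' Read a nucleotide FASTA file
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file into a
#' [Biostrings::DNAStringSet]. Residues are uppercased; only `A`, `C`, `G`,
#' `T` and `N` are accepted. Record order in the file is preserved and record
#' ids must be unique.
#'
#' @param path Path to a FASTA file.
#' @param dataset Optional dataset label (e.g. `"BES"`, `"EST"`); stored in
#'   the `dataset` metadata slot of the returned object.
#' @return A `DNAStringSet` with one element per FASTA entry.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgtACGT", ">s2", "GGCC"), fa)
#' x <- read_fasta(fa, dataset = "toy")
#' names(x)
#' @export
read_fasta <- function(path, dataset = "dataset") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ## read residues unrestricted, then validate against the strict
  ## A/C/G/T/N alphabet with a precise record/offset message
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("failed to parse FASTA '", path,
                                         "': ", conditionMessage(e)))
  if (length(x) == 0L) stop("FASTA file '", path, "' contains no records")
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA file '", path, "' has an empty record id")
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal residue '", substr(seqs[i], bad[i], bad[i]),
         "' in record '", ids[i], "' at position ", bad[i])
  }
  if (any(nchar(seqs) == 0L))
    stop("zero-length record: ", ids[which(nchar(seqs) == 0L)[1L]])
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::metadata(out)$dataset <- dataset
  out
}

#' Write sequences to FASTA
#'
#' @param x A `DNAStringSet` or named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  x <- as_dnastringset(x)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

## Coerce character vectors / DNAStringSet to a named DNAStringSet.
as_dnastringset <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    if (is.null(names(x))) stop("sequences must be named")
    return(x)
  }
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    return(Biostrings::DNAStringSet(toupper(x)))
  }
  stop("expected a DNAStringSet or named character vector")
}

#' Summarize a sequence dataset
#'
#' Computes record counts, total base pairs, and GC fraction for a dataset.
#' `N` bases are excluded from both numerator and denominator of the GC
#' fraction. Mononucleotide frequencies (over non-N bases) are also returned;
#' they feed the composition-based expected motif distributions of
#' [expected_motif_probs()].
#'
#' @param x A `DNAStringSet` or named character vector.
#' @param dataset Dataset label; defaults to the label stored by
#'   [read_fasta()], if any.
#' @return A one-row `data.frame` with columns `dataset`, `n_records`,
#'   `total_bp`, `total_mbp`, `gc_fraction`, and base frequencies
#'   `p_a`, `p_c`, `p_g`, `p_t`.
#' @examples
#' summarize_dataset(c(s1 = "AT", s2 = "GC"))$gc_fraction  # 0.5
#' @export
summarize_dataset <- function(x, dataset = NULL) {
  xs <- as_dnastringset(x)
  if (length(xs) == 0L) stop("at least one record is required")
  if (is.null(dataset)) {
    dataset <- S4Vectors::metadata(xs)$dataset
    if (is.null(dataset)) dataset <- "dataset"
  }
  af <- Biostrings::alphabetFrequency(xs, baseOnly = TRUE)
  counts <- colSums(af)
  acgt <- counts[c("A", "C", "G", "T")]
  total_bp <- sum(Biostrings::width(xs))
  denom <- sum(acgt)
  if (denom == 0L) stop("dataset has no A/C/G/T bases")
  data.frame(
    dataset = dataset,
    n_records = length(xs),
    total_bp = total_bp,
    total_mbp = total_bp / 1e6,
    gc_fraction = unname((acgt[["C"]] + acgt[["G"]]) / denom),
    p_a = unname(acgt[["A"]] / denom),
    p_c = unname(acgt[["C"]] / denom),
    p_g = unname(acgt[["G"]] / denom),
    p_t = unname(acgt[["T"]] / denom),
    stringsAsFactors = FALSE
  )
}

#' Write SSR and ORF features to GFF3
#'
#' Exports detected microsatellites and predicted ORFs as a GFF3 file
#' (feature types `microsatellite` and `ORF`). Internal coordinates are
#' 0-based half-open; the GFF3 output is 1-based inclusive, per convention.
#'
#' @param ssrs SSR `data.frame` as returned by [detect_perfect_ssrs()] (may
#'   be `NULL` or empty).
#' @param orfs ORF `data.frame` as returned by [find_orfs()] (may be `NULL`
#'   or empty).
#' @param path Output file path.
#' @param seqs Optional `DNAStringSet` (or named lengths) used to validate
#'   that features lie within sequence bounds.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(ssrs = NULL, orfs = NULL, path, seqs = NULL) {
  lens <- NULL
  if (!is.null(seqs)) {
    lens <- if (methods::is(seqs, "DNAStringSet")) {
      stats::setNames(Biostrings::width(seqs), names(seqs))
    } else if (is.numeric(seqs)) seqs else
      stats::setNames(nchar(seqs), names(seqs))
  }
  check_bounds <- function(df, what) {
    if (is.null(lens) || is.null(df) || nrow(df) == 0L) return(invisible())
    unknown <- setdiff(df$seq_id, names(lens))
    if (length(unknown))
      stop(what, " reference unknown sequence id(s): ",
           paste(unknown, collapse = ", "))
    over <- df$end > lens[df$seq_id] | df$start < 0L
    if (any(over))
      stop(what, " out of sequence bounds on ",
           paste(unique(df$seq_id[over]), collapse = ", "))
  }
  check_bounds(ssrs, "SSR feature(s)")
  check_bounds(orfs, "ORF feature(s)")

  grs <- list()
  if (!is.null(ssrs) && nrow(ssrs) > 0L) {
    grs$ssr <- GenomicRanges::GRanges(
      seqnames = ssrs$seq_id,
      ranges = IRanges::IRanges(start = ssrs$start + 1L, end = ssrs$end),
      strand = "*",
      type = "microsatellite",
      ID = sprintf("ssr%05d", seq_len(nrow(ssrs))),
      motif_class = ssrs$motif_class,
      motif_observed = ssrs$motif_observed,
      unit_len = ssrs$unit_len,
      n_units = ssrs$n_units,
      kind = ssrs$kind
    )
  }
  if (!is.null(orfs) && nrow(orfs) > 0L) {
    grs$orf <- GenomicRanges::GRanges(
      seqnames = orfs$seq_id,
      ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
      strand = orfs$strand,
      type = "ORF",
      ID = sprintf("orf%05d", seq_len(nrow(orfs))),
      frame = orfs$frame,
      orf_length = orfs$length
    )
  }
  gr <- if (length(grs)) suppressWarnings(do.call(c, unname(grs))) else
    GenomicRanges::GRanges()
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read features back from a GFF3 file
#'
#' Reparses a file written by [write_features_gff3()] into the package's SSR
#' and ORF `data.frame`s (coordinates converted back to 0-based half-open).
#'
#' @param path Path to a GFF3 file.
#' @return A list with elements `ssrs` and `orfs`.
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_ssr <- md$type == "microsatellite"
  is_orf <- md$type == "ORF"
  ssrs <- if (any(is_ssr)) {
    g <- gr[is_ssr]
    m <- S4Vectors::mcols(g)
    data.frame(
      seq_id = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1L,
      end = GenomicRanges::end(g),
      unit_len = as.integer(m$unit_len),
      motif_observed = as.character(m$motif_observed),
      motif_class = as.character(m$motif_class),
      n_units = as.numeric(m$n_units),
      total_len = GenomicRanges::end(g) - GenomicRanges::start(g) + 1L,
      kind = as.character(m$kind),
      stringsAsFactors = FALSE
    )
  } else empty_ssr_frame()
  orfs <- if (any(is_orf)) {
    g <- gr[is_orf]
    m <- S4Vectors::mcols(g)
    data.frame(
      seq_id = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1L,
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      frame = as.integer(m$frame),
      length = as.integer(m$orf_length),
      stringsAsFactors = FALSE
    )
  } else empty_orf_frame()
  list(ssrs = ssrs, orfs = orfs)
}

#' Write a dataset summary TSV
#'
#' @param summary A summary `data.frame` from [summarize_dataset()] (one or
#'   more rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_summary_tsv <- function(summary, path) {
  out <- data.frame(
    dataset = summary$dataset,
    n_records = summary$n_records,
    total_bp = summary$total_bp,
    total_mbp = round(summary$total_mbp, 2),
    gc_percent = round(100 * summary$gc_fraction, 1),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
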