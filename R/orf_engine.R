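empty_orf_frame <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(), length = integer(),
             stringsAsFactors = FALSE)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

ORF_STOPS <- c("TAA", "TAG", "TGA")

## Candidate ORFs in one oriented sequence string, one strand.
## Returns 0-based half-open coordinates in the oriented string.
orf_candidates_oriented <- function(s, min_orf_len, start_rule) {
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    starts <- seq.int(f + 1L, by = 3L, length.out = (n - f) %/% 3L)
    if (length(starts) == 0L) next
    cods <- substring(s, starts, starts + 2L)  # codons with N match nothing
    stop_i <- which(cods %in% ORF_STOPS)
    atg_i <- which(cods == "ATG")
    if (length(stop_i) == 0L || length(atg_i) == 0L) next
    ## next in-frame stop strictly after each ATG
    nxt <- stop_i[findInterval(atg_i, stop_i) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    atg_i <- atg_i[ok]; nxt <- nxt[ok]
    pick <- if (start_rule == "longest") {
      ## first in-frame ATG after the previous in-frame stop
      !duplicated(nxt)
    } else {
      ## innermost: last in-frame ATG before the stop
      !duplicated(nxt, fromLast = TRUE)
    }
    a <- atg_i[pick]; st <- nxt[pick]
    len <- (st - a) * 3L
    keep <- len >= min_orf_len
    if (!any(keep)) next
    out[[f + 1L]] <- data.frame(
      start = starts[a[keep]] - 1L,
      end = starts[st[keep]] - 1L,
      frame = f,
      length = len[keep],
      stringsAsFactors = FALSE
    )
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), frame = integer(),
               length = integer(), stringsAsFactors = FALSE)
}

#' Find open reading frames
#'
#' Searches each reading frame (both strands by default) for an `ATG` start
#' codon followed by an in-frame stop codon (`TAA`, `TAG`, or `TGA`) at
#' least `min_orf_len` nt downstream, with no intervening in-frame stop.
#' Under `start_rule = "longest"` the start is the first in-frame `ATG`
#' after the previous in-frame stop (the standard maximal-ORF convention);
#' under `"innermost"` it is the last in-frame `ATG` before the stop.
#' Codons containing `N` never match the start or a stop. Overlapping
#' candidates from different frames/strands are resolved with
#' [resolve_overlaps()] (longer ORF wins).
#'
#' @param x A `DNAStringSet` or named character vector.
#' @param min_orf_len Minimum ORF length in nt, measured from the first base
#'   of the `ATG` to the last base before the stop codon (default 100; the
#'   reported length is always a multiple of 3).
#' @param strands `"both"` (default; genomic input is unoriented) or
#'   `"forward"` (oriented input such as ESTs).
#' @param start_rule `"longest"` (default) or `"innermost"`.
#' @return A `data.frame` with columns `seq_id`, `start`, `end` (0-based
#'   half-open on the forward strand, stop codon excluded), `strand`,
#'   `frame` (0/1/2 offset on its own strand), `length`.
#' @export
find_orfs <- function(x, min_orf_len = 100L,
                      strands = c("both", "forward"),
                      start_rule = c("longest", "innermost")) {
  strands <- match.arg(strands)
  start_rule <- match.arg(start_rule)
  min_orf_len <- as.integer(min_orf_len)
  if (min_orf_len < 3L) stop("min_orf_len must be >= 3")
  xs <- as_dnastringset(x)
  seqs <- as.character(xs)
  ids <- names(xs)
  rows <- list()
  for (si in seq_along(seqs)) {
    s <- seqs[[si]]
    n <- nchar(s)
    fwd <- orf_candidates_oriented(s, min_orf_len, start_rule)
    if (nrow(fwd)) {
      fwd$seq_id <- ids[[si]]
      fwd$strand <- "+"
    }
    rev <- NULL
    if (strands == "both") {
      rev <- orf_candidates_oriented(revcomp_chr(s), min_orf_len, start_rule)
      if (nrow(rev)) {
        ## map oriented [start,end) back to forward-strand coordinates
        fstart <- n - rev$end
        fend <- n - rev$start
        rev$start <- fstart
        rev$end <- fend
        rev$seq_id <- ids[[si]]
        rev$strand <- "-"
      }
    }
    cand <- rbind(if (nrow(fwd)) fwd,
                  if (!is.null(rev) && nrow(rev)) rev)
    if (!is.null(cand) && nrow(cand))
      rows[[length(rows) + 1L]] <- resolve_overlaps(cand)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_orf_frame()
  out <- out[, c("seq_id", "start", "end", "strand", "frame", "length")]
  out <- out[order(out$seq_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping ORF candidates
#'
#' Greedy retention by descending length (ties broken by smaller start, then
#' `+` strand): a candidate overlapping an already-retained ORF is
#' discarded, so the retained set has no overlaps. The result does not
#' depend on the input order.
#'
#' @param candidates ORF candidate `data.frame` (one sequence's worth, or
#'   any set -- overlap is only tested within a `seq_id`).
#' @return The retained subset, same columns.
#' @export
resolve_overlaps <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(candidates)
  if (is.null(candidates$seq_id)) candidates$seq_id <- "."
  ord <- order(-candidates$length, candidates$start,
               match(candidates$strand, c("+", "-")))
  cand <- candidates[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    prior <- which(keep & cand$seq_id == cand$seq_id[i])
    clash <- length(prior) &&
      any(cand$start[prior] < cand$end[i] & cand$start[i] < cand$end[prior])
    keep[i] <- !clash
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify SSR placement relative to ORFs
#'
#' Each SSR is `inside` when its span lies fully within a retained ORF,
#' `outside` when disjoint from all retained ORFs, and `bridging` when it
#' partially overlaps an ORF boundary. Bridging SSRs are excluded from the
#' inside/outside goodness-of-fit tests downstream.
#'
#' @param ssrs SSR `data.frame` from [detect_perfect_ssrs()].
#' @param orfs ORF `data.frame` from [find_orfs()].
#' @return `ssrs` with an added `status` column
#'   (`inside`/`outside`/`bridging`).
#' @export
classify_placement <- function(ssrs, orfs) {
  if (nrow(ssrs) == 0L) {
    ssrs$status <- character()
    return(ssrs)
  }
  status <- vapply(seq_len(nrow(ssrs)), function(i) {
    o <- orfs[orfs$seq_id == ssrs$seq_id[i], , drop = FALSE]
    if (nrow(o) == 0L) return("outside")
    s <- ssrs$start[i]; e <- ssrs$end[i]
    if (any(o$start <= s & e <= o$end)) return("inside")
    if (all(e <= o$start | o$end <= s)) return("outside")
    "bridging"
  }, character(1))
  ssrs$status <- status
  ssrs
}

#' Fraction of dataset bases inside retained ORFs
#'
#' @param orfs ORF `data.frame` from [find_orfs()] (non-overlapping within a
#'   sequence).
#' @param total_bp Total base pairs of the dataset (e.g.
#'   `summarize_dataset(x)$total_bp`).
#' @return Proportion of bases inside ORFs.
#' @export
orf_fraction <- function(orfs, total_bp) {
  if (total_bp <= 0) stop("total_bp must be positive")
  sum(orfs$end - orfs$start) / total_bp
}
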