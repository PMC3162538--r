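#' Search configuration for microsatellite detection
#'
#' Thresholds follow the common SSR-mining convention for marker development:
#' a repeat is reported when it spans at least `min_total_len` nucleotides
#' *and* has at least `min_units` repeat units (so dinucleotides need 6
#' units, trinucleotides 4, and tetra- through octanucleotides 3).
#'
#' @param min_total_len Minimum total repeat length in nt (default 12).
#' @param min_units Minimum number of complete repeat units (default 3).
#' @param unit_len_range Inclusive range of unit lengths searched, as a
#'   length-2 integer vector (default `c(2, 8)`; may be widened to 1--10;
#'   mononucleotide runs are excluded by default).
#' @param d_max Maximum interruption, in nt, between consecutive perfect
#'   repeats merged into one compound microsatellite (default 100).
#' @return A list of class `ssr_search_config`.
#' @export
ssr_search_config <- function(min_total_len = 12L, min_units = 3L,
                              unit_len_range = c(2L, 8L), d_max = 100L) {
  min_total_len <- as.integer(min_total_len)
  min_units <- as.integer(min_units)
  unit_len_range <- as.integer(unit_len_range)
  d_max <- as.integer(d_max)
  if (length(unit_len_range) != 2L || any(is.na(unit_len_range)) ||
      unit_len_range[1L] > unit_len_range[2L])
    stop("unit_len_range must be an increasing length-2 integer vector")
  if (unit_len_range[1L] < 1L || unit_len_range[2L] > 10L)
    stop("unit lengths outside 1-10 are not supported")
  if (min_total_len < unit_len_range[1L])
    stop("min_total_len must be >= the smallest unit length")
  if (min_units < 1L) stop("min_units must be >= 1")
  if (d_max < 0L) stop("d_max must be >= 0")
  structure(list(min_total_len = min_total_len, min_units = min_units,
                 unit_len_range = unit_len_range, d_max = d_max),
            class = "ssr_search_config")
}

## TRUE when the unit is not a whole-number repetition of a shorter motif.
is_primitive_unit <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        unit == strrep(substr(unit, 1L, d), k %/% d)) return(FALSE)
  }
  TRUE
}

#' Canonical motif class of a repeat unit
#'
#' The canonical class of a unit is the lexicographically smallest of its
#' cyclic rotations. Classes are formed by rotation only -- a motif and its
#' reverse complement are *not* merged, so `AG` and `CT` are distinct
#' classes. This yields 6 dinucleotide and 20 trinucleotide classes.
#'
#' @param unit Character vector of repeat units over `A`, `C`, `G`, `T`.
#'   Units must be primitive (not a repetition of a shorter motif).
#' @return Character vector of canonical class labels.
#' @examples
#' canonical_motif("GA")   # "AG"
#' canonical_motif("TC")   # "CT" (not merged with AG)
#' canonical_motif("CAA")  # "AAC"
#' @export
canonical_motif <- function(unit) {
  if (length(unit) == 0L) return(character())
  unit <- toupper(unit)
  if (any(is.na(unit) | !nzchar(unit)))
    stop("repeat unit must be non-empty")
  bad <- grepl("[^ACGT]", unit)
  if (any(bad))
    stop("repeat unit '", unit[bad][1L],
         "' contains characters outside A/C/G/T")
  out <- character(length(unit))
  for (k in unique(nchar(unit))) {
    idx <- nchar(unit) == k
    u <- unit[idx]
    for (d in seq_len(max(0L, k - 1L))) {
      if (k %% d != 0L) next
      np <- u == strrep(substr(u, 1L, d), k %/% d)
      if (any(np))
        stop("unit '", u[np][1L], "' is a repetition of a shorter motif")
    }
    out[idx] <- canonical_rotation(u, k)
  }
  out
}

## vectorized minimal cyclic rotation for equal-length units
canonical_rotation <- function(u, k) {
  canon <- u
  if (k > 1L) {
    for (i in seq_len(k - 1L))
      canon <- pmin(canon, paste0(substring(u, i + 1L, k),
                                  substring(u, 1L, i)))
  }
  canon
}

.motif_enum_cache <- new.env(parent = emptyenv())

## all primitive units of length k (cached; 4^k enumeration, vectorized)
primitive_units <- function(k) {
  key <- as.character(k)
  hit <- get0(key, envir = .motif_enum_cache)
  if (!is.null(hit)) return(hit)
  units <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                       stringsAsFactors = FALSE))
  keep <- rep(TRUE, length(units))
  for (d in seq_len(max(0L, k - 1L))) {
    if (k %% d != 0L) next
    keep <- keep & units != strrep(substr(units, 1L, d), k %/% d)
  }
  out <- units[keep]
  assign(key, out, envir = .motif_enum_cache)
  out
}

#' Enumerate canonical motif classes for a unit length
#'
#' @param k Unit length (1--10).
#' @return Sorted character vector of all canonical classes of primitive
#'   units of length `k` (6 for `k = 2`, 20 for `k = 3`).
#' @export
motif_classes <- function(k) {
  k <- as.integer(k)
  if (k < 1L || k > 10L) stop("k must be in 1..10")
  key <- paste0("classes_", k)
  hit <- get0(key, envir = .motif_enum_cache)
  if (!is.null(hit)) return(hit)
  out <- sort(unique(canonical_rotation(primitive_units(k), k)))
  assign(key, out, envir = .motif_enum_cache)
  out
}

empty_ssr_frame <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             unit_len = integer(), motif_observed = character(),
             motif_class = character(), n_units = numeric(),
             total_len = integer(), kind = character(),
             stringsAsFactors = FALSE)
}

#' Detect perfect microsatellites
#'
#' Scans each sequence for perfect tandem repeats at every unit length in
#' `cfg$unit_len_range`, reporting only repeats that satisfy both the
#' minimum-span and minimum-unit thresholds. Detection is strand-specific
#' and deterministic. For each unit length the scan is leftmost-greedy: runs
#' consist of complete units only, a run whose unit is a whole-number
#' repetition of a shorter motif is reported only at the shorter unit
#' length, and runs are broken at `N` bases.
#'
#' @param x A `DNAStringSet` or named character vector.
#' @param cfg An [ssr_search_config()].
#' @return A `data.frame` with one row per locus and columns `seq_id`,
#'   `start`, `end` (0-based half-open), `unit_len`, `motif_observed` (the
#'   unit as it occurs at `start`), `motif_class`, `n_units`, `total_len`,
#'   `kind` (`"perfect"`), sorted by `(seq_id, start, unit_len)`.
#' @examples
#' detect_perfect_ssrs(c(s = "GGTTGACACACACACACTGGT"))
#' @export
detect_perfect_ssrs <- function(x, cfg = ssr_search_config()) {
  stopifnot(inherits(cfg, "ssr_search_config"))
  xs <- as_dnastringset(x)
  seqs <- as.character(xs)
  ids <- names(xs)
  ks <- seq(cfg$unit_len_range[1L], cfg$unit_len_range[2L])
  rows <- vector("list", length(seqs) * length(ks))
  ri <- 0L
  for (si in seq_along(seqs)) {
    s <- seqs[[si]]
    for (k in ks) {
      m <- max(cfg$min_units, ceiling(cfg$min_total_len / k))
      if (nchar(s) < m * k) next
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, m - 1L)
      hits <- gregexpr(pat, s, perl = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      len <- attr(hits, "match.length")
      start1 <- as.integer(hits)
      unit <- substr(rep(s, length(start1)), start1, start1 + k - 1L)
      keep <- vapply(unit, is_primitive_unit, logical(1), USE.NAMES = FALSE)
      if (!any(keep)) next
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        seq_id = ids[[si]],
        start = start1[keep] - 1L,
        end = start1[keep] - 1L + len[keep],
        unit_len = k,
        motif_observed = unit[keep],
        motif_class = canonical_motif(unit[keep]),
        n_units = len[keep] / k,
        total_len = len[keep],
        kind = "perfect",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (ri) do.call(rbind, rows[seq_len(ri)]) else empty_ssr_frame()
  out <- out[order(out$seq_id, out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group perfect microsatellites into compound loci
#'
#' Consecutive perfect repeats on the same sequence separated by at most
#' `cfg$d_max` nt (overlaps count as gap <= 0) are merged into one compound
#' locus spanning from the first start to the last end. Loci absorbed into a
#' compound are removed from the perfect-only set, so the two outputs
#' partition the input.
#'
#' @param perfect A perfect-SSR `data.frame` from [detect_perfect_ssrs()].
#' @param cfg An [ssr_search_config()]; only `d_max` is used.
#' @return A list with elements `perfect` (perfect loci not in any compound)
#'   and `compound` (one row per compound locus, with `n_members`, a
#'   `members` list-column of constituent rows, and `motif_class` giving the
#'   member classes joined by `+`).
#' @export
group_compound_ssrs <- function(perfect, cfg = ssr_search_config()) {
  stopifnot(inherits(cfg, "ssr_search_config"))
  if (nrow(perfect) == 0L)
    return(list(perfect = perfect, compound = empty_compound_frame()))
  perfect <- perfect[order(perfect$seq_id, perfect$start, perfect$unit_len), ,
                     drop = FALSE]
  rownames(perfect) <- NULL
  n <- nrow(perfect)
  grp <- integer(n)
  grp[1L] <- 1L
  for (i in seq_len(n - 1L)) {
    same <- perfect$seq_id[i + 1L] == perfect$seq_id[i]
    gap <- perfect$start[i + 1L] - max(perfect$end[grp == grp[i]])
    grp[i + 1L] <- if (same && gap <= cfg$d_max) grp[i] else grp[i] + 1L
  }
  sizes <- table(grp)
  singleton <- grp %in% as.integer(names(sizes)[sizes == 1L])
  perfect_only <- perfect[singleton, , drop = FALSE]
  rownames(perfect_only) <- NULL
  comp_ids <- as.integer(names(sizes)[sizes > 1L])
  compound <- if (length(comp_ids)) {
    do.call(rbind, lapply(comp_ids, function(g) {
      mem <- perfect[grp == g, , drop = FALSE]
      rownames(mem) <- NULL
      out <- data.frame(
        seq_id = mem$seq_id[1L],
        start = min(mem$start),
        end = max(mem$end),
        unit_len = NA_integer_,
        motif_observed = paste(mem$motif_observed, collapse = "+"),
        motif_class = paste(mem$motif_class, collapse = "+"),
        n_units = sum(mem$n_units),
        total_len = max(mem$end) - min(mem$start),
        kind = "compound",
        n_members = nrow(mem),
        stringsAsFactors = FALSE
      )
      out$members <- list(mem)
      out
    }))
  } else empty_compound_frame()
  rownames(compound) <- NULL
  list(perfect = perfect_only, compound = compound)
}

empty_compound_frame <- function() {
  out <- data.frame(seq_id = character(), start = integer(), end = integer(),
                    unit_len = integer(), motif_observed = character(),
                    motif_class = character(), n_units = numeric(),
                    total_len = integer(), kind = character(),
                    n_members = integer(), stringsAsFactors = FALSE)
  out$members <- list()
  out
}

#' Write SSR loci to TSV (1-based inclusive coordinates)
#'
#' @param ssrs SSR `data.frame` (perfect and/or compound rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssr_tsv <- function(ssrs, path) {
  out <- data.frame(
    seq_id = ssrs$seq_id,
    start = ssrs$start + 1L,
    end = ssrs$end,
    k = ssrs$unit_len,
    motif_observed = ssrs$motif_observed,
    motif_class = ssrs$motif_class,
    n_units = ssrs$n_units,
    total_len = ssrs$total_len,
    kind = ssrs$kind,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
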