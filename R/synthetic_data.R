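BASES <- c("A", "C", "G", "T")

ALL_CODONS <- do.call(paste0, expand.grid(BASES, BASES, BASES,
                                          stringsAsFactors = FALSE))
## sense codons usable in planted ORF interiors: no stop, no ATG
SAFE_CODONS <- setdiff(ALL_CODONS, c(ORF_STOPS, "ATG"))
## trinucleotide motifs safe to embed codon-aligned inside an ORF
SAFE_INNER_MOTIFS <- c("AAG", "AAC", "ACC", "AGC", "AGG", "ACT")

## run body() with the global RNG saved/restored so generators are pure
with_preserved_rng <- function(seed, body) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  body()
}

#' Simulation spec for synthetic sequence datasets
#'
#' Describes a sequence dataset with planted microsatellites and open
#' reading frames. Defaults emulate a BAC-end-like genomic sample: 600 bp
#' records at 38.3% GC, a repeat-type mix dominated by tri- and
#' tetranucleotides, unit counts just above the reporting thresholds, and a
#' small compound fraction. Background sequence is drawn from the zero-order
#' composition model and then repaired until it contains no unintended SSR
#' meeting the thresholds and no unintended ORF, so the emitted ground truth
#' is exact.
#'
#' @param n_records Number of records.
#' @param record_len Record length in bp.
#' @param gc GC fraction of the background composition.
#' @param n_ssr Number of planted SSR features (a compound feature counts
#'   once but contributes two perfect loci).
#' @param k_probs Named probability vector over unit lengths `"2"`..`"8"`
#'   for planted SSRs.
#' @param unit_lambda Named numeric vector: Poisson mean of extra units
#'   above the per-k minimum, per unit length.
#' @param compound_fraction Fraction of planted SSR features that are a
#'   two-member compound (gap 3--20 nt).
#' @param p_ssr_in_orf Probability that a planted SSR is placed inside a
#'   planted ORF (such SSRs are frame-aligned trinucleotides from a
#'   stop-free motif set).
#' @param n_orf Number of planted ORFs.
#' @param min_orf_len Minimum ORF length in nt (coding length, stop
#'   excluded).
#' @param orf_extra_codons Poisson mean of interior codons beyond the
#'   minimum.
#' @param strands Strand mode used when verifying recovery (`"both"` or
#'   `"forward"`).
#' @param cfg [ssr_search_config()] used when verifying recovery.
#' @param seed Mandatory integer seed.
#' @return A list of class `sequence_sim_spec`.
#' @export
sequence_sim_spec <- function(n_records = 30L, record_len = 600L, gc = 0.383,
                              n_ssr = 20L,
                              k_probs = c(`2` = 0.17, `3` = 0.41, `4` = 0.24,
                                          `5` = 0.115, `6` = 0.03,
                                          `7` = 0.017, `8` = 0.018),
                              unit_lambda = c(`2` = 1.8, `3` = 0.3,
                                              `4` = 0.3, `5` = 0.1,
                                              `6` = 0.1, `7` = 0.05,
                                              `8` = 0.05),
                              compound_fraction = 0.026,
                              p_ssr_in_orf = 0.15,
                              n_orf = 8L, min_orf_len = 100L,
                              orf_extra_codons = 15,
                              strands = c("both", "forward"),
                              cfg = ssr_search_config(),
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  strands <- match.arg(strands)
  if (abs(sum(k_probs) - 1) > 1e-8) stop("k_probs must sum to 1")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (compound_fraction < 0 || compound_fraction > 1 ||
      p_ssr_in_orf < 0 || p_ssr_in_orf > 1)
    stop("fractions must be in [0, 1]")
  structure(list(n_records = as.integer(n_records),
                 record_len = as.integer(record_len), gc = gc,
                 n_ssr = as.integer(n_ssr), k_probs = k_probs,
                 unit_lambda = unit_lambda,
                 compound_fraction = compound_fraction,
                 p_ssr_in_orf = p_ssr_in_orf,
                 n_orf = as.integer(n_orf),
                 min_orf_len = as.integer(min_orf_len),
                 orf_extra_codons = orf_extra_codons,
                 strands = strands, cfg = cfg, seed = as.integer(seed)),
            class = "sequence_sim_spec")
}

base_freqs_from_gc <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

sample_bases <- function(n, freqs) {
  sample(BASES, n, replace = TRUE, prob = freqs)
}

## minimum unit count at unit length k under cfg
min_units_at <- function(k, cfg) {
  max(cfg$min_units, ceiling(cfg$min_total_len / k))
}

random_rotation <- function(motif) {
  k <- nchar(motif)
  i <- sample.int(k, 1L) - 1L
  paste0(substr(motif, i + 1L, k), substr(motif, 1L, i))
}

## --- feature planning -------------------------------------------------

plan_ssr_feature <- function(spec) {
  k <- as.integer(sample(names(spec$k_probs), 1L, prob = spec$k_probs))
  cls <- sample(motif_classes(k), 1L)
  n_units <- min_units_at(k, spec$cfg) +
    stats::rpois(1L, spec$unit_lambda[[as.character(k)]])
  list(type = "ssr", k = k, unit = random_rotation(cls), n_units = n_units,
       block_len = k * n_units)
}

plan_compound_feature <- function(spec) {
  a <- plan_ssr_feature(spec)
  b <- plan_ssr_feature(spec)
  gap <- sample(3:20, 1L)
  list(type = "compound", members = list(a, b), gap = gap,
       block_len = a$block_len + gap + b$block_len)
}

plan_orf_feature <- function(spec, inner = NULL) {
  min_int <- ceiling(spec$min_orf_len / 3) - 1L
  n_int <- min_int + stats::rpois(1L, spec$orf_extra_codons)
  if (!is.null(inner)) n_int <- max(n_int, inner$n_units + 6L)
  len_nt <- 3L * (1L + n_int)           # ATG + interior, stop excluded
  list(type = "orf", n_int = n_int, len_nt = len_nt, inner = inner,
       block_len = 3L + len_nt + 3L)    # guard stop + body + stop
}

plan_inner_ssr <- function(spec) {
  cls <- sample(SAFE_INNER_MOTIFS, 1L)
  n_units <- min_units_at(3L, spec$cfg) +
    stats::rpois(1L, spec$unit_lambda[["3"]])
  list(type = "ssr", k = 3L, unit = cls, n_units = n_units,
       block_len = 3L * n_units)
}

## --- record assembly --------------------------------------------------

## write an SSR at 1-based position s1; returns truth row fields
write_ssr_block <- function(env, s1, feat) {
  chars <- strsplit(feat$unit, "")[[1L]]
  idx <- s1:(s1 + feat$block_len - 1L)
  env$ch[idx] <- rep(chars, feat$n_units)
  env$prot[idx] <- TRUE
  data.frame(start = s1 - 1L, end = s1 - 1L + feat$block_len,
             unit_len = feat$k,
             motif_class = canonical_motif(feat$unit),
             n_units = feat$n_units, inside_orf = FALSE,
             stringsAsFactors = FALSE)
}

## enforce that a planted repeat is not extendable at either flank
guard_ssr_flanks <- function(env, s1, e1, k, freqs) {
  n <- length(env$ch)
  lp <- s1 - 1L
  if (lp >= 1L && env$ch[lp] == env$ch[lp + k]) {
    if (env$prot[lp]) return(FALSE)
    env$ch[lp] <- sample(setdiff(BASES, env$ch[lp + k]), 1L,
                         prob = freqs[setdiff(BASES, env$ch[lp + k])])
  }
  rp <- e1 + 1L
  if (rp <= n && env$ch[rp] == env$ch[rp - k]) {
    if (env$prot[rp]) return(FALSE)
    env$ch[rp] <- sample(setdiff(BASES, env$ch[rp - k]), 1L,
                         prob = freqs[setdiff(BASES, env$ch[rp - k])])
  }
  TRUE
}

## write an ORF block starting (guard codon) at 1-based position s1
write_orf_block <- function(env, s1, feat) {
  guard <- strsplit("TAA", "")[[1L]]
  atg <- strsplit("ATG", "")[[1L]]
  stop_cod <- strsplit(sample(ORF_STOPS, 1L), "")[[1L]]
  interior <- sample(SAFE_CODONS, feat$n_int, replace = TRUE)
  inner_truth <- NULL
  if (!is.null(feat$inner)) {
    inn <- feat$inner
    n_cod <- inn$n_units
    at <- sample(2:(feat$n_int - n_cod), 1L)   # codon index in interior
    ## neighbour codons must not extend the repeat (unit is primitive,
    ## so constraining one boundary base suffices)
    u <- strsplit(inn$unit, "")[[1L]]
    left_ok <- SAFE_CODONS[substr(SAFE_CODONS, 3L, 3L) != u[3L]]
    right_ok <- SAFE_CODONS[substr(SAFE_CODONS, 1L, 1L) != u[1L]]
    interior[at - 1L] <- sample(left_ok, 1L)
    interior[at + n_cod] <- sample(right_ok, 1L)
    interior[at:(at + n_cod - 1L)] <- inn$unit
    inner_start1 <- s1 + 3L + 3L + 3L * (at - 1L)  # guard + ATG + offset
    inner_truth <- data.frame(
      start = inner_start1 - 1L,
      end = inner_start1 - 1L + inn$block_len,
      unit_len = 3L, motif_class = canonical_motif(inn$unit),
      n_units = inn$n_units, inside_orf = TRUE, stringsAsFactors = FALSE)
  }
  body <- c(guard, atg, strsplit(paste(interior, collapse = ""), "")[[1L]],
            stop_cod)
  idx <- s1:(s1 + feat$block_len - 1L)
  env$ch[idx] <- body
  env$prot[idx] <- TRUE
  orf_start0 <- s1 - 1L + 3L
  list(orf = data.frame(start = orf_start0,
                        end = orf_start0 + feat$len_nt,
                        strand = "+",
                        frame = orf_start0 %% 3L,
                        length = feat$len_nt, stringsAsFactors = FALSE),
       inner = inner_truth,
       interior_starts1 = s1 + 6L + 3L * (seq_len(feat$n_int) - 1L))
}

## set a codon (1-based start q1, forward coordinates) to a stop read on
## `strand`
set_stop_triple <- function(env, q1, strand) {
  s <- sample(ORF_STOPS, 1L)
  if (strand == "-") s <- revcomp_chr(s)
  env$ch[q1:(q1 + 2L)] <- strsplit(s, "")[[1L]]
}

feature_key <- function(df, cols) {
  if (nrow(df) == 0L) return(character())
  do.call(paste, c(df[cols], sep = ":"))
}

## Build and repair one record; returns NULL when the attempt should be
## abandoned and the record regenerated.
build_record <- function(spec, feats, freqs) {
  L <- spec$record_len
  gap_min <- 10L
  blocks <- vapply(feats, function(f) as.integer(f$block_len), integer(1))
  slack <- L - sum(blocks) - (length(feats) + 1L) * gap_min
  if (slack < 0L) stop("infeasible spec: planted features exceed record space")
  extra <- if (length(feats) == 0L) slack else
    as.integer(stats::rmultinom(1L, slack,
                                rep(1, length(feats) + 1L)))
  gaps <- gap_min + extra

  env <- new.env(parent = emptyenv())
  env$ch <- sample_bases(L, freqs)
  env$prot <- logical(L)

  ssr_truth <- list(); orf_truth <- list(); interiors <- list()
  pos <- 1L
  for (i in seq_along(feats)) {
    pos <- pos + gaps[i]
    f <- feats[[i]]
    if (f$type == "ssr") {
      ssr_truth[[length(ssr_truth) + 1L]] <- write_ssr_block(env, pos, f)
    } else if (f$type == "compound") {
      a <- f$members[[1L]]; b <- f$members[[2L]]
      ssr_truth[[length(ssr_truth) + 1L]] <- write_ssr_block(env, pos, a)
      ssr_truth[[length(ssr_truth) + 1L]] <-
        write_ssr_block(env, pos + a$block_len + f$gap, b)
    } else {
      res <- write_orf_block(env, pos, f)
      orf_truth[[length(orf_truth) + 1L]] <- res$orf
      if (!is.null(res$inner))
        ssr_truth[[length(ssr_truth) + 1L]] <- res$inner
      interiors[[length(interiors) + 1L]] <- res$interior_starts1
    }
    pos <- pos + f$block_len
  }
  ssr_truth <- if (length(ssr_truth)) do.call(rbind, ssr_truth) else
    data.frame(start = integer(), end = integer(), unit_len = integer(),
               motif_class = character(), n_units = numeric(),
               inside_orf = logical(), stringsAsFactors = FALSE)
  orf_truth <- if (length(orf_truth)) do.call(rbind, orf_truth) else
    data.frame(start = integer(), end = integer(), strand = character(),
               frame = integer(), length = integer(),
               stringsAsFactors = FALSE)

  ## flank guards for background-planted repeats
  for (r in seq_len(nrow(ssr_truth))) {
    if (ssr_truth$inside_orf[r]) next
    if (!guard_ssr_flanks(env, ssr_truth$start[r] + 1L, ssr_truth$end[r],
                          ssr_truth$unit_len[r], freqs)) return(NULL)
  }

  interior_starts <- unlist(interiors)
  inner_spans <- ssr_truth[ssr_truth$inside_orf, , drop = FALSE]
  codon_is_free <- function(q1) {
    ## interior codon of a planted ORF that is not part of an inner repeat
    ## (nor one of its guard neighbours)
    q1 %in% interior_starts &&
      (nrow(inner_spans) == 0L ||
         all(q1 + 2L < inner_spans$start + 1L - 3L |
               q1 > inner_spans$end + 3L))
  }

  truth_ssr_key <- feature_key(ssr_truth, c("start", "end", "unit_len"))
  truth_orf_key <- feature_key(orf_truth, c("start", "end", "strand"))

  for (iter in seq_len(200L)) {
    rec <- stats::setNames(paste(env$ch, collapse = ""), "rec")
    det_ssr <- detect_perfect_ssrs(rec, spec$cfg)
    det_orf <- find_orfs(rec, spec$min_orf_len, strands = spec$strands,
                         start_rule = "longest")
    det_ssr_key <- feature_key(det_ssr, c("start", "end", "unit_len"))
    det_orf_key <- feature_key(det_orf, c("start", "end", "strand"))
    sp_ssr <- which(!(det_ssr_key %in% truth_ssr_key))
    sp_orf <- which(!(det_orf_key %in% truth_orf_key))
    mi_ssr <- which(!(truth_ssr_key %in% det_ssr_key))
    mi_orf <- which(!(truth_orf_key %in% det_orf_key))
    if (!length(sp_ssr) && !length(sp_orf) &&
        !length(mi_ssr) && !length(mi_orf))
      return(list(seq = rec[[1L]], ssr = ssr_truth, orf = orf_truth))

    fixed <- FALSE
    if (length(sp_ssr)) {
      row <- det_ssr[sp_ssr[1L], ]
      span <- (row$start + 1L):row$end
      free <- span[!env$prot[span]]
      if (length(free)) {
        p <- free[ceiling(length(free) / 2)]
        env$ch[p] <- sample(setdiff(BASES, env$ch[p]), 1L)
        fixed <- TRUE
      } else {
        cods <- span[span %in% interior_starts]
        cods <- cods[vapply(cods, codon_is_free, logical(1))]
        if (length(cods)) {
          env$ch[cods[1L]:(cods[1L] + 2L)] <-
            strsplit(sample(SAFE_CODONS, 1L), "")[[1L]]
          fixed <- TRUE
        }
      }
    } else if (length(sp_orf)) {
      row <- det_orf[sp_orf[1L], ]
      ## in-frame codon starts of the spurious ORF, forward coordinates
      q <- seq.int(row$start + 1L, row$end - 2L, by = 3L)
      free <- q[vapply(q, function(p) all(!env$prot[p:(p + 2L)]),
                       logical(1))]
      if (length(free)) {
        set_stop_triple(env, sample(free, 1L), row$strand)
        fixed <- TRUE
      } else {
        cods <- q[vapply(q, codon_is_free, logical(1))]
        if (length(cods)) {
          env$ch[cods[1L]:(cods[1L] + 2L)] <-
            strsplit(sample(SAFE_CODONS, 1L), "")[[1L]]
          fixed <- TRUE
        }
      }
    } else if (length(mi_ssr)) {
      row <- ssr_truth[mi_ssr[1L], ]
      if (!row$inside_orf &&
          guard_ssr_flanks(env, row$start + 1L, row$end, row$unit_len,
                           freqs))
        fixed <- TRUE
    }
    ## missing ORFs with no spurious overlap are not repairable in place
    if (!fixed) return(NULL)
  }
  NULL
}

#' Generate sequences with planted SSRs and ORFs
#'
#' Deterministic given the spec's seed. Background sequence is sampled from
#' the zero-order composition model and repaired so that running
#' [detect_perfect_ssrs()] and [find_orfs()] on the output recovers exactly
#' the planted feature set -- the returned ground truth is exact.
#'
#' @param spec A [sequence_sim_spec()].
#' @return A list: `records` (`DNAStringSet`), `ssr_truth` and `orf_truth`
#'   (`data.frame`s with `seq_id` and 0-based half-open coordinates), and
#'   `spec`.
#' @export
gen_sequences <- function(spec) {
  stopifnot(inherits(spec, "sequence_sim_spec"))
  with_preserved_rng(spec$seed, function() {
    freqs <- base_freqs_from_gc(spec$gc)
    ## assign features to records
    feats_of <- rep(list(list()), spec$n_records)
    add_feat <- function(f) {
      ord <- sample.int(spec$n_records)
      for (ri in ord) {
        used <- sum(vapply(feats_of[[ri]],
                           function(x) as.integer(x$block_len),
                           integer(1)))
        need <- used + f$block_len +
          (length(feats_of[[ri]]) + 2L) * 10L
        if (need <= spec$record_len) {
          feats_of[[ri]][[length(feats_of[[ri]]) + 1L]] <<- f
          return(invisible())
        }
      }
      stop("infeasible spec: planted features exceed sequence space")
    }
    orf_slots <- integer(0)
    n_inner <- 0L
    if (spec$n_ssr > 0L) {
      inner_flags <- stats::runif(spec$n_ssr) < spec$p_ssr_in_orf
      n_inner <- min(sum(inner_flags), spec$n_orf)
    }
    for (i in seq_len(spec$n_orf)) {
      inner <- if (i <= n_inner) plan_inner_ssr(spec) else NULL
      add_feat(plan_orf_feature(spec, inner))
    }
    n_bg_ssr <- spec$n_ssr - n_inner
    for (i in seq_len(max(0L, n_bg_ssr))) {
      f <- if (stats::runif(1) < spec$compound_fraction)
        plan_compound_feature(spec) else plan_ssr_feature(spec)
      add_feat(f)
    }

    records <- character(spec$n_records)
    ssr_rows <- list(); orf_rows <- list()
    for (ri in seq_len(spec$n_records)) {
      id <- sprintf("syn%04d", ri)
      res <- NULL
      for (attempt in seq_len(50L)) {
        res <- build_record(spec, feats_of[[ri]], freqs)
        if (!is.null(res)) break
      }
      if (is.null(res))
        stop("failed to realize record ", id,
             "; the spec appears infeasible")
      records[ri] <- res$seq
      if (nrow(res$ssr)) {
        res$ssr$seq_id <- id
        ssr_rows[[length(ssr_rows) + 1L]] <- res$ssr
      }
      if (nrow(res$orf)) {
        res$orf$seq_id <- id
        orf_rows[[length(orf_rows) + 1L]] <- res$orf
      }
    }
    names(records) <- sprintf("syn%04d", seq_len(spec$n_records))
    ssr_truth <- if (length(ssr_rows)) do.call(rbind, ssr_rows) else
      data.frame(seq_id = character(), start = integer(), end = integer(),
                 unit_len = integer(), motif_class = character(),
                 n_units = numeric(), inside_orf = logical(),
                 stringsAsFactors = FALSE)
    orf_truth <- if (length(orf_rows)) do.call(rbind, orf_rows) else
      data.frame(seq_id = character(), start = integer(), end = integer(),
                 strand = character(), frame = integer(),
                 length = integer(), stringsAsFactors = FALSE)
    ssr_truth <- ssr_truth[order(ssr_truth$seq_id, ssr_truth$start), ,
                           drop = FALSE]
    orf_truth <- orf_truth[order(orf_truth$seq_id, orf_truth$start), ,
                           drop = FALSE]
    rownames(ssr_truth) <- rownames(orf_truth) <- NULL
    out <- Biostrings::DNAStringSet(records)
    S4Vectors::metadata(out)$dataset <- "synthetic"
    list(records = out, ssr_truth = ssr_truth, orf_truth = orf_truth,
         spec = spec)
  })
}

#' Simulation spec for marker panels
#'
#' Describes synthetic F2 screening matrices, transferability matrices and
#' diploid genotype tables. Defaults mirror a 300-marker panel (156
#' enrichment-library and 144 sequence-mined markers) screened in 7 F2
#' populations, a 23-accession transferability panel (8 source-species
#' accessions, 8 congeneric, 7 confamilial) with success probabilities
#' 0.86/0.58/0.41, and a 65-diploid, 10-locus diversity panel whose
#' allele-frequency vector has gene diversity `1 - sum(p^2) = 0.84`.
#'
#' Screening calls use a marker-level propensity model: within each
#' repeat-number class a marker is polymorphism-prone with probability
#' `p_prone`, and a prone marker segregates in each population with
#' probability `q_pop` (codominant with probability `codom_share` given
#' segregation). This reproduces the field observation that percent
#' polymorphic and mean polymorphism index rise together with repeat
#' number.
#'
#' @param n_markers,n_gssr Total markers and how many carry the `GSSR`
#'   source tag (the rest are `BSSR`).
#' @param n_pops Number of screening populations.
#' @param class_probs `data.frame` with columns `class`, `p_prone`,
#'   `q_pop` for the four repeat-number classes.
#' @param codom_share P(codominant | segregating).
#' @param missing_rate,ambiguous_rate,noamp_rate Per-cell rates.
#' @param gssr_units_mu,gssr_units_size Negative-binomial parameters for
#'   GSSR summed repeat units (offset +3).
#' @param bssr_units_lambda Poisson mean for BSSR units (offset +2).
#' @param group_sizes,group_success Transferability panel structure and
#'   per-group success probabilities.
#' @param size_window Expected-size window in bp.
#' @param n_individuals,n_loci,allele_freqs Diversity panel structure.
#' @param missing_geno_rate Per-genotype missing rate.
#' @param seed Mandatory integer seed.
#' @return A list of class `panel_sim_spec`.
#' @export
panel_sim_spec <- function(n_markers = 300L,
                           n_gssr = ceiling(0.52 * n_markers), n_pops = 7L,
                           class_probs = data.frame(
                             class = c("<6", "6-10", "11-15", ">15"),
                             p_prone = c(0.76, 0.76, 0.93, 0.77),
                             q_pop = c(0.15, 0.24, 0.30, 0.44),
                             stringsAsFactors = FALSE),
                           codom_share = 0.55,
                           missing_rate = 0.02, ambiguous_rate = 0.06,
                           noamp_rate = 0.05,
                           gssr_units_mu = 13, gssr_units_size = 3,
                           bssr_units_lambda = 2.4,
                           group_sizes = c(carota = 8L,
                                           daucus_non_carota = 8L,
                                           non_daucus = 7L),
                           group_success = c(carota = 0.86,
                                             daucus_non_carota = 0.58,
                                             non_daucus = 0.41),
                           size_window = 100,
                           n_individuals = 65L, n_loci = 10L,
                           allele_freqs = c(0.25, 0.2, 0.15, 0.1, 0.1,
                                            0.1, 0.05, 0.05),
                           missing_geno_rate = 0.02,
                           seed) {
  if (missing(seed)) stop("a seed is mandatory")
  n_gssr <- as.integer(n_gssr)
  stopifnot(n_gssr <= n_markers, all(group_sizes >= 1L),
            abs(sum(allele_freqs) - 1) < 1e-8,
            all(allele_freqs > 0))
  probs <- c(class_probs$p_prone, class_probs$q_pop, codom_share,
             missing_rate, ambiguous_rate, noamp_rate, group_success,
             missing_geno_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  structure(list(n_markers = as.integer(n_markers),
                 n_gssr = as.integer(n_gssr), n_pops = as.integer(n_pops),
                 class_probs = class_probs, codom_share = codom_share,
                 missing_rate = missing_rate,
                 ambiguous_rate = ambiguous_rate, noamp_rate = noamp_rate,
                 gssr_units_mu = gssr_units_mu,
                 gssr_units_size = gssr_units_size,
                 bssr_units_lambda = bssr_units_lambda,
                 group_sizes = group_sizes, group_success = group_success,
                 size_window = size_window,
                 n_individuals = as.integer(n_individuals),
                 n_loci = as.integer(n_loci), allele_freqs = allele_freqs,
                 missing_geno_rate = missing_geno_rate,
                 seed = as.integer(seed)),
            class = "panel_sim_spec")
}

#' Generate a synthetic F2 screening matrix
#'
#' @param spec A [panel_sim_spec()].
#' @return A `screening_matrix` with an extra attribute `params` recording
#'   the generating class probabilities.
#' @export
gen_screening_matrix <- function(spec) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  with_preserved_rng(spec$seed, function() {
    n <- spec$n_markers
    src <- c(rep("GSSR", spec$n_gssr), rep("BSSR", n - spec$n_gssr))
    units <- numeric(n)
    units[src == "GSSR"] <- 3 + stats::rnbinom(sum(src == "GSSR"),
                                               size = spec$gssr_units_size,
                                               mu = spec$gssr_units_mu)
    units[src == "BSSR"] <- 2 + stats::rpois(sum(src == "BSSR"),
                                             spec$bssr_units_lambda)
    cls <- as.character(bin_repeat_class(units))
    cp <- spec$class_probs
    prone <- stats::runif(n) < cp$p_prone[match(cls, cp$class)]
    q <- ifelse(prone, cp$q_pop[match(cls, cp$class)], 0)
    calls <- matrix("monomorphic", n, spec$n_pops,
                    dimnames = list(sprintf("mk%03d", seq_len(n)),
                                    sprintf("pop%d", seq_len(spec$n_pops))))
    for (j in seq_len(spec$n_pops)) {
      u <- stats::runif(n)
      seg <- stats::runif(n) < q
      codom <- stats::runif(n) < spec$codom_share
      calls[, j] <- ifelse(
        u < spec$missing_rate, "missing",
        ifelse(u < spec$missing_rate + spec$noamp_rate, "no_amplification",
        ifelse(u < spec$missing_rate + spec$noamp_rate +
                 spec$ambiguous_rate, "ambiguous",
        ifelse(seg, ifelse(codom, "codominant", "dominant"),
               "monomorphic"))))
    }
    sm <- new_screening_matrix(
      markers = data.frame(marker = rownames(calls), source = src,
                           total_units = units, stringsAsFactors = FALSE),
      calls = calls)
    attr(sm, "params") <- cp
    sm
  })
}

#' Generate a synthetic transferability matrix
#'
#' Group-structured amplification success emulating the decay of
#' heterologous amplification with phylogenetic distance from the source
#' species.
#'
#' @param spec A [panel_sim_spec()].
#' @return A `transfer_matrix`.
#' @export
gen_transfer_matrix <- function(spec) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  with_preserved_rng(spec$seed + 1L, function() {
    n <- spec$n_markers
    markers <- data.frame(marker = sprintf("mk%03d", seq_len(n)),
                          expected_size = round(stats::runif(n, 120, 320)),
                          stringsAsFactors = FALSE)
    groups <- rep(names(spec$group_sizes), spec$group_sizes)
    accessions <- data.frame(
      accession = sprintf("acc%02d", seq_along(groups)),
      group = groups, stringsAsFactors = FALSE)
    outcome <- matrix("none", n, nrow(accessions),
                      dimnames = list(markers$marker, accessions$accession))
    sizes <- matrix(vector("list", length(outcome)), n, nrow(accessions),
                    dimnames = dimnames(outcome))
    for (ai in seq_len(nrow(accessions))) {
      p <- spec$group_success[[accessions$group[ai]]]
      hit <- stats::runif(n) < p
      ## successful amplicons drift by whole repeat steps within the window
      drift <- 2 * stats::rbinom(n, size = 20, prob = 0.5) - 20
      drift <- pmax(pmin(drift, spec$size_window), -spec$size_window)
      off <- stats::runif(n) < 0.35
      off_shift <- sample(c(-1, 1), n, replace = TRUE) *
        round(stats::runif(n, spec$size_window + 10,
                           spec$size_window + 150))
      for (mi in seq_len(n)) {
        if (hit[mi]) {
          sz <- markers$expected_size[mi] + drift[mi]
          sizes[[mi, ai]] <- sz
          outcome[mi, ai] <- "expected_size"
        } else if (off[mi]) {
          sz <- markers$expected_size[mi] + off_shift[mi]
          sizes[[mi, ai]] <- sz
          outcome[mi, ai] <- "off_size"
        }
      }
    }
    new_transfer_matrix(markers, accessions, outcome, sizes)
  })
}

#' Generate a synthetic diploid genotype table
#'
#' Genotypes are drawn locus-by-locus from the spec's allele-frequency
#' vector (alleles spaced 2 bp apart from a random base size, as for
#' dinucleotide repeats sized on a capillary sequencer).
#'
#' @param spec A [panel_sim_spec()].
#' @return A `genotype_table` with attribute `true_div` = `1 - sum(p^2)`.
#' @export
gen_genotypes <- function(spec) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  with_preserved_rng(spec$seed + 2L, function() {
    p <- spec$allele_freqs
    rows <- list()
    for (li in seq_len(spec$n_loci)) {
      base <- round(stats::runif(1, 150, 400))
      allele_sizes <- base + 2 * (seq_along(p) - 1L)
      draw <- function()
        allele_sizes[sample.int(length(p), spec$n_individuals,
                                replace = TRUE, prob = p)]
      a1 <- draw()
      a2 <- draw()
      miss <- stats::runif(spec$n_individuals) < spec$missing_geno_rate
      a1[miss] <- NA; a2[miss] <- NA
      rows[[li]] <- data.frame(
        individual = sprintf("ind%02d", seq_len(spec$n_individuals)),
        locus = sprintf("loc%02d", li),
        allele1 = pmin(a1, a2), allele2 = pmax(a1, a2),
        stringsAsFactors = FALSE)
    }
    gt <- new_genotype_table(do.call(rbind, rows))
    attr(gt, "true_div") <- 1 - sum(p^2)
    gt
  })
}
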