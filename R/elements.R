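#' Detector parameters
#'
#' Collects the tunable parameters of element detection with their defaults:
#' candidate lengths 4..2000 positions; shallow-column handling (neutral rate
#' below 0.5 substitutions/site, runs of at least 10 such positions excluded
#' outright, isolated ones penalized); score discretization tolerance 0.1 RS;
#' one pseudocount of uniform prior per histogram bin; a permissive linear
#' candidate pruning threshold of `q * length * median neutral rate`;
#' 5 shuffles for false-positive estimation; a 5% false-positive cutoff
#' counted in number of predictions; and ~2 Mb region chunks.
#'
#' @param min_length,max_length Candidate element length bounds (positions).
#' @param shallow_cutoff Neutral-rate cutoff below which a position is
#'   "shallow" (substitutions/site).
#' @param shallow_run Minimum run length of consecutive shallow positions
#'   excluded from the null histogram (and treated as a hard break for
#'   candidates); also the minimum unscored run usable as a region boundary.
#' @param tol Score discretization tolerance, in RS units.
#' @param prior_weight Pseudocount added to every histogram bin.
#' @param q Candidate pruning slope: candidates must score at least
#'   `q * L * median_neutral_rate`.
#' @param n_shuffles Number of permuted tracks for false-positive estimation.
#' @param fp_cutoff Stop accepting predictions once the estimated fraction of
#'   false predictions among those accepted exceeds this value.
#' @param chunk_size Region size for [chunk_regions()].
#' @return A named list of class `"gerp_params"`.
#' @export
gerp_params <- function(min_length = 4L, max_length = 2000L,
                        shallow_cutoff = 0.5, shallow_run = 10L,
                        tol = 0.1, prior_weight = 1,
                        q = 0.05, n_shuffles = 5L, fp_cutoff = 0.05,
                        chunk_size = 2e6) {
  stopifnot(min_length >= 1L, max_length >= min_length, tol > 0,
            shallow_run >= 1L, n_shuffles >= 1L, prior_weight >= 0)
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 shallow_cutoff = shallow_cutoff,
                 shallow_run = as.integer(shallow_run),
                 tol = tol, prior_weight = prior_weight, q = q,
                 n_shuffles = as.integer(n_shuffles),
                 fp_cutoff = fp_cutoff, chunk_size = chunk_size),
            class = "gerp_params")
}

# Penalty (in RS units) applied to shallow positions that survive run
# exclusion: half the neutral-rate shortfall, capped at 0.5 RS.
shallow_penalty <- function(n, shallow_cutoff) {
  pmin(0.5 * pmax(shallow_cutoff - n, 0), 0.5)
}

# Per-region preprocessing shared by the histogram, candidate enumeration and
# permutation: effective (penalty-adjusted) scores, the frozen long shallow
# runs, and the usable mask.
effective_scores <- function(track, params) {
  scored <- track$scored
  shallow <- scored & track$neutral_rate < params$shallow_cutoff
  r <- rle(shallow)
  frozen <- inverse.rle(list(
    lengths = r$lengths,
    values = r$values & r$lengths >= params$shallow_run))
  eff <- track$rs
  pen <- shallow & !frozen
  eff[pen] <- eff[pen] - shallow_penalty(track$neutral_rate[pen],
                                         params$shallow_cutoff)
  eff[!scored] <- NA_real_
  list(eff = eff, shallow = shallow, frozen = frozen,
       usable = scored & !frozen)
}

# round-half-away-from-zero discretization to multiples of tol
discretize_scores <- function(x, tol) {
  as.integer(sign(x) * floor(abs(x) / tol + 0.5))
}

#' Discretized score histogram (the null model)
#'
#' `score_histogram()` wraps a probability vector over consecutive
#' discretized score bins; bin `i` represents score `(kmin + i - 1) * tol`.
#' `build_histogram()` constructs the null from a region's scored positions:
#' long runs of shallow positions and any `excluded` intervals are left out,
#' remaining shallow positions contribute their penalty-adjusted score, and a
#' uniform prior pseudocount is added to every bin of the observed score
#' range before normalization, so no bin has probability zero.
#'
#' @param probs Numeric vector of bin probabilities (will be normalized).
#' @param kmin Integer score index of the first bin.
#' @param tol Discretization tolerance in RS units.
#' @return An object of class `"score_histogram"`.
#' @export
score_histogram <- function(probs, kmin, tol) {
  stopifnot(length(probs) >= 1, all(probs >= 0), sum(probs) > 0, tol > 0)
  probs <- probs / sum(probs)
  structure(list(probs = probs, kmin = as.integer(kmin),
                 kmax = as.integer(kmin) + length(probs) - 1L, tol = tol),
            class = "score_histogram")
}

#' @export
print.score_histogram <- function(x, ...) {
  cat("Discretized score histogram: ", length(x$probs), " bins over [",
      x$kmin * x$tol, ", ", x$kmax * x$tol, "] RS (tol ", x$tol, ")\n",
      sep = "")
  invisible(x)
}

#' @rdname score_histogram
#' @param track A scored track data frame (one region).
#' @param params A [gerp_params()].
#' @param excluded Optional logical vector (same length as the region)
#'   marking positions to leave out, e.g. clearly constrained intervals
#'   found by a preliminary pass.
#' @export
build_histogram <- function(track, params = gerp_params(), excluded = NULL) {
  es <- effective_scores(track, params)
  use <- es$usable
  if (!is.null(excluded)) {
    stopifnot(length(excluded) == nrow(track))
    use <- use & !excluded
  }
  if (!any(use))
    stop("unusable region: all positions excluded from the null histogram")
  k <- discretize_scores(es$eff[use], params$tol)
  kmin <- min(k); kmax <- max(k)
  counts <- tabulate(k - kmin + 1L, nbins = kmax - kmin + 1L)
  score_histogram(counts + params$prior_weight, kmin, params$tol)
}

#' Empirical segment p-value by dynamic programming
#'
#' The probability that the sum of `L` independent draws from the discretized
#' null score distribution is at least `S` — the p-value of a candidate
#' element of length `L` and score `S` under the region's null.  Computed by
#' iterated convolution of the discretized distribution with tail
#' aggregation; queries are batched and grouped by `L` internally.
#'
#' @param L Integer vector of element lengths (>= 1).
#' @param S Numeric vector of element scores (raw RS sums).
#' @param hist A [score_histogram()].
#' @return Numeric vector of p-values in `[0, 1]`, non-increasing in `S` for
#'   fixed `L`.
#' @export
pvalue <- function(L, S, hist) {
  stopifnot(inherits(hist, "score_histogram"), length(L) == length(S))
  if (!length(L)) return(numeric())
  cpp_pvalue_batch(hist$probs, hist$kmin, hist$tol,
                   as.integer(L), as.numeric(S))
}

#' Enumerate candidate constrained elements in a region
#'
#' Candidates start at the first position of a maximal run of non-negative
#' (effective) RS scores and end at the last position of such a run — i.e.
#' both endpoints are non-negative and cannot be extended outward — possibly
#' spanning negative stretches between runs.  Unscored positions, long
#' shallow runs, and region edges are hard breaks.  Candidates are restricted
#' to lengths in `[min_length, max_length]` and to scores of at least
#' `q * L * median_neutral_rate` (a permissive pruning of hopeless
#' candidates), and are assigned p-values when a histogram is supplied.
#'
#' @param track A scored track data frame (one region).
#' @param params A [gerp_params()].
#' @param hist Optional [score_histogram()] for p-values.
#' @return Data frame with `start`, `end` (0-based half-open row offsets
#'   within the region), `length`, `score`, and `pvalue` (NA without `hist`).
#' @export
enumerate_candidates <- function(track, params = gerp_params(), hist = NULL) {
  es <- effective_scores(track, params)
  med_n <- median(track$neutral_rate[track$scored])
  eff0 <- ifelse(is.na(es$eff), 0, es$eff)
  slope <- if (!is.finite(params$q)) -Inf
           else params$q * ifelse(is.na(med_n), 0, med_n)
  cand <- cpp_enumerate_candidates(eff0, es$usable,
                                   params$min_length, params$max_length,
                                   slope)
  out <- data.frame(start = cand$start, end = cand$end,
                    length = cand$end - cand$start, score = cand$score)
  out$pvalue <- if (is.null(hist)) rep(NA_real_, nrow(out)) else
    pvalue(out$length, out$score, hist)
  out
}

# Batched p-values for several candidate tables against one histogram: a
# single dynamic program serves all queries, grouped by length internally.
pvalue_split <- function(cand_list, hist) {
  ns <- vapply(cand_list, nrow, 1L)
  pv <- pvalue(unlist(lapply(cand_list, `[[`, "length")),
               unlist(lapply(cand_list, `[[`, "score")), hist)
  ends <- cumsum(ns)
  lapply(seq_along(cand_list), function(i) {
    if (ns[i] == 0L) numeric() else pv[(ends[i] - ns[i] + 1L):ends[i]]
  })
}

# Greedy non-overlapping selection of ALL candidates in significance order
# (ascending p, ties: longer first, then leftmost).  Returns the accepted
# candidates ordered by acceptance.
select_all <- function(candidates, span) {
  if (!nrow(candidates)) return(candidates[0, , drop = FALSE])
  o <- order(candidates$pvalue, -candidates$length, candidates$start) - 1L
  acc <- cpp_greedy_select(candidates$start, candidates$end, o, span)
  sel <- candidates[o + 1L, , drop = FALSE][acc[o + 1L], , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Greedy significance-ranked selection of elements
#'
#' Candidates are accepted from smallest to largest p-value (ties broken in
#' favor of the longer element, then the leftmost), discarding any candidate
#' overlapping a previously accepted one.  Acceptance stops when the
#' estimated fraction of false predictions among those accepted — the mean
#' number of null (shuffle) predictions at or below the current p-value,
#' divided by the number accepted — first exceeds `fp_cutoff`.
#'
#' @param candidates Data frame from [enumerate_candidates()] with p-values.
#' @param null_pvalues List of numeric vectors: the p-values of predictions
#'   selected in each permuted track (see [estimate_fpr()]).  An empty list
#'   disables the stop rule.
#' @param fp_cutoff False-positive fraction at which to stop.
#' @param span Region length in positions.
#' @return The accepted candidates with `rank` and `expected_false` columns,
#'   in acceptance (significance) order.
#' @export
select_elements <- function(candidates, null_pvalues = list(),
                            fp_cutoff = 0.05, span = NULL) {
  if (is.null(span))
    span <- if (nrow(candidates)) max(candidates$end) else 0L
  sel <- select_all(candidates, span)
  if (!nrow(sel)) {
    sel$rank <- integer()
    sel$expected_false <- numeric()
    return(sel)
  }
  ef <- expected_false_at(sel$pvalue, null_pvalues)
  if (length(null_pvalues)) {
    viol <- which(ef > fp_cutoff * seq_len(nrow(sel)))
    keep <- if (length(viol)) viol[1] - 1L else nrow(sel)
    sel <- sel[seq_len(keep), , drop = FALSE]
    ef <- ef[seq_len(keep)]
  }
  sel$rank <- seq_len(nrow(sel))
  sel$expected_false <- ef
  rownames(sel) <- NULL
  sel
}

# mean over shuffles of the number of null p-values <= each p (p ascending)
expected_false_at <- function(p, null_pvalues) {
  if (!length(null_pvalues)) return(rep(0, length(p)))
  counts <- vapply(null_pvalues,
                   function(np) findInterval(p, sort(np)), numeric(length(p)))
  if (length(p) == 1L) counts <- matrix(counts, nrow = 1L)
  rowMeans(counts)
}

#' Permute a scored track (null shuffle)
#'
#' Shuffles the per-position records (neutral rate, rescaling, RS score)
#' uniformly at random within the region.  Unscored positions and long runs
#' of shallow positions stay in place, so the multiset of scores and the
#' unusable coordinates are preserved exactly.
#'
#' @param track A scored track data frame (one region).
#' @param params A [gerp_params()] (controls the shallow-run definition).
#' @param seed Integer seed; the same seed yields the same permutation.
#' @return A permuted copy of `track`.
#' @export
permute_track <- function(track, params = gerp_params(), seed = 1L) {
  es <- effective_scores(track, params)
  idx <- which(es$usable)
  out <- track
  if (length(idx) > 1) {
    perm <- with_local_seed(seed, sample(idx))
    cols <- c("neutral_rate", "rescaling", "rs", "scored")
    out[idx, cols] <- track[perm, cols]
  }
  out
}

# --- per-region detection -------------------------------------------------

# Runs the full two-pass machinery on one region.  Returns the accepted
# sequence (before the fp stop), per-rank expected false counts and bases,
# plus the final histogram and exclusion mask.
detect_region <- function(track, params, seed) {
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      score = numeric(), pvalue = numeric())
  res <- list(selected = empty, expected_false = numeric(),
              expected_false_bases = numeric(), null_pvalues = list(),
              null_bases = list(), excluded = rep(FALSE, nrow(track)),
              hist = NULL)
  if (!any(track$scored)) return(res)
  span <- nrow(track)

  # preliminary pass: null histogram without exclusions, fp cutoff 0
  h0 <- build_histogram(track, params)
  cand <- enumerate_candidates(track, params)
  if (!nrow(cand)) return(res)
  cand0n <- lapply(seq_len(params$n_shuffles), function(s) {
    pt <- permute_track(track, params, derive_seed(seed, 1L, s))
    enumerate_candidates(pt, params)
  })
  pv <- pvalue_split(c(list(cand), cand0n), h0)  # one DP for all tracks
  cand$pvalue <- pv[[1]]
  null0 <- lapply(seq_along(cand0n), function(i) {
    cand0n[[i]]$pvalue <- pv[[i + 1L]]
    select_all(cand0n[[i]], span)$pvalue
  })
  minnull <- suppressWarnings(min(unlist(null0), Inf))
  sel0 <- select_all(cand, span)
  excl_elems <- sel0[sel0$pvalue < minnull, , drop = FALSE]
  excluded <- rep(FALSE, span)
  for (i in seq_len(nrow(excl_elems)))
    excluded[(excl_elems$start[i] + 1L):excl_elems$end[i]] <- TRUE

  # final pass: histogram without clearly constrained positions
  h1 <- tryCatch(build_histogram(track, params, excluded),
                 error = function(e) h0)
  cand1n <- lapply(seq_len(params$n_shuffles), function(s) {
    pt <- permute_track(track, params, derive_seed(seed, 2L, s))
    enumerate_candidates(pt, params)
  })
  pv <- pvalue_split(c(list(cand), cand1n), h1)
  cand$pvalue <- pv[[1]]
  nulls <- lapply(seq_along(cand1n), function(i) {
    cand1n[[i]]$pvalue <- pv[[i + 1L]]
    select_all(cand1n[[i]], span)
  })
  sel <- select_all(cand, span)
  res$selected <- sel
  res$null_pvalues <- lapply(nulls, `[[`, "pvalue")
  res$null_bases <- lapply(nulls, `[[`, "length")
  res$expected_false <- expected_false_at(sel$pvalue, res$null_pvalues)
  res$expected_false_bases <- null_bases_at(sel$pvalue, nulls)
  res$excluded <- excluded
  res$hist <- h1
  res
}

# mean over shuffles of total null prediction bases at or below each p
null_bases_at <- function(p, nulls) {
  if (!length(nulls)) return(rep(0, length(p)))
  per <- vapply(nulls, function(nd) {
    if (!nrow(nd)) return(rep(0, length(p)))
    o <- order(nd$pvalue)
    cs <- cumsum(nd$length[o])
    i <- findInterval(p, nd$pvalue[o])
    ifelse(i == 0, 0, cs[pmax(i, 1L)])
  }, numeric(length(p)))
  if (length(p) == 1L) per <- matrix(per, nrow = 1L)
  rowMeans(per)
}

# apply the fp stop to a detect_region result; cutoff NULL disables it
stop_index <- function(res, fp_cutoff) {
  n <- nrow(res$selected)
  if (!n || is.null(fp_cutoff)) return(n)
  viol <- which(res$expected_false > fp_cutoff * seq_len(n))
  if (length(viol)) viol[1] - 1L else n
}

#' Detect constrained elements in a scored track
#'
#' Runs the full detection pipeline: the track is split into regions
#' ([chunk_regions()]); within each region a preliminary pass (false-positive
#' cutoff 0) identifies clearly constrained intervals that are excluded from
#' the final null histogram; candidates are enumerated, assigned DP p-values,
#' and selected greedily in significance order; permuted copies of the region
#' provide the expected number (and bases) of false predictions as a function
#' of the p-value threshold, which stops acceptance at `fp_cutoff`.
#'
#' @param track A scored track data frame (see [score_alignment()] or
#'   [read_rates()]).
#' @param params A [gerp_params()].
#' @param seed Integer seed governing all shuffles (per-region, per-shuffle
#'   streams are derived deterministically from it).
#' @param fp_cutoff Override of `params$fp_cutoff`; `NULL` disables the stop
#'   (all greedily selected candidates are reported).
#' @return A list with:
#'   \describe{
#'     \item{elements}{data frame `chrom`, `start`, `end` (0-based half-open
#'       reference coordinates), `length`, `score`, `pvalue`, `rank`
#'       (significance rank across the track).}
#'     \item{fpr}{data frame mapping each accepted element's p-value to the
#'       expected number of false predictions and false bases at that
#'       threshold, with the observed prediction count.}
#'     \item{regions}{the region table used.}
#'   }
#' @export
find_elements <- function(track, params = gerp_params(), seed = 1L,
                          fp_cutoff = params$fp_cutoff) {
  regions <- chunk_regions(track, params$chunk_size, params$shallow_run)
  chrom <- attr(track, "chrom") %||% "chr1"
  elems <- list(); fpr <- list()
  for (ri in seq_len(nrow(regions))) {
    rows <- regions$start[ri]:(regions$end[ri] - 1L)
    sub <- track[rows, , drop = FALSE]
    res <- detect_region(sub, params, derive_seed(seed, 100L, ri))
    k <- stop_index(res, fp_cutoff)
    if (!k) next
    sel <- res$selected[seq_len(k), , drop = FALSE]
    off <- track$pos[rows[1]]
    elems[[length(elems) + 1L]] <- data.frame(
      chrom = chrom,
      start = off + sel$start, end = off + sel$end,
      length = sel$length, score = sel$score, pvalue = sel$pvalue)
    fpr[[length(fpr) + 1L]] <- data.frame(
      pvalue = sel$pvalue,
      expected_false = res$expected_false[seq_len(k)],
      expected_false_bases = res$expected_false_bases[seq_len(k)],
      observed = seq_len(k))
  }
  if (!length(elems)) {
    elements <- data.frame(chrom = character(), start = integer(),
                           end = integer(), length = integer(),
                           score = numeric(), pvalue = numeric(),
                           rank = integer())
    fpr_tab <- data.frame(pvalue = numeric(), expected_false = numeric(),
                          expected_false_bases = numeric(),
                          observed = integer())
    return(list(elements = elements, fpr = fpr_tab, regions = regions))
  }
  elements <- do.call(rbind, elems)
  o <- order(elements$pvalue, -elements$length, elements$start)
  elements <- elements[o, , drop = FALSE]
  elements$rank <- seq_len(nrow(elements))
  rownames(elements) <- NULL
  list(elements = elements, fpr = do.call(rbind, fpr), regions = regions)
}

#' Shuffle-based false-positive-rate estimate
#'
#' Runs the full candidate generation and greedy selection machinery on
#' `n_shuffles` permuted copies of each region and reports, at each p-value
#' threshold realized by the real track's selected predictions, the mean
#' number of null predictions and null prediction bases at or below that
#' threshold.
#'
#' @inheritParams find_elements
#' @param n_shuffles Number of permuted tracks (overrides `params`).
#' @return Data frame `pvalue`, `expected_false`, `expected_false_bases`,
#'   `observed` (cumulative real predictions at that threshold).
#' @export
estimate_fpr <- function(track, params = gerp_params(), seed = 1L,
                         n_shuffles = params$n_shuffles) {
  params$n_shuffles <- as.integer(n_shuffles)
  find_elements(track, params, seed, fp_cutoff = NULL)$fpr
}

#' Detection saturation curve B(c), F(c), B*(c)
#'
#' For each false-positive cutoff c in `cutoffs`, `B(c)` is the number of
#' bases inside elements accepted before the stop rule triggers at cutoff c,
#' `F(c)` the expected number of false-positive bases at the corresponding
#' p-value threshold (from the shuffles), and `B*(c) = B(c) - F(c)` the
#' adjusted detectable constraint.  `max B*` estimates the total number of
#' constrained bases detectable in the track.
#'
#' @inheritParams find_elements
#' @param cutoffs Numeric vector of false-positive cutoffs in `[0, 1]`.
#' @return Data frame `cutoff`, `B`, `F`, `Bstar`, with attributes
#'   `max_Bstar` and `argmax_cutoff`.
#' @export
detection_curve <- function(track, cutoffs = seq(0, 0.5, by = 0.05),
                            params = gerp_params(), seed = 1L) {
  stopifnot(all(cutoffs >= 0), all(cutoffs <= 1))
  regions <- chunk_regions(track, params$chunk_size, params$shallow_run)
  B <- F_ <- rep(0, length(cutoffs))
  for (ri in seq_len(nrow(regions))) {
    rows <- regions$start[ri]:(regions$end[ri] - 1L)
    res <- detect_region(track[rows, , drop = FALSE], params,
                         derive_seed(seed, 100L, ri))
    n <- nrow(res$selected)
    if (!n) next
    cumb <- cumsum(res$selected$length)
    for (j in seq_along(cutoffs)) {
      viol <- which(res$expected_false > cutoffs[j] * seq_len(n))
      k <- if (length(viol)) viol[1] - 1L else n
      if (k > 0) {
        B[j] <- B[j] + cumb[k]
        F_[j] <- F_[j] + res$expected_false_bases[k]
      }
    }
  }
  out <- data.frame(cutoff = cutoffs, B = B, F = F_, Bstar = B - F_)
  attr(out, "max_Bstar") <- max(out$Bstar)
  attr(out, "argmax_cutoff") <- out$cutoff[which.max(out$Bstar)]
  out
}
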