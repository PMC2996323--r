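#' Likelihood of an alignment column under a rescaled tree
#'
#' Computes `Pr(c_1, ..., c_k | T_r)`, the probability of the observed leaf
#' nucleotides when every branch of `tree` is multiplied by `r`, by
#' Felsenstein's pruning algorithm (post-order dynamic programming over the
#' tree, linear in the number of leaves).  Species with a gap or ambiguity
#' code are marginalized out, which under a reversible model gives exactly
#' the likelihood on the tree with those species projected out, for every
#' `r`.
#'
#' @param column Named character vector of bases (names are species, values
#'   in A/C/G/T, anything else treated as missing), or a named integer vector
#'   with codes 0..3 / -1.
#' @param tree A `"phylo"` neutral tree whose tip labels cover the column's
#'   species.
#' @param model An [hky_model()].
#' @param r Non-negative rescaling factor.
#' @return The likelihood, a number in (0, 1] (0 is possible only at r = 0
#'   for a non-invariant column).
#' @export
column_likelihood <- function(column, tree, model, r) {
  stopifnot(is.numeric(r), length(r) == 1, r >= 0)
  td <- tree_data(tree)
  states <- column_states(column, td$tips)
  if (sum(states >= 0) < 1) stop("column has no observed species")
  cpp_column_likelihood(states, r, td$parent, td$child, td$elen,
                        td$ntip, td$nnode, td$root,
                        model$V1, model$V2, model$lambda, model$freq)
}

column_states <- function(column, tips) {
  if (is.character(column)) {
    if (is.null(names(column))) stop("column must be named by species")
    vals <- encode_bases(column)
  } else {
    vals <- as.integer(column)
    if (is.null(names(column))) stop("column must be named by species")
  }
  unknown <- setdiff(names(column)[vals >= 0], tips)
  if (length(unknown))
    stop("species in column absent from tree: ",
         paste(unknown, collapse = ", "))
  states <- rep(-1L, length(tips))
  i <- match(names(column), tips)
  states[i[!is.na(i)]] <- vals[!is.na(i)]
  states
}

#' Maximum-likelihood rescaling and RS score for one column
#'
#' Projects out gapped/ambiguous species; if fewer than 3 remain, returns the
#' unscored sentinel (`neutral_rate = 0`, `rs = 0`, `scored = FALSE`).
#' Otherwise the site-specific neutral rate n is the total branch length of
#' the projected tree, the rescaling r is estimated by bounded Brent
#' maximization of the column likelihood over `[0, rmax]`, and the rejected
#' substitutions score is `RS = n * (1 - r)`, ranging from `-2n` (substitution
#' surplus at the cap r = 3) to `+n` (complete constraint).
#'
#' @inheritParams column_likelihood
#' @param rmax Cap on the rate estimate (default 3).
#' @param rtol Absolute tolerance on r for the optimizer (default 1e-4;
#'   scores are later discretized, so finer precision is wasted).
#' @return A list with `neutral_rate`, `rescaling`, `rs`, `scored`.
#' @export
estimate_rate <- function(column, tree, model, rmax = 3, rtol = 1e-4) {
  td <- tree_data(tree)
  states <- matrix(column_states(column, td$tips), ncol = 1)
  m <- cpp_score_columns(states, td$parent, td$child, td$elen,
                         td$ntip, td$nnode, td$root,
                         model$V1, model$V2, model$lambda, model$freq,
                         rmax, rtol)
  list(neutral_rate = unname(m[1, 1]), rescaling = unname(m[1, 2]),
       rs = unname(m[1, 3]), scored = unname(m[1, 4]) == 1)
}

#' Score every column of an alignment in rejected substitutions
#'
#' Applies [estimate_rate()] independently to every column (results do not
#' depend on evaluation order) and returns a dense scored track covering the
#' reference span of the alignment; reference positions not covered by any
#' column are unscored.
#'
#' @param aln A [ref_alignment()] whose species are all present in `tree`
#'   (tree species absent from the alignment count as gapped everywhere).
#' @param tree The neutral `"phylo"` tree.
#' @param model An [hky_model()].
#' @inheritParams estimate_rate
#' @return A data frame (one row per reference position from the first to the
#'   last covered position) with columns `pos` (0-based), `neutral_rate`,
#'   `rescaling`, `rs`, `scored`, and a `chrom` attribute.
#' @export
score_alignment <- function(aln, tree, model, rmax = 3, rtol = 1e-4) {
  stopifnot(inherits(aln, "ref_alignment"))
  td <- tree_data(tree)
  unknown <- setdiff(rownames(aln$states), td$tips)
  if (length(unknown))
    stop("alignment species absent from tree: ",
         paste(unknown, collapse = ", "))
  if (ncol(aln$states) == 0)
    return(scored_track(integer(), numeric(), numeric(), numeric(),
                        logical(), attr(aln, "chrom") %||% aln$chrom))
  states <- matrix(-1L, nrow = td$ntip, ncol = ncol(aln$states))
  states[match(rownames(aln$states), td$tips), ] <- aln$states
  m <- cpp_score_columns(states, td$parent, td$child, td$elen,
                         td$ntip, td$nnode, td$root,
                         model$V1, model$V2, model$lambda, model$freq,
                         rmax, rtol)
  span <- min(aln$positions):max(aln$positions)
  out <- scored_track(pos = span,
                      neutral_rate = 0, rescaling = NA_real_, rs = 0,
                      scored = FALSE, chrom = aln$chrom)
  i <- match(aln$positions, span)
  out$neutral_rate[i] <- m[, 1]
  out$rescaling[i] <- m[, 2]
  out$rs[i] <- m[, 3]
  out$scored[i] <- m[, 4] == 1
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' 3-periodicity bias of a scored segment
#'
#' The maximum over the three possible reading frames of the mean RS score at
#' codon positions 1 and 2 minus the mean RS score at codon position 3.
#' A strong positive bias is the signature of protein-coding constraint,
#' where third codon positions are largely free to vary; the frame maximum
#' makes the metric usable without knowing the reading frame (or whether one
#' exists).  Unscored positions are excluded from the means.
#'
#' @param track A scored track data frame (contiguous slice), or a numeric
#'   vector of RS scores with `NA` marking unscored positions.
#' @return The bias (numeric scalar); frames in which either mean is empty
#'   are skipped.
#' @export
periodicity_bias <- function(track) {
  if (is.data.frame(track)) {
    rs <- ifelse(track$scored, track$rs, NA_real_)
  } else {
    rs <- as.numeric(track)
  }
  n <- length(rs)
  if (n < 3) stop("segment must have at least 3 positions")
  codon <- function(o) ((seq_len(n) - 1 + o) %% 3) + 1
  best <- -Inf
  for (o in 0:2) {
    cp <- codon(o)
    m12 <- mean(rs[cp != 3], na.rm = TRUE)
    m3 <- mean(rs[cp == 3], na.rm = TRUE)
    if (is.nan(m12) || is.nan(m3)) next
    best <- max(best, m12 - m3)
  }
  if (!is.finite(best)) return(NA_real_)
  best
}
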