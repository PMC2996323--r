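#' Default neutral tree and model for simulations
#'
#' `default_tree()` builds a balanced binary phylogeny (16 leaves named
#' `sp01`..`sp16`) with equal branch lengths scaled to a total phylogenetic
#' scope of 5.8 substitutions per neutral site, mirroring the depth of a
#' mammal-wide alignment.  `default_model()` is HKY85 with
#' transition/transversion ratio 2 and mildly AT-rich stationary frequencies
#' (A/T 0.3, C/G 0.2), typical of mammalian genomic background.
#'
#' @param n_leaves Number of leaves (a power of two).
#' @param scope Total branch length, substitutions/site.
#' @return A `"phylo"` tree / an [hky_model()].
#' @export
default_tree <- function(n_leaves = 16L, scope = 5.8) {
  tr <- ape::stree(n_leaves, type = "balanced")
  tr$tip.label <- sprintf("sp%02d", seq_len(n_leaves))
  tr$edge.length <- rep(scope / nrow(tr$edge), nrow(tr$edge))
  tr
}

#' @rdname default_tree
#' @export
default_model <- function() {
  hky_model(kappa = 2, freq = c(0.3, 0.2, 0.2, 0.3))
}

#' Simulate one alignment column
#'
#' Draws a root state from the model's stationary frequencies and evolves it
#' down every branch of the tree using [transition_matrix()] with the branch
#' length multiplied by `r` — i.e. samples from exactly the distribution
#' whose likelihood [column_likelihood()] evaluates.  Uses (and advances) the
#' current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param tree A `"phylo"` neutral tree.
#' @param model An [hky_model()].
#' @param r Rescaling factor (>= 0; 0 yields an invariant column).
#' @return Named character vector of bases, one per tree leaf.
#' @export
simulate_column <- function(tree, model, r) {
  st <- simulate_states(tree, model, rep(r, 1L))
  setNames(decode_bases(st[, 1]), rownames(st))
}

# Sample leaf states for length(r) columns; returns ntip x ncol int matrix.
simulate_states <- function(tree, model, r) {
  stopifnot(all(r >= 0))
  td <- tree_data(tree)
  ncols <- length(r)
  states <- matrix(0L, nrow = td$nnode, ncol = ncols)
  states[td$root, ] <- sample.int(4L, ncols, replace = TRUE,
                                  prob = model$freq) - 1L
  groups <- split(seq_len(ncols), r)
  # preorder = reverse postorder: parents before children
  for (e in rev(seq_along(td$child))) {
    p <- td$parent[e]; ch <- td$child[e]; len <- td$elen[e]
    for (g in groups) {
      P <- pmax(transition_matrix(model, r[g[1]] * len), 0)
      ps <- states[p, g]
      for (a in 0:3) {
        idx <- g[ps == a]
        if (length(idx))
          states[ch, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                        prob = P[a + 1L, ]) - 1L
      }
    }
  }
  out <- states[seq_len(td$ntip), , drop = FALSE]
  rownames(out) <- td$tips
  out
}

#' Piecewise constraint profile with planted elements
#'
#' Builds a per-column rescaling profile: neutral background at
#' `background_r` with constrained blocks planted at the given positions.
#' A block may be uniformly constrained or 3-periodic ("codon pattern"):
#' positions 1 and 2 of each triplet evolve at `r`, position 3 at `r3`.
#'
#' @param n_col Number of columns.
#' @param background_r Background rescaling (1 = neutral).
#' @param blocks Data frame with columns `start` (0-based), `length`, `r`,
#'   and optionally `periodic` (logical) and `r3`.
#' @return List with `r` (numeric profile of length `n_col`) and `blocks`
#'   (the blocks with an added half-open `end` column).
#' @export
constraint_profile <- function(n_col, background_r = 1, blocks = NULL) {
  r <- rep(background_r, n_col)
  if (is.null(blocks) || !nrow(blocks)) {
    return(list(r = r, blocks = data.frame(start = integer(),
                                           end = integer(), r = numeric())))
  }
  if (is.null(blocks$periodic)) blocks$periodic <- FALSE
  if (is.null(blocks$r3)) blocks$r3 <- blocks$r
  blocks$end <- blocks$start + blocks$length
  if (any(blocks$end > n_col) || any(blocks$start < 0))
    stop("block outside [0, n_col)")
  for (i in seq_len(nrow(blocks))) {
    idx <- (blocks$start[i] + 1L):blocks$end[i]
    if (blocks$periodic[i]) {
      codon <- ((seq_along(idx) - 1L) %% 3L) + 1L
      r[idx] <- ifelse(codon == 3L, blocks$r3[i], blocks$r[i])
    } else {
      r[idx] <- blocks$r[i]
    }
  }
  list(r = r, blocks = blocks)
}

#' Simulate a reference-projected alignment with known ground truth
#'
#' Columns are drawn independently under the HKY85 model on the neutral tree
#' rescaled per column by the supplied profile ([simulate_column()]'s
#' distribution).  Gaps are then injected independently per species and
#' column at rate `gap_rate` (the reference is never gapped), emulating
#' missing data; the real gap process is autocorrelated, so this is adequate
#' for exercising projection logic but not a realistic indel model.
#'
#' @param n_col Number of columns (reference positions).
#' @param r Per-column rescaling: a scalar or a vector of length `n_col`
#'   (see [constraint_profile()]).
#' @param tree,model Neutral tree and substitution model; defaults
#'   [default_tree()] / [default_model()].
#' @param gap_rate Per-species, per-column gap probability in `[0, 1)`.
#' @param reference Reference species (a tree leaf; default the first).
#' @param chrom Chromosome name for the simulated reference.
#' @param seed Integer seed; the same seed yields a byte-identical alignment.
#' @return List with `alignment` (a [ref_alignment()]) and `r_true` (the
#'   per-column rescaling profile used).
#' @export
simulate_alignment <- function(n_col, r = 1, tree = default_tree(),
                               model = default_model(), gap_rate = 0.1,
                               reference = NULL, chrom = "sim", seed = 1L) {
  stopifnot(gap_rate >= 0, gap_rate < 1)
  if (length(r) == 1L) r <- rep(r, n_col)
  stopifnot(length(r) == n_col)
  if (is.null(reference)) reference <- tree$tip.label[1]
  stopifnot(reference %in% tree$tip.label)
  states <- with_local_seed(seed, {
    st <- simulate_states(tree, model, r)
    if (gap_rate > 0) {
      others <- setdiff(rownames(st), reference)
      mask <- matrix(runif(length(others) * n_col) < gap_rate,
                     nrow = length(others))
      st[others, ][mask] <- -1L
    }
    st
  })
  list(alignment = ref_alignment(states, reference, chrom = chrom),
       r_true = r)
}
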