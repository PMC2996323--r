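# Independent oracles and shared fixtures, all built in code.

# Exhaustive-enumeration likelihood: sums over every assignment of internal
# node states on the explicitly projected tree.  Independent of the pruning
# implementation (uses only transition_matrix and tree bookkeeping).
brute_likelihood <- function(column, tree, model, r) {
  present <- names(column)[toupper(column) %in% c("A", "C", "G", "T")]
  ptr <- project_tree(tree, present)
  if (is.null(ptr)) stop("brute oracle needs >= 3 present species")
  td <- gerpr:::tree_data(ptr)
  nint <- td$nnode - td$ntip
  states <- rep(NA_integer_, td$nnode)
  states[seq_len(td$ntip)] <- gerpr:::encode_bases(column[td$tips])
  Ps <- lapply(seq_along(td$child),
               function(e) transition_matrix(model, r * td$elen[e]))
  tot <- 0
  for (idx in 0:(4^nint - 1)) {
    s <- states
    x <- idx
    for (j in seq_len(nint)) {
      s[td$ntip + j] <- x %% 4
      x <- x %/% 4
    }
    pr <- model$freq[s[td$root] + 1]
    for (e in seq_along(td$child))
      pr <- pr * Ps[[e]][s[td$parent[e]] + 1, s[td$child[e]] + 1]
    tot <- tot + pr
  }
  unname(tot)
}

# Exhaustive p-value: enumerates every sequence of L bin draws.
brute_pvalue <- function(L, S, hist) {
  B <- length(hist$probs)
  ks <- (hist$kmin:hist$kmax) * hist$tol
  kdisc <- hist$kmin:hist$kmax
  tot <- 0
  for (idx in 0:(B^L - 1)) {
    x <- idx
    ssum <- 0
    p <- 1
    for (j in seq_len(L)) {
      b <- x %% B + 1
      x <- x %/% B
      ssum <- ssum + kdisc[b]
      p <- p * hist$probs[b]
    }
    if (ssum * hist$tol >= S - 1e-9) tot <- tot + p
  }
  tot
}

# small shared fixtures
tree3 <- function() parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
tree4 <- function() parse_newick("((A:0.1,B:0.2):0.05,(C:0.3,D:0.4):0.05);")
tree4_cat <- function() parse_newick("(((A:0.15,B:0.1):0.1,C:0.25):0.05,D:0.4);")

model_test <- function() hky_model(kappa = 2, freq = c(0.3, 0.2, 0.2, 0.3))

# a bare scored track from an RS vector (deep neutral rate, fully scored)
toy_track <- function(rs, n = 1.0, scored = NULL) {
  if (is.null(scored)) scored <- rep(TRUE, length(rs))
  gerpr:::scored_track(pos = seq_along(rs) - 1L,
                       neutral_rate = ifelse(scored, n, 0),
                       rescaling = NA_real_, rs = ifelse(scored, rs, 0),
                       scored = scored)
}

random_column <- function(tips, gap_rate = 0) {
  b <- sample(c("A", "C", "G", "T"), length(tips), replace = TRUE)
  if (gap_rate > 0) b[runif(length(tips)) < gap_rate] <- "-"
  setNames(b, tips)
}
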