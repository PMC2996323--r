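#' HKY85 substitution model
#'
#' Builds the HKY85 continuous-time Markov model of nucleotide substitution,
#' parameterized by the transition/transversion ratio `kappa` and the
#' stationary base frequencies.  The rate matrix is normalized so that the
#' expected number of substitutions per unit branch length equals one at
#' stationarity; branch lengths of the neutral tree are therefore interpreted
#' directly as expected substitutions per site.
#'
#' The model is time reversible: `pi_a * p_ab(t) == pi_b * p_ba(t)`.
#' Transition probabilities are computed from the eigendecomposition of the
#' symmetrized rate matrix, precomputed at construction.
#'
#' @param kappa Transition/transversion rate ratio (> 0).  The default 2.0 is
#'   the conventional mammalian value.
#' @param freq Stationary frequencies, a numeric vector of length 4 in the
#'   order A, C, G, T; must be positive (minimum 1e-6) and sum to 1.
#' @return An object of class `"hky_model"`.
#' @examples
#' m <- hky_model(kappa = 2, freq = c(0.3, 0.2, 0.2, 0.3))
#' transition_matrix(m, 0.1)
#' @export
hky_model <- function(kappa = 2.0, freq = rep(0.25, 4)) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa > 0)
  freq <- as.numeric(freq)
  if (length(freq) != 4)
    stop("freq must have length 4 (A, C, G, T)")
  if (any(freq < 1e-6))
    stop("stationary frequencies below 1e-6 are not allowed")
  if (abs(sum(freq) - 1) > 1e-8)
    stop("stationary frequencies must sum to 1")
  freq <- freq / sum(freq)
  names(freq) <- c("A", "C", "G", "T")

  # unnormalized rates: kappa for transitions (A<->G, C<->T), 1 otherwise
  mult <- matrix(1, 4, 4)
  mult[1, 3] <- mult[3, 1] <- kappa
  mult[2, 4] <- mult[4, 2] <- kappa
  Q <- mult * rep(freq, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freq * diag(Q))
  Q <- Q / rate
  dimnames(Q) <- list(names(freq), names(freq))

  # reversible => D^{1/2} Q D^{-1/2} is symmetric; eigendecompose once
  d <- sqrt(freq)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  structure(list(kappa = kappa, freq = freq, Q = Q,
                 lambda = es$values,
                 V1 = es$vectors / d,            # D^{-1/2} U
                 V2 = t(es$vectors * d)),        # U' D^{1/2}
            class = "hky_model")
}

#' @export
print.hky_model <- function(x, ...) {
  cat("HKY85 substitution model\n")
  cat("  kappa:", format(x$kappa), "\n")
  cat("  stationary frequencies:",
      paste(sprintf("%s=%.4f", names(x$freq), x$freq), collapse = " "), "\n")
  invisible(x)
}

#' Transition probability matrix p_ab(t)
#'
#' The 4x4 matrix whose entry (a, b) is the probability that nucleotide a has
#' been substituted by b after branch length t, under the (unit-normalized)
#' HKY85 model.  Rows sum to one; at t = 0 the matrix is the identity and as
#' t grows every row converges to the stationary frequencies.
#'
#' @param model An [hky_model()].
#' @param t Branch length, in expected substitutions per site (>= 0).
#' @return A 4x4 row-stochastic matrix with rows/columns A, C, G, T.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "hky_model"))
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0)
    stop("branch length t must be a single non-negative number")
  P <- model$V1 %*% (exp(model$lambda * t) * model$V2)
  dimnames(P) <- dimnames(model$Q)
  P
}

#' Empirical stationary frequencies from an alignment
#'
#' Counts A/C/G/T over all species and columns of a reference-projected
#' alignment (gaps and ambiguity codes ignored), floors at 1e-6 and
#' renormalizes.
#'
#' @param aln A [ref_alignment()].
#' @return Named numeric vector of length 4 summing to one.
#' @export
estimate_frequencies <- function(aln) {
  stopifnot(inherits(aln, "ref_alignment"))
  s <- aln$states
  counts <- tabulate(s[s >= 0] + 1L, nbins = 4L)
  if (sum(counts) == 0) stop("alignment contains no nucleotides")
  f <- pmax(counts / sum(counts), 1e-6)
  f <- f / sum(f)
  setNames(f, c("A", "C", "G", "T"))
}
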