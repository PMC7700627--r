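# JTT (Jones-Taylor-Thornton 1992) empirical amino-acid substitution model.
#
# The exchangeability matrix and equilibrium frequencies are shipped as
# plain-text data (inst/extdata/jtt_rates.tsv, jtt_freqs.tsv). The rate
# matrix Q is built as Q_ij = s_ij * pi_j, scaled so the expected number of
# substitutions per site per unit time is 1; transition probabilities
# P(t) = exp(Qt) come from a symmetric eigendecomposition (the chain is
# reversible, so D^{1/2} Q D^{-1/2} is symmetric).

.jtt <- function() {
  if (is.null(.gf_cache$jtt)) {
    s <- as.matrix(utils::read.delim(.gf_extdata("jtt_rates.tsv"),
                                     row.names = 1, check.names = FALSE))
    bf <- utils::read.delim(.gf_extdata("jtt_freqs.tsv"))
    pi <- setNames(bf$freq, bf$aa)
    ord <- AA20
    s <- s[ord, ord]
    pi <- pi[ord] / sum(pi[ord])
    Q <- s * rep(pi, each = 20)
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    scale <- -sum(pi * diag(Q))
    Q <- Q / scale
    d <- sqrt(pi)
    B <- diag(d) %*% Q %*% diag(1 / d)
    B <- (B + t(B)) / 2
    eig <- eigen(B, symmetric = TRUE)
    .gf_cache$jtt <- list(
      pi = pi, Q = Q,
      U = diag(1 / d) %*% eig$vectors,      # right transform
      Uinv = t(eig$vectors) %*% diag(d),    # left transform
      lambda = eig$values
    )
  }
  .gf_cache$jtt
}

#' JTT equilibrium amino-acid frequencies
#' @return Named numeric vector over the 20 residues.
#' @export
jtt_frequencies <- function() .jtt()$pi

#' JTT transition probability matrix
#'
#' `P(t) = exp(Qt)` for the unit-scaled JTT rate matrix; `t` is in expected
#' substitutions per site.
#'
#' @param t Branch length (>= 0).
#' @return A 20 x 20 row-stochastic matrix.
#' @export
jtt_prob <- function(t) {
  if (t < 0) abort("branch length must be >= 0")
  j <- .jtt()
  P <- j$U %*% (exp(j$lambda * t) * j$Uinv)
  P[P < 0] <- 0
  dimnames(P) <- list(AA20, AA20)
  P
}
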