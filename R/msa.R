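# Minimal progressive multiple aligner for simulated fixtures.
#
# Guide tree from k-mer distances (average-linkage), then profile-profile
# Needleman-Wunsch with a linear gap penalty. This is a deliberately small
# utility so downstream phylogenetics can be exercised on simulated
# families; it is not a production multiple-sequence aligner.

.kmer_dist <- function(seqs, k = 3) {
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      t1 <- table(kmers[[i]])
      t2 <- table(kmers[[j]])
      common <- intersect(names(t1), names(t2))
      shared <- sum(pmin(t1[common], t2[common]))
      denom <- max(1, min(length(kmers[[i]]), length(kmers[[j]])))
      d[i, j] <- d[j, i] <- 1 - shared / denom
    }
  }
  d
}

# profile: 21 x L frequency matrix (rows AA20 + gap)
.seqs_to_profile <- function(rows) {
  L <- nchar(rows[1])
  m <- do.call(rbind, strsplit(rows, ""))
  prof <- matrix(0, 21, L, dimnames = list(c(AA20, "-"), NULL))
  for (a in seq_len(21)) {
    prof[a, ] <- colMeans(m == c(AA20, "-")[a])
  }
  prof
}

.profile_nw <- function(rows1, rows2, gap = 8) {
  M <- .blosum62()[AA20, AA20]
  M21 <- rbind(cbind(M, rep(-4, 20)), c(rep(-4, 20), 0))
  p1 <- .seqs_to_profile(rows1)
  p2 <- .seqs_to_profile(rows2)
  S <- t(p1) %*% M21 %*% p2
  n1 <- ncol(p1)
  n2 <- ncol(p2)
  D <- matrix(0, n1 + 1, n2 + 1)
  D[, 1] <- -gap * (0:n1)
  D[1, ] <- -gap * (0:n2)
  ptr <- matrix(0L, n1 + 1, n2 + 1)  # 1 diag, 2 up (gap in 2), 3 left
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      cand <- c(D[i, j] + S[i, j], D[i, j + 1] - gap, D[i + 1, j] - gap)
      w <- which.max(cand)
      D[i + 1, j + 1] <- cand[w]
      ptr[i + 1, j + 1] <- w
    }
  }
  # traceback
  i <- n1; j <- n2
  path <- list()
  while (i > 0 || j > 0) {
    w <- if (i == 0) 3L else if (j == 0) 2L else ptr[i + 1, j + 1]
    path[[length(path) + 1]] <- w
    if (w == 1L) { i <- i - 1; j <- j - 1 }
    else if (w == 2L) i <- i - 1
    else j <- j - 1
  }
  path <- rev(unlist(path))
  gap1 <- path != 3L  # TRUE where profile 1 advances
  gap2 <- path != 2L
  expand <- function(rows, adv) {
    vapply(rows, function(s) {
      chars <- strsplit(s, "")[[1]]
      out <- character(length(adv))
      out[adv] <- chars
      out[!adv] <- "-"
      paste(out, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  c(expand(rows1, gap1), expand(rows2, gap2))
}

#' Progressive multiple alignment (fixture-scale)
#'
#' Aligns a protein collection by average-linkage guide tree on k-mer
#' distances and profile-profile Needleman-Wunsch. Intended for simulated
#' families of modest size, not genome-scale data.
#'
#' @param x A protein sequence tibble.
#' @return An alignment tibble (`id`, gapped `seq`), rows in input order.
#' @export
align_progressive <- function(x) {
  n <- nrow(x)
  if (n < 2) abort("need >= 2 sequences")
  d <- .kmer_dist(x$seq)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  groups <- lapply(seq_len(n), function(i) {
    list(ids = x$id[i], rows = x$seq[i])
  })
  merged <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    pick <- function(v) if (v < 0) groups[[-v]] else merged[[v]]
    g1 <- pick(hc$merge[step, 1])
    g2 <- pick(hc$merge[step, 2])
    rows <- .profile_nw(g1$rows, g2$rows)
    merged[[step]] <- list(ids = c(g1$ids, g2$ids), rows = rows)
  }
  res <- merged[[n - 1]]
  ord <- match(x$id, res$ids)
  tibble(id = x$id, seq = res$rows[ord])
}
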