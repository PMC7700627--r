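# Shared fixtures and independent oracles.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_prot <- function(len, seed = NULL) {
  draw <- function() paste(sample(AA, len, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

toy_matrix <- function(letters = c("A", "C", "G", "T"), match = 2,
                       mismatch = -1) {
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

# Independent affine-gap Smith-Waterman (plain-R Gotoh DP), used as the
# oracle for the Biostrings-backed implementation.
oracle_sw_score <- function(q, s, mat, gap_open, gap_extend) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc)
  m <- length(sc)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0
  M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- mat[qc[i - 1], sc[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Independent fine-grid scan of the charge function for the pI oracle.
grid_pi_oracle <- function(seq, step = 1e-5) {
  pH <- seq(0, 14, by = step)
  chars <- strsplit(seq, "")[[1]]
  counts <- table(factor(chars, levels = AA))
  nt <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
          E = 7.7)[chars[1]]
  if (is.na(nt)) nt <- 7.5
  ct <- c(D = 4.55, E = 4.75)[chars[length(chars)]]
  if (is.na(ct)) ct <- 3.55
  pos <- 1 / (1 + 10^(pH - nt)) +
    counts[["K"]] / (1 + 10^(pH - 10.0)) +
    counts[["R"]] / (1 + 10^(pH - 12.0)) +
    counts[["H"]] / (1 + 10^(pH - 5.98))
  neg <- 1 / (1 + 10^(ct - pH)) +
    counts[["D"]] / (1 + 10^(4.05 - pH)) +
    counts[["E"]] / (1 + 10^(4.45 - pH)) +
    counts[["C"]] / (1 + 10^(9.0 - pH)) +
    counts[["Y"]] / (1 + 10^(10.0 - pH))
  charge <- pos - neg
  pH[which.min(abs(charge))]
}

# Brute-force tree likelihood: explicit summation over all internal-node
# state assignments (independent of the pruning implementation).
brute_loglik <- function(tree, aln) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  pi <- genefamr::jtt_frequencies()
  root <- tr$edge[nrow(tr$edge), 1]
  codes <- lapply(aln$seq, function(s) match(strsplit(s, "")[[1]], AA))
  names(codes) <- aln$id
  S <- length(codes[[1]])
  internals <- setdiff(seq_len(nnode), seq_len(ntip))
  Ps <- lapply(seq_len(nrow(tr$edge)), function(e) {
    genefamr::jtt_prob(tr$edge.length[e])
  })
  total <- 0
  for (site in seq_len(S)) {
    states <- integer(nnode)
    for (i in seq_len(ntip)) states[i] <- codes[[tr$tip.label[i]]][site]
    combos <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
    lik <- 0
    for (r in seq_len(nrow(combos))) {
      states[internals] <- combos[r, ]
      p <- pi[states[root]]
      for (e in seq_len(nrow(tr$edge))) {
        p <- p * Ps[[e]][states[tr$edge[e, 1]], states[tr$edge[e, 2]]]
      }
      lik <- lik + p
    }
    total <- total + log(unname(lik))
  }
  total
}

# Table-6-style printed count pairs used by the arithmetic-surface checks:
# nine rows of the HSP70 family and four of HSP90, with published totals.
hsp70_rows <- tibble::tribble(
  ~gene_id, ~syn, ~nonsyn, ~total, ~ratio,
  "HSPA4L", 18, 6, 24, 0.33,
  "HSPA4", 13, 3, 16, 0.23,
  "HSPA13", 24, 9, 33, 0.38,
  "HSPA14", 8, 2, 10, 0.25,
  "HSP70", 39, 23, 62, 0.59,
  "HSPA8", 72, 8, 80, 0.11,
  "HSP70.1", 17, 1, 18, 0.06,
  "HSPA1L", 22, 3, 25, 0.14,
  "HSPA6", 19, 4, 23, 0.21
)
hsp70_total <- c(syn = 232, nonsyn = 59, total = 291, ratio = 0.25)

hsp90_rows <- tibble::tribble(
  ~gene_id, ~syn, ~nonsyn, ~total, ~ratio,
  "TRP1", 111, 17, 128, 0.15,
  "HSP90AA1", 23, 1, 24, 0.04,
  "HSP90B1", 19, 0, 19, 0.00,
  "HSP90AB1", 22, 1, 23, 0.05
)
hsp90_total <- c(syn = 175, nonsyn = 19, total = 194, ratio = 0.11)

# Build a codon_alignment object directly from codon vectors (bypassing the
# protein aligner) for coordinate-convention tests.
make_codon_alignment <- function(ref_codons, alt_codons, gene_id = "g") {
  structure(list(gene_id = gene_id, ref_label = "ref", alt_label = "alt",
                 codons = tibble::tibble(ref_codon = ref_codons,
                                         alt_codon = alt_codons)),
            class = "codon_alignment")
}
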