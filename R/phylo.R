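# Distance and likelihood phylogenetics under the JTT model: complete
# deletion, neighbor joining, Felsenstein-pruning log-likelihood, NNI
# hill-climbing and bootstrap supports. Trees are ape "phylo" objects
# (Newick-serializable; supports stored as internal node labels).

.aln_chars <- function(aln) {
  if (nrow(aln) < 2) abort("alignment needs >= 2 rows")
  if (anyDuplicated(aln$id)) abort("alignment ids must be unique")
  lens <- nchar(aln$seq)
  if (length(unique(lens)) != 1) abort("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$id
  m
}

.check_gapless <- function(aln) {
  if (any(grepl("[-X]", aln$seq))) {
    abort("alignment contains gaps or missing data; apply complete_deletion() first")
  }
}

#' Remove alignment columns with gaps or missing data
#'
#' Complete-deletion filtering: every column containing `-` or `X` in any
#' row is removed; row order is preserved.
#'
#' @param aln An alignment tibble (`id`, `seq`; equal-length gapped rows).
#' @return The filtered alignment tibble.
#' @export
complete_deletion <- function(aln) {
  m <- .aln_chars(aln)
  keep <- colSums(m == "-" | m == "X") == 0
  if (!any(keep)) {
    abort(paste0("complete deletion removed every column; a pairwise-",
                 "deletion fallback is not implemented"))
  }
  tibble(id = aln$id,
         seq = unname(apply(m[, keep, drop = FALSE], 1, paste,
                            collapse = "")))
}

.golden_min <- function(f, lo, hi, tol = 1e-7) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

#' Maximum-likelihood JTT distance between two gapless protein sequences
#'
#' Maximizes the site-wise likelihood `prod_i pi[a_i] P(a_i -> b_i; t)`
#' under the JTT model by golden-section search on \[0, 10\] substitutions
#' per site. Symmetric in its arguments (JTT is reversible) and 0 exactly
#' for identical sequences.
#'
#' @param a,b Equal-length gapless protein strings.
#' @return Estimated distance in substitutions per site.
#' @export
jtt_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("sequences must have equal length")
  if (nchar(a) < 1) abort("empty sequence")
  ai <- match(strsplit(a, "")[[1]], AA20)
  bi <- match(strsplit(b, "")[[1]], AA20)
  if (anyNA(ai) || anyNA(bi)) abort("non-standard residue in sequence")
  if (identical(ai, bi)) return(0)
  N <- matrix(tabulate((ai - 1) * 20 + bi, nbins = 400), 20, 20, byrow = TRUE)
  pi <- jtt_frequencies()
  nll <- function(t) {
    P <- jtt_prob(t)
    lp <- log(pmax(pi * P, 1e-300))
    -sum(N * lp)
  }
  .golden_min(nll, 0, 10)
}

#' Pairwise JTT distance matrix of an alignment
#'
#' @param aln A gapless alignment tibble.
#' @return A symmetric labelled distance matrix (substitutions/site).
#' @export
jtt_dist_matrix <- function(aln) {
  .check_gapless(aln)
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- jtt_distance(aln$seq[i], aln$seq[j])
    }
  }
  d
}

.fmt_bl <- function(x) sprintf("%.10g", max(x, 0))

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining. Negative intermediate branch lengths
#' are clamped to 0 with the deficit transferred to the sister edge (so the
#' joined pair's path length is preserved); join ties break by the smallest
#' (row, column) index pair.
#'
#' @param d Square symmetric distance matrix with a zero diagonal, labelled
#'   rows/columns, >= 3 taxa.
#' @return An unrooted tree of class `c("gf_tree", "phylo")`.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-9) abort("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix diagonal must be zero")
  n <- nrow(d)
  if (n < 3) abort("need >= 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  frag <- labels

  while (n > 3) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    idx <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0; if (li < 0) li <- 0 }
    newfrag <- paste0("(", frag[i], ":", .fmt_bl(li), ",",
                      frag[j], ":", .fmt_bl(lj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(d2) <- colnames(d2) <- paste0("n", seq_len(n - 1))
    d <- d2
    n <- n - 1
  }

  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", .fmt_bl(la), ",",
                frag[2], ":", .fmt_bl(lb), ",",
                frag[3], ":", .fmt_bl(lc), ");")
  tr <- ape::read.tree(text = nwk)
  class(tr) <- c("gf_tree", "phylo")
  tr
}

# Precompute the pruning scaffold (postorder edges, tip indicator
# matrices) for a tree/alignment pair and return a fast evaluator of the
# log-likelihood as a function of the edge-length vector (in the reordered
# tree's edge order).
.loglik_machine <- function(tree, aln) {
  m <- .aln_chars(aln)
  S <- ncol(m)
  codes <- matrix(match(m, AA20), nrow = nrow(m))
  if (anyNA(codes)) abort("non-standard residue in alignment")
  rownames(codes) <- rownames(m)

  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  tips <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    x <- codes[match(tr$tip.label[i], rownames(codes)), ]
    mat <- matrix(0, 20, S)
    mat[cbind(x, seq_len(S))] <- 1
    tips[[i]] <- mat
  }
  edge <- tr$edge
  root <- edge[nrow(edge), 1]
  pi <- jtt_frequencies()
  nnode <- ntip + tr$Nnode

  eval_ll <- function(el) {
    L <- vector("list", nnode)
    L[seq_len(ntip)] <- tips
    scale_log <- 0
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1]
      contrib <- jtt_prob(el[e]) %*% L[[edge[e, 2]]]
      if (is.null(L[[par]])) {
        L[[par]] <- contrib
      } else {
        L[[par]] <- L[[par]] * contrib
        cs <- colSums(L[[par]])
        if (any(cs < 1e-150)) {
          cs[cs == 0] <- 1
          L[[par]] <- sweep(L[[par]], 2, cs, "/")
          scale_log <- scale_log + sum(log(cs))
        }
      }
    }
    sum(log(colSums(pi * L[[root]]))) + scale_log
  }
  list(tree = tr, eval = eval_ll)
}

#' Log-likelihood of a tree given a gapless alignment
#'
#' Felsenstein pruning under the JTT model with equilibrium frequencies at
#' an arbitrary (unrooted) reference node; sites are independent and there
#' is no rate heterogeneity. Invariant to re-rooting along any edge
#' (reversibility / pulley principle).
#'
#' @param tree A `phylo` tree whose tip labels match the alignment ids.
#' @param aln A gapless alignment tibble.
#' @return The log-likelihood (numeric scalar).
#' @export
tree_loglik <- function(tree, aln) {
  .check_gapless(aln)
  if (!setequal(tree$tip.label, aln$id)) {
    abort("tree tip labels do not match alignment ids")
  }
  mach <- .loglik_machine(tree, aln)
  mach$eval(mach$tree$edge.length)
}

# coordinate-wise branch-length optimization (Brent via optimize, tol 1e-6);
# operates on (and returns) the postorder-reordered tree
.optimize_bl <- function(tree, aln, max_sweeps = 3, tol = 1e-6) {
  mach <- .loglik_machine(tree, aln)
  tree <- mach$tree
  el <- tree$edge.length
  ll <- mach$eval(el)
  for (sweep in seq_len(max_sweeps)) {
    prev <- ll
    for (e in seq_along(el)) {
      f <- function(x) {
        el2 <- el
        el2[e] <- x
        mach$eval(el2)
      }
      opt <- optimize(f, interval = c(0, 10), maximum = TRUE, tol = tol)
      if (opt$objective > ll) {
        el[e] <- opt$maximum
        ll <- opt$objective
      }
    }
    if (ll - prev < tol) break
  }
  tree$edge.length <- el
  attr(tree, "loglik") <- ll
  tree
}

#' Maximum-likelihood tree search by NNI hill climbing
#'
#' Starting from a neighbor-joining tree (or a supplied start tree),
#' optimizes every branch length (Brent's method, tolerance `1e-6`), then
#' repeatedly evaluates all nearest-neighbor-interchange rearrangements,
#' accepting the best one while it improves the log-likelihood by more than
#' `1e-6`. The returned log-likelihood is never below the start tree's.
#'
#' @param aln A gapless alignment tibble.
#' @param start Optional start tree; default is NJ on [jtt_dist_matrix()].
#' @param max_rounds Safety cap on NNI acceptance rounds.
#' @return A `c("gf_tree", "phylo")` tree with attribute `loglik`.
#' @export
ml_search <- function(aln, start = NULL, max_rounds = 50) {
  .check_gapless(aln)
  tree <- start %||% neighbor_joining(jtt_dist_matrix(aln))
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  tree <- .optimize_bl(tree, aln)
  ll <- attr(tree, "loglik")
  for (round in seq_len(max_rounds)) {
    cands <- tryCatch(phangorn::nni(tree), error = function(e) NULL)
    if (is.null(cands) || length(cands) == 0) break
    # multiPhylo objects share tip labels in an attribute; expand them
    cands <- lapply(ape::.uncompressTipLabel(cands), identity)
    best <- NULL
    best_ll <- ll
    for (cand in cands) {
      if (is.null(cand$edge.length)) {
        cand$edge.length <- rep(0.1, nrow(cand$edge))
      }
      cand$edge.length[is.na(cand$edge.length) |
                         cand$edge.length < 1e-8] <- 0.1
      cand <- .optimize_bl(cand, aln)
      if (attr(cand, "loglik") > best_ll + 1e-6) {
        best <- cand
        best_ll <- attr(cand, "loglik")
      }
    }
    if (is.null(best)) break
    tree <- best
    ll <- best_ll
  }
  class(tree) <- c("gf_tree", "phylo")
  attr(tree, "loglik") <- ll
  tree
}

#' Bootstrap supports for an alignment's tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds a
#' tree per replicate (neighbor joining on JTT distances by default, or full
#' ML with `method = "ml"`), and annotates each internal edge of the
#' point-estimate tree with the percentage of replicates containing that
#' bipartition (stored as integer internal node labels). Deterministic for a
#' fixed seed.
#'
#' @param aln A gapless alignment tibble.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param method `"nj"` (default) or `"ml"` per replicate.
#' @return The point-estimate tree with `node.label` supports in \[0, 100\]
#'   and attribute `bootstrap_trees` (a `multiPhylo` of replicates).
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1,
                              method = c("nj", "ml")) {
  method <- match.arg(method)
  if (n_reps < 1) abort("n_reps must be >= 1")
  .check_gapless(aln)
  build <- function(a) {
    if (method == "nj") neighbor_joining(jtt_dist_matrix(a)) else ml_search(a)
  }
  point <- build(aln)
  m <- .aln_chars(aln)
  S <- ncol(m)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(S, S, replace = TRUE)
      build(tibble(id = aln$id,
                   seq = apply(m[, cols, drop = FALSE], 1, paste,
                               collapse = "")))
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  pct <- round(100 * counts / n_reps)
  point$node.label <- as.character(pct)
  attr(point, "bootstrap_trees") <- reps
  point
}

#' Majority-rule consensus of bootstrap replicate trees
#'
#' @param tree A tree from [bootstrap_support()].
#' @param p Minimum split frequency (default 0.5 = majority rule).
#' @return A consensus `phylo` tree.
#' @export
bootstrap_consensus <- function(tree, p = 0.5) {
  reps <- attr(tree, "bootstrap_trees")
  if (is.null(reps)) abort("tree carries no bootstrap replicates")
  ape::consensus(reps, p = p)
}

#' @export
tidy.gf_tree <- function(x, ...) {
  ntip <- length(x$tip.label)
  child <- x$edge[, 2]
  tibble(
    parent = x$edge[, 1],
    node = child,
    label = ifelse(child <= ntip, x$tip.label[child],
                   if (!is.null(x$node.label)) {
                     x$node.label[child - ntip]
                   } else NA_character_),
    branch_length = x$edge.length,
    is_tip = child <= ntip
  )
}

#' @export
glance.gf_tree <- function(x, ...) {
  tibble(n_tips = length(x$tip.label),
         n_internal = x$Nnode,
         total_length = sum(x$edge.length),
         loglik = attr(x, "loglik") %||% NA_real_)
}

#' Write a tree to Newick
#'
#' Branch lengths are substitutions/site; bootstrap supports (if present)
#' are serialized as internal node labels.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return A `c("gf_tree", "phylo")` tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  class(tr) <- c("gf_tree", "phylo")
  tr
}

#' @export
autoplot.gf_tree <- function(object, ...) {
  tr <- object
  ntip <- length(tr$tip.label)
  xpos <- ape::node.depth.edgelength(tr)
  ypos <- ape::node.height(tr)
  df <- tibble(
    x = xpos[tr$edge[, 1]], xend = xpos[tr$edge[, 2]],
    y = ypos[tr$edge[, 2]], yend = ypos[tr$edge[, 2]],
    y0 = ypos[tr$edge[, 1]]
  )
  tips <- tibble(x = xpos[seq_len(ntip)], y = ypos[seq_len(ntip)],
                 label = tr$tip.label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = df,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_segment(data = df,
                          ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = .data$y0, yend = .data$y)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = -0.05, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.2))) +
    ggplot2::labs(x = "substitutions/site", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}
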