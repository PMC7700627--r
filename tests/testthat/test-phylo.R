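test_that("complete deletion removes exactly the gapped/missing columns", {
  aln <- tibble::tibble(id = c("a", "b"), seq = c("A-C", "AGC"))
  expect_equal(complete_deletion(aln)$seq, c("AC", "AC"))
  clean <- tibble::tibble(id = c("a", "b"), seq = c("ACD", "ACE"))
  expect_equal(complete_deletion(clean), clean)
  degenerate <- tibble::tibble(id = c("a", "b"), seq = c("-A", "A-"))
  expect_error(complete_deletion(degenerate), "every column")
  missing <- tibble::tibble(id = c("a", "b"), seq = c("XAC", "AAC"))
  expect_equal(complete_deletion(missing)$seq, c("AC", "AC"))
})

test_that("JTT ML distance: zero iff identical, symmetric, matches grid scan", {
  expect_identical(jtt_distance("ACDE", "ACDE"), 0)
  withr::with_seed(51, {
    pair <- evolve_on_tree(ape::read.tree(text = "(A:0.3,B:0.3);"),
                           rand_prot(50), seed = 1)
    a <- pair$seq[1]
    b <- pair$seq[2]
    expect_equal(jtt_distance(a, b), jtt_distance(b, a), tolerance = 1e-6)
    expect_gt(jtt_distance(a, b), 0)
    # independent dense-grid scan of the same likelihood over [0, 10]
    ai <- match(strsplit(a, "")[[1]], AA)
    bi <- match(strsplit(b, "")[[1]], AA)
    pi <- jtt_frequencies()
    tgrid <- seq(1e-4, 10, by = 1e-4)
    nll <- vapply(tgrid, function(t) {
      P <- jtt_prob(t)
      -sum(log(pi[ai] * P[cbind(ai, bi)]))
    }, numeric(1))
    expect_lt(abs(jtt_distance(a, b) - tgrid[which.min(nll)]), 1e-3)
  })
  expect_error(jtt_distance("ACD", "AC"), "equal length")
})

test_that("distance grows stochastically with simulated divergence", {
  root <- rand_prot(200, seed = 77)
  dists <- vapply(c(0.05, 0.2, 0.5, 1.0), function(t) {
    tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t / 2, t / 2))
    aln <- evolve_on_tree(tr, root, seed = 5)
    jtt_distance(aln$seq[1], aln$seq[2])
  }, numeric(1))
  expect_true(all(diff(dists) > 0))
})

test_that("neighbor joining solves the three-point case and additive trees", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  # additive 4-taxon matrices: NJ recovers the generating topology and
  # path lengths; agrees with the reference NJ implementation in ape
  withr::with_seed(53, {
    for (case in 1:10) {
      bl <- runif(5, 0.1, 1)   # A,B,C,D pendant + internal
      d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
      d4["A", "B"] <- d4["B", "A"] <- bl[1] + bl[2]
      d4["C", "D"] <- d4["D", "C"] <- bl[3] + bl[4]
      for (x in c("A", "B")) for (y in c("C", "D")) {
        d4[x, y] <- d4[y, x] <- bl[match(x, LETTERS)] + bl[5] +
          bl[match(y, LETTERS)]
      }
      tr4 <- neighbor_joining(d4)
      truth <- ape::read.tree(text = "((A,B),C,D);")
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr4), truth)), 0)
      # path lengths reproduce the additive input
      pd <- ape::cophenetic.phylo(tr4)[rownames(d4), colnames(d4)]
      expect_equal(pd, d4, tolerance = 1e-9)
      ref <- ape::nj(d4)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr4), ape::unroot(ref))), 0)
    }
  })

  dbad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(neighbor_joining(dbad), "3 taxa|symmetric|square")
})

test_that("pruning log-likelihood equals brute-force state summation", {
  withr::with_seed(57, {
    # 2 taxa, 1 site: direct summation over the single internal state
    t2 <- ape::read.tree(text = "(A:0.3,B:0.5);")
    aln2 <- tibble::tibble(id = c("A", "B"), seq = c("M", "K"))
    pi <- jtt_frequencies()
    direct <- log(sum(pi * jtt_prob(0.3)[, "M"] * jtt_prob(0.5)[, "K"]))
    expect_equal(tree_loglik(t2, aln2), direct, tolerance = 1e-10)
    expect_equal(brute_loglik(t2, aln2), direct, tolerance = 1e-10)

    # all leaf counts 2..4, site counts 1..3, random lengths and sequences
    for (ntaxa in 2:4) {
      for (nsites in 1:3) {
        nwk <- switch(as.character(ntaxa),
                      "2" = "(A:%f,B:%f);",
                      "3" = "(A:%f,B:%f,C:%f);",
                      "4" = "((A:%f,B:%f):%f,C:%f,D:%f);")
        bl <- runif(ntaxa + (ntaxa == 4), 0.05, 0.8)
        tr <- ape::read.tree(text = do.call(sprintf, c(list(nwk), as.list(bl))))
        aln <- tibble::tibble(
          id = LETTERS[seq_len(ntaxa)],
          seq = vapply(seq_len(ntaxa), function(i) rand_prot(nsites),
                       character(1))
        )
        expect_equal(tree_loglik(tr, aln), brute_loglik(tr, aln),
                     tolerance = 1e-8)
      }
    }
  })
})

test_that("pruning likelihood is invariant to re-rooting and has the t=0 limit", {
  withr::with_seed(59, {
    tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,C:0.25,D:0.4);")
    aln <- tibble::tibble(id = LETTERS[1:4],
                          seq = vapply(1:4, function(i) rand_prot(30),
                                       character(1)))
    ll <- tree_loglik(tr, aln)
    for (node in c(1, 2, 4)) {
      rerooted <- ape::root(tr, outgroup = tr$tip.label[node],
                            resolve.root = TRUE)
      expect_equal(tree_loglik(rerooted, aln), ll, tolerance = 1e-8)
    }
    # identical sequences on a zero-length star: loglik = sum log pi
    s <- rand_prot(25)
    star <- ape::read.tree(text = "(A:0,B:0,C:0);")
    aln0 <- tibble::tibble(id = c("A", "B", "C"), seq = rep(s, 3))
    pi <- jtt_frequencies()
    expect_equal(tree_loglik(star, aln0),
                 sum(log(pi[strsplit(s, "")[[1]]])), tolerance = 1e-8)
  })
})

test_that("pruning log-likelihood matches the independent phangorn evaluator", {
  withr::with_seed(61, {
    tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,(C:0.25,D:0.4):0.1);")
    aln <- evolve_on_tree(tr, rand_prot(60), seed = 3)
    mat <- do.call(rbind, strsplit(aln$seq, ""))
    rownames(mat) <- aln$id
    dat <- phangorn::phyDat(mat, type = "AA")
    fit <- phangorn::pml(tr, dat, model = "JTT")
    expect_equal(tree_loglik(tr, aln), as.numeric(stats::logLik(fit)),
                 tolerance = 1e-4)
  })
})

test_that("NNI search improves the start tree and finds the best topology", {
  tr <- ape::read.tree(text = "((A:0.15,B:0.18):0.4,C:0.12,D:0.15);")
  aln <- evolve_on_tree(tr, rand_prot(200, seed = 63), seed = 8)
  start <- neighbor_joining(jtt_dist_matrix(aln))
  ml <- ml_search(aln, start = start)
  expect_gte(attr(ml, "loglik"), tree_loglik(start, aln))
  # exhaustive check over all 3 unrooted 4-taxon topologies
  topos <- c("((A,B),C,D);", "((A,C),B,D);", "((A,D),B,C);")
  lls <- vapply(topos, function(t) {
    cand <- ape::read.tree(text = t)
    cand$edge.length <- rep(0.2, nrow(cand$edge))
    attr(genefamr:::.optimize_bl(cand, aln), "loglik")
  }, numeric(1))
  best_topo <- ape::read.tree(text = topos[which.max(lls)])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ml), ape::unroot(best_topo))), 0)
})

test_that("bootstrap supports are deterministic percentages in [0, 100]", {
  tr <- ape::read.tree(text = "((A:0.15,B:0.18):0.4,C:0.12,D:0.15);")
  aln <- evolve_on_tree(tr, rand_prot(150, seed = 67), seed = 12)
  b1 <- bootstrap_support(aln, n_reps = 50, seed = 4)
  b2 <- bootstrap_support(aln, n_reps = 50, seed = 4)
  expect_equal(b1$node.label, b2$node.label)
  expect_equal(ape::write.tree(b1), ape::write.tree(b2))
  sup <- as.numeric(b1$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  # strongly congruent signal: the true split is near-unanimous
  expect_gte(min(sup), 95)
  # newick round trip keeps supports
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(b1, path)
  back <- read_newick(path)
  expect_equal(back$node.label, b1$node.label)
})
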