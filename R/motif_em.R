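# Conserved-motif discovery: ZOOPS (zero-or-one occurrence per sequence)
# expectation-maximization over a position-weight matrix, with sequential
# site masking for multi-motif discovery.

.encode_seqs <- function(x) {
  lapply(seq_len(nrow(x)), function(i) {
    v <- match(strsplit(x$seq[i], "")[[1]], AA20)
    if (anyNA(v)) {
      abort(paste0("sequence '", x$id[i], "' contains non-standard residues"))
    }
    v
  })
}

.background_freqs <- function(xlist, pseudocount = 0.01) {
  counts <- tabulate(unlist(xlist)[unlist(xlist) > 0], nbins = 20) + pseudocount
  setNames(counts / sum(counts), AA20)
}

# one EM run from an initial PWM; xlist uses 0 for masked positions
.em_run <- function(xlist, width, bg, theta0, gamma0 = 0.5,
                    max_iter = 200, tol = 1e-4, pseudocount = 0.01) {
  n <- length(xlist)
  lbg <- log(bg)

  # valid window start positions per sequence (no masked residue inside)
  valid <- lapply(xlist, function(v) {
    m <- length(v) - width + 1
    if (m < 1) return(integer())
    ok <- vapply(seq_len(m), function(j) all(v[j:(j + width - 1)] > 0),
                 logical(1))
    which(ok)
  })

  theta <- theta0
  gamma <- gamma0

  # constant background log-probability of all unmasked residues
  const <- sum(vapply(xlist, function(v) sum(lbg[v[v > 0]]), numeric(1)))

  trace <- numeric()
  prev <- -Inf
  ll <- -Inf
  for (iter in seq_len(max_iter)) {
    lt <- log(theta) - lbg   # 20 x width log-likelihood-ratio matrix
    counts <- matrix(pseudocount, nrow = 20, ncol = width)
    q_sum <- 0
    ll <- const
    zs <- vector("list", n)
    for (i in seq_len(n)) {
      v <- xlist[[i]]
      js <- valid[[i]]
      m <- length(js)
      if (m == 0) {
        ll <- ll + log(1 - gamma)
        zs[[i]] <- numeric()
        next
      }
      lsc <- vapply(js, function(j) {
        sum(lt[cbind(v[j:(j + width - 1)], seq_len(width))])
      }, numeric(1))
      lpj <- log(gamma / m) + lsc
      l0 <- log(1 - gamma)
      mx <- max(c(l0, lpj))
      denom <- exp(l0 - mx) + sum(exp(lpj - mx))
      ll <- ll + mx + log(denom)
      z <- exp(lpj - mx) / denom
      zs[[i]] <- z
      q_sum <- q_sum + sum(z)
      for (idx in seq_along(js)) {
        if (z[idx] < 1e-12) next
        w <- v[js[idx]:(js[idx] + width - 1)]
        counts[cbind(w, seq_len(width))] <-
          counts[cbind(w, seq_len(width))] + z[idx]
      }
    }
    # the M-step with pseudocounts maximizes a MAP objective (Dirichlet
    # prior on the PWM); that penalized objective is the one EM guarantees
    # to be non-decreasing, so it drives the trace and the stop rule
    obj <- ll + pseudocount * sum(log(theta))
    trace <- c(trace, obj)
    if (obj < prev - 1e-6) {
      abort("internal error: EM objective decreased")
    }
    if (iter > 1 && obj - prev < tol) {
      prev <- obj
      break
    }
    prev <- obj
    theta <- sweep(counts, 2, colSums(counts), "/")
    gamma <- min(max(q_sum / n, 1e-4), 1 - 1e-4)
  }

  # site calls: a sequence holds a site if its posterior mass exceeds 1/2
  sites <- tibble(seq_index = integer(), start = integer())
  for (i in seq_len(n)) {
    z <- zs[[i]]
    if (length(z) && sum(z) > 0.5) {
      sites <- bind_rows(sites, tibble(seq_index = i,
                                       start = valid[[i]][which.max(z)]))
    }
  }
  list(theta = theta, gamma = gamma, loglik = ll, objective = prev,
       trace = trace,
       sites = sites,
       q_total = sum(vapply(zs, function(z) sum(z), numeric(1))))
}

.motif_ic <- function(theta, bg, n_eff) {
  ic_col <- colSums(theta * (log2(theta) - log2(bg)))
  bias <- 19 / (2 * log(2) * max(n_eff, 1))
  list(ic = sum(ic_col), ic_col = ic_col,
       ic_adj = sum(pmax(0, ic_col - bias)))
}

.build_motif <- function(run, x, width, bg, index = 1L, ic_floor = 8) {
  ics <- .motif_ic(run$theta, bg, run$q_total)
  consensus <- paste(AA20[apply(run$theta, 2, which.max)], collapse = "")
  out <- list(
    index = index, width = width, pwm = run$theta, consensus = consensus,
    sites = tibble(id = x$id[run$sites$seq_index], start = run$sites$start),
    n_sites = nrow(run$sites), gamma = run$gamma,
    loglik = run$loglik, objective_trace = run$trace,
    ic = ics$ic, ic_per_column = ics$ic_col, ic_adj = ics$ic_adj,
    low_confidence = ics$ic_adj < ic_floor, background = bg
  )
  class(out) <- "motif"
  out
}

#' Discover one ungapped motif by ZOOPS expectation-maximization
#'
#' Fits a position-weight matrix of the given width under the ZOOPS model
#' (each sequence carries zero or one site) with a 0-order background
#' estimated from all input residues. EM is restarted from `n_starts`
#' randomly chosen length-`width` subsequences and the start with the
#' highest final log-likelihood is returned. Iteration stops when the
#' log-likelihood gain falls below `tol` (default `1e-4`) or after
#' `max_iter` (default 200) iterations. With the Dirichlet pseudocount
#' prior, the EM monotonicity guarantee applies to the penalized (MAP)
#' objective; it is asserted non-decreasing on every run and returned as
#' `objective_trace`.
#'
#' @param x A protein sequence tibble; every sequence must be at least
#'   `width` residues long.
#' @param width Motif width in residues (>= 2).
#' @param n_starts Number of random restarts (>= 1).
#' @param seed Integer seed; results are reproducible given
#'   `(x, width, seed)`.
#' @param max_iter,tol EM stopping controls.
#' @param pseudocount Added per residue when forming the PWM from expected
#'   counts.
#' @return A `motif` object: `pwm` (20 x width, columns sum to 1),
#'   `consensus`, `sites` (tibble of `id`, 1-based `start`), `n_sites`,
#'   `gamma`, `loglik`, `objective_trace`, information content (`ic`, raw, and
#'   `ic_adj`, small-sample corrected) and a `low_confidence` flag.
#' @export
em_zoops <- function(x, width, n_starts = 10, seed = 1, max_iter = 200,
                     tol = 1e-4, pseudocount = 0.01) {
  if (nrow(x) == 0) abort("empty input")
  if (width < 2) abort("width must be >= 2")
  if (n_starts < 1) abort("n_starts must be >= 1")
  short <- which(nchar(x$seq) < width)
  if (length(short)) {
    abort(paste0("sequence '", x$id[short[1]], "' is shorter than width ",
                 width))
  }
  xlist <- .encode_seqs(x)
  bg <- .background_freqs(xlist, pseudocount)
  withr::with_seed(seed, {
    run <- .em_best(xlist, width, bg, n_starts, max_iter, tol, pseudocount)
  })
  .build_motif(run, x, width, bg)
}

.theta_from_window <- function(win, width) {
  theta <- matrix(0.5 / 19, nrow = 20, ncol = width,
                  dimnames = list(AA20, NULL))
  for (k in seq_len(width)) theta[win[k], k] <- 0.5
  theta
}

.theta_from_sites <- function(xlist, sites, width, pseudocount = 0.01) {
  counts <- matrix(pseudocount * 10, nrow = 20, ncol = width,
                   dimnames = list(AA20, NULL))
  for (r in seq_len(nrow(sites))) {
    w <- xlist[[sites$seq_index[r]]][sites$start[r]:(sites$start[r] + width - 1)]
    counts[cbind(w, seq_len(width))] <- counts[cbind(w, seq_len(width))] + 1
  }
  sweep(counts, 2, colSums(counts), "/")
}

# MEME-style column-shift refinement: re-seed EM from the called sites
# shifted left/right and keep the best penalized objective, escaping
# phase-shifted local optima
.shift_refine <- function(run, xlist, width, bg, max_iter, tol, pseudocount) {
  repeat {
    improved <- FALSE
    for (s in setdiff(-(width - 1):(width - 1), 0)) {
      sites <- run$sites
      if (nrow(sites) < 2) break
      sh <- sites
      sh$start <- sh$start + s
      ok <- vapply(seq_len(nrow(sh)), function(r) {
        v <- xlist[[sh$seq_index[r]]]
        st <- sh$start[r]
        st >= 1 && st + width - 1 <= length(v) &&
          all(v[st:(st + width - 1)] > 0)
      }, logical(1))
      if (sum(ok) < max(2, nrow(sh) / 2)) next
      theta0 <- .theta_from_sites(xlist, sh[ok, ], width, pseudocount)
      cand <- .em_run(xlist, width, bg, theta0, gamma0 = run$gamma,
                      max_iter = max_iter, tol = tol,
                      pseudocount = pseudocount)
      if (cand$objective > run$objective + 1e-6) {
        run <- cand
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  run
}

.em_best <- function(xlist, width, bg, n_starts, max_iter, tol, pseudocount) {
  best <- NULL
  ok <- which(vapply(xlist, function(v) length(v) >= width, logical(1)))
  for (s in seq_len(n_starts)) {
    # draw a start window containing no masked residue
    for (try in 1:50) {
      i <- ok[sample.int(length(ok), 1)]
      j <- sample.int(length(xlist[[i]]) - width + 1, 1)
      win <- xlist[[i]][j:(j + width - 1)]
      if (all(win > 0)) break
      win <- NULL
    }
    if (is.null(win)) next
    run <- .em_run(xlist, width, bg, .theta_from_window(win, width),
                   max_iter = max_iter, tol = tol,
                   pseudocount = pseudocount)
    if (is.null(best) || run$objective > best$objective) best <- run
  }
  if (is.null(best)) abort("no unmasked start window available")
  .shift_refine(best, xlist, width, bg, max_iter, tol, pseudocount)
}

#' Discover up to `max_motifs` motifs with sequential masking
#'
#' Repeats [em_zoops()] over the candidate widths, keeps the motif with the
#' highest information content per column, masks its sites (masked residues
#' are excluded from window scoring and background counts), and iterates.
#' Discovery stops at `max_motifs` (default 10) or when the best remaining
#' motif's total bias-corrected information content falls below `ic_floor`
#' bits, which prevents reporting noise once the real motifs are exhausted.
#'
#' @param x A protein sequence tibble.
#' @param max_motifs Maximum number of motifs to report (default 10).
#' @param widths Candidate motif widths; widths longer than the shortest
#'   sequence are skipped.
#' @param seed Integer seed (mandatory determinism).
#' @param ic_floor Stopping floor in bits of total corrected information
#'   content per motif (default 8); `NULL` disables the floor.
#' @param n_starts,max_iter,tol,pseudocount Passed to the EM.
#' @return A `motif_set`: list of `motif` objects numbered in discovery
#'   order. Site lists of distinct motifs never overlap.
#' @export
discover_motifs <- function(x, max_motifs = 10, widths = c(28, 41, 50),
                            seed = 1, ic_floor = 8, n_starts = 10,
                            max_iter = 200, tol = 1e-4, pseudocount = 0.01) {
  if (nrow(x) == 0) abort("empty input")
  if (max_motifs < 1) abort("max_motifs must be >= 1")
  widths <- widths[widths <= min(nchar(x$seq))]
  if (length(widths) == 0) abort("all candidate widths exceed the shortest sequence")
  xlist <- .encode_seqs(x)
  motifs <- list()
  withr::with_seed(seed, {
    for (round in seq_len(max_motifs)) {
      bg <- .background_freqs(xlist, pseudocount)
      cand <- NULL
      cand_w <- NULL
      for (w in widths) {
        enough <- any(vapply(xlist, function(v) {
          m <- length(v) - w + 1
          m >= 1 && any(vapply(seq_len(m), function(j) all(v[j:(j + w - 1)] > 0),
                               logical(1)))
        }, logical(1)))
        if (!enough) next
        run <- .em_best(xlist, w, bg, n_starts, max_iter, tol, pseudocount)
        icpc <- .motif_ic(run$theta, bg, run$q_total)$ic_adj / w
        if (is.null(cand) || icpc > cand$icpc) {
          cand <- list(run = run, icpc = icpc)
          cand_w <- w
        }
      }
      if (is.null(cand)) break
      motif <- .build_motif(cand$run, x, cand_w, bg,
                            index = length(motifs) + 1L,
                            ic_floor = ic_floor %||% -Inf)
      if (!is.null(ic_floor) && motif$ic_adj < ic_floor) break
      # mask the called sites so later motifs cannot reuse them
      for (r in seq_len(nrow(motif$sites))) {
        i <- match(motif$sites$id[r], x$id)
        j <- motif$sites$start[r]
        xlist[[i]][j:(j + cand_w - 1)] <- 0L
      }
      motifs[[length(motifs) + 1]] <- motif
    }
  })
  structure(motifs, class = "motif_set")
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif ", x$index, "> width ", x$width, ", ", x$n_sites,
      " site(s), IC ", round(x$ic, 1), " bits (", round(x$ic_adj, 1),
      " corrected)\n  consensus: ", x$consensus, "\n", sep = "")
  invisible(x)
}

#' @export
print.motif_set <- function(x, ...) {
  cat("<motif_set> ", length(x), " motif(s)\n", sep = "")
  for (m in x) print(m)
  invisible(x)
}

#' @export
tidy.motif_set <- function(x, ...) {
  bind_rows(lapply(x, function(m) {
    tibble(motif = m$index, consensus = m$consensus, width = m$width,
           n_sites = m$n_sites, ic = m$ic, ic_adj = m$ic_adj,
           low_confidence = m$low_confidence)
  }))
}

#' @export
glance.motif_set <- function(x, ...) {
  tibble(n_motifs = length(x),
         total_ic = sum(vapply(x, function(m) m$ic, numeric(1))),
         mean_width = mean(vapply(x, function(m) m$width, numeric(1))))
}

#' Site table of a motif set
#'
#' @param x A `motif_set`.
#' @return Tibble with `motif`, `id`, `start` (1-based).
#' @export
motif_sites <- function(x) {
  bind_rows(lapply(x, function(m) {
    if (nrow(m$sites) == 0) return(tibble())
    mutate(m$sites, motif = m$index, .before = 1)
  }))
}

#' @export
autoplot.motif_set <- function(object, ...) {
  df <- bind_rows(lapply(object, function(m) {
    tibble(motif = paste0("motif ", m$index, " (w=", m$width, ")"),
           column = seq_len(m$width), ic = m$ic_per_column)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$ic)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~motif, scales = "free_x") +
    ggplot2::labs(x = "motif column", y = "information content (bits)") +
    ggplot2::theme_minimal()
}
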