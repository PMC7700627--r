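# Family-membership search: exact Smith-Waterman local alignment with
# affine gaps, Karlin-Altschul E-values, and an inclusive E-value gate with
# redundancy removal.
#
# Defaults follow protein BLAST: BLOSUM62, gap open 11 / extend 1, gapped
# Karlin-Altschul constants lambda = 0.267, K = 0.041.

KA_LAMBDA <- 0.267
KA_K <- 0.041

.blosum62 <- function() {
  if (is.null(.gf_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .gf_cache$blosum62 <- e$BLOSUM62
  }
  .gf_cache$blosum62
}

.as_seq_pair <- function(x, what) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort(paste0(what, " must be a single sequence"))
    list(id = x$id, seq = x$seq)
  } else if (is.character(x) && length(x) == 1) {
    list(id = names(x) %||% what, seq = unname(toupper(x)))
  } else {
    abort(paste0(what, " must be a one-row sequence tibble or a string"))
  }
}

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman alignment with affine gap penalties (no heuristic
#' seeding). The score is in substitution-matrix units and never negative:
#' when no residue pair scores positively the optimal local alignment is
#' empty (score 0, `NA` spans).
#'
#' @param query,subject One-row sequence tibbles or single named strings.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @return A one-row tibble: `query_id`, `subject_id`, `score`, `bitscore`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`,
#'   `align_length`, `identity` (fraction of identical alignment columns).
#' @export
smith_waterman <- function(query, subject, matrix = NULL,
                           gap_open = 11, gap_extend = 1) {
  q <- .as_seq_pair(query, "query")
  s <- .as_seq_pair(subject, "subject")
  if (!nzchar(q$seq) || !nzchar(s$seq)) abort("empty sequence")
  if (gap_open < 0 || gap_extend <= 0) abort("gap penalties must be positive")
  mat <- matrix %||% .blosum62()

  pa <- Biostrings::pairwiseAlignment(
    pattern = q$seq, subject = s$seq, type = "local",
    substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(tibble(query_id = q$id, subject_id = s$id, score = 0,
                  bitscore = (0 - log(KA_K)) / log(2),
                  query_start = NA_integer_, query_end = NA_integer_,
                  subject_start = NA_integer_, subject_end = NA_integer_,
                  align_length = 0L, identity = NA_real_))
  }
  alen <- Biostrings::nchar(pa)
  tibble(
    query_id = q$id, subject_id = s$id, score = sc,
    bitscore = (KA_LAMBDA * sc - log(KA_K)) / log(2),
    query_start = Biostrings::start(Biostrings::pattern(pa)),
    query_end = Biostrings::end(Biostrings::pattern(pa)),
    subject_start = Biostrings::start(Biostrings::subject(pa)),
    subject_end = Biostrings::end(Biostrings::subject(pa)),
    align_length = alen,
    identity = Biostrings::nmatch(pa) / alen
  )
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of chance
#' local alignments scoring at least `score` between a query of length `m`
#' and a database of `n` residues.
#'
#' @param score Alignment score(s) in matrix units.
#' @param m Query length (residues).
#' @param n Database size (total residues).
#' @param lambda,K Karlin-Altschul parameters (gapped BLOSUM62 defaults).
#' @return Expected chance hit count(s).
#' @export
evalue <- function(score, m, n, lambda = KA_LAMBDA, K = KA_K) {
  if (any(m < 1) || any(n < 1)) abort("m and n must be >= 1")
  if (lambda <= 0 || K <= 0) abort("lambda and K must be positive")
  K * m * n * exp(-lambda * score)
}

#' Search a proteome for family members
#'
#' Aligns every query against every database sequence with
#' [smith_waterman()], computes E-values against the total (deduplicated)
#' database residue count, and accepts a subject if any query reaches
#' `E <= threshold` — the gate is inclusive, so a hit at exactly the
#' threshold is retained. Exact-duplicate database sequences are collapsed
#' to one record first (the lexicographically smallest id is kept).
#'
#' @param queries,database Protein sequence tibbles.
#' @param threshold E-value acceptance threshold (default `1e-5`).
#' @param ... Passed to [smith_waterman()] (scoring parameters).
#' @return A list of class `family_search`: `hits` (tibble sorted by
#'   ascending E-value, with an `accepted` flag), `accepted` (character
#'   vector of accepted subject ids) and `collapsed` (tibble mapping removed
#'   duplicate ids to the kept id).
#' @export
search_family <- function(queries, database, threshold = 1e-5, ...) {
  if (threshold <= 0) abort("threshold must be > 0")
  res <- list(hits = tibble(), accepted = character(),
              collapsed = tibble(removed_id = character(),
                                 kept_id = character()))
  class(res) <- "family_search"
  if (nrow(database) == 0) return(res)

  # collapse exact duplicates, keeping the lexicographically smallest id
  db <- arrange(database, .data$seq, .data$id)
  dup <- duplicated(db$seq)
  if (any(dup)) {
    kept <- db$id[match(db$seq[dup], db$seq)]
    res$collapsed <- tibble(removed_id = db$id[dup], kept_id = kept)
    db <- db[!dup, , drop = FALSE]
  }
  db <- arrange(db, .data$id)
  n_db <- sum(nchar(db$seq))

  hits <- bind_rows(lapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    bind_rows(lapply(seq_len(nrow(db)), function(j) {
      smith_waterman(q, db[j, ], ...)
    })) |>
      mutate(evalue = evalue(.data$score, m = nchar(q$seq), n = n_db))
  }))
  hits <- arrange(hits, .data$evalue, .data$subject_id)
  hits$accepted <- hits$evalue <= threshold
  res$hits <- hits
  res$accepted <- sort(unique(hits$subject_id[hits$accepted]))
  res
}

#' @export
tidy.family_search <- function(x, ...) x$hits

#' @export
glance.family_search <- function(x, ...) {
  tibble(n_hits = nrow(x$hits), n_accepted = length(x$accepted),
         n_collapsed = nrow(x$collapsed),
         best_evalue = if (nrow(x$hits)) min(x$hits$evalue) else NA_real_)
}

#' @export
print.family_search <- function(x, ...) {
  cat("<family_search> ", length(x$accepted), " accepted subject(s), ",
      nrow(x$hits), " hit(s), ", nrow(x$collapsed),
      " duplicate(s) collapsed\n", sep = "")
  invisible(x)
}
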