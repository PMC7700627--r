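# Codon-aware pairwise CDS comparison: frame-preserving codon alignment via
# global protein alignment, synonymous/non-synonymous substitution calling,
# indel detection with left-aligned reference coordinates, and Ka/Ks count
# summaries.
#
# The "Ka/Ks ratio" reported here is the ratio of non-synonymous to
# synonymous substitution COUNTS (rounded half-away-from-zero to 2
# decimals), not a per-site rate estimator.

.split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

# round half away from zero to `digits` decimals
.round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Codon-aware alignment of two coding sequences
#'
#' Translates both CDS, globally aligns the proteins (Needleman-Wunsch,
#' BLOSUM62, gap open 11 / extend 1) and back-translates gaps to whole
#' `"---"` codons, so the reading frame is preserved by construction: every
#' nucleotide gap run has length divisible by 3.
#'
#' @param ref,alt One-row DNA sequence tibbles (or single named strings);
#'   lengths divisible by 3, no internal stop codons.
#' @param gene_id Gene label; defaults to the reference id.
#' @return A `codon_alignment`: list with `gene_id`, `ref_label`,
#'   `alt_label` and `codons`, a tibble of aligned codon pairs
#'   (`ref_codon`, `alt_codon`, gap codons are `"---"`).
#' @export
codon_align <- function(ref, alt, gene_id = NULL) {
  r <- .as_seq_pair(ref, "ref")
  a <- .as_seq_pair(alt, "alt")
  rp <- .translate1(r$seq, r$id)
  ap <- .translate1(a$seq, a$id)
  pa <- Biostrings::pairwiseAlignment(
    pattern = rp, subject = ap, type = "global",
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1
  )
  rg <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ag <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  rc <- .split_codons(r$seq)
  ac <- .split_codons(a$seq)
  # drop translated-away terminal stop codons from the codon lists
  rc <- rc[seq_len(nchar(rp))]
  ac <- ac[seq_len(nchar(ap))]
  ri <- ai <- 0L
  codons <- tibble(
    ref_codon = vapply(seq_along(rg), function(k) {
      if (rg[k] == "-") "---" else { ri <<- ri + 1L; rc[ri] }
    }, character(1)),
    alt_codon = vapply(seq_along(ag), function(k) {
      if (ag[k] == "-") "---" else { ai <<- ai + 1L; ac[ai] }
    }, character(1))
  )
  structure(list(gene_id = gene_id %||% r$id, ref_label = r$id,
                 alt_label = a$id, codons = codons),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", x$gene_id, ": ", x$ref_label, " vs ",
      x$alt_label, ", ", nrow(x$codons), " aligned codon(s)\n", sep = "")
  invisible(x)
}

#' Classify a single-base codon substitution
#'
#' Mutates one position of the reference codon and compares the encoded
#' amino acids under the standard genetic code. A change to a stop codon is
#' classified non-synonymous. Vectorized over its arguments.
#'
#' @param ref_codon Reference codon(s) (3 nucleotides).
#' @param offset Position within the codon (1..3).
#' @param alt_base Replacement nucleotide (must differ from the reference
#'   base at `offset`).
#' @return `"synonymous"` or `"non-synonymous"` per input.
#' @export
classify_substitution <- function(ref_codon, offset, alt_base) {
  code <- Biostrings::GENETIC_CODE
  n <- max(length(ref_codon), length(offset), length(alt_base))
  ref_codon <- rep_len(toupper(ref_codon), n)
  offset <- rep_len(offset, n)
  alt_base <- rep_len(toupper(alt_base), n)
  vapply(seq_len(n), function(i) {
    cod <- ref_codon[i]
    if (!grepl("^[ACGT]{3}$", cod)) {
      abort(paste0("invalid codon '", cod, "'"))
    }
    if (!alt_base[i] %in% c("A", "C", "G", "T")) {
      abort(paste0("invalid nucleotide '", alt_base[i], "'"))
    }
    if (!offset[i] %in% 1:3) abort("offset must be 1, 2 or 3")
    if (substr(cod, offset[i], offset[i]) == alt_base[i]) {
      abort("alt_base equals the reference base at offset")
    }
    mut <- cod
    substr(mut, offset[i], offset[i]) <- alt_base[i]
    aa_ref <- code[[cod]]
    aa_mut <- code[[mut]]
    if (aa_mut == "*" || aa_ref == "*") {
      "non-synonymous"
    } else if (aa_ref == aa_mut) "synonymous" else "non-synonymous"
  }, character(1))
}

#' Call substitutions from a codon alignment
#'
#' For each aligned non-gap codon pair differing at k positions, emits k
#' records; each differing position is classified independently with the
#' other positions held at the reference state. Positions are 1-based on
#' the ungapped reference CDS.
#'
#' @param ca A `codon_alignment`.
#' @return A tibble: `cds_position`, `codon_index`, `ref_base`, `alt_base`,
#'   `effect`.
#' @export
call_substitutions <- function(ca) {
  out <- list()
  ref_idx <- 0L
  for (k in seq_len(nrow(ca$codons))) {
    rc <- ca$codons$ref_codon[k]
    ac <- ca$codons$alt_codon[k]
    if (rc == "---") next
    ref_idx <- ref_idx + 1L
    if (ac == "---" || rc == ac) next
    rb <- strsplit(rc, "")[[1]]
    ab <- strsplit(ac, "")[[1]]
    for (off in which(rb != ab)) {
      out[[length(out) + 1]] <- tibble(
        cds_position = (ref_idx - 1L) * 3L + off,
        codon_index = ref_idx,
        ref_base = rb[off], alt_base = ab[off],
        effect = classify_substitution(rc, off, ab[off])
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(cds_position = integer(), codon_index = integer(),
                  ref_base = character(), alt_base = character(),
                  effect = character()))
  }
  bind_rows(out)
}

# left-align an indel interval: a deletion of seq[a..b] is equivalent to
# deleting seq[a-1..b-1] whenever seq[a-1] == seq[b]; shift as far left as
# possible (standard variant normalization)
.left_align <- function(bases, a, b) {
  while (a > 1 && bases[a - 1] == bases[b]) {
    a <- a - 1
    b <- b - 1
  }
  c(a, b)
}

#' Call indels from a codon alignment
#'
#' Maximal runs of gap codons are merged into single records. Gap runs in
#' the alt row are deletions (bases present in the reference, absent from
#' alt), reported as 1-based inclusive intervals on the ungapped reference
#' CDS; gap runs in the reference row are insertions, reported on the
#' ungapped alt CDS. Intervals are left-aligned against the sequence that
#' carries the bases, so placement within repeats is canonical;
#' `length_nt = end - start + 1` always.
#'
#' @param ca A `codon_alignment`.
#' @return A tibble: `start`, `end`, `length_nt`, `kind`.
#' @export
call_indels <- function(ca) {
  rgap <- ca$codons$ref_codon == "---"
  agap <- ca$codons$alt_codon == "---"
  ref_index <- cumsum(!rgap)   # reference codon index at each aligned column
  alt_index <- cumsum(!agap)
  ref_bases <- strsplit(paste(ca$codons$ref_codon[!rgap], collapse = ""), "")[[1]]
  alt_bases <- strsplit(paste(ca$codons$alt_codon[!agap], collapse = ""), "")[[1]]

  .runs <- function(gap) {
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cbind(starts[r$values], ends[r$values])
  }

  out <- list()
  del <- .runs(agap & !rgap)
  if (nrow(del)) {
    for (k in seq_len(nrow(del))) {
      a <- (ref_index[del[k, 1]] - 1L) * 3L + 1L
      b <- ref_index[del[k, 2]] * 3L
      ab <- .left_align(ref_bases, a, b)
      out[[length(out) + 1]] <- tibble(start = ab[1], end = ab[2],
                                       length_nt = ab[2] - ab[1] + 1L,
                                       kind = "deletion")
    }
  }
  ins <- .runs(rgap & !agap)
  if (nrow(ins)) {
    for (k in seq_len(nrow(ins))) {
      a <- (alt_index[ins[k, 1]] - 1L) * 3L + 1L
      b <- alt_index[ins[k, 2]] * 3L
      ab <- .left_align(alt_bases, a, b)
      out[[length(out) + 1]] <- tibble(start = ab[1], end = ab[2],
                                       length_nt = ab[2] - ab[1] + 1L,
                                       kind = "insertion")
    }
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(),
                  length_nt = integer(), kind = character()))
  }
  arrange(bind_rows(out), .data$start)
}

#' One Ka/Ks summary row from counts
#'
#' The ratio is `nonsyn / syn` rounded half-away-from-zero to 2 decimals;
#' it is 0.00 when there are no non-synonymous substitutions (and some
#' synonymous ones) and `NA` when the synonymous count is zero.
#'
#' @param gene_id Gene label.
#' @param syn,nonsyn Synonymous and non-synonymous substitution counts.
#' @return A one-row tibble: `gene_id`, `syn_count`, `nonsyn_count`,
#'   `total`, `ratio`.
#' @export
kaks_summary <- function(gene_id, syn, nonsyn) {
  if (syn < 0 || nonsyn < 0) abort("counts must be >= 0")
  ratio <- if (syn == 0) NA_real_ else .round_half_away(nonsyn / syn, 2)
  tibble(gene_id = gene_id, syn_count = as.integer(syn),
         nonsyn_count = as.integer(nonsyn),
         total = as.integer(syn + nonsyn), ratio = ratio)
}

#' Summarize called substitutions for one gene
#'
#' @param subs A substitution tibble from [call_substitutions()].
#' @param gene_id Gene label.
#' @return A one-row tibble as in [kaks_summary()].
#' @export
tally_substitutions <- function(subs, gene_id) {
  kaks_summary(gene_id,
               syn = sum(subs$effect == "synonymous"),
               nonsyn = sum(subs$effect == "non-synonymous"))
}

#' Family total row for Ka/Ks summaries
#'
#' Element-wise sums of the synonymous/non-synonymous/total counts; the
#' ratio is recomputed from the summed counts, never averaged.
#'
#' @param summaries A tibble of per-gene rows (from [kaks_summary()]).
#' @param label Label for the totals row (default `"Total"`).
#' @return A one-row tibble.
#' @export
kaks_total <- function(summaries, label = "Total") {
  if (nrow(summaries) < 1) abort("need >= 1 summary row")
  kaks_summary(label, sum(summaries$syn_count), sum(summaries$nonsyn_count))
}

#' Pairwise Ka/Ks analysis of matched CDS collections
#'
#' Runs [codon_align()], [call_substitutions()] and [call_indels()] for
#' every id present in both collections and assembles the per-gene summary
#' table with a family `Total` row.
#'
#' @param ref,alt DNA sequence tibbles with matching ids (reference species
#'   first; its CDS defines the coordinate system).
#' @param total_label Label for the totals row.
#' @return A list of class `kaks_result`: `summary` (per-gene rows plus
#'   total), `substitutions`, `indels` (with `gene_id` columns).
#' @export
kaks_pipeline <- function(ref, alt, total_label = "Total") {
  ids <- intersect(ref$id, alt$id)
  if (length(ids) == 0) abort("no shared ids between ref and alt")
  subs_all <- list()
  indels_all <- list()
  rows <- list()
  for (g in ids) {
    ca <- codon_align(ref[ref$id == g, ], alt[alt$id == g, ], gene_id = g)
    subs <- call_substitutions(ca)
    ind <- call_indels(ca)
    rows[[g]] <- tally_substitutions(subs, g)
    if (nrow(subs)) subs_all[[g]] <- mutate(subs, gene_id = g, .before = 1)
    if (nrow(ind)) indels_all[[g]] <- mutate(ind, gene_id = g, .before = 1)
  }
  per_gene <- bind_rows(rows)
  out <- list(
    summary = bind_rows(per_gene, kaks_total(per_gene, total_label)),
    substitutions = bind_rows(subs_all),
    indels = bind_rows(indels_all)
  )
  class(out) <- "kaks_result"
  out
}

#' @export
print.kaks_result <- function(x, ...) {
  cat("<kaks_result> ", nrow(x$summary) - 1, " gene(s), ",
      nrow(x$substitutions), " substitution(s), ", nrow(x$indels),
      " indel(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.kaks_result <- function(x, ...) x$summary

#' @export
glance.kaks_result <- function(x, ...) {
  tot <- x$summary[x$summary$gene_id == "Total", ]
  if (nrow(tot) == 0) tot <- kaks_total(x$summary)
  tibble(n_genes = nrow(x$summary) - nrow(tot),
         syn_total = tot$syn_count[1], nonsyn_total = tot$nonsyn_count[1],
         ratio = tot$ratio[1], n_indels = nrow(x$indels))
}

#' @export
autoplot.kaks_result <- function(object, ...) {
  df <- object$summary |>
    filter(.data$gene_id != "Total") |>
    tidyr::pivot_longer(c("syn_count", "nonsyn_count"),
                        names_to = "class", values_to = "count") |>
    mutate(class = ifelse(.data$class == "syn_count", "synonymous",
                          "non-synonymous"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "substitutions", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
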