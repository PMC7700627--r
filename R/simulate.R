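# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes: divergent CDS pairs with known substitution and
# indel truth, paralog families with planted motifs and GFF3 gene models,
# and protein evolution along a phylogeny under JTT.
#
# Every generator is a pure function of (parameters, seed); truth records
# store realized values so planted signal always validates against the
# pipeline's own callers.

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  all64[!all64 %in% c("TAA", "TAG", "TGA")]
}

# single-base mutations of a codon, classified; excludes stop-creating ones
.codon_mutations <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  out <- list()
  bases <- strsplit(codon, "")[[1]]
  for (off in 1:3) {
    for (nb in setdiff(c("A", "C", "G", "T"), bases[off])) {
      mut <- codon
      substr(mut, off, off) <- nb
      if (code[[mut]] == "*") next
      out[[length(out) + 1]] <- list(
        offset = off, alt_base = nb,
        effect = if (code[[mut]] == code[[codon]]) {
          "synonymous"
        } else "non-synonymous"
      )
    }
  }
  out
}

#' Simulate a divergent orthologous CDS pair with known truth
#'
#' Draws a random stop-free ancestral CDS, plants exactly `n_syn`
#' synonymous and `n_nonsyn` non-synonymous single-base substitutions at
#' distinct codons (verified with [classify_substitution()]; changes that
#' would create a stop codon are never planted, so both CDS stay
#' translatable), then applies whole-codon indels — frame preservation is
#' guaranteed by construction. Substitution codons are kept at least two
#' codons away from indel regions so alignment-based recovery is
#' unambiguous.
#'
#' @param n_codons Ancestor length in codons.
#' @param n_syn,n_nonsyn Substitution counts to plant.
#' @param indels Optional tibble with `codon_index`, `codon_count`, `kind`
#'   (`"deletion"` removes codons from the alt copy; `"insertion"` inserts
#'   random sense codons after the given reference codon).
#' @param seed Integer seed (byte-identical outputs for identical seeds).
#' @param id Shared gene id of the pair.
#' @return A list: `ref` and `alt` (one-row DNA sequence tibbles) and
#'   `truth` (`substitutions` and `indels` tibbles in the same format the
#'   callers emit, indel coordinates left-aligned).
#' @export
simulate_divergent_cds_pair <- function(n_codons, n_syn = 0, n_nonsyn = 0,
                                        indels = NULL, seed = 1,
                                        id = "gene1") {
  if (n_syn < 0 || n_nonsyn < 0) abort("counts must be >= 0")
  if (!is.null(indels) && nrow(indels)) {
    if (any(indels$codon_count < 1)) abort("indel codon_count must be >= 1")
    if (!all(indels$kind %in% c("insertion", "deletion"))) {
      abort("indel kind must be 'insertion' or 'deletion'")
    }
  }
  withr::with_seed(seed, {
    ref_codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)

    # codons blocked for substitutions: indel regions +/- 2 codons
    blocked <- integer()
    if (!is.null(indels) && nrow(indels)) {
      for (k in seq_len(nrow(indels))) {
        ci <- indels$codon_index[k]
        cc <- indels$codon_count[k]
        hi <- if (indels$kind[k] == "deletion") ci + cc - 1 else ci
        if (indels$kind[k] == "deletion" && hi > n_codons) {
          abort("deletion extends past the ancestor")
        }
        blocked <- c(blocked, max(1, ci - 2):min(n_codons, hi + 2))
      }
    }
    avail <- setdiff(seq_len(n_codons), blocked)
    if (length(avail) < n_syn + n_nonsyn) {
      abort("unsatisfiable plan: not enough codons for the requested counts")
    }
    picks <- avail[sample.int(length(avail), n_syn + n_nonsyn)]
    effects <- c(rep("synonymous", n_syn), rep("non-synonymous", n_nonsyn))

    alt_codons <- ref_codons
    subs <- list()
    for (k in seq_along(picks)) {
      ci <- picks[k]
      want <- effects[k]
      for (try in 1:100) {
        muts <- keep(.codon_mutations(ref_codons[ci]),
                     function(m) m$effect == want)
        if (length(muts)) break
        # resample this ancestor codon until it offers the wanted change
        ref_codons[ci] <- sample(SENSE_CODONS, 1)
        alt_codons[ci] <- ref_codons[ci]
      }
      if (length(muts) == 0) abort("unsatisfiable plan: no eligible mutation")
      m <- muts[[sample.int(length(muts), 1)]]
      mut <- ref_codons[ci]
      substr(mut, m$offset, m$offset) <- m$alt_base
      alt_codons[ci] <- mut
      subs[[k]] <- tibble(
        cds_position = (ci - 1L) * 3L + m$offset,
        codon_index = ci,
        ref_base = substr(ref_codons[ci], m$offset, m$offset),
        alt_base = m$alt_base, effect = want
      )
    }

    # apply whole-codon indels to the alt copy, highest coordinate first
    truth_indels <- list()
    ref_seq_bases <- strsplit(paste(ref_codons, collapse = ""), "")[[1]]
    if (!is.null(indels) && nrow(indels)) {
      ord <- order(-indels$codon_index)
      alt_work <- alt_codons
      for (k in ord) {
        ci <- indels$codon_index[k]
        cc <- indels$codon_count[k]
        if (indels$kind[k] == "deletion") {
          alt_work <- alt_work[-(ci:(ci + cc - 1))]
        } else {
          ins <- sample(SENSE_CODONS, cc, replace = TRUE)
          alt_work <- append(alt_work, ins, after = ci)
        }
      }
      alt_codons <- alt_work
      # truth coordinates, left-aligned like call_indels()
      alt_seq_bases <- strsplit(paste(alt_codons, collapse = ""), "")[[1]]
      for (k in seq_len(nrow(indels))) {
        ci <- indels$codon_index[k]
        cc <- indels$codon_count[k]
        if (indels$kind[k] == "deletion") {
          ab <- .left_align(ref_seq_bases, (ci - 1L) * 3L + 1L,
                            (ci + cc - 1L) * 3L)
          kind <- "deletion"
        } else {
          # alt coordinate of the inserted block: preceding deletions don't
          # apply here because indel regions never overlap
          n_del_before <- if (is.null(indels)) 0L else {
            sum(indels$codon_count[indels$kind == "deletion" &
                                     indels$codon_index + indels$codon_count - 1 < ci])
          }
          n_ins_before <- sum(indels$codon_count[indels$kind == "insertion" &
                                                   indels$codon_index < ci])
          alt_ci <- ci - n_del_before + n_ins_before
          ab <- .left_align(alt_seq_bases, alt_ci * 3L + 1L,
                            (alt_ci + cc) * 3L)
          kind <- "insertion"
        }
        truth_indels[[k]] <- tibble(start = ab[1], end = ab[2],
                                    length_nt = ab[2] - ab[1] + 1L,
                                    kind = kind)
      }
    }

    truth_subs <- if (length(subs)) {
      arrange(bind_rows(subs), .data$cds_position)
    } else {
      tibble(cds_position = integer(), codon_index = integer(),
             ref_base = character(), alt_base = character(),
             effect = character())
    }
    list(
      ref = seq_tbl(id, paste(ref_codons, collapse = ""), "dna"),
      alt = seq_tbl(id, paste(alt_codons, collapse = ""), "dna"),
      truth = list(
        substitutions = truth_subs,
        indels = if (length(truth_indels)) {
          arrange(bind_rows(truth_indels), .data$start)
        } else {
          tibble(start = integer(), end = integer(),
                 length_nt = integer(), kind = character())
        }
      )
    )
  })
}

#' Simulate a paralogous protein family with planted motifs
#'
#' Generates a root protein from JTT equilibrium frequencies and derives
#' `n_members` copies by independent per-site substitution with probability
#' `1 - identity` (to a different residue, so expected identity to the root
#' equals the target; realized identities are recorded in the truth). Each
#' motif consensus is then written verbatim at a uniform random offset with
#' its occurrence probability, without overlapping other motifs. Gene
#' models with exon counts uniform in `exon_count_range` are built for
#' every member.
#'
#' @param n_members Number of family members.
#' @param length_aa Protein length.
#' @param identity Target expected identity to the root, in (0, 1].
#' @param motifs Optional tibble with `consensus`, `prob`.
#' @param exon_count_range Length-2 integer range for exon counts.
#' @param seed Integer seed.
#' @return A list: `proteins` (sequence tibble), `models` (gene-model
#'   tibble as from [read_gff3()]), `truth` (`motif_sites`, `identity`).
#' @export
simulate_protein_family <- function(n_members = 12, length_aa = 200,
                                    identity = 0.8, motifs = NULL,
                                    exon_count_range = c(1, 20), seed = 1) {
  if (identity <= 0 || identity > 1) abort("identity must be in (0, 1]")
  if (!is.null(motifs) && nrow(motifs) &&
      any(nchar(motifs$consensus) > length_aa)) {
    abort("motif longer than protein")
  }
  withr::with_seed(seed, {
    bg <- jtt_frequencies()
    root <- sample(AA20, length_aa, replace = TRUE, prob = bg)
    ids <- sprintf("gene%02d", seq_len(n_members))
    p_mut <- 1 - identity

    site_rows <- list()
    seqs <- character(n_members)
    realized <- numeric(n_members)
    for (i in seq_len(n_members)) {
      s <- root
      hit <- runif(length_aa) < p_mut
      if (any(hit)) {
        s[hit] <- vapply(s[hit], function(cur) {
          pool <- setdiff(AA20, cur)
          sample(pool, 1, prob = bg[pool])
        }, character(1))
      }
      used <- matrix(numeric(0), ncol = 2)
      if (!is.null(motifs) && nrow(motifs)) {
        for (m in seq_len(nrow(motifs))) {
          if (runif(1) > motifs$prob[m]) next
          w <- nchar(motifs$consensus[m])
          ok_start <- NULL
          for (try in 1:100) {
            st <- sample.int(length_aa - w + 1, 1)
            if (nrow(used) == 0 ||
                all(st + w - 1 < used[, 1] | st > used[, 2])) {
              ok_start <- st
              break
            }
          }
          if (is.null(ok_start)) next
          s[ok_start:(ok_start + w - 1)] <-
            strsplit(motifs$consensus[m], "")[[1]]
          used <- rbind(used, c(ok_start, ok_start + w - 1))
          site_rows[[length(site_rows) + 1]] <-
            tibble(id = ids[i], motif = m,
                   consensus = motifs$consensus[m], start = ok_start)
        }
      }
      seqs[i] <- paste(s, collapse = "")
      realized[i] <- mean(s == root)
    }

    models <- bind_rows(lapply(seq_len(n_members), function(i) {
      rng <- exon_count_range[1]:exon_count_range[2]
      n_ex <- rng[sample.int(length(rng), 1)]
      cds_len <- 3L * length_aa
      # split the CDS into n_ex pieces of >= 3 nt
      cuts <- if (n_ex > 1) {
        sort(sample(seq_len(cds_len %/% 3 - 1), n_ex - 1)) * 3L
      } else integer()
      piece <- diff(c(0L, cuts, cds_len))
      gstart <- sample.int(5e5, 1)
      starts <- ends <- integer(n_ex)
      pos <- gstart
      for (k in seq_len(n_ex)) {
        starts[k] <- pos
        ends[k] <- pos + piece[k] - 1L
        pos <- ends[k] + 101L   # 100 nt intron
      }
      iv <- tibble(start = starts, end = ends)
      tibble(gene_id = ids[i],
             chromosome = as.character(sample.int(24, 1)),
             strand = sample(c("+", "-"), 1),
             mrna_id = paste0(ids[i], ".t1"),
             exons = list(iv), cds = list(iv), exon_count = n_ex)
    }))

    list(
      proteins = seq_tbl(ids, seqs, "protein"),
      models = models,
      truth = list(
        motif_sites = if (length(site_rows)) bind_rows(site_rows) else {
          tibble(id = character(), motif = integer(),
                 consensus = character(), start = integer())
        },
        identity = tibble(id = ids, identity_to_root = realized)
      )
    )
  })
}

#' Write gene models as GFF3
#'
#' Emits a `##gff-version 3` pragma and gene/mRNA/exon/CDS features linked
#' by ID/Parent attributes, 1-based inclusive coordinates.
#'
#' @param models A gene-model tibble (as from [read_gff3()] or
#'   [simulate_protein_family()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    ex <- g$exons[[1]]
    cd <- g$cds[[1]]
    span <- c(min(ex$start, cd$start), max(ex$end, cd$end))
    feat <- function(type, start, end, attrs) {
      paste(g$chromosome, "genefamr", type, start, end, ".", g$strand, ".",
            attrs, sep = "\t")
    }
    lines <- c(
      lines,
      feat("gene", span[1], span[2], paste0("ID=", g$gene_id)),
      feat("mRNA", span[1], span[2],
           paste0("ID=", g$mrna_id, ";Parent=", g$gene_id)),
      vapply(seq_len(nrow(ex)), function(k) {
        feat("exon", ex$start[k], ex$end[k],
             paste0("ID=", g$mrna_id, ".exon", k, ";Parent=", g$mrna_id))
      }, character(1)),
      vapply(seq_len(nrow(cd)), function(k) {
        feat("CDS", cd$start[k], cd$end[k],
             paste0("ID=", g$mrna_id, ".cds", k, ";Parent=", g$mrna_id))
      }, character(1))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Evolve a protein along a tree under JTT
#'
#' Simulates site-independent substitution along each edge of the tree
#' using the same JTT transition probabilities as the phylogenetic
#' machinery, starting from the given root sequence. Returns the (gap-free)
#' leaf alignment.
#'
#' @param tree A `phylo` tree with non-negative branch lengths
#'   (substitutions/site) and unique leaf names.
#' @param root A one-row protein sequence tibble or a single string.
#' @param seed Integer seed.
#' @return An alignment tibble (`id` = leaf names, `seq`).
#' @export
evolve_on_tree <- function(tree, root, seed = 1) {
  r <- .as_seq_pair(root, "root")
  if (anyDuplicated(tree$tip.label)) abort("leaf names must be unique")
  if (any(tree$edge.length < 0)) abort("branch lengths must be >= 0")
  x0 <- match(strsplit(r$seq, "")[[1]], AA20)
  if (anyNA(x0)) abort("root contains non-standard residues")
  S <- length(x0)
  ntip <- length(tree$tip.label)
  withr::with_seed(seed, {
    tr <- ape::reorder.phylo(tree, "postorder")
    # preorder = reversed postorder edge list
    states <- vector("list", ntip + tr$Nnode)
    root_node <- tr$edge[nrow(tr$edge), 1]
    states[[root_node]] <- x0
    for (e in rev(seq_len(nrow(tr$edge)))) {
      par <- tr$edge[e, 1]
      chi <- tr$edge[e, 2]
      P <- jtt_prob(tr$edge.length[e])
      parent_states <- states[[par]]
      child <- integer(S)
      for (a in unique(parent_states)) {
        idx <- which(parent_states == a)
        child[idx] <- sample.int(20, length(idx), replace = TRUE,
                                 prob = P[a, ])
      }
      states[[chi]] <- child
    }
    tibble(id = tr$tip.label,
           seq = vapply(seq_len(ntip), function(i) {
             paste(AA20[states[[i]]], collapse = "")
           }, character(1)))
  })
}
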