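# Sequence and gene-model I/O.
#
# Sequence collections are tibbles with columns id, seq, alphabet
# ("protein"/"dna") and desc. Coordinates are 1-based inclusive throughout
# the package, in FASTA/GFF3 convention.

PROTEIN_LETTERS <- "ACDEFGHIKLMNPQRSTVWYX"
DNA_LETTERS <- "ACGTUNRYSWKMBDHV"

.check_alphabet <- function(seqs, ids, alphabet) {
  letters_ok <- if (alphabet == "protein") PROTEIN_LETTERS else DNA_LETTERS
  bad <- !grepl(paste0("^[", letters_ok, "]*$"), seqs)
  if (any(bad)) {
    abort(paste0("sequence '", ids[which(bad)[1]], "' contains characters ",
                 "outside the ", alphabet, " alphabet"))
  }
  invisible(TRUE)
}

#' Build a sequence tibble
#'
#' Constructs the tibble format used for sequence collections throughout the
#' package, validating ids and residues.
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param seq Character vector of residues (uppercased on construction).
#'   IUPAC ambiguity codes are permitted for DNA, `X` for protein.
#' @param alphabet `"protein"` or `"dna"`.
#' @param desc Optional description strings.
#' @return A tibble with columns `id`, `seq`, `alphabet`, `desc`.
#' @export
seq_tbl <- function(id, seq, alphabet = c("protein", "dna"), desc = "") {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) abort("id and seq lengths differ")
  if (any(!nzchar(id))) abort("empty sequence id")
  if (anyDuplicated(id)) {
    abort(paste0("duplicate sequence id: '", id[duplicated(id)][1], "'"))
  }
  if (any(!nzchar(seq))) {
    abort(paste0("empty sequence for id '", id[!nzchar(seq)][1], "'"))
  }
  .check_alphabet(seq, id, alphabet)
  tibble(id = id, seq = seq, alphabet = alphabet,
         desc = rep_len(as.character(desc), length(id)))
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return A tibble of sequences (see [seq_tbl()]); an empty file yields an
#'   empty tibble. Record order is preserved and residues are uppercased.
#'   Duplicate ids are an error naming the id; non-FASTA content is a parse
#'   error naming the offending line.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(seq_tbl(character(), character(), alphabet))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(paste0("not FASTA: line ", first, " does not start with '>'"))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_tbl(ids, as.character(set), alphabet, desc)
}

#' Write a FASTA file
#'
#' Sequences are wrapped at 60 columns; descriptions, when present, follow
#' the id on the header line. `write_fasta()` then `read_fasta()` is the
#' identity on valid sequence tibbles.
#'
#' @param x A sequence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- ifelse(nzchar(x$desc %||% ""), paste(x$id, x$desc), x$id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file (gene -> mRNA -> exon/CDS hierarchy via ID/Parent
#' attributes) into one row per gene. When a gene has several mRNA isoforms
#' the isoform with the longest summed CDS length is kept; ties break by
#' lexicographic mRNA ID. A missing `##gff-version` pragma is a warning, not
#' an error.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chromosome`, `strand`,
#'   `mrna_id`, `exons` and `cds` (list-columns of tibbles with 1-based
#'   inclusive `start`/`end`, sorted and non-overlapping) and `exon_count`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1)
  if (length(first) == 0 || !grepl("^##gff-version", first)) {
    warn("GFF3 file has no ##gff-version pragma")
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      abort(paste0("GFF3 coordinate/parse error: ", conditionMessage(e)))
    }
  )
  df <- tibble(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID %||% NA_character_),
    parent = vapply(as.list(gr$Parent %||% rep(list(character()), length(gr))),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  )
  if (any(df$start > df$end)) abort("GFF3 coordinate error: start > end")

  known <- df$id[!is.na(df$id)]
  bad_parent <- setdiff(df$parent[!is.na(df$parent)], known)
  if (length(bad_parent)) {
    abort(paste0("GFF3 Parent references unknown ID: '", bad_parent[1], "'"))
  }

  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), ]
  exons <- df[df$type == "exon", ]
  cdss <- df[df$type == "CDS", ]

  .intervals <- function(sub) {
    sub <- sub[order(sub$start), c("start", "end")]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      abort("overlapping intervals within one isoform")
    }
    as_tibble(sub)
  }

  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    iso <- mrnas[mrnas$parent %in% g$id, ]
    if (nrow(iso) == 0) abort(paste0("gene '", g$id, "' has no mRNA"))
    cds_len <- vapply(iso$id, function(m) {
      sub <- cdss[cdss$parent %in% m, ]
      sum(sub$end - sub$start + 1)
    }, numeric(1))
    pick <- iso$id[order(-cds_len, iso$id)][1]
    ex <- .intervals(exons[exons$parent %in% pick, ])
    cd <- .intervals(cdss[cdss$parent %in% pick, ])
    if (nrow(ex) == 0) abort(paste0("isoform '", pick, "' has no exons"))
    tibble(gene_id = g$id, chromosome = g$chromosome, strand = g$strand,
           mrna_id = pick, exons = list(ex), cds = list(cd),
           exon_count = nrow(ex))
  })
  bind_rows(out)
}

#' Exon counts per gene
#'
#' @param models A gene-model tibble from [read_gff3()].
#' @return A tibble with `gene_id` and `exon_count` (number of exon intervals
#'   of the selected isoform).
#' @export
exon_count <- function(models) {
  tibble(gene_id = models$gene_id,
         exon_count = map_int(models$exons, nrow))
}

# translate one CDS string; terminal stop dropped, internal stop an error
.translate1 <- function(seq, id = "<cds>") {
  n <- nchar(seq)
  if (n == 0 || n %% 3 != 0) {
    abort(paste0("frame error: CDS '", id, "' length ", n,
                 " is not a multiple of 3"))
  }
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  if (anyNA(aa)) {
    abort(paste0("CDS '", id, "' contains untranslatable codon '",
                 codons[which(is.na(aa))[1]], "'"))
  }
  stops <- which(aa == "*")
  if (length(stops) && stops[length(stops)] == length(aa)) {
    aa <- aa[-length(aa)]
    stops <- stops[-length(stops)]
  }
  if (length(stops)) {
    abort(paste0("internal stop codon in CDS '", id, "' at codon ",
                 stops[1]))
  }
  paste(aa, collapse = "")
}

#' Translate coding sequences
#'
#' Standard genetic code; a terminal stop codon is dropped. A length not
#' divisible by 3 is a frame error; an internal stop codon is an error
#' naming the codon index.
#'
#' @param x A DNA sequence tibble (see [seq_tbl()]).
#' @return A protein sequence tibble with the same ids.
#' @export
translate_cds <- function(x) {
  prot <- map_chr(seq_len(nrow(x)), function(i) .translate1(x$seq[i], x$id[i]))
  seq_tbl(x$id, prot, "protein", x$desc %||% "")
}
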