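# ProtParam-style physicochemical calculators and classification flags.
#
# Classification rules used throughout: acidic iff pI < 7.0 (pI >= 7 is
# basic), unstable iff II > 40, thermostable iff AI > 65 (strict), and
# hydrophilic iff GRAVY < 0.

.check_standard <- function(seq, what, min_len = 1) {
  if (length(seq) != 1 || is.na(seq)) abort("expected a single sequence string")
  if (nchar(seq) < min_len) {
    abort(paste0(what, ": sequence length must be >= ", min_len))
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA20)
  if (length(bad)) {
    abort(paste0(what, ": non-standard residue(s) '",
                 paste(unique(chars[bad]), collapse = ""), "' at position(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  chars
}

#' Molecular weight of a protein
#'
#' Sum of average (not monoisotopic) residue masses plus one water
#' (18.0153 Da), reported in kilodaltons.
#'
#' @param seq Character vector of protein sequences (20 standard residues).
#' @return Numeric vector of masses in kDa.
#' @export
molecular_weight <- function(seq) {
  masses <- .residue_masses()
  vapply(seq, function(s) {
    chars <- .check_standard(s, "molecular_weight")
    (sum(masses[chars]) + WATER_MASS_DA) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' D/E/C/Y/H/K/R side chains with the Bjellqvist pKa set (ProtParam's
#' choice, including residue-specific terminal pKa values). The charge is
#' strictly decreasing in pH.
#'
#' @param seq A single protein sequence.
#' @param pH Numeric vector of pH values.
#' @return Net charge at each pH.
#' @export
protein_charge <- function(seq, pH) {
  chars <- .check_standard(seq, "protein_charge")
  counts <- table(factor(chars, levels = AA20))
  nterm_pka <- PKA_NTERM_BY_RESIDUE[chars[1]]
  if (is.na(nterm_pka)) nterm_pka <- PKA_POSITIVE[["Nterm"]]
  cterm_pka <- PKA_CTERM_BY_RESIDUE[chars[length(chars)]]
  if (is.na(cterm_pka)) cterm_pka <- PKA_NEGATIVE[["Cterm"]]

  pos_pkas <- c(nterm_pka, PKA_POSITIVE[["K"]], PKA_POSITIVE[["R"]],
                PKA_POSITIVE[["H"]])
  pos_n <- c(1, counts[["K"]], counts[["R"]], counts[["H"]])
  neg_pkas <- c(cterm_pka, PKA_NEGATIVE[["D"]], PKA_NEGATIVE[["E"]],
                PKA_NEGATIVE[["C"]], PKA_NEGATIVE[["Y"]])
  neg_n <- c(1, counts[["D"]], counts[["E"]], counts[["C"]], counts[["Y"]])

  vapply(pH, function(p) {
    pos <- sum(pos_n / (1 + 10^(p - pos_pkas)))
    neg <- sum(neg_n / (1 + 10^(neg_pkas - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point
#'
#' The pH at which [protein_charge()] crosses zero, found by bisection on
#' \[0, 14\] to a tolerance of 0.001 pH units. The charge function is
#' monotone decreasing, so the root exists and is unique.
#'
#' @param seq Character vector of protein sequences.
#' @return Numeric vector of pI values (pH units).
#' @export
isoelectric_point <- function(seq) {
  vapply(seq, function(s) {
    lo <- 0
    hi <- 14
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      if (protein_charge(s, mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' GRAVY (grand average of hydropathicity)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over the sequence;
#' negative values indicate a globally hydrophilic protein.
#'
#' @param seq Character vector of protein sequences.
#' @return Numeric vector of mean hydropathy values in \[-4.5, 4.5\].
#' @export
gravy <- function(seq) {
  vapply(seq, function(s) {
    chars <- .check_standard(s, "gravy")
    mean(KYTE_DOOLITTLE[chars])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Aliphatic index
#'
#' Ikai (1980): `AI = X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` where `X` is
#' the mole percent of each residue over the full sequence length.
#'
#' @param seq Character vector of protein sequences.
#' @return Numeric vector of aliphatic indices.
#' @export
aliphatic_index <- function(seq) {
  vapply(seq, function(s) {
    chars <- .check_standard(s, "aliphatic_index")
    x <- 100 * table(factor(chars, levels = AA20)) / length(chars)
    unname(x[["A"]] + 2.9 * x[["V"]] + 3.9 * (x[["I"]] + x[["L"]]))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Instability index
#'
#' Guruprasad et al. (1990): `II = (10/L) * sum` of the DIWV weights of the
#' `L - 1` overlapping dipeptides. Values above 40 predict an unstable
#' protein. Order-sensitive by construction.
#'
#' @param seq Character vector of protein sequences (length >= 2 each).
#' @return Numeric vector of instability indices.
#' @export
instability_index <- function(seq) {
  diwv <- .diwv()
  vapply(seq, function(s) {
    chars <- .check_standard(s, "instability_index", min_len = 2)
    L <- length(chars)
    idx <- cbind(match(chars[-L], rownames(diwv)),
                 match(chars[-1], colnames(diwv)))
    10 / L * sum(diwv[idx])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Physicochemical profile of a protein collection
#'
#' Aggregates the five calculators and derives the classification flags used
#' in family characterization tables: `charge_class` ("acidic" iff pI < 7,
#' otherwise "basic"), `stability` ("unstable" iff II > 40), `thermostable`
#' (AI strictly greater than 65) and `hydropathy` ("hydrophilic" iff
#' GRAVY < 0).
#'
#' @param x A protein sequence tibble (see [seq_tbl()]); each sequence must
#'   be length >= 2 with standard residues.
#' @return A tibble with one row per protein: `gene_id`, `length_aa`,
#'   `mw_kda`, `pi`, `ai`, `ii`, `gravy` and the four flag columns.
#' @export
physchem_profile <- function(x) {
  out <- tibble(
    gene_id = x$id,
    length_aa = nchar(x$seq),
    mw_kda = molecular_weight(x$seq),
    pi = isoelectric_point(x$seq),
    ai = aliphatic_index(x$seq),
    ii = instability_index(x$seq),
    gravy = gravy(x$seq)
  )
  out <- mutate(
    out,
    charge_class = ifelse(.data$pi < 7, "acidic", "basic"),
    stability = ifelse(.data$ii > 40, "unstable", "stable"),
    thermostable = .data$ai > 65,
    hydropathy = ifelse(.data$gravy < 0, "hydrophilic", "hydrophobic")
  )
  class(out) <- c("physchem_profile", class(out))
  out
}

#' Classification flags from printed table values
#'
#' Applies the family-table classification rules to already-computed numbers
#' (for example values printed in a publication), without access to the
#' underlying sequences.
#'
#' @param pi,ai,ii,gravy Numeric vectors (recycled to a common length).
#' @return A tibble with the four flag columns.
#' @export
physchem_flags <- function(pi, ai, ii, gravy) {
  tibble(
    charge_class = ifelse(pi < 7, "acidic", "basic"),
    stability = ifelse(ii > 40, "unstable", "stable"),
    thermostable = ai > 65,
    hydropathy = ifelse(gravy < 0, "hydrophilic", "hydrophobic")
  )
}

#' @export
autoplot.physchem_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gravy, y = .data$pi,
                                       colour = .data$thermostable,
                                       shape = .data$stability)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = 7, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "GRAVY", y = "pI",
                  colour = "AI > 65", shape = "Stability") +
    ggplot2::theme_minimal()
}
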