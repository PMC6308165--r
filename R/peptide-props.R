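#' Parse a one-letter peptide sequence
#'
#' Validates a plain one-letter string against the 20 canonical amino acid
#' codes and returns a [Peptide] object.  Input is case-insensitive and may
#' contain whitespace; it is stored uppercase.
#'
#' @param text character scalar, the sequence.
#' @param cterm C-terminal state, `"free_acid"` (default) or `"amide"`.
#' @param name optional label.
#' @return a [Peptide].
#' @examples
#' chmap28 <- parsePeptide("GRFKRFRKKLKRLWHKVGPFVGPILHY", name = "ChMAP-28")
#' nchar(pepSequence(chmap28))  # 27
#' @export
parsePeptide <- function(text, cterm = c("free_acid", "amide"), name = "") {
  cterm <- match.arg(cterm)
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single character string")
  clean <- toupper(gsub("[[:space:]]", "", text))
  if (!nzchar(clean))
    stop("empty peptide sequence")
  codes <- strsplit(clean, "")[[1]]
  bad <- which(!codes %in% names(.AA_MONO))
  if (length(bad))
    stop(sprintf("invalid residue code '%s' at position %d", codes[bad[1]], bad[1]))
  new("Peptide", sequence = clean, cterm = cterm, name = as.character(name))
}

.asPeptide <- function(x) {
  if (is(x, "Peptide")) x else parsePeptide(x)
}

#' @rdname peptideAccessors
#' @title Peptide accessors
#' @description Accessors for the sequence string, residue vector,
#'   C-terminal state and name of a [Peptide].
#' @param x a [Peptide] (or, for convenience, a plain sequence string).
#' @return `pepSequence`: the uppercase sequence string; `pepResidues`: a
#'   character vector of one-letter codes; `pepCterm` and `pepName`: scalars.
#' @export
pepSequence <- function(x) .asPeptide(x)@sequence

#' @rdname peptideAccessors
#' @export
pepResidues <- function(x) strsplit(pepSequence(x), "")[[1]]

#' @rdname peptideAccessors
#' @export
pepCterm <- function(x) .asPeptide(x)@cterm

#' @rdname peptideAccessors
#' @export
pepName <- function(x) .asPeptide(x)@name

.chainMass <- function(residues, table, water, amide_delta, cterm) {
  m <- sum(table[residues]) + water
  if (cterm == "amide") m <- m + amide_delta
  m
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water for the intact chain;
#' C-terminal amidation (\eqn{-OH \rightarrow -NH_2}) subtracts 0.984016 Da.
#' Full precision is returned; the conventional display rounding for
#' MALDI-scale work is one decimal.
#'
#' @param x a [Peptide] or plain sequence string (free-acid assumed).
#' @return neutral monoisotopic mass in Da.
#' @seealso [protonatedMz()] for the \eqn{[M+zH]^{z+}} ion, [averageMass()].
#' @export
monoisotopicMass <- function(x) {
  p <- .asPeptide(x)
  .chainMass(pepResidues(p), .AA_MONO, .WATER_MONO, .AMIDE_DELTA_MONO, p@cterm)
}

#' Average (isotope-abundance-weighted) mass of a peptide
#'
#' As [monoisotopicMass()] but with average residue masses; conventionally
#' displayed to the nearest integer at this peptide size.
#'
#' @inheritParams monoisotopicMass
#' @return neutral average mass in Da.
#' @export
averageMass <- function(x) {
  p <- .asPeptide(x)
  .chainMass(pepResidues(p), .AA_AVG, .WATER_AVG, .AMIDE_DELTA_AVG, p@cterm)
}

#' m/z of the protonated peptide ion
#'
#' Computes \eqn{(M + z \cdot m_H)/z} from the neutral monoisotopic mass,
#' with the proton mass fixed at 1.007276 Da.
#'
#' @inheritParams monoisotopicMass
#' @param charge positive integer charge state (default 1).
#' @return m/z of the \eqn{[M+zH]^{z+}} ion.
#' @export
protonatedMz <- function(x, charge = 1L) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge))
    stop("'charge' must be a positive integer")
  (monoisotopicMass(x) + charge * .PROTON) / charge
}

#' GRAVY: grand average of hydropathicity
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy values over all
#' residues.  Negative values indicate a hydrophilic peptide; for membrane-
#' active peptides GRAVY is a coarse proxy for hydrophobicity-driven lytic
#' activity.
#'
#' @inheritParams monoisotopicMass
#' @return unitless mean hydropathy (conventionally shown to 3 decimals).
#' @export
gravy <- function(x) {
  mean(.KD_SCALE[pepResidues(x)])
}

#' Count basic residues (Arg, Lys, His)
#'
#' His is included in the census although it is only weakly basic at
#' physiological pH; cationicity of host-defense peptides is conventionally
#' reported over all three.
#'
#' @inheritParams monoisotopicMass
#' @return integer count of R/K/H residues.
#' @export
countBasic <- function(x) {
  sum(pepResidues(x) %in% .BASIC_RESIDUES)
}

#' Residue census of a peptide
#'
#' @inheritParams monoisotopicMass
#' @return named integer vector of counts over the 20 canonical residues
#'   (zeros included), in alphabetical order.
#' @export
residueCounts <- function(x) {
  res <- pepResidues(x)
  lv <- sort(names(.AA_MONO))
  table(factor(res, levels = lv))
}

#' Descriptor table for one or more peptides
#'
#' One row per peptide: name, length, neutral monoisotopic mass, singly
#' protonated m/z, average mass, GRAVY and basic-residue count, at the
#' field's conventional display precision (mass to 1 decimal, average mass
#' to the integer, GRAVY to 3 decimals).
#'
#' @param peptides a [Peptide], a list of them, or character vector of
#'   sequences.
#' @return a `data.frame`.
#' @examples
#' peptideProps(parsePeptide("GRFKRFRKKLKRLWHKVGPFVGPILHY", name = "ChMAP-28"))
#' @export
peptideProps <- function(peptides) {
  if (is(peptides, "Peptide") || is.character(peptides) && length(peptides) == 1L)
    peptides <- list(peptides)
  rows <- lapply(peptides, function(p) {
    p <- .asPeptide(p)
    data.frame(
      name = if (nzchar(p@name)) p@name else p@sequence,
      length = nchar(p@sequence),
      cterm = p@cterm,
      mono_mass = round(monoisotopicMass(p), 1),
      mh_plus = round(protonatedMz(p, 1L), 1),
      avg_mass = round(averageMass(p)),
      gravy = round(gravy(p), 3),
      n_basic = countBasic(p),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
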