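#' @import methods
#' @importFrom stats median rnorm runif sd setNames quantile cor coef predict resid
#' @importFrom utils read.delim write.table head
NULL

## Residue-level physical constants (Da).  Monoisotopic and
## isotope-abundance-weighted (average) residue masses of the 20 canonical
## amino acids, i.e. the mass of the residue inside a chain (free amino acid
## minus water).  Standard IUPAC/unimod values.
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.AA_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

## Kyte-Doolittle hydropathy scale; range [-4.5, 4.5].
.KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

.WATER_MONO <- 18.010565
.WATER_AVG  <- 18.0153
.PROTON     <- 1.007276
## C-terminal amidation: -OH replaced by -NH2.
.AMIDE_DELTA_MONO <- -0.984016
.AMIDE_DELTA_AVG  <- -0.98476

.BASIC_RESIDUES <- c("R", "K", "H")
.CTERM_LEVELS <- c("free_acid", "amide")

## Allowed activator/repressor role weights in a pathway definition.
.ARR_VOCAB <- c(-1, -0.5, 0, 0.5, 1)

#' Peptide: a validated one-letter amino acid chain
#'
#' Holds an uppercase sequence over the 20 canonical residue codes together
#' with its C-terminal state (`"free_acid"` or `"amide"`; natural
#' cathelicidins are commonly C-terminally amidated, recombinant analogs
#' usually are not) and a free-text name.  Construct with [parsePeptide()]
#' or [readFasta()].
#'
#' @slot sequence single uppercase character string of canonical residues.
#' @slot cterm `"free_acid"` or `"amide"`.
#' @slot name free-text label.
#' @aliases Peptide
#' @exportClass Peptide
setClass("Peptide",
  representation(sequence = "character", cterm = "character",
                 name = "character"))

setValidity("Peptide", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || is.na(object@sequence) ||
      nchar(object@sequence) < 1L)
    msg <- c(msg, "sequence must be a single non-empty string")
  else {
    bad <- which(!strsplit(object@sequence, "")[[1]] %in% names(.AA_MONO))
    if (length(bad))
      msg <- c(msg, sprintf(
        "non-canonical residue code at position %d ('%s')",
        bad[1], substr(object@sequence, bad[1], bad[1])))
  }
  if (length(object@cterm) != 1L || !object@cterm %in% .CTERM_LEVELS)
    msg <- c(msg, "cterm must be 'free_acid' or 'amide'")
  if (length(msg)) msg else TRUE
})

#' @describeIn Peptide compact display
#' @param object a `Peptide`
#' @export
setMethod("show", "Peptide", function(object) {
  cat(sprintf("Peptide%s: %d residues, C-terminus %s\n",
              if (nzchar(object@name)) paste0(" '", object@name, "'") else "",
              nchar(object@sequence), object@cterm))
  cat(" ", object@sequence, "\n")
})

#' PathwayDB: gene sets with activator/repressor role weights
#'
#' Each pathway maps gene symbols to a discrete activator/repressor role
#' (ARR) weight in \{-1, -0.5, 0, 0.5, 1\}: 1 marks an activator of the
#' pathway's end function, -1 a repressor, the half weights intermediate
#' roles and 0 an unknown role.  Construct with [pathwayDB()] or
#' [readPathwayDB()].
#'
#' @slot pathways named list; each element a named numeric vector of ARR
#'   weights keyed by gene symbol.
#' @slot description named character vector of display names.
#' @aliases PathwayDB
#' @exportClass PathwayDB
setClass("PathwayDB",
  representation(pathways = "list", description = "character"))

setValidity("PathwayDB", function(object) {
  msg <- character()
  if (is.null(names(object@pathways)) || anyDuplicated(names(object@pathways)))
    msg <- c(msg, "pathways must be uniquely named")
  for (id in names(object@pathways)) {
    w <- object@pathways[[id]]
    if (!is.numeric(w) || length(w) < 1L || is.null(names(w)))
      msg <- c(msg, sprintf("pathway '%s' must be a non-empty named numeric vector", id))
    else {
      if (anyDuplicated(names(w)))
        msg <- c(msg, sprintf("pathway '%s' lists a gene more than once", id))
      bad <- !w %in% .ARR_VOCAB
      if (any(bad))
        msg <- c(msg, sprintf(
          "pathway '%s', gene '%s': ARR weight %s not in {-1, -0.5, 0, 0.5, 1}",
          id, names(w)[bad][1], format(w[bad][1])))
    }
    if (length(msg) > 5) break
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PathwayDB compact display
#' @param object a `PathwayDB`
#' @export
setMethod("show", "PathwayDB", function(object) {
  n <- length(object@pathways)
  ng <- lengths(object@pathways)
  cat(sprintf("PathwayDB: %d pathways, %d gene-role entries (%d unique genes)\n",
              n, sum(ng), length(unique(unlist(lapply(object@pathways, names))))))
  shown <- head(names(object@pathways), 3)
  for (id in shown)
    cat(sprintf("  %s (%d genes)\n", id, length(object@pathways[[id]])))
  if (n > 3) cat(sprintf("  ... and %d more\n", n - 3))
})

#' FitResult: fitted four-parameter logistic dose-response curve
#'
#' Returned by [fitDoseResponse()] and [hc50()].  `ic50` is the relative
#' midpoint (dose at the halfway point between the fitted plateaus);
#' `ic50Absolute` is the dose at which the fitted response crosses 50% of
#' control.  When the midpoint exceeds the largest tested dose the result is
#' censored and `label` carries the "> max dose" convention.
#'
#' @slot ic50,ic50Absolute numeric, dose units of the input.
#' @slot hill unitless slope factor (positive for a falling curve as fit).
#' @slot top,bottom fitted plateaus, percent.
#' @slot converged,censored logical flags.
#' @slot residualSD residual standard deviation, percent.
#' @slot direction `"decreasing"` (viability) or `"increasing"` (hemolysis/LDH).
#' @slot maxDose largest tested (or declared) dose.
#' @slot label display form, e.g. `"3.39"` or `"> 10"`.
#' @slot diagnostics character, non-empty on non-convergence or warnings.
#' @aliases FitResult
#' @exportClass FitResult
setClass("FitResult",
  representation(ic50 = "numeric", ic50Absolute = "numeric", hill = "numeric",
                 top = "numeric", bottom = "numeric", converged = "logical",
                 censored = "logical", residualSD = "numeric",
                 direction = "character", maxDose = "numeric",
                 label = "character", diagnostics = "character"))

#' @describeIn FitResult compact display
#' @param object a `FitResult`
#' @export
setMethod("show", "FitResult", function(object) {
  cat(sprintf("4PL fit (%s): midpoint = %s\n", object@direction, object@label))
  if (isTRUE(object@converged))
    cat(sprintf("  top = %.1f, bottom = %.1f, hill = %.2f, residual SD = %.2f\n",
                object@top, object@bottom, object@hill, object@residualSD))
  if (length(object@diagnostics) && nzchar(object@diagnostics[1]))
    cat("  note:", object@diagnostics[1], "\n")
})
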