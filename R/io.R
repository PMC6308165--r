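## Readers and writers.  Single tabular dialect: TSV with '#' comment
## lines; gene identifiers are opaque case-sensitive strings.

#' Read peptides from a FASTA file
#'
#' Standard FASTA via [Biostrings::readAAStringSet()]; the text after '>'
#' becomes the peptide name, wrapped sequence lines are joined.  An empty
#' file yields an empty list with a warning.
#'
#' @param path FASTA file.
#' @param cterm C-terminal state applied to all records.
#' @return list of [Peptide] objects, input order preserved.
#' @export
readFasta <- function(path, cterm = c("free_acid", "amide")) {
  cterm <- match.arg(cterm)
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    warning("no FASTA records in ", path)
    return(list())
  }
  lapply(seq_along(aa), function(i)
    parsePeptide(as.character(aa[[i]]), cterm = cterm, name = names(aa)[i]))
}

#' Read a pathway database with ARR weights
#'
#' GMT-derived text, one pathway per line:
#' `pathway_id<TAB>description<TAB>gene:ARR<TAB>gene:ARR...`, e.g.
#' `AKT1:1`, `PTEN:-1`, `GSK3B:-0.5`.  ARR must belong to
#' \{-1, -0.5, 0, 0.5, 1\}; a duplicate gene within a pathway or an
#' out-of-vocabulary weight is a parse error naming pathway and gene.
#'
#' @param path pathway file; '#' lines are comments.
#' @return a [PathwayDB].
#' @export
readPathwayDB <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  pws <- list(); desc <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed pathway line (need id, description, >=1 gene:ARR token): ",
           substr(ln, 1, 60))
    id <- f[1]
    if (id %in% names(pws)) stop("duplicate pathway id '", id, "'")
    toks <- strsplit(f[-(1:2)], ":", fixed = TRUE)
    genes <- vapply(toks, function(t)
      paste(head(t, -1), collapse = ":"), character(1))
    wtxt <- vapply(toks, function(t) t[length(t)], character(1))
    w <- suppressWarnings(as.numeric(wtxt))
    bad <- is.na(w) | !w %in% .ARR_VOCAB
    if (any(bad))
      stop(sprintf("pathway '%s', gene '%s': ARR value '%s' not in {-1, -0.5, 0, 0.5, 1}",
                   id, genes[bad][1], wtxt[bad][1]))
    if (anyDuplicated(genes))
      stop(sprintf("pathway '%s': gene '%s' listed more than once",
                   id, genes[duplicated(genes)][1]))
    pws[[id]] <- setNames(w, genes)
    desc[id] <- f[2]
  }
  pathwayDB(pws, desc)
}

#' Write a pathway database
#'
#' Inverse of [readPathwayDB()]; pathways in their stored order, weights
#' formatted so a read-write round trip is exact.
#'
#' @param db a [PathwayDB].
#' @param path output file.
#' @export
writePathwayDB <- function(db, path) {
  lines <- vapply(pathwayNames(db), function(id) {
    w <- db@pathways[[id]]
    paste(c(id, db@description[[id]],
            sprintf("%s:%g", names(w), unname(w))), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

.readTSV <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(basename(path), " lacks required column(s): ", paste(miss, collapse = ", "))
  d
}

#' Read a plate TSV
#'
#' Columns: `well`, `role`, `concentration_uM`, `replicate`, `od`; the
#' measurement wavelength may be recorded in a leading '#' comment.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readPlate <- function(path) {
  d <- .readTSV(path, c("well", "role", "concentration_uM", "replicate", "od"))
  if (any(d$od < 0)) stop("negative optical density in ", basename(path))
  d
}

#' Read a cytometry event TSV
#'
#' Columns: `event_id`, `av`, `pi`; optional condition columns
#' (`concentration_uM`, `time_h`, `inhibitor`) pass through.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readEvents <- function(path) {
  .readTSV(path, c("event_id", "av", "pi"))
}

#' Read a probe matrix and sample annotations
#'
#' Probe TSV: `probe_id`, `gene`, then one numeric column per sample.
#' Sample TSV: `sample`, `group`, `concentration_uM`, `replicate`; every
#' probe-matrix sample column must be annotated.
#'
#' @param probes_path,samples_path TSV files.
#' @return `SummarizedExperiment` (probes x samples) with `rowData$gene`
#'   and `colData` `group`/`concentration`/`replicate`.
#' @export
readProbeMatrix <- function(probes_path, samples_path) {
  p <- .readTSV(probes_path, c("probe_id", "gene"))
  s <- .readTSV(samples_path, c("sample", "group", "concentration_uM", "replicate"))
  sampleCols <- setdiff(names(p), c("probe_id", "gene"))
  miss <- setdiff(sampleCols, s$sample)
  if (length(miss))
    stop("sample annotation missing for: ", paste(miss, collapse = ", "))
  m <- as.matrix(p[, sampleCols, drop = FALSE])
  rownames(m) <- p$probe_id
  s <- s[match(sampleCols, s$sample), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = m),
    rowData = S4Vectors::DataFrame(probe_id = p$probe_id, gene = p$gene,
                                   row.names = p$probe_id),
    colData = S4Vectors::DataFrame(group = s$group,
                                   concentration = s$concentration_uM,
                                   replicate = s$replicate,
                                   row.names = s$sample))
}

## Deterministic TSV writer: fixed column order, 6 significant digits,
## no quoting -- reruns on identical input are byte-identical.
.writeTSV <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(v) formatC(signif(v, 6), format = "g"))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Coerce a FitResult to a one-row data.frame
#'
#' @param fit a [FitResult].
#' @return data.frame with the fitted parameters and flags.
#' @export
fitResultTable <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  data.frame(ic50 = fit@ic50, ic50_absolute = fit@ic50Absolute,
             hill = fit@hill, top = fit@top, bottom = fit@bottom,
             converged = fit@converged, censored = fit@censored,
             residual_sd = fit@residualSD, direction = fit@direction,
             max_dose = fit@maxDose, label = fit@label)
}

#' Write analysis results to a directory
#'
#' Dispatches on content: a PAS profile (long data.frame with `pathway`,
#' `sample`, `pas` columns) is written sorted by pathway then sample to
#' `pas_profile.tsv`; a [FitResult] to `fit_result.tsv` and
#' `fit_result.json`; quadrant fractions (output of [classifyEvents()]) to
#' `quadrant_fractions.tsv`.  Numeric columns carry 6 significant digits;
#' reruns on the same inputs produce byte-identical files.
#'
#' @param x the object to write.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeResults <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is(x, "FitResult")) {
    t <- fitResultTable(x)
    p1 <- .writeTSV(t, file.path(out_dir, "fit_result.tsv"))
    p2 <- file.path(out_dir, "fit_result.json")
    jsonlite::write_json(as.list(t), p2, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(c(p1, p2)))
  }
  if (is.numeric(x) && !is.null(attr(x, "counts"))) {
    d <- data.frame(quadrant = names(x), fraction = as.numeric(x),
                    count = as.integer(attr(x, "counts")))
    return(invisible(.writeTSV(d, file.path(out_dir, "quadrant_fractions.tsv"))))
  }
  if (is.data.frame(x) && all(c("pathway", "pas") %in% names(x))) {
    if (!"sample" %in% names(x)) x$sample <- ""
    x <- x[order(x$pathway, x$sample),
           c("pathway", "sample", "pas", "n_genes_used", "call")]
    return(invisible(.writeTSV(x, file.path(out_dir, "pas_profile.tsv"))))
  }
  if (is.data.frame(x))
    return(invisible(.writeTSV(x, file.path(out_dir, "results.tsv"))))
  stop("don't know how to write an object of class ", class(x)[1])
}

#' Write a gene x sample matrix (e.g. CNRs) as TSV
#'
#' @param m matrix or `SummarizedExperiment`.
#' @param path output TSV; first column `gene`.
#' @export
writeMatrixTSV <- function(m, path) {
  m <- .assayMatrix(m)
  d <- data.frame(gene = rownames(m), as.data.frame(m), check.names = FALSE)
  .writeTSV(d, path)
}
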