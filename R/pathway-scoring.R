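## Transcriptomic response pipeline: probe aggregation -> quantile
## normalization -> case-to-normal ratios (CNR) -> pathway activation
## strength (PAS).

#' Construct a PathwayDB
#'
#' @param pathways named list; each element a named numeric vector mapping
#'   gene symbols to ARR weights in \{-1, -0.5, 0, 0.5, 1\}.
#' @param description optional named character vector of display names;
#'   defaults to the pathway ids.
#' @return a [PathwayDB].
#' @examples
#' db <- pathwayDB(list(p1 = c(AKT1 = 1, PTEN = -1, GSK3B = -0.5)))
#' @export
pathwayDB <- function(pathways, description = NULL) {
  if (is.null(description))
    description <- setNames(names(pathways), names(pathways))
  new("PathwayDB", pathways = pathways,
      description = description[names(pathways)])
}

#' @rdname pathwayDBAccessors
#' @title PathwayDB accessors
#' @description `pathwayNames` lists pathway ids; `nPathways` counts them;
#'   `pathwayGenes` returns one pathway's gene-to-ARR weight vector.
#' @param db a [PathwayDB].
#' @param id pathway id.
#' @export
pathwayNames <- function(db) names(db@pathways)

#' @rdname pathwayDBAccessors
#' @export
nPathways <- function(db) length(db@pathways)

#' @rdname pathwayDBAccessors
#' @export
pathwayGenes <- function(db, id) {
  if (!id %in% names(db@pathways)) stop("unknown pathway '", id, "'")
  db@pathways[[id]]
}

.assayMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x)
  else as.matrix(x)
}

#' Aggregate probe signals to gene-level expression
#'
#' Floors raw probe intensities at `floor` and geometrically averages the
#' probes of each gene, per sample.  Genes with no probes are absent from
#' the output.
#'
#' @param probes a `SummarizedExperiment` of probe intensities (rows =
#'   probes) whose `rowData` has a `gene` column, or a plain matrix plus
#'   `gene` vector.
#' @param gene character vector mapping each probe row to a gene symbol
#'   (taken from `rowData(probes)$gene` when `probes` is a
#'   `SummarizedExperiment`).
#' @param floor strictly positive intensity floor applied before averaging
#'   (default 1), preventing log blow-ups from zero signals.
#' @return a `SummarizedExperiment` (genes x samples) carrying the input's
#'   `colData`, or a matrix when the input was a matrix.
#' @export
aggregateProbes <- function(probes, gene = NULL, floor = 1) {
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    stop("'floor' must be a single strictly positive intensity")
  isSE <- is(probes, "SummarizedExperiment")
  m <- .assayMatrix(probes)
  if (isSE && is.null(gene))
    gene <- SummarizedExperiment::rowData(probes)$gene
  if (is.null(gene) || length(gene) != nrow(m))
    stop("'gene' must map every probe row to a gene symbol")
  if (any(m < 0)) stop("probe signals must be non-negative")
  lm <- log(pmax(m, floor))
  sums <- rowsum(lm, group = gene)
  cnt <- as.vector(table(gene)[rownames(sums)])
  expr <- exp(sums / cnt)
  if (isSE)
    SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = expr),
      colData = SummarizedExperiment::colData(probes))
  else expr
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample's expression distribution to the across-sample mean
#' distribution, rank-wise (ties within a sample receive the mean of their
#' target quantile values).  Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`.  A single-sample input
#' is returned unchanged with a warning.
#'
#' @param expr genes x samples matrix or `SummarizedExperiment`.
#' @return object of the same kind with normalized values.
#' @export
quantileNormalize <- function(expr) {
  m <- .assayMatrix(expr)
  if (ncol(m) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(expr)
  }
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  if (is(expr, "SummarizedExperiment")) {
    SummarizedExperiment::assay(expr) <- qn
    expr
  } else qn
}

#' Case-to-normal expression ratios (CNR)
#'
#' For one case sample, the per-gene ratio of its expression to the
#' arithmetic mean expression of the control group.
#'
#' @param expr genes x samples matrix or `SummarizedExperiment` of
#'   normalized gene expression.
#' @param case single sample name (or column index); must not be a control.
#' @param controls sample names (or indices) of the control group.
#' @return named numeric vector of CNRs (one per gene), all > 0.
#' @export
computeCNR <- function(expr, case, controls) {
  m <- .assayMatrix(expr)
  idx <- function(s) if (is.character(s)) match(s, colnames(m)) else as.integer(s)
  ci <- idx(case); gi <- idx(controls)
  if (length(ci) != 1L || is.na(ci)) stop("'case' must name one sample in the matrix")
  if (length(gi) < 1L || any(is.na(gi))) stop("'controls' must name samples in the matrix")
  if (ci %in% gi) stop("the case sample cannot be part of the control group")
  ctrlMean <- rowMeans(m[, gi, drop = FALSE])
  if (any(ctrlMean <= 0))
    stop("control mean expression must be strictly positive for every gene; apply an intensity floor upstream")
  cnr <- m[, ci] / ctrlMean
  names(cnr) <- rownames(m)
  cnr
}

#' Pathway activation strength (PAS)
#'
#' For each pathway p, `PAS_p = sum_n(ARR_np * log10(CNR_n)) / N`, where the
#' sum and gene count N run over the pathway genes present in the CNR
#' vector.  ARR is the discrete activator/repressor role weight (1 for an
#' activator, -1 for a repressor, +/-0.5 intermediate, 0 unknown; 0-weight
#' genes still count toward N).  Genes absent from the data are excluded
#' from both numerator and denominator; a pathway with no measured genes is
#' reported with `pas = NA` (missing, not 0).  Positive PAS means pathway
#' activation relative to the controls, negative PAS repression.
#'
#' @param cnr named CNR vector from [computeCNR()].
#' @param db a [PathwayDB].
#' @return data.frame with columns `pathway`, `pas`, `n_genes_used`,
#'   `call` (`activated`/`repressed`/`neutral` by sign of PAS, NA when
#'   missing), one row per pathway, sorted by pathway id.
#' @examples
#' db <- pathwayDB(list(p = c(A = 1, B = -1, C = 0.5, D = 0)))
#' computePAS(c(A = 10, B = 10, C = 100, D = 5), db)$pas  # 0.25
#' @export
computePAS <- function(cnr, db) {
  stopifnot(is.numeric(cnr), !is.null(names(cnr)), is(db, "PathwayDB"))
  if (any(cnr <= 0)) stop("CNR values must be strictly positive")
  lg <- log10(cnr)
  rows <- lapply(pathwayNames(db), function(id) {
    arr <- db@pathways[[id]]
    g <- intersect(names(arr), names(cnr))
    n <- length(g)
    pas <- if (n == 0L) NA_real_ else sum(arr[g] * lg[g]) / n
    data.frame(pathway = id, pas = pas, n_genes_used = n,
               call = if (is.na(pas)) NA_character_
                      else if (pas > 0) "activated"
                      else if (pas < 0) "repressed" else "neutral",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$pathway), , drop = FALSE]
}

#' PAS profile across case samples
#'
#' Runs [computeCNR()] + [computePAS()] for every case sample against a
#' pooled control group and stacks the results in long format; optionally
#' appends a group-level profile per concentration (mean PAS over that
#' concentration's replicates).
#'
#' @param expr normalized gene expression (matrix or `SummarizedExperiment`
#'   whose `colData` has `group` and, for grouping, `concentration`).
#' @param db a [PathwayDB].
#' @param cases case sample names; default: all non-control samples.
#' @param controls control sample names; default: samples with
#'   `group == "control"` in `colData`.
#' @param group_means also emit per-concentration mean profiles (rows with
#'   `sample = "conc_<c>"`); requires `colData` annotations.
#' @return long data.frame `pathway, sample, pas, n_genes_used, call`.
#' @export
pasProfile <- function(expr, db, cases = NULL, controls = NULL,
                       group_means = FALSE) {
  isSE <- is(expr, "SummarizedExperiment")
  cd <- if (isSE) as.data.frame(SummarizedExperiment::colData(expr)) else NULL
  m <- .assayMatrix(expr)
  if (is.null(controls)) {
    if (is.null(cd) || is.null(cd$group))
      stop("supply 'controls' or colData with a 'group' column")
    controls <- colnames(m)[cd$group == "control"]
  }
  if (is.null(cases)) cases <- setdiff(colnames(m), controls)
  prof <- do.call(rbind, lapply(cases, function(s) {
    p <- computePAS(computeCNR(m, s, controls), db)
    p$sample <- s
    p
  }))
  prof <- prof[, c("pathway", "sample", "pas", "n_genes_used", "call")]
  if (group_means) {
    if (is.null(cd) || is.null(cd$concentration))
      stop("group_means requires colData with a 'concentration' column")
    conc <- setNames(cd$concentration, colnames(m))[prof$sample]
    for (cc in sort(unique(conc))) {
      sub <- prof[conc == cc, ]
      agg <- stats::aggregate(pas ~ pathway, data = sub, FUN = mean)
      ng <- sub$n_genes_used[match(agg$pathway, sub$pathway)]
      prof <- rbind(prof, data.frame(
        pathway = agg$pathway, sample = sprintf("conc_%g", cc),
        pas = agg$pas, n_genes_used = ng,
        call = ifelse(is.na(agg$pas), NA_character_,
                      ifelse(agg$pas > 0, "activated",
                             ifelse(agg$pas < 0, "repressed", "neutral")))))
    }
  }
  rownames(prof) <- NULL
  prof[order(prof$pathway, prof$sample), ]
}

#' Activation/repression calls, optionally scored against a planted truth
#'
#' Calls are by PAS sign (positive = activated, negative = repressed, zero =
#' neutral); there is no null model, so no significance is attached.  When a
#' planted truth (named vector of +1 for planted-up, -1 for planted-down
#' pathways) is supplied -- e.g. from the synthetic-data generator -- sign
#' agreement counts are computed over the perturbed pathways.
#'
#' @param profile output of [computePAS()] or [pasProfile()].
#' @param truth optional named numeric vector of planted directions.
#' @return list with `calls` (the profile) and, when truth is given,
#'   `confusion`: data.frame of per-pathway planted vs observed sign and
#'   counts `n_correct`, `n_wrong`, `n_missing`.
#' @export
classifyPathways <- function(profile, truth = NULL) {
  out <- list(calls = profile)
  if (!is.null(truth)) {
    stopifnot(!is.null(names(truth)))
    obs <- profile[profile$pathway %in% names(truth), ]
    obsSign <- sign(obs$pas)
    plantSign <- sign(truth[obs$pathway])
    conf <- data.frame(pathway = obs$pathway,
                       sample = if ("sample" %in% names(obs)) obs$sample else NA,
                       planted = as.numeric(plantSign),
                       observed = as.numeric(obsSign))
    out$confusion <- conf
    out$n_correct <- sum(!is.na(obsSign) & obsSign == plantSign)
    out$n_wrong <- sum(!is.na(obsSign) & obsSign != plantSign)
    out$n_missing <- sum(is.na(obsSign))
  }
  out
}
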