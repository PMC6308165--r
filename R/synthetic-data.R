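## Seeded generators for every input the pipeline consumes, with known
## ground truth for recovery tests.  Each generator draws from its own
## seeded stream (withr::with_seed), leaving the caller's RNG state alone.

#' Describe a synthetic expression study design
#'
#' Defaults emulate the design of a microarray cytotoxicity study on HL-60
#' cells: untreated controls plus treatment at final peptide concentrations
#' of 1.25, 2.5 and 5 uM, in triplicate, at the scale of ~2016 genes in 334
#' signaling pathways.  For desk-scale tests shrink `n_genes` /
#' `n_pathways` proportionally (e.g. 200 genes, 20 pathways).
#'
#' @param n_genes number of genes.
#' @param probes_per_gene probes synthesized per gene.
#' @param n_pathways number of pathways in the generated database.
#' @param genes_per_pathway genes sampled into each pathway.
#' @param concentrations treatment concentrations (uM), strictly increasing.
#' @param replicates replicates per group (controls and each concentration).
#' @param baseline_log2_mean,baseline_log2_sd log2-intensity distribution of
#'   gene baselines.
#' @param noise_sd per-(gene, sample) log2 measurement noise SD.
#' @param probe_noise_sd per-(probe, sample) log2 noise SD around the gene
#'   value.
#' @param planted_effects named list: pathway id (e.g. `"pw003"`) -> log2
#'   fold-change, scalar or one value per concentration.  Positive values
#'   plant activation (activator genes up, repressors down), negative
#'   repression.
#' @param seed integer seed driving the whole study draw.
#' @return validated list of class `"StudyDesign"`.
#' @export
studyDesign <- function(n_genes = 2016, probes_per_gene = 1, n_pathways = 334,
                        genes_per_pathway = 6,
                        concentrations = c(1.25, 2.5, 5), replicates = 3,
                        baseline_log2_mean = 8, baseline_log2_sd = 2,
                        noise_sd = 0.25, probe_noise_sd = 0.1,
                        planted_effects = list(), seed = 1L) {
  stopifnot(n_genes >= 1, probes_per_gene >= 1, n_pathways >= 1,
            genes_per_pathway >= 1, replicates >= 1,
            noise_sd >= 0, probe_noise_sd >= 0,
            all(diff(concentrations) > 0), all(concentrations > 0))
  if (genes_per_pathway > n_genes)
    stop("genes_per_pathway cannot exceed n_genes")
  structure(as.list(environment()), class = "StudyDesign")
}

.pwId <- function(i) sprintf("pw%03d", i)

#' Generate a synthetic expression study with planted pathway effects
#'
#' Draws log-normal baseline gene intensities, a pathway database with
#' random activator/repressor role (ARR) weights, and probe-level signals
#' for a control group plus treated triplicates per concentration.  In a
#' planted pathway each gene's intensity is multiplied by
#' `2^(lfc * ARR)`: activators move with the planted log2 fold-change,
#' repressors opposite, half-weight genes with half the log effect and
#' ARR = 0 genes not at all -- so the planted PAS direction is coherent and
#' its magnitude analytically known
#' (`lfc * log10(2) * sum(ARR^2) / N` per sample, before noise).
#'
#' @param design a [studyDesign()].
#' @return list with `probes` (`SummarizedExperiment`, probes x samples,
#'   `rowData$gene`, `colData` with `group`/`concentration`/`replicate`),
#'   `db` (a [PathwayDB]) and `truth` (planted directions and magnitudes,
#'   per-gene log2 fold-changes per concentration, expected noise-free PAS
#'   per planted pathway and concentration, and a parameter echo).
#' @export
genExpressionStudy <- function(design) {
  stopifnot(inherits(design, "StudyDesign"))
  d <- design
  withr::with_seed(d$seed, {
    genes <- sprintf("g%04d", seq_len(d$n_genes))

    ## Pathway database: disjoint gene blocks (so a planted effect cannot
    ## bleed into another pathway's score), discrete ARR weights with at
    ## least one non-zero weight per pathway so a planted effect can express.
    if (d$n_pathways * d$genes_per_pathway > d$n_genes)
      stop("disjoint pathway blocks need n_pathways * genes_per_pathway <= n_genes")
    pool <- sample(genes)
    pws <- vector("list", d$n_pathways)
    names(pws) <- .pwId(seq_len(d$n_pathways))
    for (i in seq_len(d$n_pathways)) {
      g <- pool[((i - 1) * d$genes_per_pathway + 1):(i * d$genes_per_pathway)]
      repeat {
        w <- sample(.ARR_VOCAB, length(g), replace = TRUE,
                    prob = c(0.2, 0.1, 0.15, 0.15, 0.4))
        if (any(w != 0)) break
      }
      pws[[i]] <- setNames(w, g)
    }
    db <- pathwayDB(pws)

    bad <- setdiff(names(d$planted_effects), names(pws))
    if (length(bad))
      stop("planted pathway id(s) not in the generated database: ",
           paste(bad, collapse = ", "))

    nConc <- length(d$concentrations)
    samples <- c(sprintf("ctrl_%d", seq_len(d$replicates)),
                 as.vector(t(outer(seq_len(nConc), seq_len(d$replicates),
                   function(i, r) sprintf("c%g_r%d", d$concentrations[i], r)))))
    colData <- S4Vectors::DataFrame(
      group = rep(c("control", "treated"), c(d$replicates, nConc * d$replicates)),
      concentration = c(rep(0, d$replicates),
                        rep(d$concentrations, each = d$replicates)),
      replicate = c(seq_len(d$replicates),
                    rep(seq_len(d$replicates), times = nConc)),
      row.names = samples)

    baseline <- rnorm(d$n_genes, d$baseline_log2_mean, d$baseline_log2_sd)

    ## Per-gene planted log2 fold-change at each concentration.
    lfcGene <- matrix(0, d$n_genes, nConc,
                      dimnames = list(genes, as.character(d$concentrations)))
    for (pw in names(d$planted_effects)) {
      lfc <- rep_len(d$planted_effects[[pw]], nConc)
      arr <- pws[[pw]]
      for (ci in seq_len(nConc))
        lfcGene[names(arr), ci] <- lfcGene[names(arr), ci] + lfc[ci] * arr
    }

    log2Gene <- matrix(baseline, d$n_genes, length(samples),
                       dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      cc <- colData$concentration[j]
      if (colData$group[j] == "treated")
        log2Gene[, j] <- log2Gene[, j] + lfcGene[, match(cc, d$concentrations)]
    }
    if (d$noise_sd > 0)
      log2Gene <- log2Gene + matrix(rnorm(length(log2Gene), 0, d$noise_sd),
                                    nrow(log2Gene))

    probeGene <- rep(genes, each = d$probes_per_gene)
    probeIds <- sprintf("%s_p%d", probeGene,
                        rep(seq_len(d$probes_per_gene), times = d$n_genes))
    log2Probe <- log2Gene[probeGene, , drop = FALSE]
    if (d$probe_noise_sd > 0)
      log2Probe <- log2Probe + matrix(rnorm(length(log2Probe), 0, d$probe_noise_sd),
                                      nrow(log2Probe))
    probeMat <- 2^log2Probe
    dimnames(probeMat) <- list(probeIds, samples)

    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(signal = probeMat),
      rowData = S4Vectors::DataFrame(probe_id = probeIds, gene = probeGene,
                                     row.names = probeIds),
      colData = colData)

    expectedPAS <- NULL
    if (length(d$planted_effects)) {
      expectedPAS <- sapply(names(d$planted_effects), function(pw) {
        lfc <- rep_len(d$planted_effects[[pw]], nConc)
        arr <- pws[[pw]]
        lfc * log10(2) * sum(arr^2) / length(arr)
      })
      expectedPAS <- matrix(expectedPAS, nrow = nConc,
                            dimnames = list(as.character(d$concentrations),
                                            names(d$planted_effects)))
    }

    list(probes = se, db = db,
         truth = list(
           planted = d$planted_effects,
           direction = vapply(d$planted_effects,
                              function(v) sign(v[1]), numeric(1)),
           gene_log2fc = lfcGene,
           expected_pas = expectedPAS,
           design = unclass(d)))
  })
}

#' Generate a four-parameter logistic dose-response dataset
#'
#' Mean responses on the 4PL curve plus i.i.d. Gaussian noise per replicate.
#'
#' @param ic50 planted midpoint (same units as `doses`).
#' @param hill slope factor; positive = falling curve (viability),
#'   negative = rising (hemolysis).
#' @param top,bottom plateaus, percent.
#' @param doses tested doses (>= 4 distinct, strictly positive).
#' @param noise_sd Gaussian response noise SD, percentage points.
#' @param replicates replicates per dose.
#' @param seed integer seed.
#' @return a [doseResponseDataset()].
#' @export
genDoseResponse <- function(ic50, hill = 2, top = 100, bottom = 0,
                            doses = 10^seq(-1, 1.2, length.out = 8),
                            noise_sd = 5, replicates = 3, seed = 1L) {
  stopifnot(ic50 > 0, all(doses > 0), noise_sd >= 0, replicates >= 1)
  withr::with_seed(seed, {
    conc <- rep(doses, each = replicates)
    mu <- .fourPL(conc, top, bottom, log10(ic50), hill)
    resp <- mu + rnorm(length(conc), 0, noise_sd)
    doseResponseDataset(conc, resp,
                        replicate = rep(seq_len(replicates), times = length(doses)))
  })
}

.DEFAULT_CLOUDS <- data.frame(
  quadrant = c("viable", "early_apoptotic", "late_apoptotic_necrotic",
               "av_neg_pi_pos"),
  mean_av = c(1.5, 3.0, 3.0, 1.5),   # log10 intensity
  mean_pi = c(1.5, 1.5, 3.0, 3.0),
  sd_av = 0.15, sd_pi = 0.15)

#' Generate a synthetic AV/PI event table
#'
#' A mixture of four bivariate log-normal clouds (one per quadrant) with
#' planted weights.  Default cloud centres sit at 10^1.5 (negative) and
#' 10^3 (positive) AU per channel with SD 0.15 on the log10 scale, well
#' separated by gates around 10^2.25 ~ 178 AU.
#'
#' @param fractions length-4 numeric (viable, early apoptotic, late
#'   apoptotic/necrotic, AV-PI+), summing to 1.
#' @param channel_params data.frame like the default: per quadrant
#'   `mean_av`, `mean_pi`, `sd_av`, `sd_pi` on the log10 scale.
#' @param n_events number of events (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `av`, `pi`, `component` (the sampled
#'   quadrant, for truth checks).
#' @export
genCytometry <- function(fractions, channel_params = .DEFAULT_CLOUDS,
                         n_events = 10000, seed = 1L) {
  stopifnot(length(fractions) == 4, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0), n_events >= 1)
  if (any(channel_params$sd_av < 0) || any(channel_params$sd_pi < 0))
    stop("channel SDs must be non-negative")
  withr::with_seed(seed, {
    comp <- sample.int(4, n_events, replace = TRUE, prob = fractions)
    av <- 10^rnorm(n_events, channel_params$mean_av[comp],
                   channel_params$sd_av[comp])
    pi <- 10^rnorm(n_events, channel_params$mean_pi[comp],
                   channel_params$sd_pi[comp])
    data.frame(event_id = seq_len(n_events), av = av, pi = pi,
               component = channel_params$quadrant[comp])
  })
}

#' Generate a synthetic plate reading
#'
#' Back-computes sample optical densities from planted percentages through
#' the assay's own formula (so a zero-noise plate round-trips exactly), and
#' adds Gaussian OD noise.  Control wells use the assay's role vocabulary:
#' hemolysis `zero_lysis_control`/`full_lysis_control`, LDH
#' `spontaneous`/`maximal`, MTT `blank`/`untreated`.
#'
#' @param assay `"hemolysis"`, `"ldh"` or `"mtt"`.
#' @param true_percent_per_dose named numeric: names are doses (uM), values
#'   the planted percent (hemolysis/release/viability).
#' @param control_ods length-2 numeric `c(low, high)`: the negative- and
#'   positive-control OD levels (for MTT, blank and untreated).
#' @param noise_sd OD noise SD (AU) applied to every well.
#' @param replicates wells per condition.
#' @param seed integer seed.
#' @return data.frame with columns `well`, `role`, `concentration_uM`,
#'   `replicate`, `od`.
#' @export
genPlate <- function(assay = c("hemolysis", "ldh", "mtt"),
                     true_percent_per_dose,
                     control_ods = c(low = 0.1, high = 1.0),
                     noise_sd = 0, replicates = 3, seed = 1L) {
  assay <- match.arg(assay)
  stopifnot(length(control_ods) == 2, control_ods[2] > control_ods[1],
            noise_sd >= 0, replicates >= 1,
            !is.null(names(true_percent_per_dose)))
  roles <- switch(assay,
    hemolysis = c("zero_lysis_control", "full_lysis_control"),
    ldh = c("spontaneous", "maximal"),
    mtt = c("blank", "untreated"))
  lo <- control_ods[[1]]; hi <- control_ods[[2]]
  withr::with_seed(seed, {
    doses <- as.numeric(names(true_percent_per_dose))
    sampleOD <- lo + true_percent_per_dose / 100 * (hi - lo)
    rows <- rbind(
      data.frame(role = roles[1], concentration_uM = NA_real_,
                 replicate = seq_len(replicates), od_mean = lo),
      data.frame(role = roles[2], concentration_uM = NA_real_,
                 replicate = seq_len(replicates), od_mean = hi),
      data.frame(role = "sample",
                 concentration_uM = rep(doses, each = replicates),
                 replicate = rep(seq_len(replicates), times = length(doses)),
                 od_mean = rep(sampleOD, each = replicates)))
    od <- rows$od_mean + rnorm(nrow(rows), 0, noise_sd)
    data.frame(well = sprintf("W%02d", seq_len(nrow(rows))),
               role = rows$role, concentration_uM = rows$concentration_uM,
               replicate = rows$replicate, od = pmax(od, 0))
  })
}

#' Quantify a plate into percent responses
#'
#' Applies the assay's percent formula to each sample well, using the mean
#' OD of the matching control roles.
#'
#' @param plate data.frame from [genPlate()] or [readPlate()].
#' @param assay `"hemolysis"`, `"ldh"` or `"mtt"`.
#' @return data.frame with `concentration`, `response` (percent),
#'   `replicate`, suitable for [fitDoseResponse()] / [hc50()].
#' @export
quantifyPlate <- function(plate, assay = c("hemolysis", "ldh", "mtt")) {
  assay <- match.arg(assay)
  roles <- switch(assay,
    hemolysis = c("zero_lysis_control", "full_lysis_control"),
    ldh = c("spontaneous", "maximal"),
    mtt = c("blank", "untreated"))
  fun <- switch(assay, hemolysis = hemolysisPercent, ldh = ldhReleasePercent,
                mtt = function(s, lo, hi) mttViabilityPercent(s, hi, lo))
  lo <- mean(plate$od[plate$role == roles[1]])
  hi <- mean(plate$od[plate$role == roles[2]])
  if (!is.finite(lo) || !is.finite(hi))
    stop(sprintf("plate lacks '%s'/'%s' control wells", roles[1], roles[2]))
  s <- plate[plate$role == "sample", ]
  data.frame(concentration = s$concentration_uM,
             response = fun(s$od, lo, hi),
             replicate = s$replicate)
}
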