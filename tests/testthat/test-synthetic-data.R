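test_that("all generators are deterministic in their seed and leave the RNG alone", {
  des <- studyDesign(n_genes = 40, n_pathways = 4, genes_per_pathway = 6, seed = 7)
  a <- genExpressionStudy(des); b <- genExpressionStudy(des)
  expect_identical(SummarizedExperiment::assay(a$probes),
                   SummarizedExperiment::assay(b$probes))
  expect_identical(a$db@pathways, b$db@pathways)

  expect_identical(genDoseResponse(3, seed = 5), genDoseResponse(3, seed = 5))
  expect_false(identical(genDoseResponse(3, seed = 5)$response,
                         genDoseResponse(3, seed = 6)$response))
  expect_identical(genCytometry(c(.7, .1, .1, .1), n_events = 100, seed = 2),
                   genCytometry(c(.7, .1, .1, .1), n_events = 100, seed = 2))
  expect_identical(genPlate("mtt", c(`1` = 80, `2` = 50, `4` = 20, `8` = 5),
                            noise_sd = 0.02, seed = 3),
                   genPlate("mtt", c(`1` = 80, `2` = 50, `4` = 20, `8` = 5),
                            noise_sd = 0.02, seed = 3))

  set.seed(99); before <- .Random.seed
  invisible(genDoseResponse(3, seed = 5))
  expect_identical(before, .Random.seed)
})

test_that("noiseless dose-response data sit exactly on the 4PL curve", {
  doses <- c(0.5, 1, 2, 4, 8)
  d <- genDoseResponse(ic50 = 2, hill = 1, top = 100, bottom = 0,
                       doses = doses, noise_sd = 0, replicates = 2, seed = 1)
  expect_equal(d$response[d$concentration == 2], c(50, 50))  # midpoint identity
  expected <- 100 / (1 + (doses / 2))  # hill = 1 closed form
  expect_equal(as.numeric(tapply(d$response, d$concentration, unique)[as.character(doses)]),
               expected, tolerance = 1e-12)
})

test_that("cytometry generator honors degenerate weights and single events", {
  all.viable <- genCytometry(c(1, 0, 0, 0), n_events = 200, seed = 4)
  expect_true(all(all.viable$component == "viable"))
  one <- genCytometry(c(0, 0, 1, 0), n_events = 1, seed = 4)
  expect_equal(nrow(one), 1L)
  expect_equal(one$component, "late_apoptotic_necrotic")
  expect_error(genCytometry(c(.5, .5, .2, 0), n_events = 10), "sum")
})

test_that("plates round-trip planted percentages exactly at zero noise", {
  pl <- genPlate("hemolysis", c(`12.5` = 0, `25` = 10, `50` = 50, `100` = 100),
                 noise_sd = 0, seed = 1)
  q <- quantifyPlate(pl, "hemolysis")
  expect_equal(as.numeric(tapply(q$response, q$concentration, unique)),
               c(0, 10, 50, 100))
  pm <- genPlate("mtt", c(`1` = 100, `3` = 50, `6` = 0, `10` = 0),
                 noise_sd = 0, seed = 1)
  qm <- quantifyPlate(pm, "mtt")
  expect_equal(as.numeric(tapply(qm$response, qm$concentration, unique)),
               c(100, 50, 0, 0))
  pl2 <- genPlate("ldh", c(`1` = 25, `2` = 50, `4` = 75, `8` = 100),
                  noise_sd = 0, seed = 1)
  q2 <- quantifyPlate(pl2, "ldh")
  expect_equal(as.numeric(tapply(q2$response, q2$concentration, unique)),
               c(25, 50, 75, 100))
})

test_that("a planted rising hemolysis curve is recovered by the HC50 fit", {
  doses <- 10^seq(0.5, 2.6, length.out = 8)
  truth <- 100 / (1 + (100 / doses)^2)  # rising 4PL, hc50 = 100, hill 2
  pl <- genPlate("hemolysis", setNames(truth, doses), noise_sd = 0.01,
                 control_ods = c(0.05, 1.2), seed = 11)
  f <- hc50(quantifyPlate(pl, "hemolysis"))
  expect_equal(f@ic50, 100, tolerance = 0.05)
})

test_that("expression studies with no planted effect and no noise give PAS 0 everywhere", {
  des <- studyDesign(n_genes = 60, n_pathways = 6, genes_per_pathway = 8,
                     noise_sd = 0, probe_noise_sd = 0, seed = 10)
  st <- genExpressionStudy(des)
  expr <- aggregateProbes(st$probes)
  for (s in c("c1.25_r1", "c5_r3"))
    expect_equal(computePAS(computeCNR(expr, s, ctrlSamples()), st$db)$pas,
                 rep(0, 6))
})

test_that("a planted 2-fold activation is scored positive in every treated sample, others zero", {
  des <- studyDesign(n_genes = 80, n_pathways = 8, genes_per_pathway = 8,
                     noise_sd = 0, probe_noise_sd = 0,
                     planted_effects = list(pw004 = 1), seed = 12)
  st <- genExpressionStudy(des)
  expr <- aggregateProbes(st$probes)
  treated <- setdiff(colnames(expr), ctrlSamples())
  for (s in treated) {
    p <- computePAS(computeCNR(expr, s, ctrlSamples()), st$db)
    expect_gt(p$pas[p$pathway == "pw004"], 0)
    expect_equal(p$pas[p$pathway != "pw004"], rep(0, 7))
    # analytic magnitude: lfc * log10(2) * sum(ARR^2) / N
    arr <- pathwayGenes(st$db, "pw004")
    expect_equal(p$pas[p$pathway == "pw004"],
                 log10(2) * sum(arr^2) / length(arr), tolerance = 1e-9)
  }
  expect_error(genExpressionStudy(
    studyDesign(n_genes = 80, n_pathways = 8, genes_per_pathway = 8,
                planted_effects = list(nope = 1), seed = 1)),
    "not in the generated database")
})

test_that("recovery error grows monotonically with generator noise", {
  medErr <- vapply(c(0, 5, 15), function(ns) {
    errs <- vapply(1:9, function(s) {
      d <- genDoseResponse(ic50 = 5, hill = 2, noise_sd = ns, seed = s,
                           doses = 10^seq(-0.5, 1.5, length.out = 8))
      abs(fitDoseResponse(d, max_dose = Inf)@ic50 - 5) / 5
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(medErr) > 0) || (medErr[1] == 0 && medErr[2] < medErr[3]))
})
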