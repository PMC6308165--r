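test_that("probe aggregation takes floored geometric means per gene", {
  m <- matrix(c(4, 9, 5), ncol = 1, dimnames = list(c("p1", "p2", "p3"), "s1"))
  gene <- c("gA", "gA", "gB")
  e <- aggregateProbes(m, gene)
  expect_equal(e["gA", "s1"], 6)       # sqrt(4 * 9)
  expect_equal(e["gB", "s1"], 5)       # single probe passes through
  m0 <- matrix(c(0, 4), ncol = 1, dimnames = list(c("p1", "p2"), "s1"))
  expect_equal(aggregateProbes(m0, c("g", "g"), floor = 1)[1, 1], 2)  # sqrt(1*4)
  expect_error(aggregateProbes(m, gene, floor = 0), "strictly positive")
})

test_that("quantile normalization equalizes distributions rank-wise", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6))
  rownames(m) <- paste0("g", 1:3)
  qn <- quantileNormalize(m)
  expect_equal(unname(qn[, "s1"]), c(1.5, 3.0, 4.5))  # hand-computed row means of sorted columns
  expect_equal(unname(qn[, "s2"]), c(1.5, 3.0, 4.5))

  # identical columns are left unchanged
  mi <- cbind(a = c(5, 1, 9), b = c(5, 1, 9))
  expect_equal(quantileNormalize(mi), mi, ignore_attr = TRUE)

  # permuting gene order permutes the output identically
  set.seed(2)
  m2 <- matrix(rexp(60), 20, 3, dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  perm <- sample(20)
  expect_equal(quantileNormalize(m2)[perm, ], quantileNormalize(m2[perm, ]))

  # idempotence
  q1 <- quantileNormalize(m2)
  expect_equal(quantileNormalize(q1), q1, tolerance = 1e-12)

  expect_warning(one <- quantileNormalize(m2[, 1, drop = FALSE]), ">= 2 samples")
  expect_equal(one, m2[, 1, drop = FALSE])
})

test_that("CNR is the case-to-control-mean ratio per gene", {
  m <- cbind(c1 = c(10, 8), c2 = c(20, 8), c3 = c(30, 8), case = c(15, 16))
  rownames(m) <- c("g1", "g2")
  cnr <- computeCNR(m, "case", c("c1", "c2", "c3"))
  expect_equal(unname(cnr["g1"]), 0.75)   # 15 / mean(10,20,30)
  expect_equal(unname(cnr["g2"]), 2)
  # a sample identical to every control has CNR 1 everywhere
  mi <- cbind(c1 = c(3, 7), c2 = c(3, 7), case = c(3, 7))
  rownames(mi) <- c("g1", "g2")
  expect_equal(unname(computeCNR(mi, "case", c("c1", "c2"))), c(1, 1))
  expect_error(computeCNR(m, "c1", c("c1", "c2")), "cannot be part")
  z <- cbind(c1 = c(0, 1), case = c(1, 1)); rownames(z) <- c("g1", "g2")
  expect_error(computeCNR(z, "case", "c1"), "strictly positive")
})

test_that("PAS reproduces the worked activator/repressor example", {
  p <- computePAS(toyCNR, toyDB())
  # brute-force oracle: (1*1 + (-1)*1 + 0.5*2 + 0*log10(5)) / 4
  expect_equal(p$pas, 0.25)
  expect_equal(p$n_genes_used, 4L)
  expect_equal(p$call, "activated")
})

test_that("PAS is zero at CNR = 1, missing genes shrink N, empty pathways are NA", {
  db <- pathwayDB(list(p1 = c(A = 1, B = -1), p2 = c(X = 1, Y = 0.5)))
  flat <- c(A = 1, B = 1, X = 1, Y = 1)
  expect_equal(computePAS(flat, db)$pas, c(0, 0))
  expect_equal(computePAS(flat, db)$call, c("neutral", "neutral"))
  # only A measured: N = 1, not 2
  part <- computePAS(c(A = 10, X = 1, Y = 1), db)
  expect_equal(part$pas[part$pathway == "p1"], 1)
  expect_equal(part$n_genes_used[part$pathway == "p1"], 1L)
  # no p2 gene measured -> missing, not zero
  none <- computePAS(c(A = 10, B = 2), db)
  expect_true(is.na(none$pas[none$pathway == "p2"]))
  expect_error(computePAS(c(A = -1), db), "strictly positive")
})

test_that("PAS obeys the CNR scaling law and size-weighted additivity", {
  set.seed(7)
  genes <- paste0("g", 1:12)
  arr <- setNames(sample(c(-1, -0.5, 0, 0.5, 1), 12, replace = TRUE), genes)
  cnr <- setNames(10^runif(12, -1, 1), genes)
  dbAB <- pathwayDB(list(A = arr[1:5], B = arr[6:12], AB = arr))
  p <- computePAS(cnr, dbAB)
  pasA <- p$pas[p$pathway == "A"]; pasB <- p$pas[p$pathway == "B"]
  expect_equal(p$pas[p$pathway == "AB"], (5 * pasA + 7 * pasB) / 12,
               tolerance = 1e-12)
  for (c0 in c(0.1, 3, 42)) {
    shifted <- computePAS(cnr * c0, dbAB)
    expect_equal(shifted$pas[shifted$pathway == "AB"],
                 p$pas[p$pathway == "AB"] + log10(c0) * sum(arr) / 12,
                 tolerance = 1e-12)
  }
})

test_that("profiles stack per-sample scores and optional concentration means", {
  des <- studyDesign(n_genes = 60, n_pathways = 6, genes_per_pathway = 8,
                     noise_sd = 0, probe_noise_sd = 0,
                     planted_effects = list(pw002 = 1), seed = 2)
  st <- genExpressionStudy(des)
  expr <- aggregateProbes(st$probes)
  prof <- pasProfile(expr, st$db, group_means = TRUE)
  expect_setequal(unique(prof$sample),
                  c(colnames(expr)[4:12], sprintf("conc_%g", c(1.25, 2.5, 5))))
  up <- prof[prof$pathway == "pw002" & !startsWith(prof$sample, "conc"), ]
  expect_true(all(up$pas > 0))
  expect_true(all(up$call == "activated"))
})

test_that("sign calls agree with a planted perturbation truth", {
  des <- studyDesign(n_genes = 100, n_pathways = 10, genes_per_pathway = 8,
                     noise_sd = 0, probe_noise_sd = 0,
                     planted_effects = list(pw001 = 1, pw005 = -1), seed = 3)
  st <- genExpressionStudy(des)
  expr <- aggregateProbes(st$probes)
  p <- computePAS(computeCNR(expr, "c2.5_r1", ctrlSamples()), st$db)
  res <- classifyPathways(p, truth = c(pw001 = 1, pw005 = -1))
  expect_equal(res$n_correct, 2L)
  expect_equal(res$n_wrong, 0L)
  expect_equal(res$n_missing, 0L)
})
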