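toy_cq <- function() {
  data.frame(sample = rep(c("S1", "S2"), each = 6),
             group = rep(c("a", "b"), each = 6),
             gene = rep(rep(c("g1", "g2"), each = 3), 2),
             replicate = rep(1:3, 4),
             cq = c(20, 20, 20, 22, 22, 22, 22, 22, 22, 25, 25, 25),
             stringsAsFactors = FALSE)
}

test_that("replicate collapse gives mean, SD and SE with n-1 denominator", {
  d <- data.frame(sample = "S1", group = "a", gene = "g",
                  replicate = 1:3, cq = c(20, 20, 20))
  m <- collapse_replicates(d)
  expect_equal(m$cq, 20); expect_equal(m$sd, 0)
  d2 <- d[1:2, ]; d2$cq <- c(19, 21)
  m2 <- collapse_replicates(d2)
  expect_equal(m2$cq, 20)
  expect_equal(m2$sd, sqrt(2))
  d1 <- d[1, ]; d1$cq <- 25
  expect_warning(m1 <- collapse_replicates(d1), "single replicate")
  expect_equal(m1$cq, 25); expect_equal(m1$se, 0)
})

test_that("relative quantities are efficiency-corrected and calibrated", {
  m <- collapse_replicates(toy_cq())
  # E = 1: S2 is 2 cycles later for g1 -> two doublings less
  rq1 <- cq_to_rq(m, efficiency_set(c(g1 = 1, g2 = 1)))
  expect_equal(unname(rq1$rq["g1", ]), c(1, 0.25))
  expect_equal(unname(rq1$rq["g2", ]), c(1, 2^-3))
  expect_identical(unname(rq1$calibrator), c("S1", "S1"))
  # every gene has RQ = 1 exactly at its calibrator, and RQ <= 1 elsewhere
  expect_true(all(rq1$rq <= 1))
  # E = 0.9 for a 3-cycle offset gives 1.9^-3
  rq2 <- cq_to_rq(m, efficiency_set(c(g1 = 1, g2 = 0.9)))
  expect_equal(unname(rq2$rq["g2", "S2"]), 1.9^-3)
  # missing efficiency is an error
  expect_error(cq_to_rq(m, efficiency_set(c(g1 = 1))), "g2")
})

test_that("RQ standard errors follow the delta method", {
  m <- collapse_replicates(toy_cq())
  m$se <- 0.2
  rq <- cq_to_rq(m, efficiency_set(c(g1 = 1, g2 = 1)))
  expect_equal(unname(rq$se["g1", "S2"]), 0.25 * log(2) * 0.2)
})

test_that("incomplete samples are dropped before analysis", {
  d <- collapse_replicates(toy_cq())
  d <- d[!(d$sample == "S2" & d$gene == "g2"), ]
  d3 <- rbind(d, data.frame(sample = "S3", group = "b", gene = c("g1", "g2"),
                            n = 1L, cq = c(21, 23), sd = NA_real_, se = 0))
  expect_message(rq <- cq_to_rq(d3, efficiency_set(c(g1 = 1, g2 = 1))), "S2")
  expect_identical(colnames(rq$rq), c("S1", "S3"))
})

test_that("normalization factors are geometric means with propagated error", {
  m <- rq_matrix(rbind(g1 = c(1, 1, 0.5), g2 = c(4, 1, 0.5),
                       g3 = c(1, 1, 0.5)))
  # f = 1 is the identity on that gene's RQ
  nf1 <- normalization_factor(m, "g2")
  expect_equal(unname(nf1$nf), c(4, 1, 0.5))
  # {1, 4} -> 2; {0.5, 0.5, 0.5} -> 0.5
  expect_equal(unname(normalization_factor(m, c("g1", "g2"))$nf[1]), 2)
  expect_equal(unname(normalization_factor(m, c("g1", "g2", "g3"))$nf[3]), 0.5)
  expect_error(normalization_factor(m, character(0)), "at least one")
  # SE: NF * (1/f) * sqrt(sum relative SEs squared)
  se <- rbind(g1 = c(0.1, 0, 0), g2 = c(0.4, 0, 0), g3 = c(0, 0, 0))
  m2 <- rq_matrix(m$rq, se = se)
  nf <- normalization_factor(m2, c("g1", "g2"))
  expect_equal(unname(nf$se[1]), 2 * 0.5 * sqrt(0.1^2 + 0.1^2))
})

test_that("normalized relative quantities rescale to the chosen group", {
  rq <- rq_matrix(rbind(tgt = c(1, 2, 4, 8), ref = c(1, 1, 1, 1)),
                  groups = setNames(c("a", "b", "c", "d"), sprintf("S%02d", 1:4)))
  nf <- normalization_factor(rq, "ref")
  nrq <- normalized_rq(rq, "tgt", nf, rescale_group = "a")
  expect_equal(nrq$nrq, c(1, 2, 4, 8))
  # a target identical to the factor is flat at 1
  nrq2 <- normalized_rq(rq, "ref", nf, rescale_group = "a")
  expect_equal(nrq2$nrq, rep(1, 4))
  expect_error(normalized_rq(rq, "tgt", nf, rescale_group = "z"), "rescale")
})

test_that("zero-noise simulation round-trips the generating fold profile", {
  genes <- c(lapply(1:3, function(i) gene_sim_spec(paste0("ref", i))),
             list(gene_sim_spec("tgt", profile = c(1, 2, 8, 4))))
  spec <- cq_sim_spec(genes, groups = rep(c("a", "b", "c", "d"), each = 2),
                      n_replicates = 2, loading_sd = 0.5, seed = 3)
  sim <- simulate_cq(spec)
  eff <- unit_efficiencies(c(paste0("ref", 1:3), "tgt"))
  rq <- cq_to_rq(collapse_replicates(sim$data), eff)
  nf <- normalization_factor(rq, paste0("ref", 1:3))
  nrq <- normalized_rq(rq, "tgt", nf, rescale_group = "a")
  prof <- tapply(nrq$nrq, nrq$group, mean)
  expect_equal(as.numeric(prof[c("a", "b", "c", "d")]), c(1, 2, 8, 4),
               tolerance = 1e-9)
})

test_that("Pfaffl ratios reduce to 2^ddCq at unit efficiency", {
  m <- data.frame(sample = rep(c("S1", "S2"), each = 2),
                  group = rep(c("green", "pink"), each = 2),
                  gene = rep(c("tgt", "ref"), 2),
                  cq = c(25, 20, 22, 20))
  eff <- efficiency_set(c(tgt = 1, ref = 1))
  # dCq_t = 3, dCq_r = 0 -> 8; identical shifts cancel to 1
  expect_equal(pfaffl_ratio(m, "tgt", "ref", "pink", "green", eff), 8)
  m2 <- m; m2$cq <- c(25, 23, 22, 20)
  expect_equal(pfaffl_ratio(m2, "tgt", "ref", "pink", "green", eff), 1)
  # efficiency-corrected closed form
  m3 <- data.frame(sample = rep(c("S1", "S2"), each = 2),
                   group = rep(c("green", "pink"), each = 2),
                   gene = rep(c("tgt", "ref"), 2),
                   cq = c(25, 20, 25 - 3.2, 20 - 1.1))
  eff3 <- efficiency_set(c(tgt = 0.95, ref = 0.90))
  expect_equal(pfaffl_ratio(m3, "tgt", "ref", "pink", "green", eff3),
               1.95^3.2 / 1.90^1.1)
  expect_error(pfaffl_ratio(m, "tgt", "ref", "blue", "green", eff), "blue")
})

test_that("gene- and sample-wise Cq shifts behave as pure rescalings", {
  base <- toy_cq()
  eff <- efficiency_set(c(g1 = 1, g2 = 1))
  rq0 <- cq_to_rq(collapse_replicates(base), eff)
  # shifting one gene's Cq by a constant leaves Pfaffl ratios unchanged
  shifted <- base
  shifted$cq[shifted$gene == "g1"] <- shifted$cq[shifted$gene == "g1"] + 2.7
  p0 <- pfaffl_ratio(collapse_replicates(base), "g1", "g2", "b", "a", eff)
  p1 <- pfaffl_ratio(collapse_replicates(shifted), "g1", "g2", "b", "a", eff)
  expect_equal(p0, p1, tolerance = 1e-10)
  # shifting every gene in one sample divides its RQ and NF alike
  shifted2 <- base
  sel <- shifted2$sample == "S2"
  shifted2$cq[sel] <- shifted2$cq[sel] + 1.3
  rq2 <- cq_to_rq(collapse_replicates(shifted2), eff)
  nf0 <- normalization_factor(rq0, c("g1", "g2"))
  nf2 <- normalization_factor(rq2, c("g1", "g2"))
  expect_equal(unname(rq0$rq[, "S2"] / rq2$rq[, "S2"]),
               rep(2^1.3, 2), tolerance = 1e-10)
  expect_equal(unname(nf0$nf["S2"] / nf2$nf["S2"]), 2^1.3, tolerance = 1e-10)
  # so the normalized quantity at that sample is unchanged
  n0 <- normalized_rq(rq0, "g1", nf0)
  n2 <- normalized_rq(rq2, "g1", nf2)
  expect_equal(n0$nrq, n2$nrq, tolerance = 1e-10)
})
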