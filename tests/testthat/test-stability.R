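test_that("M is zero for proportional genes and ranks constancy first", {
  m <- rq_matrix(rbind(g1 = c(1, 2, 4), g2 = 3 * c(1, 2, 4)))
  expect_equal(unname(genorm_m(m)), c(0, 0))
  m3 <- rq_matrix(rbind(A = c(1, 1, 1, 1), B = c(1, 2, 1, 2),
                        C = c(1, 0.5, 1, 0.5)))
  M <- genorm_m(m3)
  expect_equal(M, oracle_genorm_m(m3$rq), tolerance = 1e-14)
  # B and C are anti-correlated, so the flat gene is the most stable
  expect_lt(M["A"], min(M["B"], M["C"]))
  expect_error(genorm_m(rq_matrix(rbind(A = c(1, 2)))), "2 genes")
})

test_that("M is invariant to per-gene and per-sample rescaling", {
  for (s in 1:20) {
    m <- random_rq_matrix(s)
    M0 <- genorm_m(rq_matrix(m))
    g_scale <- exp(rnorm(nrow(m)))
    s_scale <- exp(rnorm(ncol(m)))
    M1 <- genorm_m(rq_matrix(m * g_scale))
    M2 <- genorm_m(rq_matrix(sweep(m, 2, s_scale, "*")))
    expect_equal(M0, M1, tolerance = 1e-10)
    expect_equal(M0, M2, tolerance = 1e-10)
  }
})

test_that("stepwise elimination matches the brute-force oracle", {
  for (s in 1:50) {
    m <- random_rq_matrix(s)
    rk <- genorm_rank(rq_matrix(m))
    orc <- oracle_elimination(m)
    expect_identical(attr(rk, "elimination_order"), orc$order)
    expect_identical(sort(rk$gene[rk$rank == 1]), orc$final_pair)
    # reported M at elimination equals the oracle M at that step
    retained <- rownames(m)
    for (g in orc$order) {
      expect_equal(rk$M[rk$gene == g],
                   unname(oracle_genorm_m(m[retained, , drop = FALSE])[g]),
                   tolerance = 1e-12)
      retained <- setdiff(retained, g)
    }
  }
})

test_that("exactly two genes share the final (best) rank", {
  for (s in c(3, 17, 42)) {
    rk <- genorm_rank(rq_matrix(random_rq_matrix(s, n_genes = 6)))
    expect_identical(sum(rk$rank == 1), 2L)
    expect_setequal(rk$rank, c(1, 1, 3:6))
  }
})

test_that("ties eliminate the later gene label first and are logged", {
  m <- rq_matrix(rbind(A = c(1, 2, 4, 8), B = c(1, 2, 4, 8),
                       C = c(2, 4, 8, 16)))
  rk <- genorm_rank(m)
  # all three proportional: all M = 0, C removed first by label order
  expect_equal(rk$M, rep(0, 3))
  expect_identical(attr(rk, "elimination_order"), "C")
  expect_match(attr(rk, "ties"), "eliminated C")
  expect_setequal(rk$gene[rk$rank == 1], c("A", "B"))
})

test_that("adding noise to a gene raises its M in expectation", {
  deltas <- vapply(1:100, function(s) {
    set.seed(s)
    base <- matrix(exp(rnorm(5 * 8, 0, 0.2)), 5, 8,
                   dimnames = list(paste0("g", 1:5), NULL))
    M0 <- oracle_genorm_m(base)["g1"]
    noisy <- base
    noisy["g1", ] <- noisy["g1", ] * exp(rnorm(8, 0, 0.5))
    M1 <- genorm_m(rq_matrix(noisy))["g1"]
    M1 - M0
  }, 0)
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.9)
})

test_that("qBase CVs match a direct spreadsheet-style recomputation", {
  m <- rbind(g1 = c(1, 0.8, 0.5, 0.9), g2 = c(0.9, 1, 0.6, 0.8),
             g3 = c(0.2, 0.3, 0.1, 0.25))
  rq <- rq_matrix(m)
  res <- qbase_cv(rq)
  # direct recomputation: geometric-mean factor, per-gene CV, arithmetic mean
  nf <- apply(m, 2, function(x) prod(x)^(1 / 3))
  cvs <- apply(sweep(m, 2, nf, "/"), 1, function(x) sd(x) / mean(x))
  expect_equal(res$cv, cvs, tolerance = 1e-12)
  expect_equal(res$mean_cv, mean(cvs), tolerance = 1e-12)
  # one reference normalizes to itself: CV 0
  expect_equal(unname(qbase_cv(rq, "g1")$cv), 0)
  # proportional references: all normalized series constant
  prop <- rq_matrix(rbind(a = c(1, 2, 3), b = c(2, 4, 6)))
  expect_equal(qbase_cv(prop)$mean_cv, 0, tolerance = 1e-12)
})

test_that("acceptability uses strict thresholds on M and CV", {
  cls <- classify_acceptability(c(g1 = 0.49, g2 = 0.51, g3 = 0.5),
                                c(g1 = 0.24, g2 = 0.1, g3 = 0.1))
  expect_identical(cls$gene$accepted, c(TRUE, FALSE, FALSE))
  setc <- classify_acceptability(c(a = 0.4, b = 0.4), c(a = 0.35, b = 0.18))
  expect_false(setc$set$accepted)  # genes stable but the set's mean CV too high
  expect_equal(setc$set$mean_cv, 0.265)
  expect_true(classify_acceptability(c(a = 0.4, b = 0.4),
                                     c(a = 0.2, b = 0.2))$set$accepted)
})

test_that("the fitted stability report is coherent end to end", {
  sim <- simulate_cq(recovery_panel_spec(101))
  eff <- unit_efficiencies(unique(sim$data$gene))
  fit <- gene_stability(sim$data, eff)
  expect_s3_class(fit, "stability_report")
  expect_identical(sum(fit$ranking$rank == 1), 2L)
  expect_identical(sort(fit$ranking$rank), sort(c(1L, 1L, 3:10)))
  expect_false(any(fit$ranking$flagged))  # all M far below geNorm's 1.5
  expect_identical(names(coef(fit)), fit$ranking$gene)
  s <- summary(fit)
  expect_identical(s$best_pair, fit$best_pair)
  expect_output(print(fit), "best pair")
  expect_output(print(s), "elimination order")
})

test_that("stable genes outrank regulated genes on simulated panels", {
  hits <- vapply(1:25, function(s) {
    sim <- simulate_cq(recovery_panel_spec(1000 + s))
    fit <- gene_stability(sim$data, unit_efficiencies(unique(sim$data$gene)))
    all(grepl("^stab", fit$best_pair))
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("reference-set comparison detects peak-shifting references", {
  m <- rq_matrix(rbind(r1 = c(1, 1, 1, 1), r2 = c(1, 1.05, 1, 0.95),
                       bad = c(1, 0.25, 2, 1),
                       tgt = c(1, 2, 8, 4)),
                 groups = setNames(c("a", "b", "c", "d"), sprintf("S%02d", 1:4)))
  # identical sets: every fold exactly 1, SEM 0
  same <- compare_reference_sets(m, c("r1", "r2"), c("r1", "r2"))
  expect_equal(same$fold$fold, rep(1, 4))
  expect_equal(same$sem_fold, 0)
  expect_equal(same$max_abs_log2_fold, 0)
  # adding a gene proportional to a mutually-proportional set changes nothing
  mp <- rq_matrix(rbind(p1 = c(1, 2, 4, 8), p2 = 3 * c(1, 2, 4, 8),
                        p3 = 0.5 * c(1, 2, 4, 8)))
  prop <- compare_reference_sets(mp, c("p1", "p2"), c("p1", "p2", "p3"))
  expect_equal(prop$fold$fold, rep(1, 4), tolerance = 1e-12)
  # a compensating unstable single reference moves the target's peak
  cmp <- compare_reference_sets(m, c("r1", "r2"), "bad", targets = "tgt",
                                rescale_group = "a")
  expect_identical(cmp$targets$tgt$peak_a, "c")
  expect_true(cmp$targets$tgt$peak_shifted)
})
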