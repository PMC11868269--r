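test_that("relative quantities follow (1+E)^-dCt with per-gene min referencing", {
  m <- make_ct(rbind(gA = c(20, 21, 22)))
  q <- relative_quantities(m)
  expect_equal(unname(q$q["gA", ]), c(1, 0.5, 0.25))

  q2 <- relative_quantities(make_ct(rbind(gA = c(20, 21))),
                            efficiencies = 0.9)
  expect_equal(unname(q2$q["gA", ]), c(1, 1 / 1.9), tolerance = 1e-12)

  # per-gene shift leaves the Q row unchanged
  a <- relative_quantities(make_ct(rbind(gA = c(20, 21, 22),
                                         gB = c(18, 19, 17))))
  b <- relative_quantities(make_ct(rbind(gA = c(20, 21, 22) + 3,
                                         gB = c(18, 19, 17))))
  expect_equal(a$q, b$q)
  expect_true(all(apply(a$q, 1, max) == 1))
})

test_that("delta-Ct scores match hand arithmetic and the pairwise oracle", {
  m2 <- make_ct(rbind(gA = c(20, 21, 22, 23), gB = c(22, 23, 24, 25)))
  s2 <- delta_ct_stability(m2)
  expect_equal(s2$score, c(0, 0))  # constant offset

  m2b <- make_ct(rbind(gA = c(20, 20.5, 19.8), gB = c(22, 22.1, 22.6)))
  s2b <- delta_ct_stability(m2b)
  expect_equal(s2b$score[1], s2b$score[2])  # two genes: symmetric
  expect_equal(s2b$score[1], sd(m2b$ct[1, ] - m2b$ct[2, ]))

  f1 <- fixture_f1()
  s <- delta_ct_stability(f1)
  expect_equal(sd(f1$ct["g1", ] - f1$ct["g2", ]), 0.0957, tolerance = 1e-3)
  expect_equal(setNames(s$score, s$gene_id), oracle_delta_ct(f1$ct),
               tolerance = 1e-12)

  expect_error(delta_ct_stability(make_ct(rbind(gA = c(20, 21, 22)))),
               "at least 2")
})

test_that("geNorm M equals the delta-Ct score at E = 1 and responds to duplicated rows", {
  f1 <- fixture_f1()
  M <- genorm_m_values(relative_quantities(f1))
  s <- delta_ct_stability(f1)
  expect_equal(M$score, s$score, tolerance = 1e-9)
  expect_equal(setNames(M$score, M$gene_id),
               oracle_genorm_m(oracle_q(f1$ct)), tolerance = 1e-12)

  # an exact duplicate pair has pairwise SD 0, lowering both genes' M
  dup <- make_ct(rbind(g1 = f1$ct["g1", ], g2 = f1$ct["g2", ],
                       g3 = f1$ct["g3", ], g1b = f1$ct["g1", ]))
  Md <- genorm_m_values(relative_quantities(dup))
  expect_lt(Md$score[Md$gene_id == "g1"], M$score[M$gene_id == "g1"])
})

test_that("cross-method identity M == delta-Ct holds on random matrices", {
  for (seed in 1:25) {
    m <- random_ct_matrix(5, 8, seed = seed)
    M <- genorm_m_values(relative_quantities(m))
    s <- delta_ct_stability(m)
    expect_equal(M$score, s$score, tolerance = 1e-9)
  }
})

test_that("geNorm stepwise exclusion and pairwise variation match brute force", {
  # g3 carries a large independent condition effect -> excluded first
  withr::with_seed(4, {
    base <- rnorm(8, 0, 0.1)
    ct <- rbind(g1 = 20 + base + rnorm(8, 0, 0.05),
                g2 = 22 + base + rnorm(8, 0, 0.05),
                g3 = 25 + rnorm(8, 0, 1.5),
                g4 = 24 + base + rnorm(8, 0, 0.3))
  })
  m <- make_ct(ct)
  q <- relative_quantities(m)
  tr <- genorm_ranking(q)
  br <- oracle_genorm_exclusion(oracle_q(ct))
  expect_equal(tr$exclusion$gene_id[1], "g3")
  expect_equal(tr$exclusion$gene_id, br$excluded)
  expect_setequal(tr$final_pair, br$final_pair)
  expect_setequal(tr$ranking, rownames(ct))

  # NF for two genes is the per-sample sqrt of the product
  qq <- q$q[tr$ranking[1:2], ]
  nf2 <- sqrt(qq[1, ] * qq[2, ])
  v23 <- oracle_v_value(oracle_q(ct), tr$ranking[1:2], tr$ranking[1:3])
  expect_equal(tr$v$v[tr$v$n == 2], v23, tolerance = 1e-12)
  expect_equal(nf2, exp(colMeans(log(qq))), tolerance = 1e-12)

  expect_error(genorm_ranking(relative_quantities(
    make_ct(ct[1:2, ]))), "at least 3")
})

test_that("appending a lower-ranked duplicate of the top gene leaves V(2/3) on the original top pair unchanged", {
  withr::with_seed(9, {
    common <- rnorm(10, 0, 0.05)
    ct <- rbind(g1 = 20 + common + rnorm(10, 0, 0.02),
                g2 = 21 + common + rnorm(10, 0, 0.02),
                g3 = 23 + common + rnorm(10, 0, 0.4),
                g4 = 24 + rnorm(10, 0, 1.2))
  })
  q1 <- relative_quantities(make_ct(ct))
  tr1 <- genorm_ranking(q1)
  top2 <- tr1$ranking[1:2]
  v_direct <- oracle_v_value(oracle_q(ct), top2, tr1$ranking[1:3])
  expect_equal(tr1$v$v[tr1$v$n == 2], v_direct, tolerance = 1e-12)
})

test_that("NormFinder matches the straight-line oracle for one group", {
  f1 <- fixture_f1()
  nf <- normfinder_stability(relative_quantities(f1))
  br <- oracle_normfinder(oracle_q(f1$ct))
  expect_equal(setNames(nf$scores$score, nf$scores$gene_id), br$rho,
               tolerance = 1e-9)
  for (seed in 1:10) {
    m <- random_ct_matrix(5, 8, seed = seed)
    nf <- normfinder_stability(relative_quantities(m))
    br <- oracle_normfinder(oracle_q(m$ct))
    expect_equal(setNames(nf$scores$score, nf$scores$gene_id), br$rho,
                 tolerance = 1e-9)
    expect_equal(order(nf$scores$score), order(br$rho))
  }
})

test_that("grouped NormFinder matches the oracle and centers deviations within groups", {
  for (seed in 1:10) {
    n_groups <- 2L + (seed %% 3L)
    S <- 4L * n_groups
    m <- random_ct_matrix(5, S, seed = 100 + seed)
    grouping <- rep(paste0("grp", seq_len(n_groups)), each = 4L)
    nf <- normfinder_stability(relative_quantities(m), grouping = grouping)
    br <- oracle_normfinder(oracle_q(m$ct), groups = grouping)
    expect_equal(setNames(nf$scores$score, nf$scores$gene_id), br$rho,
                 tolerance = 1e-9)
    expect_true(all(abs(colSums(nf$detail$d)) < 1e-9))
    expect_equal(nf$detail$gamma2, br$gamma2, tolerance = 1e-9)
  }
})

test_that("NormFinder degenerate inputs behave as documented", {
  # all genes constant -> all stability values 0
  m <- make_ct(rbind(gA = rep(20, 4), gB = rep(22, 4), gC = rep(25, 4)))
  nf <- normfinder_stability(relative_quantities(m))
  expect_equal(nf$scores$score, c(0, 0, 0))

  q <- relative_quantities(random_ct_matrix(5, 8, seed = 2))
  expect_error(normfinder_stability(q, grouping = c(rep("a", 7), "b")),
               "at least 2 samples")
  q2 <- relative_quantities(random_ct_matrix(2, 8, seed = 2))
  expect_error(normfinder_stability(q2), "at least 3")

  # identical group structure -> gamma2 collapses to 0 and pooled fallback
  ct <- random_ct_matrix(4, 6, seed = 3)$ct
  m2 <- make_ct(cbind(ct, ct))
  nf2 <- normfinder_stability(relative_quantities(m2),
                              grouping = rep(c("a", "b"), each = 6))
  expect_true(nf2$detail$pooled_fallback)
  expect_equal(nf2$detail$gamma2, 0)
  expect_true(all(nf2$scores$score >= 0))
})

test_that("BestKeeper statistics match direct arithmetic and the SD < 1 flag", {
  m <- make_ct(rbind(gA = c(19, 20, 21), gB = c(30, 30.1, 29.9),
                     gC = rep(20, 3)))
  bk <- bestkeeper_stats(m)
  a <- bk[bk$gene_id == "gA", ]
  expect_equal(a$sd_ct, 1.0)
  expect_equal(a$cv_pct, 5.0)
  expect_false(a$stable)           # flag is false exactly when SD >= 1
  expect_true(all(bk$stable == (bk$sd_ct < 1.0)))
  expect_equal(bk$gene_id, c("gC", "gB", "gA"))  # ordered by SD (ties by CV)
  c_row <- bk[bk$gene_id == "gC", ]
  expect_equal(c_row$sd_ct, 0)
  expect_equal(c_row$cv_pct, 0)

  for (seed in 1:5) {
    mm <- random_ct_matrix(5, 8, seed = seed)
    got <- bestkeeper_stats(mm)
    br <- oracle_bestkeeper(mm$ct)
    got <- got[match(br$gene_id, got$gene_id), ]
    expect_equal(got$sd_ct, br$sd_ct, tolerance = 1e-12)
    expect_equal(got$cv_pct, br$cv_pct, tolerance = 1e-12)
    expect_equal(got$r_index, br$r_index, tolerance = 1e-12)
  }
})

test_that("per-gene Ct shifts and permutations leave scores invariant as documented", {
  m <- random_ct_matrix(5, 8, seed = 42)
  shift <- m$ct + matrix(c(1, -2, 0.5, 3, -1), 5, 8)
  ms <- make_ct(shift)

  s0 <- delta_ct_stability(m)
  s1 <- delta_ct_stability(ms)
  expect_equal(s1$score, s0$score, tolerance = 1e-9)

  M0 <- genorm_m_values(relative_quantities(m))
  M1 <- genorm_m_values(relative_quantities(ms))
  expect_equal(M1$score, M0$score, tolerance = 1e-9)
  expect_equal(genorm_ranking(relative_quantities(ms))$ranking,
               genorm_ranking(relative_quantities(m))$ranking)

  n0 <- normfinder_stability(relative_quantities(m))
  n1 <- normfinder_stability(relative_quantities(ms))
  expect_equal(n1$scores$score, n0$scores$score, tolerance = 1e-9)

  # BestKeeper: SD unchanged, CV changes (documented asymmetry)
  b0 <- bestkeeper_stats(m)
  b1 <- bestkeeper_stats(ms)
  expect_equal(sort(b1$sd_ct), sort(b0$sd_ct), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(sort(b1$cv_pct), sort(b0$cv_pct))))

  # sample and gene permutations
  perm_cols <- m$ct[, sample(8)]
  perm <- make_ct(perm_cols[c(3, 1, 5, 2, 4), ])
  sp <- delta_ct_stability(perm)
  expect_equal(setNames(sp$score, sp$gene_id)[s0$gene_id],
               setNames(s0$score, s0$gene_id), tolerance = 1e-9)
  bp <- bestkeeper_stats(perm)
  expect_equal(bp$sd_ct, b0$sd_ct, tolerance = 1e-9)
})

test_that("inflating a gene's condition-effect SD raises its expected score under every method", {
  score_matrix <- function(tau3) {
    genes <- data.frame(gene_id = paste0("g", 1:4),
                        base_ct = c(20, 22, 24, 26),
                        tau = c(0.1, 0.1, tau3, 0.1),
                        sigma_bio = 0.2, sigma_tech = 0)
    cells <- data.frame(condition = paste0("c", 1:8), timepoint = "0")
    spec <- synthetic_spec(genes, cells, n_bio = 2L, n_tech = 1L)
    vapply(1:20, function(s) {
      sim <- simulate_ct_experiment(spec, rng_seed = s)
      m <- sim$ct
      q <- relative_quantities(m)
      c(delta_ct = delta_ct_stability(m)$score[3],
        genorm = genorm_m_values(q)$score[3],
        normfinder = normfinder_stability(q)$scores$score[3],
        bestkeeper = setNames(bestkeeper_stats(m)$sd_ct,
                              bestkeeper_stats(m)$gene_id)["g3"])
    }, numeric(4))
  }
  lo <- rowMeans(score_matrix(0.3))
  hi <- rowMeans(score_matrix(1.2))
  expect_true(all(hi > lo))
})
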