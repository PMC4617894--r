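test_that("jaccard_matrix computes pairwise overlap correctly", {
  J <- jaccard_matrix(list(a = c("r1", "r2", "r3"),
                           b = c("r2", "r3", "r4"),
                           c = c("r1", "r2", "r3"),
                           d = c("x1", "x2")))$matrix
  expect_equal(J["a", "b"], 0.5)          # 2 shared of 4 total
  expect_equal(J["a", "c"], 1)
  expect_equal(J["a", "d"], 0)
  expect_equal(diag(J), c(a = 1, b = 1, c = 1, d = 1))
  expect_identical(J, t(J))
  expect_true(all(J >= 0 & J <= 1))
})

test_that("pathway_activity reports retained fractions per subsystem", {
  toy <- make_toy_model()
  cons <- restrict_model(toy, fastcc(toy))
  ctx <- reconstruct(cons, core_sets(core = "R2"))
  pa <- pathway_activity(ctx, cons)
  rownames(pa) <- pa$subsystem
  expect_equal(pa["PathX", "fraction"], 1)     # R1, R2 both retained
  expect_equal(pa["PathY", "fraction"], 0)     # R3 not retained
  expect_equal(pa["Exchange", "fraction"], 2 / 3)  # R_EXA, R_EXC of three

  # empty context: all fractions zero
  empty <- ctx
  empty$retained <- character(0)
  expect_true(all(pathway_activity(empty, cons)$fraction == 0))
  # full context: all fractions one
  full <- ctx
  full$retained <- reaction_ids(cons)
  expect_true(all(pathway_activity(full, cons)$fraction == 1))
  # the min_reactions flag drops small subsystems
  expect_equal(nrow(pathway_activity(ctx, cons, min_reactions = 3)), 1)
})

test_that("pathway_regulation applies (up - down) / size", {
  toy <- make_toy_model()
  ctx <- reconstruct(restrict_model(toy, fastcc(toy)), core_sets(core = "R2"))
  # PathX has 2 reactions; mark R1 up
  pr <- pathway_regulation(ctx, toy, up = "R1", down = character(0))
  rownames(pr) <- pr$subsystem
  expect_equal(pr["PathX", "score"], 0.5)
  pr2 <- pathway_regulation(ctx, toy, up = c("R1", "R2"), down = character(0))
  rownames(pr2) <- pr2$subsystem
  expect_equal(pr2["PathX", "score"], 1)
  pr3 <- pathway_regulation(ctx, toy, up = "R1", down = "R2")
  rownames(pr3) <- pr3$subsystem
  expect_equal(pr3["PathX", "score"], 0)
  expect_true(all(pr$score >= -1 & pr$score <= 1))
})

test_that("condition_rank averages replicates and ranks with ties", {
  expr <- matrix(c(5, 3, 1), 1, 3,
                 dimnames = list("g", c("c1", "c2", "c3")))
  r <- condition_rank(expr, c("c1", "c2", "c3"))
  expect_equal(r["g", ], c(c1 = 1, c2 = 2, c3 = 3))

  tie <- matrix(c(5, 5, 1), 1, 3,
                dimnames = list("g", c("c1", "c2", "c3")))
  rt <- condition_rank(tie, c("c1", "c2", "c3"))
  expect_equal(rt["g", ], c(c1 = 1.5, c2 = 1.5, c3 = 3))

  single <- matrix(4, 1, 1, dimnames = list("g", "c1"))
  expect_equal(condition_rank(single, "c1")["g", "c1"], 1)

  # replicates aggregate by mean before ranking
  rep2 <- matrix(c(1, 9, 4, 4), 1, 4, dimnames = list("g", NULL))
  rr <- condition_rank(rep2, c("A", "A", "B", "B"))
  expect_equal(rr["g", ], c(A = 1, B = 2))   # mean 5 vs 4
})

test_that("gene knockouts follow the one-percent essentiality rule", {
  # GA controls the high-capacity transporter, GB a tiny parallel one
  m <- contextcore:::build_model(
    mets_df(c("A_e", "A_c")),
    list(EX = list(mets = c(A_e = -1), lb = -1000, ub = 1000,
                   subsystem = "Exchange"),
         TA = list(mets = c(A_e = -1, A_c = 1), lb = 0, ub = 100,
                   gpr = "GA", subsystem = "Transport"),
         TB = list(mets = c(A_e = -1, A_c = 1), lb = 0, ub = 0.5,
                   gpr = "GB", subsystem = "Transport"),
         BIO = list(mets = c(A_c = -1), lb = 0, ub = 1000,
                    subsystem = "Biomass")),
    objective = "BIO")
  res <- gene_knockouts(m, "BIO")
  rownames(res) <- res$gene
  expect_equal(res["GA", "wt_growth"], 100.5, tolerance = 1e-6)
  expect_true(res["GA", "essential"])        # ~99.5 % drop
  expect_false(res["GB", "essential"])       # ~0.498 % drop < 1 %
  expect_equal(res["GB", "decrease"], 0.5 / 100.5, tolerance = 1e-6)

  # isozyme rescue: both genes in an OR rule are non-essential
  m2 <- contextcore:::build_model(
    mets_df(c("A_e", "A_c")),
    list(EX = list(mets = c(A_e = -1), lb = -1000, ub = 1000),
         TA = list(mets = c(A_e = -1, A_c = 1), lb = 0, ub = 100,
                   gpr = "GA or GB"),
         BIO = list(mets = c(A_c = -1), lb = 0, ub = 1000)),
    objective = "BIO")
  res2 <- gene_knockouts(m2, "BIO")
  expect_false(any(res2$essential))

  # sole controller of the only biomass path: growth zero, essential
  m3 <- contextcore:::build_model(
    mets_df(c("A_e", "A_c")),
    list(EX = list(mets = c(A_e = -1), lb = -1000, ub = 1000),
         TA = list(mets = c(A_e = -1, A_c = 1), lb = 0, ub = 100,
                   gpr = "GA"),
         BIO = list(mets = c(A_c = -1), lb = 0, ub = 1000)),
    objective = "BIO")
  res3 <- gene_knockouts(m3, "BIO")
  expect_equal(res3$ko_growth, 0, tolerance = 1e-9)
  expect_true(res3$essential)

  # a gene absent from every GPR changes nothing
  res4 <- gene_knockouts(m3, "BIO", genes = "GHOST")
  expect_equal(res4$ko_growth, res4$wt_growth)
  expect_false(res4$essential)
})

test_that("rank_set_enrichment returns KS and permutation statistics", {
  same <- rank_set_enrichment(1:50, 1:50, n_null = 200, seed = 1)
  expect_equal(same$D, 0)
  expect_equal(same$p_ks, 1)

  sep <- rank_set_enrichment(1:20, 101:200, n_null = 200, seed = 1)
  expect_equal(sep$D, 1)
  expect_lt(sep$p_ks, 1e-6)
  expect_lte(sep$p_perm, 0.05)
})

test_that("hypergeometric tail matches exact enumeration", {
  expect_equal(hypergeom_enrichment(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(10, 5, 4, 0), 1)
  # brute-force agreement over a grid with N <= 12
  for (N in c(5, 8, 12)) for (K in c(2, N %/% 2)) for (n in c(2, N %/% 2)) {
    for (k in 0:min(K, n)) {
      expect_equal(hypergeom_enrichment(N, K, n, k),
                   oracle_hyper_tail(N, K, n, k), tolerance = 1e-12)
    }
  }
})
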