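test_that("Yule trees are ultrametric with the requested tip count", {
  t2 <- yule_tree(2, 5, seed = 1)
  expect_identical(ape::Ntip(t2), 2L)
  el <- t2$edge.length
  expect_equal(el[1], el[2])  # a single cherry with equal pendant edges

  t20 <- yule_tree(20, 5, seed = 2)
  expect_identical(ape::Ntip(t20), 20L)
  expect_true(ape::is.ultrametric(t20, tol = 1e-6))
  expect_true(all(t20$edge.length >= 0))

  # deterministic given the seed
  expect_identical(ape::write.tree(yule_tree(20, 5, seed = 7)),
                   ape::write.tree(yule_tree(20, 5, seed = 7)))
})

test_that("mean Yule root height matches the analytic expectation", {
  n <- 10; lambda <- 2; reps <- 500
  set.seed(123)
  hts <- replicate(reps, max(ape::node.depth.edgelength(yule_tree(n, lambda))))
  expected <- sum(1 / (lambda * (2:n)))
  se <- sqrt(sum(1 / (lambda * (2:n))^2) / reps)
  expect_lt(abs(mean(hts) - expected), 3 * se)
})

test_that("grafting reroutes the recipient and conserves everything else", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")

  # height 0.5 on a hand-built tree: LCA(A,B) at height 1, so tau = 0.5
  gt <- graft_hgt(tree, "A", "B", 0.5)
  cg <- ape::cophenetic.phylo(gt)
  expect_equal(cg["A", "B"], 1)                   # 2 * tau
  expect_equal(cg["A", "C"], 4)                   # follows B's lineage
  expect_equal(cg["C", "D"], 3)                   # untouched
  expect_equal(cg["B", "C"], 4)
  expect_true(ape::is.ultrametric(gt, tol = 1e-9))

  # height 1: the gene tree keeps all species-tree distances
  g1 <- ape::cophenetic.phylo(graft_hgt(tree, "A", "B", 1))
  co <- ape::cophenetic.phylo(tree)
  nm <- rownames(co)
  expect_equal(g1[nm, nm], co[nm, nm], tolerance = 1e-9)

  # height 0: transfer at the leaves, identical gene copies
  g0 <- ape::cophenetic.phylo(graft_hgt(tree, "A", "B", 0))
  expect_equal(g0["A", "B"], 0)

  expect_error(graft_hgt(tree, "A", "A", 0.5), "distinct")
  expect_error(graft_hgt(tree, "A", "B", 1.5), "height")
  bad <- tree; bad$edge.length[1] <- 9
  expect_error(graft_hgt(bad, "A", "B", 0.5), "ultrametric")
})

test_that("grafted strain distance is monotone in height; others fixed", {
  set.seed(17)
  tree <- yule_tree(12, 5)
  sp <- sample(tree$tip.label, 2)
  others <- setdiff(tree$tip.label, sp)
  co <- ape::cophenetic.phylo(tree)
  lca_h <- co[sp[1], sp[2]] / 2
  d_prev <- -1
  for (h in seq(0, 1, by = 0.2)) {
    cg <- ape::cophenetic.phylo(graft_hgt(tree, sp[1], sp[2], h))
    expect_equal(cg[sp[1], sp[2]], 2 * h * lca_h, tolerance = 1e-9)
    expect_gt(cg[sp[1], sp[2]], d_prev)
    expect_equal(cg[others, others], co[others, others], tolerance = 1e-9)
    # donor-side distances unchanged too
    expect_equal(cg[sp[2], others], co[sp[2], others], tolerance = 1e-9)
    d_prev <- cg[sp[1], sp[2]]
  }
})

test_that("JC evolution: zero branches copy, divergence matches closed form", {
  frozen <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  s <- evolve_jc(frozen, 50, seed = 3)
  expect_identical(unname(s["A"]), unname(s["B"]))
  expect_identical(unname(s["A"]), unname(s["C"]))

  tr <- ape::read.tree(text = "(A:0.15,B:0.15);")
  s <- evolve_jc(tr, 80, seed = 4)
  expect_identical(nchar(unname(s)), c(80L, 80L))
  expect_true(all(strsplit(paste(s, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))

  # empirical mismatch fraction vs (3/4)(1 - exp(-4 d / 3)) at d = 0.3
  set.seed(5)
  l <- 500; reps <- 200
  hs <- replicate(reps, {
    s <- evolve_jc(tr, l)
    hamming_distance(s[["A"]], s[["B"]])$h
  })
  p <- jc_to_hamming(0.3)
  se <- sqrt(p * (1 - p) / (l * reps))
  expect_lt(abs(mean(hs) - p), 3 * se)
})

test_that("replicates are deterministic and maximal at a leaf-level event", {
  r1 <- run_replicate(n_taxa = 10, gene_length = 100, hgt_height = 0.3,
                      seed = 99)
  r2 <- run_replicate(n_taxa = 10, gene_length = 100, hgt_height = 0.3,
                      seed = 99)
  expect_identical(r1, r2)
  expect_named(r1$distances, c("d_gw_ref", "d_gh_ref", "d_gw_s", "d_gh_s"))

  # transfer at the leaves with a long gene: identification is certain
  set.seed(100)
  rej <- replicate(30, run_replicate(gene_length = 10000,
                                     hgt_height = 0)$reject)
  expect_true(all(rej))
})

test_that("sweeps average the requested number of replicates per point", {
  sw <- sweep_height(heights = c(0, 0.5), n_replicates = 5, seed = 42)
  expect_s3_class(sw, "hgt_sweep")
  expect_identical(nrow(sw), 2L)
  expect_true(all(sw$rate >= 0 & sw$rate <= 1))
  expect_identical(attr(sw, "n_replicates"), 5)

  sw2 <- sweep_height(heights = c(0, 0.5), n_replicates = 5, seed = 42)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))

  fp <- sweep_fp(lengths = c(30, 60), n_replicates = 5, seed = 8)
  expect_identical(nrow(fp), 2L)
  expect_true(all(fp$rate >= 0 & fp$rate <= 1))
})
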