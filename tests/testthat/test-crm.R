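test_that("expected ratio is the reference-distance quotient", {
  expect_equal(expected_ratio(0.583, 0.541), 1.077, tolerance = 1e-3)
  expect_identical(expected_ratio(0.3, 0.3), 1)
  # divergence time cancels: scaling both distances leaves rho unchanged
  for (c in c(0.1, 2, 17)) {
    expect_equal(expected_ratio(c * 0.583, c * 0.541),
                 expected_ratio(0.583, 0.541))
  }
  expect_error(expected_ratio(0.5, 0), "uninformative witness")
  expect_error(expected_ratio(0.5, Inf), "finite")
})

test_that("expected distance scales the witness strain distance", {
  expect_equal(expected_distance(1.077, 0.0237), 0.0255,
               tolerance = 5e-5 / 0.0255)
  expect_identical(expected_distance(1, 0.042), 0.042)
  expect_identical(expected_distance(2.5, 0), 0)
  expect_error(expected_distance(-1, 0.1), "positive")
})

test_that("two-cell and closed-form chi-square agree and match hand sums", {
  # worked example at the precision its inputs are printed
  expect_equal(chi_square_stat(1472, 0.00795, 0.02507), 17.65,
               tolerance = 0.01 / 17.65)
  expect_identical(chi_square_stat(500, 0.2, 0.2), 0)

  # explicit two-cell oracle at l = 100
  O <- c(10, 90); E <- c(20, 80)
  expect_equal(chi_square_stat(100, 0.10, 0.20), sum((O - E)^2 / E))

  expect_error(chi_square_stat(100, 0.1, 0), "degenerate")
  expect_error(chi_square_stat(100, 0.1, 1), "degenerate")
  expect_error(chi_square_stat(0, 0.1, 0.2), "length")
})

test_that("chi-square is invariant under complementing both fractions", {
  set.seed(21)
  for (i in 1:50) {
    l <- sample(10:5000, 1)
    ho <- runif(1, 0, 0.99); he <- runif(1, 0.01, 0.99)
    expect_equal(chi_square_stat(l, ho, he),
                 chi_square_stat(l, 1 - ho, 1 - he))
  }
})

test_that("1-DoF upper-tail probability matches the normal-tail oracle", {
  expect_identical(chi_square_pvalue(0), 1)
  # X ~ chi2_1 is Z^2: P(X > x) = 2 (1 - Phi(sqrt(x)))
  for (x in c(0.5, 3.841, 6.635, 17.65)) {
    expect_equal(chi_square_pvalue(x), 2 * (1 - pnorm(sqrt(x))),
                 tolerance = 1e-9)
  }
  expect_equal(chi_square_pvalue(3.841), 0.05, tolerance = 1e-3)
  expect_equal(chi_square_pvalue(17.65), 2.7e-5, tolerance = 0.02)
})

test_that("a single CRM test composes the three stages verbatim", {
  set.seed(31)
  l <- 600
  base_h <- random_dna(l); base_w <- random_dna(l)
  aln <- list(
    gh = ortholog_alignment("gh", c(
      s1 = base_h, s2 = mutate_sites(base_h, 4),
      r1 = mutate_sites(base_h, 3), r2 = mutate_sites(base_h, 150))),
    gw = ortholog_alignment("gw", c(
      s1 = base_w, s2 = mutate_sites(base_w, 12),
      r1 = mutate_sites(base_w, 2), r2 = mutate_sites(base_w, 140)))
  )
  rec <- crm_single_test("gh", "gw", "s1", "s2", "r1", "r2", aln)
  expect_false(rec$skipped)

  # hand-assembled pipeline from the exported primitives
  d <- function(g, x, y) gene_distance(aln[[g]], x, y)
  rho <- expected_ratio(d("gh", "r1", "r2")$jc, d("gw", "r1", "r2")$jc)
  d_exp <- expected_distance(rho, d("gw", "s1", "s2")$jc)
  h_exp <- jc_to_hamming(d_exp)
  chi2 <- chi_square_stat(l, d("gh", "s1", "s2")$hamming, h_exp)
  expect_equal(rec$rho, rho)
  expect_equal(rec$d_exp, d_exp)
  expect_equal(rec$h_exp, h_exp)
  expect_equal(rec$chi2, chi2)
  expect_equal(rec$p, chi_square_pvalue(chi2))
  expect_identical(rec$length, 600L)
  expect_identical(rec$direction,
                   if (rec$d_obs < rec$d_exp) "shorter" else "longer")
})

test_that("worked-example distances flow through the CRM test end to end", {
  # plug the printed JC distances in via the primitives (no sequences)
  rho <- expected_ratio(0.583, 0.541)
  d_exp <- expected_distance(rho, 0.0237)
  chi2 <- chi_square_stat(1472, jc_to_hamming(0.0080), jc_to_hamming(d_exp))
  expect_equal(chi2, 17.65, tolerance = 0.05 / 17.65)
  expect_lt(chi_square_pvalue(chi2), 0.01)
})

test_that("impossible tests are skipped with a reason, never dropped silently", {
  set.seed(41)
  l <- 200
  base <- random_dna(l)
  sat <- mutate_sites(base, 190)  # hamming 0.95: saturated
  aln <- list(
    gh = ortholog_alignment("gh", c(s1 = base, s2 = base,
                                    r1 = base, r2 = sat)),
    gw = ortholog_alignment("gw", c(s1 = base, s2 = mutate_sites(base, 5),
                                    r1 = base, r2 = mutate_sites(base, 50))))
  rec <- crm_single_test("gh", "gw", "s1", "s2", "r1", "r2", aln)
  expect_true(rec$skipped)
  expect_match(rec$reason, "saturated")

  # witness identical between the references: ratio undefined
  aln2 <- list(
    gh = ortholog_alignment("gh", c(s1 = base, s2 = base,
                                    r1 = base, r2 = mutate_sites(base, 50))),
    gw = ortholog_alignment("gw", c(s1 = base, s2 = mutate_sites(base, 5),
                                    r1 = base, r2 = base)))
  expect_match(crm_single_test("gh", "gw", "s1", "s2", "r1", "r2",
                               aln2)$reason, "uninformative witness")

  # missing organism
  aln3 <- list(
    gh = ortholog_alignment("gh", c(s1 = base, s2 = base, r1 = base)),
    gw = aln2$gw)
  expect_match(crm_single_test("gh", "gw", "s1", "s2", "r1", "r2",
                               aln3)$reason, "missing ortholog")
})

test_that("identical strain genomes yield an empty report", {
  ids <- sprintf("g%02d", 1:30)
  gs <- list(A = genome("A", ids), B = genome("B", ids))
  res <- near_hgt(gs, list(), c("A", "B"), c("R1", "R2"), k = 5)
  expect_s3_class(res, "near_hgt")
  expect_identical(nrow(res$report), 0L)
})

test_that("eight strains enumerate 28 unordered pairs", {
  ids <- sprintf("g%02d", 1:30)
  orgs <- paste0("S", 1:8)
  gs <- lapply(orgs, genome, genes = ids)
  names(gs) <- orgs
  res <- near_hgt(gs, list(), orgs, c("R1", "R2"), k = 5)
  expect_length(res$profiles, 28L)
  expect_identical(length(res$profiles), ncol(utils::combn(8, 2)))
})

test_that("Bonferroni correction multiplies by the per-gene test count", {
  fx <- make_fixture(n_strains = 2, n_references = 3, seed = 13)
  res <- near_hgt(fx$genomes, fx$alignments, fx$strains, fx$references)
  expect_gt(nrow(res$tests), 0L)
  by_gene <- split(res$tests, list(res$tests$s1, res$tests$s2, res$tests$gene),
                   drop = TRUE)
  for (df in by_gene) {
    expect_equal(df$p_corrected, pmin(1, df$p * nrow(df)))
    expect_true(all(df$p_corrected >= df$p))
  }
  # witness eligibility: candidates never serve as witnesses
  cand <- unique(res$report$gene)
  expect_false(any(res$tests$witness %in% cand))
})
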