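test_that("neighborhoods respect the radius, wrap-around and linear ends", {
  g25 <- genome("A", sprintf("g%02d", 1:25))
  expect_length(neighborhood(g25, "g01", 10), 20)
  expect_length(neighborhood(g25, "g13", 10), 20)

  g5 <- genome("B", c("a", "b", "c", "d", "e"))
  expect_setequal(neighborhood(g5, "a", 3), c("b", "c", "d", "e"))

  lin <- genome("C", c("a", "b", "c", "d"), topology = "linear")
  expect_setequal(neighborhood(lin, "a", 2), c("b", "c"))
  expect_setequal(neighborhood(lin, "c", 2), c("a", "b", "d"))

  expect_error(neighborhood(g5, "zz", 2), "not in genome")
  expect_error(neighborhood(g5, "a", 0), "k")
})

test_that("synteny index matches direct enumeration and is symmetric", {
  ids <- sprintf("g%02d", 1:25)
  a <- genome("A", ids); b <- genome("B", ids)
  for (g in c("g01", "g12", "g25"))
    expect_identical(synteny_index(g, a, b, 10), 20L)

  # gene absent from one genome has SI 0 by definition
  c25 <- genome("C", c(setdiff(ids, "g05"), "zz"))
  expect_identical(synteny_index("g05", a, c25, 10), 0L)

  g1 <- genome("G1", c("a", "b", "g", "c", "d", "e"))
  g2 <- genome("G2", c("c", "b", "g", "a", "x", "y"))
  expect_identical(synteny_index("g", g1, g2, 2),
                   brute_si("g", g1$genes, g2$genes, 2))

  set.seed(42)
  for (i in 1:25) {
    n <- sample(8:40, 1); k <- sample(1:5, 1)
    pool <- sprintf("x%03d", 1:n)
    p <- genome("P", sample(pool)); q <- genome("Q", sample(pool))
    gene <- sample(pool, 1)
    si <- synteny_index(gene, p, q, k)
    expect_identical(si, synteny_index(gene, q, p, k))
    expect_identical(si, brute_si(gene, p$genes, q$genes, k))
    expect_true(si >= 0 && si <= 2 * k)
  }
})

test_that("average SI identities hold and match the brute-force mean", {
  ids <- sprintf("g%02d", 1:25)
  a <- genome("A", ids)
  expect_identical(average_si(a, a, 10), 1)

  b <- genome("B", paste0("other_", 1:30))
  expect_identical(average_si(a, b, 10), 0)

  g1 <- c("a", "b", "c", "u1", "u2", "u3")
  g2 <- c("c", "b", "a", "v1", "v2", "v3")
  expect_equal(average_si(genome("X", g1), genome("Y", g2), 1),
               brute_average_si(g1, g2, 1))

  set.seed(7)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    shared <- sprintf("s%02d", seq_len(sample(3:n, 1)))
    g1 <- sample(c(shared, sprintf("p%02d", 1:4)))
    g2 <- sample(c(shared, sprintf("q%02d", 1:4)))
    k <- sample(1:4, 1)
    expect_equal(average_si(genome("X", g1), genome("Y", g2), k),
                 brute_average_si(g1, g2, k))
  }
})

test_that("SI cutoff and candidate selection match a count-and-check oracle", {
  # empty low tail: all mass at the top level
  expect_identical(si_cutoff(make_profile(rep(20, 50)), 0.05), -1L)
  # 4 of 100 at zero: 4% < 5%, and the mass at 20 stops the cutoff
  p4 <- make_profile(c(rep(0, 4), rep(20, 96)))
  expect_identical(si_cutoff(p4, 0.05), 0L)
  expect_identical(si_candidates(p4, 0.05)$candidates$gene,
                   sprintf("g%04d", 1:4))
  # 6 of 100 at zero: 6% >= 5%
  expect_identical(si_cutoff(make_profile(c(rep(0, 6), rep(20, 94))), 0.05),
                   -1L)
  expect_identical(nrow(si_candidates(make_profile(rep(20, 40)),
                                      0.05)$candidates), 0L)

  set.seed(99)
  for (i in 1:100) {
    k <- sample(2:10, 1)
    si <- sample(0:(2 * k), sample(20:200, 1), replace = TRUE,
                 prob = stats::dbeta(seq(0.01, 0.99, length.out = 2 * k + 1),
                                     4, 1))
    delta <- stats::runif(1, 0.01, 0.3)
    prof <- make_profile(si, k = k)
    cut <- si_cutoff(prof, delta)
    expect_identical(cut, brute_cutoff(si, delta))
    cand <- si_candidates(prof, delta)$candidates
    expect_setequal(cand$gene, prof$gene[prof$si <= cut])
    if (nrow(cand) > 1) {
      expect_true(all(diff(cand$si) >= 0))
    }
  }
})

test_that("strict candidate rule excludes genes sitting at the cutoff", {
  p <- make_profile(c(rep(0, 2), rep(3, 2), rep(20, 96)))
  expect_identical(si_cutoff(p, 0.05), 3L)
  expect_identical(nrow(si_candidates(p, 0.05, rule = "leq")$candidates), 4L)
  expect_identical(si_candidates(p, 0.05, rule = "lt")$candidates$si,
                   c(0L, 0L))
})

test_that("relocating one gene zeroes its SI and spares distant genes", {
  ids <- sprintf("g%02d", 1:60)
  base <- genome("A", ids)
  k <- 5
  # move g10 (position 10) to between g40 and g41: > 2k away on the circle
  moved <- append(setdiff(ids, "g10"), "g10", after = 39)
  mod <- genome("B", moved)
  prof <- si_profile(base, mod, k = k)
  expect_identical(prof$si[prof$gene == "g10"], 0L)
  # genes farther than k from both the origin and destination sites
  untouched <- sprintf("g%02d", c(20:30, 50:60))
  expect_true(all(prof$si[prof$gene %in% untouched] == 2L * k))
  cand <- si_candidates(prof, 0.05)
  expect_identical(cand$candidates$gene, "g10")
})

test_that("SI histogram tallies union and core masses", {
  ids <- sprintf("g%02d", 1:25)
  h <- si_histogram(si_profile(genome("A", ids), genome("B", ids), 10))
  expect_identical(h$n_union[h$si == 20], 25L)
  expect_identical(sum(h$n_union), 25L)

  dis <- si_histogram(si_profile(genome("A", ids),
                                 genome("B", paste0("z", 1:10)), 10))
  expect_identical(dis$n_union[dis$si == 0], 35L)
  expect_identical(sum(dis$n_union[dis$si > 0]), 0L)

  set.seed(3)
  g1 <- sample(ids); g2 <- sample(ids)
  prof <- si_profile(genome("A", g1), genome("B", g2), 3)
  h <- si_histogram(prof)
  tally <- vapply(0:6, function(v)
    sum(vapply(ids, brute_si, 0L, genes1 = g1, genes2 = g2, k = 3) == v),
    integer(1))
  expect_identical(h$n_union, tally)
})

test_that("recipient inference needs a unique low-SI intersection", {
  ids <- sprintf("g%02d", 1:60)
  relocate <- function(after) append(setdiff(ids, "g10"), "g10", after = after)
  A <- genome("A", relocate(39))  # g10 moved in A only
  B <- genome("B", ids); C <- genome("C", ids)
  profs <- list(si_profile(A, B, 5), si_profile(A, C, 5), si_profile(B, C, 5))
  expect_identical(infer_recipient("g10", profs), "A")

  # low SI in a single pair only: cannot intersect
  expect_identical(infer_recipient("g10", profs[1]), "undetermined")

  # low SI in all three pairs: no unique organism in the intersection
  A2 <- genome("A", relocate(39))
  B2 <- genome("B", relocate(45))
  C2 <- genome("C", relocate(50))
  profs2 <- list(si_profile(A2, B2, 5), si_profile(A2, C2, 5),
                 si_profile(B2, C2, 5))
  expect_identical(infer_recipient("g10", profs2), "undetermined")
})
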