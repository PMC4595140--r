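#' Random ultrametric Yule species tree
#'
#' Pure-birth (Yule) tree: while `k` lineages exist the waiting time to the
#' next speciation is exponential with rate `k * birth_rate`; after the n-th
#' lineage appears one further exponential waiting time (rate
#' `n * birth_rate`) elapses before the present, so all tips are extant and
#' the tree is ultrametric. Branch lengths are on the expected
#' substitutions-per-site scale (rate x time with rate 1). Expected root
#' height is `sum_{k=2}^{n} 1 / (k * birth_rate)`.
#'
#' @param n_taxa Number of tips (`>= 2`).
#' @param birth_rate Speciation rate per lineage (`> 0`).
#' @param labels Optional tip labels (default `t1 .. tn`).
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return An ultrametric `ape::phylo` tree.
#' @export
yule_tree <- function(n_taxa, birth_rate = 5, labels = NULL, seed = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 2L) stop("'n_taxa' must be >= 2")
  if (!is.numeric(birth_rate) || birth_rate <= 0)
    stop("'birth_rate' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_taxa))
  if (length(labels) != n_taxa || anyDuplicated(labels))
    stop("'labels' must be ", n_taxa, " unique names")

  # grow: active lineages carry the time their parent split
  kids <- list(); plen <- numeric(0); birth <- numeric(0)
  new_node <- function() {
    kids[[length(kids) + 1L]] <<- integer(0)
    plen[length(plen) + 1L] <<- NA_real_
    birth[length(birth) + 1L] <<- NA_real_
    length(kids)
  }
  root <- new_node(); birth[root] <- 0
  active <- c(new_node(), new_node())
  kids[[root]] <- active
  birth[active] <- 0
  t_now <- 0
  for (k in 2:(n_taxa - 1L)) {
    if (n_taxa == 2L) break
    t_now <- t_now + stats::rexp(1, k * birth_rate)
    i <- if (length(active) == 1L) active else sample(active, 1L)
    birth_i <- birth[i]
    ch <- c(new_node(), new_node())
    kids[[i]] <- ch
    birth[ch] <- t_now
    plen[i] <- t_now - birth_i
    active <- c(setdiff(active, i), ch)
  }
  t_now <- t_now + stats::rexp(1, n_taxa * birth_rate)
  plen[active] <- t_now - birth[active]
  lab <- character(length(kids))
  lab[active] <- labels[seq_along(active)]
  tree <- ape::read.tree(text = write_newick(root, kids, plen, lab))
  tree
}

# recursive newick writer over a kids/plen/labels node store
write_newick <- function(root, kids, plen, lab) {
  rec <- function(v) {
    if (length(kids[[v]]) == 0L) {
      node <- lab[v]
    } else {
      node <- paste0("(", paste(vapply(kids[[v]], rec, ""), collapse = ","), ")")
    }
    if (is.na(plen[v])) node else paste0(node, ":", sprintf("%.12g", plen[v]))
  }
  paste0(rec(root), ";")
}

tree_node_heights <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}

is_ultrametric_tree <- function(tree, tol = 1e-8) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol * max(d, 1e-12)
}

# phylo -> (kids, plen, lab, root) store used by the tree surgery
phylo_store <- function(tree) {
  n <- ape::Ntip(tree); m <- tree$Nnode
  kids <- vector("list", n + m)
  plen <- rep(NA_real_, n + m)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    kids[[p]] <- c(kids[[p]], c)
    plen[c] <- tree$edge.length[e]
  }
  lab <- character(n + m)
  lab[seq_len(n)] <- tree$tip.label
  list(kids = kids, plen = plen, lab = lab, root = n + 1L)
}

#' Graft an HGT event into a species tree
#'
#' Builds the gene tree of a horizontally transferred gene: the recipient
#' tip `s1` is detached and re-attached onto the lineage of the donor `s2`
#' so that the two coalesce at height `height * t(s1, LCA(s1, s2))` above
#' the present (`height = 0`: transfer at the leaves, identical gene copies;
#' `height = 1`: at the LCA, gene tree equals the species tree). All
#' pairwise path lengths not involving `s1` are untouched and the tree stays
#' ultrametric.
#'
#' @param tree Ultrametric `phylo` tree.
#' @param s1 Recipient tip label (the re-routed lineage).
#' @param s2 Donor tip label.
#' @param height Event height as a fraction of the `s1`-to-LCA path, in
#'   `[0, 1]`.
#' @return The gene tree as a `phylo` object.
#' @export
graft_hgt <- function(tree, s1, s2, height) {
  stopifnot(inherits(tree, "phylo"))
  if (!is_ultrametric_tree(tree)) stop("tree must be ultrametric")
  if (!all(c(s1, s2) %in% tree$tip.label) || s1 == s2)
    stop("'s1' and 's2' must be two distinct tips of the tree")
  if (height < 0 || height > 1) stop("'height' must be in [0, 1]")
  lca <- ape::getMRCA(tree, c(s1, s2))
  tau <- height * tree_node_heights(tree)[lca]

  st <- phylo_store(tree)
  kids <- st$kids; plen <- st$plen; lab <- st$lab; root <- st$root
  parent <- rep(NA_integer_, length(kids))
  for (v in seq_along(kids)) for (c in kids[[v]]) parent[c] <- v

  # detach tip s1, suppressing its now-degree-2 parent
  i1 <- match(s1, lab)
  p <- parent[i1]
  kids[[p]] <- setdiff(kids[[p]], i1)
  if (length(kids[[p]]) == 1L) {
    c <- kids[[p]]
    if (p == root) {
      root <- c; plen[c] <- NA_real_
    } else {
      g <- parent[p]
      kids[[g]][kids[[g]] == p] <- c
      parent[c] <- g
      plen[c] <- plen[c] + plen[p]
    }
    kids[[p]] <- integer(0)
  }

  # heights above present after removal
  h <- rep(NA_real_, length(kids))
  fill_h <- function(v) {
    if (length(kids[[v]]) == 0L) { h[v] <<- 0; return(0) }
    ch <- vapply(kids[[v]], fill_h, 0)
    h[v] <<- ch[1] + plen[kids[[v]][1]]
    h[v]
  }
  fill_h(root)

  new_tip <- length(kids) + 1L
  kids[[new_tip]] <- integer(0)
  plen[new_tip] <- tau
  lab[new_tip] <- s1

  i2 <- match(s2, lab)
  if (tau >= h[root] - 1e-12 * max(h[root], 1)) {
    # event exactly at (or numerically at) the old root
    kids[[root]] <- c(kids[[root]], new_tip)
  } else {
    # find the edge on s2's ancestry spanning height tau and bisect it
    v <- i2
    while (h[parent[v]] < tau) v <- parent[v]
    a <- parent[v]
    x <- length(kids) + 1L
    kids[[x]] <- c(v, new_tip)
    plen[x] <- h[a] - tau
    lab[x] <- ""
    kids[[a]][kids[[a]] == v] <- x
    plen[v] <- tau - h[v]
  }
  ape::read.tree(text = write_newick(root, kids, plen, lab))
}

#' Evolve a gene along a tree under the Jukes-Cantor model
#'
#' Draws a uniform random root sequence over `{A, C, G, T}` and applies, on
#' every branch, the JC substitution process: a site differs from its parent
#' with probability `(3/4)(1 - exp(-(4/3) b))` for branch length `b`
#' (expected substitutions per site), and a changed site takes one of the
#' other three states uniformly.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param length Number of sites (`>= 1`).
#' @param seed Optional integer seed.
#' @return Named character vector of tip sequences.
#' @export
evolve_jc <- function(tree, length, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("'length' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  nnode <- n + tree$Nnode
  bases <- c("A", "C", "G", "T")
  seqs <- matrix(NA_integer_, nrow = nnode, ncol = length)
  root <- n + 1L
  seqs[root, ] <- sample.int(4L, length, replace = TRUE)
  edge <- tree$edge; elen <- tree$edge.length
  ord <- order(ape::node.depth.edgelength(tree)[edge[, 2]])  # parents first
  for (e in ord) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    s <- seqs[p, ]
    pd <- -0.75 * expm1(-(4 / 3) * elen[e])
    hit <- which(stats::runif(length) < pd)
    if (length(hit) > 0L) {
      s[hit] <- (s[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L
    }
    seqs[ch, ] <- s
  }
  out <- apply(seqs[seq_len(n), , drop = FALSE], 1L, function(r)
    paste(bases[r], collapse = ""))
  names(out) <- tree$tip.label
  out
}

# JC distance between two simulated sequences; NA when saturated
sim_jc_distance <- function(a, b) {
  h <- hamming_distance(a, b)$h
  if (h >= 0.75) return(list(h = h, jc = NA_real_, saturated = TRUE))
  list(h = h, jc = jc_correct(h), saturated = FALSE)
}

#' One replicate of the HGT detection simulation
#'
#' Simulates a Yule species tree, picks a strain pair and a disjoint
#' reference pair, evolves a witness gene on the species tree and the
#' transferred gene on the grafted gene tree (or on the species tree for the
#' null / false-positive model), estimates the four JC distances from the
#' simulated sequences, and applies the CRM chi-square test on the Hamming
#' scale. Replicates in which a distance saturates or the expectation
#' degenerates are redrawn (by continuing the RNG stream) and counted.
#'
#' @param n_taxa Number of tips of the species tree.
#' @param gene_length Sites per gene (both genes share it).
#' @param hgt_height Event height in `[0, 1]`, see [graft_hgt()].
#' @param birth_rate Yule speciation rate; controls divergence scale.
#' @param delta_rho Significance level of the chi-square test.
#' @param null_model If `TRUE`, no HGT is grafted (false-positive model).
#' @param s_distance If non-`NULL`, the tree is rescaled so the strain-pair
#'   path length equals this value (substitutions per site).
#' @param s_pair,r_pair Optional fixed tip labels; chosen per
#'   `pair_choice` when `NULL`.
#' @param pair_choice How to choose unspecified pairs on each simulated
#'   tree: `"deep"` (default) picks the most diverged tip pair as strains
#'   and the most diverged pair among the remaining tips as references —
#'   the idealized setting of a power study; `"random"` draws uniform
#'   disjoint pairs.
#' @param seed Optional integer seed.
#' @param max_redraw Redraw budget before giving up.
#' @return List with `reject`, the four JC `distances` (`d_gw_ref`,
#'   `d_gh_ref`, `d_gw_s`, `d_gh_s`), `chi2`, `p` and `redraws`.
#' @export
run_replicate <- function(n_taxa = 20, gene_length = 70, hgt_height = 0.5,
                          birth_rate = 5, delta_rho = 0.01,
                          null_model = FALSE, s_distance = NULL,
                          s_pair = NULL, r_pair = NULL,
                          pair_choice = c("deep", "random"),
                          seed = NULL, max_redraw = 200) {
  pair_choice <- match.arg(pair_choice)
  if (!is.null(seed)) set.seed(seed)
  redraws <- 0L
  repeat {
    tree <- yule_tree(n_taxa, birth_rate)
    tips <- tree$tip.label
    if (pair_choice == "deep" && (is.null(s_pair) || is.null(r_pair))) {
      co <- ape::cophenetic.phylo(tree)
      deepest <- function(m) rownames(m)[which(m == max(m), arr.ind = TRUE)[1, ]]
      sp <- if (is.null(s_pair)) deepest(co) else s_pair
      rest <- setdiff(tips, sp)
      rp <- if (is.null(r_pair)) deepest(co[rest, rest]) else r_pair
    } else {
      sp <- if (is.null(s_pair)) sample(tips, 2L) else s_pair
      rp <- if (is.null(r_pair)) sample(setdiff(tips, sp), 2L) else r_pair
    }
    if (length(intersect(sp, rp)) > 0L) stop("strain and reference pairs overlap")
    if (!is.null(s_distance)) {
      d_now <- tree_pair_distance(tree, sp[1], sp[2])
      tree$edge.length <- tree$edge.length * (s_distance / d_now)
    }
    gene_tree <- if (null_model) tree else
      graft_hgt(tree, sp[1], sp[2], hgt_height)
    seq_w <- evolve_jc(tree, gene_length)
    seq_h <- evolve_jc(gene_tree, gene_length)
    d_gw_ref <- sim_jc_distance(seq_w[[rp[1]]], seq_w[[rp[2]]])
    d_gh_ref <- sim_jc_distance(seq_h[[rp[1]]], seq_h[[rp[2]]])
    d_gw_s <- sim_jc_distance(seq_w[[sp[1]]], seq_w[[sp[2]]])
    d_gh_s <- sim_jc_distance(seq_h[[sp[1]]], seq_h[[sp[2]]])
    ok <- !d_gw_ref$saturated && !d_gh_ref$saturated &&
      !d_gw_s$saturated && !d_gh_s$saturated &&
      d_gw_ref$jc > 0 && d_gh_ref$jc > 0 && d_gw_s$jc > 0
    if (ok) {
      rho <- d_gh_ref$jc / d_gw_ref$jc
      h_exp <- jc_to_hamming(rho * d_gw_s$jc)
      ok <- h_exp > 0 && h_exp < 0.75
    }
    if (ok) {
      chi2 <- chi_square_stat(gene_length, d_gh_s$h, h_exp)
      p <- chi_square_pvalue(chi2)
      return(list(
        reject = p <= delta_rho,
        distances = c(d_gw_ref = d_gw_ref$jc, d_gh_ref = d_gh_ref$jc,
                      d_gw_s = d_gw_s$jc, d_gh_s = d_gh_s$jc),
        chi2 = chi2, p = p, redraws = redraws))
    }
    redraws <- redraws + 1L
    if (redraws > max_redraw) stop("replicate redraw budget exhausted")
  }
}

tree_pair_distance <- function(tree, a, b) {
  h <- tree_node_heights(tree)
  2 * h[ape::getMRCA(tree, c(a, b))]
}

sweep_core <- function(grid, var_name, n_replicates, rep_args) {
  rows <- lapply(seq_along(grid), function(i) {
    args <- rep_args
    args[[var_name]] <- grid[i]
    reps <- lapply(seq_len(n_replicates), function(j) do.call(run_replicate, args))
    dmat <- t(vapply(reps, `[[`, numeric(4), "distances"))
    data.frame(
      value = grid[i],
      rate = mean(vapply(reps, `[[`, logical(1), "reject")),
      d_gw_ref = mean(dmat[, 1]), d_gh_ref = mean(dmat[, 2]),
      d_gw_s = mean(dmat[, 3]), d_gh_s = mean(dmat[, 4]),
      redraws = sum(vapply(reps, `[[`, integer(1), "redraws")))
  })
  do.call(rbind, rows)
}

new_sweep <- function(df, swept, n_replicates, params) {
  names(df)[1] <- swept
  structure(df, swept = swept, n_replicates = n_replicates,
            params = params, class = c("hgt_sweep", "data.frame"))
}

#' Power of HGT detection as a function of event height
#'
#' Identification rate (fraction of replicates in which the chi-square test
#' rejects) per event height, with the mean of the four JC distances.
#'
#' @param heights Grid of event heights in `[0, 1]`.
#' @param gene_length Sites per gene.
#' @param n_replicates Replicates per grid point.
#' @param n_taxa,birth_rate,delta_rho Passed to [run_replicate()].
#' @param seed Optional integer seed for the whole sweep.
#' @return Data.frame of class `"hgt_sweep"`.
#' @export
sweep_height <- function(heights = seq(0, 1, by = 0.1), gene_length = 70,
                         n_replicates = 20, n_taxa = 20, birth_rate = 5,
                         delta_rho = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- sweep_core(heights, "hgt_height", n_replicates,
                   list(n_taxa = n_taxa, gene_length = gene_length,
                        birth_rate = birth_rate, delta_rho = delta_rho))
  new_sweep(df, "height", n_replicates,
            list(gene_length = gene_length, n_taxa = n_taxa,
                 birth_rate = birth_rate, delta_rho = delta_rho))
}

#' Power of HGT detection as a function of gene length
#'
#' @param lengths Grid of gene lengths (bp).
#' @param hgt_height Event height, default 0.7.
#' @inheritParams sweep_height
#' @return Data.frame of class `"hgt_sweep"`.
#' @export
sweep_length <- function(lengths = c(20, 40, 80, 160, 320, 640),
                         hgt_height = 0.7, n_replicates = 20, n_taxa = 20,
                         birth_rate = 5, delta_rho = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- sweep_core(lengths, "gene_length", n_replicates,
                   list(n_taxa = n_taxa, hgt_height = hgt_height,
                        birth_rate = birth_rate, delta_rho = delta_rho))
  new_sweep(df, "gene_length", n_replicates,
            list(hgt_height = hgt_height, n_taxa = n_taxa,
                 birth_rate = birth_rate, delta_rho = delta_rho))
}

#' False-positive rate of the CRM test (no HGT simulated)
#'
#' Both genes evolve on the species tree; rejections are false alarms.
#' Either the gene length is swept at a fixed strain-pair distance, or the
#' strain-pair distance is swept at a fixed gene length (the tree is
#' rescaled so the strain pair sits at the requested path length).
#'
#' @param lengths Grid of gene lengths; used when `distances` is `NULL`.
#' @param distances Grid of strain-pair path lengths (substitutions/site).
#' @param organism_distance Fixed strain-pair distance for the length sweep.
#' @param gene_length Fixed gene length for the distance sweep.
#' @inheritParams sweep_height
#' @return Data.frame of class `"hgt_sweep"` (`rate` is the FP rate).
#' @export
sweep_fp <- function(lengths = c(20, 80, 320, 1250, 5000, 10000),
                     distances = NULL, organism_distance = 0.2,
                     gene_length = 640, n_replicates = 20, n_taxa = 20,
                     birth_rate = 5, delta_rho = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(distances)) {
    df <- sweep_core(lengths, "gene_length", n_replicates,
                     list(n_taxa = n_taxa, null_model = TRUE,
                          s_distance = organism_distance,
                          birth_rate = birth_rate, delta_rho = delta_rho))
    new_sweep(df, "gene_length", n_replicates,
              list(null_model = TRUE, organism_distance = organism_distance,
                   n_taxa = n_taxa, birth_rate = birth_rate,
                   delta_rho = delta_rho))
  } else {
    df <- sweep_core(distances, "s_distance", n_replicates,
                     list(n_taxa = n_taxa, null_model = TRUE,
                          gene_length = gene_length,
                          birth_rate = birth_rate, delta_rho = delta_rho))
    new_sweep(df, "organism_distance", n_replicates,
              list(null_model = TRUE, gene_length = gene_length,
                   n_taxa = n_taxa, birth_rate = birth_rate,
                   delta_rho = delta_rho))
  }
}

#' @export
print.hgt_sweep <- function(x, ...) {
  cat(sprintf("<hgt_sweep> over %s, %d replicates/point\n",
              attr(x, "swept"), attr(x, "n_replicates")))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.hgt_sweep <- function(x, ...) {
  swept <- attr(x, "swept")
  graphics::plot(x[[1]], x$rate, type = "b", pch = 19, ylim = c(0, 1),
                 xlab = swept, ylab = "identification rate", ...)
  invisible(x)
}
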