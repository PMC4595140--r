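#' Per-gene synteny-index profile for a genome pair
#'
#' Computes the synteny index of every gene in the union of two genomes'
#' gene sets. Genes present in only one genome get SI 0. The profile is the
#' input to the cutoff and candidate-selection step of the HGT screen.
#'
#' @inheritParams synteny_index
#' @param require_core Error if the genomes share no genes (default `FALSE`).
#' @return An object of class `"si_profile"`: a data.frame with columns
#'   `gene`, `si`, `in_core`, and attributes `pair` (the two organism ids)
#'   and `k`.
#' @export
si_profile <- function(g1, g2, k = 10, require_core = FALSE) {
  g1 <- as_genome(g1); g2 <- as_genome(g2)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be an integer >= 1")
  genes1 <- g1$genes; genes2 <- g2$genes
  core <- intersect(genes1, genes2)
  if (require_core && length(core) == 0L) stop("no shared genes")
  union_genes <- union(genes1, genes2)
  si <- integer(length(union_genes))
  names(si) <- union_genes
  if (length(core) > 0L) {
    nb1 <- neighborhood_sets(g1, k)
    nb2 <- neighborhood_sets(g2, k)
    si[core] <- vapply(core, function(g) {
      length(intersect(nb1[[g]], nb2[[g]]))
    }, integer(1))
  }
  out <- data.frame(
    gene = union_genes,
    si = unname(si),
    in_core = union_genes %in% core,
    stringsAsFactors = FALSE
  )
  structure(out,
            pair = c(g1$organism_id, g2$organism_id),
            k = k,
            class = c("si_profile", "data.frame"))
}

# All k-neighborhoods of a genome at once (list keyed by gene id).
neighborhood_sets <- function(genome, k) {
  g <- genome$genes
  n <- length(g)
  offs <- c(seq_len(k), -seq_len(k))
  out <- vector("list", n)
  names(out) <- g
  for (pos in seq_len(n)) {
    if (genome$topology == "circular") {
      idx <- (pos + offs - 1L) %% n + 1L
      idx <- unique(idx[idx != pos])
    } else {
      idx <- c(seq(pos - k, pos - 1L), seq(pos + 1L, pos + k))
      idx <- idx[idx >= 1L & idx <= n]
    }
    out[[pos]] <- unique(g[idx])
  }
  out
}

#' @export
print.si_profile <- function(x, ...) {
  pair <- attr(x, "pair"); k <- attr(x, "k")
  cat(sprintf("<si_profile> %s vs %s (k = %d)\n", pair[1], pair[2], k))
  cat(sprintf("  %d genes in union, %d in core; mean SI/2k = %.3f\n",
              nrow(x), sum(x$in_core), mean(x$si) / (2 * k)))
  invisible(x)
}

#' SI cutoff for HGT candidate selection
#'
#' The cutoff `C(delta_si)` is the largest observed SI value `c` such that
#' the fraction of core (shared) genes with `SI <= c` is strictly below
#' `delta_si`; levels carrying no gene do not raise the cutoff. A value of
#' -1 means the low tail is empty: no gene qualifies as a candidate.
#'
#' @param profile An [si_profile()] object.
#' @param delta_si Threshold fraction in (0, 1).
#' @return Integer cutoff in `-1 .. 2k`.
#' @export
si_cutoff <- function(profile, delta_si = 0.05) {
  stopifnot(inherits(profile, "si_profile"))
  if (!is.numeric(delta_si) || delta_si <= 0 || delta_si >= 1)
    stop("'delta_si' must be in (0, 1)")
  core_si <- profile$si[profile$in_core]
  if (length(core_si) == 0L) stop("no shared genes")
  lev <- sort(unique(core_si))
  frac <- cumsum(tabulate(match(core_si, lev), length(lev))) / length(core_si)
  ok <- lev[frac < delta_si]
  if (length(ok) == 0L) -1L else as.integer(max(ok))
}

#' SI-based HGT candidate genes for a genome pair
#'
#' Selects core genes whose SI falls at or below the [si_cutoff()]. The
#' strict-inequality variant (`rule = "lt"`) is available because the
#' candidate rule can be read either way; the inclusive rule is the default.
#'
#' @inheritParams si_cutoff
#' @param rule `"leq"` (candidates have `SI <= C`) or `"lt"` (`SI < C`).
#' @return Object of class `"si_candidates"`: list with `cutoff`,
#'   `delta_si`, `rule` and a data.frame `candidates` (gene, si) sorted by
#'   (si, gene).
#' @export
si_candidates <- function(profile, delta_si = 0.05, rule = c("leq", "lt")) {
  rule <- match.arg(rule)
  cutoff <- si_cutoff(profile, delta_si)
  core <- profile[profile$in_core, , drop = FALSE]
  keep <- if (rule == "leq") core$si <= cutoff else core$si < cutoff
  cand <- core[keep, c("gene", "si"), drop = FALSE]
  cand <- cand[order(cand$si, cand$gene), , drop = FALSE]
  rownames(cand) <- NULL
  structure(
    list(pair = attr(profile, "pair"), k = attr(profile, "k"),
         delta_si = delta_si, cutoff = cutoff, rule = rule,
         candidates = cand),
    class = "si_candidates"
  )
}

#' @export
print.si_candidates <- function(x, ...) {
  cat(sprintf("<si_candidates> %s vs %s: cutoff C(%.3g) = %d, %d candidate(s)\n",
              x$pair[1], x$pair[2], x$delta_si, x$cutoff, nrow(x$candidates)))
  if (nrow(x$candidates) > 0L) print(utils::head(x$candidates, 20L))
  invisible(x)
}

#' Histogram of SI values for a genome pair
#'
#' Tally of SI values over `0 .. 2k`. Two tallies are reported: over the
#' union of both gene sets (genes private to one genome count at SI 0) and
#' over the core (shared) genes only.
#'
#' @inheritParams si_cutoff
#' @return Data.frame with columns `si`, `n_union`, `n_core`.
#' @export
si_histogram <- function(profile) {
  stopifnot(inherits(profile, "si_profile"))
  k <- attr(profile, "k")
  breaks <- 0:(2L * k)
  data.frame(
    si = breaks,
    n_union = vapply(breaks, function(v) sum(profile$si == v), integer(1)),
    n_core = vapply(breaks, function(v)
      sum(profile$si[profile$in_core] == v), integer(1))
  )
}

#' Infer the recipient organism of a transferred gene
#'
#' A transferred gene shows low SI between the recipient and every other
#' genome carrying the gene in its ancestral neighborhood, but high SI among
#' the non-recipient genomes. Given all pairwise SI profiles over three or
#' more genomes, the recipient is the single organism common to every
#' low-SI pair, provided the gene is not a candidate in any pair of the
#' remaining organisms. Anything else is `"undetermined"`.
#'
#' @param gene Gene identifier.
#' @param profiles List of [si_profile()] objects (all pairs over the
#'   analyzed genomes, or at least all pairs where the gene is shared).
#' @param delta_si Candidate threshold passed to [si_cutoff()].
#' @param rule Candidate rule, see [si_candidates()].
#' @return Organism id, or `"undetermined"`.
#' @export
infer_recipient <- function(gene, profiles, delta_si = 0.05,
                            rule = c("leq", "lt")) {
  rule <- match.arg(rule)
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  low_pairs <- list(); high_pairs <- list()
  for (p in profiles) {
    stopifnot(inherits(p, "si_profile"))
    row <- p[p$gene == gene, , drop = FALSE]
    if (nrow(row) == 0L || !row$in_core) next
    cutoff <- tryCatch(si_cutoff(p, delta_si), error = function(e) NA_integer_)
    if (is.na(cutoff)) next
    is_cand <- if (rule == "leq") row$si <= cutoff else row$si < cutoff
    if (is_cand) low_pairs[[length(low_pairs) + 1L]] <- attr(p, "pair")
    else high_pairs[[length(high_pairs) + 1L]] <- attr(p, "pair")
  }
  if (length(low_pairs) < 2L) return("undetermined")
  common <- Reduce(intersect, low_pairs)
  if (length(common) != 1L) return("undetermined")
  # the gene must not look transferred among the remaining organisms
  for (pair in low_pairs) if (!common %in% pair) return("undetermined")
  others_ok <- vapply(high_pairs, function(pair) !(common %in% pair), logical(1))
  if (length(high_pairs) == 0L || !any(others_ok)) return("undetermined")
  common
}
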