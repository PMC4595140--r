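#' Genome as an ordered sequence of gene identifiers
#'
#' Builds a genome object at gene-order resolution: an ordered vector of gene
#' identifiers on a circular (default, bacterial chromosome) or linear
#' (contig) topology. Duplicate identifiers (paralogs) are canonicalized by
#' keeping the first occurrence in genome order; the dropped ranks are kept in
#' the `"duplicates"` attribute so callers can report them.
#'
#' @param organism_id Single string naming the organism.
#' @param genes Character vector of gene identifiers in genomic order.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `"genome"`.
#' @examples
#' g <- genome("strainA", c("dnaA", "gyrB", "recA", "rpoB"))
#' length(g$genes)
#' @export
genome <- function(organism_id, genes, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!is.character(organism_id) || length(organism_id) != 1L || is.na(organism_id))
    stop("'organism_id' must be a single string")
  genes <- as.character(genes)
  if (length(genes) == 0L || anyNA(genes) || any(!nzchar(genes)))
    stop("'genes' must be a non-empty character vector without NA/empty ids")
  dup <- duplicated(genes)
  dropped <- genes[dup]
  genes <- genes[!dup]
  structure(
    list(organism_id = organism_id, genes = genes, topology = topology),
    duplicates = dropped,
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d genes, %s\n",
              x$organism_id, length(x$genes), x$topology))
  n <- min(6L, length(x$genes))
  cat("  head:", paste(x$genes[seq_len(n)], collapse = " "),
      if (length(x$genes) > n) "..." else "", "\n")
  nd <- length(attr(x, "duplicates"))
  if (nd > 0L) cat(sprintf("  (%d duplicate identifiers dropped)\n", nd))
  invisible(x)
}

#' @export
length.genome <- function(x) length(x$genes)

as_genome <- function(x) {
  if (!inherits(x, "genome")) stop("expected a 'genome' object")
  x
}

#' Gene neighborhood in a genome
#'
#' Returns the set of up to `k` genes upstream and `k` genes downstream of a
#' focal gene. For circular genomes positions wrap around; a neighborhood can
#' never exceed the other `n - 1` genes. For linear genomes the neighborhood
#' is truncated at the ends. The focal gene itself is excluded.
#'
#' @param genome A [genome()] object.
#' @param gene Gene identifier present in `genome`.
#' @param k Neighborhood radius in genes (`k >= 1`).
#' @return Character vector (a set) of neighbor gene identifiers.
#' @export
neighborhood <- function(genome, gene, k) {
  genome <- as_genome(genome)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be an integer >= 1")
  g <- genome$genes
  n <- length(g)
  pos <- match(gene, g)
  if (is.na(pos)) stop("gene not in genome")
  if (genome$topology == "circular") {
    idx <- (pos + c(seq_len(k), -seq_len(k)) - 1L) %% n + 1L
    idx <- unique(idx[idx != pos])
  } else {
    idx <- c(seq(pos - k, pos - 1L), seq(pos + 1L, pos + k))
    idx <- idx[idx >= 1L & idx <= n]
  }
  unique(g[idx])
}

#' Synteny index of a gene between two genomes
#'
#' The synteny index (SI) of a gene shared by two genomes is the number of
#' genes common to its k-neighborhoods in both genomes, an integer in
#' `[0, 2k]`. A gene absent from either genome has SI 0 by definition.
#'
#' @param gene Gene identifier.
#' @param g1,g2 [genome()] objects.
#' @param k Neighborhood radius.
#' @return Integer SI value.
#' @examples
#' a <- genome("A", letters[1:10])
#' b <- genome("B", letters[1:10])
#' synteny_index("e", a, b, k = 3)  # identical genomes: 2k
#' @export
synteny_index <- function(gene, g1, g2, k) {
  g1 <- as_genome(g1); g2 <- as_genome(g2)
  if (!(gene %in% g1$genes) || !(gene %in% g2$genes)) return(0L)
  n1 <- neighborhood(g1, gene, k)
  n2 <- neighborhood(g2, gene, k)
  length(intersect(n1, n2))
}

#' Average synteny index between two genomes
#'
#' Mean of `SI(g)/2k` over the union of the two genomes' gene sets; genes
#' present in only one genome contribute 0. Equals 1 for identical genomes
#' and 0 for genomes with disjoint gene sets.
#'
#' @inheritParams synteny_index
#' @return A number in `[0, 1]`.
#' @export
average_si <- function(g1, g2, k = 10) {
  prof <- si_profile(g1, g2, k = k, require_core = FALSE)
  mean(prof$si) / (2 * k)
}
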