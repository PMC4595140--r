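# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (explicit position arithmetic,
# count-and-check loops) rather than calling package internals.

# k-neighborhood by explicit position enumeration
brute_neighborhood <- function(genes, gene, k, topology = "circular") {
  n <- length(genes)
  pos <- which(genes == gene)
  idx <- integer(0)
  for (off in c(-(k:1), 1:k)) {
    j <- pos + off
    if (topology == "circular") {
      j <- ((j - 1) %% n) + 1
      idx <- c(idx, j)
    } else if (j >= 1 && j <= n) {
      idx <- c(idx, j)
    }
  }
  setdiff(unique(genes[idx]), gene)
}

brute_si <- function(gene, genes1, genes2, k, topology = "circular") {
  if (!(gene %in% genes1) || !(gene %in% genes2)) return(0L)
  length(intersect(brute_neighborhood(genes1, gene, k, topology),
                   brute_neighborhood(genes2, gene, k, topology)))
}

brute_average_si <- function(genes1, genes2, k) {
  pool <- union(genes1, genes2)
  vals <- vapply(pool, brute_si, 0L, genes1 = genes1, genes2 = genes2, k = k)
  sum(vals / (2 * k)) / length(pool)
}

# largest observed SI level with cumulative core fraction < delta, else -1
brute_cutoff <- function(core_si, delta) {
  best <- -1L
  for (v in sort(unique(core_si), decreasing = TRUE)) {
    if (mean(core_si <= v) < delta) { best <- as.integer(v); break }
  }
  best
}

# wrap a bare vector of core SI values into the si_profile contract
make_profile <- function(core_si, k = 10, pair = c("X", "Y")) {
  df <- data.frame(gene = sprintf("g%04d", seq_along(core_si)),
                   si = as.integer(core_si),
                   in_core = TRUE, stringsAsFactors = FALSE)
  structure(df, pair = pair, k = as.integer(k),
            class = c("si_profile", "data.frame"))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# mutate exactly m sites of a sequence (guaranteed mismatches)
mutate_sites <- function(seq, m) {
  v <- strsplit(seq, "")[[1]]
  idx <- sample(seq_along(v), m)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
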