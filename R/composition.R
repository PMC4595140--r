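#' Word-frequency spectrum of a nucleotide sequence
#'
#' The spectrum of a sequence for word length `w` is the vector of relative
#' frequencies of all `4^w` overlapping words (step 1). In GC mode the
#' spectrum is two-dimensional: frequency of G+C versus A+T. Words touching
#' a non-ACGT character are ignored.
#'
#' @param sequence Nucleotide string (case-insensitive).
#' @param word_length Word length (1-4), ignored when `gc = TRUE`.
#' @param gc Use the G+C / A+T two-component spectrum instead of words.
#' @return Named numeric vector of frequencies summing to 1.
#' @examples
#' spectrum_of("ACGT", 2)    # 1/3 each at AC, CG, GT
#' spectrum_of("GGCC", gc = TRUE)
#' @export
spectrum_of <- function(sequence, word_length = 4, gc = FALSE) {
  v <- seq_chars(sequence)
  code <- match(v, c("A", "C", "G", "T"))  # NA for N/-
  if (gc) {
    ok <- !is.na(code)
    if (!any(ok)) stop("sequence has no unambiguous nucleotides")
    f <- c(GC = sum(code[ok] %in% c(2L, 3L)), AT = sum(code[ok] %in% c(1L, 4L)))
    return(f / sum(f))
  }
  w <- as.integer(word_length)
  if (is.na(w) || w < 1L || w > 4L) stop("'word_length' must be in 1..4")
  ids <- word_ids(code, w)
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0L) stop("sequence shorter than word length")
  counts <- tabulate(ids, nbins = 4L^w)
  names(counts) <- all_words(w)
  counts / sum(counts)
}

# base-4 id (1-based) of the word starting at each position; NA where the
# word runs off the end or touches an ambiguous character
word_ids <- function(code, w) {
  n <- length(code)
  if (n < w) return(rep(NA_integer_, 0L))
  ids <- code - 1L
  if (w > 1L) {
    for (j in seq_len(w - 1L)) {
      ids <- ids * 4L + (c(code[-seq_len(j)], rep(NA_integer_, j)) - 1L)
    }
  }
  ids[seq_len(n - w + 1L)] + 1L
}

all_words <- function(w) {
  b <- c("A", "C", "G", "T")
  out <- b
  # id order: first character most significant (AA, AC, AG, AT, CA, ...)
  if (w > 1L) for (j in 2:w)
    out <- as.vector(vapply(out, function(p) paste0(p, b), character(4)))
  out
}

#' Sliding-window composition scan of a genome
#'
#' Computes, for every window along the (linearized) genome, the Euclidean
#' distance between the window's word spectrum and the whole-genome
#' spectrum. Transferred segments of foreign origin tend to sit in windows
#' whose spectra are unusually far from the genome's.
#'
#' @param sequence Genome nucleotide string.
#' @param word_length Word length of the spectrum (1-4).
#' @param window Window size in bp (default 2000).
#' @param step Step between window starts in bp (default 10).
#' @param gc Use the G+C spectrum instead of word frequencies.
#' @return Object of class `"composition_scan"`: data.frame with `start`,
#'   `end` (0-based half-open) and `distance`; the genome spectrum is kept
#'   in the `"genome_spectrum"` attribute.
#' @export
window_scan <- function(sequence, word_length = 4, window = 2000, step = 10,
                        gc = FALSE) {
  v <- seq_chars(sequence)
  n <- length(v)
  window <- as.integer(window); step <- as.integer(step)
  if (n < window) stop("genome shorter than window")
  if (step < 1L) stop("'step' must be >= 1")
  code <- match(v, c("A", "C", "G", "T"))
  if (gc) {
    gcv <- as.integer(code %in% c(2L, 3L))
    gcv[is.na(code)] <- NA_integer_
    genome_spec <- spectrum_of(sequence, gc = TRUE)
    starts <- seq(0L, n - window, by = step)
    dist <- vapply(starts, function(s) {
      x <- gcv[(s + 1L):(s + window)]
      x <- x[!is.na(x)]
      f <- c(sum(x), length(x) - sum(x)) / length(x)
      sqrt(sum((f - genome_spec)^2))
    }, 0)
  } else {
    w <- as.integer(word_length)
    ids <- word_ids(code, w)
    nb <- 4L^w
    gcount <- tabulate(ids[!is.na(ids)], nbins = nb)
    genome_spec <- gcount / sum(gcount)
    names(genome_spec) <- all_words(w)
    starts <- seq(0L, n - window, by = step)
    dist <- vapply(starts, function(s) {
      wi <- ids[(s + 1L):(s + window - w + 1L)]
      wi <- wi[!is.na(wi)]
      f <- tabulate(wi, nbins = nb) / length(wi)
      sqrt(sum((f - genome_spec)^2))
    }, 0)
  }
  structure(
    data.frame(start = starts, end = starts + window, distance = dist),
    genome_spectrum = genome_spec,
    word_length = if (gc) NA_integer_ else as.integer(word_length),
    gc = gc, window = window, step = step,
    class = c("composition_scan", "data.frame"))
}

#' @export
print.composition_scan <- function(x, ...) {
  cat(sprintf("<composition_scan> %d windows (size %d, step %d), %s spectrum\n",
              nrow(x), attr(x, "window"), attr(x, "step"),
              if (attr(x, "gc")) "G+C" else
                paste0(attr(x, "word_length"), "-mer")))
  cat(sprintf("  distance: min %.4g, median %.4g, max %.4g\n",
              min(x$distance), stats::median(x$distance), max(x$distance)))
  invisible(x)
}

#' Atypical windows of a composition scan
#'
#' A window is delta-atypical when its distance to the genome spectrum is
#' strictly greater than the empirical `1 - delta` quantile of all window
#' distances of the same genome.
#'
#' @param scan A [window_scan()] result.
#' @param delta Level in (0, 1); default 0.05.
#' @return The scan data.frame with a logical `atypical` column and the
#'   threshold in attribute `"threshold"`.
#' @export
atypical_windows <- function(scan, delta = 0.05) {
  stopifnot(inherits(scan, "composition_scan"))
  if (delta <= 0 || delta >= 1) stop("'delta' must be in (0, 1)")
  thr <- stats::quantile(scan$distance, probs = 1 - delta, names = FALSE,
                         type = 7)
  out <- scan
  out$atypical <- scan$distance > thr
  attr(out, "threshold") <- thr
  out
}

#' Composition-atypical genes
#'
#' Maps delta-atypical windows onto gene coordinates: under the default
#' `"any"` rule a gene is atypical when at least one overlapping window is
#' atypical; under `"majority"` more than half of its overlapping windows
#' must be. Genes with no overlapping window are reported as uncovered.
#'
#' @param scan A [window_scan()] result.
#' @param genes Data.frame with columns `gene`, `start`, `end`
#'   (0-based half-open coordinates on the scanned sequence).
#' @param delta Level in (0, 1).
#' @param rule `"any"` or `"majority"`.
#' @return Data.frame with `gene`, `n_windows`, `n_atypical`, `atypical`
#'   (NA for uncovered genes).
#' @export
atypical_genes <- function(scan, genes, delta = 0.05,
                           rule = c("any", "majority")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(genes),
            all(c("gene", "start", "end") %in% names(genes)))
  calls <- atypical_windows(scan, delta)
  res <- lapply(seq_len(nrow(genes)), function(i) {
    ov <- calls$start < genes$end[i] & calls$end > genes$start[i]
    nw <- sum(ov); na <- sum(calls$atypical[ov])
    data.frame(gene = genes$gene[i], n_windows = nw, n_atypical = na,
               atypical = if (nw == 0L) NA else
                 if (rule == "any") na >= 1L else na > nw / 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
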