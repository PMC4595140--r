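#' Normalized Hamming distance between two aligned sequences
#'
#' Counts mismatching sites over alignment columns where both sequences carry
#' an unambiguous nucleotide (A, C, G or T); columns containing a gap (`-`)
#' or `N` in either sequence are excluded pairwise. Input is
#' case-insensitive.
#'
#' @param a,b Aligned nucleotide strings of equal length.
#' @return List with `h` (mismatch fraction) and `sites_used` (number of
#'   comparable columns).
#' @examples
#' hamming_distance("ACGT", "ACGA")$h       # 0.25
#' hamming_distance("AC-T", "ACGT")$h       # 0 over 3 sites
#' @export
hamming_distance <- function(a, b) {
  va <- seq_chars(a); vb <- seq_chars(b)
  if (length(va) != length(vb)) stop("sequences differ in length")
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  sites <- sum(ok)
  if (sites == 0L) stop("no comparable sites")
  list(h = sum(va[ok] != vb[ok]) / sites, sites_used = sites)
}

seq_chars <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), c("A", "C", "G", "T", "N", "-"))
  if (length(bad) > 0L)
    stop("invalid sequence characters: ", paste(bad, collapse = " "))
  x
}

#' Jukes-Cantor correction of a Hamming distance
#'
#' Converts an observed mismatch fraction `h` into the Jukes-Cantor
#' evolutionary distance `d = -(3/4) log(1 - (4/3) h)` (expected
#' substitutions per site). Distances at or beyond the JC saturation point
#' `h >= 3/4` are undefined.
#'
#' @param h Hamming fraction in `[0, 0.75)`.
#' @return JC distance `d >= 0`.
#' @export
jc_correct <- function(h) {
  if (any(h < 0)) stop("negative hamming distance")
  if (any(h >= 0.75)) stop("saturated distance")
  -0.75 * log1p(-(4 / 3) * h)
}

#' Jukes-Cantor distance to expected Hamming fraction
#'
#' The forward JC formula `h = (3/4)(1 - exp(-(4/3) d))`; exact inverse of
#' [jc_correct()].
#'
#' @param d JC distance (`d >= 0`).
#' @return Hamming fraction in `[0, 0.75)`.
#' @export
jc_to_hamming <- function(d) {
  if (any(d < 0)) stop("negative distance")
  -0.75 * expm1(-(4 / 3) * d)
}

#' Per-gene ortholog alignment
#'
#' Container for one gene's aligned nucleotide sequences across organisms.
#'
#' @param gene_id Gene identifier.
#' @param sequences Named character vector, one aligned sequence per
#'   organism; equal lengths, alphabet `A C G T N -` (case-insensitive).
#' @return Object of class `"ortholog_alignment"`.
#' @export
ortholog_alignment <- function(gene_id, sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named by organism id")
  if (anyDuplicated(names(sequences)))
    stop("duplicate organism ids in alignment")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L || lens[1] == 0L)
    stop("aligned sequences must share one positive length")
  sequences <- toupper(sequences)
  for (s in sequences) seq_chars(s)  # alphabet validation
  structure(list(gene_id = gene_id, sequences = sequences,
                 length = unname(lens[1])),
            class = "ortholog_alignment")
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat(sprintf("<ortholog_alignment> %s: %d organisms x %d columns\n",
              x$gene_id, length(x$sequences), x$length))
  invisible(x)
}

#' Pairwise gene distance between two organisms
#'
#' Hamming and Jukes-Cantor distances for one gene between two organisms of
#' an ortholog alignment. A Hamming fraction at or above the JC saturation
#' point 3/4 is flagged (`saturated = TRUE`, `jc = NA`) rather than raised,
#' so callers can skip the gene and log the reason.
#'
#' @param alignment An [ortholog_alignment()].
#' @param x,y Organism ids present in the alignment.
#' @return List with `gene_id`, `pair`, `hamming`, `jc`, `sites_used`,
#'   `saturated`.
#' @export
gene_distance <- function(alignment, x, y) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  for (org in c(x, y)) {
    if (!org %in% names(alignment$sequences))
      stop("organism not in alignment: ", org)
  }
  hd <- hamming_distance(alignment$sequences[[x]], alignment$sequences[[y]])
  saturated <- hd$h >= 0.75
  list(gene_id = alignment$gene_id, pair = c(x, y),
       hamming = hd$h,
       jc = if (saturated) NA_real_ else jc_correct(hd$h),
       sites_used = hd$sites_used,
       saturated = saturated)
}
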