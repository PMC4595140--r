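#' Read a genome's gene order from TSV, GFF3 or a GenBank feature table
#'
#' TSV files carry two columns (1-based rank, gene identifier). GFF3 files
#' (1-based inclusive coordinates) are read with rtracklayer when available;
#' CDS features are ordered by (start, end, id), strand ignored, and named
#' by the first available `gene`, `Name`, `locus_tag` or `ID` attribute.
#' GenBank flat files are parsed from the FEATURES table (CDS or gene
#' features, `/gene=` or `/locus_tag=` qualifiers); no installed R package
#' parses local GenBank files, so a minimal reader is included here.
#'
#' @param path File path.
#' @param format `"tsv"`, `"gff3"` or `"genbank"`; guessed from the file
#'   extension by default.
#' @param organism_id Organism id; default the file base name.
#' @param topology Passed to [genome()].
#' @return A [genome()] object.
#' @export
read_gene_order <- function(path, format = c("auto", "tsv", "gff3", "genbank"),
                            organism_id = NULL,
                            topology = c("circular", "linear")) {
  format <- match.arg(format)
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     gff = , gff3 = "gff3",
                     gb = , gbk = , gbff = "genbank",
                     "tsv")
  }
  if (is.null(organism_id))
    organism_id <- sub("\\.[^.]*$", "", basename(path))
  genes <- switch(format,
                  tsv = read_gene_order_tsv(path),
                  gff3 = read_gene_order_gff3(path),
                  genbank = read_gene_order_genbank(path))
  genome(organism_id, genes, topology)
}

read_gene_order_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty gene-order file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad) > 0L)
    stop("malformed gene-order line(s) ", paste(bad, collapse = ", "),
         " in ", path)
  rank <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  if (anyNA(rank))
    stop("non-integer rank on line(s) ",
         paste(which(is.na(rank)), collapse = ", "), " in ", path)
  gene <- vapply(parts, `[[`, "", 2L)
  gene[order(rank)]
}

read_gene_order_gff3 <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
    if (length(gr) == 0L) stop("no CDS features in ", path)
    meta <- as.data.frame(gr)
    nm <- rep(NA_character_, nrow(meta))
    for (col in c("gene", "Name", "locus_tag", "ID")) {
      if (col %in% names(meta)) {
        v <- as.character(meta[[col]])
        nm[is.na(nm) & !is.na(v)] <- v[is.na(nm) & !is.na(v)]
      }
    }
    if (anyNA(nm)) stop("CDS feature(s) without gene/Name/locus_tag/ID in ", path)
    ord <- order(meta$start, meta$end, nm)
    return(nm[ord])
  }
  # fallback: GFF3 is 9-column TSV
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 9L) stop("not a GFF3 file: ", path)
  df <- df[df[[3]] == "CDS", , drop = FALSE]
  if (nrow(df) == 0L) stop("no CDS features in ", path)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  nm <- attr_field(df[[9]], "gene")
  for (key in c("Name", "locus_tag", "ID")) {
    miss <- is.na(nm)
    if (!any(miss)) break
    nm[miss] <- attr_field(df[[9]][miss], key)
  }
  if (anyNA(nm)) stop("CDS feature(s) without gene/Name/locus_tag/ID in ", path)
  nm[order(df[[4]], df[[5]], nm)]
}

read_gene_order_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 0L) stop("no FEATURES table in ", path)
  stop_at <- grep("^(ORIGIN|CONTIG|//)", lines)
  stop_at <- if (length(stop_at)) min(stop_at[stop_at > feat_start[1]]) else
    length(lines) + 1L
  block <- lines[(feat_start[1] + 1L):(stop_at - 1L)]
  # feature headers sit at column 6, qualifiers at column 22
  hdr <- grepl("^ {5}\\S", block)
  idx <- which(hdr)
  genes <- character(0); starts <- integer(0)
  for (i in seq_along(idx)) {
    line <- block[idx[i]]
    key <- sub("^ +(\\S+).*$", "\\1", line)
    if (!key %in% c("CDS", "gene")) next
    loc <- sub("^ +\\S+ +", "", line)
    start <- suppressWarnings(as.integer(sub("^\\D*(\\d+).*$", "\\1", loc)))
    if (is.na(start)) stop("unparseable location '", loc, "' in ", path)
    to <- if (i < length(idx)) idx[i + 1L] - 1L else length(block)
    quals <- block[idx[i]:to]
    name <- NA_character_
    for (q in c("gene", "locus_tag")) {
      m <- grep(paste0('^ +/', q, '="?'), quals, value = TRUE)
      if (length(m) > 0L) {
        name <- sub(paste0('^ +/', q, '="?([^"]*)"?.*$'), "\\1", m[1])
        break
      }
    }
    if (is.na(name)) next
    # CDS and gene features for the same locus: keep first occurrence
    if (!name %in% genes) { genes <- c(genes, name); starts <- c(starts, start) }
  }
  if (length(genes) == 0L) stop("no named CDS/gene features in ", path)
  genes[order(starts)]
}

#' Write a gene order as rank/identifier TSV
#'
#' @param genome A [genome()] object.
#' @param path Output file.
#' @export
write_gene_order <- function(genome, path) {
  genome <- as_genome(genome)
  utils::write.table(
    data.frame(rank = seq_along(genome$genes), gene = genome$genes),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-gene ortholog alignment from FASTA
#'
#' One FASTA file per gene; record ids are organism ids. The gene id
#' defaults to the file base name.
#'
#' @param path FASTA file.
#' @param gene_id Optional gene identifier.
#' @return An [ortholog_alignment()].
#' @export
read_alignment <- function(path, gene_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(gene_id)) gene_id <- sub("\\.[^.]*$", "", basename(path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no sequences in ", path)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  names(seqs) <- sub("\\s.*$", "", names(dna))
  ortholog_alignment(gene_id, seqs)
}

#' Read a directory of per-gene FASTA alignments
#'
#' @param dir Directory containing one `<gene>.fasta`/`.fa` file per gene.
#' @return Named list of [ortholog_alignment()] objects keyed by gene id.
#' @export
read_alignment_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  if (length(files) == 0L) stop("no FASTA files in ", dir)
  out <- lapply(files, read_alignment)
  names(out) <- vapply(out, `[[`, "", "gene_id")
  out
}

#' Write a per-gene alignment as FASTA
#'
#' @param alignment An [ortholog_alignment()].
#' @param path Output file.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (org in names(alignment$sequences)) {
    writeLines(c(paste0(">", org), alignment$sequences[[org]]), con)
  }
  invisible(path)
}

#' Write the Near HGT report as TSV (and optionally full records as JSON)
#'
#' @param x A [near_hgt()] result.
#' @param path Output TSV path.
#' @param json_path Optional path for a JSON dump of all per-test records,
#'   skips and parameters.
#' @export
write_report <- function(x, path, json_path = NULL) {
  stopifnot(inherits(x, "near_hgt"))
  utils::write.table(x$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(params = x$params, report = x$report, tests = x$tests,
           skips = x$skips),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}
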