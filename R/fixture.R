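#' Synthetic strain data set with known transfers
#'
#' Generates a fully specified test bed for the detector: an ultrametric
#' species tree over a shallow strain clade and a deeper reference clade,
#' one Jukes-Cantor alignment per gene, identical ancestral gene orders, and
#' `n_transfers` implanted HGT events. Each transfer re-routes the gene tree
#' of one gene (recipient lineage coalescing with the donor at
#' `transfer_height` of their divergence, see [graft_hgt()]) and relocates
#' the gene in the recipient's gene order to a position more than `2 k`
#' genes away from its ancestral site, mimicking insertion at a random
#' location.
#'
#' @param n_strains Number of strain genomes (`>= 2`).
#' @param n_references Number of reference organisms (`>= 2`).
#' @param n_genes Genes per genome.
#' @param gene_length Alignment columns per gene.
#' @param n_transfers Number of implanted transfers (0 for a null data set).
#' @param strain_divergence Height of the strain clade (substitutions/site).
#' @param reference_divergence Height of the reference clade.
#' @param root_height Root height; must exceed both clade heights.
#' @param transfer_height Event height fraction in `[0, 1]` (0 = at the
#'   leaves, i.e. a very recent transfer).
#' @param k Neighborhood radius used to place relocations out of reach.
#' @param seed Optional integer seed; the same seed reproduces the fixture
#'   exactly.
#' @return Object of class `"hgt_fixture"`: named lists `genomes` and
#'   `alignments`, character vectors `strains` and `references`, the
#'   species `tree`, a `truth` data.frame (gene, donor, recipient, height)
#'   and `params`.
#' @export
make_fixture <- function(n_strains = 3, n_references = 2, n_genes = 60,
                         gene_length = 1000, n_transfers = 1,
                         strain_divergence = 0.02,
                         reference_divergence = 0.3, root_height = 0.6,
                         transfer_height = 0.1, k = 10, seed = NULL) {
  stopifnot(n_strains >= 2, n_references >= 2, n_genes >= 4 * k + 4,
            n_transfers >= 0, n_transfers <= n_strains)
  if (root_height <= max(strain_divergence, reference_divergence))
    stop("'root_height' must exceed both clade heights")
  if (!is.null(seed)) set.seed(seed)

  strains <- paste0("S", seq_len(n_strains))
  refs <- paste0("R", seq_len(n_references))
  tree <- two_clade_tree(strains, strain_divergence, refs,
                         reference_divergence, root_height)

  genes <- sprintf("g%03d", seq_len(n_genes))
  # implant transfers: choose genes, donor/recipient strain pairs
  truth <- data.frame(gene = character(0), donor = character(0),
                      recipient = character(0), height = numeric(0),
                      stringsAsFactors = FALSE)
  gene_trees <- stats::setNames(vector("list", n_genes), genes)
  if (n_transfers > 0L) {
    t_genes <- sample(genes, n_transfers)
    recipients <- sample(strains, n_transfers)
    for (i in seq_len(n_transfers)) {
      donor <- sample(setdiff(strains, recipients[i]), 1L)
      gene_trees[[t_genes[i]]] <-
        graft_hgt(tree, recipients[i], donor, transfer_height)
      truth <- rbind(truth, data.frame(
        gene = t_genes[i], donor = donor, recipient = recipients[i],
        height = transfer_height, stringsAsFactors = FALSE))
    }
  }

  alignments <- lapply(genes, function(g) {
    gt <- if (is.null(gene_trees[[g]])) tree else gene_trees[[g]]
    ortholog_alignment(g, evolve_jc(gt, gene_length))
  })
  names(alignments) <- genes

  genomes <- lapply(c(strains, refs), function(org) {
    order_g <- genes
    here <- truth[truth$recipient == org, , drop = FALSE]
    for (g in here$gene) order_g <- relocate_gene(order_g, g, k)
    genome(org, order_g, topology = "circular")
  })
  names(genomes) <- c(strains, refs)

  structure(
    list(genomes = genomes, alignments = alignments,
         strains = strains, references = refs, tree = tree,
         truth = truth,
         params = list(n_genes = n_genes, gene_length = gene_length,
                       strain_divergence = strain_divergence,
                       reference_divergence = reference_divergence,
                       root_height = root_height,
                       transfer_height = transfer_height, k = k)),
    class = "hgt_fixture")
}

#' @export
print.hgt_fixture <- function(x, ...) {
  cat(sprintf("<hgt_fixture> %d strains + %d references, %d genes x %d bp, %d transfer(s)\n",
              length(x$strains), length(x$references),
              x$params$n_genes, x$params$gene_length, nrow(x$truth)))
  if (nrow(x$truth) > 0L) print(x$truth, row.names = FALSE)
  invisible(x)
}

# ((strains):len, (references):len); both clades rescaled to exact heights
two_clade_tree <- function(strains, h_s, refs, h_r, h_root) {
  sub_nwk <- function(labels, h) {
    if (length(labels) == 1L) return(paste0(labels, ":", sprintf("%.12g", h)))
    t <- yule_tree(length(labels), birth_rate = 1, labels = labels)
    ht <- max(ape::node.depth.edgelength(t))
    t$edge.length <- t$edge.length * (h / ht)
    nwk <- ape::write.tree(t)
    sub(";$", "", nwk)
  }
  stalk_s <- h_root - h_s; stalk_r <- h_root - h_r
  txt <- sprintf("(%s:%.12g,%s:%.12g);",
                 sub_nwk(strains, h_s), stalk_s,
                 sub_nwk(refs, h_r), stalk_r)
  ape::read.tree(text = txt)
}

# move one gene to a uniformly drawn slot more than 2k genes away (circular)
relocate_gene <- function(order_g, gene, k) {
  n <- length(order_g)
  pos <- match(gene, order_g)
  rest <- order_g[-pos]
  repeat {
    slot <- sample.int(n - 1L, 1L)  # insert after rest[slot]
    new_pos <- slot + 1L
    d <- abs(new_pos - pos)
    d <- min(d, n - d)
    if (d > 2L * k) break
  }
  append(rest, gene, after = slot)
}

#' Write a fixture to disk in the package's input formats
#'
#' Gene orders as TSV, one FASTA alignment per gene under `alignments/`,
#' the species tree as Newick, organism roles and ground truth as TSV.
#'
#' @param fixture A [make_fixture()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "hgt_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  for (org in names(fixture$genomes))
    write_gene_order(fixture$genomes[[org]],
                     file.path(dir, paste0(org, ".tsv")))
  for (g in names(fixture$alignments))
    write_alignment(fixture$alignments[[g]],
                    file.path(dir, "alignments", paste0(g, ".fasta")))
  ape::write.tree(fixture$tree, file.path(dir, "species_tree.nwk"))
  roles <- data.frame(
    organism = c(fixture$strains, fixture$references),
    role = c(rep("strain", length(fixture$strains)),
             rep("reference", length(fixture$references))))
  utils::write.table(roles, file.path(dir, "roles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a fixture directory back into genomes and alignments
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `genomes`, `alignments`, `strains`, `references`.
#' @export
read_fixture <- function(dir) {
  roles <- utils::read.delim(file.path(dir, "roles.tsv"),
                             stringsAsFactors = FALSE)
  genomes <- lapply(roles$organism, function(org)
    read_gene_order(file.path(dir, paste0(org, ".tsv")), format = "tsv",
                    organism_id = org))
  names(genomes) <- roles$organism
  list(genomes = genomes,
       alignments = read_alignment_dir(file.path(dir, "alignments")),
       strains = roles$organism[roles$role == "strain"],
       references = roles$organism[roles$role == "reference"])
}
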