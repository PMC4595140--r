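#' Expected rate ratio between candidate and witness gene
#'
#' Under constant relative mutability, the ratio of two genes' evolutionary
#' rates is the same along every lineage, so the ratio of their JC distances
#' between any reference pair estimates it (the shared divergence time
#' cancels).
#'
#' @param d_h_ref JC distance of the candidate gene between the two
#'   reference organisms.
#' @param d_w_ref JC distance of the witness gene between the same pair.
#' @return The ratio `rho = d_h_ref / d_w_ref`.
#' @examples
#' expected_ratio(0.583, 0.541)  # 1.077
#' @export
expected_ratio <- function(d_h_ref, d_w_ref) {
  if (!is.finite(d_h_ref) || !is.finite(d_w_ref))
    stop("reference distances must be finite")
  if (d_w_ref <= 0) stop("uninformative witness")
  if (d_h_ref <= 0) stop("uninformative candidate reference distance")
  d_h_ref / d_w_ref
}

#' Expected inter-strain distance of the candidate gene
#'
#' Multiplies the rate ratio by the witness gene's observed distance between
#' the two strains; this is the JC distance the candidate should show if it
#' evolved vertically.
#'
#' @param rho Rate ratio from [expected_ratio()].
#' @param d_w_strain Witness JC distance between the two strains.
#' @return Expected JC distance.
#' @export
expected_distance <- function(rho, d_w_strain) {
  if (rho <= 0) stop("'rho' must be positive")
  if (d_w_strain < 0) stop("negative witness distance")
  rho * d_w_strain
}

#' Chi-square statistic for observed vs expected divergence
#'
#' One-degree-of-freedom goodness-of-fit statistic treating each alignment
#' column as a coin flip (mismatch / match). Both the explicit two-cell form
#' `sum (O - E)^2 / E` and the algebraically identical closed form
#' `l (h_obs - h_exp)^2 / (h_exp (1 - h_exp))` are evaluated and checked
#' against each other; distances are on the Hamming (mismatch-fraction)
#' scale.
#'
#' @param length Number of sites `l >= 1`.
#' @param h_obs Observed mismatch fraction in `[0, 1)`.
#' @param h_exp Expected mismatch fraction in `(0, 1)`.
#' @return The chi-square statistic.
#' @examples
#' chi_square_stat(1472, 0.00795, 0.02507)  # 17.65
#' @export
chi_square_stat <- function(length, h_obs, h_exp) {
  if (length < 1) stop("'length' must be >= 1")
  if (h_obs < 0 || h_obs >= 1) stop("'h_obs' must be in [0, 1)")
  if (h_exp <= 0 || h_exp >= 1) stop("degenerate expectation")
  two_cell <- (length * h_obs - length * h_exp)^2 / (length * h_exp) +
    (length * (1 - h_obs) - length * (1 - h_exp))^2 / (length * (1 - h_exp))
  closed <- length * (h_obs - h_exp)^2 / (h_exp * (1 - h_exp))
  if (abs(two_cell - closed) > 1e-9 * max(closed, 1))
    stop("internal error: chi-square forms disagree")
  closed
}

#' Upper-tail p-value of a 1-DoF chi-square statistic
#'
#' @param chi2 Statistic (`>= 0`).
#' @return `P(X >= chi2)` for `X ~ chi^2_1`.
#' @export
chi_square_pvalue <- function(chi2) {
  if (any(chi2 < 0)) stop("'chi2' must be >= 0")
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' One CRM test of a candidate gene against a witness and a reference pair
#'
#' Assembles the constant-relative-mutability validation for a single
#' (candidate gene, strain pair, witness gene, reference pair) combination:
#' rate ratio from the reference pair, expected inter-strain distance,
#' conversion of observed and expected JC distances to the Hamming scale,
#' and the 1-DoF chi-square. Conditions that make the test impossible
#' (saturated distances, a zero witness distance, degenerate expectation)
#' yield a skip record with a reason instead of an error.
#'
#' @param g_h Candidate gene id.
#' @param g_w Witness gene id.
#' @param s1,s2 Strain organism ids.
#' @param r1,r2 Reference organism ids.
#' @param alignments Named list of [ortholog_alignment()] objects keyed by
#'   gene id; must contain `g_h` and `g_w`.
#' @return List of class `"crm_test"`; `$skipped` is `TRUE` with `$reason`
#'   set when the test could not be performed.
#' @export
crm_single_test <- function(g_h, g_w, s1, s2, r1, r2, alignments) {
  skip <- function(reason) {
    structure(list(gene = g_h, witness = g_w,
                   strain_pair = c(s1, s2), reference_pair = c(r1, r2),
                   skipped = TRUE, reason = reason),
              class = "crm_test")
  }
  aln_h <- alignments[[g_h]]; aln_w <- alignments[[g_w]]
  if (is.null(aln_h) || is.null(aln_w)) return(skip("missing alignment"))
  orgs <- c(s1, s2, r1, r2)
  if (!all(orgs %in% names(aln_h$sequences)) ||
      !all(orgs %in% names(aln_w$sequences)))
    return(skip("missing ortholog"))

  d_h_ref <- gene_distance(aln_h, r1, r2)
  d_w_ref <- gene_distance(aln_w, r1, r2)
  d_w_s   <- gene_distance(aln_w, s1, s2)
  d_h_s   <- gene_distance(aln_h, s1, s2)
  if (d_h_ref$saturated || d_w_ref$saturated || d_w_s$saturated ||
      d_h_s$saturated)
    return(skip("saturated distance"))
  if (d_w_ref$jc <= 0) return(skip("uninformative witness"))
  if (d_h_ref$jc <= 0) return(skip("zero candidate reference distance"))

  rho <- expected_ratio(d_h_ref$jc, d_w_ref$jc)
  d_exp <- expected_distance(rho, d_w_s$jc)
  h_exp <- jc_to_hamming(d_exp)
  if (h_exp >= 0.75) return(skip("expected distance saturated"))
  if (h_exp <= 0) return(skip("degenerate expectation"))
  h_obs <- d_h_s$hamming
  len <- d_h_s$sites_used
  chi2 <- chi_square_stat(len, h_obs, h_exp)
  structure(
    list(gene = g_h, witness = g_w,
         strain_pair = c(s1, s2), reference_pair = c(r1, r2),
         rho = rho, d_obs = d_h_s$jc, d_exp = d_exp,
         h_obs = h_obs, h_exp = h_exp, length = len,
         chi2 = chi2, p = chi_square_pvalue(chi2),
         direction = if (d_h_s$jc < d_exp) "shorter" else "longer",
         skipped = FALSE, reason = NA_character_),
    class = "crm_test"
  )
}

#' @export
print.crm_test <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat(sprintf("<crm_test> %s (witness %s) [%s|%s]: SKIPPED (%s)\n",
                x$gene, x$witness, paste(x$strain_pair, collapse = ","),
                paste(x$reference_pair, collapse = ","), x$reason))
  } else {
    cat(sprintf(
      "<crm_test> %s (witness %s): rho = %.4g, d_obs = %.4g, d_exp = %.4g, chi2 = %.4g, p = %.3g (%s)\n",
      x$gene, x$witness, x$rho, x$d_obs, x$d_exp, x$chi2, x$p, x$direction))
  }
  invisible(x)
}

#' Near HGT: screen and validate transfers between closely related genomes
#'
#' The full two-stage detector. For every unordered pair of strain genomes,
#' genes in anomalous neighborhoods are flagged by the synteny-index screen
#' ([si_candidates()]); each flagged gene is then validated with the CRM
#' chi-square test against every eligible witness gene and every reference
#' pair, with a per-gene Bonferroni correction over the tests actually
#' performed. Witness genes are core genes of the strain pair, present in
#' both reference organisms, that are not themselves SI candidates for the
#' pair. When three or more strains are analyzed, a recipient hypothesis is
#' derived from the pattern of low-SI pairs ([infer_recipient()]).
#'
#' @param genomes Named list of [genome()] objects, one per strain
#'   (names are organism ids; each genome's `organism_id` must match).
#' @param alignments Named list of [ortholog_alignment()] objects keyed by
#'   gene id, covering strains and references.
#' @param strains Character vector (`>= 2`) of strain organism ids.
#' @param references Character vector (`>= 2`) of reference organism ids,
#'   disjoint from `strains`.
#' @param k Neighborhood radius for the SI screen.
#' @param delta_si Candidate threshold fraction, see [si_cutoff()].
#' @param delta_rho Significance level on the Bonferroni-corrected p-value.
#' @param rule Candidate rule, see [si_candidates()].
#' @return Object of class `"near_hgt"` with elements `report` (one row per
#'   strain pair x candidate gene), `tests` (every CRM test record),
#'   `skips` (every skipped test with its reason), `profiles` (SI profiles
#'   per strain pair) and `params`.
#' @export
near_hgt <- function(genomes, alignments, strains, references,
                     k = 10, delta_si = 0.05, delta_rho = 0.01,
                     rule = c("leq", "lt")) {
  rule <- match.arg(rule)
  stopifnot(length(strains) >= 2L, length(references) >= 2L)
  if (length(intersect(strains, references)) > 0L)
    stop("'strains' and 'references' must be disjoint")
  if (delta_si <= 0 || delta_si >= 1 || delta_rho <= 0 || delta_rho >= 1)
    stop("thresholds must be in (0, 1)")
  for (s in strains) {
    if (is.null(genomes[[s]])) stop("no genome for strain ", s)
  }

  pairs <- utils::combn(sort(strains), 2L)
  profiles <- list()
  for (j in seq_len(ncol(pairs))) {
    s1 <- pairs[1, j]; s2 <- pairs[2, j]
    profiles[[paste(s1, s2, sep = "|")]] <-
      si_profile(genomes[[s1]], genomes[[s2]], k = k)
  }

  ref_pairs <- utils::combn(sort(references), 2L)
  tests <- list(); skips <- list(); report <- list()

  for (j in seq_len(ncol(pairs))) {
    s1 <- pairs[1, j]; s2 <- pairs[2, j]
    prof <- profiles[[paste(s1, s2, sep = "|")]]
    if (sum(prof$in_core) == 0L) {
      skips[[length(skips) + 1L]] <- data.frame(
        s1 = s1, s2 = s2, gene = NA_character_, witness = NA_character_,
        r1 = NA_character_, r2 = NA_character_,
        reason = "no shared genes", stringsAsFactors = FALSE)
      next
    }
    cand <- si_candidates(prof, delta_si, rule)
    if (nrow(cand$candidates) == 0L) next
    cand_genes <- cand$candidates$gene
    core_genes <- prof$gene[prof$in_core]
    witness_pool <- setdiff(core_genes, cand_genes)

    for (gi in seq_along(cand_genes)) {
      g_h <- cand_genes[gi]
      recs <- list()
      for (rj in seq_len(ncol(ref_pairs))) {
        r1 <- ref_pairs[1, rj]; r2 <- ref_pairs[2, rj]
        aln_h <- alignments[[g_h]]
        if (is.null(aln_h) ||
            !all(c(r1, r2) %in% names(aln_h$sequences))) next
        for (g_w in witness_pool) {
          aln_w <- alignments[[g_w]]
          if (is.null(aln_w) ||
              !all(c(s1, s2, r1, r2) %in% names(aln_w$sequences))) next
          rec <- crm_single_test(g_h, g_w, s1, s2, r1, r2, alignments)
          if (isTRUE(rec$skipped)) {
            skips[[length(skips) + 1L]] <- data.frame(
              s1 = s1, s2 = s2, gene = g_h, witness = g_w, r1 = r1, r2 = r2,
              reason = rec$reason, stringsAsFactors = FALSE)
          } else {
            recs[[length(recs) + 1L]] <- rec
          }
        }
      }
      n_tests <- length(recs)
      if (n_tests > 0L) {
        df <- data.frame(
          s1 = s1, s2 = s2, gene = g_h,
          witness = vapply(recs, `[[`, "", "witness"),
          r1 = vapply(recs, function(r) r$reference_pair[1], ""),
          r2 = vapply(recs, function(r) r$reference_pair[2], ""),
          rho = vapply(recs, `[[`, 0, "rho"),
          d_obs = vapply(recs, `[[`, 0, "d_obs"),
          d_exp = vapply(recs, `[[`, 0, "d_exp"),
          length = vapply(recs, `[[`, 0, "length"),
          chi2 = vapply(recs, `[[`, 0, "chi2"),
          p = vapply(recs, `[[`, 0, "p"),
          direction = vapply(recs, `[[`, "", "direction"),
          stringsAsFactors = FALSE)
        df$p_corrected <- pmin(1, df$p * n_tests)
        tests[[length(tests) + 1L]] <- df
        sig <- df[df$p_corrected <= delta_rho, , drop = FALSE]
        n_wit <- length(unique(sig$witness))
        best <- if (nrow(sig) > 0L) sig[which.min(sig$p_corrected), ] else
          df[which.min(df$p_corrected), ]
      } else {
        n_wit <- 0L
        best <- NULL
      }
      recipient <- if (length(strains) >= 3L)
        infer_recipient(g_h, profiles, delta_si, rule) else "undetermined"
      report[[length(report) + 1L]] <- data.frame(
        s1 = s1, s2 = s2, gene = g_h,
        si = cand$candidates$si[gi], cutoff = cand$cutoff,
        n_tests = n_tests,
        n_significant_witnesses = n_wit,
        min_p_corrected = if (is.null(best)) NA_real_ else
          min(1, best$p_corrected),
        direction = if (is.null(best)) NA_character_ else best$direction,
        putative_hgt = n_wit > 0L,
        recipient = recipient,
        stringsAsFactors = FALSE)
    }
  }

  empty_skips <- data.frame(s1 = character(), s2 = character(),
                            gene = character(), witness = character(),
                            r1 = character(), r2 = character(),
                            reason = character(), stringsAsFactors = FALSE)
  empty_report <- data.frame(s1 = character(), s2 = character(),
                             gene = character(), si = integer(),
                             cutoff = integer(), n_tests = integer(),
                             n_significant_witnesses = integer(),
                             min_p_corrected = numeric(),
                             direction = character(),
                             putative_hgt = logical(),
                             recipient = character(), stringsAsFactors = FALSE)
  structure(
    list(
      report = if (length(report)) do.call(rbind, report) else empty_report,
      tests = if (length(tests)) do.call(rbind, tests) else NULL,
      skips = if (length(skips)) do.call(rbind, skips) else empty_skips,
      profiles = profiles,
      params = list(strains = strains, references = references, k = k,
                    delta_si = delta_si, delta_rho = delta_rho, rule = rule)
    ),
    class = "near_hgt"
  )
}

#' @export
print.near_hgt <- function(x, ...) {
  np <- length(x$profiles)
  cat(sprintf("<near_hgt> %d strains (%d pairs), %d references; k = %d, delta_si = %.3g, delta_rho = %.3g\n",
              length(x$params$strains), np, length(x$params$references),
              x$params$k, x$params$delta_si, x$params$delta_rho))
  rep <- x$report
  cat(sprintf("  %d candidate gene/pair combinations tested; %d putative HGT\n",
              nrow(rep), sum(rep$putative_hgt)))
  if (nrow(rep) > 0L) {
    print(rep[order(rep$min_p_corrected),
              c("s1", "s2", "gene", "si", "n_significant_witnesses",
                "min_p_corrected", "direction", "recipient")],
          row.names = FALSE)
  }
  if (nrow(x$skips) > 0L)
    cat(sprintf("  (%d tests skipped; see $skips)\n", nrow(x$skips)))
  invisible(x)
}

#' @export
summary.near_hgt <- function(object, ...) {
  rep <- object$report
  hits <- rep[rep$putative_hgt, , drop = FALSE]
  out <- list(
    n_pairs = length(object$profiles),
    n_candidates = nrow(rep),
    n_putative = nrow(hits),
    putative = hits,
    n_skipped = nrow(object$skips),
    skip_reasons = if (nrow(object$skips)) table(object$skips$reason) else NULL
  )
  class(out) <- "summary.near_hgt"
  out
}

#' @export
print.summary.near_hgt <- function(x, ...) {
  cat(sprintf("Near HGT summary: %d strain pairs, %d SI candidates, %d putative HGT, %d skipped tests\n",
              x$n_pairs, x$n_candidates, x$n_putative, x$n_skipped))
  if (x$n_putative > 0L)
    print(x$putative[, c("s1", "s2", "gene", "n_significant_witnesses",
                         "min_p_corrected", "direction", "recipient")],
          row.names = FALSE)
  if (!is.null(x$skip_reasons)) print(x$skip_reasons)
  invisible(x)
}
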