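# TE-surrounded gene detection and its association with transcriptional
# silencing. A gene is TE-surrounded when a repeat longer than `min_len`
# (strict) intersects the flank window on BOTH sides of the gene span:
# left window [start - window, start), right window [end, end + window).
# "Upstream/downstream" is taken strand-agnostically as left/right; because
# both sides are required the call is strand-invariant.

#' Per-gene flanking-repeat report
#'
#' A repeat qualifies for a flank when its length strictly exceeds `min_len`
#' and its interval intersects the half-open flank window; intersection, not
#' containment, so a repeat overlapping the gene body counts for the side(s)
#' whose window it reaches, at distance 0. Windows truncated by a scaffold
#' edge are flagged; a qualifying repeat inside the truncated window still
#' counts.
#'
#' @param gs A [gene_set].
#' @param repeats Repeat table ([repeat_hits()]).
#' @param window Flank window in bp (default 1000).
#' @param min_len Minimum repeat length in bp, strict (default 400).
#' @param scaffold_lengths Optional named vector for truncation flags.
#' @return data.frame per gene: n_left, n_right, min distances (NA when no
#'   hit), truncation flags, and te_surrounded.
#' @export
flanking_repeats <- function(gs, repeats, window = 1000, min_len = 400,
                             scaffold_lengths = NULL) {
  stopifnot(inherits(gs, "gene_set"), window >= 0)
  g <- gs$genes
  rep_ok <- repeats[repeats$length > min_len, , drop = FALSE]
  unknown <- setdiff(unique(g$scaffold), unique(repeats$scaffold))
  if (length(unknown) && nrow(repeats))
    message("no repeats annotated on scaffold(s): ",
            paste(utils::head(unknown, 3), collapse = ", "))
  res <- data.frame(gene_id = g$gene_id,
                    n_left = 0L, n_right = 0L,
                    left_dist = NA_integer_, right_dist = NA_integer_,
                    left_truncated = g$start - window < 0,
                    right_truncated = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(scaffold_lengths))
    res$right_truncated <- g$end + window >
      unname(scaffold_lengths[g$scaffold])
  if (window == 0) {                    # degenerate: empty flank windows
    res$te_surrounded <- FALSE
    return(res)
  }
  for (sc in unique(g$scaffold)) {
    gi <- which(g$scaffold == sc)
    r <- rep_ok[rep_ok$scaffold == sc, , drop = FALSE]
    if (!nrow(r)) next
    for (i in gi) {
      gs_ <- g$start[i]; ge <- g$end[i]
      left <- r$end > max(gs_ - window, 0) & r$start < gs_
      right <- r$start < ge + window & r$end > ge
      res$n_left[i] <- sum(left)
      res$n_right[i] <- sum(right)
      if (any(left)) res$left_dist[i] <- min(pmax(gs_ - r$end[left], 0L))
      if (any(right)) res$right_dist[i] <- min(pmax(r$start[right] - ge, 0L))
    }
  }
  res$te_surrounded <- res$n_left > 0 & res$n_right > 0
  res
}

#' Detailed flank hits
#'
#' Long-format companion of [flanking_repeats()]: one row per qualifying
#' (gene, side, repeat) triple with the edge-to-edge distance.
#'
#' @inheritParams flanking_repeats
#' @return data.frame: gene_id, side ("left"/"right"), family, repeat_class,
#'   start, end, distance.
#' @export
flank_hits <- function(gs, repeats, window = 1000, min_len = 400) {
  g <- gs$genes
  rep_ok <- repeats[repeats$length > min_len, , drop = FALSE]
  out <- list()
  if (window == 0) rep_ok <- rep_ok[0, , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    r <- rep_ok[rep_ok$scaffold == g$scaffold[i], , drop = FALSE]
    if (!nrow(r)) next
    gs_ <- g$start[i]; ge <- g$end[i]
    left <- r[r$end > max(gs_ - window, 0) & r$start < gs_, , drop = FALSE]
    right <- r[r$start < ge + window & r$end > ge, , drop = FALSE]
    if (nrow(left))
      out[[length(out) + 1]] <- data.frame(
        gene_id = g$gene_id[i], side = "left", family = left$family,
        repeat_class = left$repeat_class, start = left$start, end = left$end,
        distance = pmax(gs_ - left$end, 0L), stringsAsFactors = FALSE)
    if (nrow(right))
      out[[length(out) + 1]] <- data.frame(
        gene_id = g$gene_id[i], side = "right", family = right$family,
        repeat_class = right$repeat_class, start = right$start,
        end = right$end, distance = pmax(right$start - ge, 0L),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), side = character(),
                      family = character(), repeat_class = character(),
                      start = integer(), end = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' TE-surrounded gene set
#'
#' @inheritParams flanking_repeats
#' @return Character vector of gene ids with a qualifying repeat on both
#'   flanks.
#' @export
classify_te_surrounded <- function(gs, repeats, window = 1000, min_len = 400) {
  fr <- flanking_repeats(gs, repeats, window, min_len)
  fr$gene_id[fr$te_surrounded]
}

#' Silencing association of TE-surrounded genes
#'
#' Counts silent genes inside and outside the TE-surrounded set and tests the
#' 2x2 association (TE-surrounded x silent) with the Fisher exact test.
#' "Silent" defaults to NOT expressed (FPKM <= threshold in every stage);
#' `rule = "zero"` restricts to all-stage zero FPKM.
#'
#' @param te_surrounded Character vector of TE-surrounded gene ids.
#' @param expression Expression table.
#' @param rule "not_expressed" (default) or "zero".
#' @param threshold FPKM threshold for the not-expressed rule (default 1).
#' @return List with counts, percentages (1 decimal) and the Fisher p-value.
#' @export
suppression_association <- function(te_surrounded, expression,
                                    rule = c("not_expressed", "zero"),
                                    threshold = 1) {
  rule <- match.arg(rule)
  validate_expression_table(expression)
  missing <- setdiff(te_surrounded, expression$gene_id)
  if (length(missing))
    stop("TE-surrounded gene(s) missing from expression table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  silent <- if (rule == "zero") is_silent_zero(expression)
            else !is_expressed(expression, threshold)
  in_te <- expression$gene_id %in% te_surrounded
  a <- sum(silent & in_te); b <- sum(!silent & in_te)
  c_ <- sum(silent & !in_te); d <- sum(!silent & !in_te)
  list(n_te_surrounded = a + b,
       n_silent_among = a,
       pct_silent_among = ratio_percent(a, a + b),
       n_silent_background = c_,
       background_silent_pct = if (c_ + d > 0) ratio_percent(c_, c_ + d)
                               else NA_real_,
       overall_silent_pct = ratio_percent(a + c_, a + b + c_ + d),
       fisher_p = fisher_exact2x2(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)),
       table = matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                      dimnames = list(c("te", "background"),
                                      c("silent", "expressed"))))
}

#' Paralog/ortholog rescue evidence for silent TE-surrounded genes
#'
#' Two lines of evidence that silent TE-surrounded genes are real genes
#' rather than annotation artifacts: (A) the gene has a same-family paralog
#' that is NOT TE-surrounded and is expressed (> `threshold` FPKM in at least
#' one stage); (B) the gene's family has members in at least `min_genomes`
#' other genomes.
#'
#' @param silent_te_genes Character vector: silent TE-surrounded gene ids.
#' @param gene_families data.frame gene_id, family_id (focal genome).
#' @param family_genomes data.frame family_id, genome (long format, one row
#'   per family-genome pair; the focal genome should not be listed).
#' @param expression Expression table.
#' @param te_surrounded All TE-surrounded gene ids.
#' @param min_genomes Minimum genome count for evidence B (default 5, >=).
#' @param threshold FPKM threshold for "normally expressed" (default 1).
#' @return List with counts and percentages relative to `silent_te_genes`.
#' @export
rescue_evidence <- function(silent_te_genes, gene_families, family_genomes,
                            expression, te_surrounded, min_genomes = 5,
                            threshold = 1) {
  validate_expression_table(expression)
  stopifnot(all(c("gene_id", "family_id") %in% names(gene_families)),
            all(c("family_id", "genome") %in% names(family_genomes)))
  expressed_ids <- expression$gene_id[is_expressed(expression, threshold)]
  fam_of <- split(gene_families$family_id, gene_families$gene_id)
  members_of <- split(gene_families$gene_id, gene_families$family_id)
  genome_counts <- tapply(family_genomes$genome, family_genomes$family_id,
                          function(g) length(unique(g)))
  rescued_paralog <- vapply(silent_te_genes, function(gid) {
    fams <- fam_of[[gid]]
    if (is.null(fams)) return(FALSE)
    paralogs <- setdiff(unique(unlist(members_of[fams])), gid)
    any(paralogs %in% expressed_ids & !paralogs %in% te_surrounded)
  }, logical(1))
  rescued_ortholog <- vapply(silent_te_genes, function(gid) {
    fams <- fam_of[[gid]]
    if (is.null(fams)) return(FALSE)
    any(!is.na(genome_counts[fams]) & genome_counts[fams] >= min_genomes)
  }, logical(1))
  n <- length(silent_te_genes)
  list(n_silent_te = n,
       n_paralog_rescued = sum(rescued_paralog),
       pct_paralog_rescued = if (n) ratio_percent(sum(rescued_paralog), n) else NA,
       n_ortholog_rescued = sum(rescued_ortholog),
       pct_ortholog_rescued = if (n) ratio_percent(sum(rescued_ortholog), n) else NA,
       paralog_rescued_ids = silent_te_genes[rescued_paralog],
       ortholog_rescued_ids = silent_te_genes[rescued_ortholog])
}
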