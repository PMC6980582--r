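# Stage-wise expression classification over the three developmental stages
# (hyphae, primordia, fruiting body): expressed/silent calls, the seven
# expression patterns with the co-overexpression rule, transition up/down
# sets, the constitutive top-k set, and Fisher exact enrichment.

STAGES <- c("hyphae", "primordia", "fruiting")

validate_expression_table <- function(tbl) {
  stopifnot(is.data.frame(tbl), all(c("gene_id", STAGES) %in% names(tbl)))
  m <- as.matrix(tbl[, STAGES])
  if (anyNA(m) || any(!is.finite(m))) stop("missing/non-finite FPKM value")
  if (any(m < 0)) stop("negative FPKM value")
  if (anyDuplicated(tbl$gene_id)) stop("duplicate gene_id in expression table")
  invisible(tbl)
}

#' Expressed-gene call
#'
#' A gene is expressed when its FPKM strictly exceeds the threshold in at
#' least one stage (the ">1 FPKM" support rule).
#'
#' @param tbl Expression table (gene_id, hyphae, primordia, fruiting).
#' @param threshold FPKM threshold, strict (default 1).
#' @return Logical vector aligned with `tbl` rows.
#' @export
is_expressed <- function(tbl, threshold = 1) {
  validate_expression_table(tbl)
  apply(as.matrix(tbl[, STAGES]) > threshold, 1, any)
}

#' Strict-zero silence call
#'
#' TRUE when FPKM is exactly 0 in every stage; companion to [is_expressed()]
#' for claims worded "zero FPKM values".
#'
#' @inheritParams is_expressed
#' @export
is_silent_zero <- function(tbl) {
  validate_expression_table(tbl)
  apply(as.matrix(tbl[, STAGES]) == 0, 1, all)
}

#' Pseudocount log2 fold change
#'
#' `log2((a + pseudocount) / (b + pseudocount))`. This deterministic estimator
#' stands in for bootstrap-based logFC; the classification rules downstream
#' only consume thresholded values.
#'
#' @param fpkm_a,fpkm_b Non-negative FPKM vectors.
#' @param pseudocount Added to both (default 1 FPKM).
#' @return log2 fold change of a over b.
#' @export
pairwise_logfc <- function(fpkm_a, fpkm_b, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  log2((fpkm_a + pseudocount) / (fpkm_b + pseudocount))
}

#' Seven-pattern expression classification
#'
#' Labels each gene with exactly one of H, P, F (single-stage enriched:
#' that stage exceeds both others with logFC > threshold), HP, PF, HF
#' (co-overexpressed: both stages exceed the third with logFC > threshold and
#' differ from each other by |logFC| < threshold), or NS.
#'
#' @param tbl Expression table.
#' @param lfc_threshold logFC cutoff (default 1, strict).
#' @param pseudocount Passed to [pairwise_logfc()].
#' @return data.frame: gene_id, pattern, logfc_hp, logfc_pf, logfc_hf.
#' @export
classify_pattern <- function(tbl, lfc_threshold = 1, pseudocount = 1) {
  validate_expression_table(tbl)
  h <- tbl$hyphae; p <- tbl$primordia; f <- tbl$fruiting
  l_hp <- pairwise_logfc(h, p, pseudocount)
  l_pf <- pairwise_logfc(p, f, pseudocount)
  l_hf <- pairwise_logfc(h, f, pseudocount)
  t <- lfc_threshold
  pat <- rep("NS", nrow(tbl))
  pat[l_hp >  t & l_hf >  t] <- "H"
  pat[-l_hp > t & l_pf >  t] <- "P"
  pat[-l_pf > t & -l_hf > t] <- "F"
  pat[l_hf >  t & l_pf >  t & abs(l_hp) < t] <- "HP"
  pat[-l_hp > t & -l_hf > t & abs(l_pf) < t] <- "PF"
  pat[l_hp >  t & -l_pf > t & abs(l_hf) < t] <- "HF"
  data.frame(gene_id = tbl$gene_id, pattern = pat,
             logfc_hp = l_hp, logfc_pf = l_pf, logfc_hf = l_hf,
             stringsAsFactors = FALSE)
}

#' Up/down gene sets for a stage transition
#'
#' @param tbl Expression table.
#' @param stage_a,stage_b Stage names ("hyphae", "primordia", "fruiting");
#'   the transition runs a -> b.
#' @param lfc_threshold logFC cutoff (default 1, strict).
#' @param pseudocount Passed to [pairwise_logfc()].
#' @return List with `up` and `down` gene-id vectors (disjoint).
#' @export
transition_de <- function(tbl, stage_a, stage_b, lfc_threshold = 1,
                          pseudocount = 1) {
  validate_expression_table(tbl)
  if (!stage_a %in% STAGES || !stage_b %in% STAGES)
    stop("unknown stage name; expected one of ", paste(STAGES, collapse = ", "))
  l <- pairwise_logfc(tbl[[stage_b]], tbl[[stage_a]], pseudocount)
  list(up = tbl$gene_id[l > lfc_threshold],
       down = tbl$gene_id[l < -lfc_threshold])
}

#' Constitutively high expression set
#'
#' Genes that rank in the top k by FPKM in every stage. Ties at rank k are
#' broken by gene_id lexicographic order so the result is reproducible.
#'
#' @param tbl Expression table.
#' @param k Rank cutoff (default 1000).
#' @return Character vector of gene ids.
#' @export
constitutive_top_k <- function(tbl, k = 1000) {
  validate_expression_table(tbl)
  if (k > nrow(tbl)) stop("k exceeds number of genes")
  tops <- lapply(STAGES, function(s) {
    o <- order(-tbl[[s]], tbl$gene_id)
    tbl$gene_id[o][seq_len(k)]
  })
  Reduce(intersect, tops)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computed by hypergeometric summation with the conventional two-sided rule:
#' the p-value sums the probabilities of all tables (under fixed margins) whose
#' point probability does not exceed that of the observed table, up to a
#' relative tolerance of 1e-7 on the comparison.
#'
#' @param tab 2x2 integer matrix (or vector a,b,c,d filled by row).
#' @return p-value in (0, 1].
#' @export
fisher_exact2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row-1 margin (white balls)
  n <- sum(tab[2, ])   # row-2 margin (black balls)
  k <- sum(tab[, 1])   # column-1 margin (drawn)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher exact enrichment over categories
#'
#' For each category, tests the 2x2 table (in/out foreground x in/out
#' category) over the background universe with [fisher_exact2x2()].
#'
#' @param foreground Character vector of gene ids (subset of background).
#' @param background Character vector of gene ids (the universe).
#' @param category_map data.frame with columns gene_id, category (a gene may
#'   appear in several categories).
#' @param alpha Significance cutoff on the raw p (default 0.01).
#' @param bh Add a Benjamini-Hochberg adjusted column (default FALSE, raw
#'   p-values are the primary output).
#' @return data.frame per category: counts, direction, p, significant.
#' @export
fisher_enrichment <- function(foreground, background, category_map,
                              alpha = 0.01, bh = FALSE) {
  if (!length(foreground)) stop("empty foreground")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  stopifnot(all(c("gene_id", "category") %in% names(category_map)))
  cm <- category_map[category_map$gene_id %in% background, , drop = FALSE]
  cats <- sort(unique(cm$category))
  n_fg <- length(unique(foreground))
  n_bg <- length(unique(background))
  rows <- lapply(cats, function(cat) {
    members <- unique(cm$gene_id[cm$category == cat])
    a <- sum(members %in% foreground)
    b <- n_fg - a
    c_ <- length(members) - a
    d <- n_bg - n_fg - c_
    p <- fisher_exact2x2(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))
    data.frame(category = cat, fg_in = a, fg_out = b, bg_in = c_, bg_out = d,
               direction = if (a / n_fg >= length(members) / n_bg)
                 "enriched" else "depleted",
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (bh) res$p_bh <- stats::p.adjust(res$p, "BH")
  res$significant <- res$p < alpha
  res
}
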