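# Assembly and gene-model summary statistics: N50, GC partitions, gene
# density, percent coding, complete-CDS filtering, intergenic distances.

count_bases <- function(seq, chars) {
  nchar(seq) - nchar(gsub(paste0("[", chars, "]"), "", seq, ignore.case = TRUE))
}

gc_percent <- function(seqs) {
  gc <- sum(vapply(seqs, count_bases, 0, chars = "GC"))
  acgt <- sum(vapply(seqs, count_bases, 0, chars = "ACGT"))
  if (acgt == 0) return(NA_real_)
  100 * gc / acgt
}

#' Assembly statistics
#'
#' N50 is the length L such that sequences of length >= L, taken in decreasing
#' order, cumulatively cover at least half the total assembly. GC content is
#' (G+C)/(A+C+G+T); N and other ambiguity codes are excluded from the
#' denominator so gap runs do not deflate GC.
#'
#' @param seqs Named character vector of scaffold sequences.
#' @return List with total_length, n_sequences, n50, gc_overall (percent).
#' @export
assembly_stats <- function(seqs) {
  if (length(seqs) == 0) stop("empty sequence set")
  lens <- nchar(seqs)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1]]
  list(total_length = sum(lens), n_sequences = length(seqs),
       n50 = unname(n50), gc_overall = gc_percent(seqs))
}

# Merge 0-based half-open intervals (two-column matrix start,end) per scaffold.
merge_intervals <- function(start, end) {
  if (!length(start)) return(cbind(start = integer(), end = integer()))
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i]) else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

extract_intervals <- function(seq, iv) {
  if (!nrow(iv)) return("")
  paste0(substring(seq, iv[, 1] + 1L, iv[, 2]), collapse = "")
}

#' GC content partitioned into coding and non-coding space
#'
#' Coding space is the per-scaffold union of all CDS intervals (a base counts
#' once no matter how many genes cover it); non-coding is its complement.
#'
#' @param seqs Named character vector of scaffold sequences.
#' @param gs A [gene_set].
#' @return List with gc_coding and gc_noncoding (percent; NA when the
#'   partition is empty).
#' @export
partitioned_gc <- function(seqs, gs) {
  stopifnot(inherits(gs, "gene_set"))
  cds <- merge(gs$cds, gs$genes[, c("gene_id", "scaffold")], by = "gene_id")
  if (nrow(cds)) {
    lens <- nchar(seqs)
    if (!all(cds$scaffold %in% names(seqs)))
      stop("CDS on unknown scaffold: ", setdiff(cds$scaffold, names(seqs))[1])
    if (any(cds$end > lens[cds$scaffold]))
      stop("CDS interval out of scaffold bounds")
  }
  coding <- character(); noncoding <- character()
  for (sc in names(seqs)) {
    rows <- cds[cds$scaffold == sc, , drop = FALSE]
    iv <- merge_intervals(rows$start, rows$end)
    coding <- c(coding, extract_intervals(seqs[[sc]], iv))
    # complement of the merged intervals
    len <- nchar(seqs[[sc]])
    bounds <- c(0L, as.vector(t(iv)), len)
    comp <- matrix(bounds, ncol = 2, byrow = TRUE)
    comp <- comp[comp[, 2] > comp[, 1], , drop = FALSE]
    noncoding <- c(noncoding, extract_intervals(seqs[[sc]], comp))
  }
  list(gc_coding = if (sum(nchar(coding))) gc_percent(coding) else NA_real_,
       gc_noncoding = if (sum(nchar(noncoding))) gc_percent(noncoding) else NA_real_)
}

# Lower median: for an even count, the smaller of the two central values.
lower_median <- function(x) {
  if (!length(x)) return(NA_real_)
  sort(x)[ceiling(length(x) / 2)]
}

#' Gene-model statistics
#'
#' Introns are the gaps between consecutive exons of a gene. Percent coding
#' uses the per-scaffold union of CDS intervals so overlapping CDS bases are
#' counted once. Medians are lower medians (reproducible integers).
#'
#' @param gs A [gene_set].
#' @param total_length Assembly length in bp.
#' @return List of gene statistics (density in genes/Mbp, sizes in nt).
#' @export
gene_stats <- function(gs, total_length) {
  stopifnot(inherits(gs, "gene_set"), total_length > 0)
  cds <- merge(gs$cds, gs$genes[, c("gene_id", "scaffold")], by = "gene_id")
  cds_union <- 0
  for (sc in unique(cds$scaffold)) {
    iv <- merge_intervals(cds$start[cds$scaffold == sc],
                          cds$end[cds$scaffold == sc])
    cds_union <- cds_union + sum(iv[, 2] - iv[, 1])
  }
  per_gene_cds <- tapply(gs$cds$end - gs$cds$start, gs$cds$gene_id, sum)
  ex <- gs$exons
  exon_lens <- ex$end - ex$start
  exons_per_gene <- tapply(rep(1L, nrow(ex)), ex$gene_id, sum)
  intron_lens <- unlist(lapply(split(ex, ex$gene_id), function(g) {
    if (nrow(g) < 2) return(integer())
    g$start[-1] - g$end[-nrow(g)]
  }), use.names = FALSE)
  introns_per_gene <- pmax(exons_per_gene - 1L, 0L)
  list(n_genes = nrow(gs$genes),
       gene_density = nrow(gs$genes) / (total_length / 1e6),
       percent_coding = 100 * cds_union / total_length,
       mean_cds_length = if (length(per_gene_cds)) mean(per_gene_cds) else NA_real_,
       total_exons = nrow(ex),
       total_introns = sum(introns_per_gene),
       mean_exon_length = if (length(exon_lens)) mean(exon_lens) else NA_real_,
       mean_intron_length = if (length(intron_lens)) mean(intron_lens) else NA_real_,
       median_exons_per_gene = lower_median(as.integer(exons_per_gene)),
       median_introns_per_gene = lower_median(as.integer(introns_per_gene)))
}

#' Percent coding from aggregate inputs
#'
#' Convenience form used in summary reports when only the printed aggregates
#' are available: total coding nucleotides over genome length.
#'
#' @param n_genes Number of genes.
#' @param mean_cds_nt Mean coding-sequence length in nt.
#' @param total_bp Genome length in bp.
#' @param digits Rounding digits (default 2).
#' @return Percent coding, rounded.
#' @export
percent_coding_from_means <- function(n_genes, mean_cds_nt, total_bp, digits = 2) {
  round(100 * n_genes * mean_cds_nt / total_bp, digits)
}

#' Percentage of a count over a total at the printed rounding
#'
#' The package's summary reports print ratios as percentages rounded to a
#' fixed number of decimals; this is the single formatting path they use.
#'
#' @param numerator,denominator Counts (or sizes in the same unit).
#' @param digits Decimals (default 1).
#' @return Numeric percentage.
#' @export
ratio_percent <- function(numerator, denominator, digits = 1) {
  stopifnot(denominator > 0)
  round(100 * numerator / denominator, digits)
}

#' Flag complete coding sequences
#'
#' Complete means: length divisible by 3, starts with ATG, ends with a stop
#' codon (TAA/TAG/TGA), and no in-frame internal stop. Codons containing N are
#' never treated as stops.
#'
#' @param cds_seqs Named character vector of nucleotide sequences (ACGTN).
#' @return data.frame with id, complete (logical), reason.
#' @export
filter_complete_cds <- function(cds_seqs) {
  stopifnot(length(cds_seqs) > 0)
  bad <- grepl("[^ACGTNacgtn]", cds_seqs)
  if (any(bad))
    stop("non-ACGTN character in sequence '", names(cds_seqs)[bad][1], "'")
  stops <- c("TAA", "TAG", "TGA")
  res <- vapply(cds_seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n %% 3 != 0) return("frame")
    if (substr(s, 1, 3) != "ATG") return("no_start")
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    if (!codons[length(codons)] %in% stops) return("no_stop")
    if (any(codons[-length(codons)] %in% stops)) return("internal_stop")
    "complete"
  }, character(1))
  data.frame(id = names(cds_seqs), complete = res == "complete",
             reason = unname(res), stringsAsFactors = FALSE)
}

#' Intergenic distances
#'
#' For each gene, the edge-to-edge distance (bp) to the nearest neighbouring
#' gene on its left (5') and right (3') side, strand-agnostically. At scaffold
#' ends the distance to the scaffold boundary is reported and flagged
#' truncated. Overlapping neighbours give distance 0, flagged.
#'
#' @param gs A [gene_set].
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @return data.frame: gene_id, dist_5p, dist_3p, trunc_5p, trunc_3p, overlap.
#' @export
intergenic_distances <- function(gs, scaffold_lengths) {
  stopifnot(inherits(gs, "gene_set"))
  g <- gs$genes
  if (!all(g$scaffold %in% names(scaffold_lengths)))
    stop("gene on unknown scaffold: ",
         setdiff(g$scaffold, names(scaffold_lengths))[1])
  out <- lapply(split(g, g$scaffold), function(sg) {
    sg <- sg[order(sg$start, sg$end), , drop = FALSE]
    n <- nrow(sg)
    len <- scaffold_lengths[[sg$scaffold[1]]]
    left <- c(NA, sg$end[-n])       # previous gene's end
    right <- c(sg$start[-1], NA)    # next gene's start
    d5 <- ifelse(is.na(left), sg$start, pmax(sg$start - left, 0L))
    d3 <- ifelse(is.na(right), len - sg$end, pmax(right - sg$end, 0L))
    data.frame(gene_id = sg$gene_id,
               dist_5p = as.integer(d5), dist_3p = as.integer(d3),
               trunc_5p = is.na(left), trunc_3p = is.na(right),
               overlap = (!is.na(left) & left > sg$start) |
                         (!is.na(right) & right < sg$end),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome summary report
#'
#' Assembly plus gene statistics, in the layout of a genome-paper summary
#' table.
#'
#' @param seqs Named character vector of scaffold sequences.
#' @param gs A [gene_set].
#' @return Named list of statistics.
#' @export
genome_summary <- function(seqs, gs) {
  asm <- assembly_stats(seqs)
  part <- partitioned_gc(seqs, gs)
  gen <- gene_stats(gs, asm$total_length)
  c(asm, part, gen)
}
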