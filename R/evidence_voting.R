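# Multi-tool evidence integration: secretome voting with the exclusion
# cascade (TM/ER/GPI), SSP and cysteine-rich classification, CAZyme
# agreement voting, gene-support evidence flags, and Pfam-list tagging.

CAZY_CLASSES <- c("GH", "GT", "PL", "CE", "AA", "CBM")

#' Secretome vote
#'
#' A gene enters the preliminary secreted set when at least `min_votes` of the
#' predictor columns say "Y".
#'
#' @param votes data.frame: gene_id plus one Y/N column per predictor.
#' @param min_votes Minimum agreeing predictors (default 3 of 4).
#' @param predictors Predictor column names; default: all non-gene_id columns.
#' @return Character vector of gene ids.
#' @export
secretome_vote <- function(votes, min_votes = 3, predictors = NULL) {
  stopifnot("gene_id" %in% names(votes))
  if (is.null(predictors)) predictors <- setdiff(names(votes), "gene_id")
  if (length(predictors) < 1) stop("no predictor columns")
  m <- as.matrix(votes[, predictors, drop = FALSE])
  if (anyNA(m) || !all(m %in% c("Y", "N")))
    stop("verdicts must be Y or N with no missing values")
  votes$gene_id[rowSums(m == "Y") >= min_votes]
}

# split a ";"-separated numeric field ("." or "" = none)
split_int_field <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s %in% c("", ".")) return(integer())
    as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

validate_topology <- function(topology) {
  need <- c("gene_id", "protein_length", "cys_count", "tm_starts", "tm_ends",
            "er_motif", "gpi_anchor")
  miss <- setdiff(need, names(topology))
  if (length(miss)) stop("topology table missing column(s): ",
                         paste(miss, collapse = ", "))
  invisible(topology)
}

#' Apply the secreted-protein exclusion cascade
#'
#' Drops genes flagged with an ER-retention motif or a GPI anchor, and genes
#' with transmembrane helices -- unless exactly one helix exists and it starts
#' within `n_term_window` aa of the N-terminus, in which case that single
#' N-terminal helix is treated as the signal peptide and the gene is kept.
#' The three exclusions commute.
#'
#' @param preliminary Gene ids from [secretome_vote()].
#' @param topology data.frame: gene_id, protein_length, cys_count, tm_starts,
#'   tm_ends (";"-separated aa coordinates, "." for none), er_motif,
#'   gpi_anchor (logical or "Y"/"N").
#' @param n_term_window N-terminal window in aa (default 70; helix start <=
#'   window).
#' @return Character vector: the secreted set.
#' @export
apply_exclusions <- function(preliminary, topology, n_term_window = 70) {
  validate_topology(topology)
  topo <- topology[match(preliminary, topology$gene_id), , drop = FALSE]
  if (anyNA(topo$gene_id))
    stop("gene(s) missing from topology table: ",
         paste(utils::head(preliminary[is.na(topo$gene_id)], 5), collapse = ", "))
  as_flag <- function(x) if (is.logical(x)) x else x %in% c("Y", "TRUE", "true")
  er <- as_flag(topo$er_motif)
  gpi <- as_flag(topo$gpi_anchor)
  starts <- split_int_field(topo$tm_starts)
  tm_excluded <- vapply(starts, function(s) {
    if (length(s) == 0) return(FALSE)
    !(length(s) == 1 && s[1] <= n_term_window)
  }, logical(1))
  preliminary[!er & !gpi & !tm_excluded]
}

#' Small and cysteine-rich secreted proteins
#'
#' SSPs are secreted proteins strictly shorter than `max_len` aa;
#' cysteine-rich SSPs have a cysteine fraction strictly above `cys_frac_min`.
#'
#' @param secreted Gene ids (after exclusions).
#' @param topology Topology table (needs protein_length, cys_count).
#' @param max_len SSP length cutoff in aa (default 300, strict <).
#' @param cys_frac_min Cysteine fraction cutoff (default 0.03, strict >).
#' @return List with `ssp` and `cysteine_rich` gene-id vectors.
#' @export
classify_ssp <- function(secreted, topology, max_len = 300,
                         cys_frac_min = 0.03) {
  validate_topology(topology)
  topo <- topology[match(secreted, topology$gene_id), , drop = FALSE]
  len <- as.numeric(topo$protein_length)
  cys <- as.numeric(topo$cys_count)
  if (any(is.na(len)) || any(len <= 0)) stop("invalid (zero-length?) protein")
  ssp <- secreted[len < max_len]
  frac <- cys / len
  list(ssp = ssp,
       cysteine_rich = secreted[len < max_len & frac > cys_frac_min])
}

# parse one predictor cell into a character vector of family labels
split_family_field <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s %in% c("", ".", "none")) return(character())
    strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

#' CAZyme agreement voting
#'
#' A gene is assigned family X when at least `min_agree` predictors call
#' exactly X. A gene may carry several families if each independently meets
#' the rule; with no agreeing family it stays unassigned.
#'
#' @param cazy data.frame: gene_id plus one column per predictor; cells are
#'   ";"-separated family labels (e.g. "GH5;CBM1") or "." for none.
#' @param min_agree Minimum agreeing predictors (default 2 of 3).
#' @param predictors Predictor columns; default: all non-gene_id columns.
#' @return data.frame gene_id, family (one row per assignment).
#' @export
cazyme_vote <- function(cazy, min_agree = 2, predictors = NULL) {
  stopifnot("gene_id" %in% names(cazy))
  if (is.null(predictors)) predictors <- setdiff(names(cazy), "gene_id")
  calls <- lapply(predictors, function(p) split_family_field(cazy[[p]]))
  all_labels <- unique(unlist(calls))
  bad <- all_labels[!grepl(paste0("^(", paste(CAZY_CLASSES, collapse = "|"),
                                  ")[0-9]+$"), all_labels)]
  if (length(bad)) stop("invalid CAZyme family label: ", bad[1])
  out <- lapply(seq_len(nrow(cazy)), function(i) {
    per_tool <- lapply(calls, function(tool) unique(tool[[i]]))
    fams <- unique(unlist(per_tool))
    if (!length(fams)) return(NULL)
    support <- vapply(fams, function(f)
      sum(vapply(per_tool, function(s) f %in% s, logical(1))), 0L)
    hit <- fams[support >= min_agree]
    if (!length(hit)) return(NULL)
    data.frame(gene_id = cazy$gene_id[i], family = sort(hit),
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(gene_id = character(), family = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-support evidence flags
#'
#' Three independent lines of support per gene: RNA-seq (expressed, FPKM >
#' threshold in >= 1 stage), functional domain (>= 1 Pfam domain), ortholog
#' (member of a family spanning strictly more than `min_genomes` genomes).
#'
#' @param expression Expression table.
#' @param pfam_table data.frame gene_id, domain (one row per assignment).
#' @param gene_families data.frame gene_id, family_id.
#' @param family_genomes data.frame family_id, genome.
#' @param min_genomes Genome count that must be strictly exceeded (default 5).
#' @param threshold FPKM threshold (default 1).
#' @return data.frame: gene_id, rnaseq_supported, domain_supported,
#'   ortholog_supported, supported.
#' @export
gene_support_evidence <- function(expression, pfam_table, gene_families,
                                  family_genomes, min_genomes = 5,
                                  threshold = 1) {
  validate_expression_table(expression)
  ids <- expression$gene_id
  rnaseq <- is_expressed(expression, threshold)
  domain <- ids %in% pfam_table$gene_id
  genome_counts <- tapply(family_genomes$genome, family_genomes$family_id,
                          function(g) length(unique(g)))
  strong_fams <- names(genome_counts)[genome_counts > min_genomes]
  ortho <- ids %in% gene_families$gene_id[gene_families$family_id %in% strong_fams]
  data.frame(gene_id = ids, rnaseq_supported = rnaseq,
             domain_supported = domain, ortholog_supported = ortho,
             supported = rnaseq | domain | ortho,
             stringsAsFactors = FALSE)
}

#' Filter or tag genes by a Pfam domain list
#'
#' In "remove" mode, splits genes into those carrying no listed domain (kept)
#' and those carrying at least one (removed) -- e.g. dropping TE-derived gene
#' models by gag/reverse-transcriptase domains. In "tag" mode returns only
#' the matching set -- e.g. transcription-factor tagging from a DNA-binding
#' domain list.
#'
#' @param gene_ids Character vector of genes to screen.
#' @param pfam_table data.frame gene_id, domain.
#' @param domain_list Character vector of Pfam accessions (PF + 5 digits).
#' @param mode "remove" (default) or "tag".
#' @return List(kept, removed) in remove mode; character vector in tag mode.
#' @export
filter_by_domain_list <- function(gene_ids, pfam_table, domain_list,
                                  mode = c("remove", "tag")) {
  mode <- match.arg(mode)
  bad <- domain_list[!grepl("^PF[0-9]{5}$", domain_list)]
  if (length(bad)) stop("malformed Pfam accession: ", bad[1])
  hit_ids <- unique(pfam_table$gene_id[pfam_table$domain %in% domain_list])
  matched <- gene_ids[gene_ids %in% hit_ids]
  if (mode == "tag") return(matched)
  list(kept = setdiff(gene_ids, matched), removed = matched)
}

#' Full secretome pipeline
#'
#' Vote, exclusion cascade, and SSP classification in one call.
#'
#' @param votes Secretion vote table.
#' @param topology Topology table.
#' @param min_votes,n_term_window,max_len,cys_frac_min Stage parameters.
#' @return List: preliminary, secreted, ssp, cysteine_rich.
#' @export
secretome_pipeline <- function(votes, topology, min_votes = 3,
                               n_term_window = 70, max_len = 300,
                               cys_frac_min = 0.03) {
  prelim <- secretome_vote(votes, min_votes)
  secreted <- apply_exclusions(prelim, topology, n_term_window)
  ssp <- classify_ssp(secreted, topology, max_len, cys_frac_min)
  list(preliminary = prelim, secreted = secreted,
       ssp = ssp$ssp, cysteine_rich = ssp$cysteine_rich)
}
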