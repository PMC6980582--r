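# RIP-style dinucleotide hypermutation statistics on repeat-family
# alignments. Each family is a gap-allowed alignment of copies against a
# model sequence (majority consensus by default). A model C -> copy T event
# is binned by the model's 3' neighbour (context CpA/CpC/CpG/CpT); a model
# G -> copy A event is the same event seen on the reverse strand and maps to
# the complement of the model's 5' neighbour.

RIP_CONTEXTS <- c("CpA", "CpC", "CpG", "CpT")
BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Repeat family alignment container
#'
#' @param family_id Family identifier.
#' @param copies Named character vector of aligned copies (equal length,
#'   alphabet ACGTN-).
#' @param model Optional aligned model sequence; built by majority consensus
#'   when NULL.
#' @return Object of class `repeat_family`.
#' @export
repeat_family <- function(family_id, copies, model = NULL) {
  stopifnot(nzchar(family_id), length(copies) >= 1)
  lens <- nchar(copies)
  if (length(unique(lens)) != 1) stop("aligned copies differ in length")
  if (any(grepl("[^ACGTN-]", toupper(copies))))
    stop("alignment alphabet must be ACGTN-")
  if (is.null(model)) model <- build_consensus(copies)
  if (nchar(model) != lens[1]) stop("model length differs from copies")
  structure(list(family_id = family_id, model = toupper(model),
                 copies = stats::setNames(toupper(copies), names(copies))),
            class = "repeat_family")
}

#' Majority-consensus model sequence
#'
#' Per column: the majority base among A/C/G/T characters, ties broken by the
#' fixed order A < C < G < T; a column whose gaps outnumber its bases (or with
#' no base at all) emits a gap. N counts as neither base nor gap.
#'
#' @param copies Character vector of equal-length aligned sequences.
#' @return Consensus string.
#' @export
build_consensus <- function(copies) {
  stopifnot(length(copies) >= 2)
  m <- do.call(rbind, strsplit(toupper(copies), ""))
  apply_col <- function(col) {
    counts <- tabulate(match(col, BASES), nbins = 4)
    gaps <- sum(col == "-")
    if (sum(counts) == 0 || gaps > sum(counts)) return("-")
    BASES[which.max(counts)]  # which.max takes the first max: A<C<G<T
  }
  paste0(apply(m, 2, apply_col), collapse = "")
}

#' Highest-GC copy as model
#'
#' Alternative model choice: the copy with the highest GC fraction (over its
#' non-gap bases); ties broken by copy order.
#'
#' @param copies Character vector of aligned copies.
#' @return The selected copy.
#' @export
highest_gc_copy <- function(copies) {
  gc <- vapply(copies, function(s) {
    s <- toupper(s)
    b <- count_bases(s, "ACGT")
    if (b == 0) return(-1)
    count_bases(s, "GC") / b
  }, 0)
  copies[[which.max(gc)]]
}

# index of nearest non-gap model position before/after i, or NA
nearest_nongap <- function(chars, i, dir) {
  j <- i + dir
  while (j >= 1 && j <= length(chars)) {
    if (chars[j] != "-") return(j)
    j <- j + dir
  }
  NA_integer_
}

#' Substitution counts of one copy against the model
#'
#' Comparison is restricted to columns where both model and copy carry a base
#' (no gap, no N). Transitions are A<->G and C<->T; all other substitutions
#' are transversions. Model-C -> copy-T events are binned by the model's next
#' non-gap base (context CpX); model-G -> copy-A events are binned as
#' reverse-strand C->T with context CpX where X is the complement of the
#' model's previous non-gap base.
#'
#' @param model,copy Equal-length aligned sequences.
#' @return List: transitions, transversions, c_to_t_by_context (named counts
#'   over CpA/CpC/CpG/CpT).
#' @export
count_mutations <- function(model, copy) {
  if (nchar(model) != nchar(copy)) stop("model/copy length mismatch")
  mc <- strsplit(toupper(model), "")[[1]]
  cc <- strsplit(toupper(copy), "")[[1]]
  comparable <- mc %in% BASES & cc %in% BASES
  diff <- comparable & mc != cc
  ti <- diff & ((mc == "A" & cc == "G") | (mc == "G" & cc == "A") |
                (mc == "C" & cc == "T") | (mc == "T" & cc == "C"))
  ctx <- stats::setNames(integer(4), RIP_CONTEXTS)
  for (i in which(diff)) {
    x <- NA_character_
    if (mc[i] == "C" && cc[i] == "T") {
      j <- nearest_nongap(mc, i, +1L)
      if (!is.na(j) && mc[j] %in% BASES) x <- mc[j]
    } else if (mc[i] == "G" && cc[i] == "A") {
      j <- nearest_nongap(mc, i, -1L)
      if (!is.na(j) && mc[j] %in% BASES) x <- COMPLEMENT[[mc[j]]]
    }
    if (!is.na(x)) {
      key <- paste0("Cp", x)
      ctx[key] <- ctx[key] + 1L
    }
  }
  list(transitions = sum(ti), transversions = sum(diff) - sum(ti),
       c_to_t_by_context = ctx)
}

#' Family-level RIP statistics
#'
#' Pools per-copy substitution counts into a family transition/transversion
#' ratio and computes the fraction of copies carrying a dominant C->T
#' context. A copy's dominant context is the strict argmax of its context
#' counts (declared only when the maximum is positive and strictly exceeds
#' the runner-up). The family's dominant context is the most frequent
#' per-copy dominant context (ties broken in CpA < CpC < CpG < CpT order).
#'
#' @param family A [repeat_family].
#' @param min_copies Minimum copies required (default 3); smaller families
#'   return NULL with a message.
#' @param min_context_count Minimum count for a dominant context (default 1).
#' @return List with family_id, n_copies, transitions, transversions,
#'   titv_ratio (Inf when transversions are 0 and transitions > 0, NA when
#'   both are 0), per_copy (data.frame), biased_fraction, dominant_context.
#' @export
family_rip_statistics <- function(family, min_copies = 3,
                                  min_context_count = 1) {
  stopifnot(inherits(family, "repeat_family"))
  if (length(family$copies) < min_copies) {
    message("family ", family$family_id, " skipped: fewer than ",
            min_copies, " copies")
    return(NULL)
  }
  counts <- lapply(family$copies, count_mutations, model = family$model)
  ti <- sum(vapply(counts, `[[`, 0, "transitions"))
  tv <- sum(vapply(counts, `[[`, 0, "transversions"))
  titv <- if (tv > 0) ti / tv else if (ti > 0) Inf else NA_real_
  dom <- vapply(counts, function(x) {
    v <- sort(x$c_to_t_by_context, decreasing = TRUE)
    if (v[1] >= min_context_count && v[1] > v[2]) {
      names(x$c_to_t_by_context)[which.max(x$c_to_t_by_context)]
    } else NA_character_
  }, character(1))
  biased_fraction <- mean(!is.na(dom))
  family_dom <- if (any(!is.na(dom))) {
    tab <- table(factor(dom, levels = RIP_CONTEXTS))
    RIP_CONTEXTS[which.max(tab)]
  } else NA_character_
  per_copy <- data.frame(
    copy = names(family$copies),
    transitions = vapply(counts, `[[`, 0, "transitions"),
    transversions = vapply(counts, `[[`, 0, "transversions"),
    titv = ifelse(vapply(counts, `[[`, 0, "transversions") > 0,
                  vapply(counts, `[[`, 0, "transitions") /
                    vapply(counts, `[[`, 0, "transversions"), NA),
    dominant_context = dom,
    stringsAsFactors = FALSE)
  ctx_tot <- Reduce(`+`, lapply(counts, `[[`, "c_to_t_by_context"))
  rownames(per_copy) <- NULL
  list(family_id = family$family_id, n_copies = length(family$copies),
       transitions = ti, transversions = tv, titv_ratio = titv,
       context_counts = ctx_tot, per_copy = per_copy,
       biased_fraction = biased_fraction, dominant_context = family_dom)
}

#' Classify a repeat family as RIP-affected
#'
#' A family is called RIP-affected when its pooled transition/transversion
#' ratio strictly exceeds `titv_min` (an infinite ratio passes; an undefined
#' 0/0 ratio fails, flagged) AND the fraction of copies with a dominant C->T
#' context strictly exceeds `bias_min`.
#'
#' @param stats Output of [family_rip_statistics()].
#' @param titv_min Transition/transversion cutoff (default 2, strict).
#' @param bias_min Biased-copy fraction cutoff (default 1/3, strict).
#' @return List (a family RIP call): stats fields plus is_rip and
#'   titv_undefined.
#' @export
classify_rip_family <- function(stats, titv_min = 2, bias_min = 1/3) {
  if (is.null(stats)) return(NULL)
  undefined <- is.na(stats$titv_ratio)
  pass_titv <- !undefined && stats$titv_ratio > titv_min
  c(stats, list(is_rip = pass_titv && stats$biased_fraction > bias_min,
                titv_undefined = undefined))
}

#' Genome-wide RIP summary
#'
#' @param calls List of family RIP calls ([classify_rip_family()]); NULL
#'   entries (skipped families) are dropped.
#' @return List: n_families, n_rip, context_histogram (named counts of
#'   dominant contexts among RIP-called families), modal_context.
#' @export
genome_rip_summary <- function(calls) {
  calls <- Filter(Negate(is.null), calls)
  if (!length(calls)) stop("no family calls")
  is_rip <- vapply(calls, `[[`, logical(1), "is_rip")
  dom <- vapply(calls[is_rip], function(x)
    if (is.na(x$dominant_context)) "none" else x$dominant_context, "")
  hist <- table(factor(dom, levels = c(RIP_CONTEXTS, "none")))
  hist <- hist[hist > 0]
  list(n_families = length(calls), n_rip = sum(is_rip),
       context_histogram = as.list(hist),
       modal_context = if (length(hist)) names(hist)[which.max(hist)]
                       else NA_character_)
}

#' Read a repeat-family alignment from multi-FASTA
#'
#' @param path Aligned multi-FASTA for one family.
#' @param family_id Family id; defaults to the file name without extension.
#' @param model "build" (majority consensus, default), "first" (first record
#'   is the model) or "max_gc" (highest-GC copy).
#' @return A [repeat_family].
#' @export
read_family_alignment <- function(path, family_id = NULL,
                                  model = c("build", "first", "max_gc")) {
  model <- match.arg(model)
  if (is.null(family_id))
    family_id <- tools::file_path_sans_ext(basename(path), compression = TRUE)
  family_id <- sub("\\.aln$", "", family_id)
  seqs <- read_fasta(path)
  switch(model,
    build = repeat_family(family_id, seqs),
    first = repeat_family(family_id, seqs[-1], model = seqs[[1]]),
    max_gc = repeat_family(family_id, seqs, model = highest_gc_copy(seqs)))
}
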