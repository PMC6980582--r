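# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-implementations (brute force / closed form) that do
# not share code with the package internals they check.

# N50 by literal definition: largest L such that sequences of length >= L
# cover at least half the total.
oracle_n50 <- function(lens) {
  total <- sum(lens)
  best <- 0
  for (L in sort(unique(lens))) {
    if (sum(lens[lens >= L]) >= total / 2) best <- L
  }
  best
}

# All-pairs flank qualification: for each gene, scan every repeat and test
# window intersection literally.
oracle_te_surrounded <- function(genes_df, repeats_df, window = 1000,
                                 min_len = 400) {
  hits <- character()
  for (i in seq_len(nrow(genes_df))) {
    gsta <- genes_df$start[i]; gend <- genes_df$end[i]
    left_ok <- FALSE; right_ok <- FALSE
    for (j in seq_len(nrow(repeats_df))) {
      if (repeats_df$scaffold[j] != genes_df$scaffold[i]) next
      if (repeats_df$end[j] - repeats_df$start[j] <= min_len) next
      rs <- repeats_df$start[j]; re <- repeats_df$end[j]
      # intersection of [rs, re) with [gsta - window, gsta)
      if (max(rs, gsta - window) < min(re, gsta)) left_ok <- TRUE
      # intersection of [rs, re) with [gend, gend + window)
      if (max(rs, gend) < min(re, gend + window)) right_ok <- TRUE
    }
    if (left_ok && right_ok) hits <- c(hits, genes_df$gene_id[i])
  }
  hits
}

# Expression-pattern decision table recomputed from scratch: compare the
# three stage values pairwise on the log2 ratio of pseudocounted FPKM and
# walk an explicit decision list.
oracle_pattern <- function(h, p, f, t = 1, pc = 1) {
  lr <- function(a, b) log2(a + pc) - log2(b + pc)
  over <- function(a, b) lr(a, b) > t
  close_ <- function(a, b) abs(lr(a, b)) < t
  if (over(h, p) && over(h, f)) return("H")
  if (over(p, h) && over(p, f)) return("P")
  if (over(f, p) && over(f, h)) return("F")
  if (over(h, f) && over(p, f) && close_(h, p)) return("HP")
  if (over(p, h) && over(f, h) && close_(p, f)) return("PF")
  if (over(h, p) && over(f, p) && close_(h, f)) return("HF")
  "NS"
}

# Two-sided Fisher p by closed-form hypergeometric enumeration (lchoose,
# no dhyper): sum of probabilities of tables no more probable than observed.
oracle_fisher2x2 <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  supp <- lo:hi
  logp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  probs <- exp(logp)
  pobs <- probs[supp == a]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Per-column substitution recount walking the alignment once, with its own
# gap-skipping context lookup.
oracle_count_mutations <- function(model, copy) {
  m <- strsplit(toupper(model), "")[[1]]
  c_ <- strsplit(toupper(copy), "")[[1]]
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ti <- 0L; tv <- 0L
  ctx <- c(CpA = 0L, CpC = 0L, CpG = 0L, CpT = 0L)
  for (i in seq_along(m)) {
    if (!(m[i] %in% bases) || !(c_[i] %in% bases) || m[i] == c_[i]) next
    pair <- paste0(m[i], c_[i])
    if (pair %in% c("AG", "GA", "CT", "TC")) ti <- ti + 1L else tv <- tv + 1L
    nb <- NA_character_
    if (pair == "CT") {
      j <- i + 1
      while (j <= length(m) && m[j] == "-") j <- j + 1
      if (j <= length(m) && m[j] %in% bases) nb <- m[j]
    } else if (pair == "GA") {
      j <- i - 1
      while (j >= 1 && m[j] == "-") j <- j - 1
      if (j >= 1 && m[j] %in% bases) nb <- comp[[m[j]]]
    }
    if (!is.na(nb)) ctx[paste0("Cp", nb)] <- ctx[paste0("Cp", nb)] + 1L
  }
  list(transitions = ti, transversions = tv, c_to_t_by_context = ctx)
}

# random helpers for property tests
random_gene_df <- function(n, scaffolds, max_pos = 20000, gene_len = 500) {
  start <- sample(0:(max_pos - gene_len), n, replace = TRUE)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             scaffold = sample(scaffolds, n, replace = TRUE),
             start = start, end = start + gene_len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_repeat_df <- function(n, scaffolds, max_pos = 20000) {
  start <- sample(0:(max_pos - 1), n, replace = TRUE)
  len <- sample(c(100, 300, 400, 401, 500, 1200), n, replace = TRUE)
  repeat_hits(scaffold = sample(scaffolds, n, replace = TRUE),
              start = start, end = start + len,
              strand = sample(c("+", "-"), n, replace = TRUE),
              family = sprintf("fam%02d", sample(9, n, replace = TRUE)),
              repeat_class = sample(c("LTR/Gypsy", "LTR/Copia", "DNA"), n,
                                    replace = TRUE))
}

toy_gene_set <- function(genes_df) {
  exons <- data.frame(gene_id = genes_df$gene_id, start = genes_df$start,
                      end = genes_df$end, stringsAsFactors = FALSE)
  gene_set(genes_df, exons, exons)
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(lapply(strsplit(s, ""), rev), paste0, "", collapse = ""))
}
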