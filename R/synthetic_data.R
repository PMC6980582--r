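# Synthetic genomes with planted ground truth. The generator emits exactly
# the file formats the analysis modules read, and every planted label is
# verifiable from the emitted files alone.
#
# RNG discipline: one base seed in the config; each sub-generator derives its
# own stream by a fixed offset (genome +0, expression +10000, votes +20000,
# homology +25000, family i +30000+i) so regenerating one component never
# perturbs the others.

#' Simulation configuration
#'
#' Defaults describe the stated world of the analyses: a 5 x 1 Mbp genome
#' with 500 genes of which 20% are planted TE-surrounded (flanking repeats
#' longer than 400 bp within 1000 bp on both sides); TE-surrounded genes are
#' silenced with probability 0.832 against a background of 0.32; RIP families
#' carry C->T mutations at CpG sites at 20x the background transversion rate.
#'
#' @param seed Base RNG seed.
#' @param n_scaffolds,scaffold_length,n_genes,gene_length Genome geometry.
#' @param frac_te_surrounded Fraction of genes planted TE-surrounded.
#' @param te_length_range Planted repeat length range (min must exceed
#'   min_te_len when TE-surrounded genes are requested).
#' @param flank_gap Distance (bp) from gene edge to planted repeat; must be
#'   strictly below `window`.
#' @param window,min_te_len Detector parameters the plants are built against.
#' @param p_silent_given_te,p_silent_background Silencing probabilities.
#' @param fpkm_log_mean,fpkm_log_sd Lognormal FPKM parameters (log scale).
#' @param n_families,copies_per_family,family_length Repeat-family geometry.
#' @param rip_rate Per-eligible-site C->T probability.
#' @param rip_context Planted dinucleotide context (CpA/CpC/CpG/CpT).
#' @param background_transversion_rate Per-site transversion probability.
#' @param gc_content Background GC fraction.
#' @param frac_secreted,frac_cazyme Planted label fractions for vote tables.
#' @param frac_paralog_rescued,frac_ortholog_rescued Fractions of silent
#'   TE-surrounded genes given rescue evidence.
#' @return Validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_scaffolds = 5L, scaffold_length = 1e6,
                              n_genes = 500L, gene_length = 1500L,
                              frac_te_surrounded = 0.2,
                              te_length_range = c(500L, 1500L),
                              flank_gap = 200L,
                              window = 1000L, min_te_len = 400L,
                              p_silent_given_te = 0.832,
                              p_silent_background = 0.32,
                              fpkm_log_mean = 1.5, fpkm_log_sd = 1.5,
                              n_families = 20L, copies_per_family = 10L,
                              family_length = 800L,
                              rip_rate = 0.1, rip_context = "CpG",
                              background_transversion_rate = 0.005,
                              gc_content = 0.5,
                              frac_secreted = 0.08, frac_cazyme = 0.05,
                              frac_paralog_rescued = 0.26,
                              frac_ortholog_rescued = 0.497) {
  cfg <- as.list(environment())
  probs <- c(frac_te_surrounded, p_silent_given_te, p_silent_background,
             rip_rate, background_transversion_rate, gc_content,
             frac_secreted, frac_cazyme, frac_paralog_rescued,
             frac_ortholog_rescued)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (te_length_range[1] <= 0 || te_length_range[2] < te_length_range[1])
    stop("invalid te_length_range")
  if (!rip_context %in% RIP_CONTEXTS)
    stop("rip_context must be one of ", paste(RIP_CONTEXTS, collapse = ", "))
  if (fpkm_log_sd <= 0) stop("fpkm_log_sd must be positive")
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc) {
  paste0(sample(BASES, n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

gene_id_fmt <- function(i) sprintf("gene_%04d", i)

#' Simulate a genome with planted TE-surrounded genes
#'
#' Genes are placed one per isolated slot; slots are padded by the detector
#' window plus the maximal repeat length, so a repeat planted for one gene
#' can never reach another gene's flank window. Exactly
#' `round(frac_te_surrounded * n_genes)` genes get a qualifying repeat
#' (length > min_te_len) at `flank_gap` bp on BOTH flanks. The remaining
#' genes cycle through decoy contexts: no repeat, a qualifying repeat on one
#' flank only, or repeats of length exactly `min_te_len` (rejected by the
#' strict length filter) on both flanks.
#'
#' @param config A [simulation_config()].
#' @return List: sequences (named character), genes ([gene_set]), repeats
#'   (repeat table), truth (list with te_surrounded_ids, decoy types).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  te_max <- cfg$te_length_range[2]
  if (cfg$frac_te_surrounded > 0) {
    if (cfg$te_length_range[1] <= cfg$min_te_len)
      stop("te_length_range minimum must exceed min_te_len (",
           cfg$min_te_len, ") to plant detectable repeats")
    if (cfg$flank_gap >= cfg$window)
      stop("flank_gap must be strictly below the detector window")
  }
  pad <- cfg$window
  slot <- 2 * pad + 2 * (te_max + cfg$flank_gap) + cfg$gene_length
  slots_per_scaffold <- floor(cfg$scaffold_length / slot)
  if (slots_per_scaffold * cfg$n_scaffolds < cfg$n_genes)
    stop("config error: ", cfg$n_genes, " genes do not fit ",
         cfg$n_scaffolds, " x ", cfg$scaffold_length,
         " bp scaffolds at slot width ", slot)
  set.seed(cfg$seed)

  scaffold_ids <- sprintf("scaffold_%02d", seq_len(cfg$n_scaffolds))
  seqs <- stats::setNames(
    vapply(scaffold_ids, function(s)
      random_dna(cfg$scaffold_length, cfg$gc_content), ""),
    scaffold_ids)

  # round-robin gene placement over scaffolds
  scaf_idx <- rep(seq_len(cfg$n_scaffolds), length.out = cfg$n_genes)
  slot_idx <- (seq_len(cfg$n_genes) - 1) %/% cfg$n_scaffolds
  gene_start <- slot_idx * slot + pad + te_max + cfg$flank_gap
  gene_end <- gene_start + cfg$gene_length
  ids <- gene_id_fmt(seq_len(cfg$n_genes))
  genes <- data.frame(gene_id = ids, scaffold = scaffold_ids[scaf_idx],
                      start = as.integer(gene_start),
                      end = as.integer(gene_end),
                      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  # two exons with a 100 bp intron when the gene is long enough
  if (cfg$gene_length >= 800) {
    exons <- rbind(
      data.frame(gene_id = ids, start = genes$start, end = genes$start + 600L),
      data.frame(gene_id = ids, start = genes$start + 700L, end = genes$end))
  } else {
    exons <- data.frame(gene_id = ids, start = genes$start, end = genes$end)
  }
  gs <- gene_set(genes, exons, exons)

  n_te <- round(cfg$frac_te_surrounded * cfg$n_genes)
  te_ids <- sort(sample(ids, n_te))
  decoy_pool <- setdiff(ids, te_ids)
  decoy_type <- stats::setNames(
    rep_len(c("none", "left_only", "right_only", "short_both"),
            length(decoy_pool)),
    sample(decoy_pool))

  rlen <- function(n) sample(seq(cfg$te_length_range[1], te_max), n,
                             replace = TRUE)
  fam_pool <- c("Gypsy-1", "Gypsy-2", "Copia-1", "Copia-2", "LINE-1", "DNA-1")
  cls_pool <- c("LTR/Gypsy", "LTR/Gypsy", "LTR/Copia", "LTR/Copia",
                "LINE/L1", "DNA/TcMar")
  mk_rep <- function(gene_row, side, len) {
    if (side == "left") {
      e <- genes$start[gene_row] - cfg$flank_gap
      s <- e - len
    } else {
      s <- genes$end[gene_row] + cfg$flank_gap
      e <- s + len
    }
    k <- sample(length(fam_pool), 1)
    data.frame(scaffold = genes$scaffold[gene_row], start = s, end = e,
               strand = sample(c("+", "-"), 1), family = fam_pool[k],
               repeat_class = cls_pool[k], stringsAsFactors = FALSE)
  }
  reps <- list()
  for (gid in te_ids) {
    i <- match(gid, ids)
    reps[[length(reps) + 1]] <- mk_rep(i, "left", rlen(1))
    reps[[length(reps) + 1]] <- mk_rep(i, "right", rlen(1))
  }
  for (gid in names(decoy_type)) {
    i <- match(gid, ids)
    reps[[length(reps) + 1]] <- switch(
      decoy_type[[gid]],
      none = NULL,
      left_only = mk_rep(i, "left", rlen(1)),
      right_only = mk_rep(i, "right", rlen(1)),
      short_both = rbind(mk_rep(i, "left", cfg$min_te_len),
                         mk_rep(i, "right", cfg$min_te_len)))
  }
  reps <- do.call(rbind, Filter(Negate(is.null), reps))
  reps <- reps[order(reps$scaffold, reps$start), , drop = FALSE]
  repeats <- repeat_hits(reps$scaffold, reps$start, reps$end, reps$strand,
                         reps$family, reps$repeat_class)
  list(sequences = seqs, genes = gs, repeats = repeats,
       truth = list(te_surrounded_ids = te_ids,
                    decoy_type = as.list(decoy_type)))
}

#' Simulate one RIP-mutated repeat family
#'
#' A consensus of length `family_length` is drawn at the configured GC; each
#' copy then receives C->T mutations at forward-strand sites whose 3'
#' neighbour matches `rip_context` (and the symmetric reverse-strand G->A
#' events) with probability `rip_rate`, plus background transversions at
#' `background_transversion_rate` on the remaining sites. The alignment is
#' gap-free by construction and the original consensus is kept as the model.
#'
#' @param config A [simulation_config()].
#' @param family_id Family identifier.
#' @param index Family index (fixed RNG offset; default 1).
#' @return List: family ([repeat_family]), planted (per-copy data.frame with
#'   rip_events, bg_events, context).
#' @export
simulate_rip_family <- function(config, family_id, index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed + 30000L + index)
  cons <- strsplit(random_dna(cfg$family_length, cfg$gc_content), "")[[1]]
  x <- substr(cfg$rip_context, 3, 3)           # the 3' neighbour base
  n <- length(cons)
  fwd <- which(cons == "C" & c(cons[-1], "") == x)
  rev_ <- which(cons == "G" & c("", cons[-n]) == COMPLEMENT[[x]])
  eligible <- union(fwd, rev_)
  copies <- character(cfg$copies_per_family)
  planted <- data.frame(copy = sprintf("%s_copy%02d", family_id,
                                       seq_len(cfg$copies_per_family)),
                        rip_events = 0L, bg_events = 0L,
                        stringsAsFactors = FALSE)
  tv_partner <- list(A = c("C", "T"), C = c("A", "G"),
                     G = c("C", "T"), T = c("A", "G"))
  for (k in seq_len(cfg$copies_per_family)) {
    cp <- cons
    hit <- eligible[stats::runif(length(eligible)) < cfg$rip_rate]
    cp[intersect(hit, fwd)] <- "T"
    cp[intersect(hit, rev_)] <- "A"
    rest <- setdiff(seq_len(n), hit)
    bg <- rest[stats::runif(length(rest)) < cfg$background_transversion_rate]
    for (i in bg) cp[i] <- sample(tv_partner[[cp[i]]], 1)
    planted$rip_events[k] <- length(hit)
    planted$bg_events[k] <- length(bg)
    copies[k] <- paste0(cp, collapse = "")
  }
  names(copies) <- planted$copy
  fam <- repeat_family(family_id, copies, model = paste0(cons, collapse = ""))
  list(family = fam, planted = planted, context = cfg$rip_context)
}

#' Simulate a stage-wise FPKM table with planted silencing
#'
#' TE-surrounded genes are planted silent (all-stage FPKM = 0) with
#' probability `p_silent_given_te`, the rest with `p_silent_background`;
#' non-silent genes draw independent lognormal FPKM values per stage.
#'
#' @param gene_ids Character vector of gene ids (or a [gene_set]).
#' @param truth Truth list holding `te_surrounded_ids`.
#' @param config A [simulation_config()].
#' @return List: table (expression table), silent_ids (planted all-zero
#'   genes).
#' @export
simulate_expression <- function(gene_ids, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(gene_ids, "gene_set")) gene_ids <- gene_ids$genes$gene_id
  set.seed(config$seed + 10000L)
  n <- length(gene_ids)
  is_te <- gene_ids %in% truth$te_surrounded_ids
  p <- ifelse(is_te, config$p_silent_given_te, config$p_silent_background)
  silent <- stats::runif(n) < p
  draw <- function() ifelse(silent, 0,
    stats::rlnorm(n, config$fpkm_log_mean, config$fpkm_log_sd))
  tbl <- data.frame(gene_id = gene_ids,
                    hyphae = draw(), primordia = draw(), fruiting = draw(),
                    stringsAsFactors = FALSE)
  list(table = tbl, silent_ids = gene_ids[silent])
}

#' Simulate predictor vote tables with planted labels
#'
#' Plants a secreted set (with SSP and cysteine-rich subsets), exclusion
#' decoys (vote-positive genes carrying a disqualifying TM helix, ER motif or
#' GPI anchor), and CAZyme family assignments. Noise-free: planted positives
#' always receive >= 3 of 4 secretion votes (resp. >= 2 agreeing CAZyme
#' calls) and planted negatives never do.
#'
#' @param gene_ids Character vector of gene ids (or a [gene_set]).
#' @param config A [simulation_config()].
#' @return List: votes (secretion table), topology, cazyme, truth (list with
#'   secreted_ids, ssp_ids, cysteine_rich_ids, excluded_ids,
#'   cazyme_assignments).
#' @export
simulate_votes <- function(gene_ids, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(gene_ids, "gene_set")) gene_ids <- gene_ids$genes$gene_id
  set.seed(config$seed + 20000L)
  n <- length(gene_ids)
  n_sec <- max(2L, round(config$frac_secreted * n))
  n_excl <- max(3L, round(0.02 * n))
  picks <- sample(gene_ids, n_sec + n_excl)
  secreted <- sort(picks[seq_len(n_sec)])
  excluded <- sort(picks[n_sec + seq_len(n_excl)])
  others <- setdiff(gene_ids, c(secreted, excluded))

  # protein lengths / cysteine counts
  len <- stats::setNames(sample(300:900, n, replace = TRUE), gene_ids)
  ssp <- sort(sample(secreted, ceiling(length(secreted) / 2)))
  len[ssp] <- sample(80:299, length(ssp), replace = TRUE)
  cys <- stats::setNames(pmax(0L, round(0.01 * len)), gene_ids)
  cysrich <- sort(sample(ssp, max(1L, ceiling(length(ssp) / 3))))
  cys[cysrich] <- ceiling(0.05 * len[cysrich])   # 5% > 3% cutoff

  # secretion votes: positives (and exclusion decoys) >= 3 Y, negatives <= 2
  n_yes <- stats::setNames(integer(n), gene_ids)
  n_yes[c(secreted, excluded)] <- sample(3:4, n_sec + n_excl, replace = TRUE)
  n_yes[others] <- sample(0:2, length(others), replace = TRUE)
  vote_mat <- t(vapply(gene_ids, function(g) {
    v <- rep("N", 4)
    v[sample(4, n_yes[[g]])] <- "Y"
    v
  }, character(4)))
  votes <- data.frame(gene_id = gene_ids,
                      signalp = vote_mat[, 1], wolfpsort = vote_mat[, 2],
                      targetp = vote_mat[, 3], protcomp = vote_mat[, 4],
                      stringsAsFactors = FALSE)

  # topology: secreted genes pass the cascade (no helix, or one N-terminal
  # helix); excluded decoys each violate exactly one rule
  tm_starts <- stats::setNames(rep(".", n), gene_ids)
  tm_ends <- stats::setNames(rep(".", n), gene_ids)
  er <- stats::setNames(rep(FALSE, n), gene_ids)
  gpi <- stats::setNames(rep(FALSE, n), gene_ids)
  with_sp <- secreted[stats::runif(length(secreted)) < 0.3]
  for (g in with_sp) {
    s <- sample(5:50, 1)
    tm_starts[g] <- s; tm_ends[g] <- s + 20L
  }
  mode <- rep_len(c("tm_late", "tm_multi", "er", "gpi"), length(excluded))
  for (j in seq_along(excluded)) {
    g <- excluded[j]
    if (mode[j] == "tm_late") {
      s <- sample(71:(max(len[[g]] - 25, 72)), 1)
      tm_starts[g] <- s; tm_ends[g] <- s + 20L
    } else if (mode[j] == "tm_multi") {
      s1 <- sample(5:50, 1); s2 <- sample(150:(max(len[[g]] - 25, 151)), 1)
      tm_starts[g] <- paste(s1, s2, sep = ";")
      tm_ends[g] <- paste(s1 + 20L, s2 + 20L, sep = ";")
    } else if (mode[j] == "er") er[g] <- TRUE else gpi[g] <- TRUE
  }
  topology <- data.frame(gene_id = gene_ids,
                         protein_length = unname(len[gene_ids]),
                         cys_count = unname(cys[gene_ids]),
                         tm_starts = unname(tm_starts[gene_ids]),
                         tm_ends = unname(tm_ends[gene_ids]),
                         er_motif = unname(er[gene_ids]),
                         gpi_anchor = unname(gpi[gene_ids]),
                         stringsAsFactors = FALSE)

  # CAZyme assignments: planted genes get >= 2 agreeing calls
  fam_pool <- c("GH5", "GH7", "GH17", "GT2", "PL1", "CE4", "AA9", "CBM1")
  n_caz <- max(2L, round(config$frac_cazyme * n))
  caz_genes <- sort(sample(setdiff(gene_ids, secreted), n_caz))
  assign <- lapply(stats::setNames(caz_genes, caz_genes), function(g)
    sample(fam_pool, sample(1:2, 1)))
  cell <- function(fams) if (length(fams)) paste(fams, collapse = ";") else "."
  caz_cols <- matrix(".", nrow = n, ncol = 3,
                     dimnames = list(gene_ids, c("dbcan", "blastp", "pfam")))
  for (g in caz_genes) {
    for (f in assign[[g]]) {
      tools_hit <- sample(3, sample(2:3, 1))
      for (t in tools_hit)
        caz_cols[g, t] <- if (caz_cols[g, t] == ".") f
                          else paste(caz_cols[g, t], f, sep = ";")
    }
  }
  # single-tool noise calls on a few negatives (never reach min_agree = 2)
  noise <- sample(setdiff(gene_ids, caz_genes), max(1L, round(0.01 * n)))
  for (g in noise) caz_cols[g, sample(3, 1)] <- sample(fam_pool, 1)
  cazyme <- data.frame(gene_id = gene_ids,
                       dbcan = caz_cols[, 1], blastp = caz_cols[, 2],
                       pfam = caz_cols[, 3], stringsAsFactors = FALSE)
  cazyme_truth <- do.call(rbind, lapply(caz_genes, function(g)
    data.frame(gene_id = g, family = sort(assign[[g]]),
               stringsAsFactors = FALSE)))

  list(votes = votes, topology = topology, cazyme = cazyme,
       truth = list(secreted_ids = secreted, ssp_ids = ssp,
                    cysteine_rich_ids = cysrich, excluded_ids = excluded,
                    cazyme_assignments = cazyme_truth))
}

#' Simulate homology and domain tables with planted rescue evidence
#'
#' Among the silent TE-surrounded genes, plants `frac_paralog_rescued` with a
#' same-family paralog that is expressed and not TE-surrounded, and
#' `frac_ortholog_rescued` with a family spanning at least five other
#' genomes. Also plants a Pfam table with TE-derived domains (PF03732,
#' PF07727) on a TE-gene subset and transcription-factor DNA-binding domains
#' (PF01388, PF04082, PF11951) on a TF subset.
#'
#' @param gene_ids Character vector of gene ids (or a [gene_set]).
#' @param truth Truth list with te_surrounded_ids and silent_ids.
#' @param expression Expression table from [simulate_expression()].
#' @param config A [simulation_config()].
#' @return List: gene_families, family_genomes, pfam, truth (paralog /
#'   ortholog rescued ids, tf_ids, te_domain_ids).
#' @export
simulate_homology <- function(gene_ids, truth, expression, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(gene_ids, "gene_set")) gene_ids <- gene_ids$genes$gene_id
  set.seed(config$seed + 25000L)
  silent_te <- intersect(truth$te_surrounded_ids, truth$silent_ids)
  expressed <- expression$gene_id[is_expressed(expression)]
  partners <- setdiff(intersect(gene_ids, expressed), truth$te_surrounded_ids)

  n_par <- round(config$frac_paralog_rescued * length(silent_te))
  n_ort <- round(config$frac_ortholog_rescued * length(silent_te))
  par_ids <- sort(sample(silent_te, min(n_par, length(silent_te))))
  ort_ids <- sort(sample(silent_te, min(n_ort, length(silent_te))))
  if (length(par_ids) > length(partners))
    stop("not enough expressed non-TE genes to plant paralog partners")

  fams <- list(); genomes <- list()
  partner_pool <- sample(partners)
  genome_pool <- sprintf("genome_%02d", 1:10)
  fid <- 0L
  for (g in union(par_ids, ort_ids)) {
    fid <- fid + 1L
    fam <- sprintf("FAM%04d", fid)
    members <- g
    if (g %in% par_ids) {
      members <- c(members, partner_pool[1])
      partner_pool <- partner_pool[-1]
    }
    fams[[fam]] <- members
    n_gen <- if (g %in% ort_ids) sample(5:10, 1) else sample(1:4, 1)
    genomes[[fam]] <- sample(genome_pool, n_gen)
  }
  gene_families <- do.call(rbind, lapply(names(fams), function(f)
    data.frame(gene_id = fams[[f]], family_id = f, stringsAsFactors = FALSE)))
  family_genomes <- do.call(rbind, lapply(names(genomes), function(f)
    data.frame(family_id = f, genome = genomes[[f]], stringsAsFactors = FALSE)))

  unlabelled <- setdiff(gene_ids, unique(gene_families$gene_id))
  tf_ids <- sort(sample(unlabelled, max(2L, round(0.03 * length(gene_ids)))))
  te_dom_ids <- sort(sample(setdiff(unlabelled, tf_ids),
                            max(2L, round(0.02 * length(gene_ids)))))
  tf_domains <- c("PF01388", "PF04082", "PF11951")
  te_domains <- c("PF03732", "PF07727")
  pfam <- rbind(
    data.frame(gene_id = tf_ids,
               domain = sample(tf_domains, length(tf_ids), replace = TRUE),
               stringsAsFactors = FALSE),
    data.frame(gene_id = te_dom_ids,
               domain = sample(te_domains, length(te_dom_ids), replace = TRUE),
               stringsAsFactors = FALSE))
  list(gene_families = gene_families, family_genomes = family_genomes,
       pfam = pfam,
       truth = list(paralog_rescued_ids = par_ids,
                    ortholog_rescued_ids = ort_ids,
                    tf_ids = tf_ids, te_domain_ids = te_dom_ids))
}

#' Run the full simulation
#'
#' Genome, repeat families, expression, votes and homology tables with one
#' consolidated ground-truth list.
#'
#' @param config A [simulation_config()].
#' @return List of all components plus `truth`.
#' @export
simulate_all <- function(config) {
  g <- simulate_genome(config)
  expr <- simulate_expression(g$genes, g$truth, config)
  votes <- simulate_votes(g$genes, config)
  fams <- lapply(seq_len(config$n_families), function(i)
    simulate_rip_family(config, sprintf("fam%03d", i), index = i))
  truth <- c(g$truth, list(silent_ids = expr$silent_ids),
             votes$truth,
             list(rip_family_ids = vapply(fams, function(f)
                    f$family$family_id, ""),
                  rip_context = config$rip_context))
  hom <- simulate_homology(g$genes, truth, expr$table, config)
  truth <- c(truth, hom$truth)
  list(config = config, sequences = g$sequences, genes = g$genes,
       repeats = g$repeats, expression = expr$table, families = fams,
       votes = votes$votes, topology = votes$topology,
       cazyme = votes$cazyme, gene_families = hom$gene_families,
       family_genomes = hom$family_genomes, pfam = hom$pfam, truth = truth)
}

#' Write a simulation to a directory
#'
#' Emits genome.fa, genes.gff3, repeats.tsv (BED-like dialect), fpkm.tsv,
#' families/*.aln.fa (model first, as record "model"), votes/*.tsv, pfam.tsv,
#' gene_families.tsv, family_genomes.tsv and truth.json. Identical configs
#' produce byte-identical files.
#'
#' @param sim Output of [simulate_all()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "families"), showWarnings = FALSE)
  dir.create(file.path(dir, "votes"), showWarnings = FALSE)
  write_fasta(sim$sequences, file.path(dir, "genome.fa"))
  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  write_repeats_bed(sim$repeats, file.path(dir, "repeats.tsv"))
  write_tsv_report(sim$expression, file.path(dir, "fpkm.tsv"))
  for (f in sim$families) {
    fam <- f$family
    write_fasta(c(stats::setNames(fam$model, "model"), fam$copies),
                file.path(dir, "families",
                          paste0(fam$family_id, ".aln.fa")))
  }
  write_tsv_report(sim$votes, file.path(dir, "votes", "secretion.tsv"))
  write_tsv_report(sim$topology, file.path(dir, "votes", "topology.tsv"))
  write_tsv_report(sim$cazyme, file.path(dir, "votes", "cazyme.tsv"))
  write_tsv_report(sim$pfam, file.path(dir, "pfam.tsv"))
  write_tsv_report(sim$gene_families, file.path(dir, "gene_families.tsv"))
  write_tsv_report(sim$family_genomes, file.path(dir, "family_genomes.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
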