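mk_votes <- function(ids, yes) {
  m <- t(vapply(yes, function(k) {
    v <- rep("N", 4); if (k > 0) v[seq_len(k)] <- "Y"; v
  }, character(4)))
  data.frame(gene_id = ids, p1 = m[, 1], p2 = m[, 2], p3 = m[, 3],
             p4 = m[, 4], stringsAsFactors = FALSE)
}

mk_topology <- function(ids, length = 200, cys = 2, tm_starts = ".",
                        tm_ends = ".", er = FALSE, gpi = FALSE) {
  data.frame(gene_id = ids, protein_length = length, cys_count = cys,
             tm_starts = tm_starts, tm_ends = tm_ends, er_motif = er,
             gpi_anchor = gpi, stringsAsFactors = FALSE)
}

test_that("secretome vote counts Y verdicts against the threshold", {
  v <- mk_votes(c("in3", "in4", "out2", "out0"), c(3, 4, 2, 0))
  expect_setequal(secretome_vote(v), c("in3", "in4"))
  expect_equal(secretome_vote(v, min_votes = 4), "in4")
  bad <- v; bad$p1[1] <- "?"
  expect_error(secretome_vote(bad), "verdicts")
})

test_that("min_votes = 4 equals the all-programs intersection", {
  set.seed(61)
  for (i in 1:20) {
    ids <- sprintf("g%02d", 1:30)
    m <- matrix(sample(c("Y", "N"), 120, replace = TRUE), 30, 4)
    v <- data.frame(gene_id = ids, p1 = m[, 1], p2 = m[, 2], p3 = m[, 3],
                    p4 = m[, 4], stringsAsFactors = FALSE)
    want <- ids[m[, 1] == "Y" & m[, 2] == "Y" & m[, 3] == "Y" & m[, 4] == "Y"]
    expect_setequal(secretome_vote(v, 4), want)
    # |all-four intersection| <= |>=3-vote set|
    expect_lte(length(want), length(secretome_vote(v, 3)))
  }
})

test_that("exclusion cascade implements the single-N-terminal-helix exemption", {
  ids <- c("keep_nohelix", "keep_sp", "drop_late", "drop_two", "drop_er",
           "drop_gpi")
  topo <- mk_topology(ids,
                      tm_starts = c(".", "10", "100", "20;200", ".", "."),
                      tm_ends = c(".", "30", "120", "40;220", ".", "."),
                      er = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                      gpi = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  kept <- apply_exclusions(ids, topo)
  expect_setequal(kept, c("keep_nohelix", "keep_sp"))
  # helix starting exactly at the window boundary is exempt (<= 70)
  topo70 <- mk_topology("edge", tm_starts = "70", tm_ends = "90")
  expect_equal(apply_exclusions("edge", topo70), "edge")
  topo71 <- mk_topology("edge", tm_starts = "71", tm_ends = "90")
  expect_length(apply_exclusions("edge", topo71), 0)
})

test_that("exclusions commute", {
  set.seed(17)
  ids <- sprintf("g%02d", 1:40)
  topo <- mk_topology(ids,
                      tm_starts = sample(c(".", "10", "120", "10;200"), 40,
                                         replace = TRUE),
                      tm_ends = "150",
                      er = sample(c(TRUE, FALSE), 40, replace = TRUE),
                      gpi = sample(c(TRUE, FALSE), 40, replace = TRUE))
  topo$tm_ends <- vapply(strsplit(topo$tm_starts, ";"), function(s)
    if (s[1] == ".") "." else paste(as.integer(s) + 20L, collapse = ";"), "")
  full <- apply_exclusions(ids, topo)
  # only-ER then only-GPI then only-TM, any order, same result
  er_only <- topo; er_only$gpi_anchor <- FALSE; er_only$tm_starts <- "."
  gpi_only <- topo; gpi_only$er_motif <- FALSE; gpi_only$tm_starts <- "."
  tm_only <- topo; tm_only$er_motif <- FALSE; tm_only$gpi_anchor <- FALSE
  chain1 <- apply_exclusions(apply_exclusions(
    apply_exclusions(ids, er_only), gpi_only), tm_only)
  chain2 <- apply_exclusions(apply_exclusions(
    apply_exclusions(ids, tm_only), gpi_only), er_only)
  expect_setequal(chain1, full)
  expect_setequal(chain2, full)
})

test_that("SSP and cysteine-rich cutoffs are strict", {
  topo <- mk_topology(c("s299", "s300", "cys4", "cys3"),
                      length = c(299, 300, 100, 100),
                      cys = c(2, 2, 4, 3))
  res <- classify_ssp(c("s299", "s300", "cys4", "cys3"), topo)
  expect_setequal(res$ssp, c("s299", "cys4", "cys3"))
  expect_equal(res$cysteine_rich, "cys4")      # 4% > 3%; 3% is not
  topo_bad <- mk_topology("z", length = 0)
  expect_error(classify_ssp("z", topo_bad), "zero-length")
})

test_that("CAZyme agreement voting supports multi-family genes", {
  caz <- data.frame(gene_id = c("a", "b", "c", "d"),
                    t1 = c("GH5", "GH5", "GH5;CBM1", "."),
                    t2 = c("GH5", "GH7", "GH5", "."),
                    t3 = c(".", ".", "CBM1", "."),
                    stringsAsFactors = FALSE)
  res <- cazyme_vote(caz)
  expect_equal(res$family[res$gene_id == "a"], "GH5")
  expect_false("b" %in% res$gene_id)
  expect_setequal(res$family[res$gene_id == "c"], c("CBM1", "GH5"))
  expect_false("d" %in% res$gene_id)
  expect_equal(nrow(cazyme_vote(caz, min_agree = 3)), 0)
  bad <- caz; bad$t1[1] <- "XYZ9"
  expect_error(cazyme_vote(bad), "invalid CAZyme")
})

test_that("agreement equals a multiset oracle on random call tables", {
  set.seed(31)
  fams <- c("GH5", "GH7", "GT2", "CBM1")
  for (i in 1:15) {
    ids <- sprintf("g%02d", 1:20)
    cells <- function() vapply(seq_along(ids), function(j) {
      k <- sample(0:2, 1)
      if (k == 0) "." else paste(sample(fams, k), collapse = ";")
    }, "")
    caz <- data.frame(gene_id = ids, t1 = cells(), t2 = cells(),
                      t3 = cells(), stringsAsFactors = FALSE)
    res <- cazyme_vote(caz, 2)
    for (j in seq_along(ids)) {
      sets <- lapply(caz[j, c("t1", "t2", "t3")], function(s)
        if (s == ".") character() else strsplit(s, ";")[[1]])
      for (f in fams) {
        support <- sum(vapply(sets, function(s) f %in% s, logical(1)))
        got <- f %in% res$family[res$gene_id == ids[j]]
        expect_equal(got, support >= 2)
      }
    }
  }
})

test_that("gene support flags use the strict more-than rule for genomes", {
  expr <- data.frame(gene_id = c("rna", "dom", "ortho", "ortho5", "none"),
                     hyphae = c(5, 0, 0, 0, 0), primordia = 0, fruiting = 0)
  pfam <- data.frame(gene_id = "dom", domain = "PF00001")
  fams <- data.frame(gene_id = c("ortho", "ortho5"),
                     family_id = c("F6", "F5"))
  fam_gen <- data.frame(family_id = c(rep("F6", 6), rep("F5", 5)),
                        genome = c(paste0("a", 1:6), paste0("b", 1:5)))
  flags <- gene_support_evidence(expr, pfam, fams, fam_gen)
  expect_equal(flags$supported,
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_false(flags$ortholog_supported[flags$gene_id == "ortho5"])  # 5 is not > 5
  expect_true(flags$ortholog_supported[flags$gene_id == "ortho"])
})

test_that("domain-list filtering validates accessions and tags TFs", {
  pfam <- data.frame(gene_id = c("te1", "tf1", "plain"),
                     domain = c("PF07727", "PF01388", "PF00001"))
  ids <- c("te1", "tf1", "plain", "nodomain")
  res <- filter_by_domain_list(ids, pfam, c("PF03732", "PF07727"))
  expect_equal(res$removed, "te1")
  expect_setequal(res$kept, c("tf1", "plain", "nodomain"))
  expect_equal(filter_by_domain_list(ids, pfam, character()),
               list(kept = ids, removed = character()))
  tags <- filter_by_domain_list(ids, pfam,
                                c("PF01388", "PF04082", "PF11951"),
                                mode = "tag")
  expect_equal(tags, "tf1")
  expect_error(filter_by_domain_list(ids, pfam, "PF123"), "malformed")
})

test_that("voting is monotone in votes and threshold", {
  set.seed(71)
  for (i in 1:30) {
    ids <- sprintf("g%02d", 1:25)
    m <- matrix(sample(c("Y", "N"), 100, replace = TRUE), 25, 4)
    v <- data.frame(gene_id = ids, p1 = m[, 1], p2 = m[, 2], p3 = m[, 3],
                    p4 = m[, 4], stringsAsFactors = FALSE)
    s3 <- secretome_vote(v, 3)
    # adding a Y vote never removes a gene
    v2 <- v
    flip <- sample(25, 5)
    v2$p1[flip] <- "Y"
    expect_true(all(s3 %in% secretome_vote(v2, 3)))
    # raising the threshold never grows the set
    expect_true(all(secretome_vote(v, 4) %in% s3))
  }
})
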