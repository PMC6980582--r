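test_that("consensus takes the per-column majority with the fixed tie order", {
  expect_equal(build_consensus(c("ACGT", "ACGT", "ACTT")), "ACGT")
  expect_equal(build_consensus(c("A", "C")), "A")       # tie: A < C
  expect_equal(build_consensus(c("ACGT", "ACGT")), "ACGT")
  expect_equal(build_consensus(c("AA", "A-", "A-")), "A-")  # majority gap
  expect_equal(build_consensus(c("N", "N")), "-")       # no base at all
})

test_that("count_mutations handles both strand orientations", {
  r <- count_mutations("CAT", "TAT")
  expect_equal(r$transitions, 1)
  expect_equal(r$c_to_t_by_context[["CpA"]], 1)
  r2 <- count_mutations("CG", "CA")                     # reverse-strand event
  expect_equal(r2$transitions, 1)
  expect_equal(r2$c_to_t_by_context[["CpG"]], 1)
  r3 <- count_mutations("ACGT", "ACGT")
  expect_equal(r3$transitions + r3$transversions +
                 sum(r3$c_to_t_by_context), 0)
  expect_error(count_mutations("ACG", "AC"), "mismatch")
})

test_that("gap and N columns are excluded; contexts skip gaps", {
  # model C at col 1; its next non-gap base is G two columns away
  r <- count_mutations("C--GA", "T--GA")
  expect_equal(r$transitions, 1)
  expect_equal(r$c_to_t_by_context[["CpG"]], 1)
  # copy gap / N columns are not comparable
  r2 <- count_mutations("CATG", "-NTG")
  expect_equal(r2$transitions + r2$transversions, 0)
  # model G with previous non-gap base C across a gap: CpG on reverse strand
  r3 <- count_mutations("C-G", "C-A")
  expect_equal(r3$c_to_t_by_context[["CpG"]], 1)
  # hand-made gap-containing fixture vs the brute-force recount
  m <- "AC-GTNCA-GG"
  cp <- "AT-ATNTA-AG"
  expect_equal(count_mutations(m, cp), oracle_count_mutations(m, cp))
})

test_that("count_mutations equals the brute-force recount on random fixtures", {
  set.seed(21)
  alpha <- c("A", "C", "G", "T", "N", "-")
  for (i in 1:40) {
    n <- sample(10:80, 1)
    m <- paste0(sample(alpha, n, replace = TRUE,
                       prob = c(.22, .22, .22, .22, .04, .08)), collapse = "")
    cp <- paste0(sample(alpha, n, replace = TRUE,
                        prob = c(.22, .22, .22, .22, .04, .08)), collapse = "")
    got <- count_mutations(m, cp)
    want <- oracle_count_mutations(m, cp)
    expect_equal(got$transitions, want$transitions)
    expect_equal(got$transversions, want$transversions)
    expect_equal(got$c_to_t_by_context, want$c_to_t_by_context)
    # conservation: ti + tv = substituted comparable columns
    mc <- strsplit(m, "")[[1]]; cc <- strsplit(cp, "")[[1]]
    comparable <- mc %in% c("A", "C", "G", "T") & cc %in% c("A", "C", "G", "T")
    expect_equal(got$transitions + got$transversions,
                 sum(comparable & mc != cc))
  }
})

test_that("context counts are strand-symmetric", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    m <- paste0(sample(c("A", "C", "G", "T", "-"), n, replace = TRUE,
                       prob = c(.23, .23, .23, .23, .08)), collapse = "")
    cp <- paste0(sample(c("A", "C", "G", "T", "-"), n, replace = TRUE,
                        prob = c(.23, .23, .23, .23, .08)), collapse = "")
    fwd <- count_mutations(m, cp)
    rev_ <- count_mutations(revcomp(m), revcomp(cp))
    expect_equal(rev_$c_to_t_by_context, fwd$c_to_t_by_context)
    expect_equal(rev_$transitions, fwd$transitions)
    expect_equal(rev_$transversions, fwd$transversions)
  }
})

test_that("family statistics pool counts and apply the strict-argmax rule", {
  fam <- repeat_family("famX",
                       c(a = "CACACACA", b = "TATATACA", c = "CACATACA"),
                       model = "CACACACA")
  st <- family_rip_statistics(fam)
  # copy b: 3 C->T transitions (CpA); copy c: 1; copy a: 0
  expect_equal(st$transitions, 4)
  expect_equal(st$transversions, 0)
  expect_true(is.infinite(st$titv_ratio))
  expect_equal(st$biased_fraction, 2 / 3)
  expect_equal(st$dominant_context, "CpA")
  # titv 8/2 = 4 when transversions exist
  fam2 <- repeat_family("famY", c(a = "CCCCCCCCGG", b = "TTTTTTTTGG",
                                  c = "CCCCCCCCTT"),
                        model = "CCCCCCCCGG")
  st2 <- family_rip_statistics(fam2)
  expect_equal(st2$titv_ratio, 8 / 2)
})

test_that("a tied context is not dominant; small families are skipped", {
  # one copy with CpG:1 and CpA:1 -> no dominant context
  fam <- repeat_family("famZ", c(a = "CGCA", b = "TGTA", c = "CGCA"),
                       model = "CGCA")
  st <- family_rip_statistics(fam)
  expect_equal(st$per_copy$dominant_context,
               c(NA_character_, NA_character_, NA_character_)[1:3])
  expect_equal(st$biased_fraction, 0)
  expect_message(
    expect_null(family_rip_statistics(
      repeat_family("tiny", c(a = "AC", b = "AC")))),
    "skipped")
})

test_that("classification is strict at both thresholds", {
  base <- list(family_id = "f", n_copies = 3, transitions = 8,
               transversions = 2, titv_ratio = 4, biased_fraction = 2 / 3,
               dominant_context = "CpG")
  expect_true(classify_rip_family(base)$is_rip)
  expect_false(classify_rip_family(modifyList(base, list(titv_ratio = 2)))$is_rip)
  expect_false(classify_rip_family(
    modifyList(base, list(biased_fraction = 1 / 3)))$is_rip)
  expect_true(classify_rip_family(
    modifyList(base, list(titv_ratio = Inf)))$is_rip)
  undef <- classify_rip_family(
    modifyList(base, list(titv_ratio = NA_real_)))
  expect_false(undef$is_rip)
  expect_true(undef$titv_undefined)
})

test_that("RIP call fraction is non-decreasing in the planted rate", {
  rates <- c(0.002, 0.02, 0.15)
  frac_called <- vapply(rates, function(r) {
    cfg <- simulation_config(seed = 77, rip_rate = r,
                             background_transversion_rate = 0.005,
                             copies_per_family = 6, family_length = 400)
    calls <- vapply(1:20, function(i) {
      f <- simulate_rip_family(cfg, sprintf("f%02d", i), index = i)
      classify_rip_family(family_rip_statistics(f$family))$is_rip
    }, logical(1))
    mean(calls)
  }, 0)
  expect_true(all(diff(frac_called) >= 0))
  expect_gt(frac_called[3], 0.9)
})

test_that("genome summary tabulates RIP families by dominant context", {
  cfg <- simulation_config(seed = 3, rip_rate = 0.15, rip_context = "CpG",
                           copies_per_family = 8, family_length = 500)
  calls <- lapply(1:10, function(i) {
    f <- simulate_rip_family(cfg, sprintf("f%02d", i), index = i)
    classify_rip_family(family_rip_statistics(f$family))
  })
  s <- genome_rip_summary(calls)
  expect_equal(s$n_families, 10)
  expect_equal(s$n_rip, 10)
  expect_equal(s$modal_context, "CpG")
  expect_equal(s$context_histogram$CpG, 10)
  # conservation: histogram counts sum to the number of RIP families
  expect_equal(sum(unlist(s$context_histogram)), s$n_rip)
  expect_error(genome_rip_summary(list(NULL)), "no family")
})

test_that("family alignments round-trip through multi-FASTA", {
  cfg <- simulation_config(seed = 9, copies_per_family = 4,
                           family_length = 120)
  f <- simulate_rip_family(cfg, "famA", index = 1)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "famA.aln.fa")
  write_fasta(c(stats::setNames(f$family$model, "model"), f$family$copies),
              path)
  fam2 <- read_family_alignment(path, model = "first")
  expect_equal(fam2$model, f$family$model)
  expect_equal(unname(fam2$copies), unname(f$family$copies))
  expect_equal(fam2$family_id, "famA")
})
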