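# Melting temperature, candidate enumeration and specificity checking.

test_that("nearest-neighbor Tm matches an independent thermodynamics oracle", {
  # expected values computed once with an independent nearest-neighbor
  # implementation under identical parameters (unified NN table, 50 mM
  # Na+, entropic salt correction, CT/4 = 62.5 nM; self-complementary
  # duplexes: CT and symmetry entropy) and frozen here
  frozen <- c(
    "ACGTACGTACGTACGTACGTACGTACGTACGT"   = 65.429700,
    "ATGCATGCATGCATGCATGCATGCA"          = 63.436178,
    "GGGCCCGGGCCCGGGCCCGGGCCCGGGCCC"     = 86.747534,
    "AATTAATTAATTAATTAATTAATTAATT"       = 41.392922,
    "ACGTTGCAACGTGGATCCGATCGATTACA"      = 63.929345,
    "TTGACCTAGATGACCAGGTTACCAGTTGACCTAG" = 63.025021,
    "CAGTGACCTTAGGAACTGGCATCCAGTAGG"     = 63.035771,
    "TTTTACACCAGGATCCGGGGATTACAGGATTT"   = 62.454616
  )
  for (s in names(frozen)) {
    expect_equal(melting_temperature(s), unname(frozen[s]),
                 tolerance = 1e-6)
  }
  expect_error(melting_temperature("ACGT"), "shorter")
})

test_that("Tm is symmetric under reverse complement", {
  set.seed(21)
  for (rep in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(25:40, 1), TRUE),
               collapse = "")
    expect_equal(melting_temperature(s),
                 melting_temperature(reverse_complement(s)),
                 tolerance = 1e-9)
  }
})

test_that("appending G/C bases strictly increases Tm of a 25-mer", {
  set.seed(31)
  for (rep in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    gc <- paste(sample(c("G", "C"), 10, TRUE), collapse = "")
    expect_gt(melting_temperature(paste0(s, gc)), melting_temperature(s))
  }
})

test_that("degenerate Tm is the mean over concrete expansions", {
  s <- "ACGTTGCAACGTGGRTCCGAYCGATTACA"
  manual <- mean(vapply(expand_degenerate(s), melting_temperature,
                        numeric(1)))
  expect_equal(melting_temperature(s), manual, tolerance = 1e-9)
})

test_that("enumeration structural rules: junction gap 0 and length bounds", {
  # a 40-nt consensus cannot fit two 25-mers
  short <- paste(rep("ACGT", 10), collapse = "")
  expect_identical(nrow(enumerate_candidates(short)), 0L)
  set.seed(41)
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  cands <- enumerate_candidates(s)
  expect_gt(nrow(cands), 0L)
  # CP abuts the DS 3' end on the template: footprint is contiguous
  for (i in seq_len(min(nrow(cands), 25L))) {
    fp <- paste0(cands$ds_seq[i], cands$cp_seq[i])
    expect_identical(substr(s, cands$template_position[i],
                            cands$template_position[i] + nchar(fp) - 1L),
                     fp)
  }
  expect_true(all(nchar(cands$ds_seq) >= 25 & nchar(cands$ds_seq) <= 60))
  expect_true(all(abs(cands$ds_tm - 68) <= 1 & abs(cands$cp_tm - 68) <= 1))
})

test_that("enumeration equals a brute-force scan of all window triples", {
  set.seed(43)
  s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  cn <- design_constraints(min_len = 20L, max_len = 30L, tm_tol = 3)
  cands <- enumerate_candidates(s, cn)
  # oracle: direct triple loop calling melting_temperature per window
  hits <- list()
  for (start in 1:(120 - 2 * cn$min_len + 1)) {
    for (dl in cn$min_len:cn$max_len) {
      j <- start + dl - 1L
      if (j + cn$min_len > 120) break
      ds <- substr(s, start, j)
      if (abs(melting_temperature(ds) - 68) > cn$tm_tol) next
      for (cl in cn$min_len:cn$max_len) {
        if (j + cl > 120) break
        cp <- substr(s, j + 1L, j + cl)
        if (abs(melting_temperature(cp) - 68) > cn$tm_tol) next
        hits[[length(hits) + 1L]] <- c(start, dl, cl)
      }
    }
  }
  oracle <- do.call(rbind, hits)
  got <- cbind(cands$template_position, nchar(cands$ds_seq),
               nchar(cands$cp_seq))
  expect_identical(nrow(got), nrow(oracle))
  key <- function(m) sort(apply(m, 1, paste, collapse = "_"))
  expect_identical(key(got), key(oracle))
})

test_that("enumeration order is total and deterministic", {
  set.seed(47)
  s <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  a <- enumerate_candidates(s)
  b <- enumerate_candidates(s)
  expect_identical(a, b)
  key1 <- abs((a$ds_tm + a$cp_tm) / 2 - 68)
  expect_true(all(diff(key1) >= -1e-12))
})

test_that("specificity: self-match passes, 3'-terminal mismatch discriminates", {
  set.seed(53)
  tpl <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  cands <- enumerate_candidates(tpl)
  pair <- cands[1, ]
  rep1 <- check_specificity(pair, c(x = tpl))
  expect_true(rep1$pass)
  expect_identical(rep1$positive_hits, "x")
  # negative identical to the template except at the DS 3'-terminal base
  jpos <- pair$template_position + nchar(pair$ds_seq) - 1L
  old <- substr(tpl, jpos, jpos)
  neg <- tpl
  substr(neg, jpos, jpos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  rep2 <- check_specificity(pair, c(x = tpl), c(n = neg))
  expect_true(rep2$pass)
  expect_length(rep2$negative_violations, 0L)
  # a negative identical to the template is a violation
  rep3 <- check_specificity(pair, c(x = tpl), c(n = tpl))
  expect_false(rep3$pass)
  expect_identical(rep3$negative_violations, "n")
})

test_that("degenerate matching equals brute-force expansion over toy databases", {
  set.seed(59)
  bases <- c("A", "C", "G", "T")
  db <- vapply(1:20, function(i) {
    paste(sample(bases, 70, TRUE), collapse = "")
  }, character(1))
  names(db) <- paste0("t", 1:20)
  # seed a degenerate footprint into a third of them
  ds <- "ACGRTGCAACGTGGATCCGATCGATYACA"
  cp <- "TTGACCTAGATGACCAGSTTACCAGTTGA"
  fp_len <- nchar(ds) + nchar(cp)
  for (i in sample(1:20, 7)) {
    concrete <- sample(expand_degenerate(paste0(ds, cp)), 1)
    substr(db[i], 5, 4 + fp_len) <- concrete
  }
  pair <- list(probe_id = "deg", ds_seq = ds, cp_seq = cp)
  rep <- check_specificity(pair, db)
  # oracle: expand every probe realization and string-match exactly
  expansions <- expand_degenerate(paste0(ds, cp))
  oracle_hits <- names(db)[vapply(db, function(s) {
    any(vapply(expansions, function(e) grepl(e, s, fixed = TRUE),
               logical(1)))
  }, logical(1))]
  expect_setequal(rep$positive_hits, oracle_hits)
  expect_setequal(rep$positive_misses, setdiff(names(db), oracle_hits))
})

test_that("design closure: every designed pair passes its own check", {
  panel <- small_panel()
  for (i in seq_len(nrow(panel$probes))) {
    id <- panel$probes$probe_id[i]
    rep <- check_specificity(
      panel$probes[i, ],
      positives = panel$templates[id],
      negatives = panel$templates[setdiff(names(panel$templates), id)])
    expect_true(rep$pass)
  }
})

test_that("design fails cleanly when target and negative set coincide", {
  set.seed(61)
  tpl <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  res <- design_probe_set(list(list(
    positive = aligned_group("same", c(a = tpl)),
    negatives = c(n = tpl))))
  expect_identical(res$failures, "same")
  expect_identical(nrow(res$probes), 0L)
})

test_that("design is deterministic and respects the negative-set hierarchy", {
  panel1 <- synth_panel(n_targets = 2L, length_nt = 150L, seed = 19L,
                        n_subarrays = 1L)
  panel2 <- synth_panel(n_targets = 2L, length_nt = 150L, seed = 19L,
                        n_subarrays = 1L)
  expect_identical(panel1$probes, panel2$probes)
  # genus-level groups exclude same-family groups from their negatives:
  # a genus group identical to its family consensus still designs
  set.seed(67)
  fam <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  res <- design_probe_set(list(
    list(positive = aligned_group("family_A", c(f = fam)),
         level = "family", family = "A"),
    list(positive = aligned_group("genus_A1", c(g = fam)),
         level = "genus", family = "A"),
    list(positive = aligned_group("family_B", c(h = other)),
         level = "family", family = "B")))
  expect_true("genus_A1" %in% res$probes$probe_id)
  expect_identical(res$probes$level[res$probes$probe_id == "genus_A1"],
                   "sub-probe")
})

test_that("probe_set_summary reports oligo-level means and SDs", {
  p1 <- data.frame(probe_id = "a", ds_seq = paste(rep("A", 30), collapse = ""),
                   cp_seq = paste(rep("A", 40), collapse = ""),
                   ds_tm = 60, cp_tm = 70,
                   ds_degenerate = 0L, cp_degenerate = 0L)
  s <- probe_set_summary(p1)
  expect_equal(s$length_mean, 35)
  expect_equal(s$tm_mean, 65)
  expect_equal(s$n_oligos, 2L)
  # identical oligos throughout: zero dispersion
  p2 <- p1[c(1, 1, 1), ]
  p2$cp_seq <- p2$ds_seq
  p2$cp_tm <- p2$ds_tm
  s2 <- probe_set_summary(p2)
  expect_equal(s2$tm_sd, 0)
  expect_equal(s2$length_sd, 0)
  # 10-pair synthetic set vs an independent spreadsheet-style recompute
  set.seed(71)
  pairs <- data.frame(
    probe_id = paste0("p", 1:10),
    ds_seq = vapply(1:10, function(i)
      paste(sample(c("A", "C", "G", "T"), sample(25:35, 1), TRUE),
            collapse = ""), character(1)),
    cp_seq = vapply(1:10, function(i)
      paste(sample(c("A", "C", "G", "T"), sample(25:35, 1), TRUE),
            collapse = ""), character(1)))
  pairs$ds_tm <- vapply(pairs$ds_seq, melting_temperature, numeric(1))
  pairs$cp_tm <- vapply(pairs$cp_seq, melting_temperature, numeric(1))
  pairs$ds_degenerate <- 0L
  pairs$cp_degenerate <- 0L
  s10 <- probe_set_summary(pairs)
  vals_tm <- c(pairs$ds_tm, pairs$cp_tm)
  vals_len <- c(nchar(pairs$ds_seq), nchar(pairs$cp_seq))
  expect_equal(s10$tm_mean, sum(vals_tm) / 20)
  expect_equal(s10$tm_sd, sqrt(sum((vals_tm - mean(vals_tm))^2) / 19))
  expect_equal(s10$length_mean, sum(vals_len) / 20)
  expect_equal(s10$n_nondegenerate_pairs, 10L)
  expect_error(probe_set_summary(pairs[0, ]), "empty")
})

test_that("probe sets round-trip through TSV", {
  panel <- small_panel()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_probe_set(panel$probes, tsv)
  back <- read_probe_set(tsv)
  expect_identical(back$ds_seq, panel$probes$ds_seq)
  expect_identical(back$zipcode_id, panel$probes$zipcode_id)
  expect_equal(back$ds_tm, panel$probes$ds_tm, tolerance = 1e-10)
})
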