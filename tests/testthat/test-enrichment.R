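test_that("hypergeometric enrichment handles the boundary cases", {
  genes <- sprintf("g%04d", 1:1000)
  study <- genes[1:10]
  # a term covering the whole universe is unenriched by definition
  ann_all <- tibble::tibble(term = "all", gene = genes)
  res <- hypergeom_enrich(study, ann_all, genes)
  expect_equal(res$p_value, 1)
  expect_equal(res$fold_enrichment, 1)
  # zero overlap: fold 0, p ~ 1
  ann_none <- tibble::tibble(term = "none", gene = genes[900:950])
  res0 <- hypergeom_enrich(study, ann_none, genes)
  expect_equal(res0$fold_enrichment, 0)
  expect_gt(res0$p_value, 0.5)
  expect_error(hypergeom_enrich(study, ann_all, character()), "universe")
  expect_error(hypergeom_enrich("zzz", ann_all, genes), "contained")
})

test_that("hypergeometric p equals the exact tail enumeration", {
  set.seed(91)
  genes <- sprintf("g%04d", 1:1000)
  for (i in 1:20) {
    term_size <- sample(20:200, 1)
    study_size <- sample(10:100, 1)
    term_genes <- sample(genes, term_size)
    study <- c(sample(term_genes, sample(0:min(study_size, term_size), 1)))
    study <- unique(c(study, sample(setdiff(genes, term_genes),
                                    study_size - length(study))))
    ann <- tibble::tibble(term = "t", gene = term_genes)
    res <- hypergeom_enrich(study, ann, genes)
    expect_equal(res$p_value,
                 oracle_hyper_tail(res$overlap, term_size, 1000,
                                   length(study)),
                 tolerance = 1e-10, info = paste("config", i))
  }
  # symmetry: swapping study and term labels leaves p unchanged
  term_genes <- sample(genes, 50)
  study <- sample(genes, 80)
  p1 <- hypergeom_enrich(study,
                         tibble::tibble(term = "t", gene = term_genes),
                         genes)$p_value
  p2 <- hypergeom_enrich(term_genes,
                         tibble::tibble(term = "t", gene = study),
                         genes)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("best PWM scores equal the naive scan and respect conventions", {
  pwm <- consensus_pwm("GGTAGGTG")
  # a promoter carrying the exact consensus scores the PWM maximum there
  set.seed(93)
  s <- random_dna(300, seed = 93)
  planted <- paste0(substr(s, 1, 99), "GGTAGGTG", substr(s, 108, 300))
  hit <- pwm_best_score(planted, pwm)
  expect_equal(hit$offset, 100L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$score, sum(apply(pwm$log_odds, 2, max)),
               tolerance = 1e-12)

  # all-N sequence scores exactly the background expectation, zero
  expect_equal(pwm_best_score(strrep("N", 50), pwm)$score, 0)
  expect_error(pwm_best_score("ACGT", pwm), "shorter")

  # random promoters match the brute-force scan on both strands
  for (i in 1:10) {
    seq_i <- random_dna(150, seed = 500 + i)
    expect_equal(pwm_best_score(seq_i, pwm)$score,
                 oracle_pwm_scan(seq_i, pwm),
                 tolerance = 1e-10, info = paste("seq", i))
  }

  # reverse-complementing the promoter leaves the best score unchanged
  for (i in 1:5) {
    seq_i <- random_dna(200, seed = 600 + i)
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(seq_i, "")[[1]]), collapse = ""))
    expect_equal(pwm_best_score(seq_i, pwm)$score,
                 pwm_best_score(rc, pwm)$score, tolerance = 1e-10)
  }

  # the matrix scanner agrees with the single-sequence scanner
  proms <- tibble::tibble(
    gene = sprintf("g%02d", 1:8),
    sequence = vapply(1:8, function(i) random_dna(120, seed = 700 + i),
                      character(1))
  )
  panel <- list(planted = pwm, decoy = random_pwm(6, seed = 3))
  sc <- pwm_score_matrix(proms, panel)
  for (i in seq_len(8)) {
    expect_equal(sc[i, "planted"],
                 pwm_best_score(proms$sequence[i], pwm)$score,
                 tolerance = 1e-12)
  }
})

test_that("the group score test detects planted motifs and honours edges", {
  pwm <- consensus_pwm("GGTAGGTG")
  genes <- sprintf("g%04d", 1:400)
  group <- genes[1:100]
  set.seed(95)
  bound <- sample(group, 25)
  sim <- simulate_promoters(genes, pwm, bound_set = bound, seed = 95,
                            site = "consensus")
  panel <- c(list(planted = pwm),
             setNames(lapply(1:5, function(i) random_pwm(8, seed = 950 + i)),
                      paste0("decoy", 1:5)))
  sc <- pwm_score_matrix(sim$promoters, panel)
  res <- motif_group_test(sc, genes %in% group)
  expect_lt(res$fdr[res$motif == "planted"], 0.01)
  expect_gt(res$mean_group[res$motif == "planted"],
            res$mean_rest[res$motif == "planted"])

  # degenerate inputs
  expect_error(motif_group_test(sc, rep(TRUE, 400)), "universe")
  expect_error(motif_group_test(sc, rep(FALSE, 400)), "empty")
  const <- matrix(5, 10, 2, dimnames = list(letters[1:10], c("m1", "m2")))
  res_const <- motif_group_test(const, c(TRUE, rep(FALSE, 9)))
  expect_equal(res_const$p_value, c(1, 1))
})

test_that("null group assignments give uniform p-values", {
  set.seed(97)
  # fresh scores and group each replicate: independent null p-values
  pvals <- replicate(200, {
    sc <- matrix(rnorm(300), 300, 1,
                 dimnames = list(sprintf("g%03d", 1:300), "m"))
    grp <- rep(c(TRUE, FALSE), c(75, 225))
    motif_group_test(sc, grp)$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the TSS-window peak filter is strand-aware and exact", {
  tss <- tibble::tibble(
    gene = c("g1", "g2", "g3"),
    chrom = "chr1",
    tss = c(10000L, 20000L, 30000L),
    strand = c("+", "+", "-")
  )
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(9800L, 17400L, 30050L),
    end = c(9900L, 17600L, 30150L),
    tf = c("TF1", "TF1", "TF1"),
    gene = c("g1", "g2", "g3"),
    score = 0, strand = c("+", "+", "-")
  )
  wf <- promoter_window_filter(peaks, tss)
  # midpoint -150 retained; -2500 excluded; minus strand: +100 downstream
  # of a minus-strand gene is upstream offset -100, retained
  expect_equal(wf$report$offset, c(-150, -2500, -100))
  expect_equal(wf$report$retained, c(TRUE, FALSE, TRUE))
  expect_setequal(wf$genes_by_tf$TF1, c("g1", "g3"))
  expect_error(promoter_window_filter(
    dplyr::mutate(peaks, gene = c("g1", "gX", "g3")), tss), "absent")
  expect_error(promoter_window_filter(
    peaks, dplyr::mutate(tss, strand = c("+", "*", "-"))), "strand")

  # random peaks equal a brute-force interval check, and overlaps are the
  # exact membership partition
  set.seed(99)
  tss_r <- tibble::tibble(gene = sprintf("g%03d", 1:50), chrom = "chr1",
                          tss = sample(50000:60000, 50), strand = "+")
  peaks_r <- tibble::tibble(
    chrom = "chr1",
    gene = sample(tss_r$gene, 120, replace = TRUE),
    tf = sample(c("MYB13", "MYB14", "MYB15"), 120, replace = TRUE),
    score = 0, strand = "+"
  )
  mid <- tss_r$tss[match(peaks_r$gene, tss_r$gene)] +
    sample(-3000:500, 120, replace = TRUE)
  peaks_r$start <- as.integer(mid - 50)
  peaks_r$end <- as.integer(mid + 50)
  wf_r <- promoter_window_filter(peaks_r, tss_r)
  manual <- mid - tss_r$tss[match(peaks_r$gene, tss_r$gene)]
  expect_equal(wf_r$report$retained, manual >= -2000 & manual <= 0)
  sets <- wf_r$genes_by_tf
  if (length(unlist(sets))) {
    oracle <- oracle_partition(sets[vapply(sets, length, integer(1)) > 0])
    got <- deg_intersections(sets[vapply(sets, length, integer(1)) > 0])
    expect_equal(sum(got$counts$n_genes), length(oracle))
  }
})
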