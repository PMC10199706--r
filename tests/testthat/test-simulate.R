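test_that("count simulation is seed-deterministic and truth-consistent", {
  design <- make_design()
  arch <- archetype_panel(design)
  a <- simulate_counts(design, arch, genes_per_archetype = 5, seed = 7)
  b <- simulate_counts(design, arch, genes_per_archetype = 5, seed = 7)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$genes, b$truth$genes)
  c <- simulate_counts(design, arch, genes_per_archetype = 5, seed = 8)
  expect_false(identical(a$counts$counts, c$counts$counts))
  # truth labels mutually exclusive and complete
  expect_equal(nrow(a$truth$genes), nrow(a$counts$counts))
  expect_true(all(a$truth$genes$status == "archetype"))
})

test_that("negative-binomial means recover the analytic expectation", {
  # 1000 replicates of a single condition; relative error < 5 %
  d1 <- make_design(list(cultivar = 1, tissue = 1, stage = 1, soil = 1),
                    replicates = 1000)
  arch <- list(flat = gene_archetype("flat", 200, 0.05, list()))
  sim <- simulate_counts(d1, arch, genes_per_archetype = 5, seed = 3,
                         lib_size_sd = 0, baseline_log2_sd = 0)
  emp <- rowMeans(sim$counts$counts)
  expect_true(all(abs(emp - 200) / 200 < 0.05))
})

test_that("driver effects move group means as planted", {
  design <- make_design()
  flat <- list(flat = gene_archetype("flat", 150, 0.05, list()))
  sim <- simulate_counts(design, flat, genes_per_archetype = 30, seed = 5,
                         lib_size_sd = 0, baseline_log2_sd = 0)
  # empty driver set: soil group means differ by < 3 standard errors
  m <- sim$counts$counts
  soil <- sim$counts$design$soil
  for (g in seq_len(5)) {
    x <- m[g, ]
    gm <- tapply(x, soil, mean)
    se <- sqrt(var(x) / 36)
    expect_true(max(gm) - min(gm) < 3 * se * 2,
                info = paste("gene", g))
  }

  # soil-driven +2 log2: mean ratio ~ 4 within NB sampling error
  soil_arch <- list(soil = gene_archetype("soil", 150, 0.05,
                                          list(soil = c(soil_c = 2))))
  sim2 <- simulate_counts(design, soil_arch, genes_per_archetype = 200,
                          seed = 6, lib_size_sd = 0, baseline_log2_sd = 0)
  m2 <- sim2$counts$counts
  soil2 <- sim2$counts$design$soil
  ratio <- mean(m2[, soil2 == "soil_c"]) / mean(m2[, soil2 != "soil_c"])
  expect_gt(ratio, 3.6)
  expect_lt(ratio, 4.4)
})

test_that("archetype validation rejects bad parameters", {
  expect_error(gene_archetype("x", dispersion = 0), "dispersion")
  expect_error(gene_archetype("x", baseline_mean = -1), "baseline_mean")
  expect_error(gene_archetype("x", effects = list(year = c(a = 1))),
               "unknown driver")
  expect_error(simulate_counts(make_design(), list()), "archetype")
})

test_that("inadequate-profile planting honours counts and capacity", {
  sim <- benchmark_sim(10, seed = 11)
  pl <- plant_inadequate_genes(sim$counts, 5, 4, 3, seed = 12,
                               truth = sim$truth)
  tab <- table(pl$truth$genes$status)
  expect_equal(as.integer(tab[c("unexpressed", "constitutive", "outlier")]),
               c(5L, 4L, 3L))
  # unexpressed genes are essentially silent
  un <- pl$truth$genes$gene[pl$truth$genes$status == "unexpressed"]
  expect_true(all(rowSums(pl$counts$counts[un, , drop = FALSE] > 0) <= 2))
  # each outlier gene has exactly one extreme sample (robust z > 6 on log)
  out <- pl$truth$genes$gene[pl$truth$genes$status == "outlier"]
  for (g in out) {
    x <- log2(pl$counts$counts[g, ] + 1)
    z <- abs(x - median(x)) / mad(x)
    expect_equal(sum(z > 6), 1, info = g)
  }
  # zero planting is the identity
  pl0 <- plant_inadequate_genes(sim$counts, 0, 0, 0, seed = 12,
                                truth = sim$truth)
  expect_identical(pl0$counts$counts, sim$counts$counts)
  expect_error(plant_inadequate_genes(sim$counts, 100, 0, 0, seed = 1),
               "planted")
})

test_that("promoter simulation plants sites, peaks and truth coherently", {
  pwm <- consensus_pwm("GGTAGGTG")
  genes <- sprintf("g%03d", 1:40)
  bound <- genes[1:10]
  sim <- simulate_promoters(genes, pwm, bound_set = bound, seed = 4)
  expect_equal(nchar(sim$promoters$sequence), rep(600, 40))
  expect_equal(sort(sim$peaks$gene), sort(bound))
  # planted site is present at the recorded offset/strand
  tr <- sim$truth$motifs
  for (g in bound) {
    i <- match(g, tr$gene)
    s <- sim$promoters$sequence[match(g, sim$promoters$gene)]
    win <- substr(s, tr$offset[i], tr$offset[i] + pwm$width - 1)
    planted <- if (tr$strand[i] == "+") tr$site[i] else
      chartr("ACGT", "TGCA",
             paste(rev(strsplit(tr$site[i], "")[[1]]), collapse = ""))
    expect_identical(win, planted, info = g)
  }
  # peak midpoints fall inside the upstream window, strand-aware
  rep_off <- promoter_window_filter(sim$peaks, sim$tss)$report$offset
  expect_true(all(rep_off >= -2000 & rep_off <= 0))

  # empty bound set emits no peaks; bad bound set errors
  sim0 <- simulate_promoters(genes, pwm, bound_set = character(), seed = 4)
  expect_equal(nrow(sim0$peaks), 0)
  expect_error(simulate_promoters(genes, pwm, bound_set = "nope", seed = 1),
               "subset")
  expect_error(simulate_promoters(genes, pwm, length = 5, seed = 1),
               "width")
})

test_that("background base composition is respected", {
  pwm <- consensus_pwm("ACGT")
  sim <- simulate_promoters(sprintf("g%02d", 1:17), pwm, length = 600,
                            seed = 9,
                            base_freq = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25))
  seqs <- paste(sim$promoters$sequence, collapse = "")  # ~10 kb
  gc <- mean(strsplit(seqs, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.02)
})

test_that("annotation simulation plants a detectable term", {
  genes <- sprintf("g%04d", 1:1000)
  target <- genes[1:40]
  ann <- simulate_annotations(genes, n_terms = 10, target_genes = target,
                              planted_fraction = 0.5,
                              background_rate = 0.05, seed = 2)
  res <- hypergeom_enrich(target, ann$annotations, genes)
  expect_lt(res$p_value[res$term == "T_planted"], 1e-6)

  # zero background: term annotates only targets
  ann0 <- simulate_annotations(genes, n_terms = 0, target_genes = target,
                               planted_fraction = 1, background_rate = 0,
                               seed = 2)
  expect_true(all(ann0$annotations$gene %in% target))
  # no terms at all
  empty <- simulate_annotations(genes, n_terms = 0, seed = 2)
  expect_equal(nrow(empty$annotations), 0)
  expect_error(simulate_annotations(genes, background_rate = 2, seed = 1),
               "rates")
})

test_that("phenology simulation is shifted, monotone and reproducible", {
  design <- make_design()
  # offset 0, noise 0: all curves identical
  ph0 <- simulate_phenology(design, soil_offset = 0 * 7, noise_sd = 0,
                            seed = 1)
  wide <- tidyr::pivot_wider(ph0, id_cols = "series_id",
                             names_from = "date", values_from = "el")
  expect_equal(nrow(unique(wide[, -1])), 1)

  # soil_a shifted by 7 days lags at every interior date
  ph7 <- simulate_phenology(design, soil_offset = 7, noise_sd = 0, seed = 1)
  a <- ph7[ph7$soil == "soil_a" & ph7$replicate == 1, ]
  b <- ph7[ph7$soil == "soil_b" & ph7$replicate == 1, ]
  interior <- a$date > 7 & a$date < max(a$date) - 7
  expect_true(all(a$el[interior] < b$el[interior]))
  # the lag is exactly the template shift: soil_a at t equals soil_b at t-7
  expect_equal(a$el[a$date >= 7], b$el[b$date <= max(b$date) - 7],
               tolerance = 1e-12)

  # monotone after noise clipping; seeded reproducibility
  phn <- simulate_phenology(design, soil_offset = 7, noise_sd = 0.5,
                            seed = 33)
  by_series <- split(phn$el, phn$series_id)
  expect_true(all(vapply(by_series, function(x) all(diff(x) >= 0),
                         logical(1))))
  expect_identical(phn, simulate_phenology(design, soil_offset = 7,
                                           noise_sd = 0.5, seed = 33))
})
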