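test_that("pedigree templates produce the expected member counts deterministically", {
  ## 3 sibships x 3 children: 2 + 3*2 + 9 = 17 members
  ped <- build_pedigree(pedigree_template(3, 3), "X", seed = 2)
  expect_equal(nrow(ped$members), 17)
  ped2 <- build_pedigree(pedigree_template(3, 3), "X", seed = 2)
  expect_identical(ped, ped2)
  expect_equal(nrow(validate_pedigree(ped)), 0)
  expect_length(nuclear_families(ped), 4)  # grandparental + 3 sibships
})

test_that("gene dropping co-segregates trait and marker at theta = 0", {
  ## trait locus placed exactly on a SNP: each transmitted haplotype must
  ## carry a (trait, marker) allele pair present on a single parental
  ## haplotype - no recombinant mosaics at zero distance
  panel <- marker_panel(n_snp = 3, n_ms = 0, spacing_cM = 10, seed = 4)
  snp <- panel$name[2]
  truth <- simulation_truth(trait_model_dt(0.5, c(1, 1, 0)),
                            trait_cM = panel$cM[2], panel = panel)
  for (s in 1:5) {
    ped <- build_pedigree(pedigree_template(2, 2), "P", seed = s)
    gd <- gene_drop(ped, truth, seed = 50 + s)
    h <- gd$haplotypes[["1"]]
    m <- ped$members
    loci <- c(".trait", snp)
    for (i in which(!is_founder(ped))) {
      for (side in 1:2) {
        par <- if (side == 1) m$father[i] else m$mother[i]
        child_pair <- (if (side == 1) h$h1 else h$h2)[m$id[i], loci]
        par_pairs <- list(h$h1[par, loci], h$h2[par, loci])
        expect_true(any(vapply(par_pairs, identical, TRUE, y = child_pair)))
      }
    }
    expect_equal(sum(mendel_check(ped, gd$G)$family_counts), 0)
  }
})

test_that("simulated founder allele frequencies match their specification", {
  panel <- marker_panel(n_snp = 1, n_ms = 0, seed = 9)
  truth <- simulation_truth(trait_model_dt(0.2, c(1, 1, 0)), panel = panel)
  big <- pedigree("S", as.character(1:10000), NA, NA,
                  rep(c(1, 2), 5000))
  gd <- gene_drop(big, truth, seed = 33)
  p_spec <- panel$freqs[[1]][1]
  p_hat <- mean(c(gd$G$a1, gd$G$a2) == 1L)
  se <- sqrt(p_spec * (1 - p_spec) / 20000)
  expect_lt(abs(p_hat - p_spec), 2 * se)
})

test_that("phenotype simulation respects penetrances and is seed-reproducible", {
  panel <- marker_panel(n_snp = 2, n_ms = 0, seed = 1)
  ped <- build_pedigree(pedigree_template(), "P", seed = 3)
  truth_all <- simulation_truth(trait_model_dt(0.1, c(1, 1, 1)),
                                panel = panel)
  gd <- gene_drop(ped, truth_all, seed = 4)
  ph <- simulate_phenotypes(ped, gd$trait_genotype, truth_all, seed = 5)
  expect_true(all(ph$asd_status == "affected"))
  ph2 <- simulate_phenotypes(ped, gd$trait_genotype, truth_all, seed = 5)
  expect_identical(ph, ph2)
})

test_that("phenotype calibration reproduces the stated distributions", {
  big <- pedigree("S", as.character(1:10000), NA, NA, rep(c(1, 2), 5000))
  panel <- marker_panel(n_snp = 1, n_ms = 0, seed = 2)
  ## non-ASD adults: anxiety t-scores ~ N(51, 9)
  none <- simulation_truth(trait_model_dt(0.1, c(0, 0, 0)), panel = panel)
  gd <- gene_drop(big, none, seed = 6)
  ph <- simulate_phenotypes(big, gd$trait_genotype, none, seed = 7)
  expect_true(all(ph$asd_status == "unaffected"))
  expect_lt(abs(mean(ph$anx_t) - 51), 2 * 9 / sqrt(10000))
  ## ASD cases: SRS t-scores ~ N(84, 14); RBS-R totals ~ N(26, 16)
  all_aff <- simulation_truth(trait_model_dt(0.1, c(1, 1, 1)),
                              panel = panel)
  ph2 <- simulate_phenotypes(big, gd$trait_genotype, all_aff,
                             calibration = phenotype_calibration(
                               truncate_rrb = FALSE), seed = 8)
  expect_lt(abs(mean(ph2$soc_t) - 84), 2 * 14 / sqrt(10000))
  expect_lt(abs(mean(ph2$rrb_total) - 26), 2 * 16 / sqrt(10000))
  ## ASD cases carry no anxiety score (over threshold under QTT coding)
  expect_true(all(is.na(ph2$anx_t)))
  ## truncation at the instrument floor
  ph3 <- simulate_phenotypes(big, gd$trait_genotype, all_aff, seed = 8)
  expect_true(all(ph3$rrb_total >= 0))
})

test_that("ascertainment requires 3 cases across at least two nuclear families", {
  ## grandparents; child A + spouse; two grandchildren
  ped <- fixture6()$ped
  ph <- function(aff) data.frame(id = ped$members$id,
                                 asd_status = aff,
                                 stringsAsFactors = FALSE)
  ## three cases: grandparent, parent, grandchild -> spans families
  expect_true(ascertain(ped, ph(c("affected", "unaffected", "affected",
                                  "unaffected", "affected", "unaffected"))))
  ## two cases only
  expect_false(ascertain(ped, ph(c("affected", "unaffected", "affected",
                                   rep("unaffected", 3)))))
  ## three cases all within one nuclear family (A, S and child c1)
  expect_false(ascertain(ped, ph(c("unaffected", "unaffected", "affected",
                                   "affected", "affected", "unaffected"))))
})

test_that("cohort generation is deterministic and round-trips through files", {
  panel <- marker_panel(n_snp = 4, n_ms = 1, seed = 12)
  truth <- simulation_truth(trait_model_dt(0.1, c(0.9, 0.7, 0.02)),
                            trait_cM = 6, panel = panel)
  dir <- withr::local_tempdir()
  coh <- generate_cohort(3, truths = truth, seed = 90,
                         out_dir = file.path(dir, "a"))
  coh2 <- generate_cohort(3, truths = truth, seed = 90,
                          out_dir = file.path(dir, "b"))
  expect_identical(coh$G, coh2$G)
  expect_identical(coh$phenotypes, coh2$phenotypes)
  for (f in c("cohort.ped", "cohort.map", "cohort.freq", "cohort.pheno",
              "truth.json"))
    expect_identical(readLines(file.path(dir, "a", f)),
                     readLines(file.path(dir, "b", f)))
  ## bundle round-trips through the readers without validation findings
  map <- read_map(file.path(dir, "a", "cohort.map"))
  map <- read_freq(file.path(dir, "a", "cohort.freq"), map)
  back <- read_ped(file.path(dir, "a", "cohort.ped"), map)
  expect_length(back$pedigrees, 3)
  for (ped in back$pedigrees)
    expect_equal(nrow(validate_pedigree(ped)), 0)
  expect_equal(back$genotypes$a1[rownames(coh$G$a1), map$name],
               coh$G$a1[, map$name])
  ## every generated pedigree satisfies the ascertainment rule
  for (pid in names(back$pedigrees)) {
    ph <- coh$phenotypes[coh$phenotypes$pedigree == pid, ]
    expect_true(ascertain(back$pedigrees[[pid]], ph))
  }
})

test_that("heterogeneity assignments split pedigrees across trait loci", {
  panel <- marker_panel(n_snp = 4, n_ms = 0, seed = 3)
  tA <- simulation_truth(trait_model_dt(0.1, c(0.9, 0.7, 0.02)),
                         trait_cM = 0, panel = panel)
  tB <- simulation_truth(trait_model_dt(0.1, c(0.9, 0.7, 0.02)),
                         trait_cM = 12, panel = panel)
  coh <- generate_cohort(4, truths = list(tA, tB), assignment = c(1, 1, 2, 2),
                         seed = 55)
  expect_equal(coh$assignment, c(1, 1, 2, 2))
  expect_length(coh$pedigrees, 4)
})

test_that("ascertained cohorts have inflated ASD prevalence relative to the population rate", {
  panel <- marker_panel(n_snp = 2, n_ms = 0, seed = 5)
  mod <- trait_model_dt(0.1, c(0.9, 0.7, 0.02))
  truth <- simulation_truth(mod, trait_cM = 0, panel = panel)
  coh <- generate_cohort(5, truths = truth, seed = 70)
  ## population rate implied by the penetrances under HWE
  p <- mod$p
  pop_rate <- p^2 * mod$f[1] + 2 * p * (1 - p) * mod$f[2] +
    (1 - p)^2 * mod$f[3]
  cohort_rate <- mean(coh$phenotypes$asd_status == "affected")
  expect_gt(cohort_rate, pop_rate)
})
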