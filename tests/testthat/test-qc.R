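trio_geno <- function(f, m, c) {
  ped <- pedigree("F", c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
                  c(1, 2, 1))
  keys <- ped_keys(ped)
  G <- geno1(setNames(c(f[1], m[1], c[1]), keys),
             setNames(c(f[2], m[2], c[2]), keys))
  list(ped = ped, G = G)
}

test_that("Mendelian trio and duo checks flag impossible transmissions", {
  x <- trio_geno(c(1, 1), c(1, 1), c(1, 2))
  expect_equal(sum(mendel_check(x$ped, x$G)$family_counts), 1)
  x <- trio_geno(c(1, 1), c(1, 1), c(1, 1))
  expect_equal(sum(mendel_check(x$ped, x$G)$family_counts), 0)
  ## duo: child must carry a paternal allele
  x <- trio_geno(c(1, 1), c(NA, NA), c(2, 2))
  expect_equal(sum(mendel_check(x$ped, x$G)$family_counts), 1)
  ## untestable: child untyped
  x <- trio_geno(c(1, 1), c(1, 2), c(NA, NA))
  expect_equal(sum(mendel_check(x$ped, x$G)$family_counts), 0)
})

test_that("gene-dropped genotypes are Mendel-clean; injected corruptions are caught", {
  panel <- marker_panel(n_snp = 6, n_ms = 2, seed = 8)
  truth <- simulation_truth(trait_model_dt(0.1, c(0.9, 0.7, 0.02)),
                            trait_cM = 10, panel = panel)
  for (s in 1:5) {
    ped <- build_pedigree(pedigree_template(), "P", seed = s)
    gd <- gene_drop(ped, truth, seed = 100 + s)
    expect_equal(sum(mendel_check(ped, gd$G)$family_counts), 0)
  }
  ## corrupt a fully typed child at a SNP: force an allele absent from
  ## both parents
  ped <- build_pedigree(pedigree_template(), "P", seed = 1)
  gd <- gene_drop(ped, truth, seed = 42)
  fams <- nuclear_families(ped)
  child <- fams[[1]]$children[1]
  key <- paste("P", child, sep = ":")
  snp <- panel$name[panel$type == "SNP"][1]
  par_keys <- paste("P", c(fams[[1]]$father, fams[[1]]$mother), sep = ":")
  present <- unique(c(gd$G$a1[par_keys, snp], gd$G$a2[par_keys, snp]))
  if (length(present) == 1) {
    other <- setdiff(1:2, present)
    gd$G$a1[key, snp] <- other; gd$G$a2[key, snp] <- other
    expect_gt(sum(mendel_check(ped, gd$G)$child_errors[child, ]), 0)
  }
})

test_that("Hardy-Weinberg chi-square matches direct computation and the exact oracle", {
  expect_equal(hwe_test(c("1/1" = 25, "1/2" = 50, "2/2" = 25)), 1)
  ## (50, 0, 50): chi-square equals n = 100 at df 1
  p <- hwe_test(c("1/1" = 50, "1/2" = 0, "2/2" = 50))
  expect_equal(p, pchisq(100, 1, lower.tail = FALSE))
  expect_lt(p, 1e-10)
  ## derived example at n = 100 against the exact enumeration test
  p_chi <- hwe_test(c("1/1" = 30, "1/2" = 40, "2/2" = 30))
  p_ex <- exact_hwe(30, 40, 30)
  expect_lt(abs(p_chi - p_ex), 0.01)
  ## monomorphic convention
  expect_equal(hwe_test(c("1/1" = 40)), 1)
})

test_that("HWE filtering decisions are calibrated in both regimes", {
  ## under true Hardy-Weinberg proportions, neither the chi-square test nor
  ## the exact test drops markers at the pipeline's extreme thresholds
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(20:100, 1)
    pA <- runif(1, 0.1, 0.9)
    g <- sample(1:3, n, replace = TRUE,
                prob = c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2))
    cnt <- c(sum(g == 1), sum(g == 2), sum(g == 3))
    p_chi <- hwe_test(c("1/1" = cnt[1], "1/2" = cnt[2], "2/2" = cnt[3]))
    p_ex <- exact_hwe(cnt[1], cnt[2], cnt[3])
    expect_gte(p_chi, 1e-10)
    expect_gte(p_ex, 1e-10)
  }
  ## gross violations (no heterozygotes at a common variant) are dropped
  ## under either test
  for (nn in c(60, 80, 100)) {
    cnt <- c(nn / 2, 0, nn / 2)
    expect_lt(hwe_test(c("1/1" = cnt[1], "1/2" = 0, "2/2" = cnt[3])), 1e-10)
    expect_lt(exact_hwe(cnt[1], 0, cnt[3]), 1e-10)
  }
})

test_that("marker filters drop by type-specific missingness and HWE thresholds", {
  ## 100 singleton founders across 100 pedigrees, 3 markers
  n <- 100
  peds <- lapply(seq_len(n), function(i)
    pedigree(as.character(i), "x", NA, NA, if (i %% 2) 1 else 2))
  keys <- paste(seq_len(n), "x", sep = ":")
  mknames <- c("s1", "s2", "ms1")
  a1 <- matrix(1L, n, 3, dimnames = list(keys, mknames))
  a2 <- matrix(2L, n, 3, dimnames = list(keys, mknames))
  ## s1: 6% missing (dropped); s2: HWE disaster; ms1: 20% missing (kept)
  a1[1:6, 1] <- NA; a2[1:6, 1] <- NA
  a2[, 2] <- a1[, 2]  # no heterozygotes at s2: half 1/1, half 2/2
  a1[1:50, 2] <- 2L; a2[1:50, 2] <- 2L
  a1[1:20, 3] <- NA; a2[1:20, 3] <- NA
  ## the 80 typed founders at ms1 sit in exact HWE proportions
  a1[21:40, 3] <- 1L; a2[21:40, 3] <- 1L    # 20 x 1/1
  a1[41:80, 3] <- 1L; a2[41:80, 3] <- 2L    # 40 x 1/2
  a1[81:100, 3] <- 2L; a2[81:100, 3] <- 2L  # 20 x 2/2
  G <- structure(list(a1 = a1, a2 = a2), class = "genotypes")
  map <- data.frame(name = mknames, chrom = "1", cM = c(0, 1, 2),
                    type = c("SNP", "SNP", "MS"), stringsAsFactors = FALSE)
  map$alleles <- list(1:2, 1:2, 1:2)
  map$freqs <- list(c(.5, .5), c(.5, .5), c(.5, .5))
  class(map) <- c("genetic_map", "data.frame")
  res <- filter_markers(G, map, qc_thresholds(), peds)
  expect_false("s1" %in% res$retained)   # 6% > 5% SNP missingness
  expect_false("s2" %in% res$retained)   # no heterozygotes: HWE p << 1e-10
  expect_true("ms1" %in% res$retained)   # 20% < 25% MS missingness
  expect_setequal(res$drop_log$reason[res$drop_log$marker == "s1"],
                  "missingness")
  expect_setequal(res$drop_log$reason[res$drop_log$marker == "s2"], "hwe")
})

test_that("sample filter masks high-missingness individuals but keeps structure", {
  ped <- pedigree("F", c("a", "b"), c(NA, NA), c(NA, NA), c(1, 2))
  keys <- ped_keys(ped)
  nm <- sprintf("s%02d", 1:20)
  a1 <- matrix(1L, 2, 20, dimnames = list(keys, nm))
  a2 <- matrix(2L, 2, 20, dimnames = list(keys, nm))
  a1[1, 1:2] <- NA; a2[1, 1:2] <- NA  # individual a: 10% SNP missing
  G <- structure(list(a1 = a1, a2 = a2), class = "genotypes")
  map <- data.frame(name = nm, chrom = "1", cM = seq_len(20),
                    type = "SNP", stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  res <- filter_samples(G, map, qc_thresholds())
  expect_equal(res$retained, "F:b")
  expect_true(all(is.na(res$G$a1["F:a", ])))
  expect_equal(res$drop_log$sample, "F:a")
})

test_that("LD thinning drops correlated SNPs greedily and keeps independent ones", {
  nf <- 20
  peds <- lapply(seq_len(nf), function(i)
    pedigree(paste0("p", i), "x", NA, NA, 1))
  keys <- paste0("p", seq_len(nf), ":x")
  ## three SNPs: r2(1,2) > 0.2, r2(1,3) < 0.2 -> middle dropped, ends kept
  d1 <- rep(c(0L, 1L, 2L), length.out = nf)
  d2 <- d1; d2[1:4] <- 2L - d2[1:4]          # correlated with d1
  d3 <- rep(c(2L, 0L, 1L, 1L, 0L), length.out = nf)  # near-independent
  stopifnot(cor(d1, d2)^2 > 0.2, cor(d1, d3)^2 < 0.2)
  dose_to_geno <- function(d) list(a1 = ifelse(d >= 1L, 1L, 2L),
                                   a2 = ifelse(d == 2L, 1L, 2L))
  gs <- lapply(list(d1, d2, d3), dose_to_geno)
  nm <- c("s1", "s2", "s3")
  a1 <- do.call(cbind, lapply(gs, `[[`, "a1"))
  a2 <- do.call(cbind, lapply(gs, `[[`, "a2"))
  dimnames(a1) <- dimnames(a2) <- list(keys, nm)
  G <- structure(list(a1 = a1, a2 = a2), class = "genotypes")
  map <- data.frame(name = nm, chrom = "1", cM = 0:2, type = "SNP",
                    stringsAsFactors = FALSE)
  map$alleles <- list(1:2, 1:2, 1:2)
  map$freqs <- list(c(.5, .5), c(.5, .5), c(.5, .5))
  class(map) <- c("genetic_map", "data.frame")
  kept <- ld_thin(G, map, 0.2, peds)
  expect_equal(kept, c("s1", "s3"))
  ## identical columns: duplicate dropped; r2 with everything retained <= 0.2
  a2dup <- a2; a2dup[, 2] <- a2[, 1]; a1dup <- a1; a1dup[, 2] <- a1[, 1]
  Gd <- structure(list(a1 = a1dup, a2 = a2dup), class = "genotypes")
  expect_equal(ld_thin(Gd, map, 0.2, peds), c("s1", "s3"))
  ## retained set never contains an in-window pair above the threshold
  for (pair in combn(kept, 2, simplify = FALSE)) {
    d <- lapply(pair, function(nmk) {
      j <- match(nmk, nm)
      (a1[, j] == 1L) + (a2[, j] == 1L)
    })
    expect_lte(cor(d[[1]], d[[2]])^2, 0.2)
  }
})

test_that("the QC pipeline is idempotent on simulated cohorts", {
  panel <- marker_panel(n_snp = 8, n_ms = 2, seed = 13)
  truth <- simulation_truth(trait_model_dt(0.1, c(0.9, 0.7, 0.02)),
                            trait_cM = 10, panel = panel)
  coh <- generate_cohort(3, truths = truth,
                         template = pedigree_template(2, 2), seed = 77)
  ## introduce some missingness so the filters have work to do
  set.seed(1)
  drop_cells <- matrix(runif(length(coh$G$a1)) < 0.03,
                       nrow(coh$G$a1))
  coh$G$a1[drop_cells] <- NA_integer_
  coh$G$a2[drop_cells] <- NA_integer_
  q1 <- qc_pipeline(coh$pedigrees, coh$G, coh$map)
  q2 <- qc_pipeline(coh$pedigrees, q1$G, q1$map)
  expect_equal(q2$map$name, q1$map$name)
  expect_equal(q2$G$a1, q1$G$a1)
  expect_equal(q2$retained_samples, q1$retained_samples)
  expect_equal(nrow(q2$marker_log), 0)
  expect_equal(nrow(q2$sample_log), 0)
})
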