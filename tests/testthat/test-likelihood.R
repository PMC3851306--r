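test_that("founder priors are Hardy-Weinberg and two-locus priors normalize", {
  expect_equal(founder_prior(c(0.5, 0.5), c(1, 2)), 0.5)
  expect_equal(founder_prior(c(0.1, 0.9), c(1, 1)), 0.01)
  pr_t <- founder_prior(c(0.3, 0.7))
  pr_m <- founder_prior(c(0.2, 0.5, 0.3))
  joint <- outer(pr_t, pr_m)
  expect_equal(sum(joint), 1)
  expect_length(joint, 18)  # 3 trait x 6 marker unordered classes
})

test_that("two-locus transmission respects recombination", {
  ## double heterozygote with known phase D-1 / d-2
  h1 <- c(1, 1); h2 <- c(2, 2)
  expect_equal(transmission_prob(h1, h2, 0, c(1, 1)), 0.5)
  expect_equal(transmission_prob(h1, h2, 0, c(1, 2)), 0)
  expect_equal(transmission_prob(h1, h2, 0.5, c(1, 2)), 0.25)
  for (th in c(0, 0.1, 0.37, 0.5)) {
    tot <- 0
    for (t in 1:2) for (m in 1:2)
      tot <- tot + transmission_prob(h1, h2, th, c(t, m))
    expect_equal(tot, 1)
  }
})

test_that("trait penetrances follow the three model definitions", {
  dt <- trait_model_dt(0.1, c(0.9, 0.8, 0.05))
  expect_equal(trait_penetrance("affected", 2, dt), 0.8)
  expect_equal(trait_penetrance("unaffected", 2, dt), 0.2)
  expect_equal(trait_penetrance("unknown", 1, dt), 1)
  qt <- trait_model_qt(0.1, c(1, 0, -1), 1)
  expect_equal(trait_penetrance(-1, 3, qt), dnorm(0))  # value at mu_dd
  expect_equal(trait_penetrance(NA, 1, qt), 1)
  qtt <- trait_model_qtt(0.1, c(1, 0, -1), 1, threshold = 0)
  expect_equal(trait_penetrance(list(censor = "over"), 2, qtt), 0.5)
  expect_equal(trait_penetrance(list(censor = "under"), 2, qtt), 0.5)
  expect_equal(trait_penetrance(list(censor = "valued", value = 1), 1, qtt),
               dnorm(0))
  ## ordering constraints are enforced at construction
  expect_error(trait_model_dt(0.1, c(0.5, 0.8, 0.1)))
  expect_error(trait_model_qt(0.1, c(-1, 0, 1), 1))
})

test_that("single-founder and untyped-pedigree likelihoods are analytic", {
  ped <- pedigree("F", "I", NA, NA, 1)
  map <- map1(c(0.5, 0.5))
  G <- geno1(setNames(1L, "F:I"), setNames(2L, "F:I"))
  mod <- trait_model_dt(0.1, c(0.9, 0.9, 0.05))
  expect_equal(peel_likelihood(ped, G, map, "m1", NULL, mod, 0.1), log(0.5))
  ## untyped, phenotype-free pedigree: total probability 1
  ped3 <- pedigree("F", c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
                   c(1, 2, 2))
  Gm <- geno1(setNames(rep(NA_integer_, 3), ped_keys(ped3)),
              setNames(rep(NA_integer_, 3), ped_keys(ped3)))
  expect_equal(peel_likelihood(ped3, Gm, map, "m1", NULL, mod, 0.2), 0)
})

test_that("peeling equals brute-force enumeration on random pedigrees", {
  set.seed(101)
  panel_freqs <- list(c(0.5, 0.5), c(0.7, 0.3), c(0.2, 0.3, 0.5))
  for (rep in 1:12) {
    for (attempt in 1:20) {
      n <- sample(4:8, 1)
      ped <- rand_pedigree(n)
      ## larger pedigrees use the 3-allele marker: stronger genotype
      ## pruning keeps the enumeration oracle tractable
      freqs <- if (n >= 7) panel_freqs[[3]] else
        panel_freqs[[sample.int(3, 1)]]
      map <- map1(freqs, type = if (length(freqs) > 2) "MS" else "SNP")
      truth <- simulation_truth(trait_model_dt(0.3, c(0.9, 0.6, 0.1)),
                                trait_cM = 2, panel = map)
      gd <- gene_drop(ped, truth)
      G <- gd$G
      aff <- sample(c("affected", "unaffected", "unknown"), n,
                    replace = TRUE)
      trait <- dt_coding(ped, aff)
      theta <- sample(c(0, 0.05, 0.2, 0.4, 0.5), 1)
      mod <- trait_model_dt(runif(1, 0.05, 0.5),
                            sort(runif(3, 0, 1), decreasing = TRUE))
      l_bf <- bf_peel(ped, G, map, "m1", trait, mod, theta)
      if (!is.na(l_bf)) break  # redraw when enumeration exceeds its budget
    }
    l_peel <- peel_likelihood(ped, G, map, "m1", trait, mod, theta)
    expect_lt(abs(exp(l_peel - l_bf) - 1), 1e-10)
  }
  ## quantitative models against the same enumeration
  for (rep in 1:4) {
    n <- sample(4:6, 1)
    ped <- rand_pedigree(n)
    map <- map1(c(0.6, 0.4))
    truth <- simulation_truth(trait_model_qt(0.3, c(1, 0, -1), 1),
                              trait_cM = 2, panel = map)
    gd <- gene_drop(ped, truth)
    vals <- ifelse(runif(n) < 0.8, rnorm(n), NA)
    trait <- trait_coding("q", "QT", value = setNames(vals, ped_keys(ped)))
    mod <- trait_model_qt(0.2, c(1.5, 0.5, -0.5), c(0.8, 1, 1.2))
    l_peel <- peel_likelihood(ped, gd$G, map, "m1", trait, mod, 0.15)
    l_bf <- bf_peel(ped, gd$G, map, "m1", trait, mod, 0.15)
    expect_lt(abs(exp(l_peel - l_bf) - 1), 1e-10)
  }
})

test_that("likelihood is invariant to member order (peeling root choice)", {
  fx <- fixture6()
  mod <- trait_model_dt(0.05, c(0.95, 0.85, 0.03))
  ref <- peel_likelihood(fx$ped, fx$G, fx$map, "m1", fx$trait, mod, 0.1)
  m <- fx$ped$members
  set.seed(7)
  for (rep in 1:5) {
    perm <- sample(nrow(m))
    ped2 <- pedigree(fx$ped$pedigree_id, m$id[perm], m$father[perm],
                     m$mother[perm], m$sex[perm])
    expect_equal(peel_likelihood(ped2, fx$G, fx$map, "m1", fx$trait, mod,
                                 0.1), ref)
  }
})

test_that("theta = 0.5 factorizes into trait and marker likelihoods", {
  fx <- fixture6()
  mod <- trait_model_dt(0.1, c(0.9, 0.6, 0.05))
  joint <- peel_likelihood(fx$ped, fx$G, fx$map, "m1", fx$trait, mod, 0.5)
  keys <- ped_keys(fx$ped)
  G_untyped <- geno1(setNames(rep(NA_integer_, 6), keys),
                     setNames(rep(NA_integer_, 6), keys))
  l_trait <- peel_likelihood(fx$ped, G_untyped, fx$map, "m1", fx$trait,
                             mod, 0.5)
  l_marker <- peel_likelihood(fx$ped, fx$G, fx$map, "m1", NULL, mod, 0.5)
  expect_equal(joint, l_trait + l_marker, tolerance = 1e-12)
})

test_that("an untyped, phenotype-free leaf does not change the likelihood", {
  fx <- fixture6()
  mod <- trait_model_dt(0.1, c(0.9, 0.6, 0.05))
  ref <- peel_likelihood(fx$ped, fx$G, fx$map, "m1", fx$trait, mod, 0.1)
  m <- fx$ped$members
  ped2 <- pedigree("P", c(m$id, "c3"), c(m$father, "A"), c(m$mother, "S"),
                   c(m$sex, "female"))
  keys2 <- ped_keys(ped2)
  G2 <- geno1(setNames(c(fx$G$a1[, 1], NA), keys2),
              setNames(c(fx$G$a2[, 1], NA), keys2))
  expect_equal(peel_likelihood(ped2, G2, fx$map, "m1", fx$trait, mod, 0.1),
               ref)
})

test_that("with full penetrance and affected-only phenotypes the trait is uninformative", {
  fx <- fixture6()
  mod <- trait_model_dt(0.1, c(1, 1, 1))
  aff <- rep("affected", 6)
  trait <- dt_coding(fx$ped, aff)
  joint <- peel_likelihood(fx$ped, fx$G, fx$map, "m1", trait, mod, 0.1)
  marker_only <- peel_likelihood(fx$ped, fx$G, fx$map, "m1", NULL, mod, 0.1)
  expect_equal(joint, marker_only, tolerance = 1e-12)
})

test_that("Mendelian-inconsistent data give a distinctly signaled zero likelihood", {
  ped <- pedigree("F", c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
                  c(1, 2, 1))
  keys <- ped_keys(ped)
  G <- geno1(setNames(c(1L, 1L, 2L), keys), setNames(c(1L, 1L, 2L), keys))
  mod <- trait_model_dt(0.1, c(0.9, 0.6, 0.05))
  expect_identical(peel_likelihood(ped, G, map1(c(.5, .5)), "m1", NULL,
                                   mod, 0.1), -Inf)
})

test_that("the likelihood convention is symmetric under allele relabeling", {
  ## relabeling D <-> d with p -> 1-p and reversed penetrances leaves the
  ## likelihood unchanged
  fx <- fixture6()
  f <- c(0.9, 0.6, 0.05)
  l1 <- peel_likelihood(fx$ped, fx$G, fx$map, "m1", fx$trait,
                        trait_model_dt(0.2, f), 0.1)
  ## build the relabeled model manually (violates the ordering constraint,
  ## so construct via the batch path with reversed penetrances)
  mod_swap <- structure(list(kind = "DT", p = 0.8, f = rev(f)),
                        class = "trait_model")
  l2 <- peel_likelihood(fx$ped, fx$G, fx$map, "m1", fx$trait, mod_swap, 0.1)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("admixture mixes linked and unlinked likelihoods", {
  expect_equal(admixture_likelihood(log(2e-5), log(1e-5), 0.5), log(1.5e-5))
  expect_equal(admixture_likelihood(log(2e-5), log(1e-5), 0), log(1e-5))
  expect_equal(admixture_likelihood(log(2e-5), log(1e-5), 1), log(2e-5))
})
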