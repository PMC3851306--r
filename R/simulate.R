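#' Three-generation pedigree template
#'
#' Template for the extended multiplex pedigrees the simulator emulates: a
#' founding couple, their children each married to an unrelated founder, and
#' the grandchildren. The default (3 sibships of 3) yields 17 members,
#' matching the average genotyped pedigree size of the study design this
#' generator mirrors (16-24 genotyped members per family).
#'
#' @param n_sibships Number of second-generation children (each founds a
#'   nuclear family with a married-in spouse).
#' @param sibship_size Number of grandchildren per nuclear family (scalar or
#'   vector of length \code{n_sibships}).
#' @return A list of class \code{pedigree_template}.
#' @export
pedigree_template <- function(n_sibships = 3L, sibship_size = 3L) {
  sibship_size <- rep(as.integer(sibship_size), length.out = n_sibships)
  stopifnot(n_sibships >= 1, all(sibship_size >= 0))
  structure(list(n_generations = 3L, n_sibships = as.integer(n_sibships),
                 sibship_size = sibship_size),
            class = "pedigree_template")
}

#' Build a pedigree from a template
#'
#' Deterministic structure given the seed (only the sexes of children are
#' random; married-in spouses take the complementary sex). The result is
#' loop-free by construction and passes [validate_pedigree()].
#'
#' @param template A [pedigree_template()].
#' @param pedigree_id Family identifier.
#' @param seed Optional integer seed.
#' @return A \code{pedigree}.
#' @export
build_pedigree <- function(template = pedigree_template(), pedigree_id = "1",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  id <- c("1", "2"); father <- c(NA, NA); mother <- c(NA, NA)
  sex <- c("male", "female")
  nxt <- 3L
  for (s in seq_len(template$n_sibships)) {
    child <- as.character(nxt); nxt <- nxt + 1L
    spouse <- as.character(nxt); nxt <- nxt + 1L
    cs <- sample(c("male", "female"), 1)
    id <- c(id, child, spouse)
    father <- c(father, "1", NA); mother <- c(mother, "2", NA)
    sex <- c(sex, cs, if (cs == "male") "female" else "male")
    for (g in seq_len(template$sibship_size[s])) {
      gid <- as.character(nxt); nxt <- nxt + 1L
      id <- c(id, gid)
      father <- c(father, if (cs == "male") child else spouse)
      mother <- c(mother, if (cs == "male") spouse else child)
      sex <- c(sex, sample(c("male", "female"), 1))
    }
  }
  pedigree(pedigree_id, id, father, mother, sex)
}

#' Default simulated marker panel
#'
#' One chromosome region: \code{n_snp} SNPs at \code{spacing_cM} intervals
#' plus \code{n_ms} microsatellites spread evenly across the region
#' (echoing a dense SNP panel combined with a ~4 cM microsatellite scan).
#' SNP minor-allele frequencies are drawn uniformly on [0.2, 0.5];
#' microsatellites get 6 alleles with a fixed moderately skewed frequency
#' profile.
#'
#' @param n_snp,n_ms Marker counts.
#' @param spacing_cM SNP spacing in centimorgans.
#' @param chrom Chromosome label.
#' @param seed Optional seed for the frequency draws.
#' @return A \code{genetic_map} with alleles and frequencies attached.
#' @export
marker_panel <- function(n_snp = 50L, n_ms = 5L, spacing_cM = 4,
                         chrom = "1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos_snp <- (seq_len(n_snp) - 1L) * spacing_cM
  span <- max(pos_snp, 1)
  pos_ms <- if (n_ms > 0) seq(0, span, length.out = n_ms + 2)[-c(1, n_ms + 2)] + 1
  map <- data.frame(
    name = c(sprintf("c%s_snp%03d", chrom, seq_len(n_snp)),
             if (n_ms > 0) sprintf("c%s_ms%02d", chrom, seq_len(n_ms))),
    chrom = chrom,
    cM = c(pos_snp, pos_ms),
    type = c(rep("SNP", n_snp), rep("MS", n_ms)),
    stringsAsFactors = FALSE)
  map <- map[order(map$cM), , drop = FALSE]
  rownames(map) <- NULL
  map$alleles <- vector("list", nrow(map))
  map$freqs <- vector("list", nrow(map))
  ms_prof <- c(0.25, 0.20, 0.20, 0.15, 0.10, 0.10)
  for (j in seq_len(nrow(map))) {
    if (map$type[j] == "SNP") {
      maf <- stats::runif(1, 0.2, 0.5)
      map$alleles[[j]] <- 1:2
      map$freqs[[j]] <- c(1 - maf, maf)
    } else {
      map$alleles[[j]] <- 1:6
      map$freqs[[j]] <- ms_prof
    }
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Simulation ground truth
#'
#' @param model A \code{trait_model} (the generating model at the trait
#'   locus). For QT/QTT truths, ASD status (needed for ascertainment) is
#'   drawn from \code{asd_penetrance} at the same locus.
#' @param trait_chrom,trait_cM Trait-locus position (may fall between
#'   markers, or on an unrepresented chromosome for null simulations).
#' @param panel A [marker_panel()] / \code{genetic_map}.
#' @param asd_penetrance Penetrances used to assign ASD status when
#'   \code{model} is not DT (default \code{c(0.9, 0.7, 0.02)}).
#' @param qt_trait For QT/QTT truths, which phenotype column receives the
#'   genotypic values: \code{"rrb_total"}, \code{"soc_t"} or \code{"anx_t"}.
#' @return A list of class \code{simulation_truth}.
#' @export
simulation_truth <- function(model, trait_chrom = "1", trait_cM = 100,
                             panel = marker_panel(),
                             asd_penetrance = c(0.9, 0.7, 0.02),
                             qt_trait = "rrb_total") {
  stopifnot(inherits(model, "trait_model"))
  structure(list(model = model, trait_chrom = as.character(trait_chrom),
                 trait_cM = trait_cM, panel = panel,
                 asd_penetrance = asd_penetrance, qt_trait = qt_trait),
            class = "simulation_truth")
}

#' Gene-drop simulation of genotypes
#'
#' Founder haplotypes are drawn from the marker allele frequencies under
#' linkage equilibrium; transmissions follow Mendelian segregation with
#' recombination between adjacent loci given by the Haldane map function on
#' the inter-locus cM distances. The diallelic trait locus is inserted at
#' its map position and co-segregates accordingly; its genotypes are
#' returned as hidden truth, not in the observable genotype matrix.
#'
#' @param ped A \code{pedigree}.
#' @param truth A [simulation_truth()].
#' @param seed Optional integer seed.
#' @return List with \code{G} (a \code{genotypes} object over the panel),
#'   \code{trait_genotype} (named integer vector, 1 = DD, 2 = Dd, 3 = dd),
#'   and \code{haplotypes}: per chromosome, the paternal/maternal haplotype
#'   matrices \code{h1}/\code{h2} (members x loci, trait locus labelled
#'   \code{".trait"}).
#' @export
gene_drop <- function(ped, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- truth$panel
  m <- ped$members
  n <- nrow(m)
  ## per chromosome: ordered loci incl. trait locus where applicable
  hap <- list()  # hap[[chrom]][[1 or 2]]: n x nloci allele matrix
  chroms <- unique(c(map$chrom, truth$trait_chrom))
  ord <- order(match(m$id, m$id))  # members are in parent-before-child order
  ## ensure parents precede children
  depth <- rep(0L, n); names(depth) <- m$id
  repeat {
    d <- depth
    for (i in seq_len(n)) {
      pd <- 0L
      if (!is.na(m$father[i])) pd <- max(pd, depth[m$father[i]] + 1L)
      if (!is.na(m$mother[i])) pd <- max(pd, depth[m$mother[i]] + 1L)
      depth[i] <- pd
    }
    if (identical(d, depth)) break
  }
  topo <- order(depth)
  for (ch in chroms) {
    sel <- which(map$chrom == ch)
    pos <- map$cM[sel]
    frq <- map$freqs[sel]
    is_trait <- logical(length(sel))
    if (ch == truth$trait_chrom) {
      ins <- findInterval(truth$trait_cM, pos)
      pos <- append(pos, truth$trait_cM, after = ins)
      p <- truth$model$p
      frq <- append(frq, list(c(p, 1 - p)), after = ins)
      is_trait <- append(is_trait, TRUE, after = ins)
    }
    L <- length(pos)
    theta <- haldane_theta(diff(pos))
    h1 <- matrix(NA_integer_, n, L); h2 <- h1
    for (i in topo) {
      for (side in 1:2) {
        par <- if (side == 1) m$father[i] else m$mother[i]
        if (is.na(par)) {
          g <- vapply(frq, function(f)
            sample.int(length(f), 1, prob = f), 1L)
        } else {
          pi_ <- match(par, m$id)
          src <- integer(L)
          src[1] <- sample(1:2, 1)
          if (L > 1) {
            rec <- stats::runif(L - 1) < theta
            for (l in 2:L) src[l] <- if (rec[l - 1]) 3L - src[l - 1] else
              src[l - 1]
          }
          g <- ifelse(src == 1L, h1[pi_, ], h2[pi_, ])
        }
        if (side == 1) h1[i, ] <- g else h2[i, ] <- g
      }
    }
    loci <- character(length(pos))
    loci[!is_trait] <- map$name[sel]
    loci[is_trait] <- ".trait"
    dimnames(h1) <- dimnames(h2) <- list(m$id, loci)
    hap[[ch]] <- list(h1 = h1, h2 = h2, sel = sel, is_trait = is_trait)
  }
  keys <- ped_key(ped)
  a1 <- matrix(NA_integer_, n, nrow(map), dimnames = list(keys, map$name))
  a2 <- a1
  trait_geno <- rep(NA_integer_, n)
  for (ch in chroms) {
    hh <- hap[[ch]]
    mk <- !hh$is_trait
    if (any(mk)) {
      a1[, map$name[hh$sel]] <- hh$h1[, mk, drop = FALSE]
      a2[, map$name[hh$sel]] <- hh$h2[, mk, drop = FALSE]
    }
    if (any(hh$is_trait)) {
      tl <- which(hh$is_trait)
      nD <- (hh$h1[, tl] == 1L) + (hh$h2[, tl] == 1L)
      trait_geno <- 3L - nD
    }
  }
  if (all(is.na(trait_geno))) {  # trait locus on no simulated chromosome
    p <- truth$model$p
    nD <- stats::rbinom(n, 2, p)
    trait_geno <- 3L - nD
  }
  names(trait_geno) <- m$id
  list(G = structure(list(a1 = a1, a2 = a2), class = "genotypes"),
       trait_genotype = trait_geno,
       haplotypes = lapply(hap, function(h) h[c("h1", "h2")]))
}

#' Phenotype-distribution calibration
#'
#' Generating distributions for the secondary phenotypes, conditional on
#' ASD status: anxiety t-scores N(51, 9) for non-ASD adults (ASD cases are
#' unmeasured, hence over-threshold under the QTT coding); RBS-R totals
#' N(26, 16) for cases and N(4, 7) for non-cases, truncated at the
#' instrument floor of 0; SRS t-scores N(84, 14) for cases and N(48, 11)
#' for non-cases. Dichotomous secondary measures are generated so their
#' case rates match the observed rates (MPRS positivity, CELF-4 core
#' language < 84, CTOPP non-word repetition <= 7 and rapid naming < 84).
#' BAP-Q items for non-ASD adults are Likert draws whose mean is shifted
#' upward for carriers of the disease allele, making a tunable fraction of
#' carriers classify BAP-positive.
#'
#' @param anx_mean,anx_sd Non-ASD adult anxiety t-score distribution.
#' @param rrb_case_mean,rrb_case_sd,rrb_noncase_mean,rrb_noncase_sd RBS-R
#'   totals by ASD status.
#' @param soc_case_mean,soc_case_sd,soc_noncase_mean,soc_noncase_sd SRS
#'   t-scores by ASD status.
#' @param truncate_rrb Truncate RBS-R totals at 0 (instrument floor).
#' @param bapq_base_mean,bapq_carrier_shift,bapq_item_sd BAP-Q item
#'   generation: item responses are rounded clamped normals with the given
#'   base mean, carrier shift, and SD.
#' @param mprs_rate_case,mprs_rate_noncase MPRS positivity rates.
#' @param celf_case_mean,celf_noncase_mean,celf_sd CELF-4 core language.
#' @param nwr_case_mean,nwr_noncase_mean,nwr_sd CTOPP non-word repetition.
#' @param rap_case_mean,rap_noncase_mean,rap_sd CTOPP rapid naming.
#' @return A list of class \code{phenotype_calibration}.
#' @export
phenotype_calibration <- function(anx_mean = 51, anx_sd = 9,
                                  rrb_case_mean = 26, rrb_case_sd = 16,
                                  rrb_noncase_mean = 4, rrb_noncase_sd = 7,
                                  soc_case_mean = 84, soc_case_sd = 14,
                                  soc_noncase_mean = 48, soc_noncase_sd = 11,
                                  truncate_rrb = TRUE,
                                  bapq_base_mean = 2.2,
                                  bapq_carrier_shift = 1.3,
                                  bapq_item_sd = 1.2,
                                  mprs_rate_case = 0.61,
                                  mprs_rate_noncase = 0.24,
                                  celf_case_mean = 84, celf_noncase_mean = 115,
                                  celf_sd = 15,
                                  nwr_case_mean = 7.8, nwr_noncase_mean = 9.2,
                                  nwr_sd = 3,
                                  rap_case_mean = 85.5, rap_noncase_mean = 102,
                                  rap_sd = 15) {
  structure(as.list(environment()), class = "phenotype_calibration")
}

trunc0 <- function(x, active = TRUE) if (active) pmax(x, 0) else x

#' Simulate phenotypes given trait genotypes
#'
#' ASD affection is drawn from the truth penetrances applied to the hidden
#' trait genotype. Adults (founders and anyone who is a parent) receive the
#' adult instruments: BAP-Q self and informant item responses (non-ASD
#' adults; carriers of at least one disease allele are shifted upward),
#' the NEO anxiety t-score (non-ASD adults), and MPRS. All individuals
#' receive RBS-R, SRS, CELF-4 and CTOPP measures conditional on ASD status.
#' When the truth model is quantitative (QT/QTT), the column named by
#' \code{truth$qt_trait} is drawn from the genotypic normal model instead of
#' the status-conditional calibration.
#'
#' @param ped A \code{pedigree}.
#' @param trait_genotype Named integer vector from [gene_drop()].
#' @param truth A [simulation_truth()].
#' @param calibration A [phenotype_calibration()].
#' @param seed Optional integer seed.
#' @return A phenotype data frame in the layout of [read_phenotypes()].
#' @export
simulate_phenotypes <- function(ped, trait_genotype, truth,
                                calibration = phenotype_calibration(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cal <- calibration
  m <- ped$members
  n <- nrow(m)
  g <- trait_genotype[m$id]
  pen <- if (truth$model$kind == "DT") truth$model$f else
    truth$asd_penetrance
  asd <- stats::runif(n) < pen[g]
  is_parent <- m$id %in% c(m$father, m$mother)
  adult <- is_parent | is_founder(ped)
  carrier <- g <= 2L
  out <- data.frame(pedigree = ped$pedigree_id, id = m$id, sex = m$sex,
                    asd_status = ifelse(asd, "affected", "unaffected"),
                    stringsAsFactors = FALSE)
  ## BAP-Q items (non-ASD adults)
  rated <- adult & !asd
  mu_i <- cal$bapq_base_mean + ifelse(carrier, cal$bapq_carrier_shift, 0)
  likert_mat <- function() {
    mat <- matrix(NA_integer_, n, 36)
    if (any(rated)) {
      nr <- sum(rated)
      draws <- stats::rnorm(nr * 36, rep(mu_i[rated], 36), cal$bapq_item_sd)
      mat[rated, ] <- as.integer(pmin(6, pmax(1, round(draws))))
    }
    mat
  }
  self_mat <- likert_mat(); inf_mat <- likert_mat()
  for (it in 1:36) out[[paste0("bapq_self_", it)]] <- self_mat[, it]
  for (it in 1:36) out[[paste0("bapq_inf_", it)]] <- inf_mat[, it]
  ## quantitative secondary measures
  qt_col <- if (truth$model$kind %in% c("QT", "QTT")) truth$qt_trait else ""
  draw_qt <- function() stats::rnorm(n, truth$model$mu[g], truth$model$sd[g])
  out$anx_t <- ifelse(!asd & adult,
                      if (qt_col == "anx_t") draw_qt() else
                        stats::rnorm(n, cal$anx_mean, cal$anx_sd),
                      NA_real_)
  out$rrb_total <- if (qt_col == "rrb_total") draw_qt() else
    trunc0(ifelse(asd, stats::rnorm(n, cal$rrb_case_mean, cal$rrb_case_sd),
                  stats::rnorm(n, cal$rrb_noncase_mean, cal$rrb_noncase_sd)),
           cal$truncate_rrb)
  out$soc_t <- if (qt_col == "soc_t") draw_qt() else
    ifelse(asd, stats::rnorm(n, cal$soc_case_mean, cal$soc_case_sd),
           stats::rnorm(n, cal$soc_noncase_mean, cal$soc_noncase_sd))
  ## dichotomous secondary measures
  out$mprs_positive <- ifelse(adult,
    as.integer(stats::runif(n) < ifelse(asd, cal$mprs_rate_case,
                                        cal$mprs_rate_noncase)),
    NA_integer_)
  out$celf_core <- stats::rnorm(n, ifelse(asd, cal$celf_case_mean,
                                          cal$celf_noncase_mean), cal$celf_sd)
  out$ctopp_nwr <- round(stats::rnorm(n, ifelse(asd, cal$nwr_case_mean,
                                                cal$nwr_noncase_mean),
                                      cal$nwr_sd))
  out$ctopp_rap <- stats::rnorm(n, ifelse(asd, cal$rap_case_mean,
                                          cal$rap_noncase_mean), cal$rap_sd)
  out$key <- paste(out$pedigree, out$id, sep = ":")
  out
}

#' Ascertainment rule for multiplex pedigrees
#'
#' A pedigree is retained when it carries at least three ASD cases and the
#' cases are spread across at least two nuclear families: no single nuclear
#' family (counting membership as parent or as offspring) contains all
#' affected individuals.
#'
#' @param ped A \code{pedigree}.
#' @param phenotypes Phenotype data frame with \code{id} and
#'   \code{asd_status}.
#' @return \code{TRUE} (retained) or \code{FALSE} (rejected).
#' @export
ascertain <- function(ped, phenotypes) {
  aff <- phenotypes$id[phenotypes$asd_status == "affected"]
  if (length(aff) < 3) return(FALSE)
  famof <- families_of(ped)
  common <- Reduce(intersect, famof[aff])
  length(common) == 0
}

#' Generate a full simulated study cohort
#'
#' Repeatedly builds pedigrees, gene-drops genotypes, simulates phenotypes
#' and applies the ascertainment rule until \code{n_pedigrees} are retained.
#' Under between-pedigree locus heterogeneity each pedigree is assigned one
#' of several trait loci (\code{k = 1} recovers homogeneity).
#'
#' @param n_pedigrees Number of retained pedigrees (default 19).
#' @param truths List of [simulation_truth()] objects, one per trait locus.
#' @param assignment Integer vector of length \code{n_pedigrees} assigning
#'   each pedigree to a truth (default: round-robin).
#' @param template A [pedigree_template()].
#' @param calibration A [phenotype_calibration()].
#' @param seed Integer seed (reproducible bundles).
#' @param out_dir Optional directory; when given, writes \code{cohort.ped},
#'   \code{cohort.map}, \code{cohort.freq}, \code{cohort.pheno} and a
#'   \code{truth.json} sidecar.
#' @param max_reject Error when more than this many candidate pedigrees are
#'   rejected per retained pedigree.
#' @return List with \code{pedigrees}, \code{G}, \code{map},
#'   \code{phenotypes}, \code{trait_genotypes}, \code{assignment},
#'   \code{truths}.
#' @export
generate_cohort <- function(n_pedigrees = 19L, truths,
                            assignment = NULL,
                            template = pedigree_template(),
                            calibration = phenotype_calibration(),
                            seed = NULL, out_dir = NULL,
                            max_reject = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(truths, "simulation_truth")) truths <- list(truths)
  if (is.null(assignment))
    assignment <- rep_len(seq_along(truths), n_pedigrees)
  stopifnot(length(assignment) == n_pedigrees,
            all(assignment %in% seq_along(truths)))
  map <- truths[[1]]$panel
  peds <- vector("list", n_pedigrees)
  phen <- vector("list", n_pedigrees)
  tg <- vector("list", n_pedigrees)
  Gs <- vector("list", n_pedigrees)
  for (i in seq_len(n_pedigrees)) {
    truth <- truths[[assignment[i]]]
    rejects <- 0L
    repeat {
      ped <- build_pedigree(template, pedigree_id = as.character(i))
      gd <- gene_drop(ped, truth)
      ph <- simulate_phenotypes(ped, gd$trait_genotype, truth, calibration)
      if (ascertain(ped, ph)) break
      rejects <- rejects + 1L
      if (rejects > max_reject)
        stop("ascertainment probability too low: ", rejects,
             " rejections for pedigree ", i,
             " (penetrances/allele frequency make >= 3 cases across >= 2 ",
             "nuclear families too rare)")
    }
    peds[[i]] <- ped
    phen[[i]] <- ph
    tg[[i]] <- gd$trait_genotype
    Gs[[i]] <- gd$G
  }
  G <- structure(list(a1 = do.call(rbind, lapply(Gs, `[[`, "a1")),
                      a2 = do.call(rbind, lapply(Gs, `[[`, "a2"))),
                 class = "genotypes")
  phenotypes <- do.call(rbind, phen)
  names(peds) <- vapply(peds, `[[`, "", "pedigree_id")
  bundle <- list(pedigrees = peds, G = G, map = map,
                 phenotypes = phenotypes, trait_genotypes = tg,
                 assignment = assignment, truths = truths)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ped(peds, G, map, file.path(out_dir, "cohort.ped"))
    utils::write.table(
      data.frame(name = map$name, chrom = map$chrom, cM = map$cM,
                 type = map$type),
      file.path(out_dir, "cohort.map"),
      sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
    frq <- do.call(rbind, lapply(seq_len(nrow(map)), function(j)
      data.frame(marker = map$name[j], allele = map$alleles[[j]],
                 freq = map$freqs[[j]])))
    utils::write.table(frq, file.path(out_dir, "cohort.freq"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_phenotypes(phenotypes, file.path(out_dir, "cohort.pheno"))
    truth_out <- list(
      assignment = assignment,
      loci = lapply(truths, function(tr) list(
        chrom = tr$trait_chrom, cM = tr$trait_cM,
        model = tr$model[setdiff(names(tr$model), "kind")],
        kind = tr$model$kind)))
    jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}
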