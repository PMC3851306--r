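#' Genotype quality-control thresholds
#'
#' Defaults follow standard practice for mixed SNP/microsatellite linkage
#' panels: markers are dropped above 5% (SNP) or 25% (MS) missingness;
#' samples are masked above the same type-specific missingness; SNPs with a
#' Hardy-Weinberg p-value below 1e-10 and MSs below 1e-4 are dropped; SNPs
#' in linkage disequilibrium with r-squared above 0.20 are thinned.
#' Mendelian-error limits (not part of the published thresholds) default to
#' at most 1 error per marker and at most 1% of testable markers in error
#' per individual.
#'
#' @param snp_marker_missingness,ms_marker_missingness Marker missingness
#'   fractions above which a marker is dropped.
#' @param snp_sample_missingness,ms_sample_missingness Sample missingness
#'   fractions above which an individual's genotypes are masked.
#' @param hwe_p_snp,hwe_p_ms Hardy-Weinberg p-value floors.
#' @param ld_r2 Maximum tolerated composite-genotype r-squared between SNPs.
#' @param mendel_marker_max Maximum Mendel errors per marker.
#' @param mendel_sample_fraction_max Maximum fraction of an individual's
#'   testable markers showing a Mendel error.
#' @return A list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(snp_marker_missingness = 0.05,
                          ms_marker_missingness = 0.25,
                          snp_sample_missingness = 0.05,
                          ms_sample_missingness = 0.25,
                          hwe_p_snp = 1e-10,
                          hwe_p_ms = 1e-4,
                          ld_r2 = 0.20,
                          mendel_marker_max = 1L,
                          mendel_sample_fraction_max = 0.01) {
  th <- list(snp_marker_missingness = snp_marker_missingness,
             ms_marker_missingness = ms_marker_missingness,
             snp_sample_missingness = snp_sample_missingness,
             ms_sample_missingness = ms_sample_missingness,
             hwe_p_snp = hwe_p_snp, hwe_p_ms = hwe_p_ms, ld_r2 = ld_r2,
             mendel_marker_max = mendel_marker_max,
             mendel_sample_fraction_max = mendel_sample_fraction_max)
  fr <- unlist(th[c(1:4, 7, 9)])
  stopifnot(all(fr >= 0 & fr <= 1), hwe_p_snp > 0, hwe_p_snp < 1,
            hwe_p_ms > 0, hwe_p_ms < 1)
  class(th) <- "qc_thresholds"
  th
}

#' Mendelian-inconsistency check
#'
#' For every child in every nuclear family and every marker: with both
#' parents typed, the child's genotype must be reachable by Mendelian
#' transmission (one allele from each parent); with one parent typed, the
#' child must be able to have received one of that parent's alleles.
#' Configurations with the child (or both parents) untyped are untestable
#' and contribute zero errors.
#'
#' @param ped A \code{pedigree}.
#' @param G A \code{genotypes} object covering the pedigree's members.
#' @return A list with \code{family_counts} (matrix: nuclear family x
#'   marker error counts), \code{child_errors} (logical matrix: individual x
#'   marker, TRUE where that child's trio/duo is inconsistent), and
#'   \code{testable} (logical matrix, same shape: child checkable there).
#' @export
mendel_check <- function(ped, G) {
  fams <- nuclear_families(ped)
  keys <- ped_key(ped)
  ids <- ped$members$id
  nm <- ncol(G$a1)
  child_err <- matrix(FALSE, length(ids), nm,
                      dimnames = list(ids, colnames(G$a1)))
  testable <- child_err
  fam_counts <- matrix(0L, length(fams), nm,
                       dimnames = list(NULL, colnames(G$a1)))
  gk <- function(id) {
    k <- paste(ped$pedigree_id, id, sep = ":")
    list(a1 = G$a1[k, ], a2 = G$a2[k, ])
  }
  has <- function(g, x) !is.na(g$a1) & (g$a1 == x | g$a2 == x)
  for (fi in seq_along(fams)) {
    f <- fams[[fi]]
    fg <- gk(f$father); mg <- gk(f$mother)
    ft <- !is.na(fg$a1); mt <- !is.na(mg$a1)
    for (cid in f$children) {
      cg <- gk(cid)
      ct <- !is.na(cg$a1)
      err <- rep(FALSE, nm); tst <- rep(FALSE, nm)
      trio <- ct & ft & mt
      if (any(trio)) {
        ok <- (has(fg, cg$a1) & has(mg, cg$a2)) |
              (has(fg, cg$a2) & has(mg, cg$a1))
        err[trio] <- !ok[trio]; tst[trio] <- TRUE
      }
      duo_f <- ct & ft & !mt
      if (any(duo_f)) {
        ok <- has(fg, cg$a1) | has(fg, cg$a2)
        err[duo_f] <- !ok[duo_f]; tst[duo_f] <- TRUE
      }
      duo_m <- ct & !ft & mt
      if (any(duo_m)) {
        ok <- has(mg, cg$a1) | has(mg, cg$a2)
        err[duo_m] <- !ok[duo_m]; tst[duo_m] <- TRUE
      }
      child_err[cid, ] <- child_err[cid, ] | err
      testable[cid, ] <- testable[cid, ] | tst
      fam_counts[fi, ] <- fam_counts[fi, ] + err
    }
  }
  list(family_counts = fam_counts, child_errors = child_err,
       testable = testable, families = fams)
}

#' Hardy-Weinberg goodness-of-fit test
#'
#' Chi-square goodness-of-fit of founder genotype counts against
#' Hardy-Weinberg proportions computed from the observed allele frequencies,
#' with degrees of freedom = number of genotype categories minus number of
#' alleles. Monomorphic markers return p = 1 by convention.
#'
#' @param counts Named numeric vector of genotype counts; names are
#'   \code{"a/b"} allele-label pairs (e.g. \code{c("1/1" = 25, "1/2" = 50,
#'   "2/2" = 25)}). Unlisted genotype categories over the same allele set
#'   are treated as zero counts.
#' @return The chi-square p-value.
#' @export
hwe_test <- function(counts) {
  if (sum(counts) == 0) return(1)
  pairs <- strsplit(names(counts), "/", fixed = TRUE)
  a <- vapply(pairs, `[`, "", 1); b <- vapply(pairs, `[`, "", 2)
  alleles <- sort(unique(c(a, b)))
  k <- length(alleles)
  if (k < 2) return(1)
  n <- sum(counts)
  ## allele frequencies from genotype counts
  cnt <- setNames(numeric(k), alleles)
  for (i in seq_along(counts)) {
    cnt[a[i]] <- cnt[a[i]] + counts[i]
    cnt[b[i]] <- cnt[b[i]] + counts[i]
  }
  p <- cnt / (2 * n)
  ## observed counts over the full unordered-genotype category set
  cats <- outer(alleles, alleles, paste, sep = "/")
  cats <- cats[upper.tri(cats, diag = TRUE)]
  obs <- setNames(numeric(length(cats)), cats)
  key <- ifelse(match(a, alleles) <= match(b, alleles),
                paste(a, b, sep = "/"), paste(b, a, sep = "/"))
  for (i in seq_along(counts)) obs[key[i]] <- obs[key[i]] + counts[i]
  expd <- vapply(strsplit(cats, "/", fixed = TRUE), function(ab) {
    if (ab[1] == ab[2]) n * p[ab[1]]^2 else 2 * n * p[ab[1]] * p[ab[2]]
  }, 0)
  use <- expd > 0
  x2 <- sum((obs[use] - expd[use])^2 / expd[use])
  df <- length(cats) - k
  if (df < 1) return(1)
  stats::pchisq(x2, df, lower.tail = FALSE)
}

## founder genotype counts at marker j (column name or index)
founder_genotype_counts <- function(pedigrees, G, j) {
  fkeys <- unlist(lapply(pedigrees, function(p) ped_key(p)[is_founder(p)]))
  fkeys <- intersect(fkeys, rownames(G$a1))
  a1 <- G$a1[fkeys, j]; a2 <- G$a2[fkeys, j]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  tab <- table(paste(lo, hi, sep = "/"))
  setNames(as.numeric(tab), names(tab))
}

marker_missingness <- function(G, samples = rownames(G$a1)) {
  sub <- G$a1[samples, , drop = FALSE]
  if (nrow(sub) == 0) return(setNames(rep(0, ncol(sub)), colnames(sub)))
  colMeans(is.na(sub))
}

#' Marker-level QC filter
#'
#' Drops markers whose missingness is strictly above the type-specific
#' threshold, whose founder Hardy-Weinberg p-value is below the
#' type-specific floor, or whose Mendelian-error count exceeds
#' \code{mendel_marker_max}.
#'
#' @param G \code{genotypes} object.
#' @param map \code{genetic_map}.
#' @param thresholds A [qc_thresholds()] object.
#' @param pedigrees List of pedigrees (needed for the founder-based HWE test
#'   and Mendel counts; if \code{NULL} those checks are skipped).
#' @param samples Sample keys over which missingness is computed (defaults
#'   to all rows of \code{G} that are not fully missing).
#' @return List with \code{retained} (marker names) and \code{drop_log}
#'   (data frame: marker, reason, value).
#' @export
filter_markers <- function(G, map, thresholds = qc_thresholds(),
                           pedigrees = NULL, samples = NULL) {
  if (is.null(samples)) {
    full_miss <- rowMeans(is.na(G$a1)) == 1
    samples <- rownames(G$a1)[!full_miss]
  }
  miss <- marker_missingness(G, samples)
  lim <- ifelse(map$type == "SNP", thresholds$snp_marker_missingness,
                thresholds$ms_marker_missingness)
  plim <- ifelse(map$type == "SNP", thresholds$hwe_p_snp, thresholds$hwe_p_ms)
  log <- data.frame(marker = character(), reason = character(),
                    value = numeric(), stringsAsFactors = FALSE)
  drop <- miss[map$name] > lim
  for (j in which(drop))
    log[nrow(log) + 1L, ] <- list(map$name[j], "missingness", miss[map$name[j]])
  if (!is.null(pedigrees)) {
    mend <- Reduce(`+`, lapply(pedigrees, function(p)
      colSums(mendel_check(p, G)$family_counts)))
    for (j in seq_len(nrow(map))) {
      if (drop[j]) next
      if (mend[map$name[j]] > thresholds$mendel_marker_max) {
        drop[j] <- TRUE
        log[nrow(log) + 1L, ] <- list(map$name[j], "mendel",
                                      mend[map$name[j]])
      }
    }
    for (j in seq_len(nrow(map))) {
      if (drop[j]) next
      p <- hwe_test(founder_genotype_counts(pedigrees, G, map$name[j]))
      if (p < plim[j]) {
        drop[j] <- TRUE
        log[nrow(log) + 1L, ] <- list(map$name[j], "hwe", p)
      }
    }
  }
  list(retained = map$name[!drop], drop_log = log)
}

#' Sample-level QC filter
#'
#' Masks (sets missing) the genotypes of individuals whose missing fraction
#' over SNPs exceeds the SNP threshold, over MSs exceeds the MS threshold,
#' or whose Mendelian-error fraction over testable markers exceeds
#' \code{mendel_sample_fraction_max}. Pedigree structure is retained.
#'
#' @inheritParams filter_markers
#' @return List with \code{G} (masked genotypes), \code{retained} (keys of
#'   unmasked samples), and \code{drop_log}.
#' @export
filter_samples <- function(G, map, thresholds = qc_thresholds(),
                           pedigrees = NULL) {
  snp <- map$name[map$type == "SNP"]
  ms <- map$name[map$type == "MS"]
  keys <- rownames(G$a1)
  miss_snp <- if (length(snp)) rowMeans(is.na(G$a1[, snp, drop = FALSE])) else
    rep(0, length(keys))
  miss_ms <- if (length(ms)) rowMeans(is.na(G$a1[, ms, drop = FALSE])) else
    rep(0, length(keys))
  drop <- miss_snp > thresholds$snp_sample_missingness |
          miss_ms > thresholds$ms_sample_missingness
  reason <- ifelse(miss_snp > thresholds$snp_sample_missingness,
                   "snp_missingness", "ms_missingness")
  value <- pmax(miss_snp, miss_ms)
  if (!is.null(pedigrees)) {
    for (p in pedigrees) {
      mc <- mendel_check(p, G)
      nt <- rowSums(mc$testable)
      fr <- ifelse(nt > 0, rowSums(mc$child_errors) / nt, 0)
      bad <- fr > thresholds$mendel_sample_fraction_max
      if (any(bad)) {
        k <- paste(p$pedigree_id, rownames(mc$child_errors)[bad], sep = ":")
        sel <- match(k, keys)
        reason[sel][!drop[sel]] <- "mendel"
        value[sel][!drop[sel]] <- fr[bad]
        drop[sel] <- TRUE
      }
    }
  }
  ## already fully-missing rows are not re-reported
  already <- rowMeans(is.na(G$a1)) == 1
  report <- drop & !already
  G$a1[drop, ] <- NA_integer_
  G$a2[drop, ] <- NA_integer_
  list(G = G, retained = keys[!drop],
       drop_log = data.frame(sample = keys[report],
                             reason = reason[report],
                             value = value[report],
                             stringsAsFactors = FALSE))
}

## Pearson r^2 of allele-dosage vectors (0/1/2 copies of the first allele)
## over founders; composite-genotype LD, no phasing.
dosage_matrix <- function(G, map, fkeys, markers) {
  sapply(markers, function(nm) {
    j <- match(nm, map$name)
    ref <- map$alleles[[j]][1] %||% 1L
    (G$a1[fkeys, nm] == ref) + (G$a2[fkeys, nm] == ref)
  })
}

#' LD thinning of the SNP map
#'
#' Greedy left-to-right pass per chromosome over founder allele dosages: a
#' SNP is dropped when its squared Pearson correlation with any already
#' retained SNP within a window of \code{window} map positions exceeds
#' \code{r2_max}. Microsatellites are never dropped.
#'
#' @param G \code{genotypes} object.
#' @param map \code{genetic_map} (restricted to currently retained markers).
#' @param r2_max Maximum tolerated r-squared (default 0.20).
#' @param pedigrees List of pedigrees (founders define the dosage rows).
#' @param window Window size in marker positions (default 50).
#' @return Character vector of retained marker names (SNPs that survive
#'   plus all MS markers), in map order.
#' @export
ld_thin <- function(G, map, r2_max = 0.20, pedigrees, window = 50L) {
  fkeys <- unlist(lapply(pedigrees, function(p) ped_key(p)[is_founder(p)]))
  fkeys <- intersect(fkeys, rownames(G$a1))
  keep <- rep(TRUE, nrow(map))
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr & map$type == "SNP")
    if (length(idx) < 2) next
    dos <- dosage_matrix(G, map, fkeys, map$name[idx])
    kept <- integer()
    for (ii in seq_along(idx)) {
      inwin <- kept[idx[kept] >= idx[ii] - window]
      dropit <- FALSE
      for (jj in inwin) {
        r <- suppressWarnings(
          stats::cor(dos[, ii], dos[, jj], use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2_max) { dropit <- TRUE; break }
      }
      if (dropit) keep[idx[ii]] <- FALSE else kept <- c(kept, ii)
    }
  }
  map$name[keep]
}

#' Full genotype-cleaning pipeline
#'
#' Applies, in order: marker missingness, sample missingness, Mendelian
#' errors (markers with more than \code{mendel_marker_max} errors dropped;
#' high-error samples masked; for retained markers the offending nuclear
#' family's genotypes at that marker are set missing), Hardy-Weinberg
#' filtering, and LD thinning. Marker missingness is computed over samples
#' that are not fully missing, which makes the pipeline idempotent.
#'
#' @inheritParams filter_markers
#' @param ld_window Window passed to [ld_thin()].
#' @return List with cleaned \code{G}, filtered \code{map}, retained sample
#'   keys, and \code{marker_log} / \code{sample_log} drop logs.
#' @export
qc_pipeline <- function(pedigrees, G, map, thresholds = qc_thresholds(),
                        ld_window = 50L) {
  ## 1. marker missingness
  full_miss <- rowMeans(is.na(G$a1)) == 1
  mm <- filter_markers(G, map, thresholds, pedigrees = NULL,
                       samples = rownames(G$a1)[!full_miss])
  map2 <- map[map$name %in% mm$retained, , drop = FALSE]
  marker_log <- mm$drop_log
  ## 2. sample missingness + mendel-sample masking
  Gm <- G
  Gm$a1 <- Gm$a1[, map2$name, drop = FALSE]
  Gm$a2 <- Gm$a2[, map2$name, drop = FALSE]
  fs <- filter_samples(Gm, map2, thresholds, pedigrees)
  Gm <- fs$G
  ## 3. Mendel by marker: drop markers, blank offending families elsewhere
  mend_total <- setNames(rep(0, nrow(map2)), map2$name)
  for (p in pedigrees) {
    mc <- mendel_check(p, Gm)
    cnt <- colSums(mc$family_counts)
    mend_total <- mend_total + cnt
  }
  mend_drop <- mend_total > thresholds$mendel_marker_max
  for (nm in names(mend_drop)[mend_drop])
    marker_log[nrow(marker_log) + 1L, ] <- list(nm, "mendel", mend_total[nm])
  map3 <- map2[!mend_drop, , drop = FALSE]
  Gm$a1 <- Gm$a1[, map3$name, drop = FALSE]
  Gm$a2 <- Gm$a2[, map3$name, drop = FALSE]
  for (p in pedigrees) {
    mc <- mendel_check(p, Gm)
    bad <- which(mc$family_counts > 0, arr.ind = TRUE)
    if (nrow(bad)) {
      for (r in seq_len(nrow(bad))) {
        f <- mc$families[[bad[r, 1]]]
        ks <- paste(p$pedigree_id, c(f$father, f$mother, f$children),
                    sep = ":")
        Gm$a1[ks, bad[r, 2]] <- NA_integer_
        Gm$a2[ks, bad[r, 2]] <- NA_integer_
      }
    }
  }
  ## 4. HWE on founders
  plim <- ifelse(map3$type == "SNP", thresholds$hwe_p_snp,
                 thresholds$hwe_p_ms)
  hwe_drop <- rep(FALSE, nrow(map3))
  for (j in seq_len(nrow(map3))) {
    pv <- hwe_test(founder_genotype_counts(pedigrees, Gm, map3$name[j]))
    if (pv < plim[j]) {
      hwe_drop[j] <- TRUE
      marker_log[nrow(marker_log) + 1L, ] <- list(map3$name[j], "hwe", pv)
    }
  }
  map4 <- map3[!hwe_drop, , drop = FALSE]
  Gm$a1 <- Gm$a1[, map4$name, drop = FALSE]
  Gm$a2 <- Gm$a2[, map4$name, drop = FALSE]
  ## 5. LD thinning
  kept <- ld_thin(Gm, map4, thresholds$ld_r2, pedigrees, ld_window)
  for (nm in setdiff(map4$name, kept))
    marker_log[nrow(marker_log) + 1L, ] <- list(nm, "ld", NA_real_)
  map5 <- map4[map4$name %in% kept, , drop = FALSE]
  Gm$a1 <- Gm$a1[, map5$name, drop = FALSE]
  Gm$a2 <- Gm$a2[, map5$name, drop = FALSE]
  list(G = Gm, map = map5, retained_samples = fs$retained,
       marker_log = marker_log, sample_log = fs$drop_log)
}
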