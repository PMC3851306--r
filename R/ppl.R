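#' Prior specification for PPL integration
#'
#' Trait parameters, the recombination fraction theta and Smith's admixture
#' parameter alpha are integrated out of the Bayes ratio over finite grids
#' with equal prior weight on every admissible grid point ("essentially
#' uniform" priors; ordering constraints restrict the penetrance / mean
#' grids to their admissible simplex). Quantitative-trait grids live on the
#' standardized trait scale, hence the finite ranges.
#'
#' @param pi Prior probability of linkage at any one position (default
#'   0.02).
#' @param theta Recombination-fraction grid in [0, 0.5].
#' @param alpha Admixture grid in (0, 1].
#' @param dt_p,qt_p Disease-allele-frequency grids.
#' @param penetrance_step Step of the DT penetrance grid on [0, 1]; grid
#'   points are all ordered triples f_DD >= f_Dd >= f_dd.
#' @param qt_means Grid for genotypic means; grid points are ordered triples
#'   mu_DD >= mu_Dd >= mu_dd.
#' @param qt_sds Grid for the (common) genotypic standard deviation.
#' @param qtt_thresholds Grid for the QTT threshold.
#' @return A list of class \code{prior_spec}.
#' @export
prior_spec <- function(pi = 0.02,
                       theta = seq(0, 0.5, by = 0.05),
                       alpha = seq(0.1, 1, by = 0.1),
                       dt_p = c(0.001, 0.01, 0.1, 0.3, 0.5),
                       penetrance_step = 0.1,
                       qt_means = seq(-3, 3, by = 0.5),
                       qt_sds = c(0.3, 0.5, 1, 2),
                       qt_p = dt_p,
                       qtt_thresholds = seq(0, 2.5, by = 0.5)) {
  stopifnot(pi > 0, pi < 1, all(theta >= 0), all(theta <= 0.5),
            all(alpha > 0), all(alpha <= 1),
            all(dt_p > 0), all(dt_p < 1), all(qt_p > 0), all(qt_p < 1),
            penetrance_step > 0, penetrance_step <= 1, all(qt_sds > 0))
  structure(list(pi = pi, theta = theta, alpha = alpha, dt_p = dt_p,
                 penetrance_step = penetrance_step, qt_means = qt_means,
                 qt_sds = qt_sds, qt_p = qt_p,
                 qtt_thresholds = qtt_thresholds),
            class = "prior_spec")
}

## all ordered (non-increasing) triples from a value grid
ordered_triples <- function(values) {
  v <- sort(unique(values), decreasing = TRUE)
  out <- expand.grid(a = v, b = v, c = v)
  out <- out[out$a >= out$b & out$b >= out$c, , drop = FALSE]
  t(as.matrix(out))  # 3 x M, rows (high, het, low)
}

## model batch spanning the full prior grid for one trait kind
trait_grid <- function(priors, kind) {
  if (kind == "DT") {
    pen <- ordered_triples(seq(0, 1, by = priors$penetrance_step))
    M <- ncol(pen)
    p <- rep(priors$dt_p, each = M)
    return(model_batch("DT", p,
                       pen = pen[, rep(seq_len(M), length(priors$dt_p)),
                                 drop = FALSE]))
  }
  mu <- ordered_triples(priors$qt_means)
  M <- ncol(mu)
  grid <- expand.grid(m = seq_len(M), s = priors$qt_sds, p = priors$qt_p)
  if (kind == "QTT")
    grid <- expand.grid(m = seq_len(M), s = priors$qt_sds, p = priors$qt_p,
                        t = priors$qtt_thresholds)
  mu_big <- mu[, grid$m, drop = FALSE]
  sd_big <- matrix(rep(grid$s, each = 3), 3)
  if (kind == "QT")
    return(model_batch("QT", grid$p, mu = mu_big, sd = sd_big))
  model_batch("QTT", grid$p, mu = mu_big, sd = sd_big,
              threshold = grid$t)
}

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

## log Bayes-ratio surface for one pedigree at one marker:
## M x length(priors$theta) matrix of log[L(g, theta) / L(g, 0.5)].
## Grid points where both likelihoods are zero (model impossible under
## linkage and non-linkage alike) contribute no evidence: log-ratio 0.
pedigree_logR <- function(ped, G, map, marker, trait, priors, batch) {
  g <- pedigree_marker_genotypes(ped, G, marker)
  if (all(is.na(g$a1)))  # marker untyped in this pedigree: L(theta)=L(0.5)
    return(matrix(0, batch$M, length(priors$theta)))
  thetas <- c(priors$theta, 0.5)
  ll <- peel_logliks(ped, G, map, marker, trait, batch, thetas)
  denom <- ll[, length(thetas)]
  if (all(is.infinite(denom) & denom < 0))
    stop("inconsistent data: zero likelihood for pedigree ",
         ped$pedigree_id, " at marker ", marker, " over the whole grid")
  logR <- ll[, seq_along(priors$theta), drop = FALSE] - denom
  logR[is.nan(logR)] <- 0
  logR[is.infinite(denom) & denom < 0, ] <- 0
  logR
}

#' Per-pedigree Bayes ratio
#'
#' Integrates the admixture likelihood ratio
#' \eqn{[\alpha L(g, \theta) + (1 - \alpha) L(g, 0.5)] / L(g, 0.5)} over the
#' prior grids of trait parameters g, recombination fraction theta, and
#' admixture alpha, by equal-weight summation. Trait-model factors common to
#' numerator and denominator cancel in the ratio.
#'
#' @param ped A \code{pedigree}.
#' @param G \code{genotypes} object.
#' @param map \code{genetic_map} with allele frequencies.
#' @param marker Marker name.
#' @param trait A \code{trait_coding}.
#' @param priors A [prior_spec()].
#' @return The Bayes ratio (natural scale), with attribute \code{log_br}.
#' @export
pedigree_br <- function(ped, G, map, marker, trait, priors = prior_spec()) {
  batch <- trait_grid(priors, trait$kind)
  logR <- pedigree_logR(ped, G, map, marker, trait, priors, batch)
  br_from_logR(list(logR), priors)$seq
}

## Pooled and sequential log Bayes ratios from per-pedigree logR matrices.
## Sequential: BR_i = mean_{g,theta,alpha} [alpha R_i + (1 - alpha)], then
## BR_seq = prod_i BR_i. Pooled: one shared draw of (g, theta, alpha) for
## all pedigrees, BR_pool = mean_{g,theta,alpha} prod_i [alpha R_i + 1-alpha].
br_from_logR <- function(logR_list, priors) {
  la <- log(priors$alpha)
  l1a <- ifelse(priors$alpha < 1, log(1 - priors$alpha), -Inf)
  per_ped <- vapply(logR_list, function(logR) {
    terms <- vapply(seq_along(la), function(ai)
      logmeanexp(logaddexp(la[ai] + as.numeric(logR),
                           rep(l1a[ai], length(logR)))), 0)
    logmeanexp(terms)
  }, 0)
  log_seq <- sum(per_ped)
  ## pooled: sum logaddexp across pedigrees per (g, theta), then per alpha
  pooled_terms <- vapply(seq_along(la), function(ai) {
    tot <- 0
    for (logR in logR_list)
      tot <- tot + logaddexp(la[ai] + as.numeric(logR),
                             rep(l1a[ai], length(logR)))
    logmeanexp(tot)
  }, 0)
  log_pool <- logmeanexp(pooled_terms)
  list(seq = structure(exp(log_seq), log_br = log_seq, per_ped = per_ped),
       pool = structure(exp(log_pool), log_br = log_pool))
}

#' Pooled Bayes ratio across pedigrees
#'
#' Trait parameters, theta and alpha are integrated across all pedigrees as
#' a set: one shared draw of (g, alpha, theta) multiplies the per-pedigree
#' admixture likelihood ratios before averaging over the grid.
#'
#' @param pedigrees List of pedigrees.
#' @inheritParams pedigree_br
#' @return The pooled Bayes ratio, with attribute \code{log_br}.
#' @export
pooled_br <- function(pedigrees, G, map, marker, trait,
                      priors = prior_spec()) {
  batch <- trait_grid(priors, trait$kind)
  logRs <- lapply(pedigrees, pedigree_logR, G = G, map = map,
                  marker = marker, trait = trait, priors = priors,
                  batch = batch)
  br_from_logR(logRs, priors)$pool
}

#' Sequential (product) Bayes ratio
#'
#' Bayesian sequential updating across pedigrees: the marginal evidence for
#' or against linkage is accumulated as the product of per-pedigree Bayes
#' ratios, computed in log space. Order-invariant; for a single pedigree it
#' equals both the per-pedigree and the pooled Bayes ratio.
#'
#' @param brs Numeric vector of per-pedigree Bayes ratios.
#' @return The product, with attribute \code{log_br}.
#' @export
sequential_br <- function(brs) {
  stopifnot(all(brs > 0))
  lb <- sum(log(brs))
  structure(exp(lb), log_br = lb)
}

#' Posterior probability of linkage from a Bayes ratio
#'
#' \eqn{PPL = \pi BR / (\pi BR + 1 - \pi)}: the posterior probability of a
#' trait locus at the position, given prior probability \code{pi} of
#' linkage to any one position. \code{BR = 1} returns exactly \code{pi}
#' (the no-evidence point); PPL above \code{pi} is evidence for, below
#' \code{pi} evidence against, the position.
#'
#' @param br Bayes ratio(s), positive.
#' @param pi Prior probability of linkage (default 0.02).
#' @return PPL value(s) in (0, 1).
#' @export
ppl_from_br <- function(br, pi = 0.02) {
  stopifnot(all(br > 0), pi > 0, pi < 1)
  pi * br / (pi * br + 1 - pi)
}

## stable version for extreme Bayes ratios
ppl_from_logbr <- function(log_br, pi = 0.02) {
  stats::plogis(log(pi) - log1p(-pi) + log_br)
}

#' Two-point PPL genome scan
#'
#' Computes, at every marker of the map, per-pedigree Bayes ratios and their
#' pooled and sequential aggregates, and converts them to posterior
#' probabilities of linkage. Positions are the retained marker positions
#' (exact two-point analysis per marker). No multiple-testing correction is
#' applied to the PPL.
#'
#' @param pedigrees List of pedigrees.
#' @param G \code{genotypes} object (after QC).
#' @param map \code{genetic_map} with allele frequencies, QC-filtered.
#' @param trait A \code{trait_coding}.
#' @param priors A [prior_spec()].
#' @param mode \code{"pooled"}, \code{"sequential"}, or \code{"both"}.
#' @return A data frame of class \code{linkage_result}: one row per marker
#'   with \code{chrom}, \code{cM}, \code{marker}, per-pedigree columns
#'   \code{BR_<pedigree>}, \code{BR_pooled}, \code{BR_seq},
#'   \code{PPL_pooled}, \code{PPL_seq}. The fraction of positions with
#'   PPL below the prior (evidence against linkage) is attached as
#'   attribute \code{frac_against} per mode.
#' @export
genome_scan <- function(pedigrees, G, map, trait, priors = prior_spec(),
                        mode = c("both", "pooled", "sequential")) {
  mode <- match.arg(mode)
  batch <- trait_grid(priors, trait$kind)
  pid <- vapply(pedigrees, `[[`, "", "pedigree_id")
  rows <- vector("list", nrow(map))
  for (j in seq_len(nrow(map))) {
    logRs <- lapply(pedigrees, pedigree_logR, G = G, map = map,
                    marker = map$name[j], trait = trait, priors = priors,
                    batch = batch)
    br <- br_from_logR(logRs, priors)
    per <- exp(attr(br$seq, "per_ped"))
    row <- data.frame(chrom = map$chrom[j], cM = map$cM[j],
                      marker = map$name[j], stringsAsFactors = FALSE)
    for (i in seq_along(pid)) row[[paste0("BR_", pid[i])]] <- per[i]
    row$BR_pooled <- as.numeric(br$pool)
    row$BR_seq <- as.numeric(br$seq)
    row$PPL_pooled <- ppl_from_logbr(attr(br$pool, "log_br"), priors$pi)
    row$PPL_seq <- ppl_from_logbr(attr(br$seq, "log_br"), priors$pi)
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), cM = numeric(),
                      marker = character(), BR_pooled = numeric(),
                      BR_seq = numeric(), PPL_pooled = numeric(),
                      PPL_seq = numeric(), stringsAsFactors = FALSE)
  if (mode == "pooled") out$BR_seq <- out$PPL_seq <- NULL
  if (mode == "sequential") out$BR_pooled <- out$PPL_pooled <- NULL
  attr(out, "pi") <- priors$pi
  attr(out, "frac_against") <- c(
    pooled = if (!is.null(out$PPL_pooled))
      mean(out$PPL_pooled < priors$pi) else NA_real_,
    sequential = if (!is.null(out$PPL_seq))
      mean(out$PPL_seq < priors$pi) else NA_real_)
  class(out) <- c("linkage_result", "data.frame")
  out
}

#' Plot a PPL genome scan
#'
#' One track per chromosome, PPL against map position, y-axis fixed to
#' [0, 0.5]; the prior is drawn as a dashed reference line. Written as PNG.
#'
#' @param results A \code{linkage_result}.
#' @param path Output PNG path.
#' @param width,height,res Device settings passed to [grDevices::png()].
#' @return \code{path}, invisibly.
#' @export
plot_scan <- function(results, path, width = 1200, height = 400, res = 96) {
  if (!nrow(results)) stop("empty scan: nothing to plot")
  pi0 <- attr(results, "pi") %||% 0.02
  chroms <- unique(results$chrom)
  grDevices::png(path, width = width, height = max(height,
                 220 * length(chroms)), res = res)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(chroms), 1), mar = c(4, 4, 2, 1))
  for (ch in chroms) {
    sub <- results[results$chrom == ch, ]
    graphics::plot(sub$cM, sub$PPL_seq %||% sub$PPL_pooled, type = "o",
                   pch = 16, cex = 0.6, ylim = c(0, 0.5),
                   xlab = "position (cM)", ylab = "PPL",
                   main = paste("chromosome", ch))
    if (!is.null(sub$PPL_pooled) && !is.null(sub$PPL_seq))
      graphics::lines(sub$cM, sub$PPL_pooled, type = "o", pch = 1,
                      cex = 0.6, lty = 2, col = "grey40")
    graphics::abline(h = pi0, lty = 3)
  }
  invisible(path)
}
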