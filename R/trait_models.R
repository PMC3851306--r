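#' Trait models for parametric linkage
#'
#' A diallelic trait locus with disease allele D (frequency \code{p}) and
#' wild-type allele d. Genotypes are ordered DD, Dd, dd.
#'
#' \code{trait_model_dt} is the dichotomous-trait model with penetrance
#' vector \code{f} = (f_DD, f_Dd, f_dd), the probability that a carrier of
#' each genotype is affected, under the ordering constraint
#' f_DD >= f_Dd >= f_dd (the D allele never decreases risk; the model class
#' is symmetric under allele relabelling).
#'
#' \code{trait_model_qt} replaces the penetrances with three genotypic means
#' and three genotypic standard deviations on the standardized trait scale;
#' normality is assumed within genotype, not at the population level.
#' Ordering constraint: mu_DD >= mu_Dd >= mu_dd.
#'
#' \code{trait_model_qtt} extends the QT model with a threshold \code{t}:
#' individuals without a measured value may be declared over (or under) the
#' threshold, contributing the corresponding normal tail probability.
#'
#' @param p Disease allele frequency in (0, 1).
#' @param f Penetrance vector, length 3, each in [0, 1].
#' @param mu Genotypic means, length 3.
#' @param sd Genotypic standard deviations, length 3 (or scalar, recycled).
#' @param threshold Threshold on the standardized trait scale.
#' @return A list of class \code{trait_model} with element \code{kind}.
#' @export
trait_model_dt <- function(p, f) {
  stopifnot(p > 0, p < 1, length(f) == 3, all(f >= 0), all(f <= 1),
            f[1] >= f[2], f[2] >= f[3])
  structure(list(kind = "DT", p = p, f = as.numeric(f)),
            class = "trait_model")
}

#' @rdname trait_model_dt
#' @export
trait_model_qt <- function(p, mu, sd) {
  sd <- rep(as.numeric(sd), length.out = 3)
  stopifnot(p > 0, p < 1, length(mu) == 3, mu[1] >= mu[2], mu[2] >= mu[3],
            all(sd > 0))
  structure(list(kind = "QT", p = p, mu = as.numeric(mu), sd = sd),
            class = "trait_model")
}

#' @rdname trait_model_dt
#' @export
trait_model_qtt <- function(p, mu, sd, threshold) {
  m <- trait_model_qt(p, mu, sd)
  m$kind <- "QTT"
  m$threshold <- as.numeric(threshold)
  m
}

#' Linked model: trait model plus recombination and admixture
#'
#' @param trait A \code{trait_model}.
#' @param theta Recombination fraction in [0, 0.5]; 0.5 makes the marker
#'   uninformative for the trait.
#' @param alpha Smith's admixture parameter in [0, 1]: the proportion of
#'   linked pedigrees; 0 forces the unlinked likelihood.
#' @return A list of class \code{linked_model}.
#' @export
linked_model <- function(trait, theta, alpha = 1) {
  stopifnot(inherits(trait, "trait_model"),
            theta >= 0, theta <= 0.5, alpha >= 0, alpha <= 1)
  structure(list(trait = trait, theta = theta, alpha = alpha),
            class = "linked_model")
}

#' Founder genotype prior under Hardy-Weinberg equilibrium
#'
#' For a locus with allele frequencies \code{freqs}, the HWE probability of
#' an unordered genotype: \eqn{q_i^2} for homozygotes, \eqn{2 q_i q_j} for
#' heterozygotes. Two-locus founder priors are products of the single-locus
#' priors (linkage equilibrium).
#'
#' @param freqs Numeric simplex of allele frequencies.
#' @param genotype Integer pair of allele indices (unordered), or
#'   \code{NULL} to return the full vector over unordered genotypes in
#'   row-major lower-triangle order with names \code{"i/j"}.
#' @return Probability (or named vector of probabilities).
#' @export
founder_prior <- function(freqs, genotype = NULL) {
  stopifnot(abs(sum(freqs) - 1) < 1e-9, all(freqs >= 0))
  if (!is.null(genotype)) {
    i <- genotype[1]; j <- genotype[2]
    return(if (i == j) freqs[i]^2 else 2 * freqs[i] * freqs[j])
  }
  k <- length(freqs)
  out <- c()
  for (i in seq_len(k)) for (j in i:k)
    out[paste(i, j, sep = "/")] <- if (i == j) freqs[i]^2 else
      2 * freqs[i] * freqs[j]
  out
}

#' Two-locus transmission probability
#'
#' Probability that a parent with a known-phase two-locus genotype transmits
#' a given trait-marker haplotype, with recombination fraction \code{theta}.
#' The parent's genotype is given as two haplotypes; when phase is unknown,
#' callers marginalize uniformly over the two phase assignments (the
#' likelihood engine does this implicitly by working with ordered
#' genotypes).
#'
#' @param hap1,hap2 Parental haplotypes, each \code{c(trait_allele,
#'   marker_allele)}.
#' @param theta Recombination fraction in [0, 0.5].
#' @param transmitted Haplotype \code{c(trait_allele, marker_allele)} whose
#'   transmission probability is wanted.
#' @return Probability.
#' @export
transmission_prob <- function(hap1, hap2, theta, transmitted) {
  stopifnot(theta >= 0, theta <= 0.5)
  haps <- list(hap1, hap2)
  p <- 0
  for (i in 1:2) for (j in 1:2) {
    w <- if (i == j) (1 - theta) / 2 else theta / 2
    if (haps[[i]][1] == transmitted[1] && haps[[j]][2] == transmitted[2])
      p <- p + w
  }
  p
}

#' Trait penetrance factor
#'
#' Likelihood contribution of one individual's phenotype given a trait
#' genotype, under one of the three trait models.
#'
#' DT: \code{f_g} if affected, \code{1 - f_g} if unaffected, 1 if unknown.
#' QT: normal density of the observed value under (mu_g, sd_g); 1 if
#' missing. QTT: the density if a value is observed; the upper-tail
#' probability beyond the threshold for over-threshold individuals; the
#' lower tail for explicitly under-threshold individuals; 1 if unknown.
#'
#' @param phenotype For DT one of \code{"affected"/"unaffected"/"unknown"};
#'   for QT a numeric value or NA; for QTT a list \code{list(value =,
#'   censor =)} with censor one of \code{"valued"/"over"/"under"/"unknown"}.
#' @param genotype Trait genotype index: 1 = DD, 2 = Dd, 3 = dd.
#' @param model A \code{trait_model}.
#' @return Likelihood factor.
#' @export
trait_penetrance <- function(phenotype, genotype, model) {
  g <- as.integer(genotype)
  stopifnot(g %in% 1:3)
  switch(model$kind,
    DT = switch(phenotype,
                affected = model$f[g],
                unaffected = 1 - model$f[g],
                unknown = 1,
                stop("bad DT phenotype")),
    QT = if (is.na(phenotype)) 1 else
      stats::dnorm(phenotype, model$mu[g], model$sd[g]),
    QTT = switch(phenotype$censor,
                 valued = stats::dnorm(phenotype$value, model$mu[g],
                                       model$sd[g]),
                 over = stats::pnorm(model$threshold, model$mu[g],
                                     model$sd[g], lower.tail = FALSE),
                 under = stats::pnorm(model$threshold, model$mu[g],
                                      model$sd[g]),
                 unknown = 1,
                 stop("bad QTT censor")))
}

#' Admixture (heterogeneity) likelihood
#'
#' Smith's admixture model: a pedigree is linked with probability
#' \code{alpha}, so its likelihood is
#' \eqn{\alpha L(\theta) + (1 - \alpha) L(\theta = 0.5)}, computed per
#' pedigree.
#'
#' @param logL_theta Log-likelihood at the working recombination fraction.
#' @param logL_half Log-likelihood at theta = 0.5.
#' @param alpha Admixture proportion in [0, 1].
#' @return Log of the admixture likelihood.
#' @export
admixture_likelihood <- function(logL_theta, logL_half, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (alpha == 0) return(logL_half)
  if (alpha == 1) return(logL_theta)
  m <- pmax(logL_theta, logL_half)
  ifelse(is.finite(m),
         m + log(alpha * exp(logL_theta - m) +
                 (1 - alpha) * exp(logL_half - m)),
         m)
}
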