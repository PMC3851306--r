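## Independent oracles: brute-force two-locus pedigree likelihood by full
## enumeration of founder ordered genotypes and meiosis origins, an exact
## (conditional enumeration) Hardy-Weinberg test, and a naive-loop Bayes
## ratio quadrature. These deliberately share no code with the package's
## peeling / integration paths.

## trait penetrance for the oracle, mirroring the three model definitions
oracle_pen <- function(id, gcl, trait, model) {
  if (is.null(trait)) return(rep(1, length(gcl)))
  key <- trait$.keys[id]
  if (model$kind == "DT") {
    aff <- trait$affection[key]
    if (is.na(aff) || aff == "unknown") return(rep(1, length(gcl)))
    if (aff == "affected") return(model$f[gcl])
    return(1 - model$f[gcl])
  }
  if (model$kind == "QT") {
    v <- trait$value[key]
    if (is.na(v)) return(rep(1, length(gcl)))
    return(stats::dnorm(v, model$mu[gcl], model$sd[gcl]))
  }
  cens <- trait$censor[key]
  if (is.na(cens) || cens == "unknown") return(rep(1, length(gcl)))
  switch(cens,
    valued = stats::dnorm(trait$value[key], model$mu[gcl], model$sd[gcl]),
    over = stats::pnorm(model$threshold, model$mu[gcl], model$sd[gcl],
                        lower.tail = FALSE),
    under = stats::pnorm(model$threshold, model$mu[gcl], model$sd[gcl]))
}

## Full-enumeration likelihood. Configurations are founder ordered two-locus
## genotypes and, per meiosis, the grandparental origin of the trait and
## marker alleles; probability = founder HWE priors x origin probabilities
## ((1-theta)/2 or theta/2) x penetrances x marker indicators. Zero-weight
## configurations are pruned incrementally.
## Returns NA when the enumeration exceeds max_rows configurations (the
## caller redraws its random scenario): a complexity bail-out, independent
## of the likelihood value.
bf_loglik <- function(ped, ga, gb, freqs, model, trait, theta,
                      max_rows = 2e6) {
  if (!is.null(trait))
    trait$.keys <- setNames(paste(ped$pedigree_id, ped$members$id, sep = ":"),
                            ped$members$id)
  m <- ped$members; n <- nrow(m); k <- length(freqs)
  p <- model$p
  depth <- setNames(rep(0, n), m$id)
  for (r in seq_len(n)) for (i in seq_len(n)) {
    pd <- 0
    if (!is.na(m$father[i])) pd <- max(pd, depth[m$father[i]] + 1)
    if (!is.na(m$mother[i])) pd <- max(pd, depth[m$mother[i]] + 1)
    depth[i] <- pd
  }
  topo <- order(depth)
  cfg <- matrix(0L, 1, n * 4); prob <- 1
  for (i in topo) {
    if (nrow(cfg) == 0) return(-Inf)  # all configurations pruned: L = 0
    ## bail before an expansion that could exceed the row budget even
    ## without pruning (each individual multiplies rows by up to 16)
    if (nrow(cfg) * 16 > max_rows) return(NA_real_)
    id <- m$id[i]
    if (is.na(m$father[i])) {
      st <- as.matrix(expand.grid(tp = 1:2, tm = 1:2, mp = 1:k, mm = 1:k))
      w <- c(p, 1 - p)[st[, 1]] * c(p, 1 - p)[st[, 2]] *
        freqs[st[, 3]] * freqs[st[, 4]]
    } else {
      st <- as.matrix(expand.grid(ft = 1:2, fm = 1:2, mt = 1:2, mq = 1:2))
      w <- ifelse(st[, 1] == st[, 2], (1 - theta) / 2, theta / 2) *
           ifelse(st[, 3] == st[, 4], (1 - theta) / 2, theta / 2)
    }
    ## expand in chunks of parent configurations to bound peak memory
    chunks <- split(seq_len(nrow(cfg)),
                    ceiling(seq_len(nrow(cfg)) / 200000))
    cfg_parts <- list(); prob_parts <- list()
    for (ch in chunks) {
      ncfg <- cfg[rep(ch, times = nrow(st)), , drop = FALSE]
      sel <- st[rep(seq_len(nrow(st)), each = length(ch)), , drop = FALSE]
      nprob <- rep(prob[ch], times = nrow(st)) * rep(w, each = length(ch))
      if (is.na(m$father[i])) {
        S4 <- sel
      } else {
        fi <- match(m$father[i], m$id); mi <- match(m$mother[i], m$id)
        fS <- ncfg[, (fi - 1) * 4 + 1:4, drop = FALSE]
        mS <- ncfg[, (mi - 1) * 4 + 1:4, drop = FALSE]
        S4 <- cbind(ifelse(sel[, 1] == 1, fS[, 1], fS[, 2]),
                    ifelse(sel[, 3] == 1, mS[, 1], mS[, 2]),
                    ifelse(sel[, 2] == 1, fS[, 3], fS[, 4]),
                    ifelse(sel[, 4] == 1, mS[, 3], mS[, 4]))
      }
      ncfg[, (i - 1) * 4 + 1:4] <- S4
      gcl <- c(1, 2, 2, 3)[(S4[, 1] - 1) * 2 + S4[, 2]]
      a <- ga[id]; b <- gb[id]
      pen_i <- oracle_pen(id, gcl, trait, model)
      ind <- if (is.na(a)) 1 else
        as.numeric((S4[, 3] == a & S4[, 4] == b) |
                   (S4[, 3] == b & S4[, 4] == a))
      nprob <- nprob * pen_i * ind
      keep <- nprob > 0
      cfg_parts[[length(cfg_parts) + 1L]] <- ncfg[keep, , drop = FALSE]
      prob_parts[[length(prob_parts) + 1L]] <- nprob[keep]
    }
    cfg <- do.call(rbind, cfg_parts)
    prob <- unlist(prob_parts, use.names = FALSE)
  }
  log(sum(prob))
}

## convenience wrapper matching peel_likelihood's interface for one marker
bf_peel <- function(ped, G, map, marker, trait, model, theta,
                    max_rows = 2e6) {
  keys <- paste(ped$pedigree_id, ped$members$id, sep = ":")
  ga <- setNames(G$a1[keys, marker], ped$members$id)
  gb <- setNames(G$a2[keys, marker], ped$members$id)
  bf_loglik(ped, ga, gb, map$freqs[[match(marker, map$name)]],
            model, trait, theta, max_rows = max_rows)
}

## Exact conditional Hardy-Weinberg test for a diallelic marker
## (enumeration over heterozygote counts given n and the allele count).
exact_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa; nA <- 2 * nAA + nAa
  if (n == 0 || nA == 0 || nA == 2 * n) return(1)
  het <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(het, function(h) {
    a <- (nA - h) / 2; b <- n - a - h
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
      lfactorial(2 * n)
  }, 0)
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, het)] + 1e-12])
}

## Naive-loop Bayes ratio: explicit iteration over every grid point with
## brute-force likelihoods; independent of the vectorized integration and
## of the peeler.
oracle_br_dt <- function(ped, G, map, marker, trait, priors) {
  pen_vals <- seq(0, 1, by = priors$penetrance_step)
  ratios <- c()
  for (p in priors$dt_p)
    for (f1 in pen_vals) for (f2 in pen_vals) for (f3 in pen_vals) {
      if (!(f1 >= f2 && f2 >= f3)) next
      model <- trait_model_dt(p, c(f1, f2, f3))
      l_half <- bf_peel(ped, G, map, marker, trait, model, 0.5)
      for (th in priors$theta) {
        l_th <- bf_peel(ped, G, map, marker, trait, model, th)
        ## grid points impossible under both hypotheses carry no evidence
        ratios <- c(ratios, if (is.infinite(l_half)) 1 else
          exp(l_th - l_half))
      }
    }
  terms <- c()
  for (al in priors$alpha)
    terms <- c(terms, al * ratios + (1 - al))
  mean(terms)
}
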