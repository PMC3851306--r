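## Exact two-locus (trait x marker) pedigree likelihoods by Elston-Stewart
## peeling over nuclear families.
##
## State space per individual: ordered two-locus genotypes
##   s = (trait paternal allele, trait maternal allele,
##        marker paternal allele, marker maternal allele),
## i.e. 4 * k^2 states for a k-allele marker. Ordered genotypes make phase
## explicit, so uniform phase marginalization is automatic through the HWE
## founder prior and Mendelian transmission. Messages between nuclear
## families are S x M matrices (states x trait-model grid points), so the
## whole trait-parameter grid is peeled in one vectorized pass per theta.
## Per-message rescaling keeps 30-member pedigrees in double range; all
## results are returned in log space.

## ---- model batches -------------------------------------------------------

## A model batch holds M trait models column-wise for vectorized peeling.
model_batch <- function(kind, p, pen = NULL, mu = NULL, sd = NULL,
                        threshold = NULL) {
  M <- length(p)
  b <- list(kind = kind, M = M, p = as.numeric(p))
  if (kind == "DT") {
    stopifnot(ncol(pen) == M)
    b$pen <- pen
  } else {
    stopifnot(ncol(mu) == M, ncol(sd) == M)
    b$mu <- mu; b$sd <- sd
    if (kind == "QTT") {
      stopifnot(length(threshold) == M)
      b$threshold <- as.numeric(threshold)
    }
  }
  b
}

batch_from_model <- function(model) {
  switch(model$kind,
    DT = model_batch("DT", model$p, pen = matrix(model$f, 3, 1)),
    QT = model_batch("QT", model$p, mu = matrix(model$mu, 3, 1),
                     sd = matrix(model$sd, 3, 1)),
    QTT = model_batch("QTT", model$p, mu = matrix(model$mu, 3, 1),
                      sd = matrix(model$sd, 3, 1),
                      threshold = model$threshold))
}

## 3 x M penetrance factors for one individual under every model in a batch
penetrance_columns <- function(batch, trait, key) {
  M <- batch$M
  ones <- matrix(1, 3, M)
  if (is.null(trait)) return(ones)
  if (batch$kind == "DT") {
    aff <- trait$affection[key]
    if (is.na(aff) || aff == "unknown") return(ones)
    if (aff == "affected") return(batch$pen)
    return(1 - batch$pen)
  }
  if (batch$kind == "QT") {
    v <- trait$value[key]
    if (is.null(v) || is.na(v)) return(ones)
    return(matrix(stats::dnorm(v, batch$mu, batch$sd), 3, M))
  }
  ## QTT
  cens <- trait$censor[key]
  if (is.na(cens) || cens == "unknown") return(ones)
  thr <- rep(batch$threshold, each = 3)
  switch(cens,
    valued = matrix(stats::dnorm(trait$value[key], batch$mu, batch$sd),
                    3, M),
    over = matrix(stats::pnorm(thr, batch$mu, batch$sd,
                               lower.tail = FALSE), 3, M),
    under = matrix(stats::pnorm(thr, batch$mu, batch$sd), 3, M))
}

## ---- marker preparation --------------------------------------------------

## Restrict a marker's allele set to alleles observed in the pedigree plus a
## lumped "other" allele carrying the residual frequency. Standard allele
## lumping: leaves the likelihood unchanged while keeping the state space
## small for multi-allelic microsatellites.
lump_marker <- function(alleles, freqs, obs_labels) {
  obs <- sort(unique(obs_labels[!is.na(obs_labels)]))
  if (!length(obs)) {
    ## untyped in this pedigree: a single pooled allele suffices
    return(list(labels = alleles[1], freqs = 1, k = 1L))
  }
  sel <- match(obs, alleles)
  if (anyNA(sel)) stop("observed allele not in marker allele set")
  fr <- freqs[sel]
  resid <- 1 - sum(fr)
  if (resid > 1e-12) {
    list(labels = c(obs, NA), freqs = c(fr, resid),
         k = length(obs) + 1L)
  } else {
    list(labels = obs, freqs = fr / sum(fr), k = length(obs))
  }
}

## ---- the peeler ----------------------------------------------------------

## Two-locus transmission matrix: S x G, rows ordered joint genotypes,
## columns gametes g = (trait allele a, marker allele b) = (a-1)*k + b.
transmission_matrix <- function(k, theta) {
  K2 <- k * k; S <- 4L * K2; G <- 2L * k
  s <- seq_len(S)
  t_of <- (s - 1L) %/% K2 + 1L
  m_of <- (s - 1L) %% K2 + 1L
  tp <- (t_of - 1L) %/% 2L + 1L; tm <- (t_of - 1L) %% 2L + 1L
  mp <- (m_of - 1L) %/% k + 1L; mm <- (m_of - 1L) %% k + 1L
  Tm <- matrix(0, S, G)
  add <- function(a, b, w) {
    idx <- cbind(s, (a - 1L) * k + b)
    Tm[idx] <<- Tm[idx] + w
  }
  add(tp, mp, (1 - theta) / 2)   # trait and marker both from paternal strand
  add(tm, mm, (1 - theta) / 2)
  add(tp, mm, theta / 2)         # recombinant gametes
  add(tm, mp, theta / 2)
  Tm
}

## Core engine: log-likelihood of one pedigree at one marker for every
## model in `batch`, at recombination fraction theta.
##   ga, gb: named (by member id) lumped allele indices, NA = missing
##   freqs:  lumped marker allele frequencies
##   trait:  trait_coding (vectors named "<ped>:<id>") or NULL
##
## Genotype-set restriction: a typed individual's marker states are reduced
## to the (at most two) orderings of its observed genotype, so the joint
## state space is 4 x 2 for typed members and 4 x k^2 only for untyped
## ones. This is the first (non-iterated) step of Lange-Goradia set
## recoding; it leaves the likelihood unchanged because excluded states
## carry a zero marker indicator.
peel_engine <- function(ped, ga, gb, freqs, theta, batch, trait) {
  M <- batch$M
  k <- length(freqs)
  maxchunk <- max(1L, as.integer(4e6 / max(1, (4 * k * k)^2 / 8)))
  if (M > maxchunk) {
    parts <- split(seq_len(M), ceiling(seq_len(M) / maxchunk))
    return(unlist(lapply(parts, function(ii)
      peel_engine(ped, ga, gb, freqs, theta, subset_batch(batch, ii),
                  trait)), use.names = FALSE))
  }
  K2 <- k * k; G <- 2L * k
  ## full ordered-state bookkeeping (trait-major): s = (t-1)*K2 + m
  full_m <- seq_len(K2)
  full_mp <- (full_m - 1L) %/% k + 1L
  full_mm <- (full_m - 1L) %% k + 1L
  Tm <- transmission_matrix(k, theta)

  m <- ped$members
  keys <- ped_key(ped)
  n <- nrow(m)

  ## per-individual reduced state space
  tp4 <- c(1L, 1L, 2L, 2L); tm4 <- c(1L, 2L, 1L, 2L)
  gclass4 <- c(1L, 2L, 2L, 3L)
  prD <- rbind(batch$p^2, batch$p * (1 - batch$p),
               (1 - batch$p) * batch$p, (1 - batch$p)^2)  # 4 x M by (tp,tm)
  info <- vector("list", n); names(info) <- m$id
  for (i in seq_len(n)) {
    id <- m$id[i]
    a <- ga[[id]]; b <- gb[[id]]
    midx <- if (is.na(a)) full_m else
      which((full_mp == a & full_mm == b) | (full_mp == b & full_mm == a))
    nm <- length(midx)
    S <- 4L * nm
    t_of <- rep(1:4, each = nm)
    mrow <- rep(midx, times = 4L)
    srows <- (t_of - 1L) * K2 + mrow            # rows into full S x G tables
    pen <- penetrance_columns(batch, trait, keys[i])
    W <- pen[gclass4[t_of], , drop = FALSE]
    if (is.na(m$father[i])) {                   # founder: HWE prior
      pm <- freqs[full_mp[mrow]] * freqs[full_mm[mrow]]
      W <- W * prD[(tp4[t_of] - 1L) * 2L + tm4[t_of], , drop = FALSE] * pm
    }
    info[[id]] <- list(
      S = S,
      Tr = Tm[srows, , drop = FALSE],           # S x G transmission
      g1 = (tp4[t_of] - 1L) * k + full_mp[mrow],# paternal gamete per state
      g2 = (tm4[t_of] - 1L) * k + full_mm[mrow],
      W = W)
  }

  fams <- nuclear_families(ped)
  famof <- families_of(ped, fams)

  rescale <- function(v, lg) {
    mx <- apply(v, 2, max)
    sc <- ifelse(mx > 0, mx, 1)
    list(v = v / rep(sc, each = nrow(v)), lg = lg + log(sc))
  }

  collect <- function(id, excl) {
    v <- info[[id]]$W
    lg <- numeric(M)
    for (fi in setdiff(famof[[id]], excl)) {
      msg <- message_from(fi, id)
      v <- v * msg$v
      lg <- lg + msg$lg
    }
    rescale(v, lg)
  }

  ## childsum over one child: B[s_father, model, s_mother]
  childsum_arr <- function(cid, Wc, Tf, Tmo) {
    ic <- info[[cid]]
    Wg <- matrix(0, G * G, M)
    Wg[ic$g1 + (ic$g2 - 1L) * G, ] <- Wc$v
    dim(Wg) <- c(G, G * M)                    # [g1, (g2, mod)]
    A <- Tf %*% Wg                            # [s_f, (g2, mod)]
    Sf <- nrow(Tf); Sm <- nrow(Tmo)
    dim(A) <- c(Sf, G, M)
    A <- aperm(A, c(1, 3, 2))                 # [s_f, mod, g2]
    dim(A) <- c(Sf * M, G)
    B <- A %*% t(Tmo)                         # [(s_f, mod), s_m]
    dim(B) <- c(Sf, M, Sm)
    B
  }

  message_from <- function(fi, id) {
    f <- fams[[fi]]
    Tf <- info[[f$father]]$Tr
    Tmo <- info[[f$mother]]$Tr
    Sf <- nrow(Tf); Sm <- nrow(Tmo)
    to_parent <- id %in% c(f$father, f$mother)
    kids <- if (to_parent) f$children else setdiff(f$children, id)
    P <- NULL
    lg <- numeric(M)
    for (cid in kids) {
      Wc <- collect(cid, fi)
      B <- childsum_arr(cid, Wc, Tf, Tmo)
      P <- if (is.null(P)) B else P * B
      lg <- lg + Wc$lg
    }
    if (to_parent) {
      other <- if (id == f$father) f$mother else f$father
      Wo <- collect(other, fi)
      lg <- lg + Wo$lg
      if (id == f$father) {
        acc <- matrix(0, Sf, M)
        for (sm in seq_len(Sm))
          acc <- acc + (if (is.null(P)) 1 else P[, , sm]) *
            rep(Wo$v[sm, ], each = Sf)
      } else {
        acc <- matrix(0, Sm, M)
        for (sf in seq_len(Sf)) {
          slab <- if (is.null(P)) matrix(1, Sm, M) else
            t(matrix(P[sf, , ], M, Sm))
          acc <- acc + slab * rep(Wo$v[sf, ], each = Sm)
        }
      }
      return(rescale(acc, lg))
    }
    ## message to a child: contract both parents
    Wf <- collect(f$father, fi)
    Wm <- collect(f$mother, fi)
    lg <- lg + Wf$lg + Wm$lg
    A2 <- if (is.null(P)) array(1, c(Sf, M, Sm)) else P
    A2 <- A2 * array(Wf$v, c(Sf, M, Sm))
    A2 <- A2 * aperm(array(Wm$v, c(Sm, M, Sf)), c(3, 2, 1))
    E <- crossprod(Tf, matrix(A2, Sf, M * Sm)) # [g1, (mod, s_m)]
    dim(E) <- c(G * M, Sm)
    Fm <- E %*% Tmo                            # [(g1, mod), g2]
    ic <- info[[id]]
    idx <- outer(ic$g1 + (ic$g2 - 1L) * G * M, (seq_len(M) - 1L) * G, `+`)
    v <- matrix(Fm[idx], ic$S, M)
    rescale(v, lg)
  }

  ## peel every connected component of the individual/family graph
  ## (childless founders and multi-component pedigrees peel separately;
  ## their log-likelihoods add)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (f in fams) {
    mem <- match(unique(c(f$father, f$mother, f$children)), m$id)
    r0 <- find(mem[1])
    for (j in mem[-1]) { rj <- find(j); if (rj != r0) comp[rj] <- r0 }
  }
  roots <- unique(vapply(seq_len(n), find, 1L))
  total <- numeric(M)
  for (r in roots) {
    res <- collect(m$id[r], 0L)
    total <- total + res$lg + log(colSums(res$v))
  }
  total
}

subset_batch <- function(batch, ii) {
  b <- batch
  b$p <- b$p[ii]; b$M <- length(ii)
  for (f in c("pen", "mu", "sd"))
    if (!is.null(b[[f]])) b[[f]] <- b[[f]][, ii, drop = FALSE]
  if (!is.null(b$threshold)) b$threshold <- b$threshold[ii]
  b
}

## lumped genotype lookup for one pedigree at one marker
pedigree_marker_genotypes <- function(ped, G, marker) {
  keys <- ped_key(ped)
  present <- keys %in% rownames(G$a1)
  a1 <- rep(NA_integer_, length(keys)); a2 <- a1
  a1[present] <- G$a1[keys[present], marker]
  a2[present] <- G$a2[keys[present], marker]
  list(a1 = setNames(a1, ped$members$id), a2 = setNames(a2, ped$members$id))
}

## Log-likelihoods for a model batch at one marker across several thetas.
## Returns an M x length(thetas) matrix.
peel_logliks <- function(ped, G, map, marker, trait, batch,
                         thetas) {
  j <- match(marker, map$name)
  if (is.na(j)) stop("marker ", marker, " not in map")
  if (is.null(map$freqs)) stop("map has no allele frequencies attached")
  g <- pedigree_marker_genotypes(ped, G, marker)
  lump <- lump_marker(map$alleles[[j]], map$freqs[[j]], c(g$a1, g$a2))
  ga <- setNames(match(g$a1, lump$labels), names(g$a1))
  gb <- setNames(match(g$a2, lump$labels), names(g$a2))
  out <- vapply(thetas, function(th)
    peel_engine(ped, ga, gb, lump$freqs, th, batch, trait),
    numeric(batch$M))
  matrix(out, nrow = batch$M)
}

#' Pedigree log-likelihood by Elston-Stewart peeling
#'
#' Exact joint two-locus (trait x marker) likelihood of a loop-free
#' pedigree: the sum over all joint genotype configurations of founder HWE
#' priors, Mendelian two-locus transmissions with recombination
#' \code{theta}, trait penetrances, and marker-genotype indicators, computed
#' by nuclear-family peeling in log space with per-family rescaling.
#' Multi-allelic markers are reduced to the alleles observed in the pedigree
#' plus a lumped residual allele.
#'
#' A return value of \code{-Inf} signals a likelihood of exactly zero,
#' i.e. data inconsistent with the model (such as an uncorrected Mendelian
#' error).
#'
#' @param ped A \code{pedigree}.
#' @param G A \code{genotypes} object.
#' @param map A \code{genetic_map} with allele frequencies attached.
#' @param marker Marker name.
#' @param trait A \code{trait_coding} (vectors named by
#'   \code{"<pedigree>:<id>"} keys), or \code{NULL} for no phenotype data.
#' @param model A \code{trait_model}.
#' @param theta Recombination fraction in [0, 0.5].
#' @return Log-likelihood (natural log).
#' @export
peel_likelihood <- function(ped, G, map, marker, trait, model, theta) {
  stopifnot(theta >= 0, theta <= 0.5)
  if (!is.null(trait) && model$kind != trait$kind)
    stop("trait coding kind ", trait$kind, " does not match model kind ",
         model$kind)
  drop(peel_logliks(ped, G, map, marker, trait, batch_from_model(model),
                    theta))
}
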