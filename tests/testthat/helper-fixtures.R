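## Shared fixtures: tiny maps, genotype containers, random pedigrees.

## one-marker map with given allele frequencies
map1 <- function(freqs, type = "SNP", name = "m1", cM = 0, chrom = "1") {
  map <- data.frame(name = name, chrom = chrom, cM = cM, type = type,
                    stringsAsFactors = FALSE)
  map$alleles <- list(seq_along(freqs))
  map$freqs <- list(freqs)
  class(map) <- c("genetic_map", "data.frame")
  map
}

## genotypes object from named allele vectors (names = "<ped>:<id>" keys)
geno1 <- function(a1, a2, marker = "m1") {
  structure(list(
    a1 = matrix(as.integer(a1), ncol = 1,
                dimnames = list(names(a1), marker)),
    a2 = matrix(as.integer(a2), ncol = 1,
                dimnames = list(names(a1), marker))),
    class = "genotypes")
}

dt_coding <- function(ped, affection) {
  trait_coding("T", "DT",
               affection = setNames(affection, ped_keys(ped)))
}

ped_keys <- function(ped) paste(ped$pedigree_id, ped$members$id, sep = ":")

## random loop-free pedigree with n members: founder couple, then children
## who may marry in new founders and have children of their own
rand_pedigree <- function(n, pedigree_id = "R") {
  id <- c("1", "2"); father <- c(NA, NA); mother <- c(NA, NA)
  sex <- c("male", "female")
  couples <- list(c("1", "2"))
  nxt <- 3L
  while (length(id) < n) {
    cp <- couples[[sample.int(length(couples), 1)]]
    cid <- as.character(nxt); nxt <- nxt + 1L
    csex <- sample(c("male", "female"), 1)
    id <- c(id, cid); father <- c(father, cp[1]); mother <- c(mother, cp[2])
    sex <- c(sex, csex)
    if (length(id) < n && stats::runif(1) < 0.5) {
      sid <- as.character(nxt); nxt <- nxt + 1L
      id <- c(id, sid); father <- c(father, NA); mother <- c(mother, NA)
      sex <- c(sex, if (csex == "male") "female" else "male")
      couples[[length(couples) + 1L]] <-
        if (csex == "male") c(cid, sid) else c(sid, cid)
    }
  }
  pedigree(pedigree_id, id, father, mother, sex)
}

## the six-member three-generation fixture used by the oracle comparisons:
## grandparent couple, their child A married to founder S, two grandchildren
fixture6 <- function() {
  ids <- c("gp1", "gp2", "A", "S", "c1", "c2")
  ped <- pedigree("P", ids,
                  c(NA, NA, "gp1", NA, "A", "A"),
                  c(NA, NA, "gp2", NA, "S", "S"),
                  c(1, 2, 1, 2, 1, 2))
  keys <- ped_keys(ped)
  G <- geno1(setNames(c(1L, 1L, 1L, 2L, 1L, 1L), keys),
             setNames(c(2L, 1L, 2L, 2L, 2L, 2L), keys))
  map <- map1(c(0.7, 0.3))
  trait <- dt_coding(ped, c("affected", "unaffected", "affected",
                            "unaffected", "affected", "unknown"))
  list(ped = ped, G = G, map = map, trait = trait)
}
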