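#' Read a genetic map
#'
#' Whitespace-delimited file with four columns: marker name, chromosome,
#' sex-averaged position in centimorgans, and marker type (\code{SNP} or
#' \code{MS}). A header line is detected and skipped. Markers are sorted by
#' chromosome and position.
#'
#' @param path Path to the map file.
#' @return A data frame of class \code{genetic_map} with columns
#'   \code{name}, \code{chrom}, \code{cM}, \code{type}, and (once allele
#'   frequencies are attached) list columns \code{alleles}, \code{freqs}.
#' @export
read_map <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("name", "chrom", "cM", "type"))
  if (is.na(suppressWarnings(as.numeric(raw$cM[1])))) raw <- raw[-1, ]
  map <- data.frame(name = as.character(raw$name),
                    chrom = as.character(raw$chrom),
                    cM = as.numeric(raw$cM),
                    type = toupper(as.character(raw$type)),
                    stringsAsFactors = FALSE)
  if (!all(map$type %in% c("SNP", "MS")))
    stop("marker type must be SNP or MS")
  if (any(map$cM < 0)) stop("negative cM position")
  map <- map[order(map$chrom, map$cM), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Read an allele-frequency table
#'
#' Long-format TSV with header columns \code{marker}, \code{allele},
#' \code{freq}. Frequencies for each marker must sum to 1 (tolerance 1e-9).
#'
#' @param path Path to the frequency TSV.
#' @param map A \code{genetic_map}; frequencies are attached to it.
#' @return The map with list columns \code{alleles} (integer labels, in file
#'   order) and \code{freqs} populated.
#' @export
read_freq <- function(path, map) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "allele", "freq") %in% names(tab)))
  set_marker_freqs(map, split(tab, tab$marker))
}

set_marker_freqs <- function(map, by_marker) {
  map$alleles <- vector("list", nrow(map))
  map$freqs <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    sub <- by_marker[[map$name[i]]]
    if (is.null(sub)) stop("no allele frequencies for marker ", map$name[i])
    if (abs(sum(sub$freq) - 1) > 1e-9)
      stop("allele frequencies for ", map$name[i], " do not sum to 1")
    map$alleles[[i]] <- as.integer(sub$allele)
    map$freqs[[i]] <- as.numeric(sub$freq)
  }
  map
}

#' Read a pre-makeped LINKAGE pedigree file
#'
#' Whitespace-delimited columns: pedigree id, individual id, father id,
#' mother id, sex (1 = male, 2 = female), then two allele columns per marker
#' in map order. \code{0} codes a missing parent or allele.
#'
#' @param path Path to the .ped file.
#' @param map A \code{genetic_map} giving marker order (and, if allele
#'   frequencies are attached, the legal allele labels).
#' @return A list with \code{pedigrees} (list of [pedigree()] objects) and
#'   \code{genotypes} (a \code{genotypes} object, see Details).
#' @details The \code{genotypes} object holds two integer matrices \code{a1}
#'   and \code{a2} of allele labels (NA = missing), one row per individual
#'   keyed \code{"<pedigree>:<id>"}, one column per marker in map order.
#'   Unordered genotypes: (a1, a2) and (a2, a1) are equivalent.
#' @export
read_ped <- function(path, map) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  nmark <- nrow(map)
  rows <- strsplit(trimws(lines), "[ \t]+")
  nc <- lengths(rows)
  if (length(nc) && any(nc != 5 + 2 * nmark))
    stop(sprintf("column count mismatch: expected %d columns (5 + 2 x %d markers), found %d",
                 5 + 2 * nmark, nmark, nc[which(nc != 5 + 2 * nmark)[1]]))
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- matrix(character(), 0, 5 + 2 * nmark)
  pedid <- tab[, 1]
  peds <- lapply(split(seq_len(nrow(tab)), factor(pedid, unique(pedid))),
                 function(idx) {
    pedigree(pedid[idx[1]], tab[idx, 2], tab[idx, 3], tab[idx, 4],
             as.integer(tab[idx, 5]))
  })
  names(peds) <- vapply(peds, `[[`, "", "pedigree_id")
  for (ped in peds) {
    rep <- validate_pedigree(ped)
    bad <- rep[rep$fatal, , drop = FALSE]
    if (nrow(bad))
      stop("pedigree ", ped$pedigree_id, ": ", bad$type[1], " (",
           bad$message[1], ")")
  }
  al <- matrix(suppressWarnings(as.integer(tab[, -(1:5), drop = FALSE])),
               nrow = nrow(tab))
  a1 <- al[, 2 * seq_len(nmark) - 1, drop = FALSE]
  a2 <- al[, 2 * seq_len(nmark), drop = FALSE]
  a1[a1 == 0L] <- NA_integer_
  a2[a2 == 0L] <- NA_integer_
  ## half-missing genotype cells are treated as fully missing
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  keys <- paste(tab[, 1], tab[, 2], sep = ":")
  dimnames(a1) <- dimnames(a2) <- list(keys, map$name)
  if (!is.null(map$alleles)) {
    for (j in seq_len(nmark)) {
      obs <- c(a1[, j], a2[, j])
      bad <- !is.na(obs) & !(obs %in% map$alleles[[j]])
      if (any(bad))
        stop("allele label ", obs[bad][1], " not in allele set of marker ",
             map$name[j])
    }
  }
  list(pedigrees = peds,
       genotypes = structure(list(a1 = a1, a2 = a2), class = "genotypes"))
}

#' Write pedigrees and genotypes in pre-makeped LINKAGE format
#'
#' @param pedigrees List of [pedigree()] objects.
#' @param G A \code{genotypes} object (rows keyed \code{"<ped>:<id>"}).
#' @param map A \code{genetic_map} giving marker order.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ped <- function(pedigrees, G, map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ped in pedigrees) {
    m <- ped$members
    keys <- ped_key(ped)
    a1 <- G$a1[keys, map$name, drop = FALSE]
    a2 <- G$a2[keys, map$name, drop = FALSE]
    a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
    geno <- matrix(0L, nrow(m), 2 * nrow(map))
    geno[, 2 * seq_len(nrow(map)) - 1] <- a1
    geno[, 2 * seq_len(nrow(map))] <- a2
    fa <- ifelse(is.na(m$father), "0", m$father)
    mo <- ifelse(is.na(m$mother), "0", m$mother)
    sx <- ifelse(m$sex == "male", 1L, 2L)
    writeLines(paste(ped$pedigree_id, m$id, fa, mo, sx,
                     apply(geno, 1, paste, collapse = " ")), con)
  }
  invisible(path)
}

#' Estimate allele frequencies by counting founder alleles
#'
#' Counts alleles among founders across all pedigrees (missing cells
#' skipped) and attaches the estimated frequencies to the map. Used when no
#' frequency file is supplied. Markers unobserved in founders fall back to
#' equal frequencies over the observed allele set (or \{1, 2\} for SNPs).
#'
#' @param pedigrees List of pedigrees.
#' @param G \code{genotypes} object.
#' @param map \code{genetic_map}.
#' @return The map with \code{alleles}/\code{freqs} list columns set.
#' @export
estimate_founder_freqs <- function(pedigrees, G, map) {
  fkeys <- unlist(lapply(pedigrees, function(p) ped_key(p)[is_founder(p)]))
  fkeys <- intersect(fkeys, rownames(G$a1))
  map$alleles <- vector("list", nrow(map))
  map$freqs <- vector("list", nrow(map))
  for (j in seq_len(nrow(map))) {
    obs <- c(G$a1[fkeys, j], G$a2[fkeys, j])
    obs <- obs[!is.na(obs)]
    if (length(obs)) {
      tab <- table(obs)
      map$alleles[[j]] <- as.integer(names(tab))
      map$freqs[[j]] <- as.numeric(tab) / sum(tab)
    } else {
      k <- if (map$type[j] == "SNP") 2L else 2L
      map$alleles[[j]] <- seq_len(k)
      map$freqs[[j]] <- rep(1 / k, k)
    }
  }
  map
}

#' Read / write a phenotype table
#'
#' Tab-separated with a header; required key columns \code{pedigree} and
#' \code{id}. Recognised columns: \code{asd_status} (affected / unaffected /
#' unknown), \code{bapq_self_1} .. \code{bapq_self_36} and
#' \code{bapq_inf_1} .. \code{bapq_inf_36} (Likert 1..6), \code{anx_t},
#' \code{rrb_total}, \code{soc_t}, \code{mprs_positive} (0/1),
#' \code{celf_core}, \code{ctopp_nwr}, \code{ctopp_rap}. Empty or \code{NA}
#' cells are missing; \code{unknown} is distinct from \code{unaffected}.
#'
#' @param path File path.
#' @return A data frame with one row per individual, key column
#'   \code{key = "<pedigree>:<id>"} added.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  stopifnot(all(c("pedigree", "id") %in% names(tab)))
  tab$pedigree <- as.character(tab$pedigree)
  tab$id <- as.character(tab$id)
  if ("asd_status" %in% names(tab)) {
    ok <- tab$asd_status %in% c("affected", "unaffected", "unknown", NA)
    if (!all(ok)) stop("bad asd_status value: ", tab$asd_status[!ok][1])
    tab$asd_status[is.na(tab$asd_status)] <- "unknown"
  }
  lik <- grep("^bapq_(self|inf)_", names(tab))
  for (j in lik) {
    bad <- !is.na(tab[[j]]) & !(tab[[j]] %in% 1:6)
    if (any(bad)) stop("Likert response outside 1..6 in ", names(tab)[j])
  }
  tab$key <- paste(tab$pedigree, tab$id, sep = ":")
  tab
}

#' @rdname read_phenotypes
#' @param phenotypes Data frame as returned by [read_phenotypes()].
#' @export
write_phenotypes <- function(phenotypes, path) {
  tab <- phenotypes[, setdiff(names(phenotypes), "key"), drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genome-scan results
#'
#' One row per map position with chromosome, position, marker name,
#' per-pedigree Bayes ratios, pooled and sequential Bayes ratios, and the
#' corresponding PPLs, formatted to 6 significant digits.
#'
#' @param scan A \code{linkage_result} data frame from [genome_scan()].
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(scan, path) {
  out <- as.data.frame(scan)
  num <- vapply(out, is.numeric, TRUE) & names(out) != "cM"
  for (j in which(num)) out[[j]] <- sprintf("%.6g", out[[j]])
  out$cM <- sprintf("%.6g", out$cM)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(tab) <- c("linkage_result", "data.frame")
  tab
}
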