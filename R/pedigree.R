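#' Construct a pedigree
#'
#' A pedigree is an ordered collection of individuals with parent links.
#' Founders have both parent ids missing; an individual with exactly one
#' parent recorded is invalid (half-parented).
#'
#' @param pedigree_id Character scalar identifying the family.
#' @param id Character vector of individual ids, unique within the pedigree.
#' @param father,mother Character vectors of parent ids; \code{NA} (or "0")
#'   for founders.
#' @param sex Vector coded \code{1}/\code{"male"} or \code{2}/\code{"female"}.
#' @return An object of class \code{pedigree}: a list with a \code{members}
#'   data frame (id, father, mother, sex) and the \code{pedigree_id}.
#' @seealso [validate_pedigree()], [nuclear_families()]
#' @export
pedigree <- function(pedigree_id, id, father, mother, sex) {
  id <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  father[father %in% c("0", "")] <- NA_character_
  mother[mother %in% c("0", "")] <- NA_character_
  if (anyDuplicated(id))
    stop("duplicate individual id in pedigree ", pedigree_id)
  if (is.numeric(sex)) sex <- c("male", "female")[sex]
  sex <- match.arg(tolower(as.character(sex)), c("male", "female"),
                   several.ok = TRUE)
  if (length(sex) != length(id)) stop("sex length mismatch")
  members <- data.frame(id = id, father = father, mother = mother,
                        sex = sex, stringsAsFactors = FALSE)
  structure(list(pedigree_id = as.character(pedigree_id), members = members),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(x$members$father) & is.na(x$members$mother))
  cat(sprintf("Pedigree %s: %d members (%d founders)\n",
              x$pedigree_id, nrow(x$members), nf))
  invisible(x)
}

#' @export
#' @rdname pedigree
#' @param x A \code{pedigree}.
is_founder <- function(x) {
  is.na(x$members$father) & is.na(x$members$mother)
}

## Composite key used to index genotype/phenotype rows across pedigrees.
ped_key <- function(ped) paste(ped$pedigree_id, ped$members$id, sep = ":")

#' Validate pedigree structure
#'
#' Checks a parsed pedigree for structural defects: half-parented
#' individuals, unresolved parent ids, parents of the wrong sex, ancestry
#' cycles, and loops. A loop is any cycle in the undirected
#' individual--nuclear-family membership graph (consanguineous or marriage
#' loops, e.g. a first-cousin mating); loop-containing pedigrees are flagged
#' fatal because the likelihood peeler requires loop-free pedigrees.
#'
#' @param ped A \code{pedigree}.
#' @return A data frame with columns \code{type}, \code{id}, \code{message},
#'   \code{fatal}; zero rows when the pedigree is clean.
#' @export
validate_pedigree <- function(ped) {
  m <- ped$members
  out <- data.frame(type = character(), id = character(),
                    message = character(), fatal = logical(),
                    stringsAsFactors = FALSE)
  add <- function(type, id, message, fatal = TRUE) {
    out[nrow(out) + 1L, ] <<- list(type, id, message, fatal)
  }
  half <- xor(is.na(m$father), is.na(m$mother))
  for (i in which(half))
    add("half_parented", m$id[i], "exactly one parent recorded")
  for (i in seq_len(nrow(m))) {
    for (col in c("father", "mother")) {
      p <- m[[col]][i]
      if (!is.na(p)) {
        j <- match(p, m$id)
        if (is.na(j)) {
          add("unresolved_parent", m$id[i],
              sprintf("unresolved parent id '%s'", p))
        } else {
          want <- if (col == "father") "male" else "female"
          if (m$sex[j] != want)
            add("parent_sex", m$id[i],
                sprintf("%s '%s' is not %s", col, p, want), fatal = TRUE)
        }
      }
    }
  }
  ## ancestry cycles: repeated removal of parentless individuals
  ids <- m$id
  fa <- m$father; mo <- m$mother
  alive <- rep(TRUE, length(ids))
  repeat {
    free <- alive &
      (is.na(fa) | !(fa %in% ids[alive])) &
      (is.na(mo) | !(mo %in% ids[alive]))
    if (!any(free & alive)) break
    alive[free] <- FALSE
    if (!any(alive)) break
  }
  for (i in which(alive))
    add("cycle", ids[i], "individual is its own ancestor")
  ## loops: cycle in the individual/nuclear-family bipartite graph
  if (!any(alive) && !any(out$type == "unresolved_parent")) {
    fams <- nuclear_families(ped)
    if (length(fams)) {
      n_ind <- nrow(m)
      edges <- 0L
      nodes_used <- logical(n_ind)
      for (f in fams) {
        mem <- match(unique(c(f$father, f$mother, f$children)), m$id)
        edges <- edges + length(mem)
        nodes_used[mem] <- TRUE
      }
      n_nodes <- sum(nodes_used) + length(fams)
      ## connected components of the membership graph
      comp <- seq_len(n_ind + length(fams))
      find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
      for (k in seq_along(fams)) {
        f <- fams[[k]]
        fi <- n_ind + k
        for (id in unique(c(f$father, f$mother, f$children))) {
          j <- match(id, m$id)
          ra <- find(j); rb <- find(fi)
          if (ra != rb) comp[ra] <- rb
        }
      }
      roots <- unique(vapply(which(c(nodes_used, rep(TRUE, length(fams)))),
                             find, integer(1)))
      if (edges > n_nodes - length(roots))
        add("loop", NA_character_,
            "pedigree contains a loop (not peelable)", fatal = TRUE)
    }
  }
  out
}

#' Decompose a pedigree into nuclear families
#'
#' One nuclear family per distinct parent couple together with all their
#' offspring. An individual may appear in several nuclear families: as a
#' child in one and as a parent in others.
#'
#' @param ped A \code{pedigree}.
#' @return A list of nuclear families, each a list with elements
#'   \code{father}, \code{mother}, \code{children} (character ids).
#' @export
nuclear_families <- function(ped) {
  m <- ped$members
  has_par <- !is.na(m$father) & !is.na(m$mother)
  if (!any(has_par)) return(list())
  key <- paste(m$father[has_par], m$mother[has_par], sep = "\r")
  split_kids <- split(m$id[has_par], key)
  lapply(names(split_kids), function(k) {
    pp <- strsplit(k, "\r", fixed = TRUE)[[1]]
    list(father = pp[1], mother = pp[2], children = split_kids[[k]])
  })
}

#' @rdname nuclear_families
#' @export
decompose_nuclear_families <- nuclear_families

## nuclear families an individual belongs to (as parent or child);
## returns integer indices into nuclear_families(ped)
families_of <- function(ped, fams = nuclear_families(ped)) {
  out <- setNames(vector("list", nrow(ped$members)), ped$members$id)
  for (k in seq_along(fams)) {
    f <- fams[[k]]
    for (id in unique(c(f$father, f$mother, f$children)))
      out[[id]] <- c(out[[id]], k)
  }
  out
}
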