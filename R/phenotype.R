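#' Default BAP-Q scoring key
#'
#' The BAP Questionnaire has 36 items on a six-point Likert scale, split
#' into three 12-item subscales (aloof personality, pragmatic language,
#' rigid personality); a subset of items is reverse keyed (response x scores
#' 7 - x). The instrument's actual item-to-subscale assignment and reverse
#' key are not distributed with this package; this default is a synthetic
#' key (items 1-12 aloof, 13-24 pragmatic, 25-36 rigidity; every third item
#' reverse keyed) intended for simulated data. Supply the published key for
#' real questionnaires.
#'
#' @param subscale Integer/character vector of length 36 mapping items to
#'   subscales (values \code{"aloof"}, \code{"pragmatic"}, \code{"rigidity"},
#'   12 each).
#' @param reverse Integer vector of reverse-keyed item numbers.
#' @return A list of class \code{bapq_key}.
#' @export
bapq_key <- function(subscale = rep(c("aloof", "pragmatic", "rigidity"),
                                    each = 12),
                     reverse = seq(3, 36, by = 3)) {
  subscale <- match.arg(subscale, c("aloof", "pragmatic", "rigidity"),
                        several.ok = TRUE)
  stopifnot(length(subscale) == 36,
            all(table(subscale) == 12),
            all(reverse %in% 1:36))
  structure(list(subscale = subscale, reverse = as.integer(reverse)),
            class = "bapq_key")
}

#' Score the BAP Questionnaire
#'
#' Reverse-keyed items are mapped x -> 7 - x; each subscale score is the
#' mean of its 12 items and the total score is the mean of all 36 items. A
#' subscale (or the total) is scored when at least \code{min_items} of its
#' items are present, as the mean of the present items; otherwise missing.
#'
#' @param responses Numeric vector of 36 Likert responses in 1..6 (NA =
#'   missing item).
#' @param key A [bapq_key()].
#' @param min_items Minimum items per subscale required to score it
#'   (default 10 of 12; the total requires \code{3 * min_items}).
#' @return Named numeric vector \code{c(aloof, pragmatic, rigidity, total)},
#'   NA where unscorable.
#' @export
score_bapq <- function(responses, key = bapq_key(), min_items = 10L) {
  stopifnot(length(responses) == 36)
  bad <- !is.na(responses) & !(responses %in% 1:6)
  if (any(bad))
    stop("Likert response outside 1..6 at item ", which(bad)[1])
  x <- as.numeric(responses)
  x[key$reverse] <- 7 - x[key$reverse]
  sub <- vapply(c("aloof", "pragmatic", "rigidity"), function(d) {
    v <- x[key$subscale == d]
    if (sum(!is.na(v)) >= min_items) mean(v, na.rm = TRUE) else NA_real_
  }, 0)
  total <- if (sum(!is.na(x)) >= 3L * min_items) mean(x, na.rm = TRUE) else
    NA_real_
  c(sub, total = total)
}

#' Average self and informant subscale scores
#'
#' When both raters scored a domain the average is used; when only one did,
#' that rater's score is used. The rater provenance per domain selects which
#' cut-off column (self / informant / average) applies in [classify_bap()].
#'
#' @param self,informant Named numeric vectors as returned by
#'   [score_bapq()] (or \code{NULL} when that rater is absent).
#' @return A list with \code{scores} (named numeric vector) and
#'   \code{provenance} (named character vector: "self", "informant",
#'   "average", or NA when both raters are missing).
#' @export
average_ratings <- function(self = NULL, informant = NULL) {
  domains <- c("aloof", "pragmatic", "rigidity", "total")
  gets <- function(v, d) if (is.null(v) || is.na(v[d])) NA_real_ else v[[d]]
  scores <- setNames(numeric(4), domains)
  prov <- setNames(rep(NA_character_, 4), domains)
  for (d in domains) {
    s <- gets(self, d); i <- gets(informant, d)
    if (!is.na(s) && !is.na(i)) {
      scores[d] <- (s + i) / 2; prov[d] <- "average"
    } else if (!is.na(s)) {
      scores[d] <- s; prov[d] <- "self"
    } else if (!is.na(i)) {
      scores[d] <- i; prov[d] <- "informant"
    } else {
      scores[d] <- NA_real_
    }
  }
  list(scores = scores, provenance = prov)
}

#' Sex-specific BAP-Q diagnostic cut-offs
#'
#' Defaults are the published high-specificity cut-offs for the four
#' domains (aloof, pragmatic language, rigidity, total score), for each sex
#' and each rater provenance (self, informant, average of the two).
#'
#' @param table Optional replacement: a data frame with columns \code{sex},
#'   \code{domain}, \code{rater}, \code{cutoff}.
#' @return A data frame of class \code{bapq_cutoffs} (24 rows).
#' @export
bapq_cutoffs <- function(table = NULL) {
  if (is.null(table)) {
    table <- expand.grid(
      rater = c("self", "informant", "average"),
      domain = c("aloof", "pragmatic", "rigidity", "total"),
      sex = c("male", "female"),
      stringsAsFactors = FALSE)[, 3:1]
    table$cutoff <- c(
      ## male: aloof, pragmatic, rigidity, total x (self, informant, average)
      4.13, 4.19, 4.03,
      3.23, 3.29, 3.09,
      3.91, 4.20, 3.90,
      3.55, 3.63, 3.47,
      ## female
      3.45, 3.64, 3.39,
      2.94, 3.19, 2.90,
      3.70, 4.30, 3.85,
      3.17, 3.46, 3.19)
  }
  stopifnot(all(c("sex", "domain", "rater", "cutoff") %in% names(table)),
            all(table$cutoff >= 1 & table$cutoff <= 6))
  class(table) <- c("bapq_cutoffs", "data.frame")
  table
}

#' Classify the broad autism phenotype from BAP-Q scores
#'
#' An individual is BAP-positive when any scored domain (aloof, pragmatic,
#' rigidity, or total, each compared against the sex- and rater-specific
#' cut-off) meets or exceeds its cut-off; negative when at least three of
#' the four domains are scored and all scored domains fall below their
#' cut-offs; unknown otherwise.
#'
#' @param scores Named numeric vector over domains (NA = unscored), e.g.
#'   \code{average_ratings(...)$scores}.
#' @param provenance Named character vector giving the rater column per
#'   domain ("self", "informant", "average").
#' @param sex \code{"male"} or \code{"female"}.
#' @param cutoffs A [bapq_cutoffs()] table.
#' @return \code{"positive"}, \code{"negative"}, or \code{"unknown"}.
#' @export
classify_bap <- function(scores, provenance, sex, cutoffs = bapq_cutoffs()) {
  sex <- match.arg(sex, c("male", "female"))
  domains <- c("aloof", "pragmatic", "rigidity", "total")
  scored <- domains[!is.na(scores[domains])]
  if (!length(scored)) return("unknown")
  met <- vapply(scored, function(d) {
    cut <- cutoffs$cutoff[cutoffs$sex == sex & cutoffs$domain == d &
                          cutoffs$rater == provenance[[d]]]
    if (!length(cut)) stop("no cutoff for ", sex, "/", d, "/",
                           provenance[[d]])
    scores[[d]] >= cut
  }, TRUE)
  if (any(met)) return("positive")
  if (length(scored) >= 3) "negative" else "unknown"
}

#' Compound ASD and BAP trait codings
#'
#' ASD trait: ASD-affected individuals are affected; every assessed non-ASD
#' individual (including BAP-positive relatives) is unaffected; unassessed
#' individuals are unknown. BAP trait: BAP-positive or ASD-affected
#' individuals are affected; assessed BAP-negative individuals are
#' unaffected; otherwise unknown.
#'
#' @param asd_status Character vector: "affected", "unaffected", "unknown".
#' @param bap_status Character vector: "positive", "negative", "unknown"
#'   (from [classify_bap()]).
#' @return A list of two \code{trait_coding} objects, \code{asd} and
#'   \code{bap}, each a list with \code{trait_name}, \code{kind = "DT"},
#'   and \code{affection} (character vector).
#' @export
code_compound_traits <- function(asd_status, bap_status) {
  stopifnot(length(asd_status) == length(bap_status))
  asd <- ifelse(asd_status == "affected", "affected",
         ifelse(asd_status == "unaffected", "unaffected", "unknown"))
  bap <- ifelse(asd_status == "affected" | bap_status == "positive",
                "affected",
         ifelse(bap_status == "negative", "unaffected", "unknown"))
  list(asd = trait_coding("ASD", "DT", affection = asd),
       bap = trait_coding("BAP", "DT", affection = bap))
}

#' Trait coding container
#'
#' @param trait_name Label.
#' @param kind \code{"DT"}, \code{"QT"}, or \code{"QTT"}.
#' @param affection For DT: character vector over individuals.
#' @param value For QT/QTT: numeric vector (NA = missing).
#' @param censor For QTT: character vector, one of \code{"valued"},
#'   \code{"over"}, \code{"under"}, \code{"unknown"} per individual;
#'   individuals are exactly one of valued / over-threshold / under /
#'   unknown.
#' @return A list of class \code{trait_coding}.
#' @export
trait_coding <- function(trait_name, kind = c("DT", "QT", "QTT"),
                         affection = NULL, value = NULL, censor = NULL) {
  kind <- match.arg(kind)
  if (kind == "DT") {
    stopifnot(all(affection %in% c("affected", "unaffected", "unknown")))
  } else {
    stopifnot(!is.null(value))
    if (kind == "QTT") {
      stopifnot(length(censor) == length(value),
                all(censor %in% c("valued", "over", "under", "unknown")),
                all(is.na(value[censor != "valued"])),
                all(!is.na(value[censor == "valued"])))
    }
  }
  structure(list(trait_name = trait_name, kind = kind,
                 affection = affection, value = value, censor = censor),
            class = "trait_coding")
}

#' Secondary-phenotype trait codings
#'
#' Builds the seven secondary trait codings from raw measures:
#' \itemize{
#' \item CLF (DT): affected iff CELF-4 core language score < 84.
#' \item NWR (DT): affected iff CTOPP non-word repetition standard score <= 7.
#' \item RAP (DT): affected iff CTOPP rapid naming composite < 84.
#' \item PRS (DT): affected iff ASD-affected or MPRS-positive.
#' \item RRB (QT): RBS-R total score.
#' \item SOC (QT): SRS total t-score.
#' \item ANX (QTT): NEO anxiety t-score when measured; ASD cases without a
#'   score are over-threshold; non-cases without a score are under
#'   threshold.
#' }
#'
#' @param phenotypes Data frame in the layout of [read_phenotypes()].
#' @return Named list of \code{trait_coding} objects
#'   (\code{clf, nwr, rap, prs, rrb, soc, anx}).
#' @export
code_secondary_traits <- function(phenotypes) {
  n <- nrow(phenotypes)
  gc <- function(col) if (col %in% names(phenotypes)) phenotypes[[col]] else
    rep(NA_real_, n)
  dt_from <- function(x, affected) {
    ifelse(is.na(x), "unknown", ifelse(affected(x), "affected", "unaffected"))
  }
  asd <- if ("asd_status" %in% names(phenotypes)) phenotypes$asd_status else
    rep("unknown", n)
  clf <- dt_from(gc("celf_core"), function(x) x < 84)
  nwr <- dt_from(gc("ctopp_nwr"), function(x) x <= 7)
  rap <- dt_from(gc("ctopp_rap"), function(x) x < 84)
  mprs <- gc("mprs_positive")
  prs <- ifelse(asd == "affected", "affected",
         ifelse(!is.na(mprs) & mprs == 1, "affected",
         ifelse(!is.na(mprs), "unaffected", "unknown")))
  anx_v <- gc("anx_t")
  anx_cens <- ifelse(!is.na(anx_v), "valued",
              ifelse(asd == "affected", "over",
              ifelse(asd == "unaffected", "under", "unknown")))
  list(clf = trait_coding("CLF", "DT", affection = clf),
       nwr = trait_coding("NWR", "DT", affection = nwr),
       rap = trait_coding("RAP", "DT", affection = rap),
       prs = trait_coding("PRS", "DT", affection = prs),
       rrb = trait_coding("RRB", "QT", value = gc("rrb_total")),
       soc = trait_coding("SOC", "QT", value = gc("soc_t")),
       anx = trait_coding("ANX", "QTT",
                          value = ifelse(anx_cens == "valued", anx_v,
                                         NA_real_),
                          censor = anx_cens))
}

#' Standardize quantitative trait values
#'
#' Affine transform to mean 0 and (population) SD 1 over the observed
#' values; the transform parameters are retained as attributes so the
#' original scale can be reported. Trait parameters are integrated over
#' finite ranges on the standardized scale, so quantitative traits must be
#' standardized before analysis.
#'
#' @param values Numeric vector (NA = missing).
#' @return Standardized vector with attributes \code{center} and
#'   \code{scale}.
#' @export
standardize_qt <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2) stop("degenerate QT: fewer than 2 observed values")
  m <- mean(obs)
  s <- sqrt(mean((obs - m)^2))
  if (s == 0) stop("degenerate QT: zero variance")
  structure((values - m) / s, center = m, scale = s)
}

#' Build a trait coding from a phenotype table
#'
#' One-stop constructor for the codings consumed by the scan: scores the
#' BAP-Q (self and informant), averages raters, classifies BAP against the
#' sex-specific cut-offs, and assembles the requested compound or secondary
#' trait. Quantitative traits are standardized to mean 0, SD 1 over the
#' observed values (the integration grids live on that scale); the ANX
#' threshold coding keeps its censoring flags.
#'
#' @param trait One of \code{"asd"}, \code{"bap"}, \code{"clf"},
#'   \code{"nwr"}, \code{"rap"}, \code{"prs"}, \code{"rrb"}, \code{"soc"},
#'   \code{"anx"}.
#' @param phenotypes Data frame in the layout of [read_phenotypes()]; a
#'   \code{sex} column (or \code{sexes} argument) is required for BAP
#'   classification.
#' @param sexes Optional named character vector (by \code{key}) overriding
#'   the table's \code{sex} column.
#' @param cutoffs A [bapq_cutoffs()] table.
#' @param key A [bapq_key()].
#' @param standardize Standardize quantitative values (default TRUE).
#' @return A \code{trait_coding} whose vectors are named by
#'   \code{"<pedigree>:<id>"} keys.
#' @export
build_trait_coding <- function(trait, phenotypes, sexes = NULL,
                               cutoffs = bapq_cutoffs(), key = bapq_key(),
                               standardize = TRUE) {
  trait <- match.arg(tolower(trait),
                     c("asd", "bap", "clf", "nwr", "rap", "prs", "rrb",
                       "soc", "anx"))
  keys <- phenotypes$key
  if (trait %in% c("asd", "bap")) {
    bap_status <- rep("unknown", nrow(phenotypes))
    has_items <- any(grepl("^bapq_(self|inf)_", names(phenotypes)))
    if (has_items) {
      if (is.null(sexes)) {
        stopifnot("sex" %in% names(phenotypes))
        sexes <- setNames(phenotypes$sex, keys)
      }
      self_cols <- paste0("bapq_self_", 1:36)
      inf_cols <- paste0("bapq_inf_", 1:36)
      for (i in seq_len(nrow(phenotypes))) {
        sc_self <- if (all(self_cols %in% names(phenotypes)) &&
                       any(!is.na(unlist(phenotypes[i, self_cols]))))
          score_bapq(as.numeric(phenotypes[i, self_cols]), key) else NULL
        sc_inf <- if (all(inf_cols %in% names(phenotypes)) &&
                      any(!is.na(unlist(phenotypes[i, inf_cols]))))
          score_bapq(as.numeric(phenotypes[i, inf_cols]), key) else NULL
        if (is.null(sc_self) && is.null(sc_inf)) next
        avg <- average_ratings(sc_self, sc_inf)
        bap_status[i] <- classify_bap(avg$scores, avg$provenance,
                                      sexes[keys[i]], cutoffs)
      }
    }
    cc <- code_compound_traits(phenotypes$asd_status, bap_status)
    out <- cc[[trait]]
    out$affection <- setNames(out$affection, keys)
    return(out)
  }
  sec <- code_secondary_traits(phenotypes)
  out <- sec[[trait]]
  if (!is.null(out$affection)) out$affection <- setNames(out$affection, keys)
  if (!is.null(out$value)) {
    if (out$kind %in% c("QT", "QTT") && standardize &&
        sum(!is.na(out$value)) >= 2)
      out$value <- as.numeric(standardize_qt(out$value))
    out$value <- setNames(out$value, keys)
  }
  if (!is.null(out$censor)) out$censor <- setNames(out$censor, keys)
  out
}
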