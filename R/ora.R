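# Over-representation analysis of significant proteins against annotated
# term sets, with the full assay panel as the background universe.

#' Read a GMT term-annotation file
#'
#' Each line is `term <tab> description <tab> member1 <tab> member2 ...`.
#' Members are deduplicated and, when `background` is supplied, intersected
#' with the panel (annotation outside the assayed panel cannot be tested).
#'
#' @param path GMT file path.
#' @param background optional character vector of panel protein identifiers.
#' @return Named list of character vectors (term members).
#' @export
read_gmt <- function(path, background = NULL) {
  terms <- fgsea::gmtPathways(path)
  terms <- lapply(terms, unique)
  if (!is.null(background))
    terms <- lapply(terms, intersect, background)
  terms
}

#' Over-representation analysis by the one-sided hypergeometric test
#'
#' For each term the 2x2 table is `a = |hits & term|`, `b = |hits \ term|`,
#' `c = |term \ hits|`, `d = |background| - a - b - c`; the p-value is the
#' upper hypergeometric tail `P(X >= a)` (one-sided over-representation, the
#' same tail as a one-sided Fisher exact test); q-values are
#' Benjamini-Hochberg across all tested terms (every term with at least one
#' annotated panel protein). A term is significant when it has at least
#' `min_hits` hits and `q < alpha_q`. The odds ratio is the plain
#' cross-product `(a d) / (b c)`, reported as `Inf` when `b` or `c` is zero
#' (and `a d > 0`).
#'
#' @param hits character vector of significant proteins (must lie in
#'   `background`).
#' @param terms named list of term member vectors (see [read_gmt()]).
#' @param background character vector: the assay panel universe.
#' @param min_hits minimum hits for significance (default 3).
#' @param alpha_q q-value threshold (default 0.1).
#' @return data.frame with `term`, `n_hits`, `term_size`, `odds_ratio`, `p`,
#'   `q`, `significant`, sorted by p within the input term order broken by
#'   term name; plus attribute `background_size`.
#' @export
fisher_ora <- function(hits, terms, background, min_hits = 3, alpha_q = 0.1) {
  hits <- unique(hits)
  background <- unique(background)
  stray <- setdiff(hits, background)
  if (length(stray) > 0)
    stop("hit protein(s) not in the background panel: ",
         paste(head(stray, 5), collapse = ", "), call. = FALSE)
  terms <- lapply(terms, function(m) intersect(unique(m), background))
  terms <- terms[vapply(terms, length, integer(1)) >= 1]
  if (length(terms) == 0)
    return(structure(data.frame(term = character(0), n_hits = integer(0),
                                term_size = integer(0),
                                odds_ratio = numeric(0), p = numeric(0),
                                q = numeric(0), significant = logical(0)),
                     background_size = length(background)))
  N <- length(background)
  K <- length(hits)
  a <- vapply(terms, function(m) length(intersect(hits, m)), integer(1))
  m_size <- vapply(terms, length, integer(1))
  b <- K - a
  cc <- m_size - a
  d <- N - a - b - cc
  # upper tail P(X >= a) drawing |term| proteins from K hits / N-K non-hits
  p <- phyper(a - 1, K, N - K, m_size, lower.tail = FALSE)
  or <- ifelse(b * cc == 0,
               ifelse(a * d == 0, 0, Inf),
               (a * d) / (b * cc))
  or[a == 0] <- 0
  q <- bh_qvalues(p)
  out <- data.frame(term = names(terms), n_hits = a, term_size = m_size,
                    odds_ratio = or, p = unname(p), q = q,
                    significant = a >= min_hits & q < alpha_q,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "background_size") <- N
  out
}
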