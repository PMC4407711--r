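# Pairwise co-occurrence of chromosomal alterations across a tumor
# collection, tested with the two-tailed Fisher exact test.

#' Build a 2x2 contingency table from an alteration presence matrix
#'
#' @param presence Data frame with a `tumor_id` column and one 0/1 (or
#'   logical) column per alteration label (e.g. `"+14"`, `"-22"`).
#' @param alt1,alt2 Alteration column names.
#' @return One-row tibble `a` (both), `b` (first only), `c` (second only),
#'   `d` (neither).
#' @export
build_table <- function(presence, alt1, alt2) {
  for (a in c(alt1, alt2)) {
    if (!a %in% names(presence)) abort(sprintf("unknown alteration '%s'", a))
  }
  x <- as.logical(presence[[alt1]])
  y <- as.logical(presence[[alt2]])
  tibble(
    a = sum(x & y), b = sum(x & !y), c = sum(!x & y), d = sum(!x & !y)
  )
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test of association: conditioning on the margins, the
#' two-sided p-value is the sum of the probabilities of all tables whose
#' hypergeometric probability is at most that of the observed table (ties
#' included up to a relative tolerance of 1e-7). The odds ratio is the sample
#' odds ratio `(a*d) / (b*c)`.
#'
#' @param a,b,c,d Non-negative integer cell counts (`a` = both alterations,
#'   `b` = first only, `c` = second only, `d` = neither). A one-row data
#'   frame with these columns may be passed as `a`.
#' @return One-row tibble `odds_ratio`, `p`.
#' @examples
#' fisher_exact_two_tailed(18, 7, 16, 23)   # p ~ 0.021
#' @export
fisher_exact_two_tailed <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.data.frame(a)) {
    tab <- a; a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers")
  }
  m <- a + b          # tumors with the first alteration
  n_ <- c + d         # tumors without it
  k <- a + c          # tumors with the second alteration
  support <- max(0, k - n_):min(m, k)
  probs <- dhyper(support, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c)
  tibble(odds_ratio = or, p = min(1, p))
}

#' Scan alteration pairs for non-random co-occurrence
#'
#' Builds the 2x2 table and Fisher exact p for every requested pair of
#' alterations (all pairs by default), sorted by p. No multiple-testing
#' correction is applied.
#'
#' @param presence Presence data frame (see [build_table()]).
#' @param pairs Optional list of length-2 character vectors; defaults to all
#'   unordered pairs of alteration columns.
#' @return Tibble `alt1`, `alt2`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`.
#' @export
cooccurrence_scan <- function(presence, pairs = NULL) {
  alts <- setdiff(names(presence), "tumor_id")
  if (is.null(pairs)) {
    if (length(alts) < 2) abort("need at least 2 alterations to scan")
    idx <- utils::combn(alts, 2, simplify = FALSE)
    pairs <- idx
  }
  map(pairs, function(pr) {
    tab <- build_table(presence, pr[1], pr[2])
    ft <- fisher_exact_two_tailed(tab)
    tibble(alt1 = pr[1], alt2 = pr[2], tab, ft)
  }) |>
    list_rbind() |>
    arrange(.data$p)
}
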