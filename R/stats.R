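# Categorical statistics for behavioral records: handedness
# classification, the left/right -> preferred/nonpreferred transform,
# proportion tables, chi-squared and McNemar tests. Applicable to
# recorded and simulated data alike.

#' Classify handedness direction from neutral-trial selections
#'
#' Strict-majority rule over the hands chosen on laterally neutral
#' presentations (typically three): whichever of left/right was
#' chosen more often is the preferred hand. Bimanual (`"both"`)
#' grasps count toward neither hand; an exact tie is
#' `"undetermined"`.
#'
#' @param selections Character vector of `"left"`, `"right"`,
#'   `"both"`.
#' @return `"left"`, `"right"` or `"undetermined"`.
#' @examples
#' classify_handedness(c("right", "right", "left")) # "right"
#' @export
classify_handedness <- function(selections) {
  if (length(selections) == 0L)
    stop("no selections to classify handedness from")
  stopifnot(all(selections %in% c("left", "right", "both")))
  n_left <- sum(selections == "left")
  n_right <- sum(selections == "right")
  if (n_left > n_right) "left"
  else if (n_right > n_left) "right"
  else "undetermined"
}

#' Transform left/right records into the preferred frame
#'
#' Maps each record's hand through the participant's handedness
#' direction: the preferred hand becomes `"P"`, the other `"NP"`,
#' `"both"` stays `"both"`. Pooling across left- and right-handed
#' participants is only meaningful in this frame.
#'
#' @param records Data frame with at least `participant` and `hand`
#'   (`"left"`/`"right"`/`"both"`) columns.
#' @param handedness Named character vector mapping participant id to
#'   `"left"` or `"right"`, or a `handedness` column already present
#'   in `records`.
#' @return `records` with `hand` recoded to `"P"`/`"NP"`/`"both"`.
#' @export
to_preferred_frame <- function(records, handedness = NULL) {
  if (is.null(handedness)) {
    if (!"handedness" %in% names(records))
      stop("handedness not supplied and no handedness column present")
    handedness <- tapply(records$handedness, records$participant,
                         function(x) x[1])
  }
  ids <- unique(records$participant)
  known <- names(handedness)
  missing <- setdiff(as.character(ids), known)
  bad <- known[!handedness[known] %in% c("left", "right")]
  bad <- union(missing, intersect(bad, as.character(ids)))
  if (length(bad) > 0L)
    stop("handedness unknown for participant(s): ",
         paste(bad, collapse = ", "))
  pref <- handedness[as.character(records$participant)]
  records$hand <- ifelse(records$hand == "both", "both",
                         ifelse(records$hand == pref, "P", "NP"))
  records
}

#' Pearson chi-squared test for contingency tables
#'
#' Pearson's chi-squared statistic with `df = (r-1)(c-1)` for r x c
#' tables of counts, with optional Yates continuity correction for
#' 2 x 2 tables. A single row (or a plain vector) is tested as
#' goodness of fit against the uniform distribution.
#'
#' @param table Matrix of nonnegative counts, or a vector for the
#'   goodness-of-fit mode.
#' @param corrected Apply the Yates correction (2 x 2 only; default
#'   FALSE).
#' @return List with `statistic`, `df`, `p`, `method`.
#' @examples
#' chi_squared(matrix(c(10, 20, 20, 10), 2))$statistic # 6.6667
#' @export
chi_squared <- function(table, corrected = FALSE) {
  if (is.vector(table)) table <- matrix(table, nrow = 1)
  stopifnot(all(table >= 0), all(table == round(table)))
  if (nrow(table) == 1L || ncol(table) == 1L) {
    x <- as.vector(table)
    if (sum(x) == 0) stop("zero total count")
    ht <- stats::chisq.test(x)  # GOF against uniform
    method <- "Chi-squared goodness of fit (uniform)"
  } else {
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
      stop("zero marginal in contingency table")
    ht <- stats::chisq.test(table, correct = corrected)
    method <- ht$method
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, method = method)
}

#' Exact McNemar test for paired binary outcomes
#'
#' Tests whether the marginal proportion of a binary outcome differs
#' between two conditions measured on the same participants. The
#' default is the exact binomial form: under the null the `b`
#' discordant pairs of one kind among the `b + c` discordant pairs
#' are Binomial(b + c, 1/2), and the p-value is the doubled smaller
#' tail (capped at 1). With no discordant pairs the test carries no
#' information and `p = 1` by convention. A chi-squared approximation
#' (with continuity correction) is available for larger samples.
#'
#' @param outcome_a,outcome_b Logical (or 0/1) vectors of equal
#'   length: the per-participant outcome in each condition.
#' @param exact Use the exact binomial form (default TRUE).
#' @return List with `b`, `c` (discordant counts), `p`, `method`.
#' @examples
#' mcnemar_test(c(TRUE, TRUE, TRUE, TRUE, TRUE),
#'              c(FALSE, FALSE, FALSE, FALSE, FALSE))$p # 0.0625
#' @export
mcnemar_test <- function(outcome_a, outcome_b, exact = TRUE) {
  stopifnot(length(outcome_a) == length(outcome_b),
            length(outcome_a) >= 1L)
  a <- as.logical(outcome_a); b_ <- as.logical(outcome_b)
  b <- sum(a & !b_)   # discordant: yes in A, no in B
  cc <- sum(!a & b_)  # discordant: no in A, yes in B
  if (b + cc == 0L) {
    p <- 1
    method <- "Exact McNemar (no discordant pairs; p = 1 by convention)"
  } else if (exact) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    method <- "Exact McNemar (binomial on discordant pairs)"
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "McNemar chi-squared approximation (corrected)"
  }
  list(b = b, c = cc, p = p, method = method)
}

#' Proportion of preferred-hand use by group, condition and trial
#'
#' Counts and proportions of `"P"` selections among records in the
#' preferred frame. Bimanual (`"both"`) records are excluded from
#' numerator and denominator and reported in `n_both`. Groups with no
#' usable records are dropped with a warning.
#'
#' @param records Data frame in the preferred frame with a `hand`
#'   column (`"P"`/`"NP"`/`"both"`).
#' @param by Character vector of grouping column names present in
#'   `records` (default `c("condition", "label")`).
#' @return Data frame with the grouping columns plus `n`, `n_both`,
#'   `prop_preferred`.
#' @export
proportion_table <- function(records, by = c("condition", "label")) {
  stopifnot(nrow(records) > 0L, all(by %in% names(records)))
  both <- records$hand == "both"
  groups <- records[by]
  n_both <- stats::aggregate(list(n_both = both), by = groups, FUN = sum)
  use <- records[!both, , drop = FALSE]
  if (nrow(use) == 0L) {
    warning("all records are bimanual; no proportions computable")
    n_both$n <- 0L
    n_both$prop_preferred <- NA_real_
    return(n_both)
  }
  agg <- stats::aggregate(list(n = rep(1L, nrow(use)),
                               n_pref = use$hand == "P"),
                          by = use[by], FUN = sum)
  agg$prop_preferred <- agg$n_pref / agg$n
  out <- merge(agg, n_both, by = by, all = TRUE)
  dropped <- is.na(out$n)
  if (any(dropped)) {
    warning(sum(dropped), " group(s) with only bimanual records omitted")
    out <- out[!dropped, , drop = FALSE]
  }
  out$n_pref <- NULL
  rownames(out) <- NULL
  out
}

#' Synthetic behavioral-record cohort
#'
#' Generates trial-level records with independent Bernoulli
#' preferred-hand choices at configurable per-trial probabilities, so
#' the statistics layer can be exercised without any study data. One
#' participant contributes one record per condition and trial label.
#'
#' @param n_per_group Number of participants.
#' @param probs Named list: for each condition, a named numeric
#'   vector of per-trial probabilities of choosing the preferred
#'   hand, e.g. `list(control = c(T3 = 1, N1 = 0.9), test = ...)`.
#'   All probabilities must lie in `[0, 1]`.
#' @param seed Integer seed.
#' @param age_group Optional age-group label for the records.
#' @return Data frame with columns `participant`, `age_group`,
#'   `condition`, `label`, `hand` (`"P"`/`"NP"`).
#' @examples
#' rec <- generate_fixture_cohort(
#'   20, list(control = c(N1 = 1)), seed = 1)
#' table(rec$hand) # all "P"
#' @export
generate_fixture_cohort <- function(n_per_group, probs, seed,
                                    age_group = NA_character_) {
  stopifnot(n_per_group >= 1, is.list(probs), length(probs) >= 1)
  pv <- unlist(probs)
  if (any(!is.finite(pv)) || any(pv < 0) || any(pv > 1))
    stop("selection probabilities must lie in [0, 1]")
  set.seed(seed)
  rows <- list()
  for (cond in names(probs)) {
    p <- probs[[cond]]
    for (lab in names(p)) {
      is_p <- stats::runif(n_per_group) < p[[lab]]
      rows[[paste(cond, lab)]] <- data.frame(
        participant = seq_len(n_per_group), age_group = age_group,
        condition = cond, label = lab,
        hand = ifelse(is_p, "P", "NP"), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
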