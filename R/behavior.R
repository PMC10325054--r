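#' Behavior trial table
#'
#' Validates and classes a scored turning-trial table with columns
#' `animal_id`, `trial`, `side` (left/right), `stim_type`
#' (hand/cardboard), `treatment`, `response` (toward/away/none, scored
#' relative to the stimulus side).
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame with class `behavior_trial_table`.
#' @export
behavior_trial_table <- function(df) {
  need <- c("animal_id", "trial", "side", "stim_type", "treatment", "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$response), c("toward", "away", "none"))
  if (length(bad)) {
    stop("response values outside {toward, away, none}: ",
         paste(bad, collapse = ", "))
  }
  class(df) <- unique(c("behavior_trial_table", class(df)))
  df
}

#' Per-animal turn summary
#'
#' Counts toward/away/none responses and the fraction of all trials
#' that were toward-turns, per animal (optionally within one treatment).
#'
#' @param table A [behavior_trial_table()].
#' @param treatment Optional treatment filter.
#' @return Data frame (`animal_id`, `n_toward`, `n_away`, `n_none`,
#'   `n_trials`, `fraction_toward`).
#' @export
turn_summary <- function(table, treatment = NULL) {
  if (!is.null(treatment)) table <- table[table$treatment %in% treatment, ]
  if (!nrow(table)) stop("no trials after filtering")
  sp <- split(table$response, table$animal_id)
  rows <- lapply(names(sp), function(a) {
    r <- sp[[a]]
    data.frame(animal_id = a,
               n_toward = sum(r == "toward"),
               n_away = sum(r == "away"),
               n_none = sum(r == "none"),
               n_trials = length(r),
               fraction_toward = mean(r == "toward"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Direction-bias test of turning responses
#'
#' Chi-square goodness-of-fit (1 df, no continuity correction) of
#' toward vs away counts against equal expected frequencies, with
#' no-reaction trials excluded. Tests whether reactive turns are biased
#' toward the stimulus side.
#'
#' @param table A [behavior_trial_table()], or `NULL` when passing
#'   `counts` directly.
#' @param stimulus_type Optional stimulus-type filter (e.g. `"hand"`).
#' @param counts Optional length-2 numeric `c(toward, away)` to test
#'   printed counts directly.
#' @return List with `n_toward`, `n_away`, `chi_sq`, `df`, `p`.
#' @export
#' @examples
#' direction_bias_test(counts = c(31, 7))$p  # < 0.001
direction_bias_test <- function(table = NULL, stimulus_type = NULL,
                                counts = NULL) {
  if (is.null(counts)) {
    if (is.null(table)) stop("give a trial table or explicit counts")
    if (!is.null(stimulus_type)) {
      table <- table[table$stim_type %in% stimulus_type, ]
    }
    counts <- c(sum(table$response == "toward"),
                sum(table$response == "away"))
  }
  if (length(counts) != 2 || any(counts < 0)) {
    stop("counts must be two nonnegative numbers (toward, away)")
  }
  if (sum(counts) < 1) stop("no reactive trials (toward + away = 0)")
  ct <- suppressWarnings(stats::chisq.test(counts))
  list(n_toward = counts[1], n_away = counts[2],
       chi_sq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Fisher comparison of toward-rates between stimulus strengths
#'
#' Two-sided Fisher's exact test on the 2x2 table of toward vs
#' not-toward responses across two stimulus types (default hand vs
#' cardboard).
#'
#' @param table A [behavior_trial_table()], or `NULL` with `tab` given.
#' @param types Length-2 character of stimulus types to compare.
#' @param tab Optional explicit 2x2 count matrix
#'   (rows = stimulus types, columns = toward / not-toward).
#' @return List with `table` (the 2x2 matrix), `p`, `odds_ratio`.
#' @export
stimulus_strength_comparison <- function(table = NULL,
                                         types = c("hand", "cardboard"),
                                         tab = NULL) {
  if (is.null(tab)) {
    if (is.null(table)) stop("give a trial table or an explicit 2x2 table")
    sub <- table[table$stim_type %in% types, ]
    if (!all(types %in% sub$stim_type)) {
      stop("both stimulus types must be present")
    }
    tab <- t(vapply(types, function(ty) {
      r <- sub$response[sub$stim_type == ty]
      c(toward = sum(r == "toward"), other = sum(r != "toward"))
    }, numeric(2)))
  }
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in the 2x2 table")
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Unpaired comparison of per-animal toward-fractions
#'
#' Mann-Whitney rank-sum test (exact for small samples, tie-corrected)
#' of per-animal toward-fractions between two treatment groups. The
#' sampling unit is the animal.
#'
#' @param table A [behavior_trial_table()].
#' @param group_a,group_b Treatment labels of the two groups.
#' @param alternative Test sidedness.
#' @return List with `summary_a`, `summary_b` (per-animal turn
#'   summaries), `U`, `p`, `exact`.
#' @export
group_turn_comparison <- function(table, group_a, group_b,
                                  alternative = "two.sided") {
  sa <- turn_summary(table, group_a)
  sb <- turn_summary(table, group_b)
  if (nrow(sa) < 2 || nrow(sb) < 2) {
    stop("each group needs >= 2 animals")
  }
  ts <- rank_sum_test(sa$fraction_toward, sb$fraction_toward,
                      alternative = alternative)
  list(summary_a = sa, summary_b = sb, U = ts$statistic, p = ts$p,
       exact = ts$exact)
}

#' Paired comparison of per-animal toward-fractions
#'
#' Wilcoxon signed-rank test (exact for small samples; zero differences
#' dropped) of per-animal toward-fractions between two treatments
#' administered to the same animals, plus the count of animals whose
#' fraction decreased under the first treatment.
#'
#' @param table A [behavior_trial_table()] in which every animal has
#'   trials under both treatments.
#' @param treatment_a,treatment_b The two treatment labels (e.g.
#'   `"lidocaine"` vs `"ringer"`).
#' @param alternative Test sidedness.
#' @return List with `paired` (data frame of per-animal fractions and
#'   differences), `V`, `p`, `n_decreases`, `exact`.
#' @export
paired_turn_comparison <- function(table, treatment_a = "lidocaine",
                                   treatment_b = "ringer",
                                   alternative = "two.sided") {
  sa <- turn_summary(table, treatment_a)
  sb <- turn_summary(table, treatment_b)
  unpaired <- c(setdiff(sa$animal_id, sb$animal_id),
                setdiff(sb$animal_id, sa$animal_id))
  if (length(unpaired)) {
    stop("animal(s) without both treatments: ",
         paste(unique(unpaired), collapse = ", "))
  }
  sb <- sb[match(sa$animal_id, sb$animal_id), ]
  diffs <- sa$fraction_toward - sb$fraction_toward
  ts <- signed_rank_test(diffs, mu = 0, alternative = alternative)
  list(paired = data.frame(animal_id = sa$animal_id,
                           fraction_a = sa$fraction_toward,
                           fraction_b = sb$fraction_toward,
                           difference = diffs,
                           stringsAsFactors = FALSE),
       V = ts$statistic, p = ts$p,
       n_decreases = sum(diffs < 0), exact = ts$exact)
}
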