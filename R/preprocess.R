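subset_dataset <- function(data, keep) {
  structure(list(responses = data$responses[keep, , drop = FALSE],
                 group = data$group[keep], age = data$age[keep],
                 sex = data$sex[keep], community = data$community),
            class = "survey_dataset")
}

#' Remove straight-lining respondents
#'
#' Drops every respondent who gave the identical answer to all items of the
#' combined measures, a disengagement pattern that carries no relational
#' information and distorts correlations.  Row order of the remaining
#' respondents is preserved.
#'
#' @param data a `survey_dataset`.
#' @return list with `data` (filtered dataset) and `n_excluded`.
#' @export
filter_straightliners <- function(data) {
  resp <- data$responses
  constant <- apply(resp, 1, function(r) all(r == r[1]))
  list(data = subset_dataset(data, !constant),
       n_excluded = sum(constant))
}

#' Retain respondents inside a closed age interval
#'
#' @param data a `survey_dataset`.
#' @param min_age,max_age inclusive bounds in integer years.
#' @return list with `data` and `n_excluded`.
#' @export
filter_age <- function(data, min_age = 20, max_age = 29) {
  if (min_age > max_age) stop("min_age must not exceed max_age", call. = FALSE)
  keep <- data$age >= min_age & data$age <= max_age
  list(data = subset_dataset(data, keep), n_excluded = sum(!keep))
}

#' Rescale summed scale scores to 0-100
#'
#' Linear transform `(x - min) / (max - min) * 100` used to put scales with
#' different item counts on a comparable footing.
#'
#' @param scale_scores per-respondent summed scores.
#' @param min_possible,max_possible the scale's attainable score range.
#' @return scores on the 0-100 scale.
#' @export
rescale_scores <- function(scale_scores, min_possible, max_possible) {
  if (max_possible <= min_possible) {
    stop("max_possible must exceed min_possible", call. = FALSE)
  }
  if (any(scale_scores < min_possible | scale_scores > max_possible)) {
    stop("scores outside the possible range", call. = FALSE)
  }
  (scale_scores - min_possible) / (max_possible - min_possible) * 100
}

#' Cronbach's alpha internal consistency
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(row sums))`, with
#' the `n - 1` variance denominator used throughout.
#'
#' @param items respondent-by-item numeric matrix.
#' @return the alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2 || nrow(items) < 2) {
    stop("need at least 2 items and 2 respondents", call. = FALSE)
  }
  total_var <- var(rowSums(items))
  if (total_var <= 0) {
    stop("total score variance is zero; alpha undefined", call. = FALSE)
  }
  item_var <- sum(apply(items, 2, var))
  k / (k - 1) * (1 - item_var / total_var)
}

# Hittner et al. (2003) back-transformed-average z test for two dependent
# overlapping correlations r_jk and r_jh sharing variable j, where r_kh is
# the correlation between the two non-shared variables.
hittner_test <- function(r_jk, r_jh, r_kh, n) {
  clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z_jk <- atanh(clamp(r_jk))
  z_jh <- atanh(clamp(r_jh))
  rm_ <- tanh((z_jk + z_jh) / 2)
  cvar <- (r_kh * (1 - 2 * rm_^2) - 0.5 * rm_^2 * (1 - 2 * rm_^2 - r_kh^2)) /
    (1 - rm_^2)^2
  denom <- 2 - 2 * cvar
  num <- (z_jk - z_jh) * sqrt(n - 3)
  z <- if (abs(num) < 1e-14) 0 else if (denom <= 0) sign(num) * Inf else
    num / sqrt(denom)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Screen item pairs for topological overlap
#'
#' Flags near-redundant item pairs: pairs with `|r| >= r_threshold` whose
#' correlation profiles with the remaining items are statistically
#' indistinguishable.  For each candidate pair (a, b) and every third item c,
#' the dependent correlations `r(a,c)` and `r(b,c)` are compared with the
#' Hittner back-transformed-average z test; the comparison counts as "unique"
#' when significant at `alpha`.  A pair is flagged when the fraction of
#' unique comparisons falls below `unique_frac`.
#'
#' @param items respondent-by-item matrix (at least 3 items).
#' @param r_threshold absolute correlation above which a pair is examined.
#' @param unique_frac minimum fraction of distinguishable third-item profiles
#'   a legitimate pair must show.
#' @param alpha significance level of the dependent-correlation test.
#' @param method correlation method passed to [stats::cor()].
#' @return data frame of flagged pairs with columns `item_i`, `item_j`, `r`,
#'   `prop_unique`; attribute `method` records the correlation type used.
#' @export
detect_topological_overlap <- function(items, r_threshold = 0.7,
                                       unique_frac = 0.2, alpha = 0.05,
                                       method = "pearson") {
  items <- as.matrix(items)
  p <- ncol(items)
  if (p < 3) stop("need at least 3 items", call. = FALSE)
  n <- nrow(items)
  R <- cor(items, method = method)
  nm <- colnames(items)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))

  out <- list()
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      if (abs(R[a, b]) < r_threshold) next
      third <- setdiff(seq_len(p), c(a, b))
      sig <- vapply(third, function(cc) {
        hittner_test(R[a, cc], R[b, cc], R[a, b], n)$p < alpha
      }, logical(1))
      prop <- mean(sig)
      if (prop < unique_frac) {
        out[[length(out) + 1]] <- data.frame(item_i = nm[a], item_j = nm[b],
                                             r = R[a, b], prop_unique = prop)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(item_i = character(0), item_j = character(0),
               r = numeric(0), prop_unique = numeric(0))
  attr(res, "method") <- method
  res
}

#' Clean a survey dataset and produce an accounting report
#'
#' Applies straight-liner exclusion then age subsetting, computes per-scale
#' Cronbach's alpha on the retained sample and screens for topological
#' overlap.
#'
#' @param data a `survey_dataset`.
#' @param min_age,max_age closed age interval to retain.
#' @param goldbricker_r,goldbricker_unique_frac,goldbricker_alpha overlap
#'   screening thresholds (see [detect_topological_overlap()]).
#' @return list with `data` (cleaned dataset) and `report`, a
#'   `cleaning_report` holding exclusion counts, per-community alphas and
#'   flagged overlap pairs.
#' @export
clean_survey <- function(data, min_age = 20, max_age = 29,
                         goldbricker_r = 0.7, goldbricker_unique_frac = 0.2,
                         goldbricker_alpha = 0.05) {
  n_input <- nrow(data$responses)
  st <- filter_straightliners(data)
  ag <- filter_age(st$data, min_age, max_age)
  cleaned <- ag$data

  alphas <- list()
  flagged <- NULL
  if (nrow(cleaned$responses) >= 2) {
    for (cm in unique(cleaned$community)) {
      cols <- names(cleaned$community)[cleaned$community == cm]
      if (length(cols) >= 2) {
        alphas[[cm]] <- tryCatch(
          cronbach_alpha(cleaned$responses[, cols, drop = FALSE]),
          error = function(e) NA_real_)
      }
    }
    if (ncol(cleaned$responses) >= 3 && nrow(cleaned$responses) >= 10) {
      flagged <- detect_topological_overlap(
        cleaned$responses, r_threshold = goldbricker_r,
        unique_frac = goldbricker_unique_frac, alpha = goldbricker_alpha)
    }
  }

  report <- structure(list(n_input = n_input,
                           n_excluded_straightline = st$n_excluded,
                           n_excluded_age = ag$n_excluded,
                           n_final = nrow(cleaned$responses),
                           alpha_by_scale = alphas,
                           flagged_overlap_pairs = flagged,
                           correlation_method = "pearson"),
                      class = "cleaning_report")
  list(data = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(paste0("cleaning_report: %d -> %d respondents ",
                     "(%d straight-liners, %d outside age range)\n"),
              x$n_input, x$n_final, x$n_excluded_straightline,
              x$n_excluded_age))
  for (nm in names(x$alpha_by_scale)) {
    cat(sprintf("  alpha[%s] = %.3f\n", nm, x$alpha_by_scale[[nm]]))
  }
  nf <- if (is.null(x$flagged_overlap_pairs)) 0 else
    nrow(x$flagged_overlap_pairs)
  cat(sprintf("  %d overlapping item pair(s) flagged\n", nf))
  invisible(x)
}
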