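#' Coefficient of determination of a simple linear regression
#'
#' Ordinary least-squares r-squared of `y` on `x`, used to relate the
#' individual network measures to age and to the individual mu peak
#' frequency.
#'
#' @param x predictor vector (e.g. age in months).
#' @param y response vector (one network measure per subject).
#' @return scalar r-squared.
#' @export
regress_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (var(x) == 0) stop("undefined r-squared: constant predictor",
                        call. = FALSE)
  summary(lm(y ~ x))$r.squared
}

#' Mixed-design group x condition ANOVA
#'
#' Fits the 5 (age groups) x 2 (conditions) design for one measure:
#' group is a between-subject factor, condition a within-subject
#' (repeated) factor, so the model is
#' `measure ~ group * condition + Error(subject / condition)`.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)` with the
#' error term of the effect's own stratum.
#'
#' @param tbl long-format cohort table: one row per subject x condition
#'   with columns `subject_id`, `group`, `condition` and the measures.
#' @param measure name of the measure column to analyse.
#' @return data.frame with one row per effect (`group`, `condition`,
#'   `group:condition`) and columns `effect`, `F`, `df_num`, `df_den`,
#'   `p`, `eta_p2`.
#' @export
mixed_anova <- function(tbl, measure) {
  stopifnot(measure %in% names(tbl))
  tbl <- as.data.frame(tbl)
  cnt <- table(tbl$subject_id)
  if (any(cnt != 2L)) {
    stop("invalid design: every subject needs exactly one row per condition",
         call. = FALSE)
  }
  per_group <- table(tbl$group[!duplicated(tbl$subject_id)])
  if (any(per_group < 2L)) {
    stop("invalid design: every group needs at least 2 subjects",
         call. = FALSE)
  }
  df <- data.frame(y = tbl[[measure]],
                   group = factor(tbl$group),
                   condition = factor(tbl$condition),
                   subject = factor(tbl$subject_id))
  fit <- aov(y ~ group * condition + Error(subject / condition), data = df)
  sm <- summary(fit)
  between <- sm[["Error: subject"]][[1L]]
  within <- sm[["Error: subject:condition"]][[1L]]

  pick <- function(stratum, label) {
    rn <- trimws(rownames(stratum))
    i <- match(label, rn)
    r <- match("Residuals", rn)
    ss_e <- stratum[i, "Sum Sq"]
    ss_r <- stratum[r, "Sum Sq"]
    data.frame(effect = label,
               F = stratum[i, "F value"],
               df_num = stratum[i, "Df"],
               df_den = stratum[r, "Df"],
               p = stratum[i, "Pr(>F)"],
               eta_p2 = if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r) else 0,
               stringsAsFactors = FALSE)
  }
  out <- rbind(pick(between, "group"),
               pick(within, "condition"),
               pick(within, "group:condition"))
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected pairwise group comparisons
#'
#' Compares all group pairs on condition-averaged subject means with
#' pooled-SD two-sample t tests; raw p values are multiplied by the
#' number of comparisons and capped at 1.
#'
#' @param tbl long-format cohort table (see [mixed_anova()]).
#' @param measure measure column name.
#' @return data.frame with columns `group1`, `group2`, `mean_diff`
#'   (group1 - group2), `p_raw`, `p_adj`.
#' @export
bonferroni_posthoc <- function(tbl, measure) {
  stopifnot(measure %in% names(tbl))
  tbl <- as.data.frame(tbl)
  subj <- aggregate(tbl[[measure]],
                    by = list(subject_id = tbl$subject_id,
                              group = tbl$group),
                    FUN = mean)
  names(subj)[3L] <- "y"
  per_group <- table(subj$group)
  if (any(per_group < 2L)) {
    stop("invalid design: every group needs at least 2 subjects",
         call. = FALSE)
  }
  groups <- sort(unique(as.character(subj$group)))
  pairs <- utils::combn(groups, 2L)
  n_cmp <- ncol(pairs)
  # pooled SD across all groups (classical post-hoc after ANOVA)
  ss <- sum(tapply(subj$y, subj$group,
                   function(v) sum((v - mean(v))^2)))
  df_err <- nrow(subj) - length(groups)
  s_pool <- sqrt(ss / df_err)
  out <- lapply(seq_len(n_cmp), function(k) {
    g1 <- pairs[1L, k]
    g2 <- pairs[2L, k]
    y1 <- subj$y[subj$group == g1]
    y2 <- subj$y[subj$group == g2]
    se <- s_pool * sqrt(1 / length(y1) + 1 / length(y2))
    tval <- (mean(y1) - mean(y2)) / se
    p_raw <- 2 * pt(-abs(tval), df_err)
    data.frame(group1 = g1, group2 = g2,
               mean_diff = mean(y1) - mean(y2),
               p_raw = p_raw,
               p_adj = min(1, p_raw * n_cmp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
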