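#' Mean occupancy of a feature interval
#'
#' Average of the defined per-bp track values within `[start, end)`.
#' Returns `NA` when no position is defined, or when the feature is
#' shorter than `min_length` — for model-predicted occupancy a feature
#' must be at least one contact length (129 bp) long to support a
#' prediction at all, so callers scoring predicted tracks pass
#' `min_length = geom$contact_len`.
#'
#' @param track an `occupancy_track`.
#' @param start,end 0-based half-open interval.
#' @param min_length minimum feature length in bp to be scored.
#' @return mean occupancy, or `NA`.
#' @export
mean_feature_occupancy <- function(track, start, end, min_length = 0L) {
  stopifnot(inherits(track, "occupancy_track"), start < end)
  if (end - start < min_length) return(NA_real_)
  v <- track_values_at(track, start:(end - 1L))
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Per-family Spearman correlations of occupancy with sequence traits
#'
#' For every family and every (occupancy kind, correlate) pair, computes
#' the Spearman rank correlation across the family's members with a
#' two-sided p-value.  Members missing either value are dropped
#' pairwise; a family is reported untested for a pair when fewer than
#' `min_family_size` usable pairs remain or when either variable has
#' zero variance within the family.
#'
#' @param data data frame with one row per feature, containing
#'   `family_id`, the occupancy columns and the correlate columns.
#' @param occupancy_cols named character vector mapping an occupancy
#'   kind label (e.g. `"predicted"`, `"experimental"`) to its column.
#' @param correlates character vector of correlate column names
#'   (e.g. `c("gc_content", "identity", "divergence")`).
#' @param alpha two-sided significance threshold (no multiple-testing
#'   correction; per-family counts are reported raw).
#' @param min_family_size minimum usable pairs for a family to be
#'   tested.
#' @param exact_max_n use the exact permutation p-value when the family
#'   has at most this many usable pairs (and no ties); larger families
#'   use the large-sample t approximation.
#' @return data frame with columns `family_id`, `kind`, `correlate`,
#'   `n`, `rho`, `p`, `tested`, `significant`, `sign`.
#' @export
family_correlations <- function(data, occupancy_cols,
                                correlates = c("gc_content", "identity",
                                               "divergence"),
                                alpha = 0.05, min_family_size = 5L,
                                exact_max_n = 10L) {
  stopifnot("family_id" %in% names(data),
            all(occupancy_cols %in% names(data)),
            all(correlates %in% names(data)),
            alpha > 0, alpha < 1)
  kinds <- names(occupancy_cols)
  rows <- list()
  for (fam in unique(data$family_id)) {
    d <- data[data$family_id == fam, , drop = FALSE]
    for (k in kinds) {
      for (cr in correlates) {
        x <- d[[cr]]
        y <- d[[occupancy_cols[[k]]]]
        ok <- !is.na(x) & !is.na(y)
        n <- sum(ok)
        rho <- NA_real_; p <- NA_real_; tested <- FALSE
        if (n >= min_family_size &&
            stats::var(x[ok]) > 0 && stats::var(y[ok]) > 0) {
          ct <- suppressWarnings(
            stats::cor.test(x[ok], y[ok], method = "spearman",
                            alternative = "two.sided",
                            exact = n <= exact_max_n))
          rho <- unname(ct$estimate)
          p <- ct$p.value
          tested <- TRUE
        }
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = fam, kind = k, correlate = cr, n = n,
          rho = rho, p = p, tested = tested,
          significant = tested && !is.na(p) && p < alpha,
          sign = ifelse(is.na(rho), NA_integer_, as.integer(sign(rho))),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary of per-family correlations
#'
#' Collapses [family_correlations()] output into counts per
#' (kind, correlate): families tested, significant, significant with
#' positive rho, and the mean of the significant correlation
#' coefficients (NA when none are significant).
#'
#' @param summaries output of [family_correlations()].
#' @return data frame with columns `kind`, `correlate`,
#'   `n_families_tested`, `n_significant`, `n_significant_positive`,
#'   `mean_significant_rho`.
#' @export
summarize_cohort <- function(summaries) {
  key <- unique(summaries[c("kind", "correlate")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    s <- summaries[summaries$kind == key$kind[i] &
                   summaries$correlate == key$correlate[i], , drop = FALSE]
    sig <- s$tested & s$significant
    data.frame(kind = key$kind[i], correlate = key$correlate[i],
               n_families_tested = sum(s$tested),
               n_significant = sum(sig),
               n_significant_positive = sum(sig & s$rho > 0),
               mean_significant_rho =
                 if (any(sig)) mean(s$rho[sig]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of per-feature mean occupancy between groups
#'
#' Classical fixed-effects one-way analysis of variance (equal-variance
#' F test) of feature-level mean occupancy across groups, e.g.
#' transcribed vs nontranscribed features.
#'
#' @param values numeric per-feature means (`NA` dropped).
#' @param groups group label per feature.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
group_anova <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(as.character(groups[ok]))
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("ANOVA needs at least 2 groups with at least 2 members each")
  }
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ss_between <- sum(sizes * (means - grand)^2)
  df1 <- length(sizes) - 1L
  df2 <- length(values) - length(sizes)
  if (ss_between == 0) {
    # identical group means (incl. all-constant data): no effect at all
    return(list(F = 0, p = 1, df_between = df1, df_within = df2))
  }
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ht$statistic), p = ht$p.value,
       df_between = unname(ht$parameter[1L]),
       df_within = unname(ht$parameter[2L]))
}
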