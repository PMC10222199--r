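#' Per-group ANOVA effects on the property
#'
#' Quantifies the linear effects hiding inside the clustering fit: each
#' non-residual functional group becomes a binary presence factor per
#' sample, and the property is decomposed by a sequential
#' (type-I) ANOVA in group order (A, B, ...) with all pairwise interactions
#' entered after the main effects. Effects are expressed as percentages of
#' the median property:
#' \code{effect_pct(G) = 100 (mean(y | G) - median(y)) / |median(y)|}, and
#' for a pair the double difference
#' \code{mean(y | G,H) - mean(y | G only) - mean(y | H only) + mean(y | neither)}
#' on the same scale. Significance is flagged at p < 0.001.
#'
#' @param encoding a \code{class_encoding}.
#' @param y property vector.
#' @param partition an ordered \code{\link{functional_partition}} (residual
#'   group last; it is excluded from the factors).
#' @param alpha significance threshold; default 0.001.
#' @return a \code{group_effects} object: \code{main} and
#'   \code{interactions} data.frames (effect_pct, p_value, significant) and
#'   \code{median_property}. Groups present in no or in every sample are
#'   dropped with a warning; when the median property is zero, effects are
#'   reported in raw property units and flagged via \code{scaled = FALSE}.
#' @export
group_anova_effects <- function(encoding, y, partition, alpha = 0.001) {
  y <- as.numeric(y)
  resid <- residual_group(partition)
  groups <- setdiff(partition$group_order, resid)
  if (length(groups) == 0L)
    stop("partition has no non-residual group", call. = FALSE)
  pres <- group_presence(
    encoding$indicators[, names(partition$assignment), drop = FALSE],
    partition$assignment, partition$group_order)[, groups, drop = FALSE]
  keep <- colMeans(pres) > 0 & colMeans(pres) < 1
  if (any(!keep))
    warning("dropping factor(s) with no contrast (present in none or all samples): ",
            paste(groups[!keep], collapse = ", "))
  groups <- groups[keep]
  pres <- pres[, keep, drop = FALSE]
  if (length(groups) == 0L)
    stop("no group factor with contrast remains", call. = FALSE)

  med <- stats::median(y)
  scaled <- med != 0
  scale_fun <- function(delta)
    if (scaled) 100 * delta / abs(med) else delta
  if (!scaled)
    warning("median property is zero: effects reported in raw units")

  dat <- data.frame(y = y, lapply(as.data.frame(pres), factor))
  names(dat) <- c("y", groups)
  form <- if (length(groups) >= 2)
    stats::as.formula(paste("y ~ (", paste(sprintf("`%s`", groups),
                                           collapse = " + "), ")^2"))
  else stats::as.formula(sprintf("y ~ `%s`", groups))
  av <- stats::aov(form, data = dat)
  st <- summary(av)[[1]]
  terms <- trimws(rownames(st))
  pvals <- st[["Pr(>F)"]]

  p_of <- function(term) {
    i <- match(term, gsub("`", "", terms))
    if (is.na(i)) NA_real_ else pvals[i]
  }
  main <- data.frame(
    group = groups,
    effect_pct = vapply(groups, function(g)
      scale_fun(mean(y[pres[, g]]) - med), 0),
    p_value = vapply(groups, p_of, 0),
    stringsAsFactors = FALSE)
  main$significant <- !is.na(main$p_value) & main$p_value < alpha

  inter <- data.frame(group1 = character(), group2 = character(),
                      effect_pct = numeric(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (length(groups) >= 2) {
    prs <- utils::combn(groups, 2)
    for (idx in seq_len(ncol(prs))) {
      g <- prs[1, idx]; h <- prs[2, idx]
      cells <- list(both = pres[, g] & pres[, h],
                    gonly = pres[, g] & !pres[, h],
                    honly = !pres[, g] & pres[, h],
                    neither = !pres[, g] & !pres[, h])
      eff <- if (all(vapply(cells, any, TRUE)))
        scale_fun(mean(y[cells$both]) - mean(y[cells$gonly]) -
                    mean(y[cells$honly]) + mean(y[cells$neither]))
      else NA_real_
      pv <- p_of(paste0(g, ":", h))
      inter[nrow(inter) + 1L, ] <- list(g, h, eff, pv,
                                        !is.na(pv) && pv < alpha)
    }
  }
  structure(list(main = main, interactions = inter,
                 median_property = med, scaled = scaled,
                 anova = st, alpha = alpha),
            class = "group_effects")
}

#' @export
print.group_effects <- function(x, ...) {
  unit <- if (x$scaled) "% of median" else "raw units"
  cat(sprintf("Group effects (%s; median property = %s)\n", unit,
              format(x$median_property)))
  for (i in seq_len(nrow(x$main)))
    cat(sprintf("  %s: %+.1f%s (p = %.3g)%s\n", x$main$group[i],
                x$main$effect_pct[i], if (x$scaled) "%" else "",
                x$main$p_value[i],
                if (isTRUE(x$main$significant[i])) " *" else ""))
  for (i in seq_len(nrow(x$interactions)))
    cat(sprintf("  %s:%s: %+.1f%s (p = %.3g)%s\n", x$interactions$group1[i],
                x$interactions$group2[i], x$interactions$effect_pct[i],
                if (x$scaled) "%" else "", x$interactions$p_value[i],
                if (isTRUE(x$interactions$significant[i])) " *" else ""))
  invisible(x)
}

#' Cross-route comparison of key families
#'
#' Classifies every family of the common universe by which selection route
#' retained it: \code{both}, \code{linear_only}, \code{clustering_only} or
#' \code{neither}. For families kept by the linear route the sign of the
#' fitted coefficient is reported; for families kept by the clustering
#' route, the best (leftmost in group order) functional group holding one
#' of the family's classes, with a significance marker from the group's
#' ANOVA p-value when effects are supplied.
#'
#' @param lm_trace \code{selection_trace} from
#'   \code{\link{backward_select_linear}}.
#' @param fclust_trace \code{selection_trace} from
#'   \code{\link{backward_select_families}}.
#' @param effects optional \code{group_effects} for significance markers.
#' @param alpha significance threshold; default 0.001.
#' @return list with \code{table} (per-family data.frame: category, linear
#'   sign, group letter, significant) and \code{percentages} (the four
#'   category percentages over the universe).
#' @export
compare_key_families <- function(lm_trace, fclust_trace, effects = NULL,
                                 alpha = 0.001) {
  u_lm <- lm_trace$initial_families
  u_fc <- fclust_trace$initial_families
  if (!setequal(u_lm, u_fc))
    stop("family universes differ; symmetric difference: ",
         paste(union(setdiff(u_lm, u_fc), setdiff(u_fc, u_lm)),
               collapse = ", "), call. = FALSE)
  universe <- u_lm
  kept_lm <- lm_trace$final$kept_families
  kept_fc <- fclust_trace$final$kept_families
  category <- ifelse(universe %in% kept_lm & universe %in% kept_fc, "both",
              ifelse(universe %in% kept_lm, "linear_only",
              ifelse(universe %in% kept_fc, "clustering_only", "neither")))
  coefs <- lm_trace$final$coefficients
  sign_lm <- vapply(universe, function(fam) {
    if (!fam %in% kept_lm || is.null(coefs) || is.na(coefs[fam])) return("")
    if (coefs[fam] >= 0) "+" else "-"
  }, "")
  part <- fclust_trace$final$partition
  group_letter <- vapply(universe, function(fam) {
    if (!fam %in% kept_fc || is.null(part)) return("")
    cls <- names(part$assignment)[
      sub("\\|\\d+/\\d+$", "", names(part$assignment)) == fam]
    if (length(cls) == 0) return("")
    gs <- part$assignment[cls]
    gs[which.min(match(gs, part$group_order))]
  }, "")
  significant <- rep(NA, length(universe))
  if (!is.null(effects)) {
    sig_groups <- effects$main$group[effects$main$significant]
    significant <- group_letter != "" & group_letter %in% sig_groups
  }
  tab <- data.frame(family = universe, category = category,
                    linear_sign = sign_lm, group = group_letter,
                    significant = significant,
                    row.names = NULL, stringsAsFactors = FALSE)
  pct <- 100 * vapply(c("both", "linear_only", "clustering_only", "neither"),
                      function(ct) mean(category == ct), 0)
  list(table = tab, percentages = pct)
}

#' Do key families differ from the rest in overall abundance?
#'
#' Kruskal-Wallis comparison of the per-family total read counts between
#' the families retained as key and those rejected, testing whether
#' selection merely tracked abundance. Uses the tie-corrected H statistic
#' with a chi-square p-value on k - 1 degrees of freedom.
#'
#' @param table an \code{\link{abundance_table}}.
#' @param key_families,nonkey_families non-empty disjoint character vectors
#'   of family identifiers present in \code{table}.
#' @return list with \code{statistic} (H), \code{p_value}, \code{df} and
#'   the underlying \code{htest}.
#' @export
median_abundance_check <- function(table, key_families, nonkey_families) {
  if (length(key_families) == 0 || length(nonkey_families) == 0)
    stop("both family sets must be non-empty", call. = FALSE)
  unknown <- setdiff(c(key_families, nonkey_families), colnames(table))
  if (length(unknown) > 0)
    stop("families absent from table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  totals <- colSums(unclass(table))
  ht <- stats::kruskal.test(list(key = totals[key_families],
                                 nonkey = totals[nonkey_families]))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), test = ht)
}
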