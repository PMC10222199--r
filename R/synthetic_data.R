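#' Planted functional-group truth for synthetic communities
#'
#' Describes the generative model used by
#' \code{\link{plant_partition_property}}: a partition of some key
#' abundance classes into functional groups (all other classes implicitly
#' residual and inert), a property mean per assembly motif — given directly
#' and/or built additively from per-group effects and pairwise interaction
#' increments — and Gaussian noise.
#'
#' @param planted_partition named character vector: class label -> group
#'   label, over the key classes only.
#' @param motif_means optional named numeric: motif label (group labels
#'   sorted and joined by \code{"+"}, \code{"(none)"} for the empty motif)
#'   -> mean property.
#' @param group_effects optional named numeric per-group additive effect;
#'   with \code{baseline} and \code{interaction_terms} it defines the mean
#'   of any motif not listed in \code{motif_means}.
#' @param baseline property mean of the empty motif under the additive rule.
#' @param interaction_terms optional named numeric, names like \code{"A+B"}.
#' @param noise_sd non-negative Gaussian noise standard deviation.
#' @param linear_component optional named numeric of per-family
#'   coefficients applied to relative abundances (a composition effect
#'   mixed into the property).
#' @param seed integer seed governing all draws.
#' @return object of class \code{synthetic_truth}.
#' @export
synthetic_truth <- function(planted_partition, motif_means = NULL,
                            group_effects = NULL, baseline = 0,
                            interaction_terms = NULL, noise_sd = 0,
                            linear_component = NULL, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (is.null(motif_means) && is.null(group_effects))
    stop("provide motif_means or group_effects", call. = FALSE)
  structure(list(planted_partition = planted_partition,
                 motif_means = motif_means,
                 group_effects = group_effects,
                 baseline = baseline,
                 interaction_terms = interaction_terms,
                 noise_sd = noise_sd,
                 linear_component = linear_component,
                 seed = as.integer(seed),
                 realized_motifs = NULL),
            class = "synthetic_truth")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate a sample-by-family count table
#'
#' Emulates the statistical regime of rarefied amplicon family tables:
#' each family j draws a target observation frequency f_j uniformly from
#' \code{freq_range}; presence per sample is Bernoulli(f_j); present cells
#' draw a heavy-tailed positive weight (rounded-up log-normal with a
#' family-specific location drawn once per family, giving a wide abundance
#' range with low medians); each sample's weights are then multinomially
#' resampled to exactly \code{reads_per_sample} reads, mirroring
#' rarefaction to fixed depth. A single seed governs all draws.
#'
#' @param n_samples number of samples (>= 2); default 57.
#' @param n_families number of families (>= 1); default 60.
#' @param freq_range observation-frequency interval within (0, 1].
#' @param reads_per_sample fixed read depth; default 3000.
#' @param abundance_dispersion log-normal sdlog of within-family abundance.
#' @param seed integer seed.
#' @return an \code{\link{abundance_table}} whose rows all sum to
#'   \code{reads_per_sample}.
#' @export
simulate_abundance_table <- function(n_samples = 57L, n_families = 60L,
                                     freq_range = c(0.3, 1),
                                     reads_per_sample = 3000L,
                                     abundance_dispersion = 1.5,
                                     seed = 1L) {
  if (n_samples < 2L) stop("n_samples must be at least 2", call. = FALSE)
  if (n_families < 1L) stop("n_families must be at least 1", call. = FALSE)
  if (freq_range[1] <= 0 || freq_range[2] > 1 || freq_range[1] > freq_range[2])
    stop("freq_range must be an interval within (0, 1]", call. = FALSE)
  if (abundance_dispersion <= 0)
    stop("abundance_dispersion must be positive", call. = FALSE)
  with_seed(seed, {
    f <- stats::runif(n_families, freq_range[1], freq_range[2])
    meanlog <- stats::rnorm(n_families, mean = log(5), sd = 1.2)
    weights <- matrix(0, n_samples, n_families)
    for (j in seq_len(n_families)) {
      present <- stats::rbinom(n_samples, 1L, f[j]) == 1L
      if (!any(present)) present[sample.int(n_samples, 1L)] <- TRUE
      weights[present, j] <- ceiling(stats::rlnorm(sum(present), meanlog[j],
                                                   abundance_dispersion))
    }
    counts <- t(vapply(seq_len(n_samples), function(i) {
      w <- weights[i, ]
      if (all(w == 0)) w[sample.int(n_families, 1L)] <- 1
      as.integer(stats::rmultinom(1L, reads_per_sample, w))
    }, integer(n_families)))
    dimnames(counts) <- list(sprintf("s%02d", seq_len(n_samples)),
                             sprintf("fam%02d", seq_len(n_families)))
    out <- abundance_table(counts, community_label = "synthetic")
    attr(out, "target_frequencies") <- stats::setNames(f, colnames(counts))
    out
  })
}

truth_motif_mean <- function(truth, motif_label, groups) {
  if (!is.null(truth$motif_means) && motif_label %in% names(truth$motif_means))
    return(truth$motif_means[[motif_label]])
  if (!is.null(truth$group_effects)) {
    mu <- truth$baseline + sum(truth$group_effects[groups])
    if (!is.null(truth$interaction_terms) && length(groups) >= 2) {
      prs <- utils::combn(sort(groups), 2, function(p)
        paste(p, collapse = "+"))
      hit <- intersect(prs, names(truth$interaction_terms))
      mu <- mu + sum(truth$interaction_terms[hit])
    }
    return(mu)
  }
  stop(sprintf("realized motif '%s' has no defined mean and no additive rule",
               motif_label), call. = FALSE)
}

#' Generate a property from a planted partition of abundance classes
#'
#' The generative counterpart of the functional-clustering fit: each
#' sample's assembly motif is read off the planted partition (classes not
#' in the partition count as residual and do not enter the motif), its mean
#' is resolved from the truth, and Gaussian noise plus an optional linear
#' composition component are added:
#' \code{y_i = mean(motif_i) + N(0, noise_sd) + X_i beta}.
#'
#' @param encoding a \code{class_encoding} whose classes include the
#'   planted ones.
#' @param truth a \code{\link{synthetic_truth}}.
#' @param relab optional samples x families relative-abundance matrix,
#'   required when \code{truth$linear_component} is set.
#' @return a \code{\link{property_vector}} with attribute
#'   \code{realized_motifs} (per-sample motif labels) and
#'   \code{true_means} (the noiseless values).
#' @export
plant_partition_property <- function(encoding, truth, relab = NULL) {
  planted <- truth$planted_partition
  missing_cls <- setdiff(names(planted), encoding$classes$label)
  if (length(missing_cls) > 0)
    stop("planted classes absent from encoding: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  ind <- encoding$indicators[, names(planted), drop = FALSE]
  groups <- sort(unique(planted))
  pres <- group_presence(ind, planted, groups)
  motifs <- motif_labels_from_presence(pres)
  mu <- vapply(seq_along(motifs), function(i) {
    g <- groups[pres[i, ]]
    truth_motif_mean(truth, motifs[i], g)
  }, 0)
  lin <- 0
  if (!is.null(truth$linear_component)) {
    if (is.null(relab))
      stop("relab matrix required when truth has a linear_component",
           call. = FALSE)
    fams <- names(truth$linear_component)
    lin <- as.vector(relab[, fams, drop = FALSE] %*% truth$linear_component)
  }
  y <- with_seed(truth$seed,
                 mu + lin + stats::rnorm(length(mu), 0, truth$noise_sd))
  out <- property_vector(y, sample_ids = encoding$sample_ids,
                         label = "synthetic_property")
  attr(out, "realized_motifs") <- motifs
  attr(out, "true_means") <- mu
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two assignments of the same items;
#' 1 means identical partitions (up to relabelling), 0 is the expected
#' agreement of independent random partitions. Used to score planted-
#' partition recovery.
#'
#' @param a,b vectors of group labels over the same items.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Simulate a complete planted-truth study
#'
#' Convenience wrapper reproducing the whole synthetic study design used in
#' the parameter-recovery experiments: a rarefied count table, its class
#' encoding, a planted partition assigning one abundance class from each of
#' \code{n_groups * classes_per_group} distinct multi-class families to
#' \code{n_groups} functional groups (all other classes residual), additive
#' group effects on the property, and Gaussian noise scaled to a fraction
#' of the spread of the noiseless motif means.
#'
#' @param seed integer seed governing table and noise draws.
#' @param n_samples,n_families,reads_per_sample,freq_range passed to
#'   \code{\link{simulate_abundance_table}}.
#' @param n_groups number of planted functional groups.
#' @param classes_per_group planted classes per group, each from a distinct
#'   family.
#' @param noise_frac noise standard deviation as a fraction of the range of
#'   the noiseless motif means.
#' @param group_effects additive per-group property effects; defaults to
#'   distinct values so every assembly motif has a distinct mean.
#' @param baseline property mean of the empty motif.
#' @return list with \code{table}, \code{encoding}, \code{truth}, \code{y}
#'   and \code{true_assignment} (the planted class-to-group map over all
#'   classes, residual labelled \code{"(residual)"}).
#' @export
simulate_study <- function(seed = 1L, n_samples = 60L, n_families = 20L,
                           reads_per_sample = 3000L, freq_range = c(0.3, 1),
                           n_groups = 3L, classes_per_group = 3L,
                           noise_frac = 0.05,
                           group_effects = NULL, baseline = 10) {
  tab <- simulate_abundance_table(n_samples, n_families, freq_range,
                                  reads_per_sample, seed = seed)
  enc <- encode_all(tab)
  cls <- enc$classes
  # one top abundance class from each multi-class family: observation
  # frequency near 1/3, so planted groups show presence/absence contrast
  cand <- cls[cls$class_total >= 2 & cls$class_index == cls$class_total, ]
  need <- n_groups * classes_per_group
  if (nrow(cand) < need)
    stop(sprintf("only %d plantable classes for %d needed; increase n_families",
                 nrow(cand), need), call. = FALSE)
  planted_cls <- cand$label[seq_len(need)]
  glabs <- LETTERS[seq_len(n_groups)]
  planted <- stats::setNames(rep(glabs, each = classes_per_group), planted_cls)
  if (is.null(group_effects))
    group_effects <- stats::setNames(
      c(3, -2, 1.5, -1, 2.5, -0.5)[seq_len(n_groups)], glabs)
  motif_mu <- vapply(0:(2^n_groups - 1), function(m)
    baseline + sum(group_effects[bitwAnd(m, 2^(seq_len(n_groups) - 1)) > 0]),
    0)
  truth <- synthetic_truth(planted, group_effects = group_effects,
                           baseline = baseline,
                           noise_sd = noise_frac * diff(range(motif_mu)),
                           seed = seed)
  y <- plant_partition_property(enc, truth)
  true_assignment <- stats::setNames(
    rep("(residual)", ncol(enc$indicators)), colnames(enc$indicators))
  true_assignment[planted_cls] <- planted
  list(table = tab, encoding = enc, truth = truth, y = y,
       true_assignment = true_assignment)
}

#' Adjusted Rand index of planted-partition recovery
#'
#' Scores how well a fitted partition recovers a planted truth. The
#' comparison is made over the planted (key) classes plus one extra member
#' standing for the residual mass, so that a planted group silently merged
#' into the residual group is penalised, while the assignment of
#' non-planted noise classes — for which the truth defines no structure
#' beyond "residual" — does not dilute the score.
#'
#' @param truth a \code{\link{synthetic_truth}} (its
#'   \code{planted_partition} is the reference).
#' @param partition a fitted \code{\link{functional_partition}} covering
#'   the planted classes.
#' @return the adjusted Rand index in [-1, 1].
#' @export
recovery_ari <- function(truth, partition) {
  planted <- truth$planted_partition
  ref <- c(planted, "(residual-mass)" = "(residual)")
  rec <- c(partition$assignment[names(planted)],
           "(residual-mass)" = residual_group(partition))
  adjusted_rand_index(ref, rec)
}
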