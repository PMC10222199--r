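#' Construct a functional partition of abundance classes
#'
#' A functional partition assigns every relative-abundance class to exactly
#' one functional group. Groups are ordered by decreasing explanatory power
#' (labels A, B, ...) with the residual group — the default cluster of the
#' least significant classes — always last.
#'
#' @param assignment named character vector: class label -> group label.
#' @param group_order character vector of the group labels, residual last.
#' @return object of class \code{functional_partition}.
#' @export
functional_partition <- function(assignment,
                                 group_order = sort(unique(assignment))) {
  if (is.null(names(assignment)))
    stop("assignment must be a named vector (class -> group)", call. = FALSE)
  if (!setequal(unique(assignment), group_order))
    stop("group_order must list exactly the groups used in assignment",
         call. = FALSE)
  structure(list(assignment = assignment,
                 group_order = group_order,
                 n_groups = length(group_order)),
            class = "functional_partition")
}

#' @export
print.functional_partition <- function(x, ...) {
  cat(sprintf("Functional partition: %d classes in %d groups (residual: %s)\n",
              length(x$assignment), x$n_groups, residual_group(x)))
  for (g in x$group_order) {
    members <- names(x$assignment)[x$assignment == g]
    cat(sprintf("  %s: %s\n", g, paste(members, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname functional_partition
#' @param partition a \code{functional_partition}.
#' @export
residual_group <- function(partition) {
  partition$group_order[length(partition$group_order)]
}

# n x G logical matrix: group g present in sample i iff any member class is 1
group_presence <- function(indicators, assignment, group_order) {
  G <- length(group_order)
  pres <- matrix(FALSE, nrow(indicators), G,
                 dimnames = list(rownames(indicators), group_order))
  for (g in seq_len(G)) {
    members <- which(assignment == group_order[g])
    if (length(members) > 0)
      pres[, g] <- rowSums(indicators[, members, drop = FALSE]) > 0
  }
  pres
}

motif_labels_from_presence <- function(presence) {
  apply(presence, 1, function(row) {
    g <- colnames(presence)[row]
    if (length(g) == 0) "(none)" else paste(g, collapse = "+")
  })
}

#' Assembly motif of one sample
#'
#' The assembly motif is the set of functional groups represented in a
#' sample: group g belongs to the motif iff at least one class assigned to
#' g has indicator 1. Samples sharing a motif share a fitted property value.
#' An all-zero row yields the empty motif, itself a legitimate motif class.
#'
#' @param indicators one sample's binary class row (named by class labels),
#'   or a full sample x class matrix for several samples.
#' @param partition a \code{\link{functional_partition}}.
#' @return character vector of group labels present (single sample), or a
#'   character vector of motif labels like \code{"A+B"} (matrix input).
#' @export
motif_of_sample <- function(indicators, partition) {
  if (is.matrix(indicators)) {
    pres <- group_presence(indicators[, names(partition$assignment),
                                      drop = FALSE],
                           partition$assignment, partition$group_order)
    return(motif_labels_from_presence(pres))
  }
  ind <- indicators[names(partition$assignment)]
  present <- vapply(partition$group_order, function(g)
    any(ind[partition$assignment == g] > 0), TRUE)
  partition$group_order[present]
}

motif_ids_of_assignment <- function(indicators, assign_int, n_groups) {
  pres <- matrix(FALSE, nrow(indicators), n_groups)
  for (g in seq_len(n_groups)) {
    members <- which(assign_int == g)
    if (length(members) > 0)
      pres[, g] <- rowSums(indicators[, members, drop = FALSE]) > 0
  }
  as.vector(pres %*% 2^(seq_len(n_groups) - 1))
}

# residual sum of squares of the cell-mean fit over integer cell ids,
# via RSS = sum(y^2) - sum_c S_c^2 / n_c (no per-call factor machinery)
rss_of_ids <- function(y, ids) {
  f <- match(ids, unique(ids))
  s <- rowsum(y, f, reorder = FALSE)
  n_c <- tabulate(f)
  sum(y * y) - sum(s * s / n_c)
}

# R^2 of the motif-mean fit for an integer assignment vector (internal,
# used heavily by the greedy search and the exhaustive oracle)
r2_of_assignment <- function(indicators, y, assign_int, n_groups, tss) {
  ids <- motif_ids_of_assignment(indicators, assign_int, n_groups)
  1 - rss_of_ids(y - mean(y), ids) / tss
}

#' Fit a property by assembly-motif means
#'
#' The non-linear route's elementary fit: the fitted value of every sample
#' is the mean property over samples sharing its assembly motif, so the
#' explained variance is exactly the inter-motif variance fraction.
#'
#' @param encoding a \code{class_encoding}.
#' @param y property vector aligned to the encoding's samples.
#' @param partition a \code{\link{functional_partition}} over the encoding's
#'   classes.
#' @return a \code{model_fit} with route \code{"clustering"}: fitted motif
#'   means, \code{r2 = 1 - RSS/TSS}, one-way ANOVA
#'   \code{f_ratio = (SSB/(M-1))/(SSW/(n-M))} across the M observed motifs,
#'   AICc with \code{k = M}, and the per-sample motif labels in
#'   \code{$motifs}.
#' @export
fit_motif_means <- function(encoding, y, partition) {
  y <- as.numeric(y)
  ind <- encoding$indicators[, names(partition$assignment), drop = FALSE]
  n <- length(y)
  if (nrow(ind) != n) stop("encoding and y differ in length", call. = FALSE)
  if (stats::var(y) == 0)
    stop("property is constant across samples: nothing to explain",
         call. = FALSE)
  pres <- group_presence(ind, partition$assignment, partition$group_order)
  motifs <- motif_labels_from_presence(pres)
  M <- length(unique(motifs))
  fitted <- stats::ave(y, motifs)
  if (M == 1L)
    warning("a single assembly motif is observed: no variance explained")
  tss <- sum((y - mean(y))^2)
  rss <- sum((y - fitted)^2)
  f_ratio <- if (M > 1L && n > M)
    ((tss - rss) / (M - 1)) / (rss / (n - M))
  else NA_real_
  k <- min(M, n - 2L)  # AICc correction needs n - k - 1 > 0
  new_model_fit("clustering", fitted, y, k = k, n = n,
                kept_families = unique(
                  encoding$classes$family[encoding$classes$label %in%
                                            names(partition$assignment)]),
                f_ratio = f_ratio,
                residual_df = n - M,
                extra = list(motifs = motifs, n_motifs = M,
                             partition = partition))
}

#' Hierarchical functional-group tree
#'
#' Builds a hierarchy of partitions of the abundance classes into 1, 2, ...,
#' \code{max_groups} functional groups that explain the property by
#' assembly-motif means, and selects the most parsimonious level by AICc
#' computed with \code{k} = the number of observed assembly motifs.
#'
#' The search is deterministic and proceeds as a beam search over levels.
#' Level g+1 grows from each assignment kept at level g by seeding a new
#' group with each of the \code{n_restarts} single classes whose relocation
#' best increases R2; every seeded assignment is refined by
#' first-improvement moves (any class to any group, scanned in class input
#' order, until no move strictly increases R2), and the \code{n_restarts}
#' best distinct refinements form the next beam; the best one is recorded
#' as the level. The reported partition is the
#' AICc-polished assignment of the selected level: weakly informative
#' classes that the R2-maximising refinement pulled out of the residual
#' mass are returned to it whenever that improves AICc (k = observed motif
#' count), so the residual group keeps its role of default cluster of the
#' least significant classes.
#'
#' @param encoding a \code{class_encoding}.
#' @param y property vector.
#' @param max_groups deepest level to build (>= 2, <= number of classes).
#' @param n_restarts beam width: seeds tried per beam member and
#'   assignments carried between levels. Defaults to every class on small
#'   problems (up to 12 classes) and 5 otherwise.
#' @return a \code{cluster_tree}: \code{levels} (per level: integer
#'   assignment, r2, n_motifs, aicc), \code{selected} (index of the
#'   AICc-best polished level) and \code{partition}, the selected polished
#'   \code{\link{functional_partition}} relabelled by
#'   \code{\link{order_groups}} (groups A, B, ... by decreasing
#'   contribution, residual last).
#' @export
fit_tree <- function(encoding, y, max_groups = 6L, n_restarts = NULL) {
  y <- as.numeric(y)
  ind <- encoding$indicators
  m <- ncol(ind)
  if (is.null(n_restarts)) n_restarts <- if (m <= 12L) m else 5L
  if (m < 2L) stop("need at least 2 classes", call. = FALSE)
  if (max_groups < 2L) stop("max_groups must be >= 2", call. = FALSE)
  if (max_groups > m)
    stop(sprintf("max_groups (%d) exceeds the number of classes (%d)",
                 max_groups, m), call. = FALSE)
  tss <- sum((y - mean(y))^2)
  n <- length(y)

  levels <- list(level_record(ind, y, rep(1L, m), 1L, n, tss))
  beam <- list(rep(1L, m))
  for (g in 2L:max_groups) {
    # candidate seeds for the new group, ranked by the R2 of relocating the
    # single class; the refinement is restarted from the best few seeds of
    # every beam member and the top refinements carried forward (single-seed
    # hill climbing stalls easily because a class inside a large group is
    # invisible to the fit)
    pool <- list()
    seen <- character()
    for (b in beam) {
      seed_r2 <- vapply(seq_len(m), function(j) {
        if (sum(b == b[j]) == 1L) return(-Inf)
        a <- b; a[j] <- g
        r2_of_assignment(ind, y, a, g, tss)
      }, 0)
      seeds <- order(-seed_r2,
                     seq_len(m))[seq_len(min(n_restarts,
                                             sum(is.finite(seed_r2))))]
      for (s in seeds) {
        a0 <- b; a0[s] <- g
        ref <- refine_assignment(ind, y, a0, g, tss)
        key <- paste(match(ref$assignment, unique(ref$assignment)),
                     collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          pool <- c(pool, list(ref))
        }
      }
    }
    r2s <- vapply(pool, `[[`, 0, "r2")
    keep <- order(-r2s, seq_along(pool))[seq_len(min(n_restarts,
                                                     length(pool)))]
    beam <- lapply(pool[keep], `[[`, "assignment")
    levels[[g]] <- level_record(ind, y, beam[[1]], g, n, tss)
    if (levels[[g]]$r2 < levels[[g - 1]]$r2 - 1e-12) {
      # a refinement cannot be allowed to fall below the coarser level:
      # carry the previous assignment (one group stays empty)
      beam <- c(list(levels[[g - 1]]$assignment), beam)
      levels[[g]] <- level_record(ind, y, levels[[g - 1]]$assignment, g,
                                  n, tss)
    }
  }

  # polish every level under the selection criterion itself and retain the
  # most parsimonious polished model
  polished <- lapply(levels, function(lv) {
    a <- aicc_refine(ind, y, lv$assignment, lv$n_groups, n, tss)
    level_record(ind, y, a, lv$n_groups, n, tss)
  })
  score <- vapply(polished, function(p) c(p$aicc, p$n_motifs), c(0, 0))
  selected <- order(score[1, ], score[2, ], seq_along(polished))[1]
  final <- polished[[selected]]$assignment
  # drop emptied groups, renumbering in order of appearance
  final <- match(final, sort(unique(final)))
  part <- partition_from_int(final, colnames(ind))
  part <- order_groups(part, encoding, y)
  structure(list(levels = levels, selected = selected, partition = part),
            class = "cluster_tree")
}

# First-improvement descent on (AICc over observed motifs, motif count):
# any movable class to any of the level's groups, scanned in input order,
# repeated until no move improves the score lexicographically. Moves may
# empty a group (an empty group contributes a constant absent bit and
# simply vanishes from the motifs).
aicc_refine <- function(ind, y, assign_int, G, n, tss,
                        movable = seq_along(assign_int)) {
  if (G == 1L) return(assign_int)
  cur <- level_score(ind, y, assign_int, G, n, tss)
  repeat {
    improved <- FALSE
    for (j in movable) {
      for (h in seq_len(G)) {
        if (h == assign_int[j]) next
        a <- assign_int; a[j] <- h
        sc <- level_score(ind, y, a, G, n, tss)
        if (score_improves(sc, cur)) {
          assign_int <- a
          cur <- sc
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  assign_int
}

# (aicc over observed motifs, n_motifs) for an integer assignment
level_score <- function(ind, y, assign_int, G, n, tss) {
  ids <- motif_ids_of_assignment(ind, assign_int, G)
  rss <- rss_of_ids(y - mean(y), ids)
  M <- length(unique(ids))
  a <- if (n - M - 1 > 0) {
    if (rss <= 1e-12 * tss) -Inf else aicc(rss, n, M)
  } else Inf
  c(a, M)
}

# strict lexicographic improvement of a candidate (aicc, n_motifs) score
# over the current one; infinities compared exactly, finite with tolerance
score_improves <- function(cand, cur) {
  if (is.finite(cand[1]) && is.finite(cur[1]))
    cand[1] < cur[1] - 1e-12 ||
      (abs(cand[1] - cur[1]) <= 1e-12 && cand[2] < cur[2])
  else
    cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])
}

# first-improvement local search: any class to any group, scanned in class
# input order, repeated until no move strictly increases R2; moves that
# would empty a group are not considered
refine_assignment <- function(ind, y, assign_int, g, tss,
                              movable = seq_along(assign_int)) {
  cur_r2 <- r2_of_assignment(ind, y, assign_int, g, tss)
  repeat {
    improved <- FALSE
    for (j in movable) {
      if (sum(assign_int == assign_int[j]) == 1L) next
      for (h in seq_len(g)) {
        if (h == assign_int[j]) next
        a <- assign_int; a[j] <- h
        r2 <- r2_of_assignment(ind, y, a, g, tss)
        if (r2 > cur_r2 + 1e-12) {
          assign_int <- a
          cur_r2 <- r2
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  list(assignment = assign_int, r2 = cur_r2)
}

level_record <- function(ind, y, assign_int, g, n, tss) {
  ids <- motif_ids_of_assignment(ind, assign_int, g)
  rss <- rss_of_ids(y - mean(y), ids)
  M <- length(unique(ids))
  a <- if (n - M - 1 > 0) {
    if (rss <= 1e-12 * tss) -Inf else aicc(rss, n, M)
  } else Inf
  list(assignment = assign_int, n_groups = g, r2 = 1 - rss / tss,
       n_motifs = M, aicc = a)
}

partition_from_int <- function(assign_int, class_labels) {
  labs <- paste0("G", seq_len(max(assign_int)))
  functional_partition(stats::setNames(labs[assign_int], class_labels),
                       group_order = labs[sort(unique(assign_int))])
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("Functional-group tree\n")
  for (i in seq_along(x$levels)) {
    lv <- x$levels[[i]]
    cat(sprintf("  %slevel %d: %d groups, %d motifs, R2 = %.4f, AICc = %.2f\n",
                ifelse(i == x$selected, "* ", "  "), i, lv$n_groups,
                lv$n_motifs, lv$r2, lv$aicc))
  }
  print(x$partition)
  invisible(x)
}

#' Exhaustive partition search (independent oracle)
#'
#' Enumerates every partition of the classes into at most \code{n_groups}
#' non-empty groups (restricted-growth-string enumeration, i.e. up to group
#' relabelling) and returns the assignment maximising the motif-mean R2.
#' Ties go to the first partition in enumeration order. Intended as the
#' independent upper bound against which the greedy \code{\link{fit_tree}}
#' search is audited; refuses instances with more than \code{guard}
#' candidate partitions.
#'
#' @param encoding a \code{class_encoding}.
#' @param y property vector.
#' @param n_groups maximal number of non-empty groups.
#' @param guard refusal threshold on the enumeration size.
#' @return list with \code{partition} (a \code{functional_partition}),
#'   \code{r2} and \code{n_examined}.
#' @export
exhaustive_oracle <- function(encoding, y, n_groups, guard = 1e6) {
  y <- as.numeric(y)
  ind <- encoding$indicators
  m <- ncol(ind)
  total <- sum(vapply(seq_len(min(n_groups, m)), function(j)
    stirling2(m, j), 0))
  if (total > guard)
    stop(sprintf("enumeration too large: %.0f partitions exceed the guard of %.0f",
                 total, guard), call. = FALSE)
  tss <- sum((y - mean(y))^2)
  best_r2 <- -Inf
  best_assign <- NULL
  n_examined <- 0L
  # restricted growth strings: a[1] = 1, a[j] <= max(a[1..j-1]) + 1, <= n_groups
  recurse <- function(a, j, mx) {
    if (j > m) {
      n_examined <<- n_examined + 1L
      r2 <- r2_of_assignment(ind, y, a, mx, tss)
      if (r2 > best_r2 + 1e-12) {
        best_r2 <<- r2
        best_assign <<- a
      }
      return(invisible())
    }
    for (v in seq_len(min(mx + 1L, n_groups))) {
      a[j] <- v
      recurse(a, j + 1L, max(mx, v))
    }
  }
  recurse(integer(m), 1L, 0L)
  list(partition = partition_from_int(best_assign, colnames(ind)),
       r2 = best_r2, n_examined = n_examined)
}

stirling2 <- function(n, k) {
  # second-kind Stirling number, small n only
  if (k == 0) return(as.numeric(n == 0))
  if (k > n) return(0)
  s <- matrix(0, n + 1, k + 1)
  s[1, 1] <- 1
  for (i in seq_len(n))
    for (j in seq_len(min(i, k)))
      s[i + 1, j + 1] <- j * s[i, j + 1] + s[i, j]
  s[n + 1, k + 1]
}

#' Order functional groups by explanatory contribution
#'
#' Relabels a fitted partition so that groups read A, B, ... from the one
#' that best explains the property to the one that least does, with the
#' residual group labelled last. The residual group is the group whose
#' distinction matters least (smallest R2 drop when dissolved into its best
#' alternative group); each remaining group's contribution is the R2 drop
#' when its classes are merged into the residual group. Classes within a
#' non-residual group are ordered by the R2 drop when the single class is
#' moved to the residual group; residual classes by the R2 drop when the
#' class is deleted outright.
#'
#' @param partition a \code{functional_partition}.
#' @param encoding the \code{class_encoding} it was fitted on.
#' @param y the property vector.
#' @return the relabelled \code{functional_partition}, with a
#'   \code{class_order} component giving classes left-to-right and a
#'   \code{contributions} component (named R2 drops, residual = NA).
#' @export
order_groups <- function(partition, encoding, y) {
  y <- as.numeric(y)
  ind <- encoding$indicators[, names(partition$assignment), drop = FALSE]
  tss <- sum((y - mean(y))^2)
  groups <- partition$group_order
  G <- length(groups)
  assign0 <- partition$assignment
  r2_of <- function(assignment) {
    gl <- unique(assignment)
    ai <- match(assignment, gl)
    r2_of_assignment(ind, y, ai, length(gl), tss)
  }
  r2_full <- r2_of(assign0)
  if (G == 1L) {
    out <- functional_partition(
      stats::setNames(rep("A", length(assign0)), names(assign0)), "A")
    out$class_order <- names(assign0)
    out$contributions <- stats::setNames(NA_real_, "A")
    return(out)
  }
  # residual = group whose outright deletion least changes the fit: the
  # default cluster is typically present in (nearly) every sample, so its
  # presence bit carries no information and removing its classes leaves
  # the motifs essentially unchanged
  delete_cost <- vapply(groups, function(g) {
    keep <- names(assign0)[assign0 != g]
    a <- assign0[keep]
    gl <- unique(a)
    r2_full - r2_of_assignment(ind[, keep, drop = FALSE], y,
                               match(a, gl), length(gl), tss)
  }, 0)
  resid <- groups[max(which(delete_cost == min(delete_cost)))]
  others <- setdiff(groups, resid)
  contrib <- vapply(others, function(g) {
    a <- assign0; a[a == g] <- resid; r2_full - r2_of(a)
  }, 0)
  ord <- others[order(-contrib, match(others, groups), method = "radix")]
  new_labels <- stats::setNames(LETTERS[seq_len(G)], c(ord, resid))
  assignment <- stats::setNames(unname(new_labels[assign0]), names(assign0))
  out <- functional_partition(assignment, unname(new_labels))
  # class ordering within groups
  class_drop <- vapply(names(assign0), function(cl) {
    if (assign0[[cl]] == resid) {
      keep <- setdiff(names(assign0), cl)
      a <- assign0[keep]
      gl <- unique(a)
      r2_full - r2_of_assignment(ind[, keep, drop = FALSE], y,
                                 match(a, gl), length(gl), tss)
    } else {
      a <- assign0; a[cl] <- resid; r2_full - r2_of(a)
    }
  }, 0)
  out$class_order <- unlist(lapply(unname(new_labels), function(lab) {
    members <- names(assignment)[assignment == lab]
    members[order(-class_drop[members], match(members, names(assign0)),
                  method = "radix")]
  }), use.names = FALSE)
  out$contributions <- stats::setNames(
    c(contrib[ord], NA_real_), unname(new_labels[c(ord, resid)]))
  out
}

#' Constrained family-level backward selection for the clustering route
#'
#' Removing a family removes all of its relative-abundance classes. A family
#' is a removal candidate only when every one of its classes sits in the
#' residual group; the removal is accepted only when it changes neither the
#' non-residual groups' class content nor any sample's assembly motif, and
#' when it improves the model AICc computed with \code{k} = the number of
#' remaining families. Since an accepted removal leaves the fit unchanged,
#' AICc improves through the variable-count penalty alone. Candidates are
#' scanned greedily as in \code{\link{backward_select_linear}}.
#'
#' @param encoding the full \code{class_encoding}.
#' @param y property vector.
#' @param tree a fitted \code{cluster_tree} (its selected ordered partition
#'   identifies the residual group), or a \code{functional_partition}.
#' @return a \code{selection_trace}; the final \code{model_fit} reports the
#'   kept families, AICc at \code{k} = kept family count, and
#'   \code{reported_df = p_initial - m_kept}.
#' @export
backward_select_families <- function(encoding, y, tree) {
  y <- as.numeric(y)
  partition <- if (inherits(tree, "cluster_tree")) tree$partition else tree
  resid <- residual_group(partition)
  families <- unique(encoding$classes$family)
  p_initial <- length(families)
  n <- length(y)

  cur_enc <- encoding
  cur_part <- partition
  cur_motifs <- motif_of_sample(cur_enc$indicators[, names(cur_part$assignment),
                                                   drop = FALSE], cur_part)
  base_fit <- fit_motif_means(cur_enc, y, cur_part)
  rss <- base_fit$rss
  kept <- families
  cur_aicc <- sel_score(rss, n, length(kept))
  steps <- empty_steps()

  drop_family <- function(enc, part, fam) {
    keep_classes <- names(part$assignment)[
      !(names(part$assignment) %in% enc$classes$label[enc$classes$family == fam])]
    assignment <- part$assignment[keep_classes]
    groups <- part$group_order[part$group_order %in% unique(assignment)]
    list(encoding = subset_families(enc, setdiff(unique(enc$classes$family), fam)),
         partition = functional_partition(assignment, groups))
  }

  repeat {
    residual_families <- kept[vapply(kept, function(fam) {
      cls <- cur_enc$classes$label[cur_enc$classes$family == fam]
      all(cur_part$assignment[cls] == resid)
    }, TRUE)]
    if (length(residual_families) == 0L) break
    cand <- vapply(residual_families, function(fam) {
      red <- drop_family(cur_enc, cur_part, fam)
      if (!identical(red$partition$group_order, cur_part$group_order))
        return(Inf)  # a group vanished: structure changed
      new_motifs <- motif_of_sample(
        red$encoding$indicators[, names(red$partition$assignment),
                                drop = FALSE], red$partition)
      if (!identical(new_motifs, cur_motifs)) return(Inf)
      sel_score(rss, n, length(kept) - 1L)
    }, 0)
    best <- which.min(cand)
    if (is.finite(cand[best]) && cand[best] < cur_aicc) {
      fam <- residual_families[best]
      steps[nrow(steps) + 1L, ] <- list(fam, "aicc", cur_aicc, cand[best],
                                        length(kept) - 1L, TRUE)
      red <- drop_family(cur_enc, cur_part, fam)
      cur_enc <- red$encoding
      cur_part <- red$partition
      kept <- setdiff(kept, fam)
      cur_aicc <- cand[best]
    } else break
  }
  final <- fit_motif_means(cur_enc, y, cur_part)
  final$k <- length(kept)
  final$aicc <- if (n - length(kept) - 1 <= 0) Inf else
    aicc(rss, n, length(kept))
  final$kept_families <- kept
  final$reported_df <- p_initial - length(kept)
  new_selection_trace(steps, final, families)
}

# AICc used to order candidate removals. All candidates share the same RSS
# (an accepted removal leaves the fit unchanged), so when RSS is exactly
# zero the common deviance term is -Inf and the models are ordered by the
# penalty terms alone.
sel_score <- function(rss, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  if (rss == 0) return(2 * k + 2 * k * (k + 1) / (n - k - 1))
  aicc(rss, n, k)
}
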