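#' Construct a validated sample-by-family abundance table
#'
#' The abundance table is the raw community description: one row per soil
#' sample, one column per microbial family, non-negative integer read counts.
#' All downstream analyses (multi-linear composition model, abundance-class
#' encoding, functional clustering) start from this object.
#'
#' @param counts numeric matrix of read counts, samples in rows, families in
#'   columns. Values must be non-negative and integer-valued; dimnames must
#'   give unique sample and family identifiers.
#' @param community_label free-text label for the community analysed
#'   (e.g. \code{"bacteria"}, \code{"fungi"}, \code{"combined"}).
#' @return an object of class \code{abundance_table}: the validated integer
#'   count matrix with attributes \code{community_label}, and accessors
#'   \code{n} (samples) and \code{p} (families) via \code{dim}.
#' @export
abundance_table <- function(counts, community_label = "community") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("f", seq_len(ncol(counts)))
  validate_counts(counts)
  storage.mode(counts) <- "integer"
  structure(counts,
            community_label = community_label,
            class = c("abundance_table", "matrix", "array"))
}

validate_counts <- function(counts) {
  if (!is.numeric(counts))
    stop("counts must be numeric", call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "invalid count at sample '%s', family '%s': %s (must be a finite non-negative integer)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])), call. = FALSE)
  notint <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(notint) > 0)
    stop(sprintf("non-integer count at sample '%s', family '%s': %s",
                 rownames(counts)[notint[1, 1]], colnames(counts)[notint[1, 2]],
                 format(counts[notint[1, , drop = FALSE]])), call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate family identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table (%s): n = %d samples x p = %d families\n",
              attr(x, "community_label"), nrow(x), ncol(x)))
  cat(sprintf("  reads per sample: %s (median %s)\n",
              paste(range(rowSums(x)), collapse = "-"),
              format(stats::median(rowSums(x)))))
  invisible(x)
}

#' Construct a per-sample property vector
#'
#' Holds one soil property (a SOM decomposition function measured as CO2
#' release: basal respiration, straw mineralization or priming effect, at one
#' incubation time) aligned to the sample order of a companion abundance
#' table. Units travel as metadata only.
#'
#' @param values finite numeric vector, one value per sample.
#' @param sample_ids sample identifiers; default taken from \code{names(values)}.
#' @param label free-text label, e.g. \code{"priming_effect_7d"}.
#' @param units free-text unit string, not used in computation.
#' @return object of class \code{property_vector} (a named numeric vector
#'   with \code{label} and \code{units} attributes).
#' @export
property_vector <- function(values, sample_ids = names(values),
                            label = "property", units = "") {
  values <- as.numeric(values)
  if (is.null(sample_ids))
    sample_ids <- paste0("s", seq_along(values))
  if (length(sample_ids) != length(values))
    stop("sample_ids and values differ in length", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite property value for sample(s): ",
         paste(sample_ids[!is.finite(values)], collapse = ", "), call. = FALSE)
  structure(stats::setNames(values, sample_ids),
            label = label, units = units,
            class = "property_vector")
}

#' @export
print.property_vector <- function(x, ...) {
  cat(sprintf("Property '%s' (%d samples)", attr(x, "label"), length(x)))
  if (nzchar(attr(x, "units"))) cat(sprintf(" [%s]", attr(x, "units")))
  cat("\n")
  print(summary(as.numeric(x)))
  invisible(x)
}

delim_for <- function(dialect = c("tsv", "csv")) {
  switch(match.arg(dialect), tsv = "\t", csv = ",")
}

#' Read an abundance table from a delimited text file
#'
#' The default layout has samples in rows (first column = sample identifiers)
#' and families in columns (first row = family identifiers); a transposed
#' file is accepted via \code{orientation = "families_rows"} and yields an
#' identical table.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}; decimal point only.
#' @param orientation \code{"samples_rows"} or \code{"families_rows"}.
#' @param community_label label stored on the returned table.
#' @return an \code{\link{abundance_table}}.
#' @export
read_abundance_table <- function(path, dialect = c("tsv", "csv"),
                                 orientation = c("samples_rows", "families_rows"),
                                 community_label = "community") {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, sep = delim_for(dialect), header = TRUE,
                          row.names = 1, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                   m[bad[1, 1], bad[1, 2]]), call. = FALSE)
    storage.mode(m) <- "numeric"
  }
  if (orientation == "families_rows") m <- t(m)
  abundance_table(m, community_label = community_label)
}

#' Write an abundance table to a delimited text file
#'
#' Inverse of \code{\link{read_abundance_table}}; round-trips exactly.
#'
#' @param x an \code{abundance_table}.
#' @param path output file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @export
write_abundance_table <- function(x, path, dialect = c("tsv", "csv")) {
  df <- data.frame(sample = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = delim_for(dialect), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read one or several property vectors from a delimited text file
#'
#' Accepts either a two-column layout (sample id, value) or a wide layout
#' (first column sample id, one labelled column per property, e.g. the six
#' function-by-time combinations). Values are aligned to
#' \code{reference_ids} when given; alignment is by identifier, never by row
#' order, and a missing sample is an error.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @param reference_ids optional sample order to align to (e.g.
#'   \code{rownames} of the companion abundance table).
#' @return a single \code{\link{property_vector}} if the file has one value
#'   column, otherwise a named list of them.
#' @export
read_property_table <- function(path, dialect = c("tsv", "csv"),
                                reference_ids = NULL) {
  df <- utils::read.table(path, sep = delim_for(dialect), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  vals <- df[-1]
  if (!is.null(reference_ids)) {
    missing <- setdiff(reference_ids, ids)
    if (length(missing) > 0)
      stop("property table is missing sample(s) present in the reference order: ",
           paste(missing, collapse = ", "), call. = FALSE)
    keep <- match(reference_ids, ids)
    ids <- ids[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  out <- lapply(names(vals), function(lab)
    property_vector(vals[[lab]], sample_ids = ids, label = lab))
  names(out) <- names(vals)
  if (length(out) == 1L) out[[1L]] else out
}

fmt12 <- function(x) {
  # 12 significant digits: stable diffs without false precision
  ifelse(is.na(x), NA_character_, formatC(x, digits = 12, format = "g"))
}

model_fit_summary <- function(fit) {
  list(route = fit$route, r2 = fit$r2, f_ratio = fit$f_ratio,
       aicc = fit$aicc, k = fit$k, n = fit$n,
       kept_families = fit$kept_families,
       reported_df = fit$reported_df,
       residual_df = fit$residual_df)
}

#' Write the result artifacts of a pipeline run
#'
#' Serialises whichever artifacts are supplied into a deterministic file set
#' under \code{out_dir}: class-encoding table (TSV), selection trace (TSV),
#' partition/tree (JSON), effects table (TSV) and model summary (JSON).
#' Numeric output is written with 12 significant digits, so re-running with
#' identical inputs reproduces byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param encoding optional \code{class_encoding}.
#' @param trace optional \code{selection_trace}.
#' @param partition optional \code{functional_partition} or \code{cluster_tree}.
#' @param effects optional \code{group_effects}.
#' @param fits optional named list of \code{model_fit} objects.
#' @return data.frame manifest with columns \code{kind} and \code{path}.
#' @export
write_results <- function(out_dir, encoding = NULL, trace = NULL,
                          partition = NULL, effects = NULL, fits = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  manifest <- data.frame(kind = character(), path = character(),
                         stringsAsFactors = FALSE)
  add <- function(kind, path) {
    manifest[nrow(manifest) + 1L, ] <<- list(kind, path)
  }
  if (!is.null(encoding)) {
    p <- file.path(out_dir, "class_encoding.tsv")
    write_class_encoding(encoding, p)
    add("class_encoding", p)
  }
  if (!is.null(trace)) {
    p <- file.path(out_dir, "selection_trace.tsv")
    st <- trace$steps
    st$aicc_before <- fmt12(st$aicc_before)
    st$aicc_after <- fmt12(st$aicc_after)
    utils::write.table(st, p, sep = "\t", quote = FALSE, row.names = FALSE)
    add("selection_trace", p)
  }
  if (!is.null(partition)) {
    p <- file.path(out_dir, "partition.json")
    obj <- if (inherits(partition, "cluster_tree")) {
      list(selected_level = partition$selected,
           levels = lapply(partition$levels, function(lv)
             list(n_groups = lv$n_groups, r2 = lv$r2,
                  n_motifs = lv$n_motifs, aicc = lv$aicc)),
           assignment = as.list(partition$partition$assignment),
           group_order = partition$partition$group_order)
    } else {
      list(assignment = as.list(partition$assignment),
           group_order = partition$group_order)
    }
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = 12, pretty = TRUE)
    add("partition", p)
  }
  if (!is.null(effects)) {
    p <- file.path(out_dir, "effects.tsv")
    main <- effects$main
    main$term2 <- NA_character_
    inter <- effects$interactions
    tab <- rbind(
      data.frame(term = main$group, term2 = NA_character_,
                 effect_pct = main$effect_pct, p_value = main$p_value,
                 significant = main$significant, stringsAsFactors = FALSE),
      if (nrow(inter) > 0)
        data.frame(term = inter$group1, term2 = inter$group2,
                   effect_pct = inter$effect_pct, p_value = inter$p_value,
                   significant = inter$significant, stringsAsFactors = FALSE))
    tab$effect_pct <- fmt12(tab$effect_pct)
    tab$p_value <- fmt12(tab$p_value)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    add("effects", p)
  }
  if (!is.null(fits)) {
    p <- file.path(out_dir, "model_summary.json")
    if (inherits(fits, "model_fit")) fits <- list(fit = fits)
    jsonlite::write_json(lapply(fits, model_fit_summary), p,
                         auto_unbox = TRUE, digits = 12, pretty = TRUE)
    add("model_summary", p)
  }
  manifest
}

#' Write a class encoding as a 0/1 TSV table
#'
#' Columns are class identifiers \code{"Family|c/k"}, rows samples.
#' @param encoding a \code{class_encoding}.
#' @param path output path.
#' @export
write_class_encoding <- function(encoding, path) {
  df <- data.frame(sample = encoding$sample_ids, encoding$indicators,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a class encoding written by \code{write_class_encoding}
#'
#' Class descriptors (family, class index, class total) are reconstructed
#' from the \code{"Family|c/k"} column labels; segmentation thresholds are
#' not stored in the TSV and come back as \code{NA}.
#' @param path file path.
#' @return a \code{class_encoding}.
#' @export
read_class_encoding <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ind <- as.matrix(df[-1])
  storage.mode(ind) <- "integer"
  rownames(ind) <- df[[1]]
  labs <- colnames(ind)
  parts <- regmatches(labs, regexec("^(.*)\\|(\\d+)/(\\d+)$", labs))
  if (any(lengths(parts) != 4))
    stop("malformed class label(s): ",
         paste(labs[lengths(parts) != 4], collapse = ", "), call. = FALSE)
  classes <- data.frame(
    family = vapply(parts, `[`, "", 2),
    class_index = as.integer(vapply(parts, `[`, "", 3)),
    class_total = as.integer(vapply(parts, `[`, "", 4)),
    label = labs, lower = NA_real_, upper = NA_real_,
    frequency = colMeans(ind), stringsAsFactors = FALSE)
  new_class_encoding(ind, classes, df[[1]])
}
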