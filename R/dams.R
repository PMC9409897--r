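# Differential accumulated metabolite (DAM) analysis of LC-MS
# feature-intensity tables: normalisation, pairwise statistics, significance
# calls, and the standard summaries (class breakdown, set comparison,
# clustering, PCA, volcano coordinates).

#' Assemble a feature-intensity table
#'
#' @param intensities Numeric matrix, features x samples, non-negative, with
#'   dimnames.
#' @param design Tibble(sample, condition, replicate); every condition used
#'   for testing needs >= 2 replicates (typical LC-MS designs use 3).
#' @param features Optional tibble(feature, mz, rt, name, class); defaults
#'   to unannotated ("unknown") features.
#' @return A `feature_table`.
#' @export
feature_table <- function(intensities, design, features = NULL) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)), !is.null(colnames(intensities)))
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  design <- as_tibble(design)
  stopifnot(all(c("sample", "condition", "replicate") %in% names(design)))
  if (!setequal(design$sample, colnames(intensities))) {
    stop("design samples do not match intensity matrix columns", call. = FALSE)
  }
  design <- design[match(colnames(intensities), design$sample), ]
  if (is.null(features)) {
    features <- tibble(
      feature = rownames(intensities), mz = NA_real_, rt = NA_real_,
      name = rownames(intensities), class = "unknown"
    )
  } else {
    features <- as_tibble(features)
    stopifnot("feature" %in% names(features))
    for (col in c("mz", "rt")) if (!col %in% names(features)) features[[col]] <- NA_real_
    if (!"name" %in% names(features)) features$name <- features$feature
    if (!"class" %in% names(features)) features$class <- "unknown"
    features <- features[match(rownames(intensities), features$feature), ]
  }
  if (anyDuplicated(rownames(intensities))) stop("feature ids must be unique", call. = FALSE)
  structure(
    list(intensities = intensities, design = design, features = features),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d features x %d samples (%s)\n",
    nrow(x$intensities), ncol(x$intensities),
    paste(unique(x$design$condition), collapse = ", ")
  ))
  invisible(x)
}

#' @method tidy feature_table
#' @export
tidy.feature_table <- function(x, ...) {
  as_tibble(x$intensities, rownames = "feature") %>%
    tidyr::pivot_longer(-"feature", names_to = "sample", values_to = "intensity") %>%
    left_join(x$design, by = "sample") %>%
    left_join(x$features, by = "feature")
}

# Half the smallest nonzero intensity: the pseudo-count used wherever zeros
# would break a ratio or a log.
pseudo_count <- function(x) {
  nz <- x[x > 0]
  if (!length(nz)) return(.Machine$double.eps)
  min(nz) / 2
}

#' Normalise feature intensities
#'
#' `median-scale` (default) rescales every sample so its median feature
#' intensity equals the global median (the median of per-sample medians);
#' `total-intensity` equalises column sums; `none` passes through. Scaling
#' factors are attached as attribute `"scale_factors"`.
#'
#' @param table A `feature_table`.
#' @param method Normalisation method.
#' @return A normalised `feature_table`.
#' @export
normalize_intensities <- function(table, method = c("median-scale", "total-intensity", "none")) {
  method <- match.arg(method)
  if (method == "none") return(table)
  x <- table$intensities
  stat <- switch(method,
    `median-scale` = apply(x, 2, median),
    `total-intensity` = colSums(x)
  )
  zero <- stat <= 0
  if (any(zero)) {
    stop(
      "cannot normalise: sample(s) with zero ",
      if (method == "median-scale") "median" else "total", " intensity: ",
      paste(colnames(x)[zero], collapse = ", "),
      call. = FALSE
    )
  }
  target <- median(stat)
  factors <- target / stat
  table$intensities <- sweep(x, 2, factors, `*`)
  attr(table, "scale_factors") <- setNames(factors, colnames(x))
  table
}

welch_p <- function(a, b) {
  if (sd(a) < 1e-12 && sd(b) < 1e-12) {
    # degenerate: no within-group variation; equal means are maximally
    # unsurprising, unequal means maximally surprising
    return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
  }
  tryCatch(
    t.test(a, b, var.equal = FALSE)$p.value,
    error = function(e) if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0
  )
}

#' Pairwise differential accumulation test
#'
#' For each feature computes fold change = mean(A)/mean(B) on the (ideally
#' normalised) intensities (a pseudo-count of half the smallest nonzero
#' intensity replaces zero means), its log2, and a two-sided unequal-variance
#' Welch t-test p-value on log2-transformed intensities. Significance is left
#' to [call_significant()].
#'
#' @param table A `feature_table`.
#' @param condition_a Test condition (numerator).
#' @param condition_b Reference condition (denominator).
#' @return Tibble of DAM records: feature, metabolite, class, comparison,
#'   mean_a, mean_b, fold_change, log2_fold_change, p_value, direction, plus
#'   mz/rt carried from feature metadata.
#' @export
pairwise_dam_test <- function(table, condition_a, condition_b) {
  des <- table$design
  for (cond in c(condition_a, condition_b)) {
    n <- sum(des$condition == cond)
    if (n < 2L) {
      stop(
        "condition '", cond, "' has ", n,
        " replicate(s); at least 2 are required",
        call. = FALSE
      )
    }
  }
  xa <- table$intensities[, des$sample[des$condition == condition_a], drop = FALSE]
  xb <- table$intensities[, des$sample[des$condition == condition_b], drop = FALSE]
  pc <- pseudo_count(table$intensities)
  log_all <- log2(pmax(table$intensities, pc))
  la <- log_all[, colnames(xa), drop = FALSE]
  lb <- log_all[, colnames(xb), drop = FALSE]
  mean_a <- unname(rowMeans(xa))
  mean_b <- unname(rowMeans(xb))
  fc <- ifelse(mean_a == 0, pc, mean_a) / ifelse(mean_b == 0, pc, mean_b)
  p <- vapply(
    seq_len(nrow(la)),
    function(i) welch_p(la[i, ], lb[i, ]),
    numeric(1)
  )
  lfc <- log2(fc)
  tibble(
    feature = rownames(table$intensities),
    metabolite = table$features$name,
    class = table$features$class,
    mz = table$features$mz, rt = table$features$rt,
    comparison = paste0(condition_a, " vs ", condition_b),
    mean_a = mean_a, mean_b = mean_b,
    fold_change = fc, log2_fold_change = lfc,
    p_value = p,
    direction = if_else(lfc < 0, "down", "up")
  )
}

#' One-way ANOVA with Tukey HSD post-hoc per feature
#'
#' Fits `log2(intensity) ~ condition` per feature, reporting the ANOVA F and
#' p-value plus Tukey honest-significant-difference adjusted p-values (from
#' the studentized-range distribution) for every condition pair.
#'
#' @param table A `feature_table`.
#' @param conditions Conditions to include (>= 3, each with >= 2 replicates);
#'   default all.
#' @return Tibble: feature, f_statistic, p_anova, comparison, diff (log2),
#'   p_adjusted, degenerate (flag: no within-group variance anywhere).
#' @export
anova_tukey <- function(table, conditions = unique(table$design$condition)) {
  if (length(conditions) < 3L) {
    stop("ANOVA + Tukey requires >= 3 conditions; use pairwise_dam_test() for 2", call. = FALSE)
  }
  des <- filter(table$design, .data$condition %in% conditions)
  for (cond in conditions) {
    if (sum(des$condition == cond) < 2L) {
      stop("condition '", cond, "' has fewer than 2 replicates", call. = FALSE)
    }
  }
  pc <- pseudo_count(table$intensities)
  lx <- log2(pmax(table$intensities[, des$sample, drop = FALSE], pc))
  grp <- factor(des$condition, levels = conditions)
  out <- lapply(rownames(lx), function(f) {
    y <- lx[f, ]
    degenerate <- all(tapply(y, grp, sd) < 1e-12)
    if (degenerate) {
      pairs <- utils::combn(levels(grp), 2)
      return(tibble(
        feature = f, f_statistic = NA_real_, p_anova = NA_real_,
        comparison = paste0(pairs[2, ], " vs ", pairs[1, ]),
        diff = apply(pairs, 2, function(pr) mean(y[grp == pr[2]]) - mean(y[grp == pr[1]])),
        p_adjusted = NA_real_, degenerate = TRUE
      ))
    }
    fit <- aov(y ~ grp)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$grp
    cmp <- sub("-", " vs ", rownames(tk), fixed = TRUE)
    tibble(
      feature = f, f_statistic = an[["F value"]][1], p_anova = an[["Pr(>F)"]][1],
      comparison = cmp, diff = tk[, "diff"], p_adjusted = tk[, "p adj"],
      degenerate = FALSE
    )
  })
  bind_rows(out)
}

#' Call significant DAMs
#'
#' A record is significant iff `|log2 fold change| >= lfc_threshold` and
#' `p <= alpha`; both boundaries are inclusive. Note that a fold-change cut
#' of 1.5 corresponds to |log2 FC| 0.585, not the conventional 0.5 used
#' here — the log2 threshold is operative. An optional Benjamini-Hochberg
#' correction over features is available but defaults off (raw p-values are
#' the common practice for these feature tables).
#'
#' @param dams Tibble from [pairwise_dam_test()] (columns log2_fold_change,
#'   p_value).
#' @param lfc_threshold Minimal |log2 FC| (default 0.5).
#' @param alpha Maximal p (default 0.05).
#' @param adjust Apply BH correction per comparison before thresholding.
#' @return Input with a logical `significant` column; thresholds recorded in
#'   attributes `lfc_threshold` / `alpha`.
#' @export
call_significant <- function(dams, lfc_threshold = 0.5, alpha = 0.05, adjust = FALSE) {
  dams <- as_tibble(dams)
  p <- dams$p_value
  if (adjust) {
    dams <- dams %>%
      group_by(.data$comparison) %>%
      mutate(p_used = p.adjust(.data$p_value, method = "BH")) %>%
      ungroup()
    p <- dams$p_used
  }
  dams$significant <- !is.na(dams$log2_fold_change) & !is.na(p) &
    abs(dams$log2_fold_change) >= lfc_threshold & p <= alpha
  attr(dams, "lfc_threshold") <- lfc_threshold
  attr(dams, "alpha") <- alpha
  dams
}

#' Summarise DAM calls
#'
#' Per-comparison counts of significant, up- and down-accumulated
#' metabolites with percentage shares (1 decimal), the share of tested
#' features that are significant, and a per-class breakdown by direction.
#'
#' @param dams Tibble with columns comparison, direction, significant, class.
#' @return A `dam_summary`: `comparisons` tibble (comparison, n_tested,
#'   n_significant, n_up, n_down, percent_up, percent_down,
#'   percent_significant), `classes` tibble (comparison, class, direction, n),
#'   `n_significant_total`.
#' @export
summarize_dams <- function(dams) {
  dams <- as_tibble(dams)
  if (!"significant" %in% names(dams)) {
    stop("records are not flagged; run call_significant() first", call. = FALSE)
  }
  comparisons <- dams %>%
    group_by(.data$comparison) %>%
    summarise(
      n_tested = n(),
      n_significant = sum(.data$significant),
      n_up = sum(.data$significant & .data$direction == "up"),
      n_down = sum(.data$significant & .data$direction == "down"),
      .groups = "drop"
    ) %>%
    mutate(
      percent_up = if_else(.data$n_significant > 0,
        round(100 * .data$n_up / .data$n_significant, 1), 0
      ),
      percent_down = if_else(.data$n_significant > 0,
        round(100 * .data$n_down / .data$n_significant, 1), 0
      ),
      percent_significant = if_else(.data$n_tested > 0,
        round(100 * .data$n_significant / .data$n_tested, 1), 0
      )
    )
  classes <- dams %>%
    filter(.data$significant) %>%
    count(.data$comparison, .data$class, .data$direction, name = "n")
  structure(
    list(
      comparisons = comparisons, classes = classes,
      n_significant_total = sum(comparisons$n_significant)
    ),
    class = "dam_summary"
  )
}

#' @export
print.dam_summary <- function(x, ...) {
  cat("<dam_summary>", x$n_significant_total, "significant DAMs in total\n")
  print(x$comparisons)
  invisible(x)
}

#' @method tidy dam_summary
#' @export
tidy.dam_summary <- function(x, ...) x$comparisons

#' @method glance dam_summary
#' @export
glance.dam_summary <- function(x, ...) {
  tibble(
    n_comparisons = nrow(x$comparisons),
    n_significant_total = x$n_significant_total
  )
}

#' Compare DAM sets across comparisons
#'
#' Venn-style partition of metabolite identities across the significant sets
#' of several comparisons.
#'
#' @param sets Named list; each element a character vector of metabolite ids
#'   or a flagged DAM tibble (its significant metabolites are used).
#' @return List: `membership` tibble (id + one logical column per set +
#'   `region` label), `counts` tibble (region, n). For exactly two sets the
#'   regions are named `common`, `specific_<A>`, `specific_<B>`.
#' @export
compare_dam_sets <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), length(sets) >= 2L)
  ids <- lapply(sets, function(s) {
    if (is.data.frame(s)) {
      s <- as_tibble(s)
      key <- if ("metabolite" %in% names(s)) "metabolite" else "feature"
      if ("significant" %in% names(s)) s <- filter(s, .data$significant)
      unique(s[[key]])
    } else {
      unique(as.character(s))
    }
  })
  universe <- sort(unique(unlist(ids)))
  membership <- tibble(id = universe)
  for (nm in names(ids)) membership[[nm]] <- universe %in% ids[[nm]]
  region_of <- function(row) {
    inset <- names(ids)[unlist(row[names(ids)])]
    if (length(ids) == 2L) {
      if (length(inset) == 2L) return("common")
      return(paste0("specific_", inset))
    }
    paste(inset, collapse = "&")
  }
  membership$region <- vapply(
    seq_len(nrow(membership)),
    function(i) region_of(membership[i, ]), character(1)
  )
  counts <- count(membership, .data$region, name = "n")
  list(membership = membership, counts = counts)
}

#' Hierarchical clustering of a log2 fold-change matrix
#'
#' Agglomerative clustering on the Euclidean distance matrix with average
#' linkage (configurable), as used for DAM heat maps.
#'
#' @param mat Numeric matrix (metabolites x comparisons), finite values.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return An `hclust` object (merge order, heights, row order).
#' @export
hierarchical_cluster <- function(mat, linkage = "average") {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  bad <- rownames(mat)[!apply(is.finite(mat), 1, all)]
  if (length(bad)) {
    stop("non-finite values in rows: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  hclust(dist(mat, method = "euclidean"), method = linkage)
}

#' PCA sample scores for a feature table
#'
#' Mean-centred principal component analysis of samples (features as
#' variables). Score signs are canonicalised so the largest-magnitude
#' loading of each component is positive.
#'
#' @param table A `feature_table` (or numeric matrix features x samples);
#'   needs >= 3 samples.
#' @param log_transform Work on log2 intensities (pseudo-counted); default
#'   TRUE.
#' @return A `pca_scores` list: `scores` tibble (sample, condition, PC
#'   columns), `variance_explained` (named numeric, sums to <= 1),
#'   `loadings` matrix.
#' @export
pca_scores <- function(table, log_transform = TRUE) {
  if (inherits(table, "feature_table")) {
    x <- table$intensities
    design <- table$design
  } else {
    x <- table
    design <- tibble(sample = colnames(x), condition = NA_character_)
  }
  if (ncol(x) < 3L) stop("PCA requires at least 3 samples", call. = FALSE)
  if (log_transform) x <- log2(pmax(x, pseudo_count(x)))
  X <- t(x) # samples x features
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x, rownames = "sample") %>%
    left_join(design[c("sample", "condition")], by = "sample") %>%
    select("sample", "condition", dplyr::everything())
  structure(
    list(
      scores = scores,
      variance_explained = setNames(ve, colnames(pc$x)),
      loadings = pc$rotation
    ),
    class = "pca_scores"
  )
}

#' @export
print.pca_scores <- function(x, ...) {
  cat(sprintf(
    "<pca_scores> %d samples; PC1 %.1f%%, PC2 %.1f%% variance\n",
    nrow(x$scores), 100 * x$variance_explained[1],
    if (length(x$variance_explained) > 1) 100 * x$variance_explained[2] else 0
  ))
  invisible(x)
}

#' @method tidy pca_scores
#' @export
tidy.pca_scores <- function(x, ...) x$scores

#' Volcano-plot coordinates for DAM records
#'
#' @param dams Flagged DAM tibble ([call_significant()] output).
#' @param p_cap Cap for `-log10(p)` when p underflows to 0.
#' @return Tibble (feature, metabolite, comparison, log2_fold_change,
#'   neg_log10_p, significant, direction, status) with attribute
#'   `quadrant_counts` (status x n; sums to the record count).
#' @export
volcano_data <- function(dams, p_cap = 300) {
  dams <- as_tibble(dams)
  if (!"significant" %in% names(dams)) {
    stop("records are not flagged; run call_significant() first", call. = FALSE)
  }
  out <- dams %>%
    mutate(
      neg_log10_p = pmin(-log10(pmax(.data$p_value, 10^(-p_cap))), p_cap),
      status = dplyr::case_when(
        .data$significant & .data$direction == "up" ~ "significant-up",
        .data$significant & .data$direction == "down" ~ "significant-down",
        TRUE ~ "not-significant"
      )
    ) %>%
    select(
      "feature", "metabolite", "comparison", "log2_fold_change",
      "neg_log10_p", "significant", "direction", "status"
    )
  attr(out, "quadrant_counts") <- count(out, .data$status, name = "n")
  out
}
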