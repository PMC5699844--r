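# Cluster-normalized inference: every protein-ligand cluster contributes one
# unit of mass regardless of its size, so heavily studied systems cannot
# dominate the comparison. Weighted histograms, medians, a weighted Wilcoxon
# rank-sum test, and histogram-bootstrap confidence intervals.

#' Per-ligand-instance cluster weights
#'
#' Each ligand instance in a cluster of size `s` receives weight `1/s`, so
#' every cluster contributes total mass exactly 1 and the sum of all weights
#' equals the number of clusters.
#'
#' @param clusters An `allocomp_clusters` object or a data.frame with a
#'   `cluster_id` column.
#' @return Numeric weight vector aligned with the cluster rows.
#' @export
cluster_weights <- function(clusters) {
  df <- if (inherits(clusters, "allocomp_clusters")) clusters$clusters else clusters
  stopifnot("cluster_id" %in% names(df))
  if (!nrow(df)) stop("empty cluster assignment")
  size <- table(df$cluster_id)
  if (any(size == 0)) stop("empty cluster")
  as.numeric(1 / size[df$cluster_id])
}

# histogram bin index: floor with a small forgiveness for values computed
# as ratios that land a hair under a bin edge
.bin_index <- function(values, width) {
  as.integer(floor(values / width + 1e-9))
}

#' Cluster-normalized weighted histogram of one descriptor
#'
#' Masses of bin `k` (interval `[k*w, (k+1)*w)`) are the summed weights of
#' the values falling in it. With weights from [cluster_weights()] each
#' cluster adds total mass 1, so the combined total mass equals the number
#' of clusters; dividing by it gives the display-normalized histogram. Bin
#' width is 1 for discrete descriptors and 0.001 for continuous ones
#' (see [descriptor_codes()]).
#'
#' @param values Descriptor values.
#' @param weights Aligned weights (default all 1).
#' @param code Descriptor code, used to look up the bin width.
#' @param bin_width Explicit bin width, overriding `code`.
#' @return Object of class `allocomp_whist`: list with `code`, `bin_width`,
#'   `index` (sorted bin indices), `value` (bin lower edges), `mass`, and
#'   `total_mass`. Non-finite values are excluded with a message.
#' @export
weighted_histogram <- function(values, weights = rep(1, length(values)),
                               code = NULL, bin_width = NULL) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  if (is.null(bin_width)) {
    stopifnot(!is.null(code))
    dc <- descriptor_codes()
    i <- match(code, dc$code)
    if (is.na(i)) i <- match(code, dc$column)
    if (is.na(i)) stop("unknown descriptor code: ", code)
    bin_width <- dc$bin_width[i]
  }
  bad <- !is.finite(values)
  if (any(bad)) {
    message("weighted_histogram: excluded ", sum(bad), " non-finite value(s)")
    values <- values[!bad]; weights <- weights[!bad]
  }
  if (!length(values)) stop("no finite values to bin")
  idx <- .bin_index(values, bin_width)
  agg <- rowsum(weights, idx)
  index <- as.integer(rownames(agg))
  o <- order(index)
  structure(list(code = code, bin_width = bin_width,
                 index = index[o], value = index[o] * bin_width,
                 mass = as.numeric(agg)[o],
                 total_mass = sum(weights)),
            class = "allocomp_whist")
}

#' @export
print.allocomp_whist <- function(x, ...) {
  cat(sprintf("weighted histogram%s: %d bins (width %g), total mass %g\n",
              if (is.null(x$code)) "" else paste0(" of ", x$code),
              length(x$index), x$bin_width, x$total_mass))
  invisible(x)
}

.as_whist <- function(x, weights, code, bin_width) {
  if (inherits(x, "allocomp_whist")) x
  else weighted_histogram(x, weights, code = code, bin_width = bin_width)
}

#' Weighted median (and mean) of a cluster-normalized histogram
#'
#' The weighted median is the lower edge of the first bin at which the
#' cumulative mass reaches half the total -- a deterministic convention that
#' returns integer medians for integer descriptors. With all-singleton
#' clusters (equal weights) it equals the plain sample median for odd sample
#' sizes. The weighted mean is the mass-weighted mean of bin lower edges.
#'
#' @param x An `allocomp_whist`, or raw values.
#' @param weights,code,bin_width Used to build the histogram when `x` is raw
#'   values (see [weighted_histogram()]).
#' @return A single numeric value.
#' @export
weighted_median <- function(x, weights = NULL, code = NULL, bin_width = NULL) {
  if (!inherits(x, "allocomp_whist") && is.null(weights))
    weights <- rep(1, length(x))
  h <- .as_whist(x, weights, code, bin_width)
  if (h$total_mass <= 0) stop("empty distribution")
  cum <- cumsum(h$mass)
  # relative tolerance so that a cumulative mass sitting exactly at half
  # (up to summation order) counts as reaching it
  h$value[which(cum >= h$total_mass * (0.5 - 1e-9))[1L]]
}

#' @rdname weighted_median
#' @export
weighted_mean <- function(x, weights = NULL, code = NULL, bin_width = NULL) {
  if (!inherits(x, "allocomp_whist") && is.null(weights))
    weights <- rep(1, length(x))
  h <- .as_whist(x, weights, code, bin_width)
  if (h$total_mass <= 0) stop("empty distribution")
  sum(h$value * h$mass) / h$total_mass
}

#' Weighted Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test in which each observation carries a design weight
#' (here 1/cluster-size, so each protein-ligand cluster contributes one
#' observation's worth of information). Pooled weighted mid-ranks are formed
#' from the weighted empirical distribution; the rank-sum contrast is tested
#' against the classical tie-corrected normal variance with the groups'
#' total weights playing the role of sample sizes:
#' \deqn{U = \sum_{i \in A} w_i R_i - W_A(W_A+1)/2, \quad E_0[U] = W_A W_B/2,}
#' \deqn{V_0[U] = \frac{W_A W_B}{12}\Big[(W+1) - \sum_t \frac{T_t^3-T_t}{W(W-1)}\Big],}
#' where \eqn{W_A, W_B} are the groups' total weights, \eqn{W = W_A + W_B},
#' and \eqn{T_t} is the total weight tied at value t. With unit weights this
#' is exactly the large-sample two-sided Wilcoxon rank-sum test
#' (`wilcox.test(exact = FALSE, correct = FALSE)`). Because the statistic and
#' variance depend only on the total weight at each distinct value,
#' replicating a cluster's members k-fold (weights rescaled by 1/k) leaves
#' the p-value unchanged.
#'
#' @param values_a,weights_a First group's values and positive weights.
#' @param values_b,weights_b Second group.
#' @return Two-sided p-value in `(0, 1]`; degenerate data (no rank
#'   variation) give 1.
#' @export
weighted_wilcoxon <- function(values_a, weights_a = rep(1, length(values_a)),
                              values_b, weights_b = rep(1, length(values_b))) {
  stopifnot(length(values_a) == length(weights_a),
            length(values_b) == length(weights_b),
            length(values_a) >= 1, length(values_b) >= 1,
            all(weights_a > 0), all(weights_b > 0))
  W_A <- sum(weights_a); W_B <- sum(weights_b)
  if (W_A <= 0 || W_B <= 0) stop("group with zero total weight")
  v <- sort(unique(c(values_a, values_b)))
  ta <- numeric(length(v)); tb <- numeric(length(v))
  sa <- rowsum(weights_a, match(values_a, v))
  ta[as.integer(rownames(sa))] <- sa
  sb <- rowsum(weights_b, match(values_b, v))
  tb[as.integer(rownames(sb))] <- sb
  Tt <- ta + tb
  W <- W_A + W_B
  cum <- cumsum(Tt)
  rank_v <- cum - Tt + (Tt + 1) / 2     # weighted mid-ranks
  U <- sum(ta * rank_v) - W_A * (W_A + 1) / 2
  E0 <- W_A * W_B / 2
  tie <- sum(Tt^3 - Tt)
  V0 <- (W_A * W_B / 12) * ((W + 1) - tie / (W * (W - 1)))
  if (!is.finite(V0) || V0 <= 0) return(1)
  z <- (U - E0) / sqrt(V0)
  min(1, 2 * pnorm(-abs(z)))
}

#' Bootstrap confidence interval of the median (or mean) from a histogram
#'
#' Each bootstrap replicate draws `sample_size` bin values from the
#' cluster-normalized histogram with probability proportional to bin mass
#' and computes the statistic; the 95% confidence interval is the 2.5th to
#' 97.5th percentile of the replicate statistics. The default replicate size
#' is the total mass (the number of clusters), matching the weighting unit.
#' Medians are simulated exactly via the order statistics of uniforms
#' (Beta-distributed) pushed through the histogram's quantile function,
#' which is independent of `sample_size` in cost; means use chunked
#' multinomial draws. Deterministic given `seed`.
#'
#' @param hist An `allocomp_whist` from [weighted_histogram()].
#' @param statistic `"median"` or `"mean"`.
#' @param n_samples Number of bootstrap replicates (default 100000).
#' @param sample_size Draws per replicate; default `round(total_mass)`.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @return Numeric `c(lower, upper)` -- the 2.5% and 97.5% quantiles.
#' @export
bootstrap_ci <- function(hist, statistic = c("median", "mean"),
                         n_samples = 100000, sample_size = NULL, seed = 1) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(hist, "allocomp_whist"), hist$total_mass > 0,
            n_samples >= 1)
  if (is.null(sample_size)) sample_size <- max(1L, round(hist$total_mass))
  m <- as.integer(sample_size)
  stopifnot(m >= 1)
  vals <- hist$value
  prob <- hist$mass / hist$total_mass
  if (length(vals) == 1L) return(c(vals, vals))

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  cum <- cumsum(prob)
  Q <- function(u)
    vals[pmin(length(vals), findInterval(u, cum, left.open = TRUE) + 1L)]

  if (statistic == "median") {
    if (m %% 2L == 1L) {
      r <- (m + 1L) / 2
      reps <- Q(rbeta(n_samples, r, r))
    } else {
      r <- m / 2
      u1 <- rbeta(n_samples, r, m - r + 1)
      u2 <- u1 + (1 - u1) * rbeta(n_samples, 1, m - r)
      reps <- (Q(u1) + Q(u2)) / 2
    }
  } else {
    reps <- numeric(n_samples)
    chunk <- max(1L, min(n_samples, floor(4e6 / length(vals))))
    s <- 1L
    while (s <= n_samples) {
      e <- min(s + chunk - 1L, n_samples)
      cnt <- rmultinom(e - s + 1L, m, prob)
      reps[s:e] <- colSums(cnt * vals) / m
      s <- e + 1L
    }
  }
  unname(quantile(reps, c(0.025, 0.975), names = FALSE))
}

# pull one descriptor column for the cluster rows, aligned by ligand_id
.desc_values <- function(clusters_df, desc, column) {
  i <- match(clusters_df$ligand_id, desc$ligand_id)
  if (anyNA(i)) stop("descriptor table is missing ",
                     sum(is.na(i)), " clustered ligand(s)")
  desc[[column]][i]
}

#' Compare one descriptor between two clustered ligand sets
#'
#' The weighted scheme uses every ligand with cluster weights
#' ([cluster_weights()]), the weighted Wilcoxon test and histogram-bootstrap
#' CIs; the centers scheme uses one center per cluster with unit weights,
#' the plain Wilcoxon rank-sum test and straight bootstrap CIs. A difference
#' is significant at the level iff the two-sided p-value is below `alpha`
#' (default 1e-4) *and* the 95% bootstrap CIs of the two medians do not
#' overlap.
#'
#' @param code Descriptor code (see [descriptor_codes()]).
#' @param clusters_a,clusters_b `allocomp_clusters` for the two sets
#'   (conventionally a = allosteric, b = competitive).
#' @param desc_a,desc_b Descriptor tables with `ligand_id` plus the
#'   descriptor columns ([compute_descriptors()] output with ids attached).
#' @param scheme `"weighted"` or `"centers"`.
#' @param n_boot Bootstrap replicates per CI.
#' @param seed Bootstrap seed (set b uses `seed + 1`).
#' @param alpha Significance threshold on the p-value.
#' @param compute_ci `"always"`, or `"when_p_passes"` to skip the bootstrap
#'   (CIs reported NA, verdict necessarily not significant) when the p-value
#'   already fails `alpha`.
#' @return One-row data.frame: `code`, `scheme`, `median_a`, `median_b`,
#'   `ci_lo_a`, `ci_hi_a`, `ci_lo_b`, `ci_hi_b`, `p_value`, `significant`.
#' @export
compare_descriptor <- function(code, clusters_a, clusters_b, desc_a, desc_b,
                               scheme = c("weighted", "centers"),
                               n_boot = 100000, seed = 1, alpha = 1e-4,
                               compute_ci = c("always", "when_p_passes")) {
  scheme <- match.arg(scheme)
  compute_ci <- match.arg(compute_ci)
  da <- if (inherits(clusters_a, "allocomp_clusters")) clusters_a$clusters else clusters_a
  db <- if (inherits(clusters_b, "allocomp_clusters")) clusters_b$clusters else clusters_b
  if (scheme == "centers") {
    da <- da[da$is_center, , drop = FALSE]
    db <- db[db$is_center, , drop = FALSE]
    wa <- rep(1, nrow(da)); wb <- rep(1, nrow(db))
  } else {
    wa <- cluster_weights(da); wb <- cluster_weights(db)
  }
  r <- .compare_core(code, da, wa, db, wb, desc_a, desc_b, scheme,
                     n_boot, seed, alpha, compute_ci)
  as.data.frame(r, stringsAsFactors = FALSE)
}

# shared comparison core; returns a plain list (one result row)
.compare_core <- function(code, da, wa, db, wb, desc_a, desc_b, scheme,
                          n_boot, seed, alpha, compute_ci) {
  dc <- descriptor_codes()
  column <- dc$column[match(code, dc$code)]
  if (is.na(column)) stop("unknown descriptor code: ", code)
  xa <- .desc_values(da, desc_a, column)
  xb <- .desc_values(db, desc_b, column)

  p <- if (scheme == "centers")
    suppressWarnings(wilcox.test(xa, xb, exact = FALSE)$p.value)
  else
    weighted_wilcoxon(xa, wa, xb, wb)

  ha <- weighted_histogram(xa, wa, code = code)
  hb <- weighted_histogram(xb, wb, code = code)
  med_a <- weighted_median(ha)
  med_b <- weighted_median(hb)

  if (compute_ci == "always" || (is.finite(p) && p < alpha)) {
    ci_a <- bootstrap_ci(ha, "median", n_boot, seed = seed)
    ci_b <- bootstrap_ci(hb, "median", n_boot, seed = seed + 1)
    disjoint <- ci_a[1] > ci_b[2] || ci_b[1] > ci_a[2]
    significant <- is.finite(p) && p < alpha && disjoint
  } else {
    ci_a <- ci_b <- c(NA_real_, NA_real_)
    significant <- FALSE
  }
  list(code = code, scheme = scheme,
       median_a = med_a, median_b = med_b,
       ci_lo_a = ci_a[1], ci_hi_a = ci_a[2],
       ci_lo_b = ci_b[1], ci_hi_b = ci_b[2],
       p_value = p, significant = significant)
}

#' Compare all (or selected) descriptors at one clustering level
#'
#' @inheritParams compare_descriptor
#' @param codes Descriptor codes to compare; default all 29.
#' @return Data.frame with one row per code (see [compare_descriptor()]),
#'   plus `seq_identity_pct` and `tc_threshold` taken from `clusters_a`.
#' @export
compare_all_descriptors <- function(clusters_a, clusters_b, desc_a, desc_b,
                                    codes = descriptor_codes()$code,
                                    scheme = "weighted", n_boot = 100000,
                                    seed = 1, alpha = 1e-4,
                                    compute_ci = "always") {
  da <- if (inherits(clusters_a, "allocomp_clusters")) clusters_a$clusters else clusters_a
  db <- if (inherits(clusters_b, "allocomp_clusters")) clusters_b$clusters else clusters_b
  if (scheme == "centers") {
    da <- da[da$is_center, , drop = FALSE]
    db <- db[db$is_center, , drop = FALSE]
    wa <- rep(1, nrow(da)); wb <- rep(1, nrow(db))
  } else {
    wa <- cluster_weights(da); wb <- cluster_weights(db)
  }
  rows <- lapply(codes, function(cd)
    .compare_core(cd, da, wa, db, wb, desc_a, desc_b, scheme,
                  n_boot, seed, alpha, compute_ci))
  out <- data.frame(
    code = vapply(rows, `[[`, "", "code"),
    scheme = scheme,
    median_a = vapply(rows, `[[`, 1, "median_a"),
    median_b = vapply(rows, `[[`, 1, "median_b"),
    ci_lo_a = vapply(rows, `[[`, 1, "ci_lo_a"),
    ci_hi_a = vapply(rows, `[[`, 1, "ci_hi_a"),
    ci_lo_b = vapply(rows, `[[`, 1, "ci_lo_b"),
    ci_hi_b = vapply(rows, `[[`, 1, "ci_hi_b"),
    p_value = vapply(rows, `[[`, 1, "p_value"),
    significant = vapply(rows, `[[`, TRUE, "significant"),
    stringsAsFactors = FALSE)
  lv <- if (inherits(clusters_a, "allocomp_clusters")) clusters_a$level
  else c(seq_identity_pct = NA, tc_threshold = NA)
  out$seq_identity_pct <- lv[["seq_identity_pct"]]
  out$tc_threshold <- lv[["tc_threshold"]]
  out
}

#' Robustness verdict across the four clustering levels
#'
#' A descriptor difference is accepted only if it is significant with a
#' consistent direction at every one of the four clustering levels.
#'
#' @param results Data.frame of per-level comparisons
#'   ([compare_all_descriptors()] rows for all four levels), containing
#'   `code`, `tc_threshold`, `significant`, `median_a`, `median_b`.
#' @return Data.frame `code`, `significant_all_levels`, `direction`
#'   (`"a_higher"`, `"b_higher"`, or `"none"`).
#' @export
robust_verdict <- function(results) {
  need <- c("code", "tc_threshold", "significant", "median_a", "median_b")
  stopifnot(all(need %in% names(results)))
  out <- lapply(split(results, results$code), function(r) {
    if (length(unique(r$tc_threshold)) != 4L)
      stop("robust_verdict needs results at exactly the four levels; code ",
           r$code[1L], " has ", length(unique(r$tc_threshold)))
    dir <- sign(r$median_a - r$median_b)
    ok <- all(r$significant) && length(unique(dir)) == 1L && dir[1L] != 0
    data.frame(code = r$code[1L], significant_all_levels = ok,
               direction = if (!ok) "none"
               else if (dir[1L] > 0) "a_higher" else "b_higher",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Single-level (chemistry-only) sanity-check analysis
#'
#' Ignores protein families: each ligand set is clustered globally at each
#' Tanimoto threshold and the sets are compared per threshold with the
#' weighted scheme. When every protein is unrelated to every other (each
#' family a single protein, each ligand a single target) this coincides with
#' the two-level analysis.
#'
#' @param ligands_a,ligands_b Curated ligand records for the two sets.
#' @param desc_a,desc_b Descriptor tables (with `ligand_id`).
#' @param tc_thresholds Tanimoto thresholds (default the four study levels).
#' @param codes Descriptor codes to compare.
#' @inheritParams compare_descriptor
#' @return Data.frame of comparisons with a `tc_threshold` column.
#' @export
single_level_analysis <- function(ligands_a, ligands_b, desc_a, desc_b,
                                  tc_thresholds = c(0.6, 0.75, 0.9, 1.0),
                                  codes = descriptor_codes()$code,
                                  n_boot = 100000, seed = 1, alpha = 1e-4,
                                  compute_ci = "always") {
  res <- lapply(tc_thresholds, function(tc) {
    ca <- cluster_ligand_set(ligands_a, tc)
    cb <- cluster_ligand_set(ligands_b, tc)
    compare_all_descriptors(ca, cb, desc_a, desc_b, codes = codes,
                            scheme = "weighted", n_boot = n_boot,
                            seed = seed, alpha = alpha,
                            compute_ci = compute_ci)
  })
  do.call(rbind, res)
}
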