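# End-to-end orchestration: ingest -> descriptors -> two-level clustering at
# each level -> weighted / centers comparisons -> robust verdicts -> chemical
# overlap, plus report assembly. The run is a pure function of
# (inputs, config, seed).

#' Pipeline configuration
#'
#' @param levels Data.frame of clustering levels (default all four of
#'   [clustering_levels()]). Robust verdicts require all four.
#' @param scheme `"weighted"`, `"centers"`, or `"both"`.
#' @param n_boot Bootstrap replicates per confidence interval.
#' @param seed Seed for all stochastic steps (bootstrap).
#' @param alpha Wilcoxon significance threshold (default 1e-4).
#' @param max_targets Panel-artifact threshold for curation.
#' @param tc_overlap Tanimoto threshold for the cross-set overlap count.
#' @param single_level Also run the chemistry-only single-level analysis.
#' @param n_bits ECFP6 width.
#' @param compute_ci `"always"` or `"when_p_passes"` (see
#'   [compare_descriptor()]).
#' @param codes Descriptor codes to analyze (default all 29).
#' @param set_a,set_b The two set labels (a is reported first).
#' @return List of class `allocomp_config`.
#' @export
allocomp_config <- function(levels = clustering_levels(),
                            scheme = c("weighted", "centers", "both"),
                            n_boot = 100000, seed = 1, alpha = 1e-4,
                            max_targets = 100, tc_overlap = 0.6,
                            single_level = FALSE, n_bits = 2048,
                            compute_ci = c("always", "when_p_passes"),
                            codes = descriptor_codes()$code,
                            set_a = "allosteric", set_b = "competitive") {
  scheme <- match.arg(scheme)
  compute_ci <- match.arg(compute_ci)
  structure(as.list(environment()), class = "allocomp_config")
}

# djb2 rolling hash over a string; used to stamp outputs with a config hash
.str_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

.config_hash <- function(config) {
  .str_hash(paste(deparse(config), collapse = ""))
}

#' Run the full two-set comparison pipeline
#'
#' Stages: curation ([curate_ligands()] per set, with optional assay
#' filtering), descriptor calculation, two-level clustering at each
#' configured level, weighted (and optionally center-based) comparison of
#' every descriptor, the four-level robustness verdict, and the cross-set
#' ECFP6/Tanimoto overlap count.
#'
#' @param ligands Raw ligand table (data.frame from [read_ligand_table()] or
#'   a [generate_study()]'s `$ligands`), or a path to one.
#' @param proteins Protein table (from [read_protein_fasta()] or a study's
#'   `$proteins`), or a path to a FASTA file.
#' @param assays Optional assay table or path; when given, each set is
#'   filtered by its mechanism keyword and the active-molecule rule.
#' @param config An [allocomp_config()].
#' @return Object of class `allocomp`; see [print.allocomp()],
#'   [summary.allocomp()], [write_allocomp()]. Main components:
#'   `counts`, `comparisons`, `verdicts`, `overlap`, `scatter`, `summary`
#'   (the machine-readable list serialized by [write_allocomp()]).
#' @export
allocomp_run <- function(ligands, proteins, assays = NULL,
                         config = allocomp_config()) {
  stopifnot(inherits(config, "allocomp_config"))
  if (is.character(ligands)) ligands <- read_ligand_table(ligands)
  if (is.character(proteins)) proteins <- read_protein_fasta(proteins)
  if (is.character(assays)) assays <- read_assay_table(assays)
  if (!"smiles_raw" %in% names(ligands) && "smiles" %in% names(ligands))
    names(ligands)[names(ligands) == "smiles"] <- "smiles_raw"

  labels <- c(config$set_a, config$set_b)
  if (!all(labels %in% ligands$set_label))
    stop("ligand table lacks the configured set labels: ",
         paste(setdiff(labels, ligands$set_label), collapse = ", "))

  curated <- setNames(lapply(labels, function(lb) {
    curate_ligands(ligands[ligands$set_label == lb, , drop = FALSE],
                   assays = assays, mode = lb,
                   max_targets = config$max_targets)
  }), labels)

  dc <- descriptor_codes()
  desc_cols <- unique(c("a_heavy", "SlogP",  # scatter export needs these
                        dc$column[match(config$codes, dc$code)]))
  desc <- setNames(lapply(labels, function(lb) {
    lg <- curated[[lb]]$ligands
    d <- compute_descriptors(lg$smiles_canonical, columns = desc_cols)
    cbind(ligand_id = lg$ligand_id, d, stringsAsFactors = FALSE)
  }), labels)

  # two-level clustering and per-level comparisons
  schemes <- if (config$scheme == "both") c("weighted", "centers")
  else config$scheme
  comp_rows <- list(); cluster_sets <- list(); count_rows <- list()
  for (li in seq_len(nrow(config$levels))) {
    sq <- config$levels$seq_identity_pct[li]
    tc <- config$levels$tc_threshold[li]
    cl <- setNames(lapply(labels, function(lb)
      build_protein_ligand_clusters(curated[[lb]]$ligands, proteins,
                                    sq, tc, n_bits = config$n_bits)), labels)
    cluster_sets[[sprintf("%g/%g", sq, tc)]] <- cl
    for (sc in schemes) {
      comp_rows[[length(comp_rows) + 1L]] <-
        compare_all_descriptors(cl[[1]], cl[[2]], desc[[1]], desc[[2]],
                                codes = config$codes, scheme = sc,
                                n_boot = config$n_boot, seed = config$seed,
                                alpha = config$alpha,
                                compute_ci = config$compute_ci)
    }
    count_rows[[length(count_rows) + 1L]] <- data.frame(
      seq_identity_pct = sq, tc_threshold = tc, set_label = labels,
      n_families = vapply(cl, function(x)
        length(unique(x$families$family_id)), 1L),
      n_clusters = vapply(cl, function(x)
        length(unique(x$clusters$cluster_id)), 1L),
      stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, comp_rows)
  level_counts <- do.call(rbind, count_rows)
  rownames(level_counts) <- NULL

  verdicts <- NULL
  if (nrow(config$levels) == 4L && "weighted" %in% schemes)
    verdicts <- robust_verdict(
      comparisons[comparisons$scheme == "weighted", , drop = FALSE])

  fps <- lapply(labels, function(lb)
    ecfp6(unique(curated[[lb]]$ligands$smiles_canonical), config$n_bits))
  overlap <- cross_set_neighbor_count(fps[[1]], fps[[2]], config$tc_overlap)

  single <- NULL
  if (isTRUE(config$single_level))
    single <- single_level_analysis(curated[[1]]$ligands, curated[[2]]$ligands,
                                    desc[[1]], desc[[2]],
                                    tc_thresholds = config$levels$tc_threshold,
                                    codes = config$codes,
                                    n_boot = config$n_boot, seed = config$seed,
                                    alpha = config$alpha,
                                    compute_ci = config$compute_ci)

  scatter <- do.call(rbind, lapply(labels, function(lb)
    data.frame(set_label = lb, a_heavy = desc[[lb]]$a_heavy,
               SlogP = desc[[lb]]$SlogP, stringsAsFactors = FALSE)))

  counts <- data.frame(
    set_label = labels,
    n_input_rows = vapply(labels, function(lb)
      sum(ligands$set_label == lb), 1L),
    n_unique_ligands = vapply(labels, function(lb)
      length(unique(curated[[lb]]$ligands$smiles_canonical)), 1L),
    n_proteins = vapply(labels, function(lb)
      length(unique(unlist(strsplit(curated[[lb]]$ligands$target_ids,
                                    ";", fixed = TRUE)))), 1L),
    n_rejected = vapply(labels, function(lb)
      nrow(curated[[lb]]$rejected), 1L),
    n_panel_flagged = vapply(labels, function(lb)
      length(curated[[lb]]$flagged), 1L),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL

  wsum <- comparisons[comparisons$scheme == "weighted", , drop = FALSE]
  summary_list <- list(
    config_hash = .config_hash(config), seed = config$seed,
    sets = counts,
    level_counts = level_counts,
    overlap = overlap,
    n_significant_per_level = if (nrow(wsum)) aggregate(
      significant ~ tc_threshold, wsum, sum) else NULL,
    robust = if (!is.null(verdicts))
      verdicts$code[verdicts$significant_all_levels] else character(0))

  structure(list(config = config, counts = counts,
                 level_counts = level_counts,
                 comparisons = comparisons, verdicts = verdicts,
                 overlap = overlap, single_level = single,
                 scatter = scatter, curated = curated, descriptors = desc,
                 clusters = cluster_sets, summary = summary_list),
            class = "allocomp")
}

#' @export
print.allocomp <- function(x, ...) {
  cat("allocomp comparison of", x$config$set_a, "(a) vs",
      x$config$set_b, "(b)\n")
  cat(sprintf("  %s: %d unique ligands, %d proteins; %s: %d, %d\n",
              x$counts$set_label[1], x$counts$n_unique_ligands[1],
              x$counts$n_proteins[1], x$counts$set_label[2],
              x$counts$n_unique_ligands[2], x$counts$n_proteins[2]))
  if (!is.null(x$verdicts)) {
    rb <- x$verdicts[x$verdicts$significant_all_levels, , drop = FALSE]
    if (nrow(rb))
      cat("  robust at all four levels:",
          paste(sprintf("%s (%s)", rb$code, rb$direction), collapse = ", "),
          "\n")
    else cat("  no descriptor significant at all four levels\n")
  }
  cat(sprintf("  chemical overlap at Tc >= %g: %d/%d of a near b, %d/%d of b near a\n",
              x$config$tc_overlap, x$overlap$count_a, x$overlap$total_a,
              x$overlap$count_b, x$overlap$total_b))
  invisible(x)
}

#' Summarize an allocomp run
#'
#' @param object An `allocomp` object.
#' @param scheme Which scheme's comparisons to tabulate.
#' @param ... Unused.
#' @return Data.frame: per descriptor and level, medians with CI half-widths,
#'   p-value and the significance flag.
#' @export
summary.allocomp <- function(object, scheme = "weighted", ...) {
  cp <- object$comparisons
  cp <- cp[cp$scheme == scheme, , drop = FALSE]
  data.frame(code = cp$code,
             level = sprintf("%g/%g", cp$seq_identity_pct, cp$tc_threshold),
             median_a = cp$median_a, median_b = cp$median_b,
             ci_a = sprintf("(%s, %s)", format(cp$ci_lo_a), format(cp$ci_hi_a)),
             ci_b = sprintf("(%s, %s)", format(cp$ci_lo_b), format(cp$ci_hi_b)),
             p_value = cp$p_value, significant = cp$significant,
             stringsAsFactors = FALSE)
}

#' Plot the cluster-normalized histograms of one descriptor
#'
#' Overlays the display-normalized (unit-area) weighted histograms of the
#' two sets at one clustering level, base-graphics style.
#'
#' @param x An `allocomp` object.
#' @param code Descriptor code (default `"a_aro/HA"`).
#' @param level Index into the configured levels (default 1).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot.allocomp <- function(x, code = "a_aro/HA", level = 1, ...) {
  dc <- descriptor_codes()
  column <- dc$column[match(code, dc$code)]
  lv <- names(x$clusters)[level]
  cl <- x$clusters[[lv]]
  labels <- names(cl)
  hs <- lapply(labels, function(lb) {
    df <- cl[[lb]]$clusters
    w <- cluster_weights(df)
    v <- .desc_values(df, x$descriptors[[lb]], column)
    weighted_histogram(v, w, code = code)
  })
  xr <- range(unlist(lapply(hs, `[[`, "value")))
  yr <- c(0, max(unlist(lapply(hs, function(h) h$mass / h$total_mass))))
  graphics::plot(NA, xlim = xr + c(0, hs[[1]]$bin_width), ylim = yr,
                 xlab = code, ylab = "normalized mass",
                 main = sprintf("%s at level %s", code, lv), ...)
  cols <- c("#3366ccaa", "#cc3333aa")
  for (i in seq_along(hs))
    graphics::rect(hs[[i]]$value, 0, hs[[i]]$value + hs[[i]]$bin_width,
                   hs[[i]]$mass / hs[[i]]$total_mass, col = cols[i],
                   border = NA)
  graphics::legend("topright", legend = labels, fill = cols, bty = "n")
  invisible(NULL)
}

#' Write an allocomp run's report files
#'
#' Writes `comparisons.csv` (all schemes and levels), `verdicts.csv`,
#' `level_counts.csv`, `scatter.csv` (SlogP vs heavy atoms per ligand),
#' `report.md` (a human-readable medians table with significance bolding),
#' and `summary.json` (the canonical machine-readable summary, stamped with
#' the config hash and seed). Rerunning the same inputs with the same
#' config produces byte-identical JSON.
#'
#' @param x An `allocomp` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_allocomp <- function(x, dir) {
  stopifnot(inherits(x, "allocomp"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$comparisons, file.path(dir, "comparisons.csv"),
            row.names = FALSE)
  if (!is.null(x$verdicts))
    write.csv(x$verdicts, file.path(dir, "verdicts.csv"), row.names = FALSE)
  write.csv(x$level_counts, file.path(dir, "level_counts.csv"),
            row.names = FALSE)
  write.csv(x$scatter, file.path(dir, "scatter.csv"), row.names = FALSE)
  if (!is.null(x$single_level))
    write.csv(x$single_level, file.path(dir, "single_level.csv"),
              row.names = FALSE)

  md <- c(sprintf("# allocomp report (config %s, seed %d)",
                  x$summary$config_hash, x$config$seed), "",
          sprintf("| code | level | %s | %s | p |", x$config$set_a,
                  x$config$set_b),
          "|---|---|---|---|---|")
  cp <- x$comparisons[x$comparisons$scheme ==
                        x$comparisons$scheme[1], , drop = FALSE]
  fmt <- function(m, lo, hi, sig) {
    s <- sprintf("%g (%s, %s)", m, format(lo), format(hi))
    if (isTRUE(sig)) paste0("**", s, "**") else s
  }
  for (i in seq_len(nrow(cp)))
    md <- c(md, sprintf("| %s | %g/%g | %s | %s | %.3g |",
                        cp$code[i], cp$seq_identity_pct[i],
                        cp$tc_threshold[i],
                        fmt(cp$median_a[i], cp$ci_lo_a[i], cp$ci_hi_a[i],
                            cp$significant[i]),
                        fmt(cp$median_b[i], cp$ci_lo_b[i], cp$ci_hi_b[i],
                            cp$significant[i]),
                        cp$p_value[i]))
  writeLines(md, file.path(dir, "report.md"))
  jsonlite::write_json(x$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
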