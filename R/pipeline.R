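# End-to-end orchestration: simulate (or load) -> differential contrasts ->
# Venn intersection -> panel scan / LOOCV / permutation -> independent
# validation -> distance and ordination geometry -> optional clinical table,
# with a machine-readable run report.

#' Assemble and validate a pipeline configuration
#'
#' Exactly one input source must be given: either file paths (`gct`, `cls`
#' or `annotations`) for a preprocessed cohort, or a [cohort_design()] for
#' simulation (in which case an independent validation cohort is simulated
#' from the same design at a shifted seed).
#'
#' @param design a [cohort_design()], or `NULL` when loading from files.
#' @param gct,annotations paths to a GCT matrix and a delimited annotation
#'   table (columns as in [simulate_cohort()] annotations), or `NULL`.
#' @param q_signature q-value threshold for the two signature contrasts.
#' @param q_reference_axis q-value threshold for the reference
#'   (ESC vs hepatic) differentiation-axis probes. Cohort-scale studies can
#'   afford thresholds as strict as 1e-4 here; the default suits the few
#'   reference replicates per class of the generator, where Welch p-values
#'   have a much higher attainable floor.
#' @param scan_sizes candidate panel sizes; sizes exceeding the candidate
#'   pool are clipped to it.
#' @param permutation_B permutations for the error-rate null.
#' @param metric distance metric for the geometry stage.
#' @param seed master seed; each stochastic stage uses `seed` plus a small
#'   fixed offset so stages are independently reproducible.
#' @param out_dir optional directory for TSV/JSON outputs (created on run);
#'   `NULL` keeps the run in memory.
#' @param clinical_table optional per-patient data frame for
#'   [clinical_compare()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = NULL, gct = NULL, annotations = NULL,
                            q_signature = 0.05, q_reference_axis = 0.01,
                            scan_sizes = c(5, 10, 15, 20, 30, 50, 100),
                            permutation_B = 1000,
                            metric = c("euclidean", "one_minus_pearson"),
                            seed, out_dir = NULL, clinical_table = NULL) {
  if (missing(seed)) stop("a seed is required")
  metric <- match.arg(metric)
  has_files <- !is.null(gct) || !is.null(annotations)
  if (!is.null(design) && has_files) {
    stop("give either a simulation design or input file paths, not both")
  }
  if (is.null(design) && !(!is.null(gct) && !is.null(annotations))) {
    stop("either a simulation design or both gct and annotations paths ",
         "are required")
  }
  structure(list(design = design, gct = gct, annotations = annotations,
                 q_signature = q_signature,
                 q_reference_axis = q_reference_axis,
                 scan_sizes = scan_sizes, permutation_B = permutation_B,
                 metric = metric, seed = as.integer(seed), out_dir = out_dir,
                 clinical_table = clinical_table),
            class = "pipeline_config")
}

# internal: load a cohort from config files into the simulate_cohort() shape
.load_cohort <- function(gct, annotations_path) {
  expr <- read_gct(gct)
  sep <- if (grepl("\\.csv$", annotations_path)) "," else "\t"
  ann <- utils::read.delim(annotations_path, sep = sep,
                           stringsAsFactors = FALSE)
  aligned <- align_samples(expr, ann)
  structure(list(expr = aligned$expr, annotations = aligned$annotations,
                 truth = NULL, design = NULL),
            class = "cohort")
}

#' Run the full signature-discovery pipeline
#'
#' Stage order: cohort acquisition, the two differential contrasts (young vs
#' elderly tumors; tumor vs non-tumor in young patients), Venn intersection,
#' weighted-voting panel scan over the intersection pool with LOOCV, the
#' permutation null of the error rate, validation of the frozen panel on an
#' independent cohort (simulated designs only), whole-transcriptome MDS,
#' group-to-ESC linkage distances over the age signature, reference-axis PCA
#' with tumor projection (when reference samples are present), and the
#' optional clinical comparison. A failing stage aborts with its name.
#' Rerunning an identical configuration is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report` (nested list; see
#'   [report_to_json()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  simulated <- !is.null(config$design)
  cohorts <- stage("input", {
    if (simulated) {
      design <- config$design
      design$seed <- config$seed
      # same probe plan and baselines, independent patients and noise
      list(train = simulate_cohort(design),
           validation = simulate_cohort(design,
                                        cohort_seed = config$seed + 1L))
    } else {
      list(train = .load_cohort(config$gct, config$annotations),
           validation = NULL)
    }
  })
  train <- cohorts$train

  de <- stage("differential_expression", {
    age <- cohort_contrast(train, "age")
    tumor <- cohort_contrast(train, "tumor")
    list(age = de_contrast(age$expr, age$labels, config$q_signature, "age"),
         tumor = de_contrast(tumor$expr, tumor$labels, config$q_signature,
                             "tumor"),
         age_labels = age$labels, age_expr = age$expr)
  })
  sig_int <- stage("intersection", {
    suppressMessages(
      intersect_signatures(de$age$signature, de$tumor$signature))
  })
  if (nrow(sig_int) < 2L) {
    stop("pipeline stage 'intersection' failed: intersection signature has ",
         nrow(sig_int), " probe(s); nothing to train on", call. = FALSE)
  }

  classify <- stage("weighted_voting", {
    pool <- sig_int$probe_id
    sizes <- unique(pmin(as.integer(config$scan_sizes), length(pool)))
    scan <- panel_scan(de$age_expr, de$age_labels, sizes, probes = pool)
    cv <- loocv_error(de$age_expr, de$age_labels, top_k = scan$selected,
                      probes = pool)
    perm <- permutation_test(de$age_expr, de$age_labels,
                             top_k = scan$selected, B = config$permutation_B,
                             seed = config$seed + 2L, probes = pool)
    panel <- train_panel(de$age_expr, de$age_labels, probes = pool)
    list(pool_size = length(pool), scan = scan, cv = cv, perm = perm,
         panel = panel)
  })

  validation <- if (!is.null(cohorts$validation)) {
    stage("validation", {
      va <- cohort_contrast(cohorts$validation, "age")
      validate_panel(classify$panel, va$expr, va$labels,
                     top_k = classify$scan$selected)
    })
  } else NULL

  geometry <- stage("geometry", {
    ann <- train$annotations
    grp <- ifelse(ann$tissue == "reference", ann$reference_class,
                  paste(ann$age_group, ann$tissue, sep = "_"))
    grp[grp %in% c("young_non_tumor", "elderly_non_tumor")] <- "non_tumor"
    names(grp) <- ann$sample_id
    mds <- classical_mds(pairwise_distance(train$expr,
                                           metric = config$metric), k = 2)
    dist_table <- if ("ESC" %in% grp) {
      d_sig <- pairwise_distance(train$expr, probes = de$age$signature,
                                 metric = config$metric)
      group_linkage_table(d_sig, grp[grp != "hepatic_day20"], "ESC")
    } else NULL
    projection <- if (all(c("ESC", "hepatic_day20") %in% grp)) {
      ref <- cohort_contrast(train, "reference")
      ref_de <- de_contrast(ref$expr, ref$labels, config$q_reference_axis,
                            "reference_axis")
      if (nrow(ref_de$signature) >= 2L) {
        fit <- pca_fit(ref$expr, probes = ref_de$signature)
        tumor_ids <- ann$sample_id[ann$tissue == "tumor"]
        coords <- pca_project(fit, train$expr[, tumor_ids, drop = FALSE])
        centroids <- tapply(coords[, 1L], grp[tumor_ids], mean)
        # sign the axis so that the ESC pole is positive
        esc_pc1 <- mean(fit$points[ref$labels$labels == 1L, 1L])
        hep_pc1 <- mean(fit$points[ref$labels$labels == 2L, 1L])
        flip <- if (esc_pc1 < hep_pc1) -1 else 1
        list(n_axis_probes = nrow(ref_de$signature),
             axis_var_explained = fit$var_explained[1L],
             tumor_pc1 = flip * coords[, 1L],
             centroids_pc1 = flip * centroids)
      } else NULL
    } else NULL
    list(mds = mds, dist_table = dist_table, projection = projection)
  })

  clinical <- if (!is.null(config$clinical_table)) {
    stage("clinical", clinical_compare(config$clinical_table))
  } else NULL

  report <- structure(list(
    software = list(package = "votesig",
                    version = as.character(utils::packageVersion("votesig"))),
    seed = config$seed,
    config = list(q_signature = config$q_signature,
                  q_reference_axis = config$q_reference_axis,
                  scan_sizes = as.integer(config$scan_sizes),
                  permutation_B = config$permutation_B,
                  metric = config$metric,
                  simulated = simulated),
    signatures = list(
      n_age = nrow(de$age$signature),
      n_tumor = nrow(de$tumor$signature),
      n_intersection = nrow(sig_int),
      intersection_up_down = as.list(up_down_split(sig_int))
    ),
    classifier = list(
      pool_size = classify$pool_size,
      scan = list(sizes = classify$scan$sizes,
                  errors = classify$scan$errors),
      selected_size = classify$scan$selected,
      loocv_error = classify$cv$error,
      permutation_p = classify$perm$p_value,
      validation_error = if (!is.null(validation)) validation$error else NULL
    ),
    geometry = list(
      mds_coordinates = as.data.frame(geometry$mds$points),
      esc_distances = if (!is.null(geometry$dist_table)) {
        geometry$dist_table
      } else list(),
      reference_axis = if (!is.null(geometry$projection)) {
        list(n_axis_probes = geometry$projection$n_axis_probes,
             axis_var_explained = geometry$projection$axis_var_explained,
             centroids_pc1 = as.list(geometry$projection$centroids_pc1))
      } else list()
    ),
    clinical = if (!is.null(clinical)) clinical else list()
  ), class = "run_report")

  attr(report, "objects") <- list(
    train = train, validation = cohorts$validation, de = de,
    intersection = sig_int, classify = classify,
    validation_result = validation, geometry = geometry
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    report_to_json(report, file.path(config$out_dir, "run_report.json"))
    report_to_tsv(report, config$out_dir)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed ", x$seed, "\n",
      "  signatures: age ", x$signatures$n_age, ", tumor ",
      x$signatures$n_tumor, ", intersection ", x$signatures$n_intersection,
      " (up ", x$signatures$intersection_up_down$up, ", down ",
      x$signatures$intersection_up_down$down, ")\n",
      "  classifier: selected size ", x$classifier$selected_size,
      ", LOOCV error ", format(x$classifier$loocv_error, digits = 3),
      ", permutation p ", format(x$classifier$permutation_p, digits = 3),
      if (!is.null(x$classifier$validation_error)) {
        paste0(", validation error ",
               format(x$classifier$validation_error, digits = 3))
      } else "", "\n", sep = "")
  if (is.data.frame(x$geometry$esc_distances) &&
      nrow(x$geometry$esc_distances) > 0L) {
    cat("  distance to ESC (age-signature probes):\n")
    print(x$geometry$esc_distances, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a run report as JSON
#'
#' Stable key order (the report's own), scalars unboxed, numbers at fixed
#' precision; the clinical section serializes as an empty array when absent
#' rather than a missing key.
#'
#' @param report a `run_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
report_to_json <- function(report, path) {
  out <- unclass(report)
  attr(out, "objects") <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "rows", na = "null")
  invisible(path)
}

#' Write the tabular parts of a run report as TSV files
#'
#' Emits `scan_curve.tsv`, `esc_distances.tsv`, `mds_coordinates.tsv`,
#' `intersection_signature.tsv`, `panel.tsv` and (when present)
#' `validation_predictions.tsv` and `clinical.tsv` into `dir`.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
report_to_tsv <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  objects <- attr(report, "objects")
  written <- character(0)
  emit <- function(df, name, rownames_as = NULL) {
    path <- file.path(dir, name)
    if (!is.null(rownames_as)) {
      df <- cbind(stats::setNames(data.frame(rownames(df)), rownames_as), df)
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
  }
  emit(data.frame(size = report$classifier$scan$sizes,
                  loocv_error = report$classifier$scan$errors),
       "scan_curve.tsv")
  emit(report$geometry$mds_coordinates, "mds_coordinates.tsv", "sample_id")
  if (is.data.frame(report$geometry$esc_distances)) {
    emit(report$geometry$esc_distances, "esc_distances.tsv")
  }
  if (!is.null(objects)) {
    emit(as.data.frame(objects$intersection), "intersection_signature.tsv")
    emit(as.data.frame(objects$classify$panel), "panel.tsv")
    if (!is.null(objects$validation_result)) {
      emit(objects$validation_result$predictions,
           "validation_predictions.tsv")
    }
  }
  if (is.data.frame(report$clinical) && nrow(report$clinical) > 0L) {
    emit(as.data.frame(report$clinical), "clinical.tsv")
  }
  invisible(written)
}
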