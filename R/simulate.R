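#' Describe a synthetic two-age-group tumor cohort
#'
#' The generator plants the statistical structure the downstream analysis
#' assumes: paired tumor/non-tumor samples in a young and an elderly patient
#' group, probe sets truly differential between young and elderly tumors
#' (`n_age_de`) and between tumor and non-tumor tissue (`n_tumor_de`) with a
#' configurable overlap, embryonic-stem-cell (ESC) and day-20
#' hepatic-progenitor reference profiles at the two poles of a planted
#' differentiation axis, and tumor groups displaced toward the ESC pole in
#' proportion to a stemness coordinate (young tumors at
#' `stemness_gradient`, elderly tumors at half of it, non-tumor tissue at 0).
#'
#' Shift placement follows the Venn logic of the two contrasts: probes in the
#' age/tumor overlap are shifted in young tumors only (differential in both
#' contrasts); the remaining age-differential probes are shifted in all young
#' samples (age contrast only); the remaining tumor-differential probes are
#' shifted in all tumors (tumor contrast only). The ESC reference profile
#' carries the full age-differential pattern in addition to the axis
#' displacement, emulating signatures whose age-associated genes are
#' themselves stem-cell genes.
#'
#' @param n_young,n_elderly tumor patients per age group.
#' @param paired_fraction fraction of patients contributing a matched
#'   non-tumor sample.
#' @param n_probes total probe count.
#' @param n_age_de probes truly differential young-tumor vs elderly-tumor.
#' @param n_tumor_de probes truly differential tumor vs non-tumor.
#' @param overlap probes shared between the two differential sets.
#' @param effect_size_log2 mean shift per differential probe (log2 units).
#' @param noise_sd_log2 within-group standard deviation (log2 units).
#' @param n_reference samples per reference class (ESC, hepatic day 20).
#' @param stemness_gradient in `[0, 1]`: stemness coordinate of young tumors
#'   along the differentiation axis (elderly tumors sit at half this value).
#' @param patient_sd_log2 standard deviation of the per-patient random
#'   intercept shared by a patient's tumor and non-tumor sample.
#' @param n_axis probes forming the planted differentiation axis (disjoint
#'   from the differential sets).
#' @param axis_effect_log2 per-probe displacement of the ESC pole from the
#'   hepatic pole along the axis (log2 units).
#' @param baseline_mean,baseline_sd distribution of per-probe baseline means.
#' @param seed integer seed; the same design simulates bit-identically.
#' @return a validated list of class `cohort_design`.
#' @export
cohort_design <- function(n_young = 20, n_elderly = 20, paired_fraction = 0.8,
                          n_probes = 1000, n_age_de = 50, n_tumor_de = 100,
                          overlap = 30, effect_size_log2 = 2,
                          noise_sd_log2 = 0.5, n_reference = 4,
                          stemness_gradient = 0.8, patient_sd_log2 = 0.2,
                          n_axis = 300, axis_effect_log2 = 2,
                          baseline_mean = 7, baseline_sd = 1.5, seed) {
  if (missing(seed)) stop("a seed is required")
  d <- list(n_young = n_young, n_elderly = n_elderly,
            paired_fraction = paired_fraction, n_probes = n_probes,
            n_age_de = n_age_de, n_tumor_de = n_tumor_de, overlap = overlap,
            effect_size_log2 = effect_size_log2,
            noise_sd_log2 = noise_sd_log2, n_reference = n_reference,
            stemness_gradient = stemness_gradient,
            patient_sd_log2 = patient_sd_log2, n_axis = n_axis,
            axis_effect_log2 = axis_effect_log2,
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            seed = as.integer(seed))
  counts <- c("n_young", "n_elderly", "n_probes", "n_age_de", "n_tumor_de",
              "overlap", "n_reference", "n_axis")
  for (f in counts) {
    if (length(d[[f]]) != 1L || is.na(d[[f]]) || d[[f]] < 0) {
      stop("design field '", f, "' must be a single non-negative count")
    }
  }
  if (d$overlap > min(d$n_age_de, d$n_tumor_de)) {
    stop("overlap cannot exceed min(n_age_de, n_tumor_de)")
  }
  union_de <- d$n_age_de + d$n_tumor_de - d$overlap
  if (d$n_probes < union_de + d$n_axis) {
    stop("n_probes must be at least n_age_de + n_tumor_de - overlap + n_axis")
  }
  if (d$noise_sd_log2 <= 0) stop("noise_sd_log2 must be positive")
  if (d$paired_fraction < 0 || d$paired_fraction > 1) {
    stop("paired_fraction must lie in [0, 1]")
  }
  if (d$stemness_gradient < 0 || d$stemness_gradient > 1) {
    stop("stemness_gradient must lie in [0, 1]")
  }
  structure(d, class = "cohort_design")
}

#' Simulate an expression cohort from a design
#'
#' Each sample is baseline + planted shifts + a per-patient random intercept
#' + independent Gaussian noise, all on the log2 scale. Reference samples
#' (ESC, hepatic day 20) sit at the poles of the planted differentiation
#' axis; tumor groups are displaced toward the ESC pole by their stemness
#' coordinate. Reproducible for a fixed design seed.
#'
#' Structural randomness (per-probe baselines, the planted probe sets and
#' their signs) is driven by the design seed alone, while sampling
#' randomness (patients, intercepts, noise) is driven by `cohort_seed`.
#' Cohorts simulated from one design at different `cohort_seed`s therefore
#' share the same probes, baselines and planted effects — independent
#' training and validation cohorts drawn from the same population, as on a
#' shared array platform — while differing in patients and noise.
#'
#' @param design a [cohort_design()].
#' @param cohort_seed seed for the sampling layer; defaults to the design
#'   seed.
#' @return list of class `cohort` with elements
#'   \describe{
#'     \item{expr}{[expression_matrix()] of all samples,}
#'     \item{annotations}{data frame with `sample_id`, `age_group`, `tissue`,
#'       `patient_id`, `stage`, `cohort`, `reference_class`,}
#'     \item{truth}{ground truth: planted probe id sets with effect signs and
#'       the per-sample stemness coordinate.}
#'   }
#' @export
simulate_cohort <- function(design, cohort_seed = design$seed) {
  if (!inherits(design, "cohort_design")) {
    stop("design must be created by cohort_design()")
  }
  d <- design
  set.seed(d$seed)
  width <- max(4L, nchar(as.character(d$n_probes)))
  probe_ids <- sprintf(paste0("P%0", width, "d"), seq_len(d$n_probes))
  baseline <- stats::rnorm(d$n_probes, d$baseline_mean, d$baseline_sd)

  union_de <- d$n_age_de + d$n_tumor_de - d$overlap
  de_idx <- sample.int(d$n_probes, union_de)
  age_idx <- de_idx[seq_len(d$n_age_de)]
  ov_idx <- age_idx[seq_len(d$overlap)]
  pure_age_idx <- setdiff(age_idx, ov_idx)
  pure_tumor_idx <- if (union_de > d$n_age_de) de_idx[(d$n_age_de + 1L):union_de] else integer(0)
  tumor_idx <- c(ov_idx, pure_tumor_idx)
  axis_idx <- sample(setdiff(seq_len(d$n_probes), de_idx), d$n_axis)

  age_sign <- sample(c(-1, 1), d$n_age_de, replace = TRUE)
  names(age_sign) <- probe_ids[age_idx]
  pure_tumor_sign <- sample(c(-1, 1), length(pure_tumor_idx), replace = TRUE)
  # overlap probes carry a single shared shift, so their tumor-contrast sign
  # equals their age-contrast sign
  tumor_sign <- c(age_sign[match(ov_idx, age_idx)], pure_tumor_sign)
  names(tumor_sign) <- probe_ids[tumor_idx]
  axis_sign <- sample(c(-1, 1), d$n_axis, replace = TRUE)
  names(axis_sign) <- probe_ids[axis_idx]

  # per-probe displacement of the ESC pole relative to the hepatic pole
  axis_delta <- numeric(d$n_probes)
  axis_delta[axis_idx] <- axis_sign * d$axis_effect_log2
  age_delta <- numeric(d$n_probes)
  age_delta[age_idx] <- age_sign * d$effect_size_log2
  ov_delta <- numeric(d$n_probes)
  ov_delta[ov_idx] <- age_delta[ov_idx]
  pure_age_delta <- age_delta
  pure_age_delta[ov_idx] <- 0
  pure_tumor_delta <- numeric(d$n_probes)
  pure_tumor_delta[pure_tumor_idx] <- pure_tumor_sign * d$effect_size_log2

  pad <- function(n) max(2L, nchar(as.character(n)))
  young_pat <- sprintf(paste0("Y%0", pad(d$n_young), "d"), seq_len(d$n_young))
  elderly_pat <- sprintf(paste0("E%0", pad(d$n_elderly), "d"), seq_len(d$n_elderly))
  n_young_pairs <- round(d$paired_fraction * d$n_young)
  n_elderly_pairs <- round(d$paired_fraction * d$n_elderly)

  samples <- list()
  add <- function(samples, id, age, tissue, patient, refclass, mean_vec, stem) {
    samples[[id]] <- list(id = id, age_group = age, tissue = tissue,
                          patient_id = patient, reference_class = refclass,
                          mean = mean_vec, stemness = stem)
    samples
  }
  s_young <- d$stemness_gradient
  s_elderly <- d$stemness_gradient / 2
  for (i in seq_len(d$n_young)) {
    m <- baseline + pure_age_delta + ov_delta + pure_tumor_delta +
      s_young * axis_delta
    samples <- add(samples, paste0(young_pat[i], "_T"), "young", "tumor",
                   young_pat[i], NA_character_, m, s_young)
    if (i <= n_young_pairs) {
      m <- baseline + pure_age_delta
      samples <- add(samples, paste0(young_pat[i], "_N"), "young", "non_tumor",
                     young_pat[i], NA_character_, m, 0)
    }
  }
  for (i in seq_len(d$n_elderly)) {
    m <- baseline + pure_tumor_delta + s_elderly * axis_delta
    samples <- add(samples, paste0(elderly_pat[i], "_T"), "elderly", "tumor",
                   elderly_pat[i], NA_character_, m, s_elderly)
    if (i <= n_elderly_pairs) {
      m <- baseline
      samples <- add(samples, paste0(elderly_pat[i], "_N"), "elderly",
                     "non_tumor", elderly_pat[i], NA_character_, m, 0)
    }
  }
  # ESC pole: axis displacement plus the full age-differential pattern
  for (i in seq_len(d$n_reference)) {
    m <- baseline + axis_delta + age_delta
    samples <- add(samples, sprintf("ESC_%02d", i), "reference", "reference",
                   NA_character_, "ESC", m, 1)
  }
  for (i in seq_len(d$n_reference)) {
    m <- baseline
    samples <- add(samples, sprintf("HEP_%02d", i), "reference", "reference",
                   NA_character_, "hepatic_day20", m, 0)
  }

  set.seed(as.integer(cohort_seed))
  patients <- c(young_pat, elderly_pat)
  intercepts <- stats::rnorm(length(patients), 0, d$patient_sd_log2)
  names(intercepts) <- patients

  n_samples <- length(samples)
  values <- matrix(NA_real_, d$n_probes, n_samples)
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    eta <- if (!is.na(s$patient_id)) intercepts[[s$patient_id]] else 0
    values[, j] <- s$mean + eta +
      stats::rnorm(d$n_probes, 0, d$noise_sd_log2)
  }
  sample_ids <- vapply(samples, `[[`, character(1L), "id")
  expr <- expression_matrix(values, probe_ids, sample_ids)

  annotations <- data.frame(
    sample_id = sample_ids,
    age_group = vapply(samples, `[[`, character(1L), "age_group"),
    tissue = vapply(samples, `[[`, character(1L), "tissue"),
    patient_id = vapply(samples, `[[`, character(1L), "patient_id"),
    stage = NA_character_,
    cohort = "synthetic",
    reference_class = vapply(samples, `[[`, character(1L), "reference_class"),
    stringsAsFactors = FALSE
  )
  stemness <- vapply(samples, `[[`, numeric(1L), "stemness")
  names(stemness) <- sample_ids

  truth <- list(
    age_de_probes = probe_ids[age_idx],
    tumor_de_probes = probe_ids[tumor_idx],
    overlap_probes = probe_ids[ov_idx],
    axis_probes = probe_ids[axis_idx],
    age_signs = age_sign,
    tumor_signs = tumor_sign,
    axis_signs = axis_sign,
    stemness = stemness
  )
  structure(list(expr = expr, annotations = annotations, truth = truth,
                 design = d),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$expr), " probes x ", ncol(x$expr), " samples (",
      sum(x$annotations$tissue == "tumor"), " tumor, ",
      sum(x$annotations$tissue == "non_tumor"), " non-tumor, ",
      sum(x$annotations$tissue == "reference"), " reference)\n", sep = "")
  invisible(x)
}

#' Balanced random class labels, independent of any expression data
#'
#' Used to calibrate the permutation test: labels drawn this way carry no
#' signal, so downstream p-values should be approximately uniform.
#'
#' @param n number of samples (`n >= 4`).
#' @param seed integer seed.
#' @param class_names names of the two classes.
#' @return a [class_labels()] object with a balanced two-class assignment
#'   (class sizes differ by at most one when `n` is odd).
#' @export
simulate_null_labels <- function(n, seed, class_names = c("class1", "class2")) {
  if (n < 4L) stop("n must be at least 4")
  set.seed(seed)
  labels <- sample(rep_len(c(1L, 2L), n))
  class_labels(labels, class_names)
}

#' Extract a two-class contrast from cohort annotations
#'
#' Convenience selector for the two contrasts of the analysis: young vs
#' elderly tumors (`"age"`) and tumor vs non-tumor tissue of young patients
#' (`"tumor"`), plus the reference contrast ESC vs hepatic day 20
#' (`"reference"`).
#'
#' @param cohort a `cohort` (or any list with `expr` and `annotations`).
#' @param contrast one of `"age"`, `"tumor"`, `"reference"`.
#' @return list with `expr` (matrix restricted to contrast samples) and
#'   `labels` ([class_labels()]; class 1 is the contrast class: young tumors,
#'   tumor tissue, or ESC respectively).
#' @export
cohort_contrast <- function(cohort, contrast = c("age", "tumor", "reference")) {
  contrast <- match.arg(contrast)
  ann <- cohort$annotations
  sel <- switch(contrast,
    age = ann$tissue == "tumor",
    tumor = ann$age_group == "young" & ann$tissue %in% c("tumor", "non_tumor"),
    reference = ann$age_group == "reference"
  )
  ann <- ann[sel, , drop = FALSE]
  cls <- switch(contrast,
    age = class_labels(ifelse(ann$age_group == "young", 1L, 2L),
                       c("young", "elderly"), ann$sample_id),
    tumor = class_labels(ifelse(ann$tissue == "tumor", 1L, 2L),
                         c("tumor", "non_tumor"), ann$sample_id),
    reference = class_labels(ifelse(ann$reference_class == "ESC", 1L, 2L),
                             c("ESC", "hepatic_day20"), ann$sample_id)
  )
  list(expr = cohort$expr[, ann$sample_id, drop = FALSE], labels = cls)
}
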