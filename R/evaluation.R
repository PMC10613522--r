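#' Dice similarity coefficient
#'
#' `DSC = 2|A ∩ B| / (|A| + |B|)` between two voxel sets, a value in
#' `[0, 1]` (0 = no overlap, 1 = perfect overlap).  When both masks are
#' empty the score is defined as 1 (perfect agreement on absence, which
#' genuinely occurs when a structure is missing, e.g. Fontan anatomy
#' without an RA) and the result carries attribute `both_empty = TRUE`.
#'
#' @param a,b Logical (or 0/1) arrays of identical shape.
#' @return Dice score in `[0, 1]` (stored as a fraction; multiply by 100
#'   for the percent convention used in reports).
#' @export
dice_score <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(a & b) / (na + nb)
}

#' Mean Dice over the structure vocabulary
#'
#' Arithmetic mean of the per-structure Dice scores; by default exactly
#' the 8 whole-heart structures must be supplied.
#'
#' @param per_structure Numeric Dice values.
#' @param n_expected Required number of values (default 8).
#' @return Mean Dice.
#' @export
mean_dice <- function(per_structure, n_expected = 8) {
  if (length(per_structure) != n_expected)
    stop("expected ", n_expected, " per-structure Dice values, got ",
         length(per_structure), call. = FALSE)
  mean(as.numeric(per_structure))
}

#' Per-structure, per-frame Dice table
#'
#' Scores a predicted label sequence against a reference of the same
#' frames.
#'
#' @param pred,ref Lists of integer label arrays (same length and shapes).
#' @param structures Named integer vector of structure ids (default
#'   [heart_structures()]).
#' @param subject Optional subject id recorded in the table.
#' @return `data.frame` with columns subject, frame (0-based), structure,
#'   dice, both_empty.
#' @export
dice_table <- function(pred, ref, structures = heart_structures(),
                       subject = "subject") {
  stopifnot(length(pred) == length(ref))
  rows <- list()
  for (t in seq_along(pred)) {
    for (nm in names(structures)) {
      d <- dice_score(pred[[t]] == structures[[nm]],
                      ref[[t]] == structures[[nm]])
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, frame = t - 1L, structure = nm,
        dice = as.numeric(d),
        both_empty = isTRUE(attr(d, "both_empty")))
    }
  }
  do.call(rbind, rows)
}

#' Structure volume curve from label maps
#'
#' `volume(t) = #\{voxels == structure\} * voxel volume / 1000` in ml.
#'
#' @param labels List of F integer label arrays.
#' @param spacing_mm Length-3 voxel spacing in mm.
#' @param structure Structure name or integer id within the vocabulary.
#' @return Numeric vector of F volumes (ml).
#' @export
volume_curve <- function(labels, spacing_mm, structure) {
  vocab <- heart_structures()
  if (is.character(structure)) {
    if (!structure %in% names(vocab))
      stop("unknown structure: ", structure, call. = FALSE)
    structure <- vocab[[structure]]
  }
  if (!structure %in% vocab)
    stop("structure id outside vocabulary", call. = FALSE)
  vox_ml <- prod(spacing_mm) / 1000
  vapply(labels, function(l) sum(l == structure) * vox_ml, 1)
}

#' Ejection fraction
#'
#' `EF = 100 * (EDV - ESV) / EDV` in percent.
#'
#' @param edv End-diastolic volume (ml), > 0.
#' @param esv End-systolic volume (ml), in `[0, edv]`.
#' @return EF in percent.
#' @export
ejection_fraction <- function(edv, esv) {
  if (edv <= 0) stop("EDV must be positive", call. = FALSE)
  if (esv < 0 || esv > edv)
    stop("ESV must lie in [0, EDV]", call. = FALSE)
  100 * (edv - esv) / edv
}

#' Volume-difference summary between two segmentations
#'
#' Per frame `d(t) = test - ref`; the summary pools all frames of all
#' subjects and reports the mean and SD in ml and as a percentage of a
#' per-subject normalizer: the reference end-diastolic volume
#' (`"edv"`, used for ventricles) or the largest reference volume over the
#' cycle (`"max"`, used for atria).  For a ventricular curve the two
#' coincide, since EDV is the cycle maximum.
#'
#' @param ref_curves,test_curves Lists (one numeric vector per subject) or
#'   single numeric vectors.
#' @param normalization `"edv"` or `"max"`.
#' @param ed_index Optional per-subject 0-based ED frame indices (used for
#'   `"edv"`; defaults to the reference-curve argmax).
#' @return List with `mean_ml`, `sd_ml`, `mean_pct`, `sd_pct`.
#' @export
volume_difference_summary <- function(ref_curves, test_curves,
                                      normalization = c("edv", "max"),
                                      ed_index = NULL) {
  normalization <- match.arg(normalization)
  if (!is.list(ref_curves)) ref_curves <- list(ref_curves)
  if (!is.list(test_curves)) test_curves <- list(test_curves)
  stopifnot(length(ref_curves) == length(test_curves))
  d_ml <- c(); d_pct <- c()
  for (i in seq_along(ref_curves)) {
    r <- ref_curves[[i]]; s <- test_curves[[i]]
    if (length(r) != length(s))
      stop("curve lengths differ for subject ", i, call. = FALSE)
    norm <- if (normalization == "edv" && !is.null(ed_index)) {
      r[ed_index[i] + 1L]
    } else {
      max(r)
    }
    if (norm == 0) stop("zero normalizer for subject ", i, call. = FALSE)
    d <- s - r
    d_ml <- c(d_ml, d)
    d_pct <- c(d_pct, 100 * d / norm)
  }
  list(mean_ml = mean(d_ml), sd_ml = sd(d_ml),
       mean_pct = mean(d_pct), sd_pct = sd(d_pct))
}

#' Paired comparison with normality-based test selection
#'
#' Tests the paired differences for normality (Shapiro-Wilk, alpha 0.05);
#' a paired two-tailed t-test is used when normality is not rejected,
#' otherwise a Wilcoxon signed-rank test.  All-zero differences (the
#' degenerate x == y case, where the signed-rank statistic is undefined)
#' return p = 1 with a warning.
#'
#' @param x,y Paired numeric samples of equal length >= 3.
#' @return List with `test` (`"t"` or `"wilcoxon"`), `p_value`,
#'   `shapiro_p` and `mean_difference`.
#' @export
paired_compare <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  if (all(d == 0)) {
    warning("all paired differences are zero; returning p = 1")
    return(list(test = "wilcoxon", p_value = 1, shapiro_p = NA_real_,
                mean_difference = 0))
  }
  sw <- shapiro.test(d)
  if (sw$p.value > 0.05) {
    ht <- t.test(x, y, paired = TRUE)
    list(test = "t", p_value = ht$p.value, shapiro_p = sw$p.value,
         mean_difference = mean(d))
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
    list(test = "wilcoxon", p_value = ht$p.value, shapiro_p = sw$p.value,
         mean_difference = mean(d))
  }
}

#' Full metrics report for one test subject
#'
#' Per-structure per-frame Dice, per-frame mean Dice, volume curves for
#' the four chambers, and EDV/ESV/EF per chamber (EDV/ESV read at the
#' subject's ED/ES frames).
#'
#' @param pred,ref Lists of F label arrays (prediction and reference).
#' @param series The subject's `cine_series` (for spacing and ED/ES).
#' @return List with `dice` (data.frame), `mean_dice_per_frame`,
#'   `volumes` (data.frame structure x frame), `function_indices`
#'   (data.frame with edv/esv/ef per chamber).
#' @export
metrics_report <- function(pred, ref, series) {
  vocab <- heart_structures()
  dt <- dice_table(pred, ref, vocab, subject = series$subject_id)
  mdf <- vapply(seq_along(pred) - 1L, function(t) {
    mean(dt$dice[dt$frame == t])
  }, 1)
  chambers <- c("LV", "RV", "LA", "RA")
  vols <- do.call(rbind, lapply(chambers, function(nm) {
    data.frame(structure = nm, frame = seq_along(pred) - 1L,
               volume_ml = volume_curve(pred, series$spacing_mm, nm))
  }))
  fi <- do.call(rbind, lapply(chambers, function(nm) {
    v <- vols$volume_ml[vols$structure == nm]
    edv <- max(v); esv <- min(v)
    data.frame(structure = nm, edv_ml = edv, esv_ml = esv,
               ef_pct = if (edv > 0) ejection_fraction(edv, esv) else NA_real_)
  }))
  list(dice = dt, mean_dice_per_frame = mdf, volumes = vols,
       function_indices = fi)
}
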