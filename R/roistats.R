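# ROI-level precision and accuracy indicators.
#
# All indicators use nested, unweighted averaging: voxels -> ROI (the summary
# table), ROI -> subject, subject -> population. This makes them invariant to
# differing voxel counts per ROI and differing ROI counts per subject.
# Sample standard deviations use the n-1 denominator throughout.

#' Summarize parameter maps over labelled ROIs
#'
#' @param maps A `parameter_maps` object (NaN voxels are excluded from every
#'   moment).
#' @param labels Integer label array of the same spatial shape; 0 =
#'   background.
#' @param subject Subject identifier stored in the table.
#'
#' @return A data.frame of class `roi_table` with columns `subject`, `roi`,
#'   `n_voxels`, `mean_wt2`, `sd_wt2`, `mean_ff`, `sd_ff`. Labels without a
#'   single valid voxel are dropped with a warning.
#' @export
roi_summary <- function(maps, labels, subject = "subject1") {
  stopifnot(inherits(maps, "parameter_maps"))
  if (!all(dim(labels) == dim(maps$wt2)))
    stop("labels must share the map geometry")
  ids <- sort(unique(labels[labels > 0]))
  rows <- list()
  dropped <- integer(0)
  for (id in ids) {
    sel <- labels == id
    wt2 <- maps$wt2[sel]; ff <- maps$ff[sel]
    ok <- !is.na(wt2) & !is.na(ff)
    if (!any(ok)) { dropped <- c(dropped, id); next }
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subject, roi = id, n_voxels = sum(ok),
      mean_wt2 = mean(wt2[ok]), sd_wt2 = stats::sd(wt2[ok]),
      mean_ff = mean(ff[ok]), sd_ff = stats::sd(ff[ok])
    )
  }
  if (length(dropped) > 0)
    warning("labels with no valid voxels dropped: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no ROI contains a valid voxel")
  class(out) <- c("roi_table", "data.frame")
  out
}

# subject-level means of a per-ROI column, nested and unweighted
subject_means <- function(table, col) {
  tapply(table[[col]], table$subject, mean)
}

#' Fat-fraction bias of MESE-derived maps against an external reference
#'
#' Nested unweighted mean difference of the ROI fat fractions: ROI means are
#' averaged per subject, subject means over the population, for both tables;
#' the difference is returned in percentage points. Positive values mean the
#' MESE-derived fat fraction exceeds the reference (e.g. MEGE-derived) one.
#'
#' @param table_mese,table_mege `roi_table`s with matching `(subject, roi)`
#'   rows.
#' @return Difference in percentage points.
#' @export
err_ff <- function(table_mese, table_mege) {
  key <- function(t) paste(t$subject, t$roi)
  k1 <- key(table_mese); k2 <- key(table_mege)
  if (!setequal(k1, k2) || anyDuplicated(k1) || anyDuplicated(k2)) {
    miss <- c(setdiff(k1, k2), setdiff(k2, k1))
    stop("unmatched (subject, roi) rows: ",
         paste(unique(c(miss, k1[duplicated(k1)], k2[duplicated(k2)])),
               collapse = ", "))
  }
  m1 <- mean(subject_means(table_mese, "mean_ff"))
  m2 <- mean(subject_means(table_mege, "mean_ff"))
  (m1 - m2) * 100
}

#' Pooled within-ROI standard deviation
#'
#' Square root of the nested unweighted mean of squared ROI standard
#' deviations (ROIs averaged within subject, then across subjects). Reflects
#' the small-scale variability of the fitted values: noise and local tissue
#' inhomogeneity.
#'
#' @param table A `roi_table`.
#' @param field `"wt2"` or `"ff"`.
#' @return Pooled SD in the field's units.
#' @export
pooled_sd <- function(table, field = c("wt2", "ff")) {
  field <- match.arg(field)
  col <- paste0("sd_", field)
  sq <- table
  sq$sq <- table[[col]]^2
  sqrt(mean(tapply(sq$sq, sq$subject, mean)))
}

#' Intrasubject standard deviation of ROI means
#'
#' Per subject, the standard deviation (n-1) across its ROI means, squared;
#' averaged over subjects; square root. Reflects variability over larger
#' areas, e.g. from field inhomogeneity. Subjects with fewer than two ROIs
#' are excluded with a warning.
#'
#' @param table A `roi_table`.
#' @param field `"wt2"` or `"ff"`.
#' @return Intrasubject SD in the field's units.
#' @export
intrasubject_sd <- function(table, field = c("wt2", "ff")) {
  field <- match.arg(field)
  col <- paste0("mean_", field)
  counts <- tapply(rep(1L, nrow(table)), table$subject, sum)
  keep <- names(counts)[counts >= 2]
  if (length(keep) < length(counts))
    warning("subjects with fewer than 2 ROIs excluded: ",
            paste(setdiff(names(counts), keep), collapse = ", "))
  if (length(keep) == 0) stop("no subject has two or more ROIs")
  tab <- table[table$subject %in% keep, ]
  per_subj <- tapply(tab[[col]], tab$subject, stats::sd)
  sqrt(mean(per_subj^2))
}

#' Group-level means of subject-averaged values
#'
#' Subject values are the unweighted means of their ROI means; per group the
#' mean and SD across subjects are reported (SD is `NaN` for a single
#' subject).
#'
#' @param table A `roi_table`.
#' @param groups Named character vector mapping subject id to group, or a
#'   data.frame with columns `subject` and `group`.
#' @param field `"wt2"` or `"ff"`.
#' @return data.frame with columns `group`, `mean`, `sd`, `n_subjects`.
#' @export
group_mean <- function(table, groups, field = c("wt2", "ff")) {
  field <- match.arg(field)
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$subject))
  subj <- subject_means(table, paste0("mean_", field))
  g <- groups[names(subj)]
  if (anyNA(g)) stop("subjects without a group assignment: ",
                     paste(names(subj)[is.na(g)], collapse = ", "))
  out <- lapply(split(as.numeric(subj), g), function(v) {
    data.frame(mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NaN,
               n_subjects = length(v))
  })
  if (length(out) == 0) stop("no groups present")
  res <- do.call(rbind, out)
  data.frame(group = rownames(res), res, row.names = NULL)
}
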