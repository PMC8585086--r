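#' Item catalog for the three questionnaires
#'
#' Returns the catalog of the 29 questionnaire items feeding the index:
#' the five EQ-5D-5L domains (levels 1-5), the ten ODI items (0-5) and the
#' fourteen HADS items (0-3, split into anxiety and depression subscales).
#' All items are coded so that a higher response means a worse symptom
#' burden; HADS reverse-keyed items are assumed re-coded at data entry.
#'
#' @return A data frame with one row per item and columns
#'   \code{instrument}, \code{item}, \code{label}, \code{min}, \code{max},
#'   \code{subscale}.
#' @export
#' @examples
#' cat29 <- item_catalog()
#' table(cat29$instrument)
item_catalog <- function() {
  path <- system.file("extdata", "item_catalog.json", package = "mcri")
  cat <- jsonlite::fromJSON(path)
  cat$subscale <- vapply(cat$subscale, function(x) if (is.null(x) || is.na(x)) NA_character_ else x, "")
  stopifnot(nrow(cat) == 29L, !anyDuplicated(cat$item))
  cat
}

# Non-item score columns of the cohort layout, in canonical order.
.score_cols <- c("nprs", "eq5d_index", "odi_pct", "hads_total",
                 "surface_low", "surface_medium", "surface_intense",
                 "surface_very_intense", "pgic")

#' Visit labels of the study schedule
#'
#' Baseline plus 3-, 6-, 9- and 12-month follow-ups.
#' @return Character vector \code{c("M0","M3","M6","M9","M12")}.
#' @export
visit_levels <- function() c("M0", "M3", "M6", "M9", "M12")

#' Validate a longitudinal cohort table
#'
#' Checks a wide per-(patient, visit) table against the item catalog:
#' unique (patient, visit) keys, responses inside catalog ranges (missing
#' allowed), nonnegative pain surfaces, NPRS in 0-10, PGIC in 1-7 and only
#' at follow-up visits, and consistency of the ODI percentage with its
#' items (prorated over answered items, within rounding).
#'
#' @param x data frame in the cohort layout.
#' @param catalog item catalog, default \code{item_catalog()}.
#' @return \code{x}, invisibly classed as \code{cohort_table}, with visit
#'   as a factor over \code{visit_levels()}.
#' @export
as_cohort_table <- function(x, catalog = item_catalog()) {
  need <- c("patient_id", "visit", catalog$item, .score_cols)
  extra <- setdiff(names(x), need)
  if (length(extra))
    stop("unknown cohort columns: ", paste(extra, collapse = ", "))
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("missing cohort columns: ", paste(missing_cols, collapse = ", "))
  x <- x[, need]
  if (anyDuplicated(x[c("patient_id", "visit")]))
    stop("duplicate (patient, visit) records")
  if (!all(x$visit %in% visit_levels()))
    stop("unknown visit labels: ",
         paste(unique(setdiff(x$visit, visit_levels())), collapse = ", "))
  x$visit <- factor(x$visit, levels = visit_levels())

  bad_cell <- function(col, ok) {
    bad <- which(!is.na(x[[col]]) & !ok(x[[col]]))
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf("out-of-range value %s for %s at patient %s, visit %s",
                   format(x[[col]][i]), col, x$patient_id[i],
                   as.character(x$visit[i])))
    }
  }
  for (j in seq_len(nrow(catalog))) {
    it <- catalog$item[j]; lo <- catalog$min[j]; hi <- catalog$max[j]
    bad_cell(it, function(v) v >= lo & v <= hi & v == round(v))
  }
  bad_cell("nprs", function(v) v >= 0 & v <= 10 & v == round(v))
  bad_cell("pgic", function(v) v >= 1 & v <= 7 & v == round(v))
  for (s in c("surface_low", "surface_medium", "surface_intense",
              "surface_very_intense"))
    bad_cell(s, function(v) v >= 0)
  if (any(!is.na(x$pgic) & x$visit == "M0"))
    stop("PGIC recorded at baseline; it is defined only at follow-ups")

  odi_items <- catalog$item[catalog$instrument == "ODI"]
  odi_mat <- as.matrix(x[odi_items])
  k <- rowSums(!is.na(odi_mat))
  recomputed <- ifelse(k > 0, rowSums(odi_mat, na.rm = TRUE) / (5 * k) * 100, NA)
  chk <- !is.na(x$odi_pct) & k > 0 & abs(x$odi_pct - recomputed) > 0.5 + 1e-8
  if (any(chk)) {
    i <- which(chk)[1L]
    stop(sprintf("ODI percentage %.2f inconsistent with items (%.2f) at patient %s, visit %s",
                 x$odi_pct[i], recomputed[i], x$patient_id[i],
                 as.character(x$visit[i])))
  }
  # prorate ODI percentage from answered items when the column is absent
  fill <- is.na(x$odi_pct) & k > 0
  x$odi_pct[fill] <- recomputed[fill]

  class(x) <- c("cohort_table", "data.frame")
  invisible(x)
}

#' Read a cohort CSV
#'
#' Comma-separated UTF-8, one row per (patient, visit), empty cell =
#' missing. Columns must be the catalog item ids plus
#' \code{patient_id}, \code{visit}, \code{nprs}, \code{eq5d_index},
#' \code{odi_pct}, \code{hads_total}, the four surface columns and
#' \code{pgic}; unknown columns are a hard error.
#'
#' @param path CSV file path.
#' @param catalog item catalog.
#' @return a validated \code{cohort_table}.
#' @export
load_cohort <- function(path, catalog = item_catalog()) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = "", check.names = FALSE)
  x$patient_id <- as.character(x$patient_id)
  out <- as_cohort_table(x, catalog)
  attr(out, "row.names") <- seq_len(nrow(out))
  out
}

#' Write a cohort CSV
#'
#' Inverse of \code{\link{load_cohort}}: missing cells become empty
#' strings, so a write/load round trip preserves the table including
#' missingness.
#'
#' @param table a \code{cohort_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(table, path) {
  out <- as.data.frame(table)
  out$visit <- as.character(out$visit)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pre-specified clinical item reduction
#'
#' Removes the three items judged clinically redundant with the retained
#' pain-intensity constructs before any factor analysis: the EQ-5D
#' Anxiety/Depression and Pain/Discomfort domains and the ODI
#' pain-intensity item. 29 items in, 26 retained.
#'
#' @param catalog item catalog.
#' @return an \code{item_subset}: data frame with columns \code{item} and
#'   \code{status} (\code{retained} or \code{clinical-redundancy});
#'   retained items keep catalog order.
#' @export
apply_clinical_reduction <- function(catalog = item_catalog()) {
  drop <- c("EQ5D_AnxietyDepression", "EQ5D_PainDiscomfort", "ODI_PainIntensity")
  stopifnot(all(drop %in% catalog$item))
  out <- data.frame(item = catalog$item,
                    status = ifelse(catalog$item %in% drop,
                                    "clinical-redundancy", "retained"),
                    stringsAsFactors = FALSE)
  class(out) <- c("item_subset", "data.frame")
  out
}

#' Retained items of a subset
#' @param subset an \code{item_subset}.
#' @return character vector of retained item ids, in order.
#' @export
retained_items <- function(subset) subset$item[subset$status == "retained"]

#' Pool complete item records across visits
#'
#' Stacks every (patient, visit) record that is complete on the given
#' item subset into one observation matrix (available-case principle: no
#' imputation, incomplete records are dropped).
#'
#' @param table a \code{cohort_table}.
#' @param items character vector of item ids (e.g.
#'   \code{retained_items(subset)}).
#' @return numeric matrix, rows = complete records, columns = items in
#'   the given order; row names \code{patient:visit}.
#' @export
pool_across_visits <- function(table, items) {
  if (!length(items)) stop("empty item subset")
  m <- as.matrix(table[, items, drop = FALSE])
  keep <- stats::complete.cases(m)
  if (!any(keep)) stop("no record is complete on the item subset")
  m <- m[keep, , drop = FALSE]
  rownames(m) <- paste(table$patient_id[keep], table$visit[keep], sep = ":")
  m
}
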