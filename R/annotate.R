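# Retention-index matching annotation and dataset summaries.
#
# Screened candidates are converted to retention indices and matched to
# the predicted RI of the regioisomers of their family; the nearest
# prediction within tolerance assigns the ester position.  Assignment is
# one-to-one within a family so that a ladder of co-detected regioisomers
# cannot collapse onto a single predicted position.

#' Annotate screened candidates by RI matching
#'
#' @param candidates data frame from [screen_run()] (columns `family`,
#'   `apex_rt`, `light_height`, `heavy_height`, ...).
#' @param cal an [fit_ri_calibration()] object for the run.
#' @param predictions prediction table from [expand_predictions()].
#' @param ri_tol maximum `|measured RI - predicted RI|` for an
#'   identification (RI units; the default 10 is about 0.1 carbon).
#' @return data frame of annotation records: `family`, `apex_rt`,
#'   `measured_ri`, `light_height`, `heavy_height`, `fa_carbon`,
#'   `ester_position`, `predicted_ri`, `ri_delta` (all `NA` when
#'   unmatched) and `status` (`"identified"` or `"detected_only"`).
#'   Candidates in families without predictions stay `detected_only`.
#'   Matching is greedy by ascending `|ri_delta|` with ties broken toward
#'   the lower ester position, one-to-one within each family, and is
#'   idempotent: annotating the output again changes nothing.
#' @export
annotate_by_ri <- function(candidates, cal, predictions, ri_tol = 10) {
  stopifnot(ri_tol > 0, inherits(cal, "ri_calibration"))
  out <- data.frame(
    family = candidates$family,
    apex_rt = candidates$apex_rt,
    measured_ri = rt_to_ri(candidates$apex_rt, cal),
    light_height = candidates$light_height,
    heavy_height = candidates$heavy_height,
    fa_carbon = NA_integer_,
    ester_position = NA_integer_,
    predicted_ri = NA_real_,
    ri_delta = NA_real_,
    status = "detected_only",
    stringsAsFactors = FALSE
  )
  for (fam in unique(out$family)) {
    ci <- which(out$family == fam)
    pred <- predictions[predictions$family == fam, , drop = FALSE]
    if (nrow(pred) == 0L) next
    cand_ri <- out$measured_ri[ci]
    pairs <- expand.grid(a = seq_along(ci), b = seq_len(nrow(pred)))
    pairs$delta <- cand_ri[pairs$a] - pred$predicted_ri[pairs$b]
    pairs <- pairs[abs(pairs$delta) <= ri_tol, , drop = FALSE]
    if (nrow(pairs) == 0L) next
    pairs <- pairs[order(abs(pairs$delta), pred$ester_position[pairs$b]), ,
                   drop = FALSE]
    used_a <- logical(length(ci)); used_b <- logical(nrow(pred))
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$a[k]; b <- pairs$b[k]
      if (used_a[a] || used_b[b]) next
      used_a[a] <- TRUE; used_b[b] <- TRUE
      i <- ci[a]
      out$fa_carbon[i] <- pred$fa_carbon[b]
      out$ester_position[i] <- pred$ester_position[b]
      out$predicted_ri[i] <- pred$predicted_ri[b]
      out$ri_delta[i] <- pairs$delta[k]
      out$status[i] <- "identified"
    }
  }
  out
}

# single-linkage clustering of 1-d RI values: split at gaps > tol
.ri_clusters <- function(ri, tol) {
  if (length(ri) == 0L) return(integer(0))
  o <- order(ri)
  cl <- integer(length(ri))
  cl[o] <- cumsum(c(1L, as.integer(diff(ri[o]) > tol)))
  cl
}

#' Compile per-sample annotation records into a dataset summary
#'
#' Per sample, the regioisomer count is the number of annotation records
#' (each record is one screened peak pair) and the family count the number
#' of distinct families.  Across samples, records of one family are
#' treated as the same regioisomer when their measured RIs fall in the
#' same single-linkage cluster (gap threshold `ri_tol`), which is how a
#' regioisomer observed in several foods is counted once globally.
#'
#' @param per_sample_records named list mapping sample name to an
#'   annotation data frame from [annotate_by_ri()].
#' @param ri_tol RI gap above which two observations of one family count
#'   as different regioisomers.
#' @return an object of class `dataset_summary`: list with `per_sample`
#'   (data frame of `sample`, `n_regioisomers`, `n_families`,
#'   `total_intensity`) and `global` (`n_regioisomers`, `n_families`,
#'   `n_identified` after deduplication).
#' @export
compile_dataset <- function(per_sample_records, ri_tol = 10) {
  stopifnot(length(per_sample_records) > 0, !is.null(names(per_sample_records)))
  per_sample <- do.call(rbind, lapply(names(per_sample_records), function(s) {
    rec <- per_sample_records[[s]]
    data.frame(
      sample = s,
      n_regioisomers = nrow(rec),
      n_families = length(unique(rec$family)),
      total_intensity = if (nrow(rec)) sum(rec$light_height) else 0,
      stringsAsFactors = FALSE
    )
  }))
  all_rec <- do.call(rbind, lapply(names(per_sample_records), function(s) {
    rec <- per_sample_records[[s]]
    if (nrow(rec) == 0L) return(NULL)
    cbind(sample = s, rec)
  }))
  if (is.null(all_rec) || nrow(all_rec) == 0L) {
    global <- list(n_regioisomers = 0L, n_families = 0L, n_identified = 0L)
  } else {
    n_regio <- 0L
    n_ident <- 0L
    for (fam in unique(all_rec$family)) {
      rec <- all_rec[all_rec$family == fam, , drop = FALSE]
      cl <- .ri_clusters(rec$measured_ri, ri_tol)
      n_regio <- n_regio + length(unique(cl))
      ident <- rec$status == "identified"
      n_ident <- n_ident + length(unique(cl[ident]))
    }
    global <- list(n_regioisomers = n_regio,
                   n_families = length(unique(all_rec$family)),
                   n_identified = n_ident)
  }
  structure(list(per_sample = per_sample, global = global),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("FAHFA dataset summary\n")
  cat(sprintf("  global: %d regioisomers, %d families, %d identified\n",
              x$global$n_regioisomers, x$global$n_families,
              x$global$n_identified))
  print(x$per_sample, row.names = FALSE)
  invisible(x)
}

#' Published headline counts of the food FAHFA dataset
#'
#' Reference values against which [validate_published_dataset()] compares
#' a user-supplied copy of the published tables: 1207 detected
#' regioisomers in 298 families over 16 food samples, 450 regioisomers in
#' Lycium chinense, and 132 RI-identified regioisomers.
#'
#' @return a list with `total_regioisomers`, `total_families`,
#'   `per_sample` (named numeric) and `identified_rows`.
#' @export
published_reference_counts <- function() {
  list(
    total_regioisomers = 1207,
    total_families = 298,
    per_sample = c("Lycium chinense" = 450),
    identified_rows = 132
  )
}

# locate the family / retention-index columns of a published-style sheet
.sheet_family_col <- function(df) {
  hits <- grep("family|fahfa[._ ]?id", names(df), ignore.case = TRUE, value = TRUE)
  if (length(hits)) hits[1] else NULL
}

.sheet_ri_col <- function(df) {
  hits <- grep("retention[ ._]?index|^ri$", names(df), ignore.case = TRUE,
               value = TRUE)
  if (length(hits)) hits[1] else NULL
}

#' Validate a copy of the published dataset tables
#'
#' Recomputes the headline counts of the food-FAHFA dataset from its
#' per-sample detected-regioisomer sheets and its identified list, and
#' compares them to the published reference values.  Takes either a named
#' list of data frames (one per sample) or a path to an `.xlsx` workbook
#' whose sheets are named by sample (read via the readxl package).
#'
#' Regioisomer counting across samples reuses the package's RI-clustering
#' deduplication rule (the publication's own rule is not stated).
#'
#' @param detected named list of per-sample data frames, or an `.xlsx`
#'   path.  Each sheet needs a family column (`family` / `FAHFA ID`) and,
#'   for cross-sample deduplication, a retention-index column.
#' @param identified optional data frame (or single-sheet `.xlsx` path):
#'   the identified-regioisomer list, counted by rows.
#' @param reference reference counts, see [published_reference_counts()].
#' @param required_samples sample names that must be present; a missing
#'   one raises an error naming it.
#' @param ri_tol RI clustering tolerance for deduplication.
#' @return a data frame report: `check`, `expected`, `actual`, `pass`;
#'   attribute `n_malformed` counts rows excluded for a missing family.
#' @export
validate_published_dataset <- function(detected, identified = NULL,
                                       reference = published_reference_counts(),
                                       required_samples = NULL,
                                       ri_tol = 10) {
  if (is.character(detected)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package")
    }
    sheets <- readxl::excel_sheets(detected)
    path <- detected
    detected <- lapply(sheets, function(s) {
      as.data.frame(readxl::read_excel(path, sheet = s))
    })
    names(detected) <- sheets
  }
  stopifnot(is.list(detected), !is.null(names(detected)))
  if (!is.null(required_samples)) {
    missing <- setdiff(required_samples, names(detected))
    if (length(missing)) {
      stop("missing sheet(s): ", paste(missing, collapse = ", "))
    }
  }
  n_malformed <- 0L
  per_sheet <- lapply(names(detected), function(s) {
    df <- detected[[s]]
    fc <- .sheet_family_col(df)
    if (is.null(fc)) stop("sheet '", s, "' has no family / FAHFA ID column")
    bad <- is.na(df[[fc]]) | !nzchar(as.character(df[[fc]]))
    if (any(bad)) {
      message("sheet '", s, "': ", sum(bad), " malformed row(s) excluded")
      n_malformed <<- n_malformed + sum(bad)
      df <- df[!bad, , drop = FALSE]
    }
    rc <- .sheet_ri_col(df)
    data.frame(sample = s, family = as.character(df[[fc]]),
               ri = if (is.null(rc)) NA_real_ else as.numeric(df[[rc]]),
               stringsAsFactors = FALSE)
  })
  all_rows <- do.call(rbind, per_sheet)
  # global regioisomer count: per family, RI clusters across samples
  # (rows without an RI each count as their own observation)
  n_regio <- 0L
  for (fam in unique(all_rows$family)) {
    ri <- all_rows$ri[all_rows$family == fam]
    has <- !is.na(ri)
    n_regio <- n_regio + sum(!has) +
      (if (any(has)) length(unique(.ri_clusters(ri[has], ri_tol))) else 0L)
  }
  checks <- data.frame(
    check = c("total_regioisomers", "total_families"),
    expected = c(reference$total_regioisomers, reference$total_families),
    actual = c(n_regio, length(unique(all_rows$family))),
    stringsAsFactors = FALSE
  )
  for (s in names(reference$per_sample)) {
    if (s %in% names(detected)) {
      checks <- rbind(checks, data.frame(
        check = paste0("regioisomers_", s),
        expected = unname(reference$per_sample[s]),
        actual = sum(all_rows$sample == s)
      ))
    }
  }
  if (!is.null(identified)) {
    if (is.character(identified)) {
      identified <- as.data.frame(readxl::read_excel(identified))
    }
    checks <- rbind(checks, data.frame(
      check = "identified_rows",
      expected = reference$identified_rows,
      actual = nrow(identified)
    ))
  }
  checks$pass <- checks$expected == checks$actual
  attr(checks, "n_malformed") <- n_malformed
  checks
}
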