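#' Construct an expression matrix container
#'
#' Log2 intensities, probe sets in rows and samples in columns, together with
#' the designation of which columns are control (nephrectomy) samples.
#'
#' @param values Numeric matrix of log2 intensities with unique, non-empty
#'   rownames (probe-set ids) and colnames (sample ids). All values must be
#'   finite.
#' @param control_ids Character vector of sample ids (subset of
#'   `colnames(values)`) marking the control group.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `control_ids`.
#' @export
expression_matrix <- function(values, control_ids = character()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids", call. = FALSE)
  if (!all(is.finite(values))) stop("expression values must be finite", call. = FALSE)
  control_ids <- as.character(control_ids)
  missing_ctl <- setdiff(control_ids, colnames(values))
  if (length(missing_ctl)) {
    stop("control ids absent from matrix: ", paste(missing_ctl, collapse = ", "),
         call. = FALSE)
  }
  structure(list(values = values, control_ids = control_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probe sets x %d samples (%d controls)\n",
              nrow(x$values), ncol(x$values), length(x$control_ids)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Ids of non-control (biopsy) samples
#' @param expr An `expression_matrix`.
#' @return Character vector of biopsy sample ids.
#' @export
biopsy_ids <- function(expr) {
  setdiff(colnames(expr$values), expr$control_ids)
}

# ---- GMT ----------------------------------------------------------------

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member order is
#' preserved; duplicated members within a set are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (class `gene_set_collection`)
#'   with per-set descriptions in `attr(,"description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "), call. = FALSE)
  }
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  sets <- lapply(seq_along(parts), function(i) {
    members <- parts[[i]][-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop("empty gene set: ", names_[i], call. = FALSE)
    }
    if (anyDuplicated(members)) {
      warning(sprintf("set %s: %d duplicated member(s) removed",
                      names_[i], sum(duplicated(members))), call. = FALSE)
      members <- members[!duplicated(members)]
    }
    members
  })
  names(sets) <- names_
  names(desc) <- names_
  structure(sets, description = desc, class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#' @param sets Named list of character vectors; optional
#'   `attr(,"description")`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- expression / metadata tables ---------------------------------------

#' Write / read an expression matrix as TSV
#'
#' TSV layout: first column `probe_id`, remaining columns one per sample.
#' Control designation travels in a sidecar line is not used; pass
#' `control_ids` to [read_expression()] instead.
#'
#' @param expr An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(probe_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @param control_ids Control sample ids to mark in the returned object.
#' @export
read_expression <- function(path, control_ids = character()) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  probe_ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(vals) & body != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression cell at probe '%s', sample '%s'",
                 probe_ids[bad[1, 1]], colnames(body)[bad[1, 2]]), call. = FALSE)
  }
  if (anyNA(vals)) {
    stop("missing expression values are not supported", call. = FALSE)
  }
  rownames(vals) <- probe_ids
  expression_matrix(vals, control_ids)
}

#' Per-biopsy clinical metadata schema
#'
#' Required columns: `sample_id`, `kidney_id`, `txbx_days` (time from
#' transplant to biopsy, days), `egfr` (mL/min/1.73m2), `donor_age` (years),
#' `proteinuria_pos` (0/1), `ci_score` and `ct_score` (Banff ordinal 0-3),
#' `pct_cortex` (0-100), `followup_days`, `graft_failed` (0/1),
#' `died_with_function` (0/1). Optional: `rejection_group` and rejection PC
#' columns. Missing values are real `NA`s (empty strings on disk), never
#' sentinel numbers.
#'
#' @param meta A data.frame.
#' @return The validated data.frame, invisibly classed `sample_metadata`.
#' @export
validate_metadata <- function(meta) {
  required <- c("sample_id", "kidney_id", "txbx_days", "egfr", "donor_age",
                "proteinuria_pos", "ci_score", "ct_score", "pct_cortex",
                "followup_days", "graft_failed", "died_with_function")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("metadata missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id", call. = FALSE)
  fup <- meta$followup_days
  if (any(!is.na(fup) & fup < 0)) stop("followup_days must be >= 0", call. = FALSE)
  if (!inherits(meta, "sample_metadata")) class(meta) <- c("sample_metadata", class(meta))
  meta
}

#' @rdname validate_metadata
#' @param path CSV path; empty cells are read as missing.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  validate_metadata(meta)
}

#' @rdname validate_metadata
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Cross-validate sample ids between expression and metadata
#'
#' Every non-control expression sample must appear in the metadata; the check
#' fails loudly rather than silently intersecting.
#'
#' @param expr An `expression_matrix`.
#' @param meta A `sample_metadata` data.frame.
#' @return TRUE, invisibly.
#' @export
check_sample_ids <- function(expr, meta) {
  missing <- setdiff(biopsy_ids(expr), meta$sample_id)
  if (length(missing)) {
    stop("expression samples absent from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# ---- inclusion rules ----------------------------------------------------

#' Cortex-content inclusion filter
#'
#' Retains biopsies with strictly more than `threshold` percent cortex
#' (default 10), the inclusion rule used throughout the model. Biopsies with
#' missing `pct_cortex` are kept with a warning by default.
#'
#' @param meta `sample_metadata`.
#' @param threshold Percent cortex cutoff; strict ">".
#' @param missing One of "keep" or "drop" for biopsies lacking `pct_cortex`.
#' @return Filtered metadata with attribute `cortex_filter` recording counts
#'   (`n_in`, `n_kept`, `n_dropped`, `n_missing`).
#' @export
filter_cortex <- function(meta, threshold = 10, missing = c("keep", "drop")) {
  missing <- match.arg(missing)
  if (!"pct_cortex" %in% names(meta)) stop("pct_cortex column required", call. = FALSE)
  miss <- is.na(meta$pct_cortex)
  if (any(miss)) {
    warning(sprintf("%d biopsies with missing pct_cortex %s", sum(miss),
                    if (missing == "keep") "kept" else "dropped"), call. = FALSE)
  }
  keep <- (!miss & meta$pct_cortex > threshold) | (miss & missing == "keep")
  out <- meta[keep, , drop = FALSE]
  attr(out, "cortex_filter") <- list(n_in = nrow(meta), n_kept = nrow(out),
                                     n_dropped = nrow(meta) - nrow(out),
                                     n_missing = sum(miss))
  out
}

#' Select one random biopsy per kidney
#'
#' Survival analyses use a single biopsy per transplant; this picks one
#' uniformly at random among the eligible biopsies (those with follow-up
#' recorded) of each kidney, deterministically per seed.
#'
#' @param meta `sample_metadata`.
#' @param seed Integer seed controlling the draw.
#' @return Metadata with one row per kidney; kidneys without any eligible
#'   biopsy are dropped and counted in `attr(,"dropped_kidneys")`.
#' @export
one_biopsy_per_kidney <- function(meta, seed) {
  eligible <- !is.na(meta$followup_days)
  dropped <- setdiff(unique(meta$kidney_id), unique(meta$kidney_id[eligible]))
  m <- meta[eligible, , drop = FALSE]
  rows <- split(seq_len(nrow(m)), m$kidney_id)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  pick <- vapply(rows, function(idx) {
    if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
  }, integer(1))
  out <- m[sort(pick), , drop = FALSE]
  attr(out, "dropped_kidneys") <- dropped
  out
}

# seed handling: save/restore .Random.seed so library code does not clobber
# the caller's RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
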