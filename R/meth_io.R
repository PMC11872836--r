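#' @import data.table
NULL

# -- controlled vocabularies ---------------------------------------------

#' Allowed sample group labels
#' @export
GROUP_LEVELS <- c("young", "old_control", "old_treated")

#' Allowed genomic region classes
#' @export
REGION_LEVELS <- c("promoter", "exon", "intron", "intergenic", "5'UTR", "3'UTR")

ANNOTATION_COLS <- c("cpg_id", "chrom", "start", "end", "nearest_gene",
                     "tss_distance", "region_class", "island",
                     "chromatin_state")

# -- beta matrix ----------------------------------------------------------

#' Validate a beta-value matrix
#'
#' Checks the joint invariants of a methylation matrix: unique CpG and
#' sample identifiers, all values finite and inside \[0, 1\] (values within
#' `tol` of the boundary are clamped).
#'
#' @param beta numeric matrix, CpGs in rows (rownames = CpG ids), samples in
#'   columns (colnames = sample ids).
#' @param tol boundary tolerance; betas outside `[-tol, 1 + tol]` are a
#'   validation error.
#' @return the validated (possibly clamped) matrix, invisibly classed.
#' @export
validate_beta_matrix <- function(beta, tol = 1e-9) {
  if (!is.matrix(beta) || !is.numeric(beta))
    abort("beta matrix must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    abort("beta matrix needs CpG rownames and sample colnames")
  if (anyDuplicated(rownames(beta)))
    abort("duplicate CpG ids: %s",
          paste(head(unique(rownames(beta)[duplicated(rownames(beta))]), 3),
                collapse = ", "))
  if (anyDuplicated(colnames(beta)))
    abort("duplicate sample ids: %s",
          paste(head(unique(colnames(beta)[duplicated(colnames(beta))]), 3),
                collapse = ", "))
  if (any(!is.finite(beta)))
    abort("beta matrix contains %d non-finite values", sum(!is.finite(beta)))
  bad <- beta < -tol | beta > 1 + tol
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort("beta outside [0,1]: value %.6g at CpG '%s', sample '%s'",
          beta[idx[1], idx[2]], rownames(beta)[idx[1]], colnames(beta)[idx[2]])
  }
  beta[beta < 0] <- 0
  beta[beta > 1] <- 1
  beta
}

#' Read a CpG x sample beta-value matrix from TSV
#'
#' Expects a tab-separated file with one header line of sample ids and a
#' first column `cpg_id`. CpGs with any missing value are dropped (the count
#' is reported via `message()`) unless `impute = TRUE`, in which case missing
#' cells are filled with the per-CpG mean across observed samples.
#'
#' @param path file path.
#' @param impute replace missing betas by the per-CpG mean instead of
#'   dropping the CpG row.
#' @return validated numeric matrix (rows CpGs, columns samples).
#' @export
read_beta_matrix <- function(path, impute = FALSE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L), data.table = TRUE)
  if (names(dt)[1] != "cpg_id")
    abort("beta matrix TSV must have first column 'cpg_id', found '%s'",
          names(dt)[1])
  if (ncol(dt) < 2L) abort("beta matrix has no sample columns")
  for (j in names(dt)[-1]) {
    col <- dt[[j]]
    if (is.character(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & col != "" & is.na(num))
      if (length(bad))
        abort("non-numeric beta '%s' at CpG '%s', sample column '%s'",
              col[bad[1]], dt$cpg_id[bad[1]], j)
      num[col == ""] <- NA_real_
      data.table::set(dt, j = j, value = num)
    }
  }
  beta <- as.matrix(dt[, -1])
  rownames(beta) <- dt$cpg_id
  na_row <- rowSums(is.na(beta)) > 0
  if (any(na_row)) {
    if (impute) {
      means <- rowMeans(beta, na.rm = TRUE)
      idx <- which(is.na(beta), arr.ind = TRUE)
      beta[idx] <- means[idx[, 1]]
      message(sprintf("imputed missing betas in %d CpGs by per-CpG mean",
                      sum(na_row)))
    } else {
      beta <- beta[!na_row, , drop = FALSE]
      message(sprintf("dropped %d CpGs with missing betas", sum(na_row)))
    }
  }
  validate_beta_matrix(beta)
}

#' Write a beta-value matrix to TSV
#'
#' Inverse of [read_beta_matrix()]; round-trip is value-identical.
#'
#' @param beta numeric matrix with CpG rownames and sample colnames.
#' @param path destination file.
#' @export
write_beta_matrix <- function(beta, path) {
  beta <- validate_beta_matrix(beta)
  dt <- data.table::data.table(cpg_id = rownames(beta))
  dt <- cbind(dt, data.table::as.data.table(beta))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

# -- sample sheet ---------------------------------------------------------

#' Validate a sample sheet
#'
#' A sample sheet is a data.frame with columns `sample_id`, `age_years`,
#' `group`, `species`, `max_lifespan_years`. Groups must come from
#' [GROUP_LEVELS], ages must be strictly positive, sample ids unique, and
#' the species maximum lifespan must exceed every observed age.
#'
#' @param sheet data.frame.
#' @return the sheet, classed `sample_sheet`.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "age_years", "group", "species", "max_lifespan_years")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) abort("sample sheet missing columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    abort("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(sheet$group), GROUP_LEVELS)
  if (length(bad))
    abort("unknown group label(s) %s; allowed: %s",
          paste(sQuote(bad), collapse = ", "),
          paste(GROUP_LEVELS, collapse = ", "))
  if (!is.numeric(sheet$age_years) || any(!is.finite(sheet$age_years)) ||
      any(sheet$age_years <= 0))
    abort("ages must be finite and strictly positive")
  if (!is.numeric(sheet$max_lifespan_years) ||
      any(sheet$max_lifespan_years <= sheet$age_years))
    abort("species max_lifespan_years must exceed every observed age")
  sheet <- as.data.frame(sheet)
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Read a sample sheet from CSV
#'
#' Schema: `sample_id,age_years,group,species,max_lifespan_years`.
#'
#' @param path file path.
#' @return validated `sample_sheet` data.frame.
#' @export
read_sample_sheet <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("sample_id")))
  validate_sample_sheet(dt)
}

#' Write a sample sheet to CSV
#' @param sheet validated sample sheet.
#' @param path destination file.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  data.table::fwrite(as.data.frame(sheet), path, sep = ",")
  invisible(path)
}

# -- CpG annotation -------------------------------------------------------

#' Validate a CpG annotation table
#'
#' Nine columns in fixed order: `cpg_id`, `chrom`, `start`, `end` (0-based
#' half-open), `nearest_gene`, `tss_distance` (signed bp, negative =
#' upstream of the TSS on the gene's strand), `region_class` (one of
#' [REGION_LEVELS]), `island` (logical), `chromatin_state`.
#'
#' @param ann data.frame.
#' @return the annotation, classed `cpg_annotation`.
#' @export
validate_cpg_annotation <- function(ann) {
  miss <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(miss)) abort("annotation missing columns: %s",
                          paste(miss, collapse = ", "))
  ann <- as.data.frame(ann)[, ANNOTATION_COLS]
  if (anyDuplicated(ann$cpg_id)) abort("duplicate CpG ids in annotation")
  if (any(ann$start < 0) || any(ann$end <= ann$start))
    abort("intervals must satisfy 0 <= start < end")
  bad <- setdiff(unique(ann$region_class), REGION_LEVELS)
  if (length(bad))
    abort("unknown region_class %s; allowed: %s",
          paste(sQuote(bad), collapse = ", "),
          paste(REGION_LEVELS, collapse = ", "))
  if (!is.logical(ann$island)) {
    isl <- toupper(as.character(ann$island))
    if (!all(isl %in% c("TRUE", "FALSE")))
      abort("island column must be logical TRUE/FALSE")
    ann$island <- isl == "TRUE"
  }
  if (any(is.na(ann$chromatin_state)) || any(ann$chromatin_state == ""))
    abort("every CpG needs a chromatin_state label")
  class(ann) <- c("cpg_annotation", "data.frame")
  ann
}

#' Read a CpG annotation from BED-like TSV
#' @param path file path (one header line, 9 tab-separated columns).
#' @return validated `cpg_annotation` data.frame.
#' @export
read_cpg_annotation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  validate_cpg_annotation(dt)
}

#' Write a CpG annotation to TSV
#' @param ann validated annotation.
#' @param path destination file.
#' @export
write_cpg_annotation <- function(ann, path) {
  ann <- validate_cpg_annotation(ann)
  data.table::fwrite(as.data.frame(ann), path, sep = "\t")
  invisible(path)
}

# -- clock coefficient tables --------------------------------------------

#' Read clock coefficients from CSV
#'
#' Schema: two columns `term,value`. `term` is one of `intercept`,
#' `transform`, `max_lifespan_years`, or a CpG id; `value` holds the numeric
#' weight (or the transform name for the `transform` row). A
#' `max_lifespan_years` row is required iff transform is `relative_age`.
#'
#' @param path file path.
#' @return a [clock_model] object.
#' @export
read_clock_coefficients <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (!identical(names(dt), c("term", "value")))
    abort("clock CSV must have header 'term,value'")
  if (anyDuplicated(dt$term)) abort("duplicate terms in clock CSV")
  if (!"intercept" %in% dt$term) abort("clock CSV missing 'intercept' row")
  transform <- if ("transform" %in% dt$term)
    dt$value[dt$term == "transform"] else "identity"
  lifespan <- if ("max_lifespan_years" %in% dt$term)
    as.numeric(dt$value[dt$term == "max_lifespan_years"]) else NULL
  keep <- !dt$term %in% c("intercept", "transform", "max_lifespan_years")
  w <- as.numeric(dt$value[keep])
  if (any(is.na(w))) abort("non-numeric coefficient value for term '%s'",
                           dt$term[keep][which(is.na(w))[1]])
  names(w) <- dt$term[keep]
  clock_model(intercept = as.numeric(dt$value[dt$term == "intercept"]),
              coefficients = w, transform = transform,
              max_lifespan_years = lifespan)
}

#' Write a clock model to coefficient CSV
#' @param model a `clock_model`.
#' @param path destination file.
#' @export
write_clock_coefficients <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  rows <- data.frame(term = "intercept",
                     value = format(model$intercept, digits = 17))
  rows <- rbind(rows, data.frame(term = "transform", value = model$transform))
  if (!is.null(model$max_lifespan_years))
    rows <- rbind(rows, data.frame(
      term = "max_lifespan_years",
      value = format(model$max_lifespan_years, digits = 17)))
  if (length(model$coefficients))
    rows <- rbind(rows, data.frame(
      term = names(model$coefficients),
      value = format(unname(model$coefficients), digits = 17)))
  data.table::fwrite(rows, path, sep = ",")
  invisible(path)
}

#' Write any tabular pipeline object to disk
#'
#' Generic writer dispatching on class: beta matrices go to TSV, sample
#' sheets to CSV, annotations to TSV, clock models to coefficient CSV, and
#' plain data.frames to TSV.
#'
#' @param obj object to serialize.
#' @param path destination file.
#' @export
write_table <- function(obj, path) UseMethod("write_table")

#' @export
write_table.sample_sheet <- function(obj, path) write_sample_sheet(obj, path)
#' @export
write_table.cpg_annotation <- function(obj, path) write_cpg_annotation(obj, path)
#' @export
write_table.clock_model <- function(obj, path) write_clock_coefficients(obj, path)
#' @export
write_table.matrix <- function(obj, path) write_beta_matrix(obj, path)
#' @export
write_table.data.frame <- function(obj, path) {
  data.table::fwrite(obj, path, sep = "\t")
  invisible(path)
}
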