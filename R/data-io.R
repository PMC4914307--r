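#' Construct a validated expression matrix
#'
#' An expression matrix holds log-scale expression values for molecules of a
#' single class (miRNA, lncRNA or mRNA) across a common sample set. Rows are
#' molecules, columns are samples; both identifier sets must be unique and all
#' values finite.
#'
#' @param values Numeric matrix (molecules x samples) with rownames set to
#'   molecule identifiers and colnames to sample identifiers.
#' @param molecule_class One of `"miRNA"`, `"lncRNA"`, `"mRNA"`.
#' @return An object of class `expr_matrix` (a numeric matrix with a
#'   `molecule_class` attribute).
#' @export
expression_matrix <- function(values, molecule_class) {
  molecule_class <- match.arg(molecule_class, c("miRNA", "lncRNA", "mRNA"))
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry molecule rownames and sample colnames", call. = FALSE)
  }
  dup_mol <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_mol) > 0) {
    stop("duplicated molecule id(s): ", paste(dup_mol, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite (missing values are not allowed)",
         call. = FALSE)
  }
  structure(values, molecule_class = molecule_class,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d molecules x %d samples\n",
              attr(x, "molecule_class"), nrow(x), ncol(x)))
  invisible(x)
}

#' Molecule class of an expression matrix
#' @param x An `expr_matrix`.
#' @return `"miRNA"`, `"lncRNA"` or `"mRNA"`.
#' @export
molecule_class <- function(x) attr(x, "molecule_class")

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds molecule identifiers
#' and whose header row names the samples. Missing or non-numeric cells and
#' duplicated identifiers are rejected with an error naming the offender.
#'
#' @param path Path to the TSV file.
#' @param molecule_class One of `"miRNA"`, `"lncRNA"`, `"mRNA"`.
#' @return An `expr_matrix`.
#' @export
read_expression_matrix <- function(path, molecule_class) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("expression file has no data rows: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("malformed header (need id column plus >=1 sample): ", path, call. = FALSE)
  sample_ids <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncell <- lengths(rows)
  bad <- which(ncell != length(header))
  if (length(bad) > 0) {
    stop(sprintf("line %d has %d fields, expected %d", bad[1] + 1L,
                 ncell[bad[1]], length(header)), call. = FALSE)
  }
  ids <- vapply(rows, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(sample_ids))))
  )
  if (length(sample_ids) == 1L) vals <- matrix(vals, ncol = 1L)
  if (anyNA(vals)) {
    bad_row <- which(apply(vals, 1L, anyNA))[1]
    stop(sprintf("non-numeric or missing cell at line %d (molecule %s)",
                 bad_row + 1L, ids[bad_row]), call. = FALSE)
  }
  rownames(vals) <- ids
  colnames(vals) <- sample_ids
  expression_matrix(vals, molecule_class)
}

#' Write an expression matrix to TSV
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a validated miRNA-target interaction catalog
#'
#' Reads a two-column tab-separated edge list (miRNA, target). Duplicate pairs
#' are collapsed; an empty file yields an empty catalog with a warning.
#'
#' @param path Path to the TSV edge list. May have a header line starting with
#'   `"mirna"` which is skipped.
#' @param target_class `"mRNA"` or `"lncRNA"`.
#' @return A tibble with columns `mirna_id`, `target_id`, `target_class`.
#' @export
read_interactions <- function(path, target_class) {
  target_class <- match.arg(target_class, c("mRNA", "lncRNA"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && grepl("^mirna", lines[[1]], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    warning("empty interaction file: ", path, call. = FALSE)
    return(tibble::tibble(mirna_id = character(), target_id = character(),
                          target_class = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("interaction line with fewer than 2 fields at line ",
         which(lengths(parts) < 2)[1], call. = FALSE)
  }
  tibble::tibble(
    mirna_id = vapply(parts, `[[`, character(1), 1L),
    target_id = vapply(parts, `[[`, character(1), 2L),
    target_class = target_class
  ) |>
    dplyr::distinct()
}

#' Write an interaction catalog to TSV
#' @param catalog Tibble as returned by [read_interactions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(catalog, path) {
  utils::write.table(catalog[, c("mirna_id", "target_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT-like file
#'
#' Each line is `name <tab> description <tab> member1 <tab> member2 ...`.
#' Duplicate members within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A tibble with one row per (set, member): columns `set_name`,
#'   `description`, `member_id`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(set_name = character(), description = character(),
                          member_id = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    stop("gene-set line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  purrr::map_dfr(parts, function(p) {
    tibble::tibble(set_name = p[[1]], description = p[[2]],
                   member_id = unique(p[-(1:2)]))
  })
}

#' Write gene sets to a GMT-like file
#' @param sets Tibble as returned by [read_gene_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- sets |>
    dplyr::group_by(.data$set_name) |>
    dplyr::summarise(
      line = paste(c(.data$set_name[1],
                     if ("description" %in% names(sets)) .data$description[1] else "NA",
                     .data$member_id), collapse = "\t"),
      .groups = "drop"
    )
  writeLines(lines$line, path)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Expects a TSV with named columns `sample`, `os_months`, `event` and
#' optionally `age`, `stage`, `grade`, `residual`. Empty fields in the optional
#' covariates are read as missing and tolerated; `os_months` must be
#' non-negative and `event` coded 0/1.
#'
#' @param path Path to the clinical TSV.
#' @return A tibble with columns `sample_id`, `os_months`, `event` plus any
#'   covariates present.
#' @export
read_clinical <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA"), progress = FALSE)
  names(df)[names(df) == "sample"] <- "sample_id"
  validate_clinical(dplyr::mutate(
    df,
    os_months = as.numeric(.data$os_months),
    event = as.integer(.data$event),
    dplyr::across(dplyr::any_of("age"), as.numeric)
  ))
}

validate_clinical <- function(clinical) {
  need <- c("sample_id", "os_months", "event")
  miss <- setdiff(need, names(clinical))
  if (length(miss) > 0) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(clinical$sample_id)) {
    stop("duplicated clinical sample id(s): ",
         paste(unique(clinical$sample_id[duplicated(clinical$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(clinical$os_months)) || any(clinical$os_months < 0)) {
    stop("os_months must be present and non-negative", call. = FALSE)
  }
  if (!all(clinical$event %in% c(0L, 1L))) {
    stop("event must be coded 0 (censored) / 1 (death)", call. = FALSE)
  }
  tibble::as_tibble(clinical)
}

#' Write a clinical table to TSV
#' @param clinical Tibble as returned by [read_clinical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical
  names(out)[names(out) == "sample_id"] <- "sample"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Align miRNA, lncRNA and mRNA profiles with clinical data
#'
#' Restricts the three expression layers and the clinical table to the
#' intersection of their sample identifiers, in a single canonical
#' (lexicographic) order, and reports the samples dropped from each input.
#'
#' @param mirna,lncrna,mrna `expr_matrix` objects of the corresponding class.
#' @param clinical A clinical tibble (see [read_clinical()]).
#' @return A `matched_set`: list with elements `mirna`, `lncrna`, `mrna`
#'   (aligned `expr_matrix` objects), `clinical`, `n` (shared sample count) and
#'   `dropped` (named list of dropped sample ids per input).
#' @export
align_matched_set <- function(mirna, lncrna, mrna, clinical) {
  stopifnot(inherits(mirna, "expr_matrix"), inherits(lncrna, "expr_matrix"),
            inherits(mrna, "expr_matrix"))
  clinical <- validate_clinical(clinical)
  ids <- list(mirna = colnames(mirna), lncrna = colnames(lncrna),
              mrna = colnames(mrna), clinical = clinical$sample_id)
  shared <- sort(Reduce(intersect, ids))
  if (length(shared) < 3) {
    stop("fewer than 3 samples shared across the expression layers and clinical table",
         call. = FALSE)
  }
  dropped <- purrr::map(ids, ~ setdiff(.x, shared))
  sub <- function(m) {
    expression_matrix(unclass(m)[, shared, drop = FALSE], molecule_class(m))
  }
  structure(
    list(
      mirna = sub(mirna), lncrna = sub(lncrna), mrna = sub(mrna),
      clinical = clinical[match(shared, clinical$sample_id), , drop = FALSE],
      n = length(shared), dropped = dropped
    ),
    class = "matched_set"
  )
}

#' @export
print.matched_set <- function(x, ...) {
  cat(sprintf(paste0("<matched_set> %d samples\n  miRNA: %d  lncRNA: %d  mRNA: %d",
                     " molecules\n  dropped: %s\n"),
              x$n, nrow(x$mirna), nrow(x$lncrna), nrow(x$mrna),
              paste(sprintf("%s=%d", names(x$dropped), lengths(x$dropped)),
                    collapse = " ")))
  invisible(x)
}

#' Sample identifiers of a matched set
#' @param set A `matched_set`.
#' @return Character vector of shared sample ids, in canonical order.
#' @export
matched_samples <- function(set) colnames(set$mirna)
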