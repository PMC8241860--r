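#' Protein melting data container
#'
#' Holds one protein's thermal proteome profiling measurements: relative
#' solubility at `D` temperatures for two conditions (control, treatment),
#' each with one or more replicates. Missing cells are stored as `NA`, never
#' silently dropped.
#'
#' @param protein_id single string.
#' @param temperatures strictly increasing numeric vector of `D >= 4`
#'   temperatures in degrees Celsius.
#' @param conditions character vector of length 2: `(control, treatment)`
#'   labels, in that order.
#' @param observations list of two numeric matrices (one per condition), each
#'   `n_replicates x D`, of relative solubilities (dimensionless, `>= 0`);
#'   `NA` marks a missing cell.
#' @return An object of class `protein_melting_data` with fields
#'   `protein_id`, `temperatures`, `conditions`, `observations`, `n_reps`.
#' @export
protein_melting_data <- function(protein_id, temperatures, conditions, observations) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L)
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 4L) stop("need at least 4 temperatures")
  if (any(!is.finite(temperatures))) stop("temperatures must be finite")
  if (any(diff(temperatures) <= 0)) stop("temperatures must be strictly increasing")
  if (length(conditions) != 2L || anyDuplicated(conditions))
    stop("conditions must be two distinct labels")
  if (!is.list(observations) || length(observations) != 2L)
    stop("observations must be a list of two matrices (one per condition)")
  observations <- lapply(observations, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != length(temperatures))
      stop("observation matrices must have one column per temperature")
    if (nrow(m) < 1L) stop("at least one replicate per condition")
    storage.mode(m) <- "double"
    bad <- !is.na(m) & (!is.finite(m) | m < 0)
    if (any(bad)) stop("observations must be finite and >= 0 (or NA for missing)")
    m
  })
  names(observations) <- conditions
  structure(
    list(protein_id = protein_id, temperatures = temperatures,
         conditions = as.character(conditions), observations = observations,
         n_reps = vapply(observations, nrow, integer(1))),
    class = "protein_melting_data")
}

#' @export
print.protein_melting_data <- function(x, ...) {
  cat(sprintf("<protein_melting_data> %s: %d temperatures (%.1f-%.1f degC), replicates %s, %d missing cells\n",
              x$protein_id, length(x$temperatures), min(x$temperatures),
              max(x$temperatures), paste(x$n_reps, collapse = "/"),
              n_missing_cells(x)))
  invisible(x)
}

n_missing_cells <- function(protein) {
  sum(vapply(protein$observations, function(m) sum(is.na(m)), numeric(1)))
}

is_complete <- function(protein) n_missing_cells(protein) == 0L

#' TPP dataset container
#'
#' A collection of [protein_melting_data] objects sharing a common temperature
#' grid (unless built with `ragged = TRUE`), plus experiment metadata.
#'
#' @param proteins list of `protein_melting_data` objects with unique ids.
#' @param metadata named list; conventionally `treatment`, `concentration_uM`,
#'   `intact` (TRUE for intact-cell experiments, FALSE for lysate).
#' @param ragged allow proteins to carry different temperature grids.
#' @return an object of class `tpp_dataset`.
#' @export
tpp_dataset <- function(proteins, metadata = list(), ragged = FALSE) {
  ids <- vapply(proteins, function(p) p$protein_id, character(1))
  if (anyDuplicated(ids)) stop("protein_ids must be unique")
  names(proteins) <- ids
  if (!ragged && length(proteins) > 1L) {
    grid <- proteins[[1L]]$temperatures
    same <- vapply(proteins, function(p) identical(p$temperatures, grid), logical(1))
    if (!all(same))
      stop("proteins do not share a common temperature grid (use ragged = TRUE to allow)")
  }
  structure(list(proteins = proteins, metadata = metadata, ragged = ragged),
            class = "tpp_dataset")
}

#' @export
print.tpp_dataset <- function(x, ...) {
  s <- summarize_dataset(x)
  cat(sprintf("<tpp_dataset> %d proteins (%d complete), %d temperatures\n",
              s$n_proteins, s$n_complete_proteins, length(s$temperatures)))
  invisible(x)
}

long_required_cols <- c("protein_id", "condition", "replicate",
                        "temperature_C", "rel_solubility")

#' Read a long-format TPP table
#'
#' The canonical on-disk format: one row per measured cell with columns
#' `protein_id`, `condition`, `replicate`, `temperature_C`, `rel_solubility`.
#' Rows with non-finite solubility are recorded as missing cells; duplicate
#' `(protein, condition, replicate, temperature)` cells are an error, as are
#' more than two condition labels.
#'
#' @param path file path, or a data frame already in long format.
#' @param dialect `"auto"` (by file extension), `"tsv"` or `"csv"`.
#' @param conditions optional length-2 character vector fixing the
#'   (control, treatment) order; defaults to order of first appearance.
#' @param metadata named list stored on the dataset.
#' @return a [tpp_dataset].
#' @export
read_long_table <- function(path, dialect = c("auto", "tsv", "csv"),
                            conditions = NULL, metadata = list()) {
  dialect <- match.arg(dialect)
  df <- if (is.data.frame(path)) path else {
    sep <- if (dialect == "csv" ||
               (dialect == "auto" && grepl("\\.csv$", path, ignore.case = TRUE))) "," else "\t"
    read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  }
  missing_cols <- setdiff(long_required_cols, names(df))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$temperature_C)) {
    suppressWarnings(tc <- as.numeric(df$temperature_C))
    if (any(is.na(tc) & !is.na(df$temperature_C))) stop("non-numeric temperature")
    df$temperature_C <- tc
  }
  cond_levels <- unique(as.character(df$condition))
  if (length(cond_levels) > 2L) stop("more than two conditions: ",
                                     paste(cond_levels, collapse = ", "))
  if (length(cond_levels) < 2L) stop("need exactly two condition labels")
  if (!is.null(conditions)) {
    if (!setequal(conditions, cond_levels))
      stop("supplied condition labels do not match the table")
    cond_levels <- conditions
  }
  key <- paste(df$protein_id, df$condition, df$replicate, df$temperature_C, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate measurement cell: protein %s, condition %s, replicate %s, %.6g degC",
                 dup$protein_id, dup$condition, dup$replicate, dup$temperature_C))
  }
  suppressWarnings(df$rel_solubility <- as.numeric(df$rel_solubility))
  df$rel_solubility[!is.finite(df$rel_solubility)] <- NA_real_

  proteins <- lapply(split(df, df$protein_id), function(d) {
    temps <- sort(unique(d$temperature_C))
    obs <- lapply(cond_levels, function(cc) {
      dc <- d[d$condition == cc, , drop = FALSE]
      reps <- sort(unique(dc$replicate))
      if (length(reps) == 0L)
        stop(sprintf("protein %s has no replicates in condition %s",
                     d$protein_id[1L], cc))
      m <- matrix(NA_real_, nrow = length(reps), ncol = length(temps),
                  dimnames = list(as.character(reps), NULL))
      i <- match(dc$replicate, reps)
      j <- match(dc$temperature_C, temps)
      m[cbind(i, j)] <- dc$rel_solubility
      m
    })
    protein_melting_data(d$protein_id[1L], temps, cond_levels, obs)
  })
  tpp_dataset(unname(proteins), metadata = metadata)
}

#' Read a wide-format TPP table
#'
#' Imports TPP-package-style exports: one row per protein per
#' condition/replicate, with one abundance column per temperature. The
#' `temperature_map` assigns each abundance column its temperature in degrees
#' Celsius; the resulting dataset always reports a sorted temperature grid,
#' permuting observations accordingly.
#'
#' @param path file path or data frame with columns `protein_id`, `condition`,
#'   `replicate` plus abundance columns.
#' @param temperature_map named numeric vector: names are abundance column
#'   names, values their temperatures.
#' @inheritParams read_long_table
#' @return a [tpp_dataset].
#' @export
read_wide_table <- function(path, temperature_map, dialect = c("auto", "tsv", "csv"),
                            conditions = NULL, metadata = list()) {
  dialect <- match.arg(dialect)
  df <- if (is.data.frame(path)) path else {
    sep <- if (dialect == "csv" ||
               (dialect == "auto" && grepl("\\.csv$", path, ignore.case = TRUE))) "," else "\t"
    read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  }
  id_cols <- c("protein_id", "condition", "replicate")
  missing_cols <- setdiff(id_cols, names(df))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  abundance_cols <- setdiff(names(df), id_cols)
  unmapped <- setdiff(abundance_cols, names(temperature_map))
  if (length(unmapped) > 0)
    stop("abundance columns not in temperature_map: ", paste(unmapped, collapse = ", "))
  absent <- setdiff(names(temperature_map), abundance_cols)
  if (length(absent) > 0)
    stop("temperature_map names absent from table: ", paste(absent, collapse = ", "))

  ord <- order(temperature_map)
  cols <- names(temperature_map)[ord]
  long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    data.frame(protein_id = df$protein_id[i], condition = df$condition[i],
               replicate = df$replicate[i],
               temperature_C = unname(temperature_map[ord]),
               rel_solubility = as.numeric(df[i, cols]),
               stringsAsFactors = FALSE)
  }))
  read_long_table(long, conditions = conditions, metadata = metadata)
}

#' Convert a dataset to the canonical long format
#'
#' @param ds a [tpp_dataset].
#' @return data frame with the canonical long columns; missing cells appear
#'   with `NA` solubility.
#' @export
as_long_table <- function(ds) {
  stopifnot(inherits(ds, "tpp_dataset"))
  rows <- lapply(ds$proteins, function(p) {
    do.call(rbind, lapply(p$conditions, function(cc) {
      m <- p$observations[[cc]]
      data.frame(protein_id = p$protein_id, condition = cc,
                 replicate = rep(rownames(m) %||% seq_len(nrow(m)),
                                 times = ncol(m)),
                 temperature_C = rep(p$temperatures, each = nrow(m)),
                 rel_solubility = as.vector(m), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset as a long-format delimited table
#'
#' @param ds a [tpp_dataset].
#' @param path output path; extension `.csv` selects comma separation,
#'   anything else tab.
#' @export
write_long_table <- function(ds, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(as_long_table(ds), path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Summarize a TPP dataset
#'
#' @param ds a [tpp_dataset].
#' @return list with `n_proteins`, `n_complete_proteins` (no missing cells),
#'   `temperatures` (common grid, or NULL if ragged), `conditions` and the
#'   replicate design of the first protein.
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "tpp_dataset"))
  n <- length(ds$proteins)
  complete <- if (n > 0) sum(vapply(ds$proteins, is_complete, logical(1))) else 0L
  list(
    n_proteins = n,
    n_complete_proteins = as.integer(complete),
    temperatures = if (n > 0 && !ds$ragged) ds$proteins[[1L]]$temperatures else NULL,
    conditions = if (n > 0) ds$proteins[[1L]]$conditions else NULL,
    n_reps = if (n > 0) ds$proteins[[1L]]$n_reps else NULL)
}

#' Write / read a results table
#'
#' One row per protein with the NPARC statistics, log marginal likelihoods,
#' posterior model probabilities, model-checking summaries and flags. Floats
#' are written with 6 significant digits.
#'
#' @param results data frame of per-protein results (see [run_analysis()]).
#' @param path output TSV path.
#' @export
write_results <- function(results, path) {
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6L)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
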