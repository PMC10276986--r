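# Delimited-table input/output with row-level validation, and miniature
# on-disk fixtures for tests and documentation.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a per-marker p-value table
#'
#' Reads a delimited text file (comma for `.csv`, tab otherwise) holding
#' one row per tested hypothesis.  Required columns: `marker_id`, `p`;
#' recognized optional columns: `covariate` (strictly positive),
#' `is_causal`, `maf_group`.  Invalid rows fail loudly with their row
#' number.
#'
#' @param path Path to the file.
#' @return A validated tibble.
#' @export
read_pvalue_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_delim(path, delim = delim_for(path),
                           show_col_types = FALSE, progress = FALSE)
  tab <- tibble::as_tibble(as.data.frame(tab))   # drop reader bookkeeping
  validate_pvalue_table(tab)
}

#' @rdname read_pvalue_table
#' @param data A data frame to validate (required columns `marker_id`, `p`).
#' @export
validate_pvalue_table <- function(data) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c("marker_id", "p"), names(data))
  if (length(missing_cols)) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0L) abort("The table must contain at least one row.")
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      abort(sprintf("%s in row(s) %s.", what,
                    paste(head(which(!ok), 5), collapse = ", ")))
    }
  }
  bad_row(!is.na(data$p), "Missing p-value")
  bad_row(data$p >= 0 & data$p <= 1, "p-value outside [0, 1]")
  if (anyDuplicated(data$marker_id)) abort("`marker_id` must be unique.")
  if ("covariate" %in% names(data)) {
    bad_row(!is.na(data$covariate) & is.finite(data$covariate) & data$covariate > 0,
            "Non-positive or missing covariate")
  }
  tibble::as_tibble(data)
}

#' Write a per-marker table
#'
#' Writes the table as delimited text (comma for `.csv`, tab otherwise);
#' the written file round-trips through [read_pvalue_table()].
#'
#' @param data A data frame (e.g. the output of [adjust_markers()]).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_pvalue_table <- function(data, path) {
  stopifnot(is.data.frame(data))
  readr::write_delim(data, path, delim = delim_for(path), progress = FALSE)
  invisible(path)
}

fixture_designs <- list(
  `null-only`     = list(m1 = 0, rho = 0,    trait = "quantitative"),
  `sparse-signal` = list(m1 = 8, rho = 0,    trait = "quantitative"),
  correlated      = list(m1 = 8, rho = 0.75, trait = "quantitative"),
  binary          = list(m1 = 8, rho = 0,    trait = "binary")
)

#' Generate a miniature on-disk study fixture
#'
#' Builds a deterministic toy study (n = 200 individuals, m = 400 markers)
#' of the requested kind and writes it under `dir`: `genotypes.tsv`
#' (individuals x markers), `phenotype.tsv`, `association.tsv` (the scan
#' result with truth columns — a ready-made p-value table), and
#' `design.json` echoing the resolved configuration and seed.
#'
#' @param kind One of `"null-only"`, `"sparse-signal"`, `"correlated"`,
#'   `"binary"`.
#' @param seed Integer seed; the same seed always yields byte-identical
#'   files.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly; the
#'   realized study is attached as attribute `"study"`.
#' @export
make_fixture <- function(kind, seed = 1, dir = tempfile("fixture")) {
  if (!kind %in% names(fixture_designs)) {
    abort(sprintf("Unknown fixture kind '%s'; use one of: %s.", kind,
                  paste(names(fixture_designs), collapse = ", ")))
  }
  cfg <- fixture_designs[[kind]]
  design <- simulation_design(n = 200, m = 400, m1 = cfg$m1, rho = cfg$rho,
                              trait = cfg$trait, seed = seed)
  study <- simulate_study(design)
  scan <- suppressWarnings(scan_study(study))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    association = file.path(dir, "association.tsv"),
    design = file.path(dir, "design.json")
  )
  readr::write_tsv(tibble::as_tibble(study$G), paths[["genotypes"]],
                   progress = FALSE)
  readr::write_tsv(tibble::tibble(individual = seq_along(study$y),
                                  y = as.numeric(study$y)),
                   paths[["phenotype"]], progress = FALSE)
  write_pvalue_table(scan, paths[["association"]])
  jsonlite::write_json(
    c(list(kind = kind), unclass(design)),
    paths[["design"]], auto_unbox = TRUE, null = "null", digits = NA
  )
  attr(paths, "study") <- study
  invisible(paths)
}
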