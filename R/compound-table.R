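#' Read a compound table from delimited text
#'
#' A compound table has one row per substrate with columns `id`, `smiles`,
#' at least one numeric response column (`rate_q` / `rate_r` for the packaged
#' PON1 data, or any user-named rate column), and optionally `name` and
#' logical test-set flags `is_test_q` / `is_test_r`. Row order is preserved:
#' it is the canonical compound order for every downstream matrix.
#'
#' @param path Path to a UTF-8 delimited text file with a header row.
#' @param delim Field delimiter; comma by default, tab accepted.
#' @param validate_structures If `TRUE` (default), every SMILES is checked to
#'   parse as a single connected molecule with at least 3 heavy atoms (via
#'   OpenBabel when available, otherwise a syntactic heavy-atom count).
#' @return A tibble of class `pon1_compounds` with one row per compound.
#' @export
#' @examples
#' tbl <- pon1_dataset()
#' nrow(tbl) # 30
read_compound_table <- function(path, delim = ",", validate_structures = TRUE) {
  if (!file.exists(path)) abort(paste0("Compound table not found: ", path))
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_compound_table(tbl, validate_structures = validate_structures)
}

#' Validate a compound table
#'
#' Enforces the compound-table contract: unique non-missing ids, parseable
#' structures, strictly positive rates (the response is modelled on the log
#' scale, so zero or negative rates are rejected at the door).
#'
#' @param tbl A data frame with at least `id` and `smiles` columns.
#' @inheritParams read_compound_table
#' @return The table as a validated `pon1_compounds` tibble.
#' @export
validate_compound_table <- function(tbl, validate_structures = TRUE) {
  tbl <- as_tibble(tbl)
  required <- c("id", "smiles")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("Compound table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tbl) == 0) abort("empty dataset: table has a header but no rows")
  rate_cols <- grep("^rate", names(tbl), value = TRUE)
  if (length(rate_cols) == 0) {
    abort("Compound table needs at least one response column named rate*")
  }
  if (anyNA(tbl$id) || any(tbl$id == "")) {
    abort(paste0("Missing id in row(s): ",
                 paste(which(is.na(tbl$id) | tbl$id == ""), collapse = ", ")))
  }
  dup <- tbl$id[duplicated(tbl$id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate compound id(s): ", paste(unique(dup), collapse = ", ")))
  }
  for (rc in rate_cols) {
    bad <- which(!is.finite(tbl[[rc]]) | tbl[[rc]] <= 0)
    if (length(bad) > 0) {
      abort(paste0("Non-positive or missing ", rc, " for compound(s): ",
                   paste(tbl$id[bad], collapse = ", "),
                   " (rates must be > 0; the response is log-transformed)"))
    }
  }
  if (validate_structures) check_structures(tbl$id, tbl$smiles)
  for (fc in grep("^is_test", names(tbl), value = TRUE)) {
    tbl[[fc]] <- as.logical(tbl[[fc]])
    if (anyNA(tbl[[fc]])) abort(paste0("Column ", fc, " must be TRUE/FALSE"))
  }
  class(tbl) <- c("pon1_compounds", class(tbl))
  tbl
}

# Structure validation. Heavy atoms are counted syntactically from the SMILES
# (organic-subset symbols and bracket atoms); full parse validity is checked
# through OpenBabel when the binary is present, naming the offending compound.
check_structures <- function(ids, smiles) {
  bad_na <- which(is.na(smiles) | smiles == "")
  if (length(bad_na) > 0) {
    abort(paste0("Missing structure for compound(s): ",
                 paste(ids[bad_na], collapse = ", ")))
  }
  heavy <- vapply(smiles, count_heavy_atoms, integer(1))
  small <- which(heavy < 3L)
  if (length(small) > 0) {
    abort(paste0("Structure with fewer than 3 heavy atoms for compound(s): ",
                 paste(ids[small], collapse = ", ")))
  }
  if (has_openbabel()) {
    ok <- obabel_valid(smiles)
    if (!all(ok)) {
      abort(paste0("Unparseable structure string for compound(s): ",
                   paste(ids[!ok], collapse = ", ")))
    }
  }
  invisible(TRUE)
}

# Heavy (non-hydrogen) atom count from a SMILES string: bracket atoms other
# than [H...], plus bare organic-subset symbols outside brackets.
count_heavy_atoms <- function(smi) {
  brackets <- gregexpr("\\[[^]]*\\]", smi)[[1]]
  n_bracket <- 0L
  if (brackets[1] != -1) {
    toks <- regmatches(smi, gregexpr("\\[[^]]*\\]", smi))[[1]]
    n_bracket <- sum(!grepl("^\\[[0-9]*H[^a-z]", toks))
    smi <- gsub("\\[[^]]*\\]", "", smi)
  }
  bare <- gregexpr("Cl|Br|[BCNOPSFI]|[cnops]", smi)[[1]]
  n_bare <- if (bare[1] == -1) 0L else length(bare)
  n_bracket + n_bare
}

has_openbabel <- function() nzchar(Sys.which("obabel"))

# Batch-validate SMILES by round-tripping each through obabel individually
# only for rows that fail in the batch pass (the common case is all-valid,
# which costs a single subprocess).
obabel_valid <- function(smiles) {
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), infile)
  out <- suppressWarnings(system2("obabel",
    c("-ismi", infile, "-osmi"), stdout = TRUE, stderr = FALSE))
  titles <- sub("^\\S+\\s+", "", out)
  seq_along(smiles) %in% suppressWarnings(as.integer(titles))
}

#' Write a compound table to delimited text
#'
#' Inverse of [read_compound_table()]: a written table re-loads
#' field-for-field (logical flags included).
#'
#' @param tbl A compound table (tibble or data frame).
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(tbl, path, delim = ",") {
  readr::write_delim(as_tibble(as.data.frame(tbl)), path, delim = delim)
  invisible(path)
}

#' The packaged PON1 substrate dataset
#'
#' Thirty substrates of the paraoxonase-1 Q192/R192 isozymes — lactones and
#' thiolactones of varying ring size and substitution, phenyl acetate (the
#' reference aryl ester, rate 100 for both isozymes) and five
#' organophosphates — with their relative hydrolysis rates at 1 mM substrate.
#' Rates are dimensionless, relative to phenyl acetate = 100. The SMILES are
#' curated from the compound names (the original report gives structures only
#' as drawings); stereocenters named in the compound names are encoded
#' explicitly. `is_test_q` / `is_test_r` reproduce the test-set markings of
#' the source table verbatim: 6 compounds for Q but only 5 for R, which does
#' not match the 1-in-5 ordered split rule — [ordered_split()] is the
#' normative rule when re-deriving splits.
#'
#' @param validate_structures Passed to [validate_compound_table()].
#' @return A 30-row `pon1_compounds` tibble with columns `id`, `name`,
#'   `smiles`, `rate_q`, `rate_r`, `is_test_q`, `is_test_r`.
#' @export
#' @examples
#' pon1 <- pon1_dataset()
#' dplyr::filter(pon1, id == "phenyl_acetate")$rate_q # 100
pon1_dataset <- function(validate_structures = FALSE) {
  path <- system.file("extdata", "pon1_table1.csv", package = "pon1qsar",
                      mustWork = TRUE)
  read_compound_table(path, validate_structures = validate_structures)
}

#' Log-transformed response vector for one isozyme
#'
#' The modelled response is the base-10 logarithm of the relative hydrolysis
#' rate, so the reference compound (phenyl acetate, rate 100) maps to exactly
#' 2. Base 10 is the QSAR convention; use `base` to override.
#'
#' @param tbl A compound table with a `rate_q` / `rate_r` (or `rate_<label>`)
#'   column.
#' @param isozyme `"Q"` or `"R"` (case-insensitive), or the suffix of a user
#'   rate column.
#' @param base Logarithm base, default 10.
#' @return Numeric vector of log responses, one per row of `tbl`.
#' @export
#' @examples
#' log_response(pon1_dataset(), "Q")[1] # 2: phenyl acetate, rate 100
log_response <- function(tbl, isozyme = c("Q", "R"), base = 10) {
  if (length(isozyme) == 1 && !toupper(isozyme) %in% c("Q", "R")) {
    col <- paste0("rate_", isozyme)
  } else {
    isozyme <- match.arg(toupper(isozyme[1]), c("Q", "R"))
    col <- paste0("rate_", tolower(isozyme))
  }
  if (!col %in% names(tbl)) {
    abort(paste0("No response column `", col, "` in the compound table"))
  }
  rate <- tbl[[col]]
  if (any(!is.finite(rate) | rate <= 0)) {
    bad <- which(!is.finite(rate) | rate <= 0)
    lab <- if ("id" %in% names(tbl)) tbl$id[bad] else bad
    abort(paste0("Rate must be > 0 to take logs; offending compound(s): ",
                 paste(lab, collapse = ", ")))
  }
  log(rate, base = base)
}

#' Name of the log-response for an isozyme
#' @param isozyme `"Q"` or `"R"`.
#' @return A label such as `"log_rate_q"`.
#' @export
response_name <- function(isozyme = c("Q", "R")) {
  isozyme <- match.arg(toupper(isozyme[1]), c("Q", "R"))
  paste0("log_rate_", tolower(isozyme))
}
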